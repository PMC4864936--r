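## Seeded random scaffold-graph generators. These emulate the graphs the
## scaffolder sees after edge bundling: a linear layout of unique contigs
## (possibly with repeat contigs collapsed into the gaps), concordant
## adjacency and skip edges derived from the layout, and a few corrupted
## unique-unique edges standing in for mis-mapping noise.

.layout_edges <- function(layout, sd_range, support_range) {
  ## concordant edge between consecutive layout instances
  n <- nrow(layout)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    g <- layout$start[i + 1L] - layout$end[i]
    s <- sample(sd_range[1]:sd_range[2], 1)
    out <- rbind(out, data.frame(
      c1 = layout$contig[i], o1 = layout$orient[i],
      c2 = layout$contig[i + 1L], o2 = layout$orient[i + 1L],
      gap = g + round(stats::rnorm(1, 0, s / 3)),
      sd = s, support = sample(support_range[1]:support_range[2], 1),
      stringsAsFactors = FALSE))
  }
  out
}

#' Random scaffold graph with a planted layout
#'
#' Generates a small scaffold graph from a planted linear layout: 3-7
#' unique contigs in random orientations, up to `n_repeats` repeat contigs
#' with 1-2 copies collapsed into gaps between unique neighbours, concordant
#' adjacency/skip/repeat-flank edges derived from the true geometry, and
#' 0-2 corrupted unique-unique edges with random constraints. At most 12
#' edges are kept. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param max_unique,max_repeats caps on unique and repeat contig counts.
#' @return list with `graph` (a [scaffold_graph()]) and `truth` (the planted
#'   placement data.frame).
#' @export
random_scaffold_graph <- function(seed, max_unique = 7, max_repeats = 2) {
  set.seed(seed)
  n_u <- sample(3:max_unique, 1)
  n_r <- if (max_repeats > 0) sample(0:max_repeats, 1) else 0
  uid <- sprintf("u%02d", seq_len(n_u))
  rid <- if (n_r) sprintf("r%02d", seq_len(n_r)) else character()
  ulen <- sample(2000:8000, n_u, replace = TRUE)
  rlen <- if (n_r) sample(600:1500, n_r, replace = TRUE) else integer()
  contigs <- data.frame(
    id = c(uid, rid), length = c(ulen, rlen),
    coverage = c(rep(40, n_u), rep(100, max(n_r, 0))),
    class = c(rep("unique", n_u), rep("repeat", n_r)),
    stringsAsFactors = FALSE)

  ## assign repeat copies to distinct junctions between unique neighbours
  junctions <- seq_len(n_u - 1L)
  copies <- list()
  if (n_r) {
    for (r in seq_len(n_r)) {
      ncp <- sample(1:2, 1)
      free <- setdiff(junctions, vapply(copies, `[[`, 1, "junction"))
      ncp <- min(ncp, length(free))
      if (!ncp) next
      for (j in sample(free, ncp)) {
        copies <- c(copies, list(list(junction = j, contig = rid[r],
                                      orient = sample(c("+", "-"), 1))))
      }
    }
  }

  ## build the planted layout left to right
  layout <- NULL
  pos <- 0
  for (i in seq_len(n_u)) {
    layout <- rbind(layout, data.frame(
      contig = uid[i], orient = sample(c("+", "-"), 1),
      start = pos, end = pos + ulen[i], stringsAsFactors = FALSE))
    pos <- pos + ulen[i]
    if (i < n_u) {
      cp <- Filter(function(x) x$junction == i, copies)
      if (length(cp)) {
        cp <- cp[[1]]
        gl <- sample(200:900, 1)
        rl <- rlen[match(cp$contig, rid)]
        layout <- rbind(layout, data.frame(
          contig = cp$contig, orient = cp$orient,
          start = pos + gl, end = pos + gl + rl, stringsAsFactors = FALSE))
        pos <- pos + gl + rl + sample(200:900, 1)
      } else {
        pos <- pos + sample(200:1500, 1)
      }
    }
  }

  ## edges implied by the layout: a spanning unique-unique edge for every
  ## consecutive unique pair (mate pairs span collapsed repeats), plus the
  ## two flank edges of every repeat copy
  is_u <- layout$contig %in% uid
  upos <- which(is_u)
  edges <- NULL
  mk_edge <- function(i, j, sd_rng, sup_rng) {
    s <- sample(sd_rng[1]:sd_rng[2], 1)
    data.frame(
      c1 = layout$contig[i], o1 = layout$orient[i],
      c2 = layout$contig[j], o2 = layout$orient[j],
      gap = layout$start[j] - layout$end[i] + round(stats::rnorm(1, 0, s / 3)),
      sd = s, support = sample(sup_rng[1]:sup_rng[2], 1),
      stringsAsFactors = FALSE)
  }
  for (h in seq_len(length(upos) - 1L)) {
    i <- upos[h]; j <- upos[h + 1L]
    edges <- rbind(edges, mk_edge(i, j, c(150, 350), c(5, 20)))
    if (j > i + 1L) {  # a repeat copy sits in this junction
      edges <- rbind(edges, mk_edge(i, i + 1L, c(100, 250), c(5, 15)))
      edges <- rbind(edges, mk_edge(i + 1L, j, c(100, 250), c(5, 15)))
    }
  }
  ## skip edges over one unique contig
  n_skip <- sample(0:2, 1)
  if (n_skip && length(upos) > 2) {
    for (h in sample(seq_len(length(upos) - 2L),
                     min(n_skip, length(upos) - 2L))) {
      edges <- rbind(edges, mk_edge(upos[h], upos[h + 2L], c(200, 400), c(5, 12)))
    }
  }
  ## corrupted unique-unique edges: random endpoints and constraints
  n_bad <- sample(0:2, 1)
  for (b in seq_len(n_bad)) {
    pr <- sample(uid, 2)
    edges <- rbind(edges, data.frame(
      c1 = pr[1], o1 = sample(c("+", "-"), 1),
      c2 = pr[2], o2 = sample(c("+", "-"), 1),
      gap = sample(0:8000, 1), sd = sample(100:200, 1),
      support = sample(5:8, 1), stringsAsFactors = FALSE))
  }
  if (nrow(edges) > 12) edges <- edges[seq_len(12), , drop = FALSE]
  list(graph = scaffold_graph(contigs, edges), truth = layout)
}

#' Random scaffold graph with planted border contigs
#'
#' Generates a chain of 2-3 segments of unique contigs joined by long
#' border contigs (40 kbp, far beyond any edge's concordance reach), with
#' concordant chain edges throughout and 0-2 corrupted edges confined to
#' single segments. Used to check that fenced-subgraph decomposition plus
#' stitching preserves the whole-graph optimum.
#'
#' @param seed integer seed.
#' @return list with `graph`, `truth`, and `span_bound` (the library span
#'   bound L to use for border detection).
#' @export
random_fenced_graph <- function(seed) {
  set.seed(seed)
  n_seg <- sample(2:3, 1)
  seg_sizes <- sample(2:3, n_seg, replace = TRUE)
  ids <- character(); lens <- integer()
  layout <- NULL; pos <- 0
  borders <- character()
  ctr <- 0L
  for (s in seq_len(n_seg)) {
    for (i in seq_len(seg_sizes[s])) {
      ctr <- ctr + 1L
      id <- sprintf("c%02d", ctr)
      len <- sample(2000:8000, 1)
      ids <- c(ids, id); lens <- c(lens, len)
      layout <- rbind(layout, data.frame(
        contig = id, orient = sample(c("+", "-"), 1),
        start = pos, end = pos + len, stringsAsFactors = FALSE))
      pos <- pos + len + sample(200:1500, 1)
    }
    if (s < n_seg) {
      ctr <- ctr + 1L
      id <- sprintf("c%02d", ctr)
      ids <- c(ids, id); lens <- c(lens, 40000L)
      borders <- c(borders, id)
      layout <- rbind(layout, data.frame(
        contig = id, orient = sample(c("+", "-"), 1),
        start = pos, end = pos + 40000, stringsAsFactors = FALSE))
      pos <- pos + 40000 + sample(200:1500, 1)
    }
  }
  contigs <- data.frame(id = ids, length = lens, coverage = 40,
                        class = "unique", stringsAsFactors = FALSE)
  edges <- .layout_edges(layout, c(100, 300), c(5, 20))
  ## corrupted edges within one segment (never across a border)
  seg_of <- cumsum(layout$contig %in% borders)
  n_bad <- sample(0:2, 1)
  for (b in seq_len(n_bad)) {
    sgs <- which(tabulate(seg_of + 1L) >= 2) - 1L
    sg <- sample(rep(sgs, 2), 1)
    members <- layout$contig[seg_of == sg & !(layout$contig %in% borders)]
    if (length(members) < 2) next
    pr <- sample(members, 2)
    edges <- rbind(edges, data.frame(
      c1 = pr[1], o1 = sample(c("+", "-"), 1),
      c2 = pr[2], o2 = sample(c("+", "-"), 1),
      gap = sample(0:8000, 1), sd = sample(100:200, 1),
      support = sample(5:8, 1), stringsAsFactors = FALSE))
  }
  list(graph = scaffold_graph(contigs, edges), truth = layout,
       span_bound = 16000)
}
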