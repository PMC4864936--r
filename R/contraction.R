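## Graph contraction: fenced subgraphs anchored at border contigs.
##
## A border contig is a unique contig at least as long as the largest
## library span bound L, so no concordant edge can span it in a valid
## scaffold. Removing borders splits the unique-contig graph into
## components; each component plus its adjacent borders (plus repeat
## contigs with edges into it) is a fenced subgraph that can be searched
## independently without losing global optimality, and per-subgraph
## scaffolds are stitched back together at shared borders.

#' Identify border contigs
#'
#' @param graph a [scaffold_graph()].
#' @param span_bound the largest library span bound L (bp), e.g.
#'   `max(mu + 6*sigma)` over the libraries in the current stage.
#' @return character vector of border contig ids (unique contigs with
#'   `length >= span_bound`).
#' @export
find_border_contigs <- function(graph, span_bound) {
  ct <- graph$contigs
  ct$id[ct$class == "unique" & ct$length >= span_bound]
}

#' Decompose a scaffold graph into fenced subgraphs
#'
#' Connected components of the unique-contig graph minus borders are closed
#' by their adjacent border contigs and augmented with every repeat contig
#' linked to a member. A border shared by two components belongs to both
#' subgraphs (one per side). Repeat-repeat edges are excluded throughout.
#'
#' @param graph a [scaffold_graph()].
#' @param borders character vector from [find_border_contigs()].
#' @return list of `scaffold_graph` subgraphs, ordered by their smallest
#'   member contig id; isolated borders (no non-border neighbours) form
#'   their own singleton subgraphs.
#' @export
decompose_graph <- function(graph, borders = character()) {
  ct <- graph$contigs
  e <- .scorable_edges(graph)
  uniq <- ct$id[ct$class == "unique"]
  core <- setdiff(uniq, borders)
  ## union-find over core unique contigs via unique-unique edges
  comp <- stats::setNames(seq_along(core), core)
  uu <- e[e$c1 %in% core & e$c2 %in% core, , drop = FALSE]
  if (nrow(uu)) for (i in seq_len(nrow(uu))) {
    a <- comp[[uu$c1[i]]]; b <- comp[[uu$c2[i]]]
    if (a != b) comp[comp == b] <- a
  }
  groups <- split(names(comp), comp)
  subgraphs <- list()
  used_borders <- character()
  covered <- integer()  # edge ids already assigned to a subgraph
  for (grp in groups) {
    adj_border <- unique(c(
      e$c2[e$c1 %in% grp & e$c2 %in% borders],
      e$c1[e$c2 %in% grp & e$c1 %in% borders]))
    members <- c(grp, adj_border)
    reps <- unique(c(e$c2[e$c1 %in% members], e$c1[e$c2 %in% members]))
    reps <- reps[reps %in% ct$id[ct$class == "repeat"]]
    sel <- unique(c(members, reps))
    sub_e <- e[e$c1 %in% sel & e$c2 %in% sel, , drop = FALSE]
    ## drop border-border edges that belong to no interior component
    g <- list(contigs = ct[match(sel, ct$id), , drop = FALSE], edges = sub_e)
    class(g) <- "scaffold_graph"
    subgraphs <- c(subgraphs, list(g))
    used_borders <- c(used_borders, adj_border)
    covered <- c(covered, sub_e$id)
  }
  ## border-border edges not already inside a component subgraph
  ## (adjacent borders flanking an empty junction), and isolated borders
  bb <- e[e$c1 %in% borders & e$c2 %in% borders &
            !(e$id %in% covered), , drop = FALSE]
  rep_ids <- ct$id[ct$class == "repeat"]
  if (nrow(bb)) for (i in seq_len(nrow(bb))) {
    members <- c(bb$c1[i], bb$c2[i])
    reps <- unique(c(e$c2[e$c1 %in% members], e$c1[e$c2 %in% members]))
    sel <- c(members, reps[reps %in% rep_ids])
    sub_e <- e[e$c1 %in% sel & e$c2 %in% sel &
                 !(e$c1 %in% borders & e$c2 %in% borders &
                     e$id != bb$id[i]), , drop = FALSE]
    g <- list(contigs = ct[match(sel, ct$id), , drop = FALSE], edges = sub_e)
    class(g) <- "scaffold_graph"
    subgraphs <- c(subgraphs, list(g))
    used_borders <- c(used_borders, members)
  }
  for (b in setdiff(borders, used_borders)) {
    g <- list(contigs = ct[match(b, ct$id), , drop = FALSE],
              edges = e[0, , drop = FALSE])
    class(g) <- "scaffold_graph"
    subgraphs <- c(subgraphs, list(g))
  }
  ord <- order(vapply(subgraphs, function(g) min(g$contigs$id), character(1)))
  subgraphs[ord]
}

.reverse_placement <- function(pl) {
  n <- nrow(pl)
  span_end <- max(pl$end)
  out <- pl[rev(seq_len(n)), , drop = FALSE]
  out$orient <- .flip(out$orient)
  s <- span_end - out$end
  e2 <- span_end - out$start
  out$start <- s; out$end <- e2
  rownames(out) <- NULL
  out
}

#' Stitch per-subgraph scaffolds at shared border contigs
#'
#' Scaffolds that share a border contig are concatenated at it; the
#' later scaffold (by list position) is reversed when needed so the two
#' copies of the border agree in orientation. A shared border must be
#' terminal in both scaffolds.
#'
#' @param scaffolds list of placement data.frames (`contig`, `orient`,
#'   `start`, `end`).
#' @param borders character vector of border contig ids.
#' @param repeats character vector of repeat contig ids: repeat instances
#'   placed beyond a shared border (they belong to the neighbouring
#'   subgraph, which places them authoritatively) are trimmed before
#'   joining.
#' @return list of stitched placement data.frames.
#' @export
stitch_scaffolds <- function(scaffolds, borders = character(),
                             repeats = character()) {
  if (length(scaffolds) <= 1L || !length(borders)) return(scaffolds)
  trim_past_border <- function(s, b) {
    pos <- which(s$contig == b)[1]
    if (pos > nrow(s) / 2) {
      if (pos < nrow(s)) s <- s[seq_len(pos), , drop = FALSE]
    } else {
      if (pos > 1L) s <- s[pos:nrow(s), , drop = FALSE]
    }
    rownames(s) <- NULL
    s
  }
  scafs <- scaffolds
  repeat {
    joined <- FALSE
    for (b in borders) {
      holders <- which(vapply(scafs, function(s) b %in% s$contig, logical(1)))
      if (length(holders) < 2L) next
      i <- holders[1]; j <- holders[2]
      si <- scafs[[i]]; sj <- scafs[[j]]
      pos_i <- which(si$contig == b); pos_j <- which(sj$contig == b)
      interior_unique <- function(s, pos) {
        beyond <- if (pos > nrow(s) / 2) seq(pos + 1L, length.out = nrow(s) - pos)
                  else seq_len(pos - 1L)
        any(!s$contig[beyond] %in% repeats)
      }
      if (length(pos_i) != 1L || length(pos_j) != 1L ||
          interior_unique(si, pos_i) || interior_unique(sj, pos_j))
        stop("border contig '", b, "' is interior to a subgraph scaffold")
      si <- trim_past_border(si, b)
      sj <- trim_past_border(sj, b)
      ## orient scaffold i so b is at its right end
      if (which(si$contig == b) == 1L && nrow(si) > 1L)
        si <- .reverse_placement(si)
      ## orient scaffold j so b is at its left end, matching orientation
      if (which(sj$contig == b) == nrow(sj) && nrow(sj) > 1L)
        sj <- .reverse_placement(sj)
      ob_i <- si$orient[nrow(si)]
      if (sj$orient[which(sj$contig == b)[1]] != ob_i)
        sj <- .reverse_placement(sj)
      if (sj$contig[1] != b || sj$orient[1] != ob_i)
        stop("cannot reconcile border orientation for '", b, "'")
      ## append sj (minus its border copy) after si, preserving sj's
      ## internal offsets relative to the border
      shift <- si$start[nrow(si)] - sj$start[1]
      sj2 <- sj[-1, , drop = FALSE]
      if (nrow(sj2)) {
        sj2$start <- sj2$start + shift
        sj2$end <- sj2$end + shift
        si <- rbind(si, sj2)
      }
      rownames(si) <- NULL
      scafs[[i]] <- si
      scafs[[j]] <- NULL
      joined <- TRUE
      break
    }
    if (!joined) return(scafs)
  }
}
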