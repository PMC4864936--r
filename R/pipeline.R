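## End-to-end scaffolding pipeline: library estimation, graph construction,
## contraction, exact search, stitching and gap re-sizing.

#' Build a scaffold graph from contigs and read mappings
#'
#' Estimates per-library parameters, classifies repeats by coverage,
#' bundles pairs into edges with truncation-corrected gap estimates, merges
#' edges across libraries and applies the contig-size and edge-support
#' filters.
#'
#' @param contigs contig data.frame (`id`, `length`, optional `coverage`).
#' @param mappings mapping data.frame with a `lib` column (all libraries).
#' @param config a [scafex_config()].
#' @param libraries optional pre-estimated list of `mate_library` objects
#'   (estimated from the mappings when `NULL`).
#' @return list with `graph` (filtered [scaffold_graph()]), `libraries`,
#'   `singletons` (contig ids excluded by the size filter), and
#'   `span_bound` (max library L).
#' @export
build_scaffold_graph <- function(contigs, mappings,
                                 config = scafex_config(),
                                 libraries = NULL) {
  libs <- unique(mappings$lib)
  if (is.null(libraries)) {
    libraries <- lapply(libs, function(l)
      estimate_library(mappings[mappings$lib == l, , drop = FALSE],
                       contigs, id = l, config = config))
    names(libraries) <- libs
  }
  cls <- classify_contigs(contigs, mappings, factor = config$repeat_factor)
  contigs <- cls$contigs
  edges <- NULL
  for (l in libs) {
    lb <- libraries[[l]]
    model <- insert_model(lb, bucket = config$lookup_bucket)
    raw <- bundle_pairs(lb, mappings[mappings$lib == l, , drop = FALSE],
                        contigs)
    if (!nrow(raw)) next
    for (i in seq_len(nrow(raw))) {
      est <- estimate_edge_gap(raw$shat[[i]], raw$l[i], model,
                               sigma = lb$sigma)
      edges <- rbind(edges, data.frame(
        c1 = raw$c1[i], o1 = raw$o1[i], c2 = raw$c2[i], o2 = raw$o2[i],
        gap = est$gap, sd = est$sd, support = raw$support[i], lib = l,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(edges))
    edges <- merge_libraries(edges, contigs, config)
  graph <- scaffold_graph(contigs, edges)
  filt <- apply_filters(graph, config)
  list(graph = filt$graph, libraries = libraries,
       singletons = filt$singletons,
       span_bound = max(vapply(libraries, `[[`, numeric(1), "L")))
}

#' Scaffold contigs from read mappings
#'
#' The full pipeline: graph construction ([build_scaffold_graph()]),
#' fenced-subgraph decomposition at border contigs, per-subgraph exact
#' search, stitching at shared borders, and maximum-likelihood gap
#' re-sizing. Libraries can optionally be combined in insert-size stages,
#' each stage consuming the previous stage's scaffolds as units.
#'
#' @inheritParams build_scaffold_graph
#' @return object of class `scafex_result`: list with `scaffolds` (named
#'   list of placement data.frames, singletons included), `k` (total
#'   discordant edges), `graph`, `libraries`, `flagged` (ids of
#'   hybrid-fallback scaffolds), `n_states`.
#' @export
scaffold_pipeline <- function(contigs, mappings, config = scafex_config(),
                              libraries = NULL) {
  if (isTRUE(config$staged)) {
    return(.staged_pipeline(contigs, mappings, config))
  }
  gb <- build_scaffold_graph(contigs, mappings, config, libraries)
  res <- .scaffold_graph_run(gb$graph, gb$span_bound, config)
  singles <- c(gb$singletons, res$unplaced)
  scaffolds <- res$scaffolds
  for (s in singles) {
    len <- contigs$length[match(s, contigs$id)]
    scaffolds <- c(scaffolds, list(
      data.frame(contig = s, orient = "+", start = 0, end = len,
                 stringsAsFactors = FALSE)))
  }
  names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  structure(list(scaffolds = scaffolds, k = res$k, graph = gb$graph,
                 libraries = gb$libraries,
                 flagged = names(scaffolds)[seq_along(res$flagged)][res$flagged],
                 n_states = res$n_states),
            class = "scafex_result")
}

## Search + stitch + gap re-sizing on a built graph.
.scaffold_graph_run <- function(graph, span_bound, config) {
  if (is.na(config$gap_max)) config$gap_max <- span_bound
  borders <- find_border_contigs(graph, span_bound)
  subs <- decompose_graph(graph, borders)
  if (!length(subs)) subs <- list(graph)
  scaffolds <- list(); flagged <- logical(); unplaced <- character()
  n_states <- 0L
  for (sg in subs) {
    r <- scaffold_subgraph(sg, config)
    scaffolds <- c(scaffolds, r$scaffolds)
    flagged <- c(flagged, rep(r$flagged, length(r$scaffolds)))
    unplaced <- c(unplaced, r$unplaced)
    n_states <- n_states + r$n_states
  }
  stitched <- stitch_scaffolds(
    scaffolds, borders,
    repeats = graph$contigs$id[graph$contigs$class == "repeat"])
  ## flags: a stitched scaffold is flagged if any constituent was
  flag2 <- vapply(stitched, function(sc) {
    any(vapply(seq_along(scaffolds), function(i)
      flagged[i] && any(scaffolds[[i]]$contig %in% sc$contig), logical(1)))
  }, logical(1))
  stitched <- lapply(stitched, resize_gaps, graph = graph, config = config)
  ## final discordance: edges satisfied by no scaffold (repeat edges shared
  ## between subgraphs are counted once here)
  k <- count_discordant_scaffolds(graph, stitched, config)
  placed <- unlist(lapply(stitched, `[[`, "contig"))
  unplaced <- setdiff(unique(unplaced), placed)
  ## unique contigs never placed (empty decomposition corner cases)
  missing <- setdiff(graph$contigs$id[graph$contigs$class == "unique"], placed)
  unplaced <- c(unplaced, missing)
  list(scaffolds = stitched, flagged = flag2, unplaced = unplaced, k = k,
       n_states = n_states)
}

## Staged multi-library scaffolding: run each insert-size stage in turn,
## collapsing the previous stage's scaffolds into super-contigs and
## projecting the next stage's mappings onto them.
.staged_pipeline <- function(contigs, mappings, config) {
  libs <- unique(mappings$lib)
  libraries <- lapply(libs, function(l)
    estimate_library(mappings[mappings$lib == l, , drop = FALSE],
                     contigs, id = l, config = config))
  names(libraries) <- libs
  stages <- stage_libraries(libraries, config$stage_boundaries)
  cfg1 <- config; cfg1$staged <- FALSE
  cur_contigs <- contigs
  cur_map <- list()  # contig -> member placement in original coordinates
  for (st in seq_along(stages)) {
    ids <- vapply(stages[[st]], `[[`, character(1), "id")
    mp <- mappings[mappings$lib %in% ids, , drop = FALSE]
    if (st > 1L) mp <- .project_mappings(mp, cur_map, cur_contigs)
    res <- scaffold_pipeline(cur_contigs, mp, cfg1,
                             libraries = stages[[st]])
    expanded <- lapply(res$scaffolds, .expand_placement, members = cur_map)
    if (st == length(stages)) {
      names(expanded) <- names(res$scaffolds)
      res$scaffolds <- expanded
      res$libraries <- libraries
      return(res)
    }
    ## next round: scaffolds become super-contigs
    cur_map <- list()
    new_ct <- NULL
    for (si in seq_along(expanded)) {
      sid <- sprintf("S%d_%d", st, si)
      sc <- expanded[[si]]
      sc$start <- sc$start - min(sc$start)
      sc$end <- sc$end - min(sc$start)
      cur_map[[sid]] <- sc
      orig <- contigs[match(sc$contig, contigs$id), , drop = FALSE]
      new_ct <- rbind(new_ct, data.frame(
        id = sid, length = max(sc$end) - min(sc$start),
        coverage = sum(orig$coverage * orig$length) / sum(orig$length),
        stringsAsFactors = FALSE))
    }
    cur_contigs <- new_ct
  }
}

## Project mappings from member contigs into super-contig coordinates.
.project_mappings <- function(mappings, members, super_contigs) {
  if (!length(members)) return(mappings)
  ## index: contig id -> (super id, offset, orient, member length);
  ## contigs appearing more than once (placed repeats) are ambiguous and
  ## their mappings are dropped for later stages
  idx <- list()
  multi <- character()
  for (sid in names(members)) {
    sc <- members[[sid]]
    for (t in seq_len(nrow(sc))) {
      cid <- sc$contig[t]
      if (!is.null(idx[[cid]])) { multi <- c(multi, cid); next }
      idx[[cid]] <- list(sid = sid, off = sc$start[t],
                         orient = sc$orient[t],
                         len = sc$end[t] - sc$start[t])
    }
  }
  keep <- !(mappings$contig %in% multi) &
    mappings$contig %in% names(idx)
  m <- mappings[keep, , drop = FALSE]
  if (nrow(m)) for (r in seq_len(nrow(m))) {
    h <- idx[[m$contig[r]]]
    if (h$orient == "+") {
      m$pos[r] <- h$off + m$pos[r]
    } else {
      m$pos[r] <- h$off + (h$len - m$pos[r] - m$rlen[r])
      m$strand[r] <- if (m$strand[r] == "+") "-" else "+"
    }
    m$contig[r] <- h$sid
  }
  ## mappings to contigs outside any super-contig pass through
  rest <- mappings[!keep & !(mappings$contig %in% multi), , drop = FALSE]
  out <- rbind(m, rest)
  ## drop pairs that lost a mate
  tab <- table(out$qname)
  out <- out[out$qname %in% names(tab)[tab == 2L], , drop = FALSE]
  out
}

## Expand super-contig instances back into their member contigs.
.expand_placement <- function(sc, members) {
  if (!length(members)) return(sc)
  rows <- NULL
  for (t in seq_len(nrow(sc))) {
    cid <- sc$contig[t]
    mem <- members[[cid]]
    if (is.null(mem)) {
      rows <- rbind(rows, sc[t, , drop = FALSE])
      next
    }
    slen <- max(mem$end) - min(mem$start)
    if (sc$orient[t] == "+") {
      mm <- mem
      mm$start <- sc$start[t] + mem$start
      mm$end <- sc$start[t] + mem$end
    } else {
      mm <- mem[rev(seq_len(nrow(mem))), , drop = FALSE]
      mm$orient <- .flip(mm$orient)
      s <- sc$start[t] + (slen - mm$end)
      e <- sc$start[t] + (slen - mm$start)
      mm$start <- s; mm$end <- e
    }
    rows <- rbind(rows, mm)
  }
  rownames(rows) <- NULL
  rows
}

#' @export
print.scafex_result <- function(x, ...) {
  ns <- lengths(lapply(x$scaffolds, `[[`, "contig"))
  cat(sprintf(
    "scaffolding result: %d scaffolds (%d multi-contig), %d discordant edges\n",
    length(x$scaffolds), sum(ns > 1), x$k))
  if (length(x$flagged))
    cat("  flagged (hybrid fallback):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.scafex_result <- function(object, ...) {
  print(object)
  spans <- vapply(object$scaffolds, function(s) max(s$end) - min(s$start),
                  numeric(1))
  cat(sprintf("  total span %.0f bp; largest scaffold %.0f bp; N50 %.0f bp\n",
              sum(spans), max(spans),
              corrected_n50(spans, sum(spans))))
  invisible(object)
}
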