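## Scaffold graph container: contigs are nodes, bundled mate-pair edges are
## orientation + distance constraints between two contigs.

.flip <- function(o) ifelse(o == "+", "-", "+")

#' Build a scaffold graph
#'
#' @param contigs data.frame with columns `id`, `length`, and optionally
#'   `coverage` and `class` (`"unique"` or `"repeat"`; default unique).
#' @param edges data.frame with columns `c1`, `o1`, `c2`, `o2` (endpoint
#'   contig ids and orientations), `gap` (estimated gap, bp; may be
#'   negative), `sd` (bp), `support` (pair count) and optionally `lib`.
#'   Edges are canonicalized so the lexicographically smaller contig id
#'   comes first; self-edges are rejected.
#' @return object of class `scaffold_graph`: list with elements `contigs`
#'   and `edges` (edges carry an integer `id` column).
#' @export
scaffold_graph <- function(contigs, edges = NULL) {
  stopifnot(is.data.frame(contigs), all(c("id", "length") %in% names(contigs)))
  contigs$id <- as.character(contigs$id)
  if (anyDuplicated(contigs$id))
    stop("duplicate contig id: ",
         paste(unique(contigs$id[duplicated(contigs$id)]), collapse = ", "))
  if (any(contigs$length <= 0)) stop("contig lengths must be positive")
  if (is.null(contigs$coverage)) contigs$coverage <- NA_real_
  if (is.null(contigs$class)) contigs$class <- "unique"
  stopifnot(all(contigs$class %in% c("unique", "repeat")))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(id = integer(), c1 = character(), o1 = character(),
                        c2 = character(), o2 = character(), gap = numeric(),
                        sd = numeric(), support = integer(), lib = character(),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("c1", "o1", "c2", "o2", "gap", "sd", "support") %in% names(edges)))
    edges$c1 <- as.character(edges$c1); edges$c2 <- as.character(edges$c2)
    if (any(edges$c1 == edges$c2)) stop("self-edges are not allowed")
    bad <- setdiff(c(edges$c1, edges$c2), contigs$id)
    if (length(bad)) stop("edge endpoint not in contig set: ",
                          paste(unique(bad), collapse = ", "))
    edges <- canonicalize_edges(edges)
    if (is.null(edges$lib)) edges$lib <- NA_character_
    edges$id <- seq_len(nrow(edges))
    edges <- edges[, c("id", "c1", "o1", "c2", "o2", "gap", "sd", "support", "lib")]
  }
  edges$sd <- pmax(edges$sd, 1)
  g <- list(contigs = contigs, edges = edges)
  class(g) <- "scaffold_graph"
  g
}

#' Canonicalize edge endpoint order
#'
#' Rewrites each edge so that `c1 <= c2` lexicographically, using the
#' reversal identity `(c1,o1)->(c2,o2)` == `(c2,flip(o2))->(c1,flip(o1))`.
#'
#' @param edges edge data.frame (see [scaffold_graph()]).
#' @return the canonicalized data.frame.
#' @export
canonicalize_edges <- function(edges) {
  swap <- edges$c1 > edges$c2
  if (any(swap)) {
    tmp_c <- edges$c1[swap]; tmp_o <- edges$o1[swap]
    edges$c1[swap] <- edges$c2[swap]
    edges$o1[swap] <- .flip(edges$o2[swap])
    edges$c2[swap] <- tmp_c
    edges$o2[swap] <- .flip(tmp_o)
  }
  edges
}

#' Unique-contig subgraph view
#'
#' @param graph a `scaffold_graph`.
#' @return a `scaffold_graph` restricted to unique contigs and unique-unique
#'   edges.
#' @export
unique_subgraph <- function(graph) {
  keep <- graph$contigs$class == "unique"
  ids <- graph$contigs$id[keep]
  e <- graph$edges
  e <- e[e$c1 %in% ids & e$c2 %in% ids, , drop = FALSE]
  g <- list(contigs = graph$contigs[keep, , drop = FALSE], edges = e)
  class(g) <- "scaffold_graph"
  g
}

.contig_length <- function(graph, id) {
  graph$contigs$length[match(id, graph$contigs$id)]
}

.contig_class <- function(graph, id) {
  graph$contigs$class[match(id, graph$contigs$id)]
}

## Drop edges between two repeat contigs: their concordance is ignored
## because not all repeat instances can be assumed scaffolded.
.scorable_edges <- function(graph) {
  cls <- graph$contigs$class[match(graph$edges$c1, graph$contigs$id)]
  cls2 <- graph$contigs$class[match(graph$edges$c2, graph$contigs$id)]
  graph$edges[!(cls == "repeat" & cls2 == "repeat"), , drop = FALSE]
}

#' @export
print.scaffold_graph <- function(x, ...) {
  nrep <- sum(x$contigs$class == "repeat")
  cat(sprintf("scaffold graph: %d contigs (%d repeat), %d edges\n",
              nrow(x$contigs), nrep, nrow(x$edges)))
  invisible(x)
}

#' @export
summary.scaffold_graph <- function(object, ...) {
  print(object)
  if (nrow(object$edges)) {
    cat(sprintf("  edge gap range: [%.0f, %.0f] bp; median support %.0f\n",
                min(object$edges$gap), max(object$edges$gap),
                stats::median(object$edges$support)))
  }
  invisible(object)
}
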