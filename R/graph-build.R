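## Scaffold-graph construction: coverage-based repeat classification, pair
## bundling into raw edges, truncation-bias-corrected edge length
## estimation via reverse lookup tables, multi-library edge merging, and
## the standard contig/edge filters.

#' Classify contigs as unique or repeat by read coverage
#'
#' A contig is unique iff its coverage is below `factor` times the
#' length-weighted genome mean coverage; everything else (including exactly
#' at the threshold) is a repeat.
#'
#' @param contigs contig data.frame (`id`, `length`, optionally `coverage`).
#' @param mappings optional mapping data.frame used to compute coverage as
#'   mapped bases / contig length when `contigs$coverage` is absent.
#' @param factor repeat factor (default 1.5).
#' @return list with `contigs` (with `coverage` and `class` filled) and
#'   `mean_coverage` (the length-weighted genome mean).
#' @export
classify_contigs <- function(contigs, mappings = NULL, factor = 1.5) {
  if (is.null(contigs$coverage) || all(is.na(contigs$coverage))) {
    if (is.null(mappings))
      stop("no coverage values and no mappings to compute them from")
    bases <- tapply(mappings$rlen, mappings$contig, sum)
    contigs$coverage <- as.numeric(bases[contigs$id]) / contigs$length
    contigs$coverage[is.na(contigs$coverage)] <- 0
  }
  mean_cov <- sum(contigs$coverage * contigs$length) / sum(contigs$length)
  contigs$class <- ifelse(contigs$coverage < factor * mean_cov,
                          "unique", "repeat")
  list(contigs = contigs, mean_coverage = mean_cov)
}

## Overhang of a read on its (oriented) contig:
## left role: distance from the read's oriented start to the contig's
## oriented right end; right role: oriented read end coordinate.
.overhang_left <- function(len, pos, rlen, orient_plus) {
  ifelse(orient_plus, len - pos, pos + rlen)
}
.overhang_right <- function(len, pos, rlen, orient_plus) {
  ifelse(orient_plus, pos + rlen, len - pos)
}

#' Bundle cross-contig read pairs into raw scaffold edges
#'
#' Each mapped pair linking two different contigs implies a relative
#' orientation of the two contigs and one observation of `S-hat`, the
#' total length of contig sequence overlapped by the insert (the sum of the
#' two within-contig overhangs). Pairs are grouped per unordered contig
#' pair and orientation class.
#'
#' @param library a `mate_library` (orientation is taken from it).
#' @param mappings mapping data.frame for that library.
#' @param contigs contig data.frame (`id`, `length`).
#' @return data.frame of raw edges (`c1,o1,c2,o2,support,l`) with a list
#'   column `shat` of the per-pair observations.
#' @export
bundle_pairs <- function(library, mappings, contigs) {
  p <- .pair_mappings(mappings)
  p <- p[p$contig1 != p$contig2, , drop = FALSE]
  if (!nrow(p))
    return(data.frame(c1 = character(), o1 = character(), c2 = character(),
                      o2 = character(), support = integer(), l = numeric()))
  s1 <- p$strand1 == "+"
  s2 <- p$strand2 == "+"
  if (library$orientation == "outward") { s1 <- !s1; s2 <- !s2 }
  ## left-role orientation of contig1 and right-role orientation of contig2
  ## for an inward-style fragment leaving contig1 and entering contig2
  o1 <- s1
  o2 <- if (library$orientation == "same-strand") s2 else !s2
  len1 <- contigs$length[match(p$contig1, contigs$id)]
  len2 <- contigs$length[match(p$contig2, contigs$id)]
  shat <- .overhang_left(len1, p$pos1, p$rlen1, o1) +
    .overhang_right(len2, p$pos2, p$rlen2, o2)
  e <- data.frame(c1 = p$contig1, o1 = ifelse(o1, "+", "-"),
                  c2 = p$contig2, o2 = ifelse(o2, "+", "-"),
                  stringsAsFactors = FALSE)
  e <- canonicalize_edges(e)
  key <- paste(e$c1, e$o1, e$c2, e$o2, sep = "\r")
  groups <- split(shat, key)
  ks <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    c1 = vapply(ks, `[`, "", 1), o1 = vapply(ks, `[`, "", 2),
    c2 = vapply(ks, `[`, "", 3), o2 = vapply(ks, `[`, "", 4),
    support = lengths(groups), stringsAsFactors = FALSE)
  out$l <- contigs$length[match(out$c1, contigs$id)] +
    contigs$length[match(out$c2, contigs$id)]
  out$shat <- unname(groups)
  rownames(out) <- NULL
  out
}

#' Empirical insert model with truncation-corrected lookup tables
#'
#' Wraps a library's empirical insert distribution together with a cache of
#' reverse lookup tables `g -> E(S-hat)` per contig-length-sum bucket.
#'
#' @param library a `mate_library` (its filtered same-contig distances form
#'   the empirical distribution), or a numeric vector of insert sizes.
#' @param L search range upper bound (default the library's `mu + 6*sigma`).
#' @param bucket bucket width for the contig-length sum (default 500 bp).
#' @return object of class `insert_model`.
#' @export
insert_model <- function(library, L = NULL, bucket = 500) {
  d <- if (inherits(library, "mate_library")) library$distances else library
  d <- round(d)
  if (!length(d)) stop("empty insert distribution")
  tab <- table(d)
  v <- as.numeric(names(tab))
  n <- as.numeric(tab)
  if (is.null(L)) {
    L <- if (inherits(library, "mate_library")) library$L
         else max(d)
  }
  structure(list(values = v, counts = n,
                 cs1 = cumsum(n), cs2 = cumsum(n * v),
                 mu = mean(d), sigma = max(stats::sd(d), 1),
                 L = L, bucket = bucket,
                 tables = new.env(parent = emptyenv())),
            class = "insert_model")
}

#' Reverse lookup table for gap estimation
#'
#' For every candidate gap `g` in `[0, L]` computes the expected observed
#' contig overlap `E(S-hat) = E(I | g <= I <= g + l) - g`, where `I` is the
#' empirical insert distribution and `l` the sum of the two contig lengths.
#' Computed in linear time from cumulative sums. `E(S-hat)` is
#' non-increasing in `g`, so the table can be inverted by nearest value.
#'
#' @param model an [insert_model()].
#' @param l contig-length sum (bp; callers should pass the bucketed value).
#' @return data.frame with columns `g`, `es` (`NA` where the truncated
#'   support holds no mass).
#' @export
build_lookup_table <- function(model, l) {
  g <- 0:ceiling(model$L)
  C <- l + g
  v <- model$values
  hi <- findInterval(C, v)
  lo <- findInterval(g - 1e-9, v)
  mass <- ifelse(hi > 0, model$cs1[pmax(hi, 1)], 0) -
    ifelse(lo > 0, model$cs1[pmax(lo, 1)], 0)
  sum2 <- ifelse(hi > 0, model$cs2[pmax(hi, 1)], 0) -
    ifelse(lo > 0, model$cs2[pmax(lo, 1)], 0)
  es <- ifelse(mass > 0, sum2 / mass - g, NA_real_)
  data.frame(g = g, es = es)
}

.bucketed_l <- function(l, bucket) {
  r <- l %% bucket
  b <- l - r + ifelse(r > bucket / 2, bucket, 0)  # ties round down
  max(b, 0)
}

.lookup_for <- function(model, l) {
  b <- .bucketed_l(l, model$bucket)
  key <- as.character(b)
  tab <- model$tables[[key]]
  if (is.null(tab)) {
    tab <- build_lookup_table(model, b)
    assign(key, tab, envir = model$tables)
  }
  tab
}

#' Estimate an edge's gap length from observed S-hat values
#'
#' Inverts the truncation-corrected lookup table: returns the gap whose
#' expected `S-hat` is closest to the observed mean, using the table for
#' the 500-bp bucket nearest the edge's contig-length sum. The edge SD is
#' the library SD divided by `sqrt(n)` (the standard error of the bundled
#' estimate); a single-observation edge keeps the full library SD.
#'
#' @param shat numeric vector of per-pair S-hat observations.
#' @param l contig-length sum of the edge's endpoints (bp).
#' @param model an [insert_model()].
#' @param sigma library SD (default from the model).
#' @return list with `gap`, `sd`, `flagged` (TRUE when the observed mean
#'   fell outside the table range and was clamped).
#' @export
estimate_edge_gap <- function(shat, l, model, sigma = model$sigma) {
  obs <- mean(shat)
  tab <- .lookup_for(model, l)
  ok <- !is.na(tab$es)
  if (!any(ok)) stop("lookup table holds no valid entries")
  flagged <- obs > max(tab$es[ok]) || obs < min(tab$es[ok])
  i <- which.min(abs(tab$es[ok] - obs))
  g <- tab$g[ok][i]
  n <- length(shat)
  sd_e <- if (n > 1) sigma / sqrt(n) else sigma
  list(gap = g, sd = max(sd_e, 1), flagged = flagged)
}

#' Discretized Normal insert model
#'
#' Builds an [insert_model()] from the parametric Normal(mu, sigma)
#' density discretized at 1-bp resolution over `mu +/- 6 sigma`, instead
#' of an empirical sample. Useful when the library parameters are known
#' (e.g. in simulations) and empirical tail noise is unwanted.
#'
#' @param mu,sigma insert mean and SD (bp).
#' @param L lookup range bound (default `mu + 6 sigma`).
#' @param bucket contig-length-sum bucket width (bp).
#' @return an `insert_model`.
#' @export
normal_insert_model <- function(mu, sigma, L = mu + 6 * sigma, bucket = 500) {
  v <- seq(max(0, round(mu - 6 * sigma)), round(mu + 6 * sigma))
  w <- stats::dnorm(v, mu, sigma)
  structure(list(values = v, counts = w,
                 cs1 = cumsum(w), cs2 = cumsum(w * v),
                 mu = mu, sigma = sigma,
                 L = L, bucket = bucket,
                 tables = new.env(parent = emptyenv())),
            class = "insert_model")
}

#' Naive gap estimate (no truncation correction)
#'
#' `g = mu - mean(S-hat)`; under-estimates long gaps because the observable
#' pairs are drawn from a truncated insert distribution.
#'
#' @param shat observed S-hat values.
#' @param mu library insert mean.
#' @return numeric gap estimate.
#' @export
naive_gap_estimate <- function(shat, mu) mu - mean(shat)

#' Merge scaffold edges across libraries
#'
#' Within each (contig pair, orientation class): clusters are seeded with
#' the largest-SD unmerged edge; edges whose means lie within
#' `sd_multiplier` seed-SDs are absorbed and combined by inverse-variance
#' weighting (`sd = (sum sd_i^-2)^-1/2`, support summed). If more than one
#' merged edge survives for a unique-unique pair, only the one with the
#' most supporting pairs is kept; pairs involving a repeat retain all
#' merged edges.
#'
#' @param edges data.frame (`c1,o1,c2,o2,gap,sd,support`, optionally `lib`).
#' @param contigs contig data.frame with `class` filled.
#' @param config a [scafex_config()].
#' @return merged edge data.frame.
#' @export
merge_libraries <- function(edges, contigs, config = scafex_config()) {
  if (!nrow(edges)) return(edges)
  edges <- canonicalize_edges(edges)
  if (is.null(edges$lib)) edges$lib <- NA_character_
  key <- paste(edges$c1, edges$o1, edges$c2, edges$o2, sep = "\r")
  out <- NULL
  for (k in unique(key)) {
    grp <- edges[key == k, , drop = FALSE]
    clusters <- NULL
    remaining <- grp
    while (nrow(remaining)) {
      seed <- which.max(remaining$sd)
      inwin <- abs(remaining$gap - remaining$gap[seed]) <=
        config$sd_multiplier * remaining$sd[seed]
      cl <- remaining[inwin, , drop = FALSE]
      w <- 1 / cl$sd^2
      clusters <- rbind(clusters, data.frame(
        c1 = cl$c1[1], o1 = cl$o1[1], c2 = cl$c2[1], o2 = cl$o2[1],
        gap = sum(w * cl$gap) / sum(w),
        sd = 1 / sqrt(sum(w)),
        support = sum(cl$support),
        lib = paste(unique(cl$lib), collapse = ","),
        stringsAsFactors = FALSE))
      remaining <- remaining[!inwin, , drop = FALSE]
    }
    cls1 <- contigs$class[match(clusters$c1[1], contigs$id)]
    cls2 <- contigs$class[match(clusters$c2[1], contigs$id)]
    if (nrow(clusters) > 1 &&
        identical(cls1, "unique") && identical(cls2, "unique")) {
      clusters <- clusters[order(-clusters$support, clusters$gap)[1], ,
                           drop = FALSE]
    }
    out <- rbind(out, clusters)
  }
  rownames(out) <- NULL
  out
}

#' Contig-size and edge-support filters
#'
#' Removes contigs shorter than `max(min_contig_length, 2 * pe_insert)`
#' (they are reported as unscaffolded singletons) and edges with fewer
#' supporting pairs than the threshold.
#'
#' @param graph a [scaffold_graph()].
#' @param config a [scafex_config()].
#' @param support_threshold override of `config$edge_support`.
#' @return list with `graph` (filtered) and `singletons` (ids of removed
#'   contigs).
#' @export
apply_filters <- function(graph, config = scafex_config(),
                          support_threshold = config$edge_support) {
  min_len <- max(config$min_contig_length, 2 * config$pe_insert)
  keep <- graph$contigs$length >= min_len
  singles <- graph$contigs$id[!keep]
  ct <- graph$contigs[keep, , drop = FALSE]
  e <- graph$edges
  e <- e[e$c1 %in% ct$id & e$c2 %in% ct$id &
           e$support >= support_threshold, , drop = FALSE]
  g <- list(contigs = ct, edges = e)
  class(g) <- "scaffold_graph"
  list(graph = g, singletons = singles)
}

#' Group libraries into insert-size stages
#'
#' Partition boundaries are upper-inclusive: with the default boundaries
#' (1 kbp, 10 kbp) the stages are (0, 1000], (1000, 10000], (10000, Inf).
#'
#' @param libraries list of `mate_library` objects.
#' @param boundaries numeric stage boundaries (bp).
#' @return list of library lists, one per non-empty stage, in increasing
#'   insert order.
#' @export
stage_libraries <- function(libraries, boundaries = c(1000, 10000)) {
  mus <- vapply(libraries, `[[`, numeric(1), "mu")
  stage <- vapply(mus, function(m) 1L + sum(m > boundaries), integer(1))
  out <- lapply(sort(unique(stage)), function(s) libraries[stage == s])
  out
}
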