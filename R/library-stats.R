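## Library parameter estimation from read mappings: orientation by majority
## vote over same-contig pairs, insert mean/SD from IQR-filtered pair
## distances on contigs longer than twice a preliminary insert estimate.

## Pair up mates by read id; returns a data.frame of pairs with both sides.
.pair_mappings <- function(mappings) {
  m1 <- mappings[mappings$mate == 1L, , drop = FALSE]
  m2 <- mappings[mappings$mate == 2L, , drop = FALSE]
  j <- match(m1$qname, m2$qname)
  ok <- !is.na(j)
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[j[ok], , drop = FALSE]
  data.frame(qname = m1$qname,
             contig1 = m1$contig, pos1 = m1$pos, strand1 = m1$strand,
             rlen1 = m1$rlen,
             contig2 = m2$contig, pos2 = m2$pos, strand2 = m2$strand,
             rlen2 = m2$rlen,
             stringsAsFactors = FALSE)
}

## Outermost-coordinate span of a same-contig pair (includes both reads).
.pair_span <- function(p) {
  pmax(p$pos1 + p$rlen1, p$pos2 + p$rlen2) - pmin(p$pos1, p$pos2)
}

## inward / outward / same classification of a same-contig pair.
.pair_orientation <- function(p) {
  left1 <- p$pos1 <= p$pos2
  sl <- ifelse(left1, p$strand1, p$strand2)
  sr <- ifelse(left1, p$strand2, p$strand1)
  ifelse(sl == sr, "same-strand", ifelse(sl == "+", "inward", "outward"))
}

#' Preliminary insert-size estimate
#'
#' Mean outermost span over the first 1000 same-contig pairs (in input
#' order), or all of them if fewer are available.
#'
#' @param mappings mapping data.frame (`qname`, `mate`, `contig`, `pos`,
#'   `strand`, `rlen`, `lib`).
#' @param n number of pairs to use (default 1000).
#' @return numeric estimate in bp.
#' @export
preliminary_insert <- function(mappings, n = 1000) {
  p <- .pair_mappings(mappings)
  p <- p[p$contig1 == p$contig2, , drop = FALSE]
  if (!nrow(p))
    stop("no same-contig read pairs; contigs may be too short to estimate ",
         "the insert size")
  p <- utils::head(p, n)
  mean(.pair_span(p))
}

#' IQR outlier filter for pair distances
#'
#' Keeps distances `d` with `Q1 - 3*IQR <= d <= Q3 + 3*IQR`, where the
#' quartiles (type-7 linear interpolation) are computed once on the input.
#'
#' @param distances numeric vector (at least 4 values).
#' @return the retained distances (a subset of the input).
#' @export
iqr_filter <- function(distances) {
  if (length(distances) < 4)
    stop("need at least 4 distances for quartile filtering")
  q <- stats::quantile(distances, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  distances[distances >= q[1] - 3 * iqr & distances <= q[2] + 3 * iqr]
}

#' Estimate library parameters from mappings
#'
#' Orientation is the majority class over same-contig pairs on qualifying
#' contigs (longer than twice the preliminary insert); ties follow the
#' fixed preference inward > outward > same-strand. Insert mean and SD come
#' from the IQR-filtered distances on the same contigs; the span bound is
#' `L = mu + 6*sigma` and the SD is floored at 1 bp.
#'
#' @inheritParams preliminary_insert
#' @param contigs contig data.frame with `id` and `length`.
#' @param id library id (default: from the mappings' `lib` column).
#' @param config a [scafex_config()] (supplies the support threshold).
#' @return object of class `mate_library`: list with `id`, `orientation`,
#'   `mu`, `sigma`, `q1`, `q3`, `iqr`, `L`, `support_threshold`,
#'   `n_pairs`, and `distances` (the filtered same-contig distances, kept
#'   for the empirical insert model).
#' @export
estimate_library <- function(mappings, contigs, id = NULL,
                             config = scafex_config()) {
  if (is.null(id)) id <- as.character(mappings$lib[1])
  prelim <- preliminary_insert(mappings)
  long_ids <- contigs$id[contigs$length > 2 * prelim]
  p <- .pair_mappings(mappings)
  p <- p[p$contig1 == p$contig2 & p$contig1 %in% long_ids, , drop = FALSE]
  if (!nrow(p))
    stop("no contig longer than twice the preliminary insert (",
         round(prelim), " bp); supply library parameters manually")
  orient_tab <- table(factor(.pair_orientation(p),
                             levels = c("inward", "outward", "same-strand")))
  orientation <- names(orient_tab)[which.max(orient_tab)]  # ties: first level
  d <- .pair_span(p)
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  dk <- if (length(d) >= 4) iqr_filter(d) else d
  mu <- mean(dk)
  sigma <- max(stats::sd(dk), 1)
  if (is.na(sigma)) sigma <- 1
  structure(list(id = id, orientation = orientation,
                 mu = mu, sigma = sigma,
                 q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
                 L = mu + 6 * sigma,
                 support_threshold = config$edge_support,
                 n_pairs = length(dk), distances = dk),
            class = "mate_library")
}

#' @export
print.mate_library <- function(x, ...) {
  cat(sprintf(
    "library '%s': %s, insert %.0f +/- %.0f bp (n = %d pairs), L = %.0f bp\n",
    x$id, x$orientation, x$mu, x$sigma, x$n_pairs, x$L))
  invisible(x)
}
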