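## Maximum-likelihood gap sizing for a fixed contig order/orientation.
##
## Each scaffold edge constrains the distance it spans: D_e(gaps) = (sum of
## interior contig lengths) + (sum of spanned gaps) should be close to the
## edge's gap estimate g_e, with Gaussian uncertainty sigma_e. Maximizing
## the joint likelihood is the convex weighted least squares problem
##   minimize  sum_e w_e (D_e(gaps) - g_e)^2,   w_e = n_e / sigma_e^2,
## subject to box bounds on each gap; solved by projected coordinate
## descent (deterministic sweeps, tolerance 1e-8 on the objective).

#' Build a gap system from instance lengths and edge constraints
#'
#' @param lengths contig instance lengths in scaffold order (T instances,
#'   T-1 gap variables).
#' @param constraints data.frame with columns `i`, `j` (1-based instance
#'   indexes, `i < j`), `gap` (edge estimate, bp), `sd`, and optionally
#'   `support` (default 1).
#' @param gap_min,gap_max box bounds for every gap (bp).
#' @param init optional initial gap vector (defaults to `gap_min` for gaps
#'   no constraint covers, 0 otherwise).
#' @return object of class `gap_system`.
#' @export
gap_system <- function(lengths, constraints, gap_min = -500, gap_max = 1e6,
                       init = NULL) {
  if (gap_min > gap_max) stop("infeasible bounds: gap_min > gap_max")
  nT <- length(lengths)
  ng <- nT - 1L
  if (nrow(constraints)) {
    stopifnot(all(constraints$i < constraints$j),
              all(constraints$i >= 1), all(constraints$j <= nT))
    if (is.null(constraints$support)) constraints$support <- 1
  }
  structure(list(lengths = lengths, constraints = constraints,
                 n_gaps = ng, gap_min = gap_min, gap_max = gap_max,
                 init = init),
            class = "gap_system")
}

## design row: which gaps does constraint (i, j) span, and its target
## residual (edge gap minus interior contig length)
.gap_design <- function(sys, use_support = TRUE) {
  ng <- sys$n_gaps
  cn <- sys$constraints
  ne <- nrow(cn)
  A <- matrix(0, ne, ng)
  r <- numeric(ne)
  w <- numeric(ne)
  for (e in seq_len(ne)) {
    gi <- seq(cn$i[e], cn$j[e] - 1L)
    A[e, gi] <- 1
    interior <- if (cn$j[e] - cn$i[e] > 1)
      sum(sys$lengths[(cn$i[e] + 1L):(cn$j[e] - 1L)]) else 0
    r[e] <- cn$gap[e] - interior
    w[e] <- (if (use_support) cn$support[e] else 1) / cn$sd[e]^2
  }
  list(A = A, r = r, w = w)
}

#' Unconstrained normal-equation solution of a gap system
#'
#' Closed-form weighted least squares solution (no bounds); used as the
#' reference in tests. Singular systems return `NA` for undetermined
#' directions.
#'
#' @param sys a [gap_system()].
#' @param use_support weight constraints by pair support.
#' @return numeric gap vector.
#' @export
gap_normal_solution <- function(sys, use_support = TRUE) {
  d <- .gap_design(sys, use_support)
  M <- t(d$A) %*% (d$w * d$A)
  b <- t(d$A) %*% (d$w * d$r)
  covered <- colSums(d$A) > 0
  x <- rep(NA_real_, sys$n_gaps)
  if (any(covered)) {
    x[covered] <- tryCatch(
      drop(solve(M[covered, covered, drop = FALSE], b[covered])),
      error = function(e) rep(NA_real_, sum(covered)))
  }
  x
}

#' Estimate gap sizes by bounded maximum likelihood
#'
#' Projected coordinate descent on the convex weighted least-squares
#' objective, with deterministic sweep order and a 1e-8 relative tolerance
#' on the objective change. Gaps covered by no constraint stay at their
#' initial value (the source-edge estimate when supplied, else `gap_min`).
#'
#' @param sys a [gap_system()].
#' @param use_support weight constraints by pair support (default TRUE).
#' @param max_iter sweep cap.
#' @return list with `gaps` (numeric vector), `objective`, `iterations`,
#'   and `kkt` (max KKT residual at exit).
#' @export
estimate_gap_sizes <- function(sys, use_support = TRUE, max_iter = 10000) {
  ng <- sys$n_gaps
  if (ng == 0L)
    return(list(gaps = numeric(), objective = 0, iterations = 0L, kkt = 0))
  d <- .gap_design(sys, use_support)
  covered <- colSums(d$A) > 0
  x <- if (!is.null(sys$init)) sys$init else ifelse(covered, 0, sys$gap_min)
  x <- pmin(pmax(x, sys$gap_min), sys$gap_max)
  if (!nrow(sys$constraints))
    return(list(gaps = x, objective = 0, iterations = 0L, kkt = 0))
  obj <- function(x) sum(d$w * (drop(d$A %*% x) - d$r)^2)
  ## active-set polish: solve the normal equations exactly on coordinates
  ## away from their bounds; keeps the projected solution when feasible
  polish <- function(x) {
    free <- covered & x > sys$gap_min + 1e-7 & x < sys$gap_max - 1e-7
    if (!any(free)) return(x)
    M <- t(d$A) %*% (d$w * d$A)
    b <- drop(t(d$A) %*% (d$w * d$r)) -
      drop(M[, !free, drop = FALSE] %*% x[!free])
    sol <- tryCatch(
      drop(solve(M[free, free, drop = FALSE], b[free])),
      error = function(e) NULL)
    if (is.null(sol)) return(x)
    cand <- x
    cand[free] <- pmin(pmax(sol, sys$gap_min), sys$gap_max)
    if (obj(cand) <= obj(x) + 1e-12) cand else x
  }
  f0 <- obj(x)
  it <- 0L
  repeat {
    it <- it + 1L
    for (t in which(covered)) {
      rows <- which(d$A[, t] > 0)
      resid <- drop(d$A[rows, , drop = FALSE] %*% x) - d$r[rows]
      denom <- sum(d$w[rows])
      x[t] <- x[t] - sum(d$w[rows] * resid) / denom
      x[t] <- min(max(x[t], sys$gap_min), sys$gap_max)
    }
    if (it %% 20 == 0L) x <- polish(x)
    f1 <- obj(x)
    if (f0 - f1 <= 1e-8 * max(1, abs(f0)) || it >= max_iter) break
    f0 <- f1
  }
  x <- polish(x)
  ## KKT residual: projected gradient
  gr <- drop(2 * t(d$A) %*% (d$w * (drop(d$A %*% x) - d$r)))
  pg <- gr
  pg[x <= sys$gap_min + 1e-9 & gr > 0] <- 0
  pg[x >= sys$gap_max - 1e-9 & gr < 0] <- 0
  pg[!covered] <- 0
  list(gaps = x, objective = obj(x), iterations = it, kkt = max(abs(pg)))
}

#' Gap system of a scaffold placement
#'
#' Collects, for one placement, every graph edge both of whose endpoints
#' are placed in a matching (concordant-form) instance pair, and expresses
#' it as a distance constraint over the spanned gaps.
#'
#' @param placement placement data.frame (`contig`, `orient`, `start`,
#'   `end`).
#' @param graph the [scaffold_graph()].
#' @param config a [scafex_config()].
#' @return a [gap_system()] whose initial gaps are the placement's current
#'   gaps.
#' @export
scaffold_gap_system <- function(placement, graph, config = scafex_config()) {
  ctx <- .score_ctx(graph, config)
  pl <- list(ct = match(placement$contig, ctx$ids),
             or = placement$orient == "+",
             st = placement$start, en = placement$end)
  n <- length(pl$ct)
  cons <- NULL
  for (e in seq_len(ctx$ne)) {
    if (!ctx$scor[e]) next
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      if (.edge_pair_ok(ctx, e, pl$ct[i], pl$or[i], pl$ct[j], pl$or[j],
                        pl$st[j] - pl$en[i])) {
        cons <- rbind(cons, data.frame(i = i, j = j,
                                       gap = ctx$egap[e], sd = ctx$esd[e],
                                       support = ctx$esup[e]))
      }
    }
  }
  if (is.null(cons))
    cons <- data.frame(i = integer(), j = integer(), gap = numeric(),
                       sd = numeric(), support = numeric())
  init <- if (n > 1) pl$st[-1] - pl$en[-n] else numeric()
  gmax <- if (is.na(config$gap_max)) 1e6 else config$gap_max
  gap_system(placement$end - placement$start, cons,
             gap_min = config$gap_min, gap_max = gmax, init = init)
}

#' Re-space a placement with maximum-likelihood gap sizes
#'
#' @inheritParams scaffold_gap_system
#' @return the placement with `start`/`end` recomputed from the estimated
#'   gaps (first instance kept at its original start).
#' @export
resize_gaps <- function(placement, graph, config = scafex_config()) {
  n <- nrow(placement)
  if (n <= 1L) return(placement)
  sys <- scaffold_gap_system(placement, graph, config)
  fit <- estimate_gap_sizes(sys, use_support = config$use_support_weights)
  len <- placement$end - placement$start
  start <- numeric(n)
  start[1] <- placement$start[1]
  for (t in 2:n) start[t] <- start[t - 1L] + len[t - 1L] + fit$gaps[t - 1L]
  placement$start <- start
  placement$end <- start + len
  placement
}
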