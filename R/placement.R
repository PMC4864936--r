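## Deterministic placement and concordance scoring.
##
## A placement is an ordered list of oriented contig instances with start/end
## coordinates. The same gap-inference rule is used by the exact search and
## by the brute-force oracle, so the two optimize an identical, fully
## deterministic objective: minimize the number of scorable edges that no
## pair of placed instances satisfies.

## Integer-coded scoring context; orientation "+" is coded TRUE.
.score_ctx <- function(graph, config = scafex_config()) {
  ids <- graph$contigs$id
  e <- graph$edges
  m <- config$sd_multiplier
  cls <- graph$contigs$class == "repeat"
  e1 <- match(e$c1, ids); e2 <- match(e$c2, ids)
  list(
    ids = ids,
    len = as.numeric(graph$contigs$length),
    rep = cls,
    ne = nrow(e),
    eid = e$id,
    e1 = e1, eo1 = e$o1 == "+",
    e2 = e2, eo2 = e$o2 == "+",
    egap = as.numeric(e$gap),
    esd = as.numeric(e$sd),
    esup = as.numeric(e$support),
    lo = as.numeric(e$gap) - m * as.numeric(e$sd),
    hi = as.numeric(e$gap) + m * as.numeric(e$sd),
    scor = !(cls[e1] & cls[e2]),
    m = m,
    slack = config$overlap_slack,
    gap_min = config$gap_min,
    max_copies = config$max_repeat_copies,
    ## geometric reach window of the scaffold tail
    W = if (nrow(e)) max(e$gap + m * e$sd) + config$overlap_slack else config$overlap_slack,
    inc1 = lapply(seq_along(ids), function(ci) which(e1 == ci | e2 == ci))
  )
}

.empty_placement <- function() {
  list(ct = integer(), or = logical(), st = numeric(), en = numeric())
}

.pl_append <- function(pl, ci, oi, start, len) {
  pl$ct <- c(pl$ct, ci)
  pl$or <- c(pl$or, oi)
  pl$st <- c(pl$st, start)
  pl$en <- c(pl$en, start + len)
  pl
}

## Does edge e accept the ordered instance pair (ci,oi) -> (cj,oj) at `gap`?
.edge_pair_ok <- function(ctx, e, ci, oi, cj, oj, gap) {
  ((ci == ctx$e1[e] & oi == ctx$eo1[e] & cj == ctx$e2[e] & oj == ctx$eo2[e]) |
   (ci == ctx$e2[e] & oi != ctx$eo2[e] & cj == ctx$e1[e] & oj != ctx$eo1[e])) &
    gap >= ctx$lo[e] & gap <= ctx$hi[e]
}

## Is edge e satisfied by some placed instance pair?
.edge_satisfied <- function(ctx, e, pl) {
  i1 <- which(pl$ct == ctx$e1[e]); i2 <- which(pl$ct == ctx$e2[e])
  if (!length(i1) || !length(i2)) return(FALSE)
  for (i in i1) for (j in i2) {
    if (i < j &&
        .edge_pair_ok(ctx, e, pl$ct[i], pl$or[i], pl$ct[j], pl$or[j],
                      pl$st[j] - pl$en[i])) return(TRUE)
    if (j < i &&
        .edge_pair_ok(ctx, e, pl$ct[j], pl$or[j], pl$ct[i], pl$or[i],
                      pl$st[i] - pl$en[j])) return(TRUE)
  }
  FALSE
}

## Rightward expectation of edge e from an anchor instance (ci, oi):
## returns c(partner, partner_orient_logical) or NULL.
.edge_expectation <- function(ctx, e, ci, oi) {
  if (ci == ctx$e1[e] && oi == ctx$eo1[e])
    return(list(partner = ctx$e2[e], orient = ctx$eo2[e]))
  if (ci == ctx$e2[e] && oi != ctx$eo2[e])
    return(list(partner = ctx$e1[e], orient = !ctx$eo1[e]))
  NULL
}

## Deterministic start-position choice for appending (ci, oi) to a
## placement. Candidate positions are implied by every in-reach matching
## anchored edge, at the edge's gap estimate (center) and at its lower
## window endpoint (a maximal set of satisfiable interval constraints can
## always be met at some interval's lower endpoint), plus the gap-0 tail
## fallback; positions are floored at tail_end + gap_min (modest overlap).
## Among candidates the one satisfying the most of the candidate contig's
## constraints wins; ties prefer centers, then higher edge support, then
## smaller edge id, then the smaller position.
.best_start <- function(ctx, pl, ci, oi) {
  n <- length(pl$ct)
  if (n == 0L) return(0)
  tail_end <- pl$en[n]
  floor_pos <- tail_end + ctx$gap_min
  inc <- ctx$inc1[[ci]]
  cand_pos <- tail_end; cand_rank <- 2; cand_sup <- -Inf; cand_eid <- Inf
  ## edges whose satisfaction depends on the new instance's position
  live <- integer()
  for (e in inc) {
    if (!ctx$scor[e]) next
    live <- c(live, e)
    for (i in seq_len(n)) {
      exp <- .edge_expectation(ctx, e, pl$ct[i], pl$or[i])
      if (is.null(exp) || exp$partner != ci || exp$orient != oi) next
      if (tail_end - pl$en[i] > ctx$hi[e] + ctx$slack) next
      for (rk in c(0, 1)) {
        p0 <- pl$en[i] + if (rk == 0) ctx$egap[e] else ctx$lo[e]
        cand_pos <- c(cand_pos, max(p0, floor_pos))
        cand_rank <- c(cand_rank, rk)
        cand_sup <- c(cand_sup, ctx$esup[e])
        cand_eid <- c(cand_eid, ctx$eid[e])
      }
    }
  }
  if (length(cand_pos) == 1L) return(tail_end)
  nsat <- vapply(cand_pos, function(p) {
    s <- 0L
    for (e in live) {
      for (i in seq_len(n)) {
        if (.edge_pair_ok(ctx, e, pl$ct[i], pl$or[i], ci, oi, p - pl$en[i])) {
          s <- s + 1L
          break
        }
      }
    }
    s
  }, integer(1))
  ord <- order(-nsat, cand_rank, -cand_sup, cand_eid, cand_pos)
  cand_pos[ord[1]]
}

## Place an ordered sequence of (contig code, orientation) instances.
.place_order <- function(ctx, ct, or) {
  pl <- .empty_placement()
  for (t in seq_along(ct)) {
    start <- .best_start(ctx, pl, ct[t], or[t])
    pl <- .pl_append(pl, ct[t], or[t], start, ctx$len[ct[t]])
  }
  pl
}

## Number of scorable edges not satisfied by any instance pair.
.count_discordant <- function(ctx, pl) {
  k <- 0L
  for (e in seq_len(ctx$ne)) {
    if (!ctx$scor[e]) next
    if (!.edge_satisfied(ctx, e, pl)) k <- k + 1L
  }
  k
}

## ---- user-facing wrappers ------------------------------------------------

#' Construct a placement from contig ids and orientations
#'
#' Positions each oriented contig instance left to right using the
#' deterministic gap-inference rule (adjacent matching edge estimate first,
#' else the nearest in-reach anchored edge, else gap 0).
#'
#' @param graph a [scaffold_graph()].
#' @param ids character vector of contig ids, in scaffold order (repeat ids
#'   may recur).
#' @param orients matching vector of `"+"`/`"-"`.
#' @param config a [scafex_config()].
#' @return data.frame with columns `contig`, `orient`, `start`, `end`.
#' @export
place_contigs <- function(graph, ids, orients, config = scafex_config()) {
  ctx <- .score_ctx(graph, config)
  ct <- match(ids, ctx$ids)
  if (anyNA(ct)) stop("unknown contig id: ",
                      paste(ids[is.na(ct)], collapse = ", "))
  pl <- .place_order(ctx, ct, orients == "+")
  data.frame(contig = ctx$ids[pl$ct],
             orient = ifelse(pl$or, "+", "-"),
             start = pl$st, end = pl$en, stringsAsFactors = FALSE)
}

#' Test edge concordance against a placement
#'
#' An edge is concordant if some ordered pair of placed instances of its two
#' endpoint contigs matches the edge's relative orientation and has an
#' implied gap inside `[gap - m*sd, gap + m*sd]`, where `m` is the
#' concordance multiplier. For edges touching repeat contigs any instance
#' pair may satisfy the constraint.
#'
#' @param edge single-row data.frame with `c1,o1,c2,o2,gap,sd`.
#' @param placement data.frame as returned by [place_contigs()].
#' @param m concordance window multiplier (default 6).
#' @return logical.
#' @export
is_concordant <- function(edge, placement, m = 6) {
  i1 <- which(placement$contig == edge$c1)
  i2 <- which(placement$contig == edge$c2)
  lo <- edge$gap - m * edge$sd; hi <- edge$gap + m * edge$sd
  ok_pair <- function(i, j, o_left, o_right) {
    placement$orient[i] == o_left && placement$orient[j] == o_right &&
      placement$start[j] - placement$end[i] >= lo &&
      placement$start[j] - placement$end[i] <= hi
  }
  for (i in i1) for (j in i2) {
    if (i < j && ok_pair(i, j, edge$o1, edge$o2)) return(TRUE)
    if (j < i && ok_pair(j, i, .flip(edge$o2), .flip(edge$o1))) return(TRUE)
  }
  FALSE
}

#' Count edges satisfied by no scaffold in a set
#'
#' An edge is concordant if at least one scaffold in the set contains a
#' satisfying instance pair.
#'
#' @inheritParams place_contigs
#' @param scaffolds list of placement data.frames.
#' @return integer discordant-edge count over the whole graph.
#' @export
count_discordant_scaffolds <- function(graph, scaffolds,
                                       config = scafex_config()) {
  ctx <- .score_ctx(graph, config)
  sat <- logical(ctx$ne)
  for (sc in scaffolds) {
    pl <- list(ct = match(sc$contig, ctx$ids), or = sc$orient == "+",
               st = sc$start, en = sc$end)
    for (e in which(ctx$scor & !sat)) {
      if (.edge_satisfied(ctx, e, pl)) sat[e] <- TRUE
    }
  }
  sum(ctx$scor & !sat)
}

#' Count discordant edges of a placement
#'
#' @inheritParams place_contigs
#' @param placement data.frame from [place_contigs()].
#' @return integer count of scorable (non repeat-repeat) edges left
#'   unsatisfied.
#' @export
count_discordant <- function(graph, placement, config = scafex_config()) {
  ctx <- .score_ctx(graph, config)
  pl <- list(ct = match(placement$contig, ctx$ids),
             or = placement$orient == "+",
             st = placement$start, en = placement$end)
  .count_discordant(ctx, pl)
}
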