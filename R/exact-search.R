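## Memoized fixed-parameter exact search for a minimal-repeat optimal
## scaffold of a (fenced) subgraph.
##
## The search extends a partial scaffold rightward only. Candidates are
## proposed by open (concordant dangling) edges anchored at placed unique
## contigs; edges emanating from placed repeat instances never propose
## candidates. Edge bookkeeping is three-state: open (undecided), satisfied
## (some placed instance pair meets the constraint) and dead (provably
## unsatisfiable by any extension); the dead count k drives iterative
## deepening over the allowed number of discordant edges p = 0, 1, 2, ...
## States are memoized on the active region (the tail suffix within the
## maximal concordance reach window, which contains every unconfirmed
## repeat), the open-edge set, the set of unplaced unique contigs and the
## per-repeat instance counts, with dominance pruning on k when repeats are
## present and exact (A, X) keys in unique-only mode.

.placeable_vec <- function(ctx, remaining, counts) {
  p <- logical(length(ctx$ids))
  p[remaining] <- TRUE
  rp <- which(ctx$rep)
  if (length(rp)) p[rp] <- counts[rp] < ctx$max_copies
  p
}

.state_new <- function(ctx) {
  list(pl = .empty_placement(),
       sat = logical(ctx$ne),
       dead = logical(ctx$ne),
       unconf = logical(0),
       remaining = which(!ctx$rep),
       counts = integer(length(ctx$ids)),
       k = 0L)
}

.state_open <- function(ctx, state) {
  which(ctx$scor & !state$sat & !state$dead)
}

## Confirm or drop repeat instances that have fallen out of the reach
## window of the scaffold tail: a non-essential instance (no satisfied edge
## depends on it) is removed with all other coordinates kept fixed; an
## essential one is marked confirmed and retained.
.confirm_repeats <- function(ctx, state, bound = ctx$W) {
  n <- length(state$pl$ct)
  if (!n || !any(state$unconf)) return(state)
  tail_end <- state$pl$en[n]
  idx <- 1L
  while (idx <= length(state$pl$ct)) {
    if (state$unconf[idx] && tail_end - state$pl$en[idx] > bound) {
      ci <- state$pl$ct[idx]
      essential <- FALSE
      pl_minus <- list(ct = state$pl$ct[-idx], or = state$pl$or[-idx],
                       st = state$pl$st[-idx], en = state$pl$en[-idx])
      for (e in ctx$inc1[[ci]]) {
        if (ctx$scor[e] && state$sat[e] && !.edge_satisfied(ctx, e, pl_minus)) {
          essential <- TRUE
          break
        }
      }
      if (essential) {
        state$unconf[idx] <- FALSE
        idx <- idx + 1L
      } else {
        state$pl <- pl_minus
        state$unconf <- state$unconf[-idx]
        state$counts[ci] <- state$counts[ci] - 1L
      }
    } else idx <- idx + 1L
  }
  state
}

## Append one oriented contig instance; returns the new state, or NULL when
## the extension pushes the dead-edge count beyond p.
.state_extend <- function(ctx, state, ci, oi, p) {
  start <- .best_start(ctx, state$pl, ci, oi)
  pl2 <- .pl_append(state$pl, ci, oi, start, ctx$len[ci])
  j <- length(pl2$ct)
  sat2 <- state$sat
  for (e in ctx$inc1[[ci]]) {
    if (!ctx$scor[e] || sat2[e] || state$dead[e]) next
    for (i in seq_len(j - 1L)) {
      if (.edge_pair_ok(ctx, e, pl2$ct[i], pl2$or[i], pl2$ct[j], pl2$or[j],
                        pl2$st[j] - pl2$en[i])) {
        sat2[e] <- TRUE
        break
      }
    }
  }
  remaining2 <- setdiff(state$remaining, ci)
  counts2 <- state$counts
  if (ctx$rep[ci]) counts2[ci] <- counts2[ci] + 1L
  placeable <- .placeable_vec(ctx, remaining2, counts2)
  dead2 <- state$dead
  k2 <- state$k
  for (e in which(ctx$scor & !sat2 & !dead2)) {
    if (!.edge_future_possible(ctx, e, pl2, placeable)) {
      dead2[e] <- TRUE
      k2 <- k2 + 1L
    }
  }
  if (k2 > p) return(NULL)
  st2 <- list(pl = pl2, sat = sat2, dead = dead2,
              unconf = c(state$unconf, ctx$rep[ci]),
              remaining = remaining2, counts = counts2, k = k2)
  .confirm_repeats(ctx, st2)
}

## Candidate extensions: partners of open edges with an in-reach unique
## anchor, ordered by BFS-estimated distance from the scaffold tail
## (multi-path distances combined by a weighted mean that down-weights
## longer paths by their edge count). Falls back to the remaining unique
## contigs when no edge proposes anything.
.state_candidates <- function(ctx, state) {
  n <- length(state$pl$ct)
  if (!n) return(NULL)
  tail_end <- state$pl$en[n]
  placeable <- .placeable_vec(ctx, state$remaining, state$counts)
  cand_ci <- integer(); cand_oi <- logical(); cand_d <- numeric()
  add <- function(ci, oi, d) {
    hit <- which(cand_ci == ci & cand_oi == oi)
    if (length(hit)) {
      cand_d[hit] <<- min(cand_d[hit], d)
    } else {
      cand_ci <<- c(cand_ci, ci); cand_oi <<- c(cand_oi, oi)
      cand_d <<- c(cand_d, d)
    }
  }
  open <- .state_open(ctx, state)
  for (e in open) {
    for (i in seq_len(n)) {
      if (ctx$rep[state$pl$ct[i]]) next
      exp <- .edge_expectation(ctx, e, state$pl$ct[i], state$pl$or[i])
      if (is.null(exp) || !placeable[exp$partner]) next
      if (tail_end - state$pl$en[i] > ctx$hi[e] + ctx$slack) next
      add(exp$partner, exp$orient, state$pl$en[i] + ctx$egap[e] - tail_end)
    }
  }
  if (!length(cand_ci)) {
    ## completeness fallback: restart from any remaining unique contig
    for (ci in sort(state$remaining)) {
      add(ci, TRUE, Inf); add(ci, FALSE, Inf)
    }
    if (!length(cand_ci)) return(NULL)
  } else {
    dist <- .bfs_distances(ctx, state, open)
    for (h in seq_along(cand_ci)) {
      d <- dist[[cand_ci[h]]]
      if (!is.null(d)) cand_d[h] <- d
    }
  }
  ord <- order(cand_d, ctx$ids[cand_ci], !cand_oi)
  data.frame(ci = cand_ci[ord], oi = cand_oi[ord], dist = cand_d[ord])
}

## Rightward distance propagation from the placed anchors through the
## graph, visiting each edge once in increasing-distance order and
## following orientation-consistent expectations only; nodes reachable
## over several paths get the weighted mean of the path estimates, with
## weights inverse to path edge count. Repeats and placed contigs do not
## relay.
.bfs_distances <- function(ctx, state, open) {
  n <- length(state$pl$ct)
  tail_end <- state$pl$en[n]
  est <- vector("list", length(ctx$ids))  # per node: rbind of (dist, nedge)
  used <- logical(ctx$ne)
  frontier <- NULL  # rows: node, orient (1/0), dist, nedges
  for (e in open) {
    for (i in seq_len(n)) {
      if (ctx$rep[state$pl$ct[i]]) next
      exp <- .edge_expectation(ctx, e, state$pl$ct[i], state$pl$or[i])
      if (is.null(exp)) next
      if (tail_end - state$pl$en[i] > ctx$hi[e] + ctx$slack) next
      if (used[e]) next
      used[e] <- TRUE
      d <- state$pl$en[i] + ctx$egap[e] - tail_end
      est[[exp$partner]] <- rbind(est[[exp$partner]], c(d, 1))
      frontier <- rbind(frontier, c(exp$partner, exp$orient, d, 1))
    }
  }
  while (!is.null(frontier) && nrow(frontier)) {
    h <- order(frontier[, 3], frontier[, 1])[1]
    cur <- frontier[h, ]; frontier <- frontier[-h, , drop = FALSE]
    u <- cur[1]; ou <- cur[2] > 0; du <- cur[3]; ne_u <- cur[4]
    if (u %in% state$pl$ct || ctx$rep[u]) next
    for (e in ctx$inc1[[u]]) {
      if (used[e] || !ctx$scor[e]) next
      exp <- .edge_expectation(ctx, e, u, ou)
      if (is.null(exp) || exp$partner %in% state$pl$ct) next
      used[e] <- TRUE
      dv <- du + ctx$len[u] + ctx$egap[e]
      est[[exp$partner]] <- rbind(est[[exp$partner]], c(dv, ne_u + 1))
      frontier <- rbind(frontier, c(exp$partner, exp$orient, dv, ne_u + 1))
    }
  }
  out <- vector("list", length(ctx$ids))
  for (v in seq_along(est)) {
    if (is.null(est[[v]])) next
    w <- 1 / est[[v]][, 2]
    out[[v]] <- sum(est[[v]][, 1] * w) / sum(w)
  }
  out
}

.memo_key <- function(ctx, state, unique_mode) {
  n <- length(state$pl$ct)
  tail_end <- state$pl$en[n]
  a <- which(state$pl$en >= tail_end - ctx$W)
  tok <- paste(state$pl$ct[a],
               ifelse(state$pl$or[a], "+", "-"),
               round(tail_end - state$pl$en[a]),
               sep = ":", collapse = ",")
  open <- paste(.state_open(ctx, state), collapse = ",")
  rem <- paste(state$remaining, collapse = ",")
  cnt <- paste(state$counts[ctx$rep], collapse = ",")
  key <- paste(tok, open, rem, cnt, sep = "|")
  if (unique_mode)
    key <- paste(key, paste(which(state$dead), collapse = ","), sep = "|")
  key
}

## DFS at deepening level p; returns the first completed state with final
## discordance <= p, or NULL. env carries the node counter, cap and memo.
.dfs_level <- function(ctx, state, p, env) {
  env$n <- env$n + 1L
  if (env$n > env$cap) stop(structure(
    class = c("scafex_state_cap", "error", "condition"),
    list(message = "state cap exceeded", call = NULL)))
  if (!length(state$remaining) && length(state$pl$ct)) {
    k_stop <- state$k + length(.state_open(ctx, state))
    if (k_stop <= p) return(state)
  }
  cands <- .state_candidates(ctx, state)
  if (is.null(cands)) return(NULL)
  for (h in seq_len(nrow(cands))) {
    st2 <- .state_extend(ctx, state, cands$ci[h], cands$oi[h], p)
    if (is.null(st2)) next
    if (env$memo) {
      key <- .memo_key(ctx, st2, env$unique_mode)
      prev <- env$tab[[key]]
      if (env$unique_mode) {
        if (!is.null(prev)) next
        env$tab[[key]] <- TRUE
      } else {
        if (!is.null(prev) && prev <= st2$k) next
        env$tab[[key]] <- st2$k
      }
    }
    res <- .dfs_level(ctx, st2, p, env)
    if (!is.null(res)) return(res)
  }
  NULL
}

## Exact search over one connected component (unique contigs connected via
## unique-unique edges, plus attached repeats).
.search_component <- function(graph, config) {
  ctx <- .score_ctx(graph, config)
  uniq <- which(!ctx$rep)
  n_scor <- sum(ctx$scor)
  env <- new.env(parent = emptyenv())
  env$cap <- config$state_cap
  env$memo <- isTRUE(config$memo)
  env$unique_mode <- !any(ctx$rep)
  total_states <- 0L
  for (p in 0:n_scor) {
    env$tab <- new.env(parent = emptyenv())
    env$n <- 0L
    res <- NULL
    starts <- uniq[order(ctx$ids[uniq])]
    for (ci in starts) {
      for (oi in c(TRUE, FALSE)) {
        st0 <- .state_extend(ctx, .state_new(ctx), ci, oi, p)
        if (is.null(st0)) next
        res <- .dfs_level(ctx, st0, p, env)
        if (!is.null(res)) break
      }
      if (!is.null(res)) break
    }
    total_states <- total_states + env$n
    if (!is.null(res)) {
      pl <- .minimal_repeat_reduce(ctx, res$pl)
      k <- .count_discordant(ctx, pl)
      return(list(placement = .pl_to_df(ctx, pl), k = k,
                  n_states = total_states))
    }
  }
  ## unreachable in practice: p = number of scorable edges accepts anything
  stop("search failed to complete a scaffold")
}

## Split a subgraph into searchable components: connected components of the
## unique-unique edge graph, each augmented with the repeat contigs it has
## edges to.
.subgraph_components <- function(graph) {
  ct <- graph$contigs
  uniq <- ct$id[ct$class == "unique"]
  if (!length(uniq)) return(list())
  comp <- stats::setNames(seq_along(uniq), uniq)
  e <- graph$edges
  uu <- e[e$c1 %in% uniq & e$c2 %in% uniq, , drop = FALSE]
  if (nrow(uu)) for (i in seq_len(nrow(uu))) {
    a <- comp[[uu$c1[i]]]; b <- comp[[uu$c2[i]]]
    if (a != b) comp[comp == b] <- a
  }
  lapply(unique(comp), function(cc) {
    ids <- names(comp)[comp == cc]
    reps <- unique(c(e$c2[e$c1 %in% ids], e$c1[e$c2 %in% ids]))
    reps <- setdiff(reps, uniq)
    sel <- c(ids, reps)
    sub_e <- e[e$c1 %in% sel & e$c2 %in% sel, , drop = FALSE]
    ## drop repeat-repeat edges entirely and edges from attached repeats to
    ## uniques outside the component (there are none by construction)
    g <- list(contigs = ct[ct$id %in% sel, , drop = FALSE], edges = sub_e)
    class(g) <- "scaffold_graph"
    g
  })
}

#' Find minimal-repeat optimal scaffolds for a subgraph
#'
#' Runs the memoized exact search with iterative deepening on the number of
#' discordant edges, independently on each connected component of the
#' subgraph's unique-contig graph (with attached repeats). If the number of
#' explored states exceeds `config$state_cap`, the edge-support threshold is
#' raised by `config$support_step`, weakly supported edges are dropped, the
#' search restarts, and the result is flagged (hybrid-exact fallback).
#'
#' @param subgraph a [scaffold_graph()] (typically a fenced subgraph from
#'   [decompose_graph()]).
#' @param config a [scafex_config()].
#' @return list with `scaffolds` (list of placement data.frames), `k` (total
#'   discordant count), `n_states`, `flagged` (logical), `support_threshold`
#'   (threshold actually used) and `unplaced` (repeat contigs that no
#'   scaffold uses, to be emitted as singletons).
#' @export
scaffold_subgraph <- function(subgraph, config = scafex_config()) {
  thr <- 0  # edges were already support-filtered upstream
  flagged <- FALSE
  edges0 <- subgraph$edges
  repeat {
    comps <- .subgraph_components(subgraph)
    if (!length(comps)) {
      ## no unique contigs: every repeat is its own singleton scaffold
      ct <- subgraph$contigs
      sc <- lapply(seq_len(nrow(ct)), function(i)
        data.frame(contig = ct$id[i], orient = "+", start = 0,
                   end = ct$length[i], stringsAsFactors = FALSE))
      return(list(scaffolds = sc, k = 0L, n_states = 0L, flagged = flagged,
                  support_threshold = thr, unplaced = character()))
    }
    res <- tryCatch({
      out <- lapply(comps, function(g) .search_component(g, config))
      list(ok = TRUE, out = out)
    }, scafex_state_cap = function(e) list(ok = FALSE))
    if (res$ok) {
      scaffolds <- lapply(res$out, `[[`, "placement")
      placed <- unique(unlist(lapply(scaffolds, `[[`, "contig")))
      reps <- subgraph$contigs$id[subgraph$contigs$class == "repeat"]
      return(list(scaffolds = scaffolds,
                  k = sum(vapply(res$out, `[[`, integer(1), "k")),
                  n_states = sum(vapply(res$out, `[[`, integer(1), "n_states")),
                  flagged = flagged,
                  support_threshold = thr,
                  unplaced = setdiff(reps, placed)))
    }
    ## hybrid-exact fallback: raise the support threshold and rebuild
    flagged <- TRUE
    thr <- (if (thr == 0) min(edges0$support) else thr) + config$support_step
    keep <- edges0$support >= thr
    if (!any(keep) && thr > max(edges0$support) + 1) {
      ## no edges left: emit every contig as a singleton, flagged
      ct <- subgraph$contigs
      sc <- lapply(seq_len(nrow(ct)), function(i)
        data.frame(contig = ct$id[i], orient = "+", start = 0,
                   end = ct$length[i], stringsAsFactors = FALSE))
      return(list(scaffolds = sc, k = 0L, n_states = 0L, flagged = TRUE,
                  support_threshold = thr, unplaced = character()))
    }
    subgraph$edges <- edges0[keep, , drop = FALSE]
  }
}

## ---- exported single-step wrappers (useful for inspection and testing) ---

#' Create a search state seeded with one oriented contig
#'
#' @param graph a [scaffold_graph()].
#' @param id,orient starting contig id and orientation (`"+"`/`"-"`).
#' @param config a [scafex_config()].
#' @return an opaque search-state list; see [extend_state()].
#' @export
new_search_state <- function(graph, id, orient = "+",
                             config = scafex_config()) {
  ctx <- .score_ctx(graph, config)
  ci <- match(id, ctx$ids)
  if (is.na(ci)) stop("unknown contig id: ", id)
  st <- .state_extend(ctx, .state_new(ctx), ci, orient == "+", p = Inf)
  structure(list(ctx = ctx, state = st), class = "scafex_state")
}

#' Extend a partial scaffold by one oriented contig
#'
#' Appends the contig right of the scaffold tail, reclassifies edges
#' (satisfied / open / dead), confirms or drops out-of-reach repeat
#' instances, and rejects the extension when the dead-edge count exceeds
#' `p`.
#'
#' @param x a state from [new_search_state()].
#' @param id,orient contig to append and its orientation.
#' @param p maximum allowed discordant (dead) edges.
#' @return the extended state, or `NULL` if rejected.
#' @export
extend_state <- function(x, id, orient = "+", p = Inf) {
  ci <- match(id, x$ctx$ids)
  if (is.na(ci)) stop("unknown contig id: ", id)
  st <- .state_extend(x$ctx, x$state, ci, orient == "+", p)
  if (is.null(st)) return(NULL)
  structure(list(ctx = x$ctx, state = st), class = "scafex_state")
}

#' Ordered candidate extensions of a search state
#'
#' @param x a `scafex_state`.
#' @return data.frame with `contig`, `orient` and the BFS-estimated
#'   `distance` from the scaffold tail, sorted ascending.
#' @export
order_extensions <- function(x) {
  cands <- .state_candidates(x$ctx, x$state)
  if (is.null(cands))
    return(data.frame(contig = character(), orient = character(),
                      distance = numeric()))
  data.frame(contig = x$ctx$ids[cands$ci],
             orient = ifelse(cands$oi, "+", "-"),
             distance = cands$dist, stringsAsFactors = FALSE)
}

#' Confirm or drop out-of-reach repeat instances of a state
#'
#' @param x a `scafex_state`.
#' @param bound distance from the scaffold tail (bp) beyond which an
#'   unconfirmed repeat instance is tested; defaults to the maximal edge
#'   reach window.
#' @return the updated state.
#' @export
confirm_repeats <- function(x, bound = NULL) {
  b <- if (is.null(bound)) x$ctx$W else bound
  st <- .confirm_repeats(x$ctx, x$state, bound = b)
  structure(list(ctx = x$ctx, state = st), class = "scafex_state")
}

#' @export
print.scafex_state <- function(x, ...) {
  st <- x$state
  cat(sprintf("partial scaffold: %d instances, k = %d, %d open edges\n",
              length(st$pl$ct), st$k, length(.state_open(x$ctx, st))))
  df <- .pl_to_df(x$ctx, st$pl)
  print(df)
  invisible(x)
}

#' Placement of a search state as a data.frame
#' @param x a `scafex_state`.
#' @return data.frame with `contig`, `orient`, `start`, `end`.
#' @export
state_placement <- function(x) .pl_to_df(x$ctx, x$state$pl)

#' Discordant (dead) edge count of a search state
#' @param x a `scafex_state`.
#' @return integer.
#' @export
state_discordant <- function(x) x$state$k
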