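## Brute-force scaffolding oracle: exhaustive depth-first enumeration of
## signed contig sequences (repeat contigs up to a copy bound), scored with
## the shared concordance rules. Used as the independent ground truth for
## the memoized exact search on small graphs.

## Can edge e still be satisfied by a future (rightward) placement?
## `placeable` is a logical vector over contig codes: TRUE if another
## instance of that contig can still be appended.
.edge_future_possible <- function(ctx, e, pl, placeable) {
  n <- length(pl$ct)
  tail_end <- if (n) pl$en[n] else 0
  reach <- function(ci, oi) {
    idx <- which(pl$ct == ci & pl$or == oi)
    length(idx) > 0 && any(tail_end - pl$en[idx] <= ctx$hi[e] + ctx$slack)
  }
  ## form A: (e1,eo1) then (e2,eo2)
  if (placeable[ctx$e2[e]] && (placeable[ctx$e1[e]] || reach(ctx$e1[e], ctx$eo1[e])))
    return(TRUE)
  ## form B: (e2,!eo2) then (e1,!eo1)
  if (placeable[ctx$e1[e]] && (placeable[ctx$e2[e]] || reach(ctx$e2[e], !ctx$eo2[e])))
    return(TRUE)
  FALSE
}

## Recount discordance after deleting instance `idx`, keeping all other
## instance coordinates fixed (the deleted instance's span becomes gap).
.discordant_after_removal <- function(ctx, pl, idx) {
  pl2 <- list(ct = pl$ct[-idx], or = pl$or[-idx],
              st = pl$st[-idx], en = pl$en[-idx])
  .count_discordant(ctx, pl2)
}

## Iteratively delete repeat instances whose removal leaves the discordant
## count unchanged (scan from the right); returns the reduced placement.
.minimal_repeat_reduce <- function(ctx, pl) {
  repeat {
    k <- .count_discordant(ctx, pl)
    removed <- FALSE
    for (idx in rev(seq_along(pl$ct))) {
      if (!ctx$rep[pl$ct[idx]]) next
      if (.discordant_after_removal(ctx, pl, idx) <= k) {
        pl <- list(ct = pl$ct[-idx], or = pl$or[-idx],
                   st = pl$st[-idx], en = pl$en[-idx])
        removed <- TRUE
        break
      }
    }
    if (!removed) return(pl)
  }
}

.pl_to_df <- function(ctx, pl) {
  data.frame(contig = ctx$ids[pl$ct],
             orient = ifelse(pl$or, "+", "-"),
             start = pl$st, end = pl$en, stringsAsFactors = FALSE)
}

#' Brute-force minimal-discordance scaffolding (test oracle)
#'
#' Exhaustively enumerates signed sequences containing every unique contig
#' exactly once and each repeat contig up to `max_copies` times, scoring
#' each complete sequence by its discordant-edge count under the shared
#' deterministic placement rule. Branch-and-bound pruning discards prefixes
#' whose provably-dead edge count already reaches the incumbent, which
#' preserves exactness. Intended for small graphs (about eight contig
#' instances after repeat expansion).
#'
#' @param graph a [scaffold_graph()].
#' @param config a [scafex_config()]; `max_repeat_copies` bounds repeat
#'   instance counts.
#' @param collect if `TRUE`, also collect every optimal scaffold (reduced to
#'   minimal-repeat form); otherwise only the first optimum found.
#' @return list with `k` (minimum discordant count), `scaffold` (placement
#'   data.frame of the first optimum, minimal-repeat reduced), `scaffolds`
#'   (list of optima if `collect`), and `n_states` (search nodes visited).
#' @export
brute_force_scaffold <- function(graph, config = scafex_config(),
                                 collect = FALSE) {
  ctx <- .score_ctx(graph, config)
  nC <- length(ctx$ids)
  uniq <- which(!ctx$rep)
  reps <- which(ctx$rep)
  scor_idx <- which(ctx$scor)

  best <- new.env(parent = emptyenv())
  best$k <- Inf; best$pl <- NULL; best$all <- list(); best$n <- 0L

  placeable_of <- function(remaining, counts) {
    p <- logical(nC)
    p[remaining] <- TRUE
    if (length(reps)) p[reps] <- counts[reps] < ctx$max_copies
    p
  }

  recurse <- function(pl, sat, remaining, counts) {
    best$n <- best$n + 1L
    placeable <- placeable_of(remaining, counts)
    dead <- 0L
    for (e in scor_idx) {
      if (!sat[e] && !.edge_future_possible(ctx, e, pl, placeable))
        dead <- dead + 1L
    }
    if (collect) {
      if (dead > best$k) return(invisible(NULL))
    } else if (dead >= best$k) return(invisible(NULL))
    if (!length(remaining) && length(pl$ct)) {
      score <- sum(!sat[scor_idx])
      if (score < best$k) {
        best$k <- score
        best$pl <- pl
        best$all <- list(pl)
      } else if (collect && score == best$k) {
        best$all <- c(best$all, list(pl))
      }
    }
    if (!collect && best$k == 0) return(invisible(NULL))
    cand <- c(remaining, reps[placeable[reps]])
    if (!length(cand)) return(invisible(NULL))
    for (ci in sort(cand)) for (oi in c(TRUE, FALSE)) {
      start <- .best_start(ctx, pl, ci, oi)
      pl2 <- .pl_append(pl, ci, oi, start, ctx$len[ci])
      sat2 <- sat
      j <- length(pl2$ct)
      for (e in ctx$inc1[[ci]]) {
        if (!ctx$scor[e] || sat2[e]) next
        for (i in seq_len(j - 1L)) {
          if (.edge_pair_ok(ctx, e, pl2$ct[i], pl2$or[i], pl2$ct[j], pl2$or[j],
                            pl2$st[j] - pl2$en[i])) {
            sat2[e] <- TRUE
            break
          }
        }
      }
      rem2 <- setdiff(remaining, ci)
      cnt2 <- counts
      if (ctx$rep[ci]) cnt2[ci] <- cnt2[ci] + 1L
      recurse(pl2, sat2, rem2, cnt2)
    }
    invisible(NULL)
  }

  recurse(.empty_placement(), logical(ctx$ne), uniq, integer(nC))

  if (!is.finite(best$k))
    stop("no complete scaffold enumerated (empty graph?)")
  reduced <- .minimal_repeat_reduce(ctx, best$pl)
  out <- list(k = as.integer(best$k),
              scaffold = .pl_to_df(ctx, reduced),
              n_states = best$n)
  if (collect) {
    out$scaffolds <- lapply(best$all, function(p)
      .pl_to_df(ctx, .minimal_repeat_reduce(ctx, p)))
  }
  out
}
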