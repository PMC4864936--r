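## Long-read mode: contig links (synthetic mate pairs inferred from long
## reads) become scaffold edges grouped into synthetic libraries by
## distance range, with SD fixed at 10% of the estimated distance.

.LINK_BINS <- cbind(lo = c(0, 300, 1000, 2000, 5000, 15000),
                    hi = c(300, 1000, 2000, 5000, 15000, 40000))

#' Convert contig links into synthetic mate-pair libraries
#'
#' Each link becomes a scaffold edge with `gap = distance` and
#' `sd = max(0.1 * distance, 30)`, assigned to one of the fixed,
#' lower-inclusive distance bins `[0,300), [300,1000), [1000,2000),
#' [2000,5000), [5000,15000), [15000,40000]`. Links beyond 40 kbp are
#' discarded (with a message). Duplicate links for the same oriented pair
#' are merged first: supports summed, distance by inverse-variance mean.
#'
#' @param links data.frame from [read_links_tsv()].
#' @param support_threshold minimum summed support per edge (long-read mode
#'   default 1).
#' @return list with `libraries` (per-bin list: `range`, `edges`) and
#'   `edges` (combined edge data.frame ready for [scaffold_graph()]).
#' @export
links_to_libraries <- function(links, support_threshold = 1) {
  e <- data.frame(c1 = links$c1, o1 = links$o1, c2 = links$c2, o2 = links$o2,
                  gap = links$distance,
                  sd = pmax(0.1 * links$distance, 30),
                  support = links$support, stringsAsFactors = FALSE)
  e <- canonicalize_edges(e)
  ## merge duplicates per oriented pair
  key <- paste(e$c1, e$o1, e$c2, e$o2, sep = "\r")
  if (anyDuplicated(key)) {
    parts <- split(e, key)
    e <- do.call(rbind, lapply(parts, function(g) {
      w <- 1 / g$sd^2
      gap <- sum(w * g$gap) / sum(w)
      data.frame(c1 = g$c1[1], o1 = g$o1[1], c2 = g$c2[1], o2 = g$o2[1],
                 gap = gap, sd = max(0.1 * gap, 30),
                 support = sum(g$support), stringsAsFactors = FALSE)
    }))
    rownames(e) <- NULL
  }
  over <- e$gap > 40000
  if (any(over))
    message(sum(over), " link(s) beyond 40 kbp discarded")
  e <- e[!over, , drop = FALSE]
  e <- e[e$support >= support_threshold, , drop = FALSE]
  bin <- findInterval(e$gap, .LINK_BINS[, "lo"])
  e$lib <- sprintf("lr_%d_%d", .LINK_BINS[bin, "lo"], .LINK_BINS[bin, "hi"])
  libs <- lapply(seq_len(nrow(.LINK_BINS)), function(b) {
    list(range = .LINK_BINS[b, ],
         edges = e[bin == b, , drop = FALSE])
  })
  names(libs) <- sprintf("lr_%d_%d", .LINK_BINS[, "lo"], .LINK_BINS[, "hi"])
  list(libraries = libs, edges = e)
}
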