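## Truth-based evaluation of scaffolds from the simulator: error classes
## (translocation, inversion, relocation, scaffold indel) over adjacent
## unique-contig joins, corrected N50 after breaking at every error, and
## repeat placement correctness/completeness over valid gaps.

#' N50 of fragment lengths against a genome size
#'
#' The fragment length such that strictly more than half of the genome is
#' contained in fragments at least that long.
#'
#' @param lengths fragment lengths (bp).
#' @param genome_size genome size (bp).
#' @return numeric length (0 when the fragments never reach half the
#'   genome).
#' @export
corrected_n50 <- function(lengths, genome_size) {
  lengths <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(lengths)
  i <- which(cum > genome_size / 2)
  if (!length(i)) return(0)
  lengths[i[1]]
}

#' Evaluate scaffolds against simulation truth
#'
#' Every join between consecutive unique-contig instances is classified:
#' translocation (endpoints on different chromosomes), inversion (wrong
#' relative orientation), relocation (wrong order, or separation off by
#' more than `max(1000, 6 * join_sd)` bp), scaffold indel (separation off
#' by more than 1 kbp but within the relocation tolerance), else correct.
#' Corrected N50 is computed after breaking scaffolds at every error join.
#' Repeat placement is scored over valid gaps (joins whose flanks are in
#' the right order and orientation): a gap is correctly scaffolded when the
#' placed repeat instances match the true copies in the spanned genomic
#' interval in family, order and orientation.
#'
#' @param scaffolds list of placement data.frames.
#' @param truth truth table from [derive_contigs()] (optionally with a
#'   `chrom` column; single chromosome assumed otherwise).
#' @param genome_size genome size in bp.
#' @param join_sd stand-in SD (bp) for the supporting edge in the
#'   relocation distance tolerance `max(1000, 6 * join_sd)`; default 500.
#' @return object of class `scafex_eval`: list of error counts, join
#'   counts, N50 / corrected N50 and repeat metrics.
#' @export
evaluate_scaffolds <- function(scaffolds, truth, genome_size, join_sd = 500) {
  if (is.null(truth$chrom)) truth$chrom <- "chr1"
  reloc_tol <- max(1000, 6 * join_sd)
  utruth <- truth[truth$class == "unique", , drop = FALSE]
  counts <- c(translocation = 0L, inversion = 0L, relocation = 0L,
              scaffold_indel = 0L)
  correct <- 0L; total <- 0L
  frag_lengths <- numeric()
  rep_gap_total <- 0L; rep_gap_correct <- 0L
  rep_copies_total <- 0L; rep_copies_placed <- 0L
  for (sc in scaffolds) {
    u_idx <- which(sc$contig %in% utruth$contig)
    break_after <- logical(max(length(u_idx) - 1L, 0))
    if (length(u_idx) >= 2L) for (h in seq_len(length(u_idx) - 1L)) {
      i <- u_idx[h]; j <- u_idx[h + 1L]
      total <- total + 1L
      a <- sc[i, ]; b <- sc[j, ]
      ta <- utruth[match(a$contig, utruth$contig), ]
      tb <- utruth[match(b$contig, utruth$contig), ]
      sep_s <- b$start - a$end
      cls <- NULL
      if (ta$chrom != tb$chrom) {
        cls <- "translocation"
      } else if (a$orient != b$orient) {
        cls <- "inversion"
      } else {
        forward <- a$orient == "+"
        order_ok <- if (forward) tb$start >= ta$end else ta$start >= tb$end
        true_sep <- if (forward) tb$start - ta$end else ta$start - tb$end
        if (!order_ok) {
          cls <- "relocation"
        } else if (abs(sep_s - true_sep) > reloc_tol) {
          cls <- "relocation"
        } else if (abs(sep_s - true_sep) > 1000) {
          cls <- "scaffold_indel"
        }
      }
      if (is.null(cls)) {
        correct <- correct + 1L
        ## repeat placement inside this valid gap
        forward <- a$orient == "+"
        glo <- if (forward) ta$end else tb$end
        ghi <- if (forward) tb$start else ta$start
        true_cp <- truth[truth$class == "repeat" & truth$chrom == ta$chrom &
                           truth$start >= glo & truth$end <= ghi, ,
                         drop = FALSE]
        true_cp <- true_cp[order(true_cp$start), , drop = FALSE]
        placed <- sc[seq(i + 1L, length.out = j - i - 1L), , drop = FALSE]
        if (nrow(true_cp) || nrow(placed)) {
          rep_gap_total <- rep_gap_total + 1L
          exp_ids <- true_cp$contig
          exp_strand <- true_cp$strand
          if (!forward) {
            exp_ids <- rev(exp_ids)
            exp_strand <- rev(ifelse(exp_strand == "+", "-", "+"))
          }
          ok <- nrow(placed) == length(exp_ids) &&
            (!length(exp_ids) ||
               (all(placed$contig == exp_ids) &&
                  all(placed$orient == exp_strand)))
          if (ok) rep_gap_correct <- rep_gap_correct + 1L
          rep_copies_total <- rep_copies_total + nrow(true_cp)
          rep_copies_placed <- rep_copies_placed +
            min(sum(placed$contig %in% exp_ids), nrow(true_cp))
        }
      } else {
        counts[cls] <- counts[cls] + 1L
        break_after[h] <- TRUE
      }
    }
    ## fragment lengths after breaking at error joins
    if (length(u_idx) <= 1L) {
      frag_lengths <- c(frag_lengths, max(sc$end) - min(sc$start))
    } else {
      brk <- which(break_after)
      starts <- c(1L, u_idx[brk + 1L])
      ends <- c(u_idx[brk], nrow(sc))
      for (fi in seq_along(starts)) {
        rows <- sc[starts[fi]:ends[fi], , drop = FALSE]
        frag_lengths <- c(frag_lengths, max(rows$end) - min(rows$start))
      }
    }
  }
  full_lengths <- vapply(scaffolds, function(sc) max(sc$end) - min(sc$start),
                         numeric(1))
  structure(list(
    counts = counts,
    correct_joins = correct,
    total_joins = total,
    n50 = corrected_n50(full_lengths, genome_size),
    corrected_n50 = corrected_n50(frag_lengths, genome_size),
    repeat_gap_correct_frac =
      if (rep_gap_total) rep_gap_correct / rep_gap_total else NA_real_,
    repeat_placed_frac =
      if (rep_copies_total) rep_copies_placed / rep_copies_total else NA_real_),
    class = "scafex_eval")
}

#' @export
print.scafex_eval <- function(x, ...) {
  cat("scaffold evaluation:\n")
  cat(sprintf("  joins: %d correct / %d total (%.1f%%)\n", x$correct_joins,
              x$total_joins,
              if (x$total_joins) 100 * x$correct_joins / x$total_joins else 100))
  cat(sprintf("  errors: %d translocation, %d inversion, %d relocation, %d indel\n",
              x$counts["translocation"], x$counts["inversion"],
              x$counts["relocation"], x$counts["scaffold_indel"]))
  cat(sprintf("  N50 %.0f bp, corrected N50 %.0f bp\n", x$n50, x$corrected_n50))
  if (!is.na(x$repeat_gap_correct_frac))
    cat(sprintf("  repeat gaps correct: %.1f%%, repeat copies placed: %.1f%%\n",
                100 * x$repeat_gap_correct_frac, 100 * x$repeat_placed_frac))
  invisible(x)
}
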