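## External formats: FASTA contigs (Biostrings), SAM read mappings
## (Rsamtools), AGP v2.0 + FASTA scaffold output, long-read link TSV.
## Coordinates are 0-based half-open internally; SAM's 1-based POS is
## converted at the boundary.

#' Read contigs from FASTA
#'
#' @param path FASTA file (plain or gzipped).
#' @return list with `contigs` (data.frame `id`, `length`; coverage unset)
#'   and `sequences` (a `DNAStringSet` named by id; ids are the first
#'   whitespace-delimited token of each header).
#' @export
read_contigs_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  list(contigs = data.frame(id = ids, length = Biostrings::width(seqs),
                            coverage = NA_real_, stringsAsFactors = FALSE),
       sequences = seqs)
}

#' Read paired mappings from a SAM file
#'
#' Converts through BAM (Rsamtools), keeping primary mapped records only;
#' SAM 1-based positions become 0-based. Reads are paired by name; reads
#' whose mate is missing (e.g. unmapped) are dropped with a message.
#'
#' @param path SAM file with a header.
#' @param lib library id to stamp on the records.
#' @param contigs optional contig data.frame; mapped reference names absent
#'   from it raise an error.
#' @return mapping data.frame (`qname`, `mate`, `contig`, `pos`, `strand`,
#'   `rlen`, `lib`) containing complete pairs only.
#' @export
read_sam_pairs <- function(path, lib = "lib1", contigs = NULL) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flt <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = flt,
      what = c("qname", "flag", "rname", "pos", "strand", "qwidth")))[[1]]
  if (!length(res$qname))
    return(data.frame(qname = character(), mate = integer(),
                      contig = character(), pos = integer(),
                      strand = character(), rlen = integer(),
                      lib = character(), stringsAsFactors = FALSE))
  mate <- ifelse(bitwAnd(res$flag, 128L) > 0L, 2L, 1L)
  m <- data.frame(qname = res$qname, mate = mate,
                  contig = as.character(res$rname),
                  pos = res$pos - 1L,
                  strand = as.character(res$strand),
                  rlen = res$qwidth, lib = lib, stringsAsFactors = FALSE)
  if (!is.null(contigs)) {
    bad <- setdiff(unique(m$contig), contigs$id)
    if (length(bad))
      stop("SAM reference(s) not in contig set: ", paste(bad, collapse = ", "))
  }
  tab <- table(m$qname, m$mate)
  complete <- rownames(tab)[tab[, "1"] == 1 & ncol(tab) == 2 & tab[, "2"] == 1]
  orphans <- sum(!m$qname %in% complete)
  if (orphans) message(orphans, " unpaired read(s) dropped")
  m <- m[m$qname %in% complete, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Write mapping records as SAM
#'
#' Minimal valid single-end-style SAM (one line per mate, paired flags
#' set); sequences and qualities are omitted (`*`).
#'
#' @param mappings mapping data.frame.
#' @param contigs contig data.frame (`id`, `length`) for the `@SQ` header.
#' @param path output path.
#' @export
write_sam <- function(mappings, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$id,
                     as.integer(contigs$length)), con)
  flag <- 1L + ifelse(mappings$mate == 1L, 64L, 128L) +
    ifelse(mappings$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     mappings$qname, flag, mappings$contig,
                     as.integer(mappings$pos) + 1L,
                     as.integer(mappings$rlen)), con)
  invisible(path)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write scaffolds as AGP v2.0 and FASTA
#'
#' Components of type `W` for contigs and `N` for gaps (`gap_type`
#' "scaffold", linkage "yes", evidence "paired-ends"). Non-positive
#' estimated gaps are rendered as a single `N` (AGP forbids non-positive
#' gap lengths); the raw estimate is preserved in a 10th column
#' (`est_gap=`). Flagged scaffolds are marked with a leading comment line.
#' The FASTA renders the reverse complement for `-` orientation and
#' `max(1, round(gap))` Ns per gap, so AGP and FASTA describe identical
#' structures.
#'
#' @param scaffolds list of placement data.frames (`contig`, `orient`,
#'   `start`, `end`); names become scaffold ids (default `scaffold_N`).
#' @param sequences named `DNAStringSet` (or named character vector) of
#'   contig sequences.
#' @param agp_path,fasta_path output paths (`NULL` to skip one of them).
#' @param flagged optional logical vector marking hybrid-fallback scaffolds.
#' @return invisible list of the scaffold ids written.
#' @export
write_scaffolds <- function(scaffolds, sequences, agp_path = NULL,
                            fasta_path = NULL, flagged = NULL) {
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds))))
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  seqs <- as.character(sequences)
  names(seqs) <- names(sequences)
  agp <- character()
  fa_names <- character(); fa_seqs <- character()
  for (si in seq_along(scaffolds)) {
    sc <- scaffolds[[si]]
    sid <- names(scaffolds)[si]
    if (!all(sc$contig %in% names(seqs)))
      stop("missing sequence for contig(s): ",
           paste(setdiff(sc$contig, names(seqs)), collapse = ", "))
    if (!is.null(flagged) && isTRUE(flagged[si]))
      agp <- c(agp, sprintf("# scaffold %s flagged: hybrid-exact fallback", sid))
    part <- 0L
    obj_pos <- 0L
    pieces <- character()
    for (t in seq_len(nrow(sc))) {
      if (t > 1L) {
        gap_est <- sc$start[t] - sc$end[t - 1L]
        gap_len <- max(1L, as.integer(round(gap_est)))
        part <- part + 1L
        agp <- c(agp, sprintf("%s\t%d\t%d\t%d\tN\t%d\tscaffold\tyes\tpaired-ends\test_gap=%d",
                              sid, obj_pos + 1L, obj_pos + gap_len, part,
                              gap_len, as.integer(round(gap_est))))
        obj_pos <- obj_pos + gap_len
        pieces <- c(pieces, strrep("N", gap_len))
      }
      len <- as.integer(round(sc$end[t] - sc$start[t]))
      part <- part + 1L
      agp <- c(agp, sprintf("%s\t%d\t%d\t%d\tW\t%s\t1\t%d\t%s",
                            sid, obj_pos + 1L, obj_pos + len, part,
                            sc$contig[t], len, sc$orient[t]))
      obj_pos <- obj_pos + len
      s <- seqs[[sc$contig[t]]]
      pieces <- c(pieces, if (sc$orient[t] == "-") .revcomp(s) else s)
    }
    fa_names <- c(fa_names, sid)
    fa_seqs <- c(fa_seqs, paste(pieces, collapse = ""))
  }
  if (!is.null(agp_path)) {
    writeLines(c("##agp-version\t2.0", agp), agp_path)
  }
  if (!is.null(fasta_path)) {
    out <- Biostrings::DNAStringSet(fa_seqs)
    names(out) <- fa_names
    Biostrings::writeXStringSet(out, fasta_path, width = 70)
  }
  invisible(names(scaffolds))
}

#' Read scaffold structure back from AGP
#'
#' @param path AGP file written by [write_scaffolds()].
#' @return named list of placement data.frames (`contig`, `orient`,
#'   `start`, `end`), with attribute `gap_estimates` (list of the raw
#'   per-gap estimates) and `flagged` (character vector of flagged
#'   scaffold ids).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  flagged <- sub("^# scaffold (\\S+) flagged.*$", "\\1",
                 grep("^# scaffold .* flagged", lines, value = TRUE))
  lines <- lines[!startsWith(lines, "#")]
  out <- list(); gaps <- list()
  pend_gap <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    sid <- f[1]
    if (f[5] == "W") {
      len <- as.numeric(f[8])
      prev <- out[[sid]]
      gap_here <- pend_gap[[sid]]
      start <- if (is.null(prev)) 0 else
        prev$end[nrow(prev)] + (if (is.null(gap_here)) 0 else gap_here)
      row <- data.frame(contig = f[6], orient = f[9],
                        start = start, end = start + len,
                        stringsAsFactors = FALSE)
      out[[sid]] <- rbind(prev, row)
      pend_gap[[sid]] <- NULL
    } else if (f[5] == "N") {
      est <- if (length(f) >= 10 && startsWith(f[10], "est_gap="))
        as.numeric(sub("est_gap=", "", f[10])) else as.numeric(f[6])
      pend_gap[[sid]] <- est
      gaps[[sid]] <- c(gaps[[sid]], est)
    }
  }
  attr(out, "gap_estimates") <- gaps
  attr(out, "flagged") <- flagged
  out
}

#' Read long-read contig links from TSV
#'
#' Six columns: contig 1, orientation 1, contig 2, orientation 2, estimated
#' distance (bp, non-negative), supporting-read count (>= 1). Duplicates
#' are preserved (de-duplication happens downstream).
#'
#' @param path TSV path.
#' @param contigs optional contig data.frame for id validation.
#' @return data.frame (`c1`, `o1`, `c2`, `o2`, `distance`, `support`).
#' @export
read_links_tsv <- function(path, contigs = NULL) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("c1", "o1", "c2", "o2",
                                       "distance", "support"),
                         colClasses = c("character", "character", "character",
                                        "character", "numeric", "numeric"),
                         stringsAsFactors = FALSE)
  if (any(!d$o1 %in% c("+", "-")) || any(!d$o2 %in% c("+", "-")))
    stop("link orientations must be '+' or '-'")
  if (any(d$distance < 0)) stop("negative link distance")
  if (any(d$support < 1)) stop("link support must be >= 1")
  if (!is.null(contigs)) {
    bad <- setdiff(unique(c(d$c1, d$c2)), contigs$id)
    if (length(bad))
      stop("unknown contig id(s) in links: ", paste(bad, collapse = ", "))
  }
  d
}
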