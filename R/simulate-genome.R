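## Synthetic data generation: a reference genome with planted repeat
## families, contigs tiling it with repeats collapsed, and mate pairs with
## Normal(mu, sigma) inserts mapped back onto the contigs. Coordinates are
## 0-based half-open; everything is deterministic per seed.

#' Simulate a genome with planted repeat families
#'
#' Bases are i.i.d. uniform; each repeat family copies one template
#' sequence to `copies` non-overlapping locations (minimum separation
#' `min_separation`), optionally with a per-copy substitution rate.
#'
#' @param seed integer seed.
#' @param size genome size (bp).
#' @param repeats data.frame with columns `family`, `length`, `copies` and
#'   optionally `sub_rate` (default 0); `NULL` for a repeat-free genome.
#' @param min_separation minimum distance between repeat copies and from
#'   the genome ends (bp).
#' @return list with `seq` (character, length-`size` genome), `repeats`
#'   (data.frame `family`, `copy`, `start`, `end`, `strand`), `size`.
#' @export
simulate_genome <- function(seed, size, repeats = NULL,
                            min_separation = 10000) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genome <- sample(bases, size, replace = TRUE)
  copies <- data.frame(family = character(), copy = integer(),
                       start = numeric(), end = numeric(),
                       strand = character(), stringsAsFactors = FALSE)
  if (!is.null(repeats) && nrow(repeats)) {
    if (is.null(repeats$sub_rate)) repeats$sub_rate <- 0
    occupied <- matrix(numeric(0), ncol = 2)
    for (f in seq_len(nrow(repeats))) {
      len <- repeats$length[f]
      tmpl <- sample(bases, len, replace = TRUE)
      placed <- 0L
      tries <- 0L
      while (placed < repeats$copies[f] && tries < 10000L) {
        tries <- tries + 1L
        s <- sample.int(size - len - 2L * min_separation, 1L) + min_separation
        if (nrow(occupied) &&
            any(s < occupied[, 2] + min_separation &
                s + len > occupied[, 1] - min_separation)) next
        cp <- tmpl
        if (repeats$sub_rate[f] > 0) {
          nmut <- stats::rbinom(1, len, repeats$sub_rate[f])
          if (nmut) {
            at <- sample.int(len, nmut)
            cp[at] <- sample(bases, nmut, replace = TRUE)
          }
        }
        genome[(s + 1L):(s + len)] <- cp
        occupied <- rbind(occupied, c(s, s + len))
        placed <- placed + 1L
        copies <- rbind(copies, data.frame(
          family = repeats$family[f], copy = placed,
          start = s, end = s + len, strand = "+",
          stringsAsFactors = FALSE))
      }
      if (placed < repeats$copies[f])
        warning("placed only ", placed, " of ", repeats$copies[f],
                " copies of family ", repeats$family[f])
    }
  }
  copies <- copies[order(copies$start), , drop = FALSE]
  rownames(copies) <- NULL
  list(seq = paste(genome, collapse = ""), repeats = copies, size = size)
}

#' Derive contigs from a simulated genome
#'
#' The genome is tiled into contigs broken at every repeat-copy boundary
#' and at random breakpoints inside unique regions (mean unique contig
#' length about `target_len`). Each repeat family collapses to a single
#' repeat contig whose coverage is `copies * base_cov`; unique contigs get
#' Poisson-jittered base coverage. The truth table records where every
#' contig copy sits in the genome.
#'
#' @param genome result of [simulate_genome()].
#' @param seed integer seed for breakpoints and coverage jitter.
#' @param base_cov nominal per-base read coverage used for the coverage
#'   labels (default 40).
#' @param target_len target unique contig length (bp, default 20000).
#' @param min_len minimum contig piece length (bp, default 2000).
#' @return list with `contigs` (data.frame `id,length,coverage,class` --
#'   class as planted, for reference; classification is re-derived from
#'   coverage downstream), `truth` (data.frame `contig,start,end,strand,
#'   class,family`: one row per genome copy) and `size`.
#' @export
derive_contigs <- function(genome, seed, base_cov = 40, target_len = 20000,
                           min_len = 2000) {
  set.seed(seed)
  size <- genome$size
  reps <- genome$repeats
  ## unique intervals = complement of repeat copies
  bounds <- rbind(c(-1, 0), reps[, c("start", "end")], c(size, size + 1))
  uniq_iv <- NULL
  for (i in seq_len(nrow(bounds) - 1L)) {
    s <- bounds[i, 2]; e <- bounds[i + 1L, 1]
    if (e - s >= min_len) uniq_iv <- rbind(uniq_iv, c(s, e))
  }
  truth <- NULL
  contigs <- NULL
  uc <- 0L
  for (i in seq_len(nrow(uniq_iv))) {
    s <- uniq_iv[i, 1]; e <- uniq_iv[i, 2]
    n_pieces <- max(1L, round((e - s) / target_len))
    cuts <- s
    if (n_pieces > 1L) {
      inner <- sort(sample((s + min_len):(e - min_len), n_pieces - 1L))
      ## enforce minimum piece length
      inner <- inner[c(TRUE, diff(inner) >= min_len)]
      cuts <- c(cuts, inner)
    }
    cuts <- c(cuts, e)
    for (j in seq_len(length(cuts) - 1L)) {
      uc <- uc + 1L
      id <- sprintf("u%04d", uc)
      len <- cuts[j + 1L] - cuts[j]
      cov <- stats::rpois(1, base_cov * len) / len
      contigs <- rbind(contigs, data.frame(
        id = id, length = len, coverage = cov, class = "unique",
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        contig = id, start = cuts[j], end = cuts[j + 1L], strand = "+",
        class = "unique", family = NA_character_, stringsAsFactors = FALSE))
    }
  }
  if (nrow(reps)) {
    for (f in unique(reps$family)) {
      rf <- reps[reps$family == f, , drop = FALSE]
      id <- sprintf("r_%s", f)
      len <- rf$end[1] - rf$start[1]
      cov <- stats::rpois(1, base_cov * nrow(rf) * len) / len
      contigs <- rbind(contigs, data.frame(
        id = id, length = len, coverage = cov, class = "repeat",
        stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        contig = id, start = rf$start, end = rf$end, strand = rf$strand,
        class = "repeat", family = f, stringsAsFactors = FALSE))
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(contigs = contigs, truth = truth, size = size)
}

#' Sample S-hat observations from the truncated insert model
#'
#' Draws insert sizes from `Normal(mu, sigma)` conditioned on the
#' observable window `[g, g + l]` (a mate pair spanning a gap `g` between
#' flanks of total length `l` is only seen when its insert falls there) and
#' returns `S-hat = insert - g`, the contig sequence overlapped by each
#' insert.
#'
#' @param g true gap size (bp).
#' @param l total flank (contig length sum) in bp.
#' @param mu,sigma insert distribution parameters.
#' @param n number of observations.
#' @return numeric vector of S-hat values.
#' @export
simulate_truncated_shat <- function(g, l, mu, sigma, n = 100) {
  out <- numeric(0)
  while (length(out) < n) {
    I <- round(stats::rnorm(4 * n, mu, sigma))
    I <- I[I >= g & I <= g + l]
    out <- c(out, I - g)
  }
  out[seq_len(n)]
}

#' Simulate mate-pair mappings for one library
#'
#' Fragments are drawn uniformly over the genome with Normal(mu, sigma)
#' insert sizes; the two reads (outermost `rlen` bp of the fragment, inward
#' orientation by default) are mapped onto the contig copies that fully
#' contain them (repeat-copy hits map onto the collapsed repeat contig).
#' Pairs with a read crossing a contig boundary are dropped.
#'
#' @param tiling result of [derive_contigs()].
#' @param mu,sigma insert size mean/SD (bp).
#' @param rlen read length (bp).
#' @param pair_cov base-pair coverage contributed by the pairs (e.g. 2
#'   means `n = pair_cov * size / (2 * rlen)` pairs).
#' @param lib library id.
#' @param seed integer seed.
#' @param orientation `"inward"` (default), `"outward"` or `"same-strand"`.
#' @return mapping data.frame (`qname,mate,contig,pos,strand,rlen,lib`).
#' @export
simulate_mate_pairs <- function(tiling, mu, sigma, rlen = 50, pair_cov = 2,
                                lib = "lib1", seed = 1,
                                orientation = "inward") {
  set.seed(seed)
  size <- tiling$size
  n <- round(pair_cov * size / (2 * rlen))
  ins <- round(stats::rnorm(n, mu, sigma))
  ins <- pmax(ins, 2 * rlen + 1)
  start <- floor(stats::runif(n, 0, pmax(size - ins, 1)))
  r1s <- start; r1e <- start + rlen
  r2s <- start + ins - rlen; r2e <- start + ins
  tr <- tiling$truth
  ord <- order(tr$start)
  tr <- tr[ord, , drop = FALSE]
  map_read <- function(s, e) {
    i <- findInterval(s, tr$start)
    ok <- i >= 1 & i <= nrow(tr) & e <= tr$end[pmax(i, 1)]
    contig <- ifelse(ok, tr$contig[pmax(i, 1)], NA_character_)
    fwd <- tr$strand[pmax(i, 1)] == "+"
    pos <- ifelse(fwd, s - tr$start[pmax(i, 1)],
                  tr$end[pmax(i, 1)] - e)
    list(ok = ok, contig = contig, pos = pos, flip = !fwd)
  }
  m1 <- map_read(r1s, r1e)
  m2 <- map_read(r2s, r2e)
  keep <- m1$ok & m2$ok
  str1 <- rep("+", n); str2 <- rep("-", n)
  if (orientation == "outward") { str1 <- rep("-", n); str2 <- rep("+", n) }
  if (orientation == "same-strand") str2 <- str1
  flipc <- function(s, fl) ifelse(fl, ifelse(s == "+", "-", "+"), s)
  qn <- sprintf("%s_p%07d", lib, seq_len(n))
  out <- rbind(
    data.frame(qname = qn[keep], mate = 1L, contig = m1$contig[keep],
               pos = m1$pos[keep], strand = flipc(str1, m1$flip)[keep],
               rlen = rlen, lib = lib, stringsAsFactors = FALSE),
    data.frame(qname = qn[keep], mate = 2L, contig = m2$contig[keep],
               pos = m2$pos[keep], strand = flipc(str2, m2$flip)[keep],
               rlen = rlen, lib = lib, stringsAsFactors = FALSE))
  out <- out[order(out$qname, out$mate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
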