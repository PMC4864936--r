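test_that("FASTA reading yields one contig per record with byte-true lengths", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ctgA some description", strrep("ACGT", 25),
               ">ctgB", paste(strrep("acgtn", 50))), fa)
  res <- read_contigs_fasta(fa)
  expect_equal(res$contigs$id, c("ctgA", "ctgB"))
  expect_equal(res$contigs$length, c(100, 250))

  ## wrapped lines parse to the same lengths as unwrapped (byte-count oracle)
  set.seed(3)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 137, replace = TRUE),
                collapse = "")
  wrapped <- tempfile(fileext = ".fa")
  writeLines(c(">w", substring(seq1, seq(1, 137, 60),
                               pmin(seq(1, 137, 60) + 59, 137))), wrapped)
  unwrapped <- tempfile(fileext = ".fa")
  writeLines(c(">w", seq1), unwrapped)
  expect_equal(read_contigs_fasta(wrapped)$contigs$length, nchar(seq1))
  expect_equal(read_contigs_fasta(wrapped)$contigs$length,
               read_contigs_fasta(unwrapped)$contigs$length)

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "GGCC"), dup)
  expect_error(read_contigs_fasta(dup), "duplicate.*x")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(read_contigs_fasta(empty))
})

test_that("SAM pairing converts coordinates and drops orphans", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ctgA\tLN:10000",
    "p1\t65\tctgA\t1\t60\t50M\t*\t0\t0\t*\t*",    # mate 1, POS=1 -> 0
    "p1\t145\tctgA\t3001\t60\t50M\t*\t0\t0\t*\t*", # mate 2, minus strand
    "p2\t65\tctgA\t100\t60\t50M\t*\t0\t0\t*\t*",
    "p2\t133\t*\t0\t0\t*\t*\t0\t0\t*\t*"           # mate 2 unmapped
  ), sam)
  expect_message(m <- read_sam_pairs(sam, lib = "L"), "unpaired")
  expect_equal(sort(unique(m$qname)), "p1")
  expect_equal(m$pos[m$mate == 1], 0)               # POS - 1
  expect_equal(m$pos[m$mate == 2], 3000)
  expect_equal(m$strand[m$mate == 2], "-")
  expect_error(
    read_sam_pairs(sam, contigs = data.frame(id = "other", length = 1)),
    "ctgA")
})

test_that("SAM write/read round trip is a coordinate bijection", {
  sim <- small_sim()
  mp <- utils::head(sim$mp, 200)
  sam <- tempfile(fileext = ".sam")
  write_sam(mp, sim$til$contigs, sam)
  back <- suppressMessages(read_sam_pairs(sam, lib = mp$lib[1]))
  key <- function(d) d[order(d$qname, d$mate),
                       c("qname", "mate", "contig", "pos", "strand", "rlen")]
  expect_equal(key(back), key(mp), ignore_attr = TRUE)
})

test_that("AGP + FASTA rendering matches the scaffold structure", {
  seqs <- random_seqs(c("A", "B"), c(120, 80))
  sc <- list(s1 = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                             start = c(0, 220), end = c(120, 300)))
  agp <- tempfile(fileext = ".agp"); fa <- tempfile(fileext = ".fa")
  write_scaffolds(sc, seqs, agp, fa)
  lines <- readLines(agp)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 3)                            # W, N, W
  expect_equal(strsplit(body[2], "\t")[[1]][5:6], c("N", "100"))
  rendered <- as.character(Biostrings::readDNAStringSet(fa))[[1]]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqs[["B"]])))
  expect_equal(rendered, paste0(seqs[["A"]], strrep("N", 100), rc))
  ## total scaffolded bases conserved
  expect_equal(sum(Biostrings::width(Biostrings::readDNAStringSet(fa))) - 100,
               sum(nchar(seqs)))
})

test_that("negative gaps render as 1 N with the estimate preserved", {
  seqs <- random_seqs(c("A", "B"), c(60, 60))
  sc <- list(s1 = data.frame(contig = c("A", "B"), orient = c("+", "+"),
                             start = c(0, 10), end = c(60, 70)))  # gap -50
  agp <- tempfile(); fa <- tempfile()
  write_scaffolds(sc, seqs, agp, fa)
  nline <- grep("\tN\t", readLines(agp), value = TRUE)
  f <- strsplit(nline, "\t")[[1]]
  expect_equal(f[6], "1")
  expect_equal(f[10], "est_gap=-50")
  expect_equal(nchar(as.character(Biostrings::readDNAStringSet(fa))[[1]]), 121)
})

test_that("single-contig scaffolds write one AGP line and AGP round-trips", {
  seqs <- random_seqs(c("A", "B", "C"), c(100, 90, 70))
  sc <- list(
    s1 = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                    start = c(0, 150), end = c(100, 240)),
    s2 = data.frame(contig = "C", orient = "+", start = 0, end = 70))
  agp <- tempfile()
  write_scaffolds(sc, seqs, agp)
  lines <- readLines(agp)
  expect_equal(sum(grepl("^s2\t", lines)), 1)
  back <- read_agp(agp)
  expect_equal(back$s1$contig, sc$s1$contig)
  expect_equal(back$s1$orient, sc$s1$orient)
  expect_equal(back$s1$start, sc$s1$start)
  expect_equal(back$s2$end, 70)
  expect_equal(attr(back, "gap_estimates")$s1, 50)
})

test_that("link TSV reading validates and preserves duplicates", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("ctgA\t+\tctgB\t-\t1200\t7",
               "ctgA\t+\tctgB\t-\t1200\t7"), tsv)
  d <- read_links_tsv(tsv)
  expect_equal(nrow(d), 2)           # de-duplication is downstream's job
  expect_equal(d$distance[1], 1200)
  bad <- tempfile()
  writeLines("ctgA\t+\tctgB\t-\t-5\t7", bad)
  expect_error(read_links_tsv(bad), "negative")
  expect_error(read_links_tsv(tsv, contigs = data.frame(id = "ctgA")),
               "ctgB")
})

test_that("configuration defaults, file parsing and unknown keys", {
  cfg <- scafex_config()
  expect_equal(cfg$repeat_factor, 1.5)
  expect_equal(cfg$edge_support, 5)
  expect_equal(cfg$sd_multiplier, 6)
  expect_equal(cfg$state_cap, 1e6)
  expect_equal(cfg$support_step, 1)
  expect_equal(cfg$stage_boundaries, c(1000, 10000))
  expect_equal(scafex_config(edge_support = 1)$edge_support, 1)
  f <- tempfile()
  writeLines(c("edge_support = 3", "# comment", "memo = FALSE"), f)
  cfg2 <- scafex_config(f)
  expect_equal(cfg2$edge_support, 3)
  expect_false(cfg2$memo)
  expect_error(scafex_config(no_such_key = 1), "no_such_key")
})
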