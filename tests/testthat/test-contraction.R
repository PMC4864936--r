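## chain A - B - X - C - D with long border X
bordered_chain <- function() {
  ct <- data.frame(id = c("A", "B", "X", "C", "D"),
                   length = c(3000, 4000, 40000, 3500, 3000),
                   coverage = 40, class = "unique")
  e <- data.frame(c1 = c("A", "B", "X", "C"), o1 = "+",
                  c2 = c("B", "X", "C", "D"), o2 = "+",
                  gap = c(500, 600, 700, 800), sd = 100, support = 10)
  scaffold_graph(ct, e)
}

test_that("border contigs are long unique contigs only", {
  ct <- data.frame(id = c("a", "b", "r"), length = c(20000, 15000, 50000),
                   coverage = c(40, 40, 120),
                   class = c("unique", "unique", "repeat"))
  g <- scaffold_graph(ct)
  expect_equal(find_border_contigs(g, 16000), "a")
})

test_that("decomposition closes components with their borders and shares repeats", {
  g <- bordered_chain()
  subs <- decompose_graph(g, "X")
  expect_length(subs, 2)
  sets <- lapply(subs, function(s) sort(s$contigs$id))
  expect_true(list(c("A", "B", "X")) %in% sets || any(
    vapply(sets, identical, logical(1), y = c("A", "B", "X"))))
  expect_true(any(vapply(sets, identical, logical(1), y = c("C", "D", "X"))))
  ## every unique-unique edge appears in exactly one subgraph
  all_ids <- unlist(lapply(subs, function(s) s$edges$id))
  expect_equal(sort(all_ids), sort(g$edges$id))

  ## a repeat with edges into both components joins both subgraphs
  ct <- rbind(g$contigs, data.frame(id = "R", length = 1000, coverage = 120,
                                    class = "repeat"))
  e <- rbind(g$edges[, -1],
             data.frame(c1 = c("B", "C"), o1 = "+", c2 = c("R", "R"),
                        o2 = "+", gap = 200, sd = 50, support = 8,
                        lib = NA))
  g2 <- scaffold_graph(ct, e)
  subs2 <- decompose_graph(g2, "X")
  expect_true(all(vapply(subs2, function(s) "R" %in% s$contigs$id,
                         logical(1))))

  ## no borders: a single subgraph covering the whole graph
  subs3 <- decompose_graph(g, character())
  expect_length(subs3, 1)
  expect_setequal(subs3[[1]]$contigs$id, g$contigs$id)
})

test_that("stitching joins at shared borders with orientation reconciliation", {
  s1 <- data.frame(contig = c("A", "B", "X"), orient = "+",
                   start = c(0, 3500, 8100), end = c(3000, 7500, 48100))
  s2 <- data.frame(contig = c("X", "C", "D"), orient = "+",
                   start = c(0, 40700, 45000), end = c(40000, 44200, 48000))
  st <- stitch_scaffolds(list(s1, s2), "X")
  expect_length(st, 1)
  expect_equal(st[[1]]$contig, c("A", "B", "X", "C", "D"))
  expect_equal(st[[1]]$orient, rep("+", 5))
  ## per-subgraph order preserved; offsets relative to the border kept
  expect_equal(diff(st[[1]]$start[3:4]), 40700)

  ## reversed second scaffold is flipped before joining
  s2r <- data.frame(contig = c("D", "C", "X"), orient = "-",
                    start = c(0, 3800, 8000), end = c(3000, 7300, 48000))
  st2 <- stitch_scaffolds(list(s1, s2r), "X")
  expect_length(st2, 1)
  expect_equal(st2[[1]]$contig, c("A", "B", "X", "C", "D"))

  ## a border held by a single scaffold stays a scaffold end
  st3 <- stitch_scaffolds(list(s1), "X")
  expect_identical(st3, list(s1))

  ## interior unique contig past the border is an invariant breach
  bad <- data.frame(contig = c("A", "X", "B"), orient = "+",
                    start = c(0, 3500, 44000), end = c(3000, 43500, 48000))
  expect_error(stitch_scaffolds(list(bad, s2), "X"), "interior")
})

test_that("stitched subgraph optima equal whole-graph optima on planted borders", {
  cfg <- scafex_config()
  for (seed in 0:9) {
    fg <- random_fenced_graph(seed)
    bf <- brute_force_scaffold(fg$graph, cfg)
    borders <- find_border_contigs(fg$graph, fg$span_bound)
    subs <- decompose_graph(fg$graph, borders)
    res <- lapply(subs, scaffold_subgraph, config = cfg)
    ktot <- sum(vapply(res, `[[`, integer(1), "k"))
    stitched <- stitch_scaffolds(
      unlist(lapply(res, `[[`, "scaffolds"), recursive = FALSE), borders)
    expect_equal(ktot, bf$k, info = paste("seed", seed))
    ## stitch preserves contig order up to whole-scaffold reversal
    for (s in stitched) {
      expect_true(all(s$contig %in% fg$graph$contigs$id))
    }
  }
})
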