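test_that("edge concordance windows and orientation checks", {
  edge <- data.frame(c1 = "A", o1 = "+", c2 = "B", o2 = "+",
                     gap = 3000, sd = 300)
  pl <- function(gapAB, oB = "+") data.frame(
    contig = c("A", "B"), orient = c("+", oB),
    start = c(0, 2000 + gapAB), end = c(2000, 2000 + gapAB + 1500))
  expect_true(is_concordant(edge, pl(3500)))      # window [1200, 4800]
  expect_false(is_concordant(edge, pl(10000)))    # distance violated
  expect_false(is_concordant(edge, pl(3000, oB = "-")))  # orientation
  ## reversed placement satisfies via the flipped form
  plr <- data.frame(contig = c("B", "A"), orient = c("-", "-"),
                    start = c(0, 4500), end = c(1500, 6500))
  expect_true(is_concordant(edge, plr))
})

test_that("extension bookkeeping: concordant chains, reach-death, repeat proposals", {
  g <- chain_graph()
  st <- new_search_state(g, "A", "+")
  st <- extend_state(st, "B", "+")
  st <- extend_state(st, "C", "+")
  expect_equal(state_discordant(st), 0)

  ## extending past an unsatisfied dangling edge's reach makes it discordant
  ct <- data.frame(id = c("A", "B", "C"), length = c(3000, 3000, 3000))
  e <- data.frame(c1 = c("A", "A"), o1 = "+", c2 = c("B", "C"), o2 = "+",
                  gap = c(200, 200), sd = c(30, 30), support = 10)
  g2 <- scaffold_graph(ct, e)
  st2 <- new_search_state(g2, "A", "+")
  st2 <- extend_state(st2, "C", "+")   # occupies B's window
  st2 <- extend_state(st2, "B", "+")   # B now far beyond A's reach
  expect_equal(state_discordant(st2), 1)

  ## a repeat is proposed via a unique anchor but proposes nothing itself
  g3 <- repeat_bridge_graph()
  st3 <- new_search_state(g3, "A", "+")
  cand <- order_extensions(st3)
  expect_true("R" %in% cand$contig)
  expect_equal(cand$contig[1], "R")              # nearer candidate first
  st3 <- extend_state(st3, "R", "+")
  cand2 <- order_extensions(st3)
  ## C is proposed by A's spanning edge, not by the placed repeat
  expect_true("C" %in% cand2$contig)
  st3 <- extend_state(st3, "C", "+")
  expect_equal(state_discordant(st3), 0)
})

test_that("extension ordering uses BFS distances with path down-weighting", {
  ## candidate B at 500; candidate D reachable at 1000 (1 edge) and
  ## 400 + 1000 + 1600 = 3000 (2 edges via C): weighted mean
  ## (2/3)*1000 + (1/3)*3000 = 1667
  ct <- data.frame(id = c("A", "B", "C", "D"),
                   length = c(3000, 2000, 1000, 2000))
  e <- data.frame(c1 = c("A", "A", "A", "C"), o1 = "+",
                  c2 = c("B", "D", "C", "D"), o2 = "+",
                  gap = c(500, 1000, 400, 1600), sd = 200, support = 10)
  g <- scaffold_graph(ct, e)
  st <- new_search_state(g, "A", "+")
  cand <- order_extensions(st)
  expect_equal(cand$contig, c("C", "B", "D"))   # ascending distance
  d_D <- cand$distance[cand$contig == "D"][1]
  expect_equal(d_D, 2 / 3 * 1000 + 1 / 3 * 3000, tolerance = 1e-6)
})

test_that("repeat confirmation retains essential instances and drops speculative ones", {
  g <- repeat_bridge_graph()
  st <- new_search_state(g, "A", "+")
  st <- extend_state(st, "R", "+")
  ## repeat still within reach of the tail: untouched
  st_c <- confirm_repeats(st)
  expect_equal(nrow(state_placement(st_c)), 2)
  st <- extend_state(st, "C", "+")
  ## force the confirmation window to zero: R is out of reach, but its
  ## removal would break the satisfied A-R and R-C edges -> retained
  st_c2 <- confirm_repeats(st, bound = 0)
  expect_true("R" %in% state_placement(st_c2)$contig)

  ## a speculative instance whose edges are all satisfied elsewhere is
  ## removed once out of reach
  ct <- data.frame(id = c("A", "B", "R"), length = c(3000, 3000, 800),
                   coverage = c(40, 40, 120),
                   class = c("unique", "unique", "repeat"))
  e <- data.frame(c1 = c("A", "A"), o1 = "+", c2 = c("B", "R"), o2 = "+",
                  gap = c(500, 400), sd = c(100, 80), support = 10)
  g4 <- scaffold_graph(ct, e)
  st4 <- new_search_state(g4, "A", "+")
  st4 <- extend_state(st4, "R", "+")   # satisfies A-R
  st4 <- extend_state(st4, "R", "+")   # second instance satisfies nothing new
  expect_equal(sum(state_placement(st4)$contig == "R"), 2)
  st4 <- confirm_repeats(st4, bound = 0)
  expect_equal(sum(state_placement(st4)$contig == "R"), 1)
})

test_that("subgraph search solves the worked examples exactly", {
  cfg <- scafex_config()
  r <- scaffold_subgraph(chain_graph(), cfg)
  expect_equal(r$k, 0)
  sc <- r$scaffolds[[1]]
  expect_true(identical(sc$contig, c("A", "B", "C")) ||
                identical(sc$contig, c("C", "B", "A")))

  r2 <- scaffold_subgraph(triangle_graph(), cfg)
  expect_equal(r2$k, brute_force_scaffold(triangle_graph(), cfg)$k)
  expect_equal(r2$k, 1)

  r3 <- scaffold_subgraph(repeat_bridge_graph(), cfg)
  expect_equal(r3$k, 0)
  sc3 <- r3$scaffolds[[1]]
  expect_true("R" %in% sc3$contig)
  ## dropping the repeat instance strictly increases discordance
  idx <- which(sc3$contig == "R")
  reduced <- sc3[-idx, , drop = FALSE]
  expect_gt(count_discordant(repeat_bridge_graph(), reduced, cfg), 0)

  ## a subgraph of only repeats yields singletons
  ct <- data.frame(id = c("r1", "r2"), length = c(1000, 1200),
                   coverage = 120, class = "repeat")
  r4 <- scaffold_subgraph(scaffold_graph(ct), cfg)
  expect_length(r4$scaffolds, 2)
})

test_that("search equals the brute-force oracle on random graphs", {
  cfg <- scafex_config()
  for (seed in 0:29) {
    rg <- random_scaffold_graph(seed)
    bf <- brute_force_scaffold(rg$graph, cfg)
    sr <- scaffold_subgraph(rg$graph, cfg)
    expect_equal(sr$k, bf$k, info = paste("seed", seed))
  }
})

test_that("reversing every edge yields the reversed scaffold with equal k", {
  cfg <- scafex_config()
  for (seed in c(1, 5, 12, 23)) {
    rg <- random_scaffold_graph(seed)
    g <- rg$graph
    rev_e <- g$edges[, -1]
    rev_e$o1 <- ifelse(rev_e$o1 == "+", "-", "+")
    rev_e$o2 <- ifelse(rev_e$o2 == "+", "-", "+")
    tmp <- rev_e$c1; tmp_o <- rev_e$o1
    rev_e$c1 <- rev_e$c2; rev_e$o1 <- rev_e$o2
    rev_e$c2 <- tmp; rev_e$o2 <- tmp_o
    g_rev <- scaffold_graph(g$contigs, rev_e)
    expect_equal(scaffold_subgraph(g_rev, cfg)$k,
                 scaffold_subgraph(g, cfg)$k, info = paste("seed", seed))
  }
})

test_that("memoization is sound and the state cap triggers the hybrid fallback", {
  for (seed in c(3, 17, 48)) {
    rg <- random_scaffold_graph(seed)
    on <- scaffold_subgraph(rg$graph, scafex_config(memo = TRUE))
    off <- scaffold_subgraph(rg$graph, scafex_config(memo = FALSE))
    expect_identical(on$scaffolds, off$scaffolds)
    expect_lte(on$n_states, off$n_states)
  }
  r <- scaffold_subgraph(dense_conflict_graph(), scafex_config(state_cap = 100))
  expect_true(r$flagged)
  expect_gt(r$support_threshold, 2)
  ## the escalated search still recovers the well-supported chain
  expect_equal(r$k, 0)
})
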