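## Shared fixtures: tiny graphs and a small simulated dataset, all built in
## code at test time.

chain_graph <- function() {
  scaffold_graph(
    data.frame(id = c("A", "B", "C"), length = c(3000, 4000, 3500)),
    data.frame(c1 = c("A", "B"), o1 = c("+", "+"),
               c2 = c("B", "C"), o2 = c("+", "+"),
               gap = c(500, 800), sd = c(100, 100), support = c(10, 10)))
}

## chain with one edge contradicting the implied order
triangle_graph <- function() {
  scaffold_graph(
    data.frame(id = c("A", "B", "C"), length = c(3000, 4000, 3500)),
    data.frame(c1 = c("A", "B", "A"), o1 = c("+", "+", "+"),
               c2 = c("B", "C", "C"), o2 = c("+", "+", "-"),
               gap = c(500, 800, 700), sd = c(100, 100, 100),
               support = c(10, 10, 6)))
}

## unique A, C + repeat R bridging them; flank gaps sum to the A-C estimate
repeat_bridge_graph <- function() {
  scaffold_graph(
    data.frame(id = c("A", "C", "R"), length = c(3000, 3500, 1200),
               coverage = c(40, 40, 120),
               class = c("unique", "unique", "repeat")),
    data.frame(c1 = c("A", "R", "A"), o1 = c("+", "+", "+"),
               c2 = c("R", "C", "C"), o2 = c("+", "+", "+"),
               gap = c(400, 600, 2200), sd = c(80, 80, 150),
               support = c(8, 8, 12)))
}

## dense graph with weakly supported conflicting edges: used to force the
## hybrid-exact fallback under a small state cap
dense_conflict_graph <- function() {
  ct <- data.frame(id = sprintf("c%d", 1:8), length = 3000)
  ed <- NULL
  for (i in 1:7)
    ed <- rbind(ed, data.frame(c1 = sprintf("c%d", i), o1 = "+",
                               c2 = sprintf("c%d", i + 1), o2 = "+",
                               gap = 500, sd = 100, support = 20))
  set.seed(9)
  for (b in 1:6) {
    pr <- sample(1:8, 2)
    ed <- rbind(ed, data.frame(
      c1 = sprintf("c%d", pr[1]), o1 = sample(c("+", "-"), 1),
      c2 = sprintf("c%d", pr[2]), o2 = sample(c("+", "-"), 1),
      gap = sample(0:8000, 1), sd = 100, support = 2))
  }
  scaffold_graph(ct, ed)
}

## small simulated dataset shared across tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rep_spec <- data.frame(family = c("fa", "fb"),
                             length = c(3000, 4000), copies = c(2, 2))
      gen <- simulate_genome(seed = 5, size = 3e5, repeats = rep_spec)
      til <- derive_contigs(gen, seed = 6, base_cov = 40)
      mp <- rbind(
        simulate_mate_pairs(til, 3000, 300, pair_cov = 2, lib = "mp3k",
                            seed = 7),
        simulate_mate_pairs(til, 10000, 1000, pair_cov = 2, lib = "mp10k",
                            seed = 8))
      cache <<- list(gen = gen, til = til, mp = mp)
    }
    cache
  }
})

random_seqs <- function(ids, lengths, seed = 1) {
  set.seed(seed)
  out <- vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(out) <- ids
  out
}
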