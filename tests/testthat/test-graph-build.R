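test_that("coverage classification uses the length-weighted mean and a strict threshold", {
  ct <- data.frame(id = c("a", "b"), length = c(1e5, 1e5),
                   coverage = c(10, 70))          # weighted mean 40
  r <- classify_contigs(ct, factor = 1.5)
  expect_equal(r$mean_coverage, 40)
  expect_equal(r$contigs$class, c("unique", "repeat"))  # 70 >= 60
  ct2 <- data.frame(id = c("a", "b"), length = c(1e5, 1e5),
                    coverage = c(20, 60))
  expect_equal(classify_contigs(ct2, factor = 1.5)$contigs$class[2],
               "repeat")                          # exactly at threshold
  expect_equal(classify_contigs(ct, factor = 2.0)$contigs$class[2],
               "unique")                          # 70 < 80
})

test_that("pair bundling groups by contig pair and orientation class", {
  ctg <- data.frame(id = c("A", "B"), length = c(5000, 6000))
  lb <- structure(list(orientation = "inward", sigma = 100), class = "mate_library")
  mk <- function(qn, s1, s2, p1 = 4900, p2 = 10) rbind(
    data.frame(qname = qn, mate = 1L, contig = "A", pos = p1, strand = s1,
               rlen = 50, lib = "L"),
    data.frame(qname = qn, mate = 2L, contig = "B", pos = p2, strand = s2,
               rlen = 50, lib = "L"))
  m <- do.call(rbind, lapply(sprintf("q%d", 1:5), mk, s1 = "+", s2 = "-"))
  raw <- bundle_pairs(lb, m, ctg)
  expect_equal(nrow(raw), 1)
  expect_equal(raw$support, 5)
  ## S-hat = overhang on A (5000-4900) + overhang on B (10+50)
  expect_equal(raw$shat[[1]], rep(100 + 60, 5))

  m2 <- rbind(m, do.call(rbind, lapply(sprintf("r%d", 1:3), mk,
                                       s1 = "+", s2 = "+")))
  raw2 <- bundle_pairs(lb, m2, ctg)
  expect_equal(nrow(raw2), 2)                     # two orientation classes

  same <- rbind(
    data.frame(qname = "s", mate = 1L, contig = "A", pos = 0, strand = "+",
               rlen = 50, lib = "L"),
    data.frame(qname = "s", mate = 2L, contig = "A", pos = 2000,
               strand = "-", rlen = 50, lib = "L"))
  expect_equal(nrow(bundle_pairs(lb, same, ctg)), 0)  # same-contig: no edge
})

test_that("lookup tables match closed forms and are monotone", {
  ## point mass at 3000: no truncation effect while g <= 3000
  pm <- insert_model(rep(3000, 100), L = 3000)
  tab <- build_lookup_table(pm, 100000)
  expect_equal(tab$es[tab$g %in% c(0, 1000, 2500)],
               3000 - c(0, 1000, 2500))
  ## discrete uniform on [2000, 4000]
  un <- insert_model(2000:4000, L = 4500)
  t1 <- build_lookup_table(un, 3000)   # C = g + 3000
  expect_equal(t1$es[t1$g == 1500], 3000 - 1500)   # window [1500,4500]
  t2 <- build_lookup_table(un, 1000)
  expect_equal(t2$es[t2$g == 2500], 500)           # E(I|[2500,3500]) = 3000
  ## E(S-hat) non-increasing in g wherever defined
  for (mod in list(un, normal_insert_model(3000, 300))) {
    for (l in c(1000, 4000)) {
      es <- build_lookup_table(mod, l)$es
      d <- diff(es[!is.na(es)])
      expect_true(all(d <= 1e-9))
    }
  }
})

test_that("edge gap estimation inverts the table and sets the SD", {
  pm <- insert_model(rep(3000, 100), L = 3000)
  est <- estimate_edge_gap(rep(2400, 25), 100000, pm, sigma = 120)
  expect_equal(est$gap, 600)                      # inversion of 3000 - g
  expect_equal(est$sd, 120 / 5)
  one <- estimate_edge_gap(2400, 100000, pm, sigma = 120)
  expect_equal(one$sd, 120)                       # single observation
  clamped <- estimate_edge_gap(rep(5000, 10), 100000, pm, sigma = 120)
  expect_true(clamped$flagged)
  expect_equal(clamped$gap, 0)
})

test_that("truncation-corrected estimator recovers gaps where the naive one is biased", {
  set.seed(11)
  mu <- 10000; sigma <- 1000; l <- 4000
  model <- normal_insert_model(mu, sigma)
  for (g in c(3000, 9000, 12000)) {
    shat <- simulate_truncated_shat(g, l, mu, sigma, n = 200)
    est <- estimate_edge_gap(shat, l, model, sigma = sigma)
    expect_lt(abs(est$gap - g), 500 + 3 * sigma / sqrt(200))
  }
  shat <- simulate_truncated_shat(12000, l, mu, sigma, n = 200)
  expect_lt(naive_gap_estimate(shat, mu), 12000 - 1000)  # strong underestimate
})

test_that("multi-library edge merging follows the clustering and conflict rules", {
  ct <- data.frame(id = c("A", "B", "R"), length = c(5000, 5000, 1000),
                   coverage = c(40, 40, 120),
                   class = c("unique", "unique", "repeat"))
  e <- data.frame(c1 = "A", o1 = "+", c2 = "B", o2 = "+",
                  gap = c(5000, 5200), sd = c(300, 400),
                  support = c(10, 6), lib = c("l1", "l2"))
  m <- merge_libraries(e, ct)
  expect_equal(nrow(m), 1)
  expect_equal(m$gap, 5072, tolerance = 1e-3)
  expect_equal(m$sd, 240, tolerance = 1e-3)
  expect_equal(m$support, 16)

  single <- merge_libraries(e[1, ], ct)
  expect_equal(single$gap, 5000)
  expect_equal(single$support, 10)

  ## two surviving clusters between unique contigs: max support wins
  e2 <- data.frame(c1 = "A", o1 = "+", c2 = "B", o2 = "+",
                   gap = c(3000, 20000), sd = c(100, 100),
                   support = c(8, 3), lib = c("l1", "l2"))
  m2 <- merge_libraries(e2, ct)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$support, 8)

  ## pairs involving a repeat retain all clusters
  e3 <- e2; e3$c2 <- "R"
  e3 <- canonicalize_edges(e3)
  expect_equal(nrow(merge_libraries(e3, ct)), 2)
})

test_that("contig-size and support filters follow max(500, 2x PE insert)", {
  ct <- data.frame(id = c("s", "t", "u"), length = c(550, 700, 5000),
                   coverage = 40, class = "unique")
  e <- data.frame(c1 = c("t", "t"), o1 = "+", c2 = c("u", "u"), o2 = "+",
                  gap = c(100, 3000), sd = 50, support = c(4, 5))
  g <- scaffold_graph(ct, e)
  f <- apply_filters(g, scafex_config(pe_insert = 300))
  expect_equal(f$singletons, "s")                       # 550 < 600
  expect_equal(nrow(f$graph$edges), 1)                  # support 4 dropped
  f1 <- apply_filters(g, scafex_config(pe_insert = 300, edge_support = 1))
  expect_equal(nrow(f1$graph$edges), 2)                 # long-read mode
  ## never removes a contig above threshold; endpoints stay valid
  expect_true(all(f$graph$edges$c1 %in% f$graph$contigs$id))
})

test_that("library staging partitions by insert size with inclusive bounds", {
  libs <- lapply(c(300, 3000, 10000, 20000), function(mu)
    structure(list(id = paste0("l", mu), mu = mu), class = "mate_library"))
  st <- stage_libraries(libs)
  expect_length(st, 3)
  expect_equal(vapply(st[[2]], `[[`, numeric(1), "mu"), c(3000, 10000))
  expect_length(stage_libraries(libs[2]), 1)
  ## staging disabled: one stage with everything
  expect_length(stage_libraries(libs, boundaries = numeric()), 1)
})
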