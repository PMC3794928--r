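test_that("adjacent pairs classify in genomic order", {
  g <- toy_genome(data.frame(start = c(100, 3000, 6000, 9000, 12000),
                             end = c(1000, 4000, 7000, 10000, 13000),
                             strand = "+"))
  st <- toy_statuses(g, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  np <- neighbor_pair_analysis(st, g, n_perm = 50, seed = 1,
                               top_scaffolds = 10)
  expect_equal(np$pairs$class, c("MM", "MN", "NN", "NM"))
  expect_equal(unname(np$class_counts), rep(1L, 4))
  expect_equal(np$pairs$distance[1], 3000 - 1000 - 1)
})

test_that("a single-label scaffold gives degenerate permutation p = 1", {
  g <- toy_genome(data.frame(start = seq(100, by = 2000, length.out = 8),
                             end = seq(100, by = 2000, length.out = 8) + 900,
                             strand = "+"))
  st <- toy_statuses(g, rep(TRUE, 8))
  np <- neighbor_pair_analysis(st, g, n_perm = 99, seed = 2,
                               top_scaffolds = 10)
  expect_equal(np$perm$MM$p, 1)
})

test_that("permutation engine is reproducible and seed-sensitive", {
  set.seed(99)
  starts <- cumsum(sample(1200:3000, 30))
  g <- toy_genome(data.frame(start = starts, end = starts + 800,
                             strand = "+"), scaffold_length = 100000L)
  st <- toy_statuses(g, runif(30) < 0.4)
  a <- neighbor_pair_analysis(st, g, n_perm = 200, seed = 5, top_scaffolds = 5)
  b <- neighbor_pair_analysis(st, g, n_perm = 200, seed = 5, top_scaffolds = 5)
  c <- neighbor_pair_analysis(st, g, n_perm = 200, seed = 6, top_scaffolds = 5)
  expect_identical(a$perm$MM$null, b$perm$MM$null)
  expect_false(identical(a$perm$MM$null, c$perm$MM$null))
  ## null means stable across seeds within Monte-Carlo error
  expect_lt(abs(mean(a$perm$MM$null, na.rm = TRUE) - mean(c$perm$MM$null, na.rm = TRUE)),
            4 * stats::sd(a$perm$MM$null, na.rm = TRUE) / sqrt(200))
})

test_that("run tallies and mean length follow the definition", {
  g <- toy_genome(data.frame(start = seq(100, by = 1200, length.out = 6),
                             end = seq(100, by = 1200, length.out = 6) + 700,
                             strand = "+"))
  st <- toy_statuses(g, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  rl <- run_length_analysis(st, g, null = "analytic", top_scaffolds = 5)
  expect_equal(unname(rl$observed[c("2", "3")]), c(1, 1))
  expect_equal(rl$mean_run_length, 2.5)
  ## conservation: sum(length x count) = methylated genes
  lens <- as.integer(names(rl$observed))
  expect_equal(sum(lens * rl$observed), rl$n_methylated)
})

test_that("analytic and permutation run-length nulls agree", {
  g <- toy_genome(data.frame(start = seq(100, by = 180,
                                         length.out = 1000),
                             end = seq(100, by = 180, length.out = 1000) + 80,
                             strand = "+"), scaffold_length = 200000L)
  set.seed(7)
  st <- toy_statuses(g, runif(1000) < 0.3)
  an <- run_length_analysis(st, g, null = "analytic", top_scaffolds = 5)
  pe <- run_length_analysis(st, g, null = "permutation", n_perm = 3000,
                            seed = 8, top_scaffolds = 5)
  k <- seq_len(min(6, length(an$expected), length(pe$expected)))
  mc_se <- sqrt(pmax(an$expected[k], 1) / 3000) * 3 + 0.05 * an$expected[k]
  expect_true(all(abs(an$expected[k] - pe$expected[k]) < 3 * mc_se + 0.5))
  ## totals: expected runs weighted by length account for all methylated
  lens <- seq_along(an$expected)
  expect_equal(sum(lens * an$expected), an$n_methylated, tolerance = 1e-6)
})

test_that("clustered labels shorten MM distances against the null", {
  set.seed(10)
  n <- 200
  g <- toy_genome(data.frame(start = seq(100, by = 1500, length.out = n),
                             end = seq(100, by = 1500, length.out = n) + 700,
                             strand = "+"), scaffold_length = 400000L)
  lab <- methatlas:::label_chain(n, 0.3, 0.7)
  ## push methylated genes together physically: shrink gaps inside runs
  st <- toy_statuses(g, lab)
  ## with sticky labels the MM count is inflated vs the permutation null
  np <- neighbor_pair_analysis(st, g, n_perm = 500, seed = 3,
                               top_scaffolds = 5)
  obs_mm <- np$class_counts["MM"]
  null_mean <- mean(vapply(seq_len(200), function(i) {
    sh <- sample(lab)
    sum(sh[-n] & sh[-1])
  }, 0))
  expect_gt(obs_mm, null_mean)
})

test_that("sticky simulated genomes show short MM distances vs the null", {
  ## replicated calibration: with strong stickiness, most simulated genomes
  ## put the observed MM mean distance below the null 2.5th percentile;
  ## under a 5%-level null this would happen ~2.5% of the time
  below <- low_p <- 0L
  for (sd in 44:51) {
    cfg <- sim_config(seed = sd, n_scaffolds = 12, n_genes = 160,
                      cluster_stickiness = 0.6, n_te = 0)
    g <- simulate_genome(cfg)
    st <- toy_statuses(g, g$genes$methylated)   # truth labels as statuses
    np <- neighbor_pair_analysis(st, g, n_perm = 500, seed = 4,
                                 top_scaffolds = 20)
    null <- np$perm$MM$null
    below <- below + (np$mean_distance["MM"] <
                        quantile(null, 0.025, na.rm = TRUE))
    low_p <- low_p + (np$perm$MM$p < 0.05)
  }
  expect_gte(below, 4L)    # P(>=4/8 at 2.5%) ~ 2e-5 without signal
  expect_gte(low_p, 3L)    # two-sided p is less powered; P(>=3/8) ~ 5e-3
})

test_that("orientation geometry maps strands to head/tail classes", {
  g <- toy_genome(data.frame(start = c(1000, 2300, 4000, 5200),
                             end = c(2000, 3300, 5000, 6100),
                             strand = c("-", "+", "+", "-")))
  st <- toy_statuses(g, c(TRUE, TRUE, FALSE, FALSE))
  oe <- orientation_enrichment(st, g, max_gap = 1000, top_scaffolds = 5)
  ## pair 1-2: (-,+) with 5' ends facing the 300 bp gap -> head-head
  ## pair 2-3: (+,+) -> tail-head; pair 3-4: (+,-) -> tail-tail
  expect_equal(oe$n_pairs[oe$orientation == "HH"], 1L)
  expect_equal(oe$n_pairs[oe$orientation == "TH"], 1L)
  expect_equal(oe$n_pairs[oe$orientation == "TT"], 1L)
  expect_equal(oe$n_pairs[oe$orientation == "HT"], 0L)
})
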