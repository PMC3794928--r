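test_that("expression summaries follow their definitions", {
  m <- structure(list(values = rbind(g1 = c(5, 5, 5, 5, 5),
                                     g2 = c(8, 8, 8, 8, 8),
                                     g3 = c(9, 9, 9, 9, 18))),
                 class = "expression_matrix")
  sm <- expression_summary(m, baseline = 9)
  expect_equal(sm$cv[1], 0)
  expect_equal(sm$breadth[2], 0)               # all at 8, below 9
  expect_equal(mean(c(9, 9, 9, 9, 18)), 10.8)
  expect_equal(sm$cv[3], sd(c(9, 9, 9, 9, 18)) / 10.8)
  expect_equal(round(sm$cv[3], 4), 0.3727)     # sample sd convention
  expect_equal(sm$breadth[3], 1)               # strict > baseline
})

test_that("CV matches an independent two-pass computation", {
  set.seed(50)
  v <- matrix(rnorm(200 * 5, 11, 2), 200, 5,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  sm <- expression_summary(structure(list(values = v),
                                     class = "expression_matrix"))
  two_pass <- apply(v, 1, function(x) {
    mu <- sum(x) / length(x)
    sqrt(sum((x - mu)^2) / (length(x) - 1)) / mu
  })
  expect_equal(sm$cv, unname(two_pass), tolerance = 1e-12)
})

test_that("breadth is monotone non-increasing in the baseline", {
  set.seed(51)
  v <- matrix(rnorm(100 * 5, 10, 2), 100, 5,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  m <- structure(list(values = v), class = "expression_matrix")
  b <- sapply(c(7, 9, 11, 13), function(bl)
    expression_summary(m, baseline = bl)$breadth)
  expect_true(all(diff(t(b)) <= 0))
})

test_that("the dip statistic reproduces independently solved values", {
  ## expected values computed by direct linear-programming minimisation
  ## over all unimodal cdfs (mode-position enumeration), frozen here
  cases <- list(
    list(dip = 0.109469033620,
         x = c(0.0275591132, 0.1441596127, 0.3118314520, 0.4091991364,
               0.4233264490, 0.5495936877, 0.8277025938, 0.9486494471,
               0.9504636963)),
    list(dip = 0.081152761249,
         x = c(-0.7364540870, -0.1629099480, 0.0284222413, 0.5467129866,
               5.2180915376, 5.5178806873, 5.7075432490, 6.0397221075,
               6.5988462126)),
    list(dip = 0.139952154168,
         x = c(-0.8205128822, -0.1337698463, 0.9996604294, 1.2667276783,
               4.8173970725, 6.1622769998, 6.1728560754, 6.2716683989,
               7.1102919545)),
    list(dip = 0.125,
         x = c(0.1948395632, 0.8387179933, 5.9723507196, 6.7824317923)),
    list(dip = 0.095953646399,
         x = c(-1.5471446781, -1.2250558264, -0.6414703941, 0.0637817743,
               0.0761402304, 0.1104641432, 0.1193540257, 0.8593826880,
               1.3588234217, 2.0004165463, 5.8007110979, 6.3243377490,
               6.8112178746, 6.9334826799, 7.0745162288, 7.5766895837,
               7.6672475608, 7.6829102672, 7.7622597121, 8.4385225917)))
  for (cs in cases)
    expect_equal(dip_stat(cs$x), cs$dip, tolerance = 1e-8)
  ## order invariance and the 1/(2n) floor for monotone-compatible data
  expect_equal(dip_stat(rev(cases[[1]]$x)), cases[[1]]$dip, tolerance = 1e-8)
  expect_equal(dip_stat(1:50), 1 / 100, tolerance = 1e-9)
})

test_that("dip test separates uniform from well-separated mixtures", {
  set.seed(52)
  u <- dip_unimodality(runif(800), B = 999, seed = 1)
  expect_gt(u$p.value, 0.05)
  bi <- dip_unimodality(c(rnorm(1000), rnorm(1000, 6)), B = 999, seed = 1)
  expect_lt(bi$p.value, 0.01)
})

test_that("splicing calls apply the abundance thresholds", {
  tf <- data.frame(gene_id = rep(c("g1", "g2", "g3", "g4"), c(3, 1, 2, 2)),
                   transcript = paste0("t", 1:8),
                   fraction = c(0.47, 0.41, 0.12,
                                1.0,
                                0.95, 0.05,
                                0.6, 0.4))
  lvl <- c(g1 = 10, g2 = 10, g3 = 10, g4 = 1)
  sp <- splicing_calls(tf, lvl)
  expect_true(sp$as_rnaseq[sp$gene_id == "g1"])        # second form 41%
  expect_equal(sp$major_fraction[sp$gene_id == "g1"], 0.47)
  expect_false(sp$as_rnaseq[sp$gene_id == "g2"])       # single form
  expect_false(sp$as_rnaseq[sp$gene_id == "g3"])       # 5% <= 10%
  expect_true(is.na(sp$as_rnaseq[sp$gene_id == "g4"])) # FPKM <= 2 filtered
  expect_true(sp$as_annotation[sp$gene_id == "g4"])
  ## transcript order invariance
  sp2 <- splicing_calls(tf[sample(nrow(tf)), ], lvl)
  expect_equal(sp2[order(sp2$gene_id), ]$as_rnaseq,
               sp[order(sp$gene_id), ]$as_rnaseq)
})

test_that("tiling normalization recovers scores and expressed calls", {
  set.seed(53)
  n_probes <- 600; n_arrays <- 3
  gene_of <- rep(sprintf("g%02d", 1:20), each = 30)
  true_mu <- stats::setNames(runif(20, 8, 14), sprintf("g%02d", 1:20))
  pm <- matrix(rnorm(n_probes * n_arrays, true_mu[gene_of], 0.4),
               n_probes, n_arrays,
               dimnames = list(sprintf("p%04d", 1:n_probes), NULL))
  rm_ <- matrix(rnorm(300 * n_arrays, 7, 0.5), 300, n_arrays)
  map <- data.frame(probe = rownames(pm), gene_id = gene_of)
  em <- normalize_tiling(pm, rm_, map)
  expect_equal(dim(em$values), c(20L, 3L))
  ## recovered medians within the quantile-normalization distortion bound
  expect_lt(max(abs(rowMeans(em$values) - true_mu[rownames(em$values)])), 0.5)
  ## all genes far above the random-probe background are expressed
  expect_true(all(em$expressed[true_mu[rownames(em$values)] > 10, ]))
  ## identical replicate arrays: normalization is the identity up to ties
  pm2 <- cbind(pm[, 1], pm[, 1])
  em2 <- normalize_tiling(pm2, cbind(rm_[, 1], rm_[, 1]), map)
  expect_equal(em2$values[, 1], em2$values[, 2])
  ## rank preservation within each array
  qn <- limma::normalizeQuantiles(rbind(pm, rm_))
  for (j in 1:n_arrays)
    expect_equal(order(qn[1:n_probes, j]), order(pm[, j]))
})

test_that("a gene with under half its probes above background is silent", {
  set.seed(54)
  pm <- matrix(c(rnorm(12, 12, 0.1), rnorm(18, 5, 0.1)), 30, 1)
  rownames(pm) <- sprintf("p%02d", 1:30)
  rm_ <- matrix(rnorm(200, 7, 0.5), 200, 1)
  map <- data.frame(probe = rownames(pm), gene_id = "g1")
  em <- normalize_tiling(pm, rm_, map)
  expect_false(em$expressed[1, 1])     # 12/30 = 40% above threshold
})

test_that("the association battery detects the planted expression structure", {
  s <- small_run()
  cfg <- sim_config(seed = 60, n_scaffolds = 4, scaffold_length = 80000,
                    n_genes = 60, n_te = 5)
  g <- simulate_genome(cfg)
  em <- simulate_expression(g, cfg)
  sm <- expression_summary(em)
  sp <- splicing_calls(em$transcripts, em$adult_fpkm)
  st <- data.frame(gene_id = g$genes$gene_id, n_covered = 10L,
                   n_mcpg = ifelse(g$genes$methylated, 5L, 0L),
                   pct_mcpg = ifelse(g$genes$methylated, 50, 0),
                   status = ifelse(g$genes$methylated, "methylated",
                                   "non_methylated"),
                   reason = NA, stringsAsFactors = FALSE)
  ab <- association_battery(st, sm, sp, dip_B = 500, seed = 1)
  expect_lt(ab$level_ranksum$p, 0.01)    # methylated genes expressed higher
  ## AS is independent of status by construction
  if (!is.null(ab$as_chisq)) expect_gt(ab$as_chisq$p, 0.01)
  ## identical values in both groups -> rank-sum p = 1
  sm2 <- sm; sm2$median <- 10; sm2$cv <- 0.1
  ab2 <- association_battery(st, sm2, dip_B = 100, seed = 1)
  expect_equal(ab2$level_ranksum$p, 1)
})

test_that("expression generator yields bimodal all-gene, unimodal methylated
           distributions", {
  ## expression structure is a per-gene property, so a label-only gene
  ## table at a dip-powered sample size suffices
  set.seed(61)
  n <- 1200
  g <- list(genes = data.frame(gene_id = sprintf("g%04d", 1:n),
                               methylated = runif(n) < 0.3))
  cfg <- sim_config(seed = 61)
  em <- simulate_expression(g, cfg)
  lf <- log10(em$adult_fpkm)
  all_genes <- dip_unimodality(lf, B = 999, seed = 2)
  meth <- dip_unimodality(lf[g$genes$methylated], B = 999, seed = 2)
  expect_lt(all_genes$p.value, 0.05)
  expect_gt(meth$p.value, 0.05)
  ## methylated genes are constitutive: lower CV at matched medians
  sm <- expression_summary(em)
  lab <- g$genes$methylated[match(sm$gene_id, g$genes$gene_id)]
  mid <- sm$median > 11 & sm$median < 13
  expect_lt(mean(sm$cv[lab & mid]), mean(sm$cv[!lab & mid]))
  ## non-methylated genes account for nearly all unexpressed genes
  expect_gt(mean(!lab[sm$expressed_adult == FALSE]), 0.9)
  ## zero-variance settings give CV exactly 0
  em0 <- simulate_expression(g, cfg, sd_meth = 0, sd_nonmeth = 0)
  sm0 <- expression_summary(em0)
  keep <- em0$classes[sm0$gene_id] %in% c("constitutive", "broad")
  expect_true(all(sm0$cv[keep] == 0))
})
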