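test_that("CpG enumeration yields paired Watson/Crick sites", {
  cat <- enumerate_cpg_sites(Biostrings::DNAStringSet(c(s = "ACGT")))
  expect_equal(nrow(cat), 2L)
  expect_equal(cat$pos, c(2L, 3L))
  expect_equal(cat$strand, c("+", "-"))
  expect_equal(nrow(enumerate_cpg_sites(
    Biostrings::DNAStringSet(c(s = "ATTAGGGA")))), 0L)
})

test_that("CpG site counts match the i.i.d. expectation on random sequence", {
  set.seed(33)
  gc <- 0.42
  s <- methatlas:::random_dna(100000, gc)
  n <- nrow(enumerate_cpg_sites(Biostrings::DNAStringSet(c(x = s))))
  expected <- 2 * 100000 * (gc / 2)^2
  se <- sqrt(2 * expected)   # dyads are nearly independent
  expect_lt(abs(n - expected), 3 * se)
})

test_that("CpG O/E follows its definition", {
  r <- compute_cpg_oe("CGCGCGCG")
  expect_equal(r$gc, 1.0)
  expect_equal(r$cpg_oe, 2.0)          # 4 CpG * 8 / (4 C * 4 G)
  expect_equal(compute_cpg_oe("ATATAT")$cpg_oe, 0)
  set.seed(34)
  big <- compute_cpg_oe(methatlas:::random_dna(200000, 0.5))
  expect_lt(abs(big$cpg_oe - 1), 0.05)
})

test_that("a designed CpG-rich segment yields exactly one covering island", {
  set.seed(35)
  island <- local({
    out <- character(0)
    while (sum(nchar(out)) < 600)
      out <- c(out, if (runif(1) < 0.10) "CG" else
        sample(c("A", "T", "G", "C"), 1, prob = c(0.2, 0.2, 0.3, 0.3)))
    substr(paste(out, collapse = ""), 1, 600)
  })
  flank <- paste(sample(c("A", "T"), 3000, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(s = paste0(flank, island, flank)))
  found <- detect_cpg_islands(g)
  expect_equal(nrow(found), 1L)
  overlap <- min(found$end, 3600) - max(found$start, 3001) + 1
  expect_gte(overlap / 600, 0.9)
  ## pure AT genome: nothing
  expect_equal(nrow(detect_cpg_islands(
    Biostrings::DNAStringSet(c(s = flank)))), 0L)
})

test_that("every reported island satisfies the criteria when recomputed", {
  s <- small_run()
  isl <- detect_cpg_islands(s$genome)
  expect_gt(nrow(isl), 0L)
  for (k in seq_len(nrow(isl))) {
    seg <- substr(as.character(s$genome$seq[[isl$scaffold[k]]]),
                  isl$start[k], isl$end[k])
    st <- compute_cpg_oe(seg)
    expect_gt(st$gc, 0.50)
    expect_gt(st$cpg_oe, 0.6)
    expect_gte(nchar(seg), 200L)
    expect_lte(nchar(seg), 10000L)
  }
  ## non-overlapping and sorted
  for (sc in unique(isl$scaffold)) {
    x <- isl[isl$scaffold == sc, ]
    if (nrow(x) > 1L) expect_true(all(x$start[-1] > x$end[-nrow(x)]))
  }
})

test_that("island detection is strand-invariant", {
  s <- small_run()
  g <- s$genome$seq[1]
  isl <- detect_cpg_islands(g)
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  isl_rc <- detect_cpg_islands(rc)
  L <- Biostrings::width(g)
  expect_equal(nrow(isl), nrow(isl_rc))
  mirrored <- data.frame(start = L - isl_rc$end + 1L,
                         end = L - isl_rc$start + 1L)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(isl$start, mirrored$start, tolerance = 0)
  expect_equal(isl$end, mirrored$end, tolerance = 0)
})

test_that("mCpG classification applies strict thresholds", {
  rep <- data.frame(scaffold = "s", pos = c(10, 20, 30), strand = "+",
                    context = "CpG",
                    coverage = c(10L, 9L, 10L),
                    unconverted = c(1L, 9L, 2L))
  rep$fraction <- rep$unconverted / rep$coverage
  calls <- classify_mcpg(rep)
  expect_equal(calls$mcpg, c(FALSE, FALSE, TRUE))  # 10% is not > 10%
  expect_equal(calls$covered, c(TRUE, FALSE, TRUE))
  sm <- attr(calls, "summary")
  expect_equal(sm$covered_cpgs, 2L)
  expect_equal(sm$mcpgs, 1L)
  ## order invariance: classification is a pure threshold function
  calls2 <- classify_mcpg(rep[c(3, 1, 2), ])
  expect_equal(calls2$mcpg[order(calls2$pos)], calls$mcpg)
})

test_that("mCpG recall and specificity are high at 20x", {
  s <- small_run()
  d <- cpg_dyads(s$report)
  m <- s$methylome
  key <- paste(d$scaffold, d$pos)
  truth <- m$frac[match(key, paste(m$scaffold, m$pos))]
  hi <- d$covered & !is.na(truth) & truth > 0.85
  lo <- d$covered & !is.na(truth) & truth <= 0.01
  expect_gt(sum(hi), 30L); expect_gt(sum(lo), 300L)
  expect_gte(mean(d$mcpg[hi]), 0.99)       # recall on strong sites
  expect_gte(mean(!d$mcpg[lo]), 0.99)      # specificity on background
})

test_that("mCpG clusters follow the greedy rules on designed fixtures", {
  mk <- function(unc) {
    rep <- data.frame(scaffold = "s", pos = seq(100, by = 50,
                                                length.out = length(unc)),
                      strand = "+", context = "CpG", coverage = 20L,
                      unconverted = unc)
    rep$fraction <- rep$unconverted / rep$coverage
    rep
  }
  ## 10 covered CpGs, 9 methylated at 90%
  r1 <- mk(c(rep(18L, 5), 0L, rep(18L, 4)))
  cl1 <- detect_mcpg_clusters(r1)
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$n_mcpg, 9L)
  expect_gt(cl1$frac_mcpg, 0.8)
  expect_gt(cl1$meth_pct, 40)
  ## an isolated single mCpG is not a cluster
  r2 <- mk(c(0L, 0L, 18L, 0L, 0L))
  expect_equal(nrow(detect_mcpg_clusters(r2)), 0L)
  ## fully unmethylated report
  r3 <- mk(rep(0L, 10))
  expect_equal(nrow(detect_mcpg_clusters(r3)), 0L)
})

test_that("cluster mCpGs never exceed the genome-wide mCpG total", {
  s <- small_run()
  calls <- classify_mcpg(s$report)
  cl <- detect_mcpg_clusters(s$report, calls)
  expect_gt(nrow(cl), 0L)
  expect_lte(sum(cl$n_mcpg), attr(calls, "summary")$mcpgs)
  ## every cluster satisfies its invariants
  expect_true(all(cl$frac_mcpg > 0.80))
  expect_true(all(cl$meth_pct > 40))
  expect_true(all(cl$n_mcpg >= 2L))
})

test_that("islands and clusters round-trip through BED6", {
  s <- small_run()
  isl <- detect_cpg_islands(s$genome)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(isl, f)
  bed <- utils::read.table(f, sep = "\t")
  expect_equal(nrow(bed), nrow(isl))
  expect_equal(bed$V2, isl$start - 1L)   # 0-based half-open
  expect_equal(bed$V3, isl$end)
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
})

test_that("non-CpG screening finds only conversion noise in simulation", {
  s <- small_run()
  scr <- screen_noncpg(s$report, s$placed, s$genome)
  ## background: conversion failure plus T->C error, well under 1%
  expect_lt(scr$global_fraction, 0.01)
  expect_gt(scr$global_fraction, 0.0005)
  expect_equal(nrow(scr$candidates), 0L)
})

test_that("a planted reference error is recognized as a CpG artifact", {
  ## reference says CA but every read shows CG after an apparently
  ## methylated C: a reference error masking a true CpG
  genome <- Biostrings::DNAStringSet(
    c(s = paste0(strrep("T", 30), "ACATT", strrep("T", 30))))
  reads <- vapply(1:12, function(i) paste0(strrep("T", 10), "ACGTT",
                                           strrep("T", 10)), "")
  placed <- data.frame(qname = sprintf("q%d", 1:12), scaffold = "s",
                       start = 21L, strand = "+", variant = "meth",
                       mismatches = 1L, seq_watson = reads,
                       stringsAsFactors = FALSE)
  rep <- extract_cytosine_report(placed, genome)
  scr <- screen_noncpg(rep, placed, genome)
  expect_equal(nrow(scr$candidates), 1L)
  expect_equal(scr$candidates$pos, 32L)
  expect_equal(scr$candidates$class, "reference-error CpG")
})

test_that("a genuinely methylated non-CpG site stays a candidate", {
  genome <- Biostrings::DNAStringSet(
    c(s = paste0(strrep("T", 30), "ACATT", strrep("T", 30))))
  ## 40% of reads retain C, the rest converted; following base matches ref
  reads <- c(rep(paste0(strrep("T", 10), "ACATT", strrep("T", 10)), 5),
             rep(paste0(strrep("T", 10), "ATATT", strrep("T", 10)), 7))
  placed <- data.frame(qname = sprintf("q%d", 1:12), scaffold = "s",
                       start = 21L, strand = "+", variant = "both",
                       mismatches = 0L, seq_watson = reads,
                       stringsAsFactors = FALSE)
  rep <- extract_cytosine_report(placed, genome)
  scr <- screen_noncpg(rep, placed, genome)
  expect_equal(nrow(scr$candidates), 1L)
  expect_equal(scr$candidates$class, "candidate")
})
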