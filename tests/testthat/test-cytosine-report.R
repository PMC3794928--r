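test_that("a single unconverted read gives coverage 1, fraction 1 at CpG", {
  genome <- Biostrings::DNAStringSet(c(s = "AAACGAAATTTTTTTTTTTT"))
  placed <- data.frame(qname = "q1", scaffold = "s", start = 1L,
                       strand = "+", variant = "meth", mismatches = 0L,
                       seq_watson = "AAACGAAATTTT",
                       stringsAsFactors = FALSE)
  rep <- extract_cytosine_report(placed, genome)
  site <- rep[rep$pos == 4 & rep$strand == "+", ]
  expect_equal(site$context, "CpG")
  expect_equal(site$coverage, 1L)
  expect_equal(site$unconverted, 1L)
  expect_equal(site$fraction, 1)
  ## the Crick C of the dyad (the G at 5) is untouched by this Watson read
  crick <- rep[rep$pos == 5 & rep$strand == "-", ]
  expect_equal(crick$coverage, 0L)
})

test_that("the report equals a brute-force per-column recount", {
  set.seed(30)
  cfg <- sim_config(seed = 31, n_scaffolds = 1, scaffold_length = 2000,
                    n_genes = 0, n_te = 0, coverage = 2,
                    spike_in_fraction = 0)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  r <- simulate_bisulfite_reads(g, m, cfg)
  refs <- build_converted_references(g)
  pl <- align_bisulfite_reads(r$reads[1:50], refs)
  mine <- extract_cytosine_report(pl, g)
  oracle <- oracle_pileup(pl, g)
  expect_equal(as.data.frame(mine), oracle)
})

test_that("coverage conservation: site coverage sums equal read overlaps", {
  s <- small_run()
  rep <- s$report
  ## per read: number of same-strand reference cytosines it overlaps
  total <- 0L
  for (sc in names(s$genome$seq)) {
    chars <- strsplit(as.character(s$genome$seq[[sc]]), "")[[1]]
    cum_c <- cumsum(chars == "C"); cum_g <- cumsum(chars == "G")
    p <- s$placed[s$placed$scaffold == sc, ]
    len <- nchar(p$seq_watson)
    lo <- p$start; hi <- p$start + len - 1L
    nC <- cum_c[hi] - c(0L, cum_c)[lo]
    nG <- cum_g[hi] - c(0L, cum_g)[lo]
    total <- total + sum(ifelse(p$strand == "+", nC, nG))
  }
  expect_equal(sum(rep$coverage), total)
})

test_that("dyad pooling conserves coverage and unconverted totals", {
  s <- small_run()
  cpg <- s$report[s$report$context == "CpG", ]
  d <- cpg_dyads(s$report)
  expect_equal(sum(d$coverage), sum(cpg$coverage))
  expect_equal(sum(d$unconverted), sum(cpg$unconverted))
})

test_that("observed fractions track simulated truth binomially", {
  s <- small_run()
  d <- cpg_dyads(s$report)
  m <- s$methylome
  key <- paste(d$scaffold, d$pos)
  truth <- m$frac[match(key, paste(m$scaffold, m$pos))]
  sel <- which(d$coverage >= 20 & !is.na(truth) & truth > 0.5)
  expect_gt(length(sel), 20L)
  p_unc <- truth[sel] + (1 - truth[sel]) * s$cfg$conversion_failure
  se <- sqrt(p_unc * (1 - p_unc) / d$coverage[sel])
  z <- abs(d$fraction[sel] - p_unc) / se
  ## ~99.7% within 3 s.e.; allow a small tail at finite n
  expect_gt(mean(z < 3), 0.95)
})

test_that("SAM round-trip reproduces the cytosine report exactly", {
  s <- small_run()
  pl <- s$placed[1:500, ]
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(pl, s$genome, f)
  back <- import_alignments(f, s$genome)
  r1 <- extract_cytosine_report(pl, s$genome)
  r2 <- extract_cytosine_report(back, s$genome)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("indel and secondary SAM records are excluded on import", {
  genome <- Biostrings::DNAStringSet(c(s = strrep("ACGT", 50)))
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:s\tLN:200")
  rec <- function(q, flag, pos, cigar, seq)
    sprintf("%s\t%d\ts\t%d\t255\t%s\t*\t0\t0\t%s\t%s", q, flag, pos, cigar,
            seq, strrep("I", nchar(seq)))
  sam <- c(hdr,
           rec("ok", 0, 1, "8M", "ACGTACGT"),
           rec("ins", 0, 9, "4M1I3M", "ACGTTACG"),
           rec("del", 0, 17, "4M1D4M", "ACGTCGTA"),
           rec("sec", 256, 1, "8M", "ACGTACGT"))
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, f)
  pl <- import_alignments(f, genome)
  expect_equal(pl$qname, "ok")
  expect_equal(attr(pl, "n_excluded_indel"), 2L)
  expect_equal(attr(pl, "n_excluded_secondary"), 1L)
})

test_that("conversion-efficiency arithmetic matches the published example", {
  ## raw 0.41% unconverted minus 0.10% T->C background -> 99.69% efficiency
  fake <- data.frame(scaffold = "ctl", pos = 1:10000, strand = "+",
                     context = "nonCpG", coverage = 1L,
                     unconverted = rep(c(1L, 0L), c(41, 9959)),
                     fraction = NA_real_)
  st <- estimate_conversion_efficiency(fake, background_error = 0.0010)
  expect_equal(st$raw, 0.0041)
  expect_equal(st$corrected, 0.0031)
  expect_equal(st$efficiency, 99.69)
  ## raw 0 -> efficiency 100
  fake$unconverted <- 0L
  expect_equal(estimate_conversion_efficiency(fake, 0.001)$efficiency, 100)
  ## zero coverage errors
  fake$coverage <- 0L
  expect_error(estimate_conversion_efficiency(fake, 0.001), "coverage")
})
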