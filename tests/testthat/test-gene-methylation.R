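## A hand-built single-gene genome: one scaffold, + strand gene with two
## CDS exons, for exercising status calls on designed dyad evidence.
one_gene_genome <- function(seqstr, cds1, cds2, utr5, utr3) {
  gid <- "g01"
  feats <- data.frame(
    gene_id = gid,
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "five_prime_UTR", "three_prime_UTR"),
    scaffold = "s1",
    start = c(utr5[1], utr5[1], utr5[1], cds2[1], cds1[1], cds2[1],
              utr5[1], utr3[1]),
    end = c(utr3[2], utr3[2], cds1[2], utr3[2], cds1[2], cds2[2],
            utr5[2], utr3[2]),
    strand = "+", rank = c(NA, NA, 1, 2, 1, 2, NA, NA),
    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = gid, scaffold = "s1", start = utr5[1],
                      end = utr3[2], strand = "+", n_exons = 2L,
                      tx_len = utr3[2] - utr5[1] + 1L,
                      cds_len = (cds1[2] - cds1[1] + 1L) +
                        (cds2[2] - cds2[1] + 1L),
                      is_te = FALSE, methylated = TRUE, cgi_insert = FALSE,
                      stringsAsFactors = FALSE)
  seq <- Biostrings::DNAStringSet(c(s1 = seqstr))
  structure(list(seq = seq, genes = genes, features = feats),
            class = "annotated_genome")
}

report_from_dyads <- function(pos, coverage, unconverted) {
  rep <- data.frame(scaffold = "s1", pos = pos, strand = "+",
                    context = "CpG", coverage = coverage,
                    unconverted = unconverted, stringsAsFactors = FALSE)
  rep$fraction <- ifelse(rep$coverage > 0, rep$unconverted / rep$coverage, NA)
  rep
}

test_that("gene status thresholds follow the first-1kbp CDS rule", {
  seqstr <- paste(rep("TACG", 500), collapse = "")   # CpG every 4 bp
  g <- one_gene_genome(seqstr, cds1 = c(101, 400), cds2 = c(501, 800),
                       utr5 = c(51, 100), utr3 = c(801, 900))
  dy <- seq(103, 799, by = 4)
  dy <- dy[substr(seqstr, dy, dy + 1) == "CG"]
  cds_dy <- dy[(dy >= 101 & dy <= 400) | (dy >= 501 & dy <= 800)][1:20]
  ## 15 of 20 covered dyads methylated -> 75% -> methylated
  rep <- report_from_dyads(cds_dy, 20L, rep(c(18L, 0L), c(15, 5)))
  st <- call_gene_status(rep, g)
  expect_equal(st$status, "methylated")
  expect_equal(st$n_covered, 20L)
  expect_equal(st$pct_mcpg, 75)
  ## only 3 covered dyads -> undetermined
  rep2 <- report_from_dyads(cds_dy[1:3], 20L, c(18L, 18L, 18L))
  st2 <- call_gene_status(rep2, g)
  expect_equal(st2$status, "undetermined")
  expect_match(st2$reason, "fewer than 4")
  ## exactly 10% is non-methylated (strict >)
  rep3 <- report_from_dyads(cds_dy[1:10], 20L, rep(c(18L, 0L), c(1, 9)))
  st3 <- call_gene_status(rep3, g)
  expect_equal(st3$status, "non_methylated")
})

test_that("overlapping gene models are excluded from status calls", {
  s <- small_run()
  g <- s$genome
  g2 <- g
  extra <- g$genes[1, ]
  extra$gene_id <- "dup01"
  extra$start <- extra$start + 50L; extra$end <- extra$end + 50L
  g2$genes <- rbind(g$genes, extra)
  f <- g$features[g$features$gene_id == g$genes$gene_id[1], ]
  f$gene_id <- "dup01"; f$start <- f$start + 50L; f$end <- f$end + 50L
  g2$features <- rbind(g$features, f)
  st <- call_gene_status(s$report, g2)
  expect_equal(st$status[st$gene_id == "dup01"], "undetermined")
  expect_equal(st$status[st$gene_id == g$genes$gene_id[1]], "undetermined")
  expect_match(st$reason[st$gene_id == "dup01"], "overlap")
})

test_that("status recovery at 20x meets the design target", {
  s <- small_run()
  st <- s$statuses
  det <- st$status %in% c("methylated", "non_methylated")
  truth <- s$genome$genes$methylated[match(st$gene_id, s$genome$genes$gene_id)]
  expect_gte(mean((st$status[det] == "methylated") == truth[det]), 0.95)
  expect_gt(sum(det), 10L)
})

test_that("metagene profile shows 5' CDS enrichment and exon>intron", {
  s <- small_run()
  prof <- metagene_profile(s$report, s$genome, s$statuses)
  m <- prof[prof$class == "methylated", ]
  cds <- m[m$region == "cds", ]
  cds <- cds[order(cds$bin), ]
  expect_gt(nrow(cds), 5L)
  ## early CDS bins are heavily methylated, late ones decay
  expect_gt(mean(cds$pct_mcpg[cds$bin <= 5]),
            mean(cds$pct_mcpg[cds$bin > 10]))
  ## flanks and UTRs sit far below the CDS plateau
  expect_gt(mean(cds$pct_mcpg[cds$bin <= 5]),
            m$pct_mcpg[m$region == "utr3"])
  up <- m[m$region == "upstream", ]
  expect_gt(mean(cds$pct_mcpg[cds$bin <= 5]), mean(up$pct_mcpg))
  ## exon vs intron contrast at matched ranks
  for (r in 1:3) {
    e <- m[m$region == "exon_rank5" & m$bin == r, ]
    i <- m[m$region == "intron_rank5" & m$bin == r, ]
    if (nrow(e) && nrow(i) && e$n_covered > 10 && i$n_covered > 10)
      expect_gt(e$pct_mcpg, i$pct_mcpg)
  }
})

test_that("counting conservation: profile CDS totals match status totals", {
  s <- small_run()
  prof <- metagene_profile(s$report, s$genome, s$statuses)
  cds <- prof[prof$class == "all" & prof$region == "cds" & prof$bin <= 10, ]
  st <- s$statuses
  det <- st$status %in% c("methylated", "non_methylated")
  ## covered dyads in the first 1 kbp of CDS, summed over determinable genes
  expect_equal(sum(cds$n_covered), sum(st$n_covered[det]))
  expect_equal(sum(cds$n_mcpg), sum(st$n_mcpg[det]))
})

test_that("codon windows capture the start-codon methylation step", {
  s <- small_run()
  cw <- codon_window_stats(s$report, s$genome, s$statuses)
  expect_gt(cw$start$post_pct, cw$start$pre_pct)
  expect_lt(cw$start$chisq_p, 0.01)
  ## pooling audit: percentages recompute from the returned counts
  expect_equal(cw$start$pre_pct,
               100 * cw$start$pre["mcpg"] / cw$start$pre["covered"],
               ignore_attr = TRUE)
})

test_that("TE quantification applies element filters and finds the planted
           hypermethylated family", {
  set.seed(40)
  elems <- Biostrings::DNAStringSet(c(
    te_short = methatlas:::random_dna(90, 0.45),
    te_nocpg = gsub("CG", "CT", methatlas:::random_dna(800, 0.45)),
    te_quiet1 = methatlas:::random_dna(900, 0.45),
    te_quiet2 = methatlas:::random_dna(900, 0.45),
    te_hyper = methatlas:::random_dna(900, 0.45)))
  mk_reads <- function(el, frac, n, prefix) {
    s <- as.character(elems[[el]])
    lk <- methatlas:::methylome_frac_vectors(s, data.frame(
      pos = setdiff(which(strsplit(s, "")[[1]] == "C" &
                            c(strsplit(s, "")[[1]][-1], "") == "G"),
                    integer(0)),
      frac = frac))
    b <- methatlas:::sim_read_batch(s, lk$fw, lk$fc, n, 75L, 0.003, 0.001,
                                    el, 0L)
    stats::setNames(b$reads, paste0(prefix, seq_len(n)))
  }
  set.seed(41)
  reads <- c(mk_reads("te_quiet1", 0, 80, "a"),
             mk_reads("te_quiet2", 0, 80, "b"),
             mk_reads("te_hyper", 0.10, 80, "c"))
  te <- quantify_te_methylation(reads, elems)
  excl <- attr(te, "excluded")
  expect_true("te_short" %in% excl$element)
  expect_true("te_nocpg" %in% excl$element)
  expect_setequal(te$element, c("te_quiet1", "te_quiet2", "te_hyper"))
  expect_equal(te$element[te$hypermethylated], "te_hyper")
})

test_that("5'-restricted methylation creates a spurious length correlation", {
  cfg <- sim_config(seed = 55, n_scaffolds = 5, scaffold_length = 70000,
                    n_genes = 55, n_te = 0, p_methylated_gene = 0.65,
                    coverage = 20)
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  ctrl <- simulate_control_genome(seed = 1)
  r <- simulate_bisulfite_reads(g, m, cfg, ctrl)
  refs <- build_converted_references(g)
  pl <- align_bisulfite_reads(r$reads[!r$origin$control], refs)
  rep <- extract_cytosine_report(pl, g)
  st <- call_gene_status(rep, g)
  la <- length_association(st, g, rep)
  expect_gt(la$full$n, 15L)
  expect_lt(la$full$rho, -0.3)           # whole-transcript: strong artifact
  expect_lt(abs(la$first1kb$rho), 0.3)   # fixed window: correlation gone
  expect_gt(la$first1kb$rho, la$full$rho + 0.25)
})
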