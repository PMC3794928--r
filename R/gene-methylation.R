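#' Collapse a cytosine report to CpG dyads
#'
#' Watson and Crick evidence of each CpG dyad is pooled (coverage and
#' unconverted counts summed); the dyad is keyed by its Watson-C position.
#'
#' @param report a `cytosine_report`.
#' @param min_coverage,min_fraction thresholds for the `covered` and `mcpg`
#'   flags (same conventions as [classify_mcpg()]).
#' @return data.frame `scaffold`, `pos`, `coverage`, `unconverted`,
#'   `fraction`, `covered`, `mcpg`.
#' @export
cpg_dyads <- function(report, min_coverage = 10L, min_fraction = 0.10) {
  cpg <- report[report$context == "CpG", , drop = FALSE]
  key_pos <- ifelse(cpg$strand == "+", cpg$pos, cpg$pos - 1L)
  key <- paste(cpg$scaffold, key_pos)
  cov <- rowsum(cpg$coverage, key, reorder = FALSE)
  un <- rowsum(cpg$unconverted, key, reorder = FALSE)
  first <- !duplicated(key)
  d <- data.frame(scaffold = cpg$scaffold[first], pos = key_pos[first],
                  stringsAsFactors = FALSE)
  d$coverage <- cov[match(paste(d$scaffold, d$pos), rownames(cov)), 1]
  d$unconverted <- un[match(paste(d$scaffold, d$pos), rownames(un)), 1]
  d$fraction <- ifelse(d$coverage > 0, d$unconverted / d$coverage, NA_real_)
  d$covered <- d$coverage >= min_coverage
  d$mcpg <- d$covered & d$unconverted / pmax(1L, d$coverage) > min_fraction
  d <- d[order(d$scaffold, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Call per-gene methylation status
#'
#' Pools CpG dyad evidence over the first `window` bp of each gene's
#' spliced CDS (concatenated 5'->3' in coding orientation). A gene with at
#' least `min_covered` covered dyads is *methylated* when more than
#' `min_fraction` of them are mCpGs, otherwise *non-methylated*; genes with
#' fewer covered dyads, without CDS, or overlapping another gene model are
#' *undetermined*.
#'
#' @param report a `cytosine_report`.
#' @param genome the matching `annotated_genome`.
#' @param window first-CDS window in bp (default 1000).
#' @param min_covered minimum covered dyads to determine status (default 4).
#' @param min_coverage,min_fraction dyad-level thresholds.
#' @return data.frame (class `gene_status`): `gene_id`, `n_covered`,
#'   `n_mcpg`, `pct_mcpg`, `status` in
#'   `{methylated, non_methylated, undetermined}`, `reason`.
#' @export
call_gene_status <- function(report, genome, window = 1000L,
                             min_covered = 4L, min_coverage = 10L,
                             min_fraction = 0.10) {
  d <- cpg_dyads(report, min_coverage, min_fraction)
  overl <- overlapping_gene_ids(genome)
  cds <- gene_cds_positions(genome)
  gn <- genome$genes
  out <- data.frame(gene_id = gn$gene_id, n_covered = 0L, n_mcpg = 0L,
                    pct_mcpg = NA_real_, status = "undetermined",
                    reason = NA_character_, stringsAsFactors = FALSE)
  dyad_by_sc <- split(seq_len(nrow(d)), d$scaffold)
  for (i in seq_len(nrow(gn))) {
    g <- gn$gene_id[i]
    if (g %in% overl) { out$reason[i] <- "overlapping gene model"; next }
    cp <- cds[[g]]
    if (is.null(cp) || !length(cp)) { out$reason[i] <- "no CDS"; next }
    cp <- cp[seq_len(min(window, length(cp)))]
    rows <- dyad_by_sc[[gn$scaffold[i]]]
    dd <- d[rows[d$pos[rows] %in% cp], , drop = FALSE]
    ncov <- sum(dd$covered); nm <- sum(dd$mcpg)
    out$n_covered[i] <- ncov; out$n_mcpg[i] <- nm
    if (ncov < min_covered) { out$reason[i] <- "fewer than 4 covered CpGs"; next }
    out$pct_mcpg[i] <- 100 * nm / ncov
    out$status[i] <- if (out$pct_mcpg[i] > 100 * min_fraction)
      "methylated" else "non_methylated"
  }
  class(out) <- c("gene_status", "data.frame")
  out
}

#' Metagene methylation profiles across gene architecture
#'
#' Aggregates covered CpG dyads into region/bin cells for methylated,
#' non-methylated and all determinable genes: 1 kbp flanks (100 bp bins,
#' bin 1 nearest the gene), UTRs, spliced-CDS distance bins (100 bp, first
#' 2 kbp), intron junction-distance bins (100 bp, within 500 bp of the
#' nearest exon-intron junction), coding-exon and intron ranks 1-4 from
#' both gene ends, and a length-rescaled canonical layout (each feature one
#' unit). Both the percent of mCpGs and the pooled methylation percentage
#' are reported per cell.
#'
#' @param report a `cytosine_report`.
#' @param genome the `annotated_genome`.
#' @param statuses a `gene_status` table from [call_gene_status()].
#' @param min_coverage,min_fraction dyad thresholds.
#' @return Long-format data.frame: `class`, `region`, `bin`, `n_covered`,
#'   `n_mcpg`, `pct_mcpg`, `meth_pct`.
#' @export
metagene_profile <- function(report, genome, statuses,
                             min_coverage = 10L, min_fraction = 0.10) {
  d <- cpg_dyads(report, min_coverage, min_fraction)
  d <- d[d$covered, , drop = FALSE]
  cds <- gene_cds_positions(genome)
  rows <- list()
  st <- statuses$status[match(genome$genes$gene_id, statuses$gene_id)]
  for (i in seq_len(nrow(genome$genes))) {
    if (!st[i] %in% c("methylated", "non_methylated")) next
    g <- genome$genes[i, ]
    f <- genome$features[genome$features$gene_id == g$gene_id, , drop = FALSE]
    dd <- d[d$scaffold == g$scaffold, , drop = FALSE]
    if (!nrow(dd)) next
    cells <- gene_profile_cells(g, f, cds[[g$gene_id]])
    j <- merge(dd, cells, by = "pos")   # a dyad can sit in several regions
    if (!nrow(j)) next
    rows[[length(rows) + 1L]] <- data.frame(
      class = if (st[i] == "methylated") "methylated" else "non_methylated",
      region = j$region, bin = j$bin,
      covered = 1L, mcpg = as.integer(j$mcpg),
      coverage = j$coverage, unconverted = j$unconverted,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(class = character(), region = character(),
                      bin = integer(), n_covered = integer(),
                      n_mcpg = integer(), pct_mcpg = numeric(),
                      meth_pct = numeric(), stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  long <- rbind(long, transform(long, class = "all"))
  agg <- stats::aggregate(cbind(covered, mcpg, coverage, unconverted) ~
                            class + region + bin, long, sum)
  names(agg)[names(agg) == "covered"] <- "n_covered"
  names(agg)[names(agg) == "mcpg"] <- "n_mcpg"
  agg$pct_mcpg <- 100 * agg$n_mcpg / agg$n_covered
  agg$meth_pct <- 100 * agg$unconverted / agg$coverage
  agg$coverage <- NULL; agg$unconverted <- NULL
  agg[order(agg$class, agg$region, agg$bin), ]
}

## Position -> (region, bin) assignment for one gene.
gene_profile_cells <- function(g, f, cpos) {
  pos <- integer(0); region <- character(0); bin <- integer(0)
  add <- function(p, r, b) {
    pos <<- c(pos, p); region <<- c(region, rep_len(r, length(p)))
    bin <<- c(bin, rep_len(b, length(p)))
  }
  ## flanks, 100 bp bins ordered away from the gene
  up <- if (g$strand == "+") (g$start - 1L):(g$start - 1000L) else
    (g$end + 1L):(g$end + 1000L)
  dn <- if (g$strand == "+") (g$end + 1L):(g$end + 1000L) else
    (g$start - 1L):(g$start - 1000L)
  bidx <- ceiling(seq_len(1000L) / 100L)
  keep <- up >= 1L; add(up[keep], "upstream", bidx[keep])
  keep <- dn >= 1L; add(dn[keep], "downstream", bidx[keep])
  for (k in which(f$type == "five_prime_UTR"))
    add(seq.int(f$start[k], f$end[k]), "utr5", 1L)
  for (k in which(f$type == "three_prime_UTR"))
    add(seq.int(f$start[k], f$end[k]), "utr3", 1L)
  ## spliced CDS distance bins (100 bp, first 2 kbp)
  dseq <- seq_along(cpos)
  inwin <- dseq <= 2000L
  add(cpos[inwin], "cds", ceiling(dseq[inwin] / 100L))
  ## exon/intron ranks over coding exons
  ex <- f[f$type == "CDS", , drop = FALSE]
  ex <- ex[order(ex$start, decreasing = (g$strand == "-")), , drop = FALSE]
  ne <- nrow(ex)
  for (k in seq_len(ne)) {
    p <- seq.int(ex$start[k], ex$end[k])
    if (k <= 4L) add(p, "exon_rank5", k)
    if (ne - k + 1L <= 4L) add(p, "exon_rank3", ne - k + 1L)
    add(p, "rescaled_exon", min(k, 4L))
  }
  if (ne > 1L) {
    for (k in seq_len(ne - 1L)) {
      lo <- min(ex$end[k], ex$start[k + 1L]) + 1L
      hi <- max(ex$end[k], ex$start[k + 1L]) - 1L
      if (hi < lo) next
      p <- seq.int(lo, hi)
      if (k <= 4L) add(p, "intron_rank5", k)
      if (ne - k <= 4L) add(p, "intron_rank3", ne - k)
      add(p, "rescaled_intron", min(k, 4L))
      ## junction-distance bins
      dj <- pmin(p - lo + 1L, hi - p + 1L)
      injb <- dj <= 500L
      add(p[injb], "intron_junction", ceiling(dj[injb] / 100L))
      add(p, "intron", 1L)
    }
  }
  data.frame(pos = pos, region = region, bin = bin, stringsAsFactors = FALSE)
}

#' Start- and stop-codon window methylation statistics
#'
#' Pools mCpG fractions in windows 5' and 3' of the start codon of
#' methylated genes (5' window: the `start_window` bp immediately upstream
#' of the CDS start along the transcript, crossing into the 5' flank when
#' the UTR is shorter; 3' window: the first `start_window` bp of spliced
#' CDS), with a chi-squared test on the pooled 2x2 counts. For stop codons
#' it computes per-gene pooled methylation percentages over the
#' `stop_window` bp before and after the stop (spliced CDS end vs 3' UTR),
#' keeps genes with >= 4 covered dyads in each window, stratifies by CDS
#' length (< 1 kbp vs >= 1 kbp), and runs a Wilcoxon matched-pairs
#' signed-rank test plus a sign-count chi-squared test per stratum.
#'
#' @param report a `cytosine_report`.
#' @param genome the `annotated_genome`.
#' @param statuses `gene_status` table.
#' @param start_window,stop_window window sizes in bp.
#' @param min_covered per-window covered-dyad minimum for stop windows.
#' @return list (class `codon_window_stats`) with `start` (pooled counts,
#'   fractions, chi-square p) and `stop` (per-stratum data and tests).
#' @export
codon_window_stats <- function(report, genome, statuses,
                               start_window = 500L, stop_window = 100L,
                               min_covered = 4L) {
  d <- cpg_dyads(report)
  cds <- gene_cds_positions(genome)
  meth <- statuses$gene_id[statuses$status == "methylated"]
  pre_cov <- 0L; pre_m <- 0L; post_cov <- 0L; post_m <- 0L
  stop_rows <- list()
  for (g in meth) {
    gr <- genome$genes[genome$genes$gene_id == g, ]
    cp <- cds[[g]]
    if (!length(cp)) next
    dd <- d[d$scaffold == gr$scaffold, , drop = FALSE]
    ## 5' of start: start_window transcript bases upstream of CDS start
    tx <- gene_tx_positions(genome, g)[[1]]
    cstart_idx <- match(cp[1], tx)
    pre_pos <- if (!is.na(cstart_idx) && cstart_idx > 1L)
      tx[max(1L, cstart_idx - start_window):(cstart_idx - 1L)] else integer(0)
    if (cstart_idx <= start_window) {  # extend into the upstream flank
      need <- start_window - (cstart_idx - 1L)
      pre_pos <- c(gene_flank_positions(genome, g, need, "upstream"), pre_pos)
    }
    post_pos <- cp[seq_len(min(start_window, length(cp)))]
    pr <- dd[dd$pos %in% pre_pos & dd$covered, , drop = FALSE]
    po <- dd[dd$pos %in% post_pos & dd$covered, , drop = FALSE]
    pre_cov <- pre_cov + nrow(pr); pre_m <- pre_m + sum(pr$mcpg)
    post_cov <- post_cov + nrow(po); post_m <- post_m + sum(po$mcpg)
    ## stop windows (pooled reads per window)
    last <- cp[max(1L, length(cp) - stop_window + 1L):length(cp)]
    f3 <- genome$features[genome$features$gene_id == g &
                          genome$features$type == "three_prime_UTR", ]
    if (nrow(f3)) {
      u3 <- seq.int(f3$start[1], f3$end[1])
      if (gr$strand == "-") u3 <- rev(u3)
      after <- u3[seq_len(min(stop_window, length(u3)))]
      a <- dd[dd$pos %in% last & dd$covered, , drop = FALSE]
      b <- dd[dd$pos %in% after & dd$covered, , drop = FALSE]
      if (nrow(a) >= min_covered && nrow(b) >= min_covered) {
        stop_rows[[length(stop_rows) + 1L]] <- data.frame(
          gene_id = g, cds_len = gr$cds_len,
          pre = 100 * sum(a$unconverted) / sum(a$coverage),
          post = 100 * sum(b$unconverted) / sum(b$coverage),
          stringsAsFactors = FALSE)
      }
    }
  }
  stop_df <- if (length(stop_rows)) do.call(rbind, stop_rows) else
    data.frame(gene_id = character(), cds_len = integer(),
               pre = numeric(), post = numeric(), stringsAsFactors = FALSE)
  stop_df$stratum <- ifelse(stop_df$cds_len < 1000L, "<1kbp", ">=1kbp")
  tests <- lapply(split(stop_df, stop_df$stratum), function(x) {
    if (nrow(x) < 3L || all(x$pre == x$post))
      return(list(n = nrow(x), mean_pre = mean(x$pre), mean_post = mean(x$post),
                  wmsrt_p = NA_real_, sign_p = NA_real_))
    w <- stats::wilcox.test(x$pre, x$post, paired = TRUE, exact = FALSE)
    gt <- sum(x$pre > x$post); lt <- sum(x$pre < x$post)
    sp <- if (gt + lt > 0)
      suppressWarnings(stats::chisq.test(c(gt, lt), p = c(0.5, 0.5))$p.value) else NA_real_
    list(n = nrow(x), mean_pre = mean(x$pre), mean_post = mean(x$post),
         wmsrt_p = w$p.value, sign_p = sp)
  })
  start_p <- if (pre_cov > 0 && post_cov > 0)
    stats::chisq.test(matrix(c(pre_m, pre_cov - pre_m,
                               post_m, post_cov - post_m), 2))$p.value
    else NA_real_
  structure(list(
    start = list(window = start_window,
                 pre = c(mcpg = pre_m, covered = pre_cov),
                 post = c(mcpg = post_m, covered = post_cov),
                 pre_pct = 100 * pre_m / max(1L, pre_cov),
                 post_pct = 100 * post_m / max(1L, post_cov),
                 chisq_p = start_p),
    stop = list(per_gene = stop_df, tests = tests)),
    class = "codon_window_stats")
}

#' Quantify methylation of repetitive elements from leftover reads
#'
#' Aligns the unmapped and non-uniquely mapped reads against a repeat
#' database, keeping elements longer than `min_length` with at least
#' `min_cpgs` CpGs and average read depth of at least `min_depth`, and
#' reports the pooled CpG methylation percentage per element, flagging
#' elements above `hyper_pct` as hypermethylated.
#'
#' @param leftover_reads named character vector of reads (those not
#'   uniquely placed on the genome).
#' @param repeat_db [Biostrings::DNAStringSet] of repeat elements.
#' @param min_length,min_cpgs,min_depth element filters.
#' @param hyper_pct hypermethylation flag threshold (percent).
#' @param max_mismatches mapper mismatch cap.
#' @return data.frame (class `te_methylation`): `element`, `length`,
#'   `n_cpgs`, `depth`, `meth_pct`, `hypermethylated`; attribute
#'   `excluded` logs filtered elements.
#' @export
quantify_te_methylation <- function(leftover_reads, repeat_db,
                                    min_length = 100L, min_cpgs = 4L,
                                    min_depth = 4, hyper_pct = 5,
                                    max_mismatches = 4L) {
  lens <- Biostrings::width(repeat_db)
  ncpg <- vapply(seq_along(repeat_db), function(i)
    sum(unlist(gregexpr("CG", as.character(repeat_db[[i]]),
                        fixed = TRUE)) > 0L), 0L)
  keep <- lens > min_length & ncpg >= min_cpgs
  excluded <- data.frame(element = names(repeat_db)[!keep],
                         reason = ifelse(lens[!keep] <= min_length,
                                         "too short", "too few CpGs"))
  db <- repeat_db[keep]
  if (length(db) == 0L || length(leftover_reads) == 0L) {
    out <- data.frame(element = character(), length = integer(),
                      n_cpgs = integer(), depth = numeric(),
                      meth_pct = numeric(), hypermethylated = logical())
    attr(out, "excluded") <- excluded
    class(out) <- c("te_methylation", "data.frame")
    return(out)
  }
  leftover_reads <- leftover_reads[nchar(leftover_reads) <=
                                     max(Biostrings::width(db))]
  refs <- build_converted_references(db)
  placed <- align_bisulfite_reads(leftover_reads, refs,
                                  max_mismatches = max_mismatches)
  rep <- extract_cytosine_report(placed, db)
  rows <- list()
  for (el in names(db)) {
    r <- rep[rep$scaffold == el, , drop = FALSE]
    p <- placed[placed$scaffold == el, , drop = FALSE]
    depth <- sum(nchar(p$seq_watson)) / Biostrings::width(db)[match(el, names(db))]
    cg <- r$context == "CpG"
    meth <- if (sum(r$coverage[cg]) > 0)
      100 * sum(r$unconverted[cg]) / sum(r$coverage[cg]) else NA_real_
    rows[[el]] <- data.frame(
      element = el, length = Biostrings::width(db)[match(el, names(db))],
      n_cpgs = ncpg[keep][match(el, names(db))], depth = depth,
      meth_pct = meth, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  low <- out$depth < min_depth
  if (any(low))
    excluded <- rbind(excluded, data.frame(element = out$element[low],
                                           reason = "insufficient depth"))
  out <- out[!low, , drop = FALSE]
  out$hypermethylated <- !is.na(out$meth_pct) & out$meth_pct > hyper_pct
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("te_methylation", "data.frame")
  out
}

#' Transcript length vs methylation association
#'
#' Spearman correlation of transcript length with the percent of mCpGs
#' among methylated genes, computed twice: over the full transcript and
#' over the first 1 kbp of spliced CDS. A 5'-restricted methylome produces
#' a strongly negative full-transcript correlation that disappears in the
#' fixed 1 kbp window, showing the length correlation is a windowing
#' artifact.
#'
#' @param statuses `gene_status` table.
#' @param genome the `annotated_genome`.
#' @param report a `cytosine_report`.
#' @return list (class `length_association`) with `full` and `first1kb`,
#'   each holding `rho`, `p`, `n` and a `constant` flag (rho reported as 0
#'   when the methylation percentages are constant).
#' @export
length_association <- function(statuses, genome, report) {
  d <- cpg_dyads(report)
  meth <- statuses$gene_id[statuses$status == "methylated"]
  cds <- gene_cds_positions(genome)
  tx <- gene_tx_positions(genome, meth)
  lens <- numeric(0); pfull <- numeric(0); p1kb <- numeric(0)
  for (g in meth) {
    gr <- genome$genes[genome$genes$gene_id == g, ]
    dd <- d[d$scaffold == gr$scaffold & d$covered, , drop = FALSE]
    full <- dd[dd$pos >= gr$start & dd$pos <= gr$end, , drop = FALSE]
    win <- cds[[g]][seq_len(min(1000L, length(cds[[g]])))]
    w <- dd[dd$pos %in% win, , drop = FALSE]
    if (nrow(full) == 0L || nrow(w) == 0L) next
    lens <- c(lens, gr$tx_len)
    pfull <- c(pfull, 100 * sum(full$mcpg) / nrow(full))
    p1kb <- c(p1kb, 100 * sum(w$mcpg) / nrow(w))
  }
  one <- function(x) {
    if (length(x) < 3L || stats::sd(x) == 0)
      return(list(rho = 0, p = NA_real_, n = length(x), constant = TRUE))
    ct <- suppressWarnings(stats::cor.test(lens, x, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         constant = FALSE)
  }
  structure(list(full = one(pfull), first1kb = one(p1kb)),
            class = "length_association")
}
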