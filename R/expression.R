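#' Normalize tiling-array probe intensities to gene expression scores
#'
#' Arrays are rescaled so the mean intensity of the random
#' (background-only) probes is equal across arrays, then all probes
#' (including random probes) are quantile-normalized across replicates.
#' Per gene and array, the score is the median log2 intensity of the
#' probes falling within the largest transcript, and the gene is called
#' expressed on an array when more than half of its tiled probes exceed
#' the 99th percentile of the random-probe intensities.
#'
#' @param probe_matrix matrix (probes x arrays) of log2 intensities for
#'   genomic probes.
#' @param random_probe_matrix matrix (random probes x arrays) of log2
#'   intensities for the background probes.
#' @param probe_map data.frame `probe` (rowname in `probe_matrix`) to
#'   `gene_id`.
#' @return An object of class `expression_matrix` with `values` (gene x
#'   array score matrix), `expressed` (logical gene x array), `threshold`
#'   (per-array 99th percentile background) and `n_probes` per gene.
#'   Genes with zero probes are dropped and recorded in attribute
#'   `missing_genes`.
#' @export
normalize_tiling <- function(probe_matrix, random_probe_matrix, probe_map) {
  stopifnot(ncol(probe_matrix) == ncol(random_probe_matrix))
  ## equalize arrays on random-probe means
  rmeans <- colMeans(random_probe_matrix)
  shift <- mean(rmeans) - rmeans
  pm <- sweep(probe_matrix, 2, shift, `+`)
  rm_ <- sweep(random_probe_matrix, 2, shift, `+`)
  all <- rbind(pm, rm_)
  qn <- limma::normalizeQuantiles(all)
  pm <- qn[seq_len(nrow(pm)), , drop = FALSE]
  rm_ <- qn[nrow(pm) + seq_len(nrow(rm_)), , drop = FALSE]
  thr <- apply(rm_, 2, stats::quantile, probs = 0.99)
  genes <- unique(probe_map$gene_id)
  vals <- matrix(NA_real_, length(genes), ncol(pm),
                 dimnames = list(genes, colnames(pm)))
  expr <- matrix(NA, length(genes), ncol(pm),
                 dimnames = list(genes, colnames(pm)))
  np <- integer(length(genes)); names(np) <- genes
  missing <- character(0)
  for (g in genes) {
    pr <- probe_map$probe[probe_map$gene_id == g]
    pr <- intersect(pr, rownames(pm))
    np[g] <- length(pr)
    if (!length(pr)) { missing <- c(missing, g); next }
    sub <- pm[pr, , drop = FALSE]
    vals[g, ] <- apply(sub, 2, stats::median)
    expr[g, ] <- colSums(sub > matrix(thr, nrow(sub), ncol(sub),
                                      byrow = TRUE)) > length(pr) / 2
  }
  keep <- !(genes %in% missing)
  structure(list(values = vals[keep, , drop = FALSE],
                 expressed = expr[keep, , drop = FALSE],
                 threshold = thr, n_probes = np[keep]),
            class = "expression_matrix",
            missing_genes = missing)
}

#' Per-gene expression summaries: level, CV and breadth
#'
#' @param matrix an `expression_matrix` (its `values` component is the
#'   gene x stage matrix of normalized log2 levels).
#' @param baseline expression baseline on the normalized scale; breadth
#'   counts stages strictly above it (default 9).
#' @param fpkm_expressed adult FPKM threshold for the expressed-in-adult
#'   flag (default 1).
#' @return data.frame (class `expression_summary`): `gene_id`, `median`,
#'   `cv` (sample sd / mean of the stage values), `breadth`,
#'   `expressed_adult` (NA when no FPKM data).
#' @examples
#' m <- structure(list(values = rbind(g1 = c(9, 9, 9, 9, 18))),
#'                class = "expression_matrix")
#' expression_summary(m)$cv   # sd(c(9,9,9,9,18))/mean(...) = 0.3727
#' @export
expression_summary <- function(matrix, baseline = 9, fpkm_expressed = 1) {
  v <- matrix$values
  med <- apply(v, 1, stats::median)
  cv <- apply(v, 1, stats::sd) / rowMeans(v)
  breadth <- rowSums(v > baseline)
  fp <- matrix$adult_fpkm
  out <- data.frame(gene_id = rownames(v), median = med, cv = cv,
                    breadth = breadth,
                    expressed_adult = if (!is.null(fp))
                      fp[rownames(v)] >= fpkm_expressed else NA,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("expression_summary", "data.frame")
  out
}

#' Alternative-splicing calls from transcript abundance fractions
#'
#' A gene is alternatively spliced when its second most abundant form
#' carries more than `min_second` of the transcript abundance; genes below
#' `min_fpkm` adult expression are excluded from abundance-based calls
#' (insufficient coverage to see minor forms). Annotation-based calls
#' (two or more annotated transcripts) are emitted in parallel.
#'
#' @param transcript_fractions data.frame `gene_id`, `transcript`,
#'   `fraction` (fractions sum to <= 1 per gene).
#' @param adult_level named vector of adult FPKM per gene (linear scale).
#' @param min_second abundance threshold for the AS call (default 0.10,
#'   strict).
#' @param min_fpkm expression filter for abundance-based calls (default 2).
#' @return data.frame (class `splicing_calls`): `gene_id`, `n_transcripts`,
#'   `major_fraction`, `second_fraction`, `as_rnaseq` (NA when filtered),
#'   `as_annotation`.
#' @examples
#' tf <- data.frame(gene_id = "g", transcript = c("t1", "t2", "t3"),
#'                  fraction = c(0.47, 0.41, 0.12))
#' splicing_calls(tf, c(g = 10))$as_rnaseq  # TRUE: second form > 10%
#' @export
splicing_calls <- function(transcript_fractions, adult_level,
                           min_second = 0.10, min_fpkm = 2) {
  sp <- split(transcript_fractions$fraction, transcript_fractions$gene_id)
  out <- data.frame(gene_id = names(sp), stringsAsFactors = FALSE)
  out$n_transcripts <- lengths(sp)
  srt <- lapply(sp, sort, decreasing = TRUE)
  out$major_fraction <- vapply(srt, `[`, 0, 1L)
  out$second_fraction <- vapply(srt, function(x)
    if (length(x) > 1L) x[2] else 0, 0)
  lvl <- adult_level[out$gene_id]
  out$as_rnaseq <- ifelse(is.na(lvl) | lvl <= min_fpkm, NA,
                          out$second_fraction > min_second)
  out$as_annotation <- out$n_transcripts >= 2L
  class(out) <- c("splicing_calls", "data.frame")
  out
}

#' Methylation-expression association battery
#'
#' Runs the standard battery relating gene methylation status to
#' expression, each test reported with its n: rank-sum of expression level
#' by status; CV by status within median-level strata; chi-square of
#' alternative splicing by status; Kolmogorov-Smirnov of major-form
#' fraction by status; Spearman correlation of percent mCpG with level
#' among methylated genes; logistic regression of status on level and CV;
#' dip test per class; and breadth-by-status stacked counts.
#'
#' @param statuses `gene_status` table.
#' @param summary `expression_summary` table.
#' @param splicing optional `splicing_calls` table.
#' @param strata median-level cut points for the CV comparison (default
#'   the 9/11/13 grid: strata 9-11, 11-13, >13).
#' @param min_n strata smaller than this are reported as insufficient.
#' @param dip_B,seed Monte-Carlo settings for the dip tests.
#' @return list (class `association_stats`) of named results.
#' @export
association_battery <- function(statuses, summary, splicing = NULL,
                                strata = c(9, 11, 13), min_n = 10L,
                                dip_B = 2000L, seed = 1L) {
  df <- merge(statuses, summary, by = "gene_id")
  df <- df[df$status %in% c("methylated", "non_methylated"), , drop = FALSE]
  meth <- df$status == "methylated"
  res <- list()
  res$n <- c(methylated = sum(meth), non_methylated = sum(!meth))
  ## expression level by status (p = 1 when the pooled values are constant)
  res$level_ranksum <- if (sum(meth) < 2L || sum(!meth) < 2L)
    list(statistic = NA_real_, p = NA_real_, n = nrow(df),
         note = "insufficient n")
  else if (stats::sd(df$median) == 0)
    list(statistic = NA_real_, p = 1, n = nrow(df))
  else with_n(
    stats::wilcox.test(df$median[meth], df$median[!meth], exact = FALSE),
    nrow(df))
  ## stratified CV comparison
  cuts <- c(strata, Inf)
  res$cv_by_stratum <- lapply(seq_len(length(cuts) - 1L), function(k) {
    sel <- df$median > cuts[k] & df$median <= cuts[k + 1L]
    nm <- sum(sel & meth); nn <- sum(sel & !meth)
    if (nm < min_n || nn < min_n)
      return(list(stratum = sprintf("%s-%s", cuts[k], cuts[k + 1L]),
                  n = c(nm, nn), p = NA_real_, note = "insufficient n"))
    w <- stats::wilcox.test(df$cv[sel & meth], df$cv[sel & !meth],
                            exact = FALSE)
    list(stratum = sprintf("%s-%s", cuts[k], cuts[k + 1L]),
         n = c(methylated = nm, non_methylated = nn),
         mean_cv = c(mean(df$cv[sel & meth]), mean(df$cv[sel & !meth])),
         p = w$p.value)
  })
  ## splicing
  if (!is.null(splicing)) {
    sf <- merge(df, splicing, by = "gene_id")
    ok <- !is.na(sf$as_rnaseq)
    if (sum(ok) >= min_n && length(unique(sf$status[ok])) == 2L &&
        length(unique(sf$as_rnaseq[ok])) == 2L) {
      tab <- table(sf$status[ok], sf$as_rnaseq[ok])
      res$as_chisq <- with_n(suppressWarnings(stats::chisq.test(tab)), sum(ok))
      as_m <- sf$as_rnaseq[ok] & sf$status[ok] == "methylated"
      ks <- suppressWarnings(stats::ks.test(
        sf$major_fraction[ok][sf$status[ok] == "methylated"],
        sf$major_fraction[ok][sf$status[ok] == "non_methylated"]))
      res$major_fraction_ks <- with_n(ks, sum(ok))
    }
  }
  ## methylation level vs expression among methylated genes
  mm <- df[meth & !is.na(df$pct_mcpg), , drop = FALSE]
  if (nrow(mm) >= min_n && stats::sd(mm$pct_mcpg) > 0) {
    ct <- suppressWarnings(stats::cor.test(mm$pct_mcpg, mm$median,
                                           method = "spearman"))
    res$pct_vs_level_spearman <- list(rho = unname(ct$estimate),
                                      p = ct$p.value, n = nrow(mm))
  }
  ## logistic regression status ~ level + CV
  fit <- suppressWarnings(stats::glm(meth ~ median + cv, data = df, family = stats::binomial()))
  res$logistic <- list(coef = stats::coef(summary(fit))[, c(1, 4)],
                       n = nrow(df))
  ## dip tests
  res$dip <- list(
    all = if (nrow(df) >= 4L)
      dip_unimodality(df$median, B = dip_B, seed = seed) else NULL,
    methylated = if (sum(meth) >= 4L)
      dip_unimodality(df$median[meth], B = dip_B, seed = seed) else NULL,
    non_methylated = if (sum(!meth) >= 4L)
      dip_unimodality(df$median[!meth], B = dip_B, seed = seed) else NULL)
  ## breadth by status
  res$breadth <- table(status = df$status, breadth = df$breadth)
  class(res) <- "association_stats"
  res
}

with_n <- function(test, n) list(statistic = unname(test$statistic),
                                 p = test$p.value, n = n)
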