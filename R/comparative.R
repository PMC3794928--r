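#' Assign conservation categories from an ortholog presence table
#'
#' Categories follow the standard single-copy ortholog breakdown: genes
#' present in all listed species (`all_species`), genes present only in the
#' focal species and its sister clade representative
#' (`sister_clade_specific`), genes present only in the focal species
#' (`focal_specific`), and `other`. When methylation status and expression
#' summaries are supplied, per-category methylated fractions and rank tests
#' are attached.
#'
#' @param table data.frame with a `gene_id` column and one 0/1 presence
#'   column per species.
#' @param focal name of the focal species column.
#' @param sister name of the sister-clade species column.
#' @param statuses optional `gene_status` table.
#' @param summary optional `expression_summary` table.
#' @return The table with a `category` column (class
#'   `conservation_table`); attribute `stats` holds per-category counts,
#'   methylated fractions and a chi-squared test of status by category
#'   when statuses are given.
#' @export
assign_conservation <- function(table, focal, sister,
                                statuses = NULL, summary = NULL) {
  sp <- setdiff(names(table), "gene_id")
  stopifnot(focal %in% sp, sister %in% sp)
  pres <- as.matrix(table[, sp, drop = FALSE]) > 0
  nall <- rowSums(pres)
  category <- rep("other", nrow(table))
  category[nall == length(sp)] <- "all_species"
  category[pres[, focal] & pres[, sister] & nall == 2L] <- "sister_clade_specific"
  category[pres[, focal] & nall == 1L] <- "focal_specific"
  table$category <- category
  stats <- list(counts = table(category))
  if (!is.null(statuses)) {
    st <- statuses$status[match(table$gene_id, statuses$gene_id)]
    det <- st %in% c("methylated", "non_methylated")
    stats$frac_methylated <- tapply(st[det] == "methylated",
                                    category[det], mean)
    tab <- table(category[det], st[det])
    if (all(dim(tab) >= 2L))
      stats$status_chisq <- suppressWarnings(stats::chisq.test(tab))
    if (!is.null(summary)) {
      df <- merge(data.frame(gene_id = table$gene_id, category = category),
                  merge(statuses, summary, by = "gene_id"), by = "gene_id")
      df <- df[df$status %in% c("methylated", "non_methylated"), ]
      stats$level_by_category <- lapply(split(df, df$category), function(x) {
        if (length(unique(x$status)) < 2L) return(NULL)
        w <- stats::wilcox.test(median ~ status, data = x, exact = FALSE)
        list(n = nrow(x), p = w$p.value)
      })
    }
  }
  attr(table, "stats") <- stats
  class(table) <- c("conservation_table", "data.frame")
  table
}

#' Cross-species methylation-status concordance
#'
#' Builds the 2x2 table of per-gene methylation status in two species and
#' compares the observed both-methylated fraction to the expectation under
#' independence (the product of the marginal methylated fractions), with a
#' chi-squared test of association.
#'
#' @param status_a,status_b logical (or "methylated"/other character)
#'   vectors of per-gene status in the two species, aligned on genes.
#' @return list (class `concordance_report`): `table`, `marginals`,
#'   `observed_both`, `expected_both`, `excess`, `chisq_p`, `n`.
#' @examples
#' a <- rep(c(TRUE, FALSE), c(719, 281)); b <- rep(c(TRUE, FALSE), c(477, 523))
#' concordance_analysis(a, b)$expected_both  # 0.719 * 0.477 = 0.343
#' @export
concordance_analysis <- function(status_a, status_b) {
  to_l <- function(x) if (is.logical(x)) x else x == "methylated"
  a <- to_l(status_a); b <- to_l(status_b)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)),
               dnn = c("species_a", "species_b"))
  ma <- mean(a); mb <- mean(b)
  obs <- mean(a & b)
  pv <- if (all(dim(tab) == 2L) && n >= 10L &&
            min(tab) >= 0L && stats::sd(a) > 0 && stats::sd(b) > 0)
    suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
  structure(list(table = tab, marginals = c(a = ma, b = mb),
                 observed_both = obs, expected_both = ma * mb,
                 excess = obs - ma * mb, chisq_p = pv, n = n),
            class = "concordance_report")
}

#' Paralog methylation-loss analysis
#'
#' For duplicated gene pairs in which one paralog lost methylation (M/N
#' pairs), tests whether the non-methylated copy is expressed lower, more
#' variably, and diverges faster: per-pair N minus M differences in median
#' expression, expression CV, largest stage difference, and branch length
#' to the outgroup ortholog, each under an exact two-sided Wilcoxon
#' matched-pairs signed-rank test. Pairs flagged as possible pseudogenes
#' are excluded before testing.
#'
#' @param pairs data.frame with one row per pair: `pair_id`,
#'   `median_m`, `median_n`, `cv_m`, `cv_n`, `maxdiff_m`, `maxdiff_n`,
#'   `branch_m`, `branch_n`, and optional logical `pseudogene` exclusion
#'   flag (with a `reason` column).
#' @return list (class `paralog_report`): per-metric list with
#'   `differences` (N - M), `p` (exact signed-rank), `n`; `n_excluded`.
#'   A power warning is emitted below 5 usable pairs.
#' @export
paralog_analysis <- function(pairs) {
  excl <- if ("pseudogene" %in% names(pairs)) pairs$pseudogene else
    rep(FALSE, nrow(pairs))
  use <- pairs[!excl, , drop = FALSE]
  if (nrow(use) < 5L)
    warning("fewer than 5 usable pairs; exact tests have little power")
  one <- function(m, n) {
    d <- n - m
    p <- if (all(d == 0)) 1 else
      stats::wilcox.test(n, m, paired = TRUE, exact = TRUE)$p.value
    list(differences = d, p = p, n = length(d))
  }
  structure(list(
    median = one(use$median_m, use$median_n),
    cv = one(use$cv_m, use$cv_n),
    max_stage_diff = one(use$maxdiff_m, use$maxdiff_n),
    branch_length = if (all(c("branch_m", "branch_n") %in% names(use)))
      one(use$branch_m, use$branch_n) else NULL,
    n_pairs = nrow(use), n_excluded = sum(excl)),
    class = "paralog_report")
}

#' Simulate an ortholog presence/status table
#'
#' Synthetic single-copy ortholog table with a planted conservation
#' gradient in methylation odds (conserved genes most often methylated),
#' for exercising [assign_conservation()] and [concordance_analysis()].
#'
#' @param n_genes number of genes.
#' @param species species names; the first is the focal species, the
#'   second the sister clade representative.
#' @param p_category probabilities of (all_species, sister_clade_specific,
#'   focal_specific, other).
#' @param p_meth methylated probability per category, same order.
#' @param concordance probability that the sister species copies the focal
#'   species' methylation status (rather than drawing independently).
#' @param seed RNG seed.
#' @return list with `table` (presence + category truth), `status_focal`,
#'   `status_sister` (logical vectors).
#' @export
simulate_ortholog_table <- function(n_genes = 2000L,
                                    species = c("focal", "sister", "sp3",
                                                "sp4", "sp5", "sp6", "sp7",
                                                "sp8"),
                                    p_category = c(0.5, 0.1, 0.08, 0.32),
                                    p_meth = c(0.71, 0.27, 0.14, 0.4),
                                    concordance = 0.5,
                                    seed = 1L) {
  set.seed(seed)
  cats <- c("all_species", "sister_clade_specific", "focal_specific", "other")
  cat_i <- sample.int(4L, n_genes, replace = TRUE, prob = p_category)
  pres <- matrix(0L, n_genes, length(species),
                 dimnames = list(NULL, species))
  pres[, 1] <- 1L
  for (i in seq_len(n_genes)) {
    pres[i, ] <- switch(cat_i[i],
      rep(1L, length(species)),
      c(1L, 1L, rep(0L, length(species) - 2L)),
      c(1L, rep(0L, length(species) - 1L)),
      { v <- c(1L, 0L, stats::rbinom(length(species) - 2L, 1L, 0.5))
        if (sum(v) == 1L) v[3] <- 1L
        if (sum(v) == length(species)) v[3] <- 0L
        v })
  }
  status_focal <- stats::runif(n_genes) < p_meth[cat_i]
  copy <- stats::runif(n_genes) < concordance
  status_sister <- ifelse(copy, status_focal,
                          stats::runif(n_genes) < mean(p_meth[cat_i]))
  tab <- data.frame(gene_id = sprintf("og%05d", seq_len(n_genes)),
                    pres, true_category = cats[cat_i],
                    stringsAsFactors = FALSE)
  list(table = tab, status_focal = status_focal,
       status_sister = status_sister)
}

#' Simulate paralog pairs with planted specialization of the N copy
#'
#' @param n_pairs number of M/N pairs.
#' @param median_shift,cv_shift,branch_shift planted N-minus-M effects
#'   (negative median shift = N copy expressed lower).
#' @param noise s.d. of pair-level noise.
#' @param seed RNG seed.
#' @return data.frame usable by [paralog_analysis()].
#' @export
simulate_paralog_pairs <- function(n_pairs = 20L, median_shift = -1.5,
                                   cv_shift = 0.2, branch_shift = 0.15,
                                   noise = 0.5, seed = 1L) {
  set.seed(seed)
  m_med <- stats::rnorm(n_pairs, 12, 1)
  data.frame(
    pair_id = sprintf("pair%03d", seq_len(n_pairs)),
    median_m = m_med,
    median_n = m_med + median_shift + stats::rnorm(n_pairs, 0, noise),
    cv_m = abs(stats::rnorm(n_pairs, 0.3, 0.05)),
    cv_n = abs(stats::rnorm(n_pairs, 0.3 + cv_shift, 0.05)),
    maxdiff_m = abs(stats::rnorm(n_pairs, 1, 0.3)),
    maxdiff_n = abs(stats::rnorm(n_pairs, 1 + cv_shift, 0.3)),
    branch_m = abs(stats::rnorm(n_pairs, 0.2, 0.05)),
    branch_n = abs(stats::rnorm(n_pairs, 0.2 + branch_shift, 0.05)),
    pseudogene = FALSE,
    stringsAsFactors = FALSE)
}
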