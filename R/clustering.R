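#' Neighbor-pair classes, distances and permutation nulls
#'
#' Orders determinable genes along each scaffold, classifies every adjacent
#' pair as MM/MN/NM/NN by methylation status, and measures the gap between
#' the adjacent gene spans (0 for overlapping pairs). Null distributions of
#' class counts and mean class distances are obtained by permuting the
#' methylation labels within each scaffold while holding gene positions
#' fixed, which preserves per-scaffold label counts. Two-sided permutation
#' p-values use `(1 + #{|null - mean(null)| >= |obs - mean(null)|}) / (N + 1)`.
#'
#' @param statuses `gene_status` table.
#' @param genome the `annotated_genome`.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the permutation engine.
#' @param top_scaffolds restrict to this many largest scaffolds (by length;
#'   default 100).
#' @return list (class `neighbor_pairs`): `pairs` (per-pair table),
#'   `class_counts`, `mean_distance` per class, `perm` (per-class
#'   [list] with observed, null sample, p, seed, N), `count_chisq_p`.
#' @export
neighbor_pair_analysis <- function(statuses, genome, n_perm = 5000L,
                                   seed = 1L, top_scaffolds = 100L) {
  g <- scoped_genes(statuses, genome, top_scaffolds)
  pairs <- adjacent_pairs(g)
  classes <- c("MM", "MN", "NM", "NN")
  obs_cnt <- vapply(classes, function(k) sum(pairs$class == k), 0L)
  obs_dist <- vapply(classes, function(k)
    mean(pairs$distance[pairs$class == k]), 0)
  set.seed(seed)
  null_dist <- matrix(NA_real_, n_perm, 4L, dimnames = list(NULL, classes))
  null_cnt <- matrix(NA_real_, n_perm, 4L, dimnames = list(NULL, classes))
  lab_by_sc <- split(g$methylated, g$scaffold)
  for (b in seq_len(n_perm)) {
    sh <- unsplit(lapply(lab_by_sc, sample), g$scaffold)
    pc <- pair_class(sh, pairs$i, pairs$j)
    for (k in seq_along(classes)) {
      sel <- pc == classes[k]
      null_cnt[b, k] <- sum(sel)
      null_dist[b, k] <- if (any(sel)) mean(pairs$distance[sel]) else NA_real_
    }
  }
  perm <- lapply(seq_along(classes), function(k) {
    nd <- null_dist[, k]
    p <- perm_pvalue(obs_dist[k], nd)
    list(class = classes[k], observed = obs_dist[k], null = nd,
         p = p, seed = seed, N = n_perm)
  })
  names(perm) <- classes
  exp_cnt <- colMeans(null_cnt)
  chi_p <- if (all(exp_cnt > 0))
    suppressWarnings(stats::chisq.test(obs_cnt, p = exp_cnt / sum(exp_cnt))$p.value) else NA_real_
  structure(list(pairs = pairs, class_counts = obs_cnt,
                 mean_distance = obs_dist, perm = perm,
                 count_chisq_p = chi_p, n_genes = nrow(g)),
            class = "neighbor_pairs")
}

## Determinable genes on the top scaffolds, ordered by position.
scoped_genes <- function(statuses, genome, top_scaffolds) {
  gn <- genome$genes
  st <- statuses$status[match(gn$gene_id, statuses$gene_id)]
  gn$methylated_call <- st
  gn <- gn[st %in% c("methylated", "non_methylated"), , drop = FALSE]
  lens <- Biostrings::width(genome$seq)
  keep_sc <- names(genome$seq)[order(lens, decreasing = TRUE)]
  keep_sc <- keep_sc[seq_len(min(top_scaffolds, length(keep_sc)))]
  gn <- gn[gn$scaffold %in% keep_sc, , drop = FALSE]
  gn <- gn[order(gn$scaffold, gn$start), , drop = FALSE]
  gn$methylated <- gn$methylated_call == "methylated"
  rownames(gn) <- NULL
  gn
}

adjacent_pairs <- function(g) {
  out <- list()
  for (sc in unique(g$scaffold)) {
    idx <- which(g$scaffold == sc)
    if (length(idx) < 2L) next
    i <- idx[-length(idx)]; j <- idx[-1]
    out[[sc]] <- data.frame(
      scaffold = sc, i = i, j = j,
      class = pair_class(g$methylated, i, j),
      distance = pmax(0L, g$start[j] - g$end[i] - 1L),
      orientation = orientation_class(g$strand[i], g$strand[j]),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(), i = integer(), j = integer(),
               class = character(), distance = integer(),
               orientation = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

pair_class <- function(lab, i, j) {
  paste0(ifelse(lab[i], "M", "N"), ifelse(lab[j], "M", "N"))
}

## Orientation of an ordered (upstream, downstream) gene pair. The side of
## each gene facing the shared gap is its head (5' end) or tail (3' end):
## (-,+) -> HH (divergent), (+,-) -> TT (convergent), (+,+) -> TH,
## (-,-) -> HT.
orientation_class <- function(strand_up, strand_dn) {
  up <- ifelse(strand_up == "+", "T", "H")
  dn <- ifelse(strand_dn == "+", "H", "T")
  paste0(up, dn)
}

perm_pvalue <- function(obs, null) {
  null <- null[is.finite(null)]
  if (!length(null) || !is.finite(obs)) return(NA_real_)
  mu <- mean(null)
  (1 + sum(abs(null - mu) >= abs(obs - mu))) / (length(null) + 1)
}

#' Consecutive-run distribution of methylated genes
#'
#' Tallies maximal runs of methylated genes per scaffold and compares them
#' to the expectation under random arrangement of the same per-scaffold
#' label counts, via either the closed-form run-count distribution of a
#' random binary sequence or within-scaffold label permutation. A
#' chi-squared test over pooled length bins and the observed mean run
#' length are reported.
#'
#' @param statuses `gene_status` table.
#' @param genome the `annotated_genome`.
#' @param null `"analytic"` or `"permutation"`.
#' @param n_perm permutations when `null = "permutation"`.
#' @param seed RNG seed.
#' @param top_scaffolds scaffold scope as in [neighbor_pair_analysis()].
#' @return list (class `run_lengths`): `observed` (counts by run length),
#'   `expected`, `mean_run_length`, `chisq_p`, `n_methylated`.
#' @export
run_length_analysis <- function(statuses, genome,
                                null = c("analytic", "permutation"),
                                n_perm = 2000L, seed = 1L,
                                top_scaffolds = 100L) {
  null <- match.arg(null)
  g <- scoped_genes(statuses, genome, top_scaffolds)
  lab_by_sc <- split(g$methylated, g$scaffold)
  obs <- run_tally(lab_by_sc)
  kmax <- max(c(1L, as.integer(names(obs))))
  expected <- numeric(kmax); names(expected) <- seq_len(kmax)
  if (null == "analytic") {
    for (lab in lab_by_sc) {
      e <- expected_run_counts(sum(lab), length(lab))
      k <- seq_along(e)
      if (length(e) > kmax) {      # extend if a scaffold allows longer runs
        expected <- c(expected, numeric(length(e) - kmax))
        names(expected) <- seq_along(expected)
        kmax <- length(e)
      }
      expected[k] <- expected[k] + e
    }
  } else {
    set.seed(seed)
    acc <- numeric(0)
    for (b in seq_len(n_perm)) {
      t <- run_tally(lapply(lab_by_sc, sample))
      kk <- as.integer(names(t))
      if (length(kk) && max(kk) > length(acc))
        acc <- c(acc, numeric(max(kk) - length(acc)))
      acc[kk] <- acc[kk] + t
    }
    expected <- acc / n_perm
    names(expected) <- seq_along(expected)
    if (length(expected) > kmax) kmax <- length(expected)
  }
  obs_full <- numeric(max(kmax, length(expected)))
  names(obs_full) <- seq_along(obs_full)
  obs_full[as.integer(names(obs))] <- obs
  if (length(expected) < length(obs_full)) {
    expected <- c(expected, numeric(length(obs_full) - length(expected)))
    names(expected) <- seq_along(expected)
  }
  chi_p <- run_chisq(obs_full, expected)
  nm <- sum(vapply(lab_by_sc, sum, 0L))
  nruns <- sum(obs)
  structure(list(observed = obs_full, expected = expected,
                 mean_run_length = if (nruns > 0) nm / nruns else NA_real_,
                 chisq_p = chi_p, n_methylated = nm, null = null),
            class = "run_lengths")
}

run_tally <- function(lab_by_sc) {
  lens <- unlist(lapply(lab_by_sc, function(lab) {
    r <- rle(lab)
    r$lengths[r$values]
  }), use.names = FALSE)
  table(lens)
}

## E[count of maximal runs of exactly length k] when m methylated labels are
## arranged uniformly among n positions, for k = 1..m.
expected_run_counts <- function(m, n) {
  if (m == 0L || n == 0L) return(numeric(0))
  e <- numeric(m)
  lc <- lchoose(n, m)
  lch <- function(a, b) if (a < 0L || b < 0L || b > a) -Inf else lchoose(a, b)
  for (k in seq_len(m)) {
    if (k == n) { e[k] <- if (m == n) 1 else 0; next }
    interior <- if (n - k - 1L >= 1L)
      (n - k - 1L) * exp(lch(n - k - 2L, m - k) - lc) else 0
    edge <- 2 * exp(lch(n - k - 1L, m - k) - lc)
    e[k] <- interior + edge
  }
  names(e) <- seq_len(m)
  e
}

## chi-square with expected-count pooling (cells pooled from the right
## until every expected count is >= 5; df = cells - 1).
run_chisq <- function(obs, expected) {
  if (sum(expected) <= 0) return(NA_real_)
  o <- as.numeric(obs); e <- as.numeric(expected)
  while (length(e) > 2L && e[length(e)] < 5) {
    n <- length(e)
    e[n - 1L] <- e[n - 1L] + e[n]; e <- e[-n]
    o[n - 1L] <- o[n - 1L] + o[n]; o <- o[-n]
  }
  keep <- e > 0
  o <- o[keep]; e <- e[keep]
  if (length(e) < 2L) return(NA_real_)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(e) - 1L, lower.tail = FALSE)
}

#' Orientation enrichment of methylation among close gene pairs
#'
#' Among adjacent, non-overlapping gene pairs separated by less than
#' `max_gap` bp, tests whether pair members are methylated more often than
#' the genome-wide methylated proportion within each strand-orientation
#' class (HH head-head/divergent, TT tail-tail/convergent, HT, TH).
#'
#' @param statuses `gene_status` table.
#' @param genome the `annotated_genome`.
#' @param max_gap maximum pair gap in bp (default 1000).
#' @param top_scaffolds scaffold scope.
#' @return data.frame (class `orientation_enrichment`): per orientation
#'   class the pair count, observed methylated-member fraction, expected
#'   fraction, and chi-squared p.
#' @export
orientation_enrichment <- function(statuses, genome, max_gap = 1000L,
                                   top_scaffolds = 100L) {
  g <- scoped_genes(statuses, genome, top_scaffolds)
  pairs <- adjacent_pairs(g)
  pairs <- pairs[pairs$distance > 0L & pairs$distance < max_gap, , drop = FALSE]
  p_meth <- mean(g$methylated)
  out <- lapply(c("HH", "TT", "HT", "TH"), function(k) {
    pp <- pairs[pairs$orientation == k, , drop = FALSE]
    n_members <- 2L * nrow(pp)
    n_meth <- sum(g$methylated[pp$i]) + sum(g$methylated[pp$j])
    pv <- if (n_members >= 10L)
      suppressWarnings(stats::chisq.test(c(n_meth, n_members - n_meth),
                        p = c(p_meth, 1 - p_meth))$p.value) else NA_real_
    data.frame(orientation = k, n_pairs = nrow(pp),
               frac_methylated = if (n_members > 0) n_meth / n_members else NA_real_,
               expected_frac = p_meth, chisq_p = pv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("orientation_enrichment", "data.frame")
  res
}
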