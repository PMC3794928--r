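#' Simulate stage-by-gene expression with methylation-linked structure
#'
#' Emulates the expression architecture associated with gene-body
#' methylation: methylated genes are constitutively expressed (a unimodal,
#' high-median distribution with low across-stage coefficient of
#' variation), while non-methylated genes are a mixture of silent,
#' stage-specific and broadly expressed classes, which makes the all-gene
#' marginal distribution bimodal. Also emits adult FPKM-like abundances
#' (log-normal mixture on the same pattern) and per-gene transcript
#' abundance fractions for alternative-splicing analyses (independent of
#' methylation status by construction).
#'
#' @param genome an `annotated_genome` (supplies gene ids and truth labels).
#' @param config the [sim_config()].
#' @param n_stages number of developmental stages (default from config).
#' @param sd_meth,sd_nonmeth across-stage standard deviations of the
#'   methylated / broadly expressed non-methylated classes (log2 units); 0
#'   gives CV = 0 for every gene of that class.
#' @return An object of class `expression_matrix`: list with `values`
#'   (gene x stage matrix of normalized log2 levels), `adult_fpkm` (named
#'   vector, linear scale), `transcripts` (data.frame gene_id, transcript,
#'   fraction), `classes` (generator class per gene).
#' @export
simulate_expression <- function(genome, config, n_stages = config$n_stages,
                                sd_meth = 0.6, sd_nonmeth = 1.1) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  gn <- genome$genes
  n <- nrow(gn)
  vals <- matrix(NA_real_, n, n_stages,
                 dimnames = list(gn$gene_id,
                                 sprintf("stage_%d", seq_len(n_stages))))
  cls <- character(n)
  lfpkm <- numeric(n)
  for (i in seq_len(n)) {
    if (gn$methylated[i]) {
      cls[i] <- "constitutive"
      mu <- stats::rnorm(1, 12.3, 0.9)
      vals[i, ] <- mu + stats::rnorm(n_stages, 0, sd_meth)
      lfpkm[i] <- stats::rnorm(1, 1.25, 0.45)
    } else {
      u <- stats::runif(1)
      if (u < 0.35) {                       # silent/near-silent
        cls[i] <- "silent"
        vals[i, ] <- stats::rnorm(n_stages, 7.6, 0.5)
        lfpkm[i] <- stats::rnorm(1, -0.9, 0.55)
      } else if (u < 0.75) {                # stage-specific
        cls[i] <- "stage_specific"
        on <- stats::runif(n_stages) < 0.45
        if (!any(on)) on[sample.int(n_stages, 1L)] <- TRUE
        vals[i, ] <- ifelse(on, stats::rnorm(n_stages, 11.8, 1.0),
                            stats::rnorm(n_stages, 7.8, 0.5))
        ## adult abundance depends on whether the gene is on in adults
        lfpkm[i] <- if (stats::runif(1) < 0.45)
          stats::rnorm(1, 0.7, 0.5) else stats::rnorm(1, -0.9, 0.5)
      } else {                              # broadly expressed
        cls[i] <- "broad"
        mu <- stats::rnorm(1, 11.6, 1.0)
        vals[i, ] <- mu + stats::rnorm(n_stages, 0, sd_nonmeth)
        lfpkm[i] <- stats::rnorm(1, 0.9, 0.5)
      }
    }
  }
  ## transcript abundance fractions, independent of methylation status
  tr <- list()
  for (i in seq_len(n)) {
    k <- sample(1:4, 1L, prob = c(0.45, 0.3, 0.15, 0.1))
    w <- sort(stats::rgamma(k, 1.6), decreasing = TRUE)
    w <- w / sum(w)
    tr[[i]] <- data.frame(gene_id = gn$gene_id[i],
                          transcript = sprintf("%s.t%d", gn$gene_id[i],
                                               seq_len(k)),
                          fraction = w, stringsAsFactors = FALSE)
  }
  structure(list(values = vals,
                 adult_fpkm = stats::setNames(10^lfpkm, gn$gene_id),
                 transcripts = do.call(rbind, tr),
                 classes = stats::setNames(cls, gn$gene_id)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$values), "genes x", ncol(x$values),
      "stages\n")
  invisible(x)
}
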