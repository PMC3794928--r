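#' Simulation configuration
#'
#' Builds and validates the configuration object that drives every simulator
#' in the package. Defaults emulate the structure of an adult-female insect
#' WGBS study: a sparsely methylated gene-body methylome with 5'-biased,
#' exon-enriched CpG methylation in roughly 30% of genes, near-zero
#' methylation elsewhere and in transposable-element genes, ~0.3% bisulfite
#' conversion failure, a 0.5% unmethylated spike-in control, and
#' stage-by-gene expression where methylated genes are constitutively
#' expressed (low CV) while non-methylated genes are bimodal/stage-specific.
#'
#' @param seed integer seed; the same config (including seed) reproduces
#'   byte-identical outputs.
#' @param n_scaffolds,scaffold_length number and length (bp) of scaffolds.
#' @param n_genes total gene models to place (error if they cannot be packed).
#' @param p_methylated_gene stationary probability that a (non-TE) gene is
#'   methylated.
#' @param cluster_stickiness probability that a gene copies its 5' neighbour's
#'   methylation label, producing runs of like-labelled genes. With
#'   stickiness s and methylated fraction p the mean methylated-run length is
#'   1/(1 - (s + (1-s)p)).
#' @param gc_content background GC fraction of simulated scaffolds.
#' @param cgi_insert_rate per-gene probability of a CpG-rich promoter-region
#'   insert (a detectable CpG island).
#' @param n_te number of genes flagged as expressed transposable-element
#'   genes (forced non-methylated).
#' @param read_length,coverage single-end read length (bp) and fold coverage.
#' @param conversion_failure probability that a truly unmethylated C escapes
#'   bisulfite conversion and reads as C.
#' @param seq_error per-base sequencing substitution error rate.
#' @param spike_in_fraction fraction of reads drawn from the fully
#'   unmethylated control sequence.
#' @param methylation_profile named list of piecewise per-region methylation
#'   probabilities for methylated genes (see Details).
#' @param n_stages number of developmental stages for expression simulation.
#'
#' @details The `methylation_profile` entries are probabilities that a CpG in
#' the region is a methylated site (a site drawn methylated gets a
#' within-site methylation fraction from `Beta(meth_shape1, meth_shape2)`,
#' biased toward high fractions): `upstream`, `utr5`, `cds` (first
#' `cds_plateau` bp of spliced CDS), `cds_decay_bp` (exponential length scale
#' of the 3' decay beyond the plateau), `intron_discount` (multiplier applied
#' inside introns), `utr3`, `downstream`, and `background` (true methylation
#' fraction of every CpG outside methylated-gene bodies, and of non-methylated
#' sites inside them).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_scaffolds = 1, scaffold_length = 20000,
#'                   n_genes = 5)
#' cfg$coverage
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 6L,
                       scaffold_length = 80000L,
                       n_genes = 90L,
                       p_methylated_gene = 0.30,
                       cluster_stickiness = 0.42,
                       gc_content = 0.42,
                       cgi_insert_rate = 0.15,
                       n_te = round(0.09 * n_genes),
                       read_length = 75L,
                       coverage = 20,
                       conversion_failure = 0.003,
                       seq_error = 0.002,
                       spike_in_fraction = 0.005,
                       methylation_profile = list(
                         upstream = 0.02, utr5 = 0.03,
                         cds = 0.80, cds_plateau = 1000, cds_decay_bp = 700,
                         intron_discount = 0.35, utr3 = 0.05,
                         downstream = 0.02, background = 0.005,
                         meth_shape1 = 8, meth_shape2 = 1.5),
                       n_stages = 5L) {
  cfg <- list(seed = as.integer(seed),
              n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              n_genes = as.integer(n_genes),
              p_methylated_gene = p_methylated_gene,
              cluster_stickiness = cluster_stickiness,
              gc_content = gc_content,
              cgi_insert_rate = cgi_insert_rate,
              n_te = as.integer(n_te),
              read_length = as.integer(read_length),
              coverage = coverage,
              conversion_failure = conversion_failure,
              seq_error = seq_error,
              spike_in_fraction = spike_in_fraction,
              methylation_profile = methylation_profile,
              n_stages = as.integer(n_stages))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_methylated_gene, cfg$cluster_stickiness, cfg$gc_content,
             cfg$cgi_insert_rate, cfg$conversion_failure, cfg$seq_error,
             cfg$spike_in_fraction,
             cfg$methylation_profile$upstream, cfg$methylation_profile$utr5,
             cfg$methylation_profile$cds, cfg$methylation_profile$intron_discount,
             cfg$methylation_profile$utr3, cfg$methylation_profile$downstream,
             cfg$methylation_profile$background)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities in a sim_config must lie in [0, 1]")
  if (!is.finite(cfg$coverage) || cfg$coverage <= 0)
    stop("coverage must be > 0")
  if (cfg$read_length < 20L)
    stop("read_length must be >= 20 bp")
  if (cfg$n_scaffolds < 1L || cfg$scaffold_length < 1L)
    stop("need at least one scaffold of positive length")
  if (cfg$n_genes < 0L || cfg$n_te < 0L || cfg$n_te > cfg$n_genes)
    stop("n_genes and n_te must be non-negative with n_te <= n_genes")
  if (cfg$n_stages < 2L)
    stop("n_stages must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_scaffolds, "scaffolds x",
      x$scaffold_length, "bp |", x$n_genes, "genes (", x$n_te, "TE ) | ",
      x$coverage, "x coverage,", x$read_length, "bp reads\n")
  invisible(x)
}
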