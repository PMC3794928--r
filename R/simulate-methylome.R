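#' Simulate a true methylome over the CpG dyads of a genome
#'
#' Assigns every CpG dyad a true methylation fraction. Inside methylated
#' (non-TE) genes the probability that a dyad is a methylated site follows a
#' piecewise region profile: low in the 1 kbp upstream flank and UTRs, high
#' across the first ~1 kbp of spliced CDS, decaying exponentially 3' of that
#' plateau, and discounted inside introns. Sites drawn methylated receive a
#' within-site fraction from a Beta distribution biased toward high
#' methylation; all other dyads (including every dyad of non-methylated
#' genes, TE genes and intergenic sequence) sit at the background fraction
#' (<= 1%). Both strands of a dyad share one fraction.
#'
#' @param genome an `annotated_genome` from [simulate_genome()].
#' @param config the [sim_config()] used to build it.
#' @return An object of class `true_methylome`: a data.frame with one row
#'   per CpG dyad (`scaffold`, `pos` = 1-based Watson-C position, `frac` =
#'   true methylation fraction, `region`, `gene_id`, `meth_site`).
#' @export
simulate_methylome <- function(genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  mp <- config$methylation_profile
  out <- list()
  for (sc in names(genome$seq)) {
    s <- as.character(genome$seq[[sc]])
    L <- nchar(s)
    dyads <- unlist(gregexpr("CG", s, fixed = TRUE))
    dyads <- dyads[dyads > 0L]
    pvec <- numeric(L)                 # P(dyad is a methylated site)
    region <- rep("intergenic", L)
    genevec <- rep(NA_character_, L)
    gn <- genome$genes[genome$genes$scaffold == sc, , drop = FALSE]
    for (i in seq_len(nrow(gn))) {
      g <- gn[i, ]
      lab_regions(genome, g, L, function(pos, reg) {
        region[pos] <<- reg
        genevec[pos] <<- g$gene_id
      })
      if (!g$methylated || g$is_te) next
      lev <- region_levels(genome, g, L, mp)
      pvec[lev$pos] <- lev$p
    }
    if (length(dyads)) {
      p <- pvec[dyads]
      meth_site <- stats::runif(length(dyads)) < p
      frac <- ifelse(meth_site,
                     stats::rbeta(length(dyads), mp$meth_shape1, mp$meth_shape2),
                     mp$background)
      out[[sc]] <- data.frame(scaffold = sc, pos = dyads, frac = frac,
                              region = region[dyads],
                              gene_id = genevec[dyads],
                              meth_site = meth_site,
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(), pos = integer(), frac = numeric(),
               region = character(), gene_id = character(),
               meth_site = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("true_methylome", "data.frame")
  res
}

## Call fn(positions, region_label) for every annotated region of one gene.
lab_regions <- function(genome, g, L, fn) {
  f <- genome$features[genome$features$gene_id == g$gene_id, , drop = FALSE]
  up <- gene_flank_positions(genome, g$gene_id, 1000L, "upstream")
  dn <- gene_flank_positions(genome, g$gene_id, 1000L, "downstream")
  if (length(up)) fn(up, "upstream")
  if (length(dn)) fn(dn, "downstream")
  span <- seq.int(g$start, g$end)
  fn(span, "intron")                   # default inside the span
  for (k in which(f$type == "CDS")) fn(seq.int(f$start[k], f$end[k]), "cds")
  for (k in which(f$type == "five_prime_UTR"))
    fn(seq.int(f$start[k], f$end[k]), "utr5")
  for (k in which(f$type == "three_prime_UTR"))
    fn(seq.int(f$start[k], f$end[k]), "utr3")
}

## Per-position methylated-site probability for one methylated gene.
region_levels <- function(genome, g, L, mp) {
  pos <- integer(0); p <- numeric(0)
  add <- function(q, v) {
    if (length(q)) { pos <<- c(pos, q); p <<- c(p, rep_len(v, length(q))) }
  }
  add(gene_flank_positions(genome, g$gene_id, 1000L, "upstream"), mp$upstream)
  add(gene_flank_positions(genome, g$gene_id, 1000L, "downstream"), mp$downstream)
  f <- genome$features[genome$features$gene_id == g$gene_id, , drop = FALSE]
  for (k in which(f$type == "five_prime_UTR"))
    add(seq.int(f$start[k], f$end[k]), mp$utr5)
  for (k in which(f$type == "three_prime_UTR"))
    add(seq.int(f$start[k], f$end[k]), mp$utr3)
  cpos <- gene_cds_positions(genome, g$gene_id)[[1]]
  d <- seq_along(cpos)
  lev <- ifelse(d <= mp$cds_plateau, mp$cds,
                mp$cds * exp(-(d - mp$cds_plateau) / mp$cds_decay_bp))
  pos <- c(pos, cpos); p <- c(p, lev)
  ## introns: discount times the CDS level at the preceding coding exon end
  cds <- f[f$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(cds) > 1L) {
    for (k in seq_len(nrow(cds) - 1L)) {
      ipos <- seq.int(cds$end[k] + 1L, cds$start[k + 1L] - 1L)
      ## spliced distance of the intron's 5' flanking CDS base
      flank <- if (g$strand == "+") cds$end[k] else cds$start[k + 1L]
      dflank <- match(flank, cpos)
      ilev <- mp$intron_discount *
        (if (dflank <= mp$cds_plateau) mp$cds else
           mp$cds * exp(-(dflank - mp$cds_plateau) / mp$cds_decay_bp))
      add(ipos, ilev)
    }
  }
  keep <- pos >= 1L & pos <= L
  list(pos = pos[keep], p = p[keep])
}
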