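#' Simulate an annotated genome with clustered gene methylation labels
#'
#' Generates i.i.d.-base scaffolds at the configured GC content and packs
#' non-overlapping multi-exon gene models onto them (each with 5'/3' UTRs,
#' at least two coding exons, and a strand). A subset of genes is flagged as
#' expressed transposable-element (TE) genes and forced non-methylated.
#' Methylation labels for the remaining genes are assigned by a two-state
#' chain along each scaffold: a gene copies its 5' neighbour's label with
#' probability `cluster_stickiness`, otherwise draws fresh from
#' `p_methylated_gene`, which produces runs of co-methylated neighbours like
#' those seen in real gene-body methylomes.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `annotated_genome`: a list with `seq`
#'   (a [Biostrings::DNAStringSet] of scaffolds), `genes` (one row per gene:
#'   id, scaffold, span, strand, TE flag, methylation label, structure
#'   summaries) and `features` (GFF3-like rows: gene/mRNA/exon/CDS/UTR with
#'   1-based closed coordinates).
#' @seealso [write_genome()] to serialize as FASTA + GFF3 + truth TSV.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  scaf_names <- sprintf("scaffold_%d", seq_len(config$n_scaffolds))
  scafs <- lapply(scaf_names, function(nm)
    random_dna(config$scaffold_length, config$gc_content))
  names(scafs) <- scaf_names

  genes <- list(); features <- list()
  if (config$n_genes > 0L) {
    placed <- 0L; si <- 1L
    cursor <- 1L + 200L
    prev_label <- NA
    while (placed < config$n_genes) {
      if (si > config$n_scaffolds)
        stop("infeasible packing: ", config$n_genes, " genes do not fit on ",
             config$n_scaffolds, " scaffolds of ", config$scaffold_length,
             " bp (placed ", placed, ")")
      st <- sample_gene_structure()
      ## two-state label chain, drawn at placement time: a gene copying its
      ## 5' neighbour's label also sits closer to it, so co-methylated
      ## tandem genes are physically clustered, not just run-correlated
      copied <- !is.na(prev_label) &&
        stats::runif(1) < config$cluster_stickiness
      label <- if (copied) prev_label else
        stats::runif(1) < config$p_methylated_gene
      gap <- if (copied) sample(300:800, 1L) else sample(900:2400, 1L)
      gstart <- cursor + gap
      gend <- gstart + st$tx_len - 1L
      if (gend + 200L > config$scaffold_length) {
        si <- si + 1L; cursor <- 1L + 200L; prev_label <- NA
        next
      }
      placed <- placed + 1L
      gid <- sprintf("gene%05d", placed)
      strand <- sample(c("+", "-"), 1L)
      feat <- layout_gene_features(gid, scaf_names[si], gstart, strand, st)
      genes[[placed]] <- data.frame(
        gene_id = gid, scaffold = scaf_names[si],
        start = gstart, end = gend, strand = strand,
        n_exons = st$n_exons, tx_len = st$tx_len, cds_len = st$cds_len,
        methylated = label,
        stringsAsFactors = FALSE)
      features[[placed]] <- feat
      cursor <- gend
      prev_label <- label
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), scaffold = character(),
               start = integer(), end = integer(), strand = character(),
               n_exons = integer(), tx_len = integer(), cds_len = integer(),
               methylated = logical(), stringsAsFactors = FALSE)
  features <- if (length(features)) do.call(rbind, features) else
    data.frame(gene_id = character(), type = character(),
               scaffold = character(), start = integer(), end = integer(),
               strand = character(), rank = integer(), stringsAsFactors = FALSE)

  n <- nrow(genes)
  genes$is_te <- logical(n)
  if (n > 0L && config$n_te > 0L)
    genes$is_te[sample.int(n, min(config$n_te, n))] <- TRUE

  genes$methylated[genes$is_te] <- FALSE   # TE genes are never methylated

  ## CpG-rich promoter inserts
  if (n > 0L && config$cgi_insert_rate > 0) {
    has_cgi <- stats::runif(n) < config$cgi_insert_rate
    for (i in which(has_cgi)) {
      tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i]
      lo <- max(1L, tss - 120L)
      hi <- min(config$scaffold_length, tss + 180L)
      ins <- cpg_rich_dna(hi - lo + 1L)
      s <- scafs[[genes$scaffold[i]]]
      substr(s, lo, hi) <- ins
      scafs[[genes$scaffold[i]]] <- s
    }
    genes$cgi_insert <- has_cgi
  } else {
    genes$cgi_insert <- logical(n)
  }

  out <- list(seq = Biostrings::DNAStringSet(unlist(scafs)),
              genes = genes, features = features, config = config)
  names(out$seq) <- scaf_names
  class(out) <- "annotated_genome"
  out
}

## Two-state methylation label chain: each gene copies its 5' neighbour
## with probability `stickiness`, else draws Bernoulli(p).  Stationary
## methylated fraction is p; mean methylated-run length is
## 1 / (1 - (stickiness + (1 - stickiness) * p)).
label_chain <- function(n, p, stickiness) {
  if (n == 0L) return(logical(0))
  lab <- logical(n)
  lab[1] <- stats::runif(1) < p
  if (n > 1L) {
    copy <- stats::runif(n - 1L) < stickiness
    fresh <- stats::runif(n - 1L) < p
    for (i in 2:n) lab[i] <- if (copy[i - 1L]) lab[i - 1L] else fresh[i - 1L]
  }
  lab
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

## CpG-rich, GC-rich sequence for promoter-island inserts
cpg_rich_dna <- function(n) {
  out <- character(0)
  while (sum(nchar(out)) < n) {
    out <- c(out, if (stats::runif(1) < 0.15) "CG" else
      sample(c("A", "T", "G", "C"), 1, prob = c(0.175, 0.175, 0.325, 0.325)))
  }
  substr(paste(out, collapse = ""), 1L, n)
}

## Draw one gene structure in transcript-local coordinates (5'->3').
sample_gene_structure <- function() {
  utr5 <- sample(100:300, 1L); utr3 <- sample(100:300, 1L)
  n_exons <- sample(2:8, 1L)
  ce <- sample(120:600, n_exons, replace = TRUE)
  ce[n_exons] <- ce[n_exons] - sum(ce) %% 3L
  introns <- sample(60:450, n_exons - 1L, replace = TRUE)
  list(utr5 = utr5, utr3 = utr3, n_exons = n_exons, exon_cds = ce,
       introns = introns, cds_len = sum(ce),
       tx_len = utr5 + utr3 + sum(ce) + sum(introns))
}

## Convert a local gene structure into GFF3-like feature rows.
layout_gene_features <- function(gid, scaffold, gstart, strand, st) {
  ## local transcript coordinates, 1 = 5' end of the transcript
  ne <- st$n_exons
  exon_lo <- integer(ne); exon_hi <- integer(ne)
  cds_lo <- integer(ne); cds_hi <- integer(ne)
  cur <- 1L
  for (k in seq_len(ne)) {
    lo <- cur
    len <- st$exon_cds[k] +
      (if (k == 1L) st$utr5 else 0L) + (if (k == ne) st$utr3 else 0L)
    hi <- lo + len - 1L
    exon_lo[k] <- lo; exon_hi[k] <- hi
    cds_lo[k] <- lo + (if (k == 1L) st$utr5 else 0L)
    cds_hi[k] <- hi - (if (k == ne) st$utr3 else 0L)
    cur <- hi + 1L + (if (k < ne) st$introns[k] else 0L)
  }
  tx_len <- st$tx_len
  ## map local [lo,hi] to genomic 1-based closed coordinates
  loc2gen <- function(lo, hi) {
    if (strand == "+") cbind(gstart + lo - 1L, gstart + hi - 1L)
    else cbind(gstart + (tx_len - hi), gstart + (tx_len - lo))
  }
  rows <- list()
  add <- function(type, lo, hi, rank = NA_integer_) {
    g <- loc2gen(lo, hi)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, type = type, scaffold = scaffold,
      start = g[1], end = g[2], strand = strand, rank = rank,
      stringsAsFactors = FALSE)
  }
  add("gene", 1L, tx_len); add("mRNA", 1L, tx_len)
  for (k in seq_len(ne)) add("exon", exon_lo[k], exon_hi[k], k)
  for (k in seq_len(ne)) add("CDS", cds_lo[k], cds_hi[k], k)
  add("five_prime_UTR", 1L, st$utr5)
  add("three_prime_UTR", tx_len - st$utr3 + 1L, tx_len)
  do.call(rbind, rows)
}

#' Write an annotated genome as FASTA + GFF3 + truth-label TSV
#'
#' @param genome an `annotated_genome`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_genome <- function(genome, dir, prefix = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  tsv <- file.path(dir, paste0(prefix, "_truth.tsv"))
  Biostrings::writeXStringSet(genome$seq, fa)
  export_gff3(genome, gff)
  utils::write.table(genome$genes, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, truth = tsv))
}

export_gff3 <- function(genome, path) {
  f <- genome$features
  if (nrow(f) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  te <- genome$genes$is_te[match(f$gene_id, genome$genes$gene_id)]
  id <- ifelse(f$type == "gene", f$gene_id,
        ifelse(f$type == "mRNA", paste0(f$gene_id, ".t1"),
               paste0(f$gene_id, ".t1.", tolower(f$type), ".",
                      ifelse(is.na(f$rank), 1L, f$rank))))
  parent <- ifelse(f$type == "gene", NA_character_,
            ifelse(f$type == "mRNA", f$gene_id, paste0(f$gene_id, ".t1")))
  ## CDS phase in coding order
  phase <- rep(NA_integer_, nrow(f))
  for (g in unique(f$gene_id[f$type == "CDS"])) {
    k <- which(f$gene_id == g & f$type == "CDS")
    k <- k[order(f$start[k], decreasing = f$strand[k[1]] == "-")]
    lens <- f$end[k] - f$start[k] + 1L
    phase[k] <- c(0L, cumsum(lens)[-length(k)]) %% 3L
    phase[k] <- (3L - phase[k]) %% 3L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = f$scaffold,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$phase <- phase
  S4Vectors::mcols(gr)$ID <- id
  S4Vectors::mcols(gr)$Parent <- parent
  S4Vectors::mcols(gr)$te_gene <- ifelse(f$type == "gene" & te, "true", NA)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome>", length(x$seq), "scaffolds,",
      sum(Biostrings::width(x$seq)), "bp,", nrow(x$genes), "genes (",
      sum(x$genes$is_te), "TE,", sum(x$genes$methylated), "methylated )\n")
  invisible(x)
}
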