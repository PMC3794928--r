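## Shared fixtures, built lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

## A small but complete study: 2 scaffolds, 16 genes, 20x coverage,
## spike-in control, full alignment and cytosine report.
small_run <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  cfg <- sim_config(seed = 11, n_scaffolds = 2, scaffold_length = 40000,
                    n_genes = 16, n_te = 2, coverage = 20)
  genome <- simulate_genome(cfg)
  methylome <- simulate_methylome(genome, cfg)
  control <- simulate_control_genome(seed = 12)
  reads <- simulate_bisulfite_reads(genome, methylome, cfg, control)
  refs <- build_converted_references(genome)
  genome_reads <- reads$reads[!reads$origin$control]
  placed <- align_bisulfite_reads(genome_reads, refs)
  report <- extract_cytosine_report(placed, genome)
  statuses <- call_gene_status(report, genome)
  .fixtures$small <- list(cfg = cfg, genome = genome, methylome = methylome,
                          control = control, reads = reads, refs = refs,
                          placed = placed, report = report,
                          statuses = statuses)
  .fixtures$small
}

## The full-scale study at 20x with spike-in control: used by the
## acceptance checks (status recovery, conversion efficiency, profiles).
acceptance_run <- function() {
  if (!is.null(.fixtures$acceptance)) return(.fixtures$acceptance)
  cfg <- sim_config(seed = 1, n_scaffolds = 12, scaffold_length = 75000,
                    n_genes = 180, n_te = 16)
  genome <- simulate_genome(cfg)
  methylome <- simulate_methylome(genome, cfg)
  control <- simulate_control_genome(seed = cfg$seed + 9L)
  reads <- simulate_bisulfite_reads(genome, methylome, cfg, control)
  aln <- methatlas:::align_stage(reads$reads, genome, control)
  statuses <- call_gene_status(aln$report, genome)
  .fixtures$acceptance <- list(cfg = cfg, genome = genome,
                               methylome = methylome, control = control,
                               reads = reads, aln = aln,
                               statuses = statuses)
  .fixtures$acceptance
}

## Independent brute-force pileup: per genomic cytosine, recount coverage
## and unconverted reads by direct per-column scanning.
oracle_pileup <- function(placed, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  rows <- list()
  for (sc in names(seqs)) {
    chars <- strsplit(as.character(seqs[[sc]]), "")[[1]]
    L <- length(chars)
    p <- placed[placed$scaffold == sc, , drop = FALSE]
    for (pos in seq_len(L)) {
      if (chars[pos] == "C") { strand <- "+"; un_b <- "C" }
      else if (chars[pos] == "G") { strand <- "-"; un_b <- "G" }
      else next
      ctx <- if (strand == "+") {
        if (pos < L && chars[pos + 1] == "G") "CpG" else "nonCpG"
      } else {
        if (pos > 1 && chars[pos - 1] == "C") "CpG" else "nonCpG"
      }
      cov <- 0L; un <- 0L
      if (nrow(p)) {
        for (k in seq_len(nrow(p))) {
          if (p$strand[k] != strand) next
          len <- nchar(p$seq_watson[k])
          if (p$start[k] <= pos && p$start[k] + len - 1L >= pos) {
            cov <- cov + 1L
            b <- substr(p$seq_watson[k], pos - p$start[k] + 1L,
                        pos - p$start[k] + 1L)
            if (b == un_b) un <- un + 1L
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, pos = pos, strand = strand, context = ctx,
        coverage = cov, unconverted = un, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$pos, out$strand), ]
  out$fraction <- ifelse(out$coverage > 0, out$unconverted / out$coverage,
                         NA_real_)
  rownames(out) <- NULL
  out
}

## Exact two-sided signed-rank p by full enumeration of the 2^n sign null.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ew <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_null <- as.matrix(signs) %*% r
  mean(abs(w_null - ew) >= abs(w_obs - ew) - 1e-9)
}

## Minimal hand-built annotated genome for geometry tests: genes given as
## data.frame(start, end, strand) on one scaffold.
toy_genome <- function(genes, scaffold_length = 200000L) {
  n <- nrow(genes)
  gn <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                   scaffold = "s1", start = genes$start, end = genes$end,
                   strand = genes$strand, n_exons = 2L,
                   tx_len = genes$end - genes$start + 1L,
                   cds_len = genes$end - genes$start + 1L,
                   is_te = FALSE, methylated = FALSE, cgi_insert = FALSE,
                   stringsAsFactors = FALSE)
  seq <- Biostrings::DNAStringSet(strrep("A", scaffold_length))
  names(seq) <- "s1"
  structure(list(seq = seq, genes = gn,
                 features = data.frame(gene_id = character(),
                                       type = character(),
                                       scaffold = character(),
                                       start = integer(), end = integer(),
                                       strand = character(),
                                       rank = integer())),
            class = "annotated_genome")
}

toy_statuses <- function(genome, methylated) {
  data.frame(gene_id = genome$genes$gene_id,
             n_covered = 10L, n_mcpg = ifelse(methylated, 5L, 0L),
             pct_mcpg = ifelse(methylated, 50, 0),
             status = ifelse(methylated, "methylated", "non_methylated"),
             reason = NA_character_, stringsAsFactors = FALSE)
}
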