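## Shared annotation helpers: spliced-CDS coordinate maps, overlap screens.

## Genomic positions of each gene's spliced CDS, ordered 5'->3' in coding
## orientation. Returns a named list of integer vectors.
gene_cds_positions <- function(genome, gene_ids = NULL) {
  f <- genome$features[genome$features$type == "CDS", , drop = FALSE]
  if (is.null(gene_ids)) gene_ids <- unique(f$gene_id)
  out <- vector("list", length(gene_ids)); names(out) <- gene_ids
  for (g in gene_ids) {
    rows <- f[f$gene_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) { out[[g]] <- integer(0); next }
    if (rows$strand[1] == "+") {
      rows <- rows[order(rows$start), , drop = FALSE]
      out[[g]] <- unlist(Map(seq.int, rows$start, rows$end), use.names = FALSE)
    } else {
      rows <- rows[order(rows$start, decreasing = TRUE), , drop = FALSE]
      out[[g]] <- unlist(Map(function(s, e) seq.int(e, s), rows$start, rows$end),
                         use.names = FALSE)
    }
  }
  out
}

## Genomic positions of the whole transcript span ordered 5'->3'.
gene_tx_positions <- function(genome, gene_ids = NULL) {
  gn <- genome$genes
  if (is.null(gene_ids)) gene_ids <- gn$gene_id
  out <- vector("list", length(gene_ids)); names(out) <- gene_ids
  for (g in gene_ids) {
    r <- gn[gn$gene_id == g, ]
    out[[g]] <- if (r$strand == "+") seq.int(r$start, r$end) else
      seq.int(r$end, r$start)
  }
  out
}

## Gene ids whose genomic spans overlap another gene model on the same
## scaffold; such genes are excluded from genic CpG accounting.
overlapping_gene_ids <- function(genome) {
  gn <- genome$genes
  if (nrow(gn) < 2L) return(character(0))
  bad <- character(0)
  for (sc in unique(gn$scaffold)) {
    g <- gn[gn$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) next
    ov <- g$start[-1] <= cummax(g$end[-nrow(g)])
    if (any(ov)) {
      ids <- unique(c(g$gene_id[-1][ov], g$gene_id[which(ov)]))
      bad <- c(bad, ids)
    }
  }
  unique(bad)
}

## Per-gene upstream/downstream flank positions (strand-aware, 5'->3').
gene_flank_positions <- function(genome, gene_id, width = 1000L,
                                 side = c("upstream", "downstream")) {
  side <- match.arg(side)
  r <- genome$genes[genome$genes$gene_id == gene_id, ]
  L <- Biostrings::width(genome$seq)[match(r$scaffold, names(genome$seq))]
  fivep <- (r$strand == "+") == (side == "upstream")
  if (fivep) {
    lo <- max(1L, r$start - width); hi <- r$start - 1L
    if (hi < lo) return(integer(0))
    p <- seq.int(lo, hi)
  } else {
    lo <- r$end + 1L; hi <- min(L, r$end + width)
    if (hi < lo) return(integer(0))
    p <- seq.int(lo, hi)
  }
  if (r$strand == "+") p else rev(p)
}
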