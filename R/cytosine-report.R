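#' Extract the per-cytosine methylation report from placed reads
#'
#' Piles up uniquely placed reads over every genomic cytosine on both
#' strands. Watson-strand reads inform Watson Cs (read base C = unconverted,
#' T = converted); Crick-strand reads inform Crick Cs, which sit at Watson G
#' positions (in Watson orientation, read base G = unconverted, A =
#' converted). Context is assigned from the reference: a Watson C followed
#' by G, or a Crick C whose Watson G is preceded by C, is CpG; all other
#' cytosines are non-CpG.
#'
#' @param placed a `placed_reads` object (unique placements only).
#' @param genome an `annotated_genome` or [Biostrings::DNAStringSet].
#' @return An object of class `cytosine_report`: a data.frame with one row
#'   per genomic cytosine (`scaffold`, `pos` 1-based, `strand`, `context`,
#'   `coverage`, `unconverted`, `fraction`).
#' @export
extract_cytosine_report <- function(placed, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  out <- list()
  for (si in seq_along(seqs)) {
    sc <- names(seqs)[si]
    s <- as.character(seqs[[si]])
    L <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    wpos <- which(chars == "C")
    cpos <- which(chars == "G")
    wmap <- integer(L); wmap[wpos] <- seq_along(wpos)
    cmap <- integer(L); cmap[cpos] <- seq_along(cpos)
    wctx <- ifelse(wpos < L & chars[pmin(L, wpos + 1L)] == "G", "CpG", "nonCpG")
    cctx <- ifelse(cpos > 1L & chars[pmax(1L, cpos - 1L)] == "C", "CpG", "nonCpG")
    covw <- integer(length(wpos)); unw <- integer(length(wpos))
    covc <- integer(length(cpos)); unc <- integer(length(cpos))
    p <- placed[placed$scaffold == sc, , drop = FALSE]
    if (nrow(p)) {
      if (any(p$start < 1L | p$start + nchar(p$seq_watson) - 1L > L))
        stop("placement outside scaffold bounds: corrupt input")
      for (str in c("+", "-")) {
        q <- p[p$strand == str, , drop = FALSE]
        if (!nrow(q)) next
        for (len in unique(nchar(q$seq_watson))) {
          r <- q[nchar(q$seq_watson) == len, , drop = FALSE]
          for (i in seq_len(len)) {
            pos <- r$start + i - 1L
            idx <- if (str == "+") wmap[pos] else cmap[pos]
            hit <- idx > 0L
            if (!any(hit)) next
            b <- substring(r$seq_watson[hit], i, i)
            ix <- idx[hit]
            tab <- tabulate(ix, nbins = if (str == "+") length(wpos) else length(cpos))
            ub <- tabulate(ix[b == (if (str == "+") "C" else "G")],
                           nbins = if (str == "+") length(wpos) else length(cpos))
            if (str == "+") { covw <- covw + tab; unw <- unw + ub }
            else { covc <- covc + tab; unc <- unc + ub }
          }
        }
      }
    }
    out[[sc]] <- data.frame(
      scaffold = sc,
      pos = c(wpos, cpos),
      strand = rep(c("+", "-"), c(length(wpos), length(cpos))),
      context = c(wctx, cctx),
      coverage = c(covw, covc),
      unconverted = c(unw, unc),
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$scaffold, rep$pos, rep$strand), , drop = FALSE]
  rep$fraction <- ifelse(rep$coverage > 0, rep$unconverted / rep$coverage, NA_real_)
  rownames(rep) <- NULL
  class(rep) <- c("cytosine_report", "data.frame")
  rep
}

#' Write a cytosine report as a bedGraph-like TSV
#'
#' Columns: scaffold, start (0-based), end, strand, context, coverage,
#' unconverted, fraction.
#' @param report a `cytosine_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cytosine_report <- function(report, path) {
  df <- data.frame(scaffold = report$scaffold, start = report$pos - 1L,
                   end = report$pos, strand = report$strand,
                   context = report$context, coverage = report$coverage,
                   unconverted = report$unconverted,
                   fraction = report$fraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate bisulfite conversion efficiency from the spike-in control
#'
#' The control is fully unmethylated by assumption, so every C read over a
#' control cytosine reflects either conversion failure or a T-to-C
#' sequencing error. The raw unconverted fraction (pooled over all contexts)
#' is corrected by subtracting the background T-to-C error rate, estimated
#' from reference-T positions of the control alignments when not supplied.
#'
#' @param control_report `cytosine_report` over the control sequence.
#' @param background_error T-to-C error probability; if `NULL`, estimated
#'   from `placed` + `genome`.
#' @param placed,genome control alignments and sequence, used to estimate
#'   the background when `background_error` is `NULL`.
#' @return An object of class `conversion_stats`: list with `raw`,
#'   `background`, `corrected` (all fractions) and `efficiency` (percent).
#' @examples
#' ## raw 0.41% unconverted with 0.10% T->C background -> 99.69% efficiency
#' st <- list(raw = 0.0041, background = 0.0010)
#' 100 * (1 - max(0, st$raw - st$background))
#' @export
estimate_conversion_efficiency <- function(control_report,
                                           background_error = NULL,
                                           placed = NULL, genome = NULL) {
  tot <- sum(control_report$coverage)
  if (tot == 0L) stop("zero coverage on the control sequence")
  raw <- sum(control_report$unconverted) / tot
  bg <- if (!is.null(background_error)) background_error else {
    if (is.null(placed) || is.null(genome))
      stop("supply background_error or placed + genome to estimate it")
    background_tc_rate(placed, genome)
  }
  corrected <- max(0, raw - bg)
  structure(list(raw = raw, background = bg, corrected = corrected,
                 efficiency = 100 * (1 - corrected)),
            class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("<conversion_stats> raw %.4f%% - background %.4f%% => efficiency %.2f%%\n",
              100 * x$raw, 100 * x$background, x$efficiency))
  invisible(x)
}

## T->C sequencing-error rate: fraction of read bases showing C over
## reference-T positions (strand-aware; Crick evidence is G over A).
background_tc_rate <- function(placed, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  tot <- 0; err <- 0
  for (si in seq_along(seqs)) {
    sc <- names(seqs)[si]
    chars <- strsplit(as.character(seqs[[si]]), "", fixed = TRUE)[[1]]
    p <- placed[placed$scaffold == sc, , drop = FALSE]
    if (!nrow(p)) next
    for (str in c("+", "-")) {
      q <- p[p$strand == str, , drop = FALSE]
      if (!nrow(q)) next
      tbase <- if (str == "+") "T" else "A"   # reference T on the read strand
      cbase <- if (str == "+") "C" else "G"
      for (len in unique(nchar(q$seq_watson))) {
        r <- q[nchar(q$seq_watson) == len, , drop = FALSE]
        for (i in seq_len(len)) {
          pos <- r$start + i - 1L
          isT <- chars[pos] == tbase
          if (!any(isT)) next
          b <- substring(r$seq_watson[isT], i, i)
          tot <- tot + sum(isT)
          err <- err + sum(b == cbase)
        }
      }
    }
  }
  if (tot == 0) return(0)
  err / tot
}

#' Write placed reads as SAM
#'
#' Emits a minimal SAM with `NM` (policy mismatches) and `XV` (reference
#' variant matched: meth/unmeth/both) tags. Sequences are stored in Watson
#' orientation, Crick-origin reads carry flag 16.
#'
#' @param placed a `placed_reads` object.
#' @param genome the matching genome (for `@SQ` headers).
#' @param path output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(placed, genome, path) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), Biostrings::width(seqs)))
  lens <- nchar(placed$seq_watson)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tXV:Z:%s",
                 placed$qname,
                 ifelse(placed$strand == "+", 0L, 16L),
                 placed$scaffold, placed$start, lens, placed$seq_watson,
                 vapply(lens, function(n) strrep("I", n), ""),
                 placed$mismatches, placed$variant)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Import external alignments as placed reads
#'
#' Accepts SAM produced by this package or by an external aligner against
#' the original (unconverted) genome. Records with indels in the CIGAR,
#' secondary/supplementary records and unmapped records are excluded,
#' matching the indel-free unique-placement convention.
#'
#' @param sam path to a SAM file.
#' @param genome the matching genome.
#' @return A `placed_reads` object; attribute `n_excluded_indel` counts
#'   indel-containing records and `n_excluded_secondary` non-primary ones.
#' @export
import_alignments <- function(sam, genome) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(paste0(bam, c("", ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "XV"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  indel <- grepl("[IDN]", b$cigar)
  keep <- !unmapped & !secondary & !indel
  nm <- b$tag$NM; if (is.null(nm)) nm <- rep(NA_integer_, n)
  xv <- b$tag$XV; if (is.null(xv)) xv <- rep(NA_character_, n)
  out <- data.frame(
    qname = b$qname[keep],
    scaffold = as.character(b$rname)[keep],
    start = b$pos[keep],
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    variant = xv[keep],
    mismatches = nm[keep],
    seq_watson = as.character(b$seq)[keep],
    stringsAsFactors = FALSE)
  structure(out, class = c("placed_reads", "data.frame"),
            n_reads = n, n_unique = nrow(out),
            n_excluded_indel = sum(indel & !unmapped & !secondary),
            n_excluded_secondary = sum(secondary))
}
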