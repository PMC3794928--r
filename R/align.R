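#' Trim adapters and truncate bisulfite reads
#'
#' Removes 3' adapter read-through by exact-prefix match (an adapter suffix
#' of at least `min_overlap` bases at the read 3' end, or the full adapter
#' anywhere), truncates all reads to `trim_to` bp, and drops reads shorter
#' than `min_length` after trimming.
#'
#' @param reads named character vector of read sequences.
#' @param adapter adapter sequence, or `NULL` to skip adapter trimming.
#' @param trim_to target read length in bp.
#' @param min_overlap minimum adapter overlap at the 3' end.
#' @param min_length reads shorter than this after trimming are dropped.
#' @return list with `reads` (trimmed named vector), `n_adapter` (reads with
#'   adapter removed), `adapter_rate`, `n_dropped`.
#' @export
preprocess_reads <- function(reads, adapter = NULL, trim_to = 75L,
                             min_overlap = 5L, min_length = 20L) {
  if (inherits(reads, "bisulfite_reads")) reads <- reads$reads
  n_adapter <- 0L
  if (!is.null(adapter) && nzchar(adapter)) {
    alen <- nchar(adapter)
    trimmed <- vapply(reads, function(r) {
      len <- nchar(r)
      full <- regexpr(adapter, r, fixed = TRUE)[1]
      if (full > 0L) return(substr(r, 1L, full - 1L))
      ## suffix of the read equal to a prefix of the adapter
      for (ov in seq(min(alen, len), min_overlap)) {
        if (substr(r, len - ov + 1L, len) == substr(adapter, 1L, ov))
          return(substr(r, 1L, len - ov))
      }
      r
    }, "", USE.NAMES = FALSE)
    n_adapter <- sum(nchar(trimmed) < nchar(reads))
    names(trimmed) <- names(reads)
    reads <- trimmed
  }
  reads <- vapply(reads, substr, "", 1L, trim_to, USE.NAMES = FALSE) |>
    stats::setNames(names(reads))
  keep <- nchar(reads) >= min_length
  list(reads = reads[keep],
       n_adapter = n_adapter,
       adapter_rate = n_adapter / max(1L, length(keep)),
       n_dropped = sum(!keep))
}

#' Place bisulfite reads on converted references (ungapped, seed-and-verify)
#'
#' A desk-scale bisulfite mapper: every read is matched ungapped against all
#' four converted reference variants. Candidate loci are generated by exact
#' seed matches in fully converted (three-letter) sequence space, which is a
#' superset of all placements within the mismatch cap, and each candidate is
#' then re-scored against the `meth` and `unmeth` variants under the
#' mismatch policy. The default `"bisulfite"` policy counts a read T over a
#' reference C (Watson) or read A over reference G (Crick, Watson
#' orientation) as a match; `"strict"` applies flat equality, reproducing a
#' plain mismatch-capped alignment to the partially converted references.
#' Equal-best placements on the meth/unmeth variants of the same locus
#' collapse into one placement; equal-best placements at different loci make
#' the read non-unique.
#'
#' @param reads named character vector (or `bisulfite_reads`).
#' @param refs a `converted_refs` set from [build_converted_references()].
#' @param max_mismatches maximum mismatch count (default 4).
#' @param policy `"bisulfite"` (asymmetric, default) or `"strict"`.
#' @return An object of class `placed_reads`: a data.frame of unique
#'   placements (`qname`, `scaffold`, `start` 1-based, `strand`, `variant`,
#'   `mismatches`, `seq_watson` = read in Watson orientation) with
#'   attributes `n_reads`, `n_unique`, `n_multi`, `n_unplaced`,
#'   `n_skipped_long` and `leftover` (names of reads not uniquely placed).
#' @export
align_bisulfite_reads <- function(reads, refs, max_mismatches = 4L,
                                  policy = c("bisulfite", "strict")) {
  policy <- match.arg(policy)
  if (inherits(reads, "bisulfite_reads")) reads <- reads$reads
  stopifnot(inherits(refs, "converted_refs"))
  W_meth <- as.character(refs$watson_meth)
  W_unmeth <- as.character(refs$watson_unmeth)
  C_meth_w <- as.character(Biostrings::reverseComplement(refs$crick_meth))
  C_unmeth_w <- as.character(Biostrings::reverseComplement(refs$crick_unmeth))
  scaf_len <- nchar(W_meth)
  scaf_names <- names(refs$watson_meth)

  lens <- nchar(reads)
  too_long <- lens > max(scaf_len)
  if (any(too_long))
    warning(sum(too_long), " reads longer than the longest scaffold skipped")
  use <- which(!too_long)
  reads_use <- reads[use]
  read_w <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads_use)))

  cand <- rbind(
    seed_candidates(gsub("C", "T", reads_use, fixed = TRUE), W_unmeth,
                    max_mismatches, "+"),
    seed_candidates(gsub("G", "A", read_w, fixed = TRUE), C_unmeth_w,
                    max_mismatches, "-"))
  placed <- score_candidates(cand, reads_use, read_w, W_meth, W_unmeth,
                             C_meth_w, C_unmeth_w, scaf_names, scaf_len,
                             max_mismatches, policy)
  structure(placed$unique,
            class = c("placed_reads", "data.frame"),
            n_reads = length(reads),
            n_unique = nrow(placed$unique),
            n_multi = placed$n_multi,
            n_unplaced = length(reads_use) - nrow(placed$unique) -
              placed$n_multi,
            n_skipped_long = sum(too_long),
            leftover = setdiff(names(reads), placed$unique$qname))
}

## Exact seed hits of three-letter reads in a three-letter genome.
## Returns data.frame(read_idx, scaffold_idx, start, strand).
seed_candidates <- function(conv_reads, conv_genome, max_mm, strand) {
  n <- length(conv_reads)
  if (n == 0L)
    return(data.frame(read_idx = integer(), scaffold_idx = integer(),
                      start = integer(), strand = character()))
  lens <- nchar(conv_reads)
  w <- max(8L, min(lens) %/% (max_mm + 1L))
  offs <- lapply(lens, function(L) {
    k <- min(max_mm + 1L, L %/% w)
    1L + (seq_len(max(1L, k)) - 1L) * w
  })
  read_idx <- rep(seq_len(n), lengths(offs))
  off <- unlist(offs)
  pats <- unname(substr(conv_reads[read_idx], off, off + w - 1L))
  pd <- Biostrings::PDict(pats)
  out <- list()
  for (si in seq_along(conv_genome)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(conv_genome[[si]]))
    st <- Biostrings::startIndex(m)
    hit_n <- lengths(st)
    if (sum(hit_n) == 0L) next
    pat_id <- rep(seq_along(st), hit_n)
    starts <- unlist(st) - off[pat_id] + 1L
    out[[si]] <- data.frame(read_idx = read_idx[pat_id], scaffold_idx = si,
                            start = starts, strand = strand,
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_idx = integer(), scaffold_idx = integer(),
                      start = integer(), strand = character()))
  res <- do.call(rbind, out)
  unique(res)
}

## Re-score candidates under the mismatch policy against meth and unmeth
## variants; resolve uniqueness per read.
score_candidates <- function(cand, reads, read_w, W_meth, W_unmeth,
                             C_meth_w, C_unmeth_w, scaf_names, scaf_len,
                             max_mm, policy) {
  empty <- data.frame(qname = character(), scaffold = character(),
                      start = integer(), strand = character(),
                      variant = character(), mismatches = integer(),
                      seq_watson = character(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(list(unique = empty, n_multi = 0L))
  lens <- nchar(reads)[cand$read_idx]
  keep <- cand$start >= 1L & cand$start + lens - 1L <= scaf_len[cand$scaffold_idx]
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(unique = empty, n_multi = 0L))

  cand$mm_meth <- NA_integer_; cand$mm_unmeth <- NA_integer_
  for (str in unique(cand$strand)) {
    rows <- which(cand$strand == str)
    rstr <- if (str == "+") reads[cand$read_idx[rows]] else
      read_w[cand$read_idx[rows]]
    for (len in unique(nchar(rstr))) {
      sub <- rows[nchar(rstr) == len]
      rsub <- if (str == "+") reads[cand$read_idx[sub]] else
        read_w[cand$read_idx[sub]]
      refm <- if (str == "+") W_meth else C_meth_w
      refu <- if (str == "+") W_unmeth else C_unmeth_w
      winm <- substring(refm[cand$scaffold_idx[sub]], cand$start[sub],
                        cand$start[sub] + len - 1L)
      winu <- substring(refu[cand$scaffold_idx[sub]], cand$start[sub],
                        cand$start[sub] + len - 1L)
      mmm <- integer(length(sub)); mmu <- integer(length(sub))
      for (i in seq_len(len)) {
        rb <- substring(rsub, i, i)
        bm <- substring(winm, i, i)
        bu <- substring(winu, i, i)
        if (policy == "bisulfite") {
          if (str == "+") {
            mmm <- mmm + (rb != bm & !(rb == "T" & bm == "C"))
            mmu <- mmu + (rb != bu & !(rb == "T" & bu == "C"))
          } else {
            mmm <- mmm + (rb != bm & !(rb == "A" & bm == "G"))
            mmu <- mmu + (rb != bu & !(rb == "A" & bu == "G"))
          }
        } else {
          mmm <- mmm + (rb != bm)
          mmu <- mmu + (rb != bu)
        }
      }
      cand$mm_meth[sub] <- mmm
      cand$mm_unmeth[sub] <- mmu
    }
  }
  cand$mm <- pmin(cand$mm_meth, cand$mm_unmeth)
  cand <- cand[cand$mm <= max_mm, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(unique = empty, n_multi = 0L))
  cand$variant <- ifelse(cand$mm_meth == cand$mm_unmeth, "both",
                         ifelse(cand$mm_meth < cand$mm_unmeth, "meth", "unmeth"))
  ## best placement(s) per read
  best <- stats::aggregate(mm ~ read_idx, cand, min)
  cand <- merge(cand, stats::setNames(best, c("read_idx", "best_mm")),
                by = "read_idx")
  cand <- cand[cand$mm == cand$best_mm, , drop = FALSE]
  nbest <- table(cand$read_idx)
  uniq_ids <- as.integer(names(nbest)[nbest == 1L])
  n_multi <- sum(nbest > 1L)
  u <- cand[cand$read_idx %in% uniq_ids, , drop = FALSE]
  out <- data.frame(
    qname = names(reads)[u$read_idx],
    scaffold = scaf_names[u$scaffold_idx],
    start = u$start,
    strand = u$strand,
    variant = u$variant,
    mismatches = u$mm,
    seq_watson = ifelse(u$strand == "+", unname(reads[u$read_idx]),
                        unname(read_w[u$read_idx])),
    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  list(unique = out, n_multi = n_multi)
}

#' @export
print.placed_reads <- function(x, ...) {
  cat("<placed_reads>", attr(x, "n_unique"), "unique /",
      attr(x, "n_reads"), "reads (", attr(x, "n_multi"), "multi,",
      attr(x, "n_unplaced"), "unplaced )\n")
  invisible(x)
}
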