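#' Enumerate CpG sites on both strands
#'
#' Every CG dinucleotide contributes a Watson C (at the C) and a Crick C
#' (at the G, one base 3' on the other strand). Positions involving
#' ambiguity codes are excluded.
#'
#' @param genome an `annotated_genome` or [Biostrings::DNAStringSet].
#' @return data.frame with `scaffold`, `pos` (1-based), `strand`.
#' @export
enumerate_cpg_sites <- function(genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  out <- list()
  for (sc in names(seqs)) {
    s <- as.character(seqs[[sc]])
    d <- unlist(gregexpr("CG", s, fixed = TRUE))
    d <- d[d > 0L]
    if (!length(d)) next
    out[[sc]] <- data.frame(scaffold = sc,
                            pos = c(d, d + 1L),
                            strand = rep(c("+", "-"), each = length(d)),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scaffold = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' GC fraction and CpG observed/expected ratio of a sequence
#'
#' `cpg_oe = n(CpG) * L / (n(C) * n(G))`, the observed CpG dinucleotide
#' count over its expectation from mononucleotide frequencies; 0 when the
#' sequence has no C or no G. Depletion of CpG O/E below 1 signals
#' historical germline methylation.
#'
#' @param sequence a character string, [Biostrings::DNAString] or
#'   length-1 DNAStringSet.
#' @return list with `gc` and `cpg_oe`.
#' @examples
#' compute_cpg_oe("CGCGCGCG")  # gc = 1, O/E = 2
#' @export
compute_cpg_oe <- function(sequence) {
  s <- as.character(sequence)[1]
  if (nchar(s) < 2L) stop("sequence must be at least 2 bp")
  L <- as.numeric(nchar(s))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  nC <- as.numeric(sum(chars == "C")); nG <- as.numeric(sum(chars == "G"))
  d <- unlist(gregexpr("CG", s, fixed = TRUE)); ncg <- sum(d > 0L)
  list(gc = (nC + nG) / L,
       cpg_oe = if (nC * nG == 0) 0 else ncg * L / (nC * nG))
}

#' Detect mammalian-criteria CpG islands
#'
#' Scans each scaffold with a 200 bp window at 1 bp steps; windows with
#' GC > `min_gc` and CpG O/E > `min_oe` are merged when overlapping or
#' adjacent. A merged region is kept if it still meets all criteria,
#' otherwise it is trimmed greedily from whichever end most improves the
#' failing criterion; regions longer than `max_len` are split at the
#' weakest O/E valley. Returned islands are non-overlapping and sorted.
#'
#' @param genome an `annotated_genome` or DNAStringSet.
#' @param min_len,max_len island length bounds (bp).
#' @param min_gc minimum GC fraction (exclusive).
#' @param min_oe minimum CpG O/E (exclusive).
#' @param window scan window width (bp).
#' @return data.frame with `scaffold`, `start`, `end` (1-based closed),
#'   `length`, `gc`, `cpg_oe`; class `cpg_islands`.
#' @export
detect_cpg_islands <- function(genome, min_len = 200L, max_len = 10000L,
                               min_gc = 0.50, min_oe = 0.6, window = 200L) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  res <- list()
  for (sc in names(seqs)) {
    s <- as.character(seqs[[sc]])
    L <- nchar(s)
    if (L < window) next
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- chars == "C"; isG <- chars == "G"
    cgv <- c(isC[-L] & isG[-1L], FALSE)
    cC <- cumsum(isC); cG <- cumsum(isG); cCG <- cumsum(cgv)
    stat <- function(lo, hi) {
      n <- hi - lo + 1L
      nc <- as.numeric(cC[hi] - if (lo > 1L) cC[lo - 1L] else 0L)
      ng <- as.numeric(cG[hi] - if (lo > 1L) cG[lo - 1L] else 0L)
      ncg <- if (hi > lo) cCG[hi - 1L] - (if (lo > 1L) cCG[lo - 1L] else 0L) else 0L
      gc <- (nc + ng) / n
      oe <- if (nc * ng == 0) 0 else ncg * n / (nc * ng)
      c(gc = gc, oe = oe)
    }
    lo <- seq_len(L - window + 1L); hi <- lo + window - 1L
    nc <- cC[hi] - c(0L, cC)[lo]
    ng <- cG[hi] - c(0L, cG)[lo]
    ncg <- cCG[hi - 1L] - c(0L, cCG)[lo]
    ok <- (nc + ng) / window > min_gc &
      ifelse(nc * ng == 0L, 0, ncg * window / (nc * ng)) > min_oe
    if (!any(ok)) next
    ## union of all qualifying windows (overlapping/adjacent merged)
    covered <- logical(L)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values))
      covered[starts[k]:min(L, ends[k] + window - 1L)] <- TRUE
    cr <- rle(covered)
    ce <- cumsum(cr$lengths)
    cs <- ce - cr$lengths + 1L
    iv <- cbind(cs[cr$values], ce[cr$values])
    for (k in seq_len(nrow(iv))) {
      for (piece in split_island(iv[k, 1], iv[k, 2], stat, min_oe, max_len)) {
        tr <- trim_island(piece[1], piece[2], stat, min_gc, min_oe, min_len)
        if (is.null(tr)) next
        st <- stat(tr[1], tr[2])
        if (tr[2] - tr[1] + 1L >= min_len)
          res[[length(res) + 1L]] <- data.frame(
            scaffold = sc, start = tr[1], end = tr[2],
            length = tr[2] - tr[1] + 1L, gc = st["gc"], cpg_oe = st["oe"],
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               length = integer(), gc = numeric(), cpg_oe = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cpg_islands", "data.frame")
  out
}

## Split an over-long candidate region at its weakest O/E valley (recursively).
split_island <- function(lo, hi, stat, min_oe, max_len) {
  if (hi - lo + 1L <= max_len) return(list(c(lo, hi)))
  w <- 200L
  mids <- seq(lo + w, hi - 2L * w, by = w)
  if (!length(mids)) return(list(c(lo, hi)))
  oes <- vapply(mids, function(m) stat(m, m + w - 1L)["oe"], 0)
  cut <- mids[which.min(oes)] + w %/% 2L
  c(split_island(lo, cut - 1L, stat, min_oe, max_len),
    split_island(cut, hi, stat, min_oe, max_len))
}

## Greedy end-trimming until the region meets all criteria (or is exhausted).
trim_island <- function(lo, hi, stat, min_gc, min_oe, min_len) {
  repeat {
    if (hi - lo + 1L < min_len) return(NULL)
    st <- stat(lo, hi)
    if (st["gc"] > min_gc && st["oe"] > min_oe) return(c(lo, hi))
    sl <- stat(lo + 1L, hi); sr <- stat(lo, hi - 1L)
    ## drop the end whose removal leaves the better (gc, oe) margin;
    ## exact ties trim both ends so detection stays strand-invariant
    ml <- min(sl["gc"] - min_gc, sl["oe"] - min_oe)
    mr <- min(sr["gc"] - min_gc, sr["oe"] - min_oe)
    if (abs(ml - mr) < 1e-12) { lo <- lo + 1L; hi <- hi - 1L }
    else if (ml > mr) lo <- lo + 1L else hi <- hi - 1L
  }
}

#' Write islands or clusters as BED6 (extra score columns after column 6)
#'
#' Coordinates are converted to BED's 0-based half-open convention; the
#' score column carries CpG O/E (islands) or the mCpG fraction (clusters),
#' and any remaining numeric columns are appended after the strand, with a
#' header line naming them.
#'
#' @param x a `cpg_islands` or `mcpg_clusters` data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  score <- if ("cpg_oe" %in% names(x)) x$cpg_oe else x$frac_mcpg
  extra <- setdiff(names(x), c("scaffold", "start", "end"))
  bed <- data.frame(chrom = x$scaffold, start = x$start - 1L, end = x$end,
                    name = sprintf("%s_%d", if ("cpg_oe" %in% names(x))
                      "cgi" else "mcpgcl", seq_len(nrow(x))),
                    score = round(1000 * pmin(1, score / 2)),
                    strand = ".")
  bed <- cbind(bed, x[, extra, drop = FALSE])
  writeLines(paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                    paste(extra, collapse = "\t")), path)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Classify methylated CpGs (mCpGs)
#'
#' A CpG site is *covered* at coverage >= `min_coverage` and called *mCpG*
#' when additionally more than `min_fraction` of its covering reads are
#' unconverted. With the defaults (10x, >10%) an mCpG call needs at least
#' two unconverted reads, so a single T-to-C sequencing error cannot create
#' a spurious methylated site.
#'
#' @param report a `cytosine_report`.
#' @param min_coverage coverage threshold (default 10).
#' @param min_fraction methylation fraction threshold, strict (default 0.10).
#' @return The report with logical columns `covered` and `mcpg` added
#'   (non-CpG sites are never mCpG); attribute `summary` holds covered
#'   count, mCpG count, percent mCpG among covered, and the pooled
#'   methylation percentage (unconverted reads / all reads at covered CpGs).
#' @export
classify_mcpg <- function(report, min_coverage = 10L, min_fraction = 0.10) {
  cpg <- report$context == "CpG"
  report$covered <- report$coverage >= min_coverage
  report$mcpg <- cpg & report$covered &
    report$unconverted / pmax(1L, report$coverage) > min_fraction
  ccov <- cpg & report$covered
  attr(report, "summary") <- list(
    covered_cpgs = sum(ccov),
    mcpgs = sum(report$mcpg),
    pct_mcpg = 100 * sum(report$mcpg) / max(1L, sum(ccov)),
    methylation_pct = 100 * sum(report$unconverted[ccov]) /
      max(1L, sum(report$coverage[ccov])))
  class(report) <- c("mcpg_calls", class(report))
  report
}

#' Detect methylated CpG clusters
#'
#' Greedy, deterministic clustering of mCpGs: each mCpG seeds a cluster
#' that is extended outward over neighbouring covered CpGs while more than
#' `min_frac_mcpg` of the covered CpGs inside remain mCpG and the pooled
#' methylation percentage stays above `min_meth`. Clusters closer than
#' `merge_gap` bp with no intervening run of >= `max_nonm_run` covered
#' non-mCpGs are merged when the merged region still qualifies. Clusters
#' need at least `min_mcpg` mCpGs. Methylation is pooled over reads
#' (total unconverted / total coverage), matching the region-level
#' methylation-percentage convention.
#'
#' @param report a `cytosine_report`.
#' @param calls an `mcpg_calls` object from [classify_mcpg()] (computed from
#'   `report` when missing).
#' @param min_frac_mcpg minimum mCpG fraction among covered CpGs (strict).
#' @param min_meth minimum pooled methylation fraction (strict).
#' @param merge_gap,max_nonm_run merge heuristics (bp, count).
#' @param min_mcpg minimum mCpGs per cluster.
#' @return data.frame `scaffold`, `start`, `end`, `n_covered`, `n_mcpg`,
#'   `frac_mcpg`, `meth_pct`; class `mcpg_clusters`.
#' @export
detect_mcpg_clusters <- function(report, calls = NULL, min_frac_mcpg = 0.80,
                                 min_meth = 0.40, merge_gap = 200L,
                                 max_nonm_run = 3L, min_mcpg = 2L) {
  if (is.null(calls)) calls <- classify_mcpg(report)
  ## dyad-level ordering: use covered CpG sites (either strand) sorted by pos
  k <- calls$context == "CpG" & calls$covered
  s <- calls[k, , drop = FALSE]
  res <- list()
  for (sc in unique(s$scaffold)) {
    x <- s[s$scaffold == sc, , drop = FALSE]
    x <- x[order(x$pos), , drop = FALSE]
    n <- nrow(x)
    if (n == 0L) next
    used <- logical(n)
    ccov <- cumsum(rep(1L, n)); cm <- cumsum(x$mcpg)
    cun <- cumsum(x$unconverted); ccv <- cumsum(x$coverage)
    qual <- function(lo, hi) {
      nmc <- cm[hi] - if (lo > 1L) cm[lo - 1L] else 0L
      ncv <- hi - lo + 1L
      un <- cun[hi] - if (lo > 1L) cun[lo - 1L] else 0L
      cv <- ccv[hi] - if (lo > 1L) ccv[lo - 1L] else 0L
      nmc / ncv > min_frac_mcpg && un / cv > min_meth
    }
    clusters <- list()
    for (seed in which(x$mcpg)) {
      if (used[seed]) next
      lo <- hi <- seed
      repeat {
        grown <- FALSE
        if (hi < n && !used[hi + 1L] && qual(lo, hi + 1L)) {
          hi <- hi + 1L; grown <- TRUE
        }
        if (lo > 1L && !used[lo - 1L] && qual(lo - 1L, hi)) {
          lo <- lo - 1L; grown <- TRUE
        }
        if (!grown) break
      }
      ## shrink to outermost mCpGs so boundaries are methylated sites
      while (lo < hi && !x$mcpg[lo]) lo <- lo + 1L
      while (hi > lo && !x$mcpg[hi]) hi <- hi - 1L
      used[lo:hi] <- TRUE
      clusters[[length(clusters) + 1L]] <- c(lo, hi)
    }
    if (!length(clusters)) next
    ## merge pass
    merged <- list(clusters[[1]])
    for (cl in clusters[-1]) {
      last <- merged[[length(merged)]]
      gap_bp <- x$pos[cl[1]] - x$pos[last[2]]
      between <- if (cl[1] - last[2] > 1L)
        sum(!x$mcpg[(last[2] + 1L):(cl[1] - 1L)]) else 0L
      if (gap_bp < merge_gap && between < max_nonm_run &&
          qual(last[1], cl[2])) {
        merged[[length(merged)]] <- c(last[1], cl[2])
      } else merged[[length(merged) + 1L]] <- cl
    }
    for (cl in merged) {
      lo <- cl[1]; hi <- cl[2]
      nmc <- cm[hi] - if (lo > 1L) cm[lo - 1L] else 0L
      if (nmc < min_mcpg) next
      un <- cun[hi] - if (lo > 1L) cun[lo - 1L] else 0L
      cv <- ccv[hi] - if (lo > 1L) ccv[lo - 1L] else 0L
      res[[length(res) + 1L]] <- data.frame(
        scaffold = sc, start = x$pos[lo], end = x$pos[hi],
        n_covered = hi - lo + 1L, n_mcpg = nmc,
        frac_mcpg = nmc / (hi - lo + 1L), meth_pct = 100 * un / cv,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               n_covered = integer(), n_mcpg = integer(),
               frac_mcpg = numeric(), meth_pct = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mcpg_clusters", "data.frame")
  out
}

#' Screen non-CpG cytosines for apparent methylation and artifacts
#'
#' Reports the global unconverted fraction over adequately covered non-CpG
#' cytosines and re-examines every candidate site above `threshold` against
#' read evidence: if the covering reads' consensus base immediately 3' of
#' the C is G while the reference says otherwise, the site is a CpG
#' masquerading as non-CpG through a reference error
#' (`"reference-error CpG"`); if the covering reads split into
#' haplotype-like groups (a second frequent mismatch position among the
#' same reads), it is flagged `"paralog-collapse"`; otherwise it remains a
#' `"candidate"`.
#'
#' @param report a `cytosine_report`.
#' @param placed the `placed_reads` behind it (for read re-examination;
#'   candidates keep class `"candidate"` with a warning when `NULL`).
#' @param genome the genome.
#' @param threshold candidate fraction threshold (default 0.30).
#' @param min_coverage adequate-depth threshold (default 10).
#' @return list with `n_sites`, `global_fraction`, and `candidates`
#'   (data.frame with site, fraction, class); class `noncpg_summary`.
#' @export
screen_noncpg <- function(report, placed = NULL, genome = NULL,
                          threshold = 0.30, min_coverage = 10L) {
  nn <- report$context == "nonCpG" & report$coverage >= min_coverage
  gl <- sum(report$unconverted[nn]) / max(1L, sum(report$coverage[nn]))
  cand <- report[nn & report$fraction > threshold, , drop = FALSE]
  cls <- character(nrow(cand))
  if (nrow(cand)) {
    if (is.null(placed) || is.null(genome)) {
      warning("no read access; candidates left unclassified")
      cls[] <- "candidate"
    } else {
      for (i in seq_len(nrow(cand))) {
        cls[i] <- classify_noncpg_site(cand[i, ], placed, genome)
      }
    }
  }
  cand$class <- cls
  structure(list(n_sites = sum(nn), global_fraction = gl,
                 candidates = cand),
            class = "noncpg_summary")
}

## Read-evidence classification of one non-CpG candidate.
classify_noncpg_site <- function(site, placed, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  s <- as.character(seqs[[site$scaffold]])
  p <- placed[placed$scaffold == site$scaffold &
              placed$strand == site$strand, , drop = FALSE]
  lens <- nchar(p$seq_watson)
  ov <- p$start <= site$pos & p$start + lens - 1L >= site$pos
  p <- p[ov, , drop = FALSE]
  if (!nrow(p)) return("candidate")
  ## base immediately 3' of the C on the read strand
  nxt <- if (site$strand == "+") site$pos + 1L else site$pos - 1L
  if (nxt >= 1L && nxt <= nchar(s)) {
    ok <- p$start <= nxt & p$start + nchar(p$seq_watson) - 1L >= nxt
    b <- substring(p$seq_watson[ok], nxt - p$start[ok] + 1L,
                   nxt - p$start[ok] + 1L)
    gbase <- if (site$strand == "+") "G" else "C"   # Watson-orientation G/C
    refb <- substr(s, nxt, nxt)
    if (length(b) && mean(b == gbase) > 0.5 && refb != gbase)
      return("reference-error CpG")
  }
  ## haplotype-like split: another position where covering reads disagree
  ## with the reference in a consistent ~50% fashion
  win <- max(1L, site$pos - 30L):min(nchar(s), site$pos + 30L)
  for (q in win) {
    if (q == site$pos) next
    ok <- p$start <= q & p$start + nchar(p$seq_watson) - 1L >= q
    if (sum(ok) < 4L) next
    b <- substring(p$seq_watson[ok], q - p$start[ok] + 1L, q - p$start[ok] + 1L)
    mism <- b != substr(s, q, q)
    if (mean(mism) > 0.25 && mean(mism) < 0.75) {
      ## ignore bisulfite conversion (T over reference C / A over G)
      refb <- substr(s, q, q)
      conv <- (refb == "C" & b == "T") | (refb == "G" & b == "A")
      if (mean(mism & !conv) > 0.25) return("paralog-collapse")
    }
  }
  "candidate"
}
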