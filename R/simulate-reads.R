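#' Simulate single-end bisulfite reads (with spike-in control)
#'
#' Samples read-1-sense fragments uniformly from both strands of the genome
#' and applies bisulfite chemistry per template cytosine: a C is emitted
#' with probability `frac + (1 - frac) * conversion_failure` (where `frac`
#' is the site's true methylation fraction, 0 for non-CpG cytosines) and
#' otherwise converted to T. Crick-origin fragments are the reverse
#' complement of the genomic window, with conversion applied to the template
#' strand's cytosines. Sequencing substitution errors are applied after
#' conversion. A fraction of reads is drawn from a fully unmethylated
#' control sequence, emulating an unmethylated spike-in library. Read names
#' record the true origin (`scaffold:start:strand`) for test oracles.
#'
#' @param genome an `annotated_genome`.
#' @param methylome the matching `true_methylome`.
#' @param config the [sim_config()].
#' @param control optional control sequence ([Biostrings::DNAStringSet] of
#'   length 1); required when `spike_in_fraction > 0`
#'   (see [simulate_control_genome()]).
#' @return An object of class `bisulfite_reads`: list with `reads` (named
#'   character vector of read sequences) and `origin` (data.frame: qname,
#'   scaffold, start, strand, control flag).
#' @export
simulate_bisulfite_reads <- function(genome, methylome, config,
                                     control = NULL) {
  validate_sim_config(config)
  if (config$spike_in_fraction > 0 && is.null(control))
    stop("spike_in_fraction > 0 but no control sequence supplied")
  if (config$read_length > min(Biostrings::width(genome$seq)))
    stop("read_length exceeds the shortest scaffold")
  set.seed(config$seed + 2L)
  rl <- config$read_length
  batches <- list(); serial <- 0L
  for (sc in names(genome$seq)) {
    s <- as.character(genome$seq[[sc]])
    L <- nchar(s)
    lk <- methylome_frac_vectors(s, methylome[methylome$scaffold == sc, ])
    n <- ceiling(config$coverage * L / rl)
    batches[[sc]] <- sim_read_batch(s, lk$fw, lk$fc, n, rl,
                                    config$conversion_failure,
                                    config$seq_error, sc, serial)
    serial <- serial + n
  }
  if (config$spike_in_fraction > 0) {
    cs <- as.character(control[[1]])
    cname <- if (!is.null(names(control))) names(control)[1] else "spike_control"
    f <- config$spike_in_fraction
    n_ctrl <- max(1L, round(serial * f / (1 - f)))
    zeros <- numeric(nchar(cs))
    batches[[cname]] <- sim_read_batch(cs, zeros, zeros, n_ctrl, rl,
                                       config$conversion_failure,
                                       config$seq_error, cname, serial,
                                       is_control = TRUE)
  }
  origin <- do.call(rbind, lapply(batches, `[[`, "origin"))
  rownames(origin) <- NULL
  reads <- unlist(lapply(batches, `[[`, "reads"), use.names = FALSE)
  names(reads) <- origin$qname
  structure(list(reads = reads, origin = origin), class = "bisulfite_reads")
}

## Per-position true-fraction lookups for one scaffold: fw[i] = fraction of
## the Watson C at i (0 for non-CpG Cs), fc[i] = fraction of the Crick C at
## i (the G of a CpG dyad).
methylome_frac_vectors <- function(seqstr, meth) {
  L <- nchar(seqstr)
  fw <- numeric(L); fc <- numeric(L)
  if (nrow(meth)) {
    fw[meth$pos] <- meth$frac
    fc[pmin(L, meth$pos + 1L)] <- meth$frac
  }
  list(fw = fw, fc = fc)
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

sim_read_batch <- function(seqstr, fw, fc, n, rl, conv_fail, seq_err,
                           scafname, serial_start, is_control = FALSE) {
  L <- nchar(seqstr)
  schars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  plus <- strands == "+"
  cols <- vector("list", rl)
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  for (i in seq_len(rl)) {
    pos <- ifelse(plus, starts + i - 1L, starts + rl - i)
    gbase <- schars[pos]
    tmpl <- ifelse(plus, gbase, unname(comp_base[gbase]))
    out <- tmpl
    isC <- tmpl == "C"
    if (any(isC)) {
      frac <- ifelse(plus[isC], fw[pos[isC]], fc[pos[isC]])
      p_unconv <- frac + (1 - frac) * conv_fail
      stays <- stats::runif(sum(isC)) < p_unconv
      out[isC][!stays] <- "T"
    }
    if (seq_err > 0) {
      e <- which(stats::runif(n) < seq_err)
      if (length(e))
        out[e] <- vapply(out[e], function(b) sample(other[[b]], 1L), "")
    }
    cols[[i]] <- out
  }
  reads <- do.call(paste0, cols)
  qname <- sprintf("r%07d:%s:%d:%s", serial_start + seq_len(n),
                   scafname, starts, strands)
  list(reads = reads,
       origin = data.frame(qname = qname, scaffold = scafname,
                           start = starts, strand = strands,
                           control = is_control,
                           stringsAsFactors = FALSE))
}

#' Simulate an unmethylated spike-in control sequence
#'
#' A 48.5 kbp random sequence standing in for an unmethylated phage control
#' library (synthetic; no external sequence is bundled).
#'
#' @param length control length in bp.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] of length 1 named `spike_control`.
#' @export
simulate_control_genome <- function(length = 48502L, gc = 0.50, seed = 99L) {
  set.seed(seed)
  x <- Biostrings::DNAStringSet(random_dna(length, gc))
  names(x) <- "spike_control"
  x
}

#' Write reads as FASTQ (Phred+33, uniform quality)
#'
#' @param reads a `bisulfite_reads` object or named character vector.
#' @param path output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "bisulfite_reads")) reads <- reads$reads
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of sequences
#' @param path FASTQ path.
#' @return Named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  r <- as.character(x)
  names(r) <- sub(" .*", "", names(x))
  r
}

#' @export
print.bisulfite_reads <- function(x, ...) {
  cat("<bisulfite_reads>", length(x$reads), "reads,",
      nchar(x$reads[1]), "bp\n")
  invisible(x)
}
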