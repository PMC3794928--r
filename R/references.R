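#' Build strand-specific C-to-T converted reference genomes
#'
#' Bisulfite reads carry T wherever an unmethylated template C was
#' converted, so they are placed against converted references. Four variants
#' are built, two per strand: a `meth` variant in which Cs in CpG context
#' remain C (methylated CpGs survive conversion) and an `unmeth` variant
#' with every C converted to T. The Crick variants apply the same rules to
#' the reverse-complement strand and are stored as Crick 5'->3' sequences.
#' Ambiguity codes pass through unchanged.
#'
#' @param genome an `annotated_genome` or a [Biostrings::DNAStringSet].
#' @return An object of class `converted_refs`: list with `watson_meth`,
#'   `watson_unmeth`, `crick_meth`, `crick_unmeth` (DNAStringSets of the
#'   source lengths) and `checksum` (md5 of the source sequences).
#' @examples
#' refs <- build_converted_references(Biostrings::DNAStringSet(c(s = "ACGTCA")))
#' as.character(refs$watson_meth)   # "ACGTTA": the CpG C is retained
#' @export
build_converted_references <- function(genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else
    Biostrings::DNAStringSet(genome)
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
    stop("empty genome")
  src <- as.character(seqs)
  rc <- as.character(Biostrings::reverseComplement(seqs))
  convert <- function(x, keep_cpg) {
    if (keep_cpg) gsub("C(?!G)", "T", x, perl = TRUE) else
      gsub("C", "T", x, fixed = TRUE)
  }
  mk <- function(x, keep_cpg) {
    out <- Biostrings::DNAStringSet(vapply(x, convert, "", keep_cpg = keep_cpg))
    names(out) <- names(seqs)
    out
  }
  structure(list(watson_meth = mk(src, TRUE),
                 watson_unmeth = mk(src, FALSE),
                 crick_meth = mk(rc, TRUE),
                 crick_unmeth = mk(rc, FALSE),
                 checksum = unname(vapply(src, function(s)
                   substr(digest_string(s), 1, 32), ""))),
            class = "converted_refs")
}

## md5 of a string without external deps
digest_string <- function(s) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.converted_refs <- function(x, ...) {
  cat("<converted_refs>", length(x$watson_meth), "scaffolds x 4 variants\n")
  invisible(x)
}
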