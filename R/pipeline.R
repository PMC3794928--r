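#' Run the full methylome analysis pipeline on simulated data
#'
#' Executes simulate -> align (control first, then genome) -> cytosine
#' report -> features -> gene status -> clustering statistics ->
#' expression -> association -> comparative, writing stage outputs and a
#' run manifest under `out_dir`. Stages are skipped on re-runs when their
#' input digest matches the manifest and all recorded outputs still exist
#' with matching checksums; a corrupted or missing intermediate
#' invalidates the stage and everything downstream.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param force rerun everything regardless of the manifest.
#' @param n_perm permutations for the clustering statistics.
#' @param dip_B Monte-Carlo draws for dip tests.
#' @return list (class `run_manifest`) with per-stage results, output
#'   paths, checksums, seeds and runtimes.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, n_perm = 1000L,
                         dip_B = 2000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  old <- if (!force && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else NULL
  manifest <- list(config_checksum = object_digest(config), stages = list())
  results <- list()
  upstream <- manifest$config_checksum
  fresh <- force

  run_stage <- function(name, inputs_digest, fn) {
    rec <- old$stages[[name]]
    if (!fresh && !is.null(rec) && identical(rec$digest, inputs_digest) &&
        outputs_ok(rec)) {
      manifest$stages[[name]] <<- c(rec, list(skipped = TRUE))
      return(NULL)
    }
    fresh <<- TRUE                      # invalidate downstream
    t0 <- proc.time()[3]
    out <- fn()
    manifest$stages[[name]] <<- list(
      digest = inputs_digest,
      runtime_s = round(proc.time()[3] - t0, 2),
      seed = config$seed,
      outputs = lapply(out$files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
    out$result
  }

  ## 1. simulate ----------------------------------------------------------
  sim_digest <- paste(upstream, "simulate")
  sim <- run_stage("simulate", sim_digest, function() {
    genome <- simulate_genome(config)
    methylome <- simulate_methylome(genome, config)
    control <- simulate_control_genome(seed = config$seed + 9L)
    reads <- simulate_bisulfite_reads(genome, methylome, config, control)
    files <- write_genome(genome, out_dir)
    fq <- file.path(out_dir, "reads.fastq")
    write_fastq(reads, fq)
    cfa <- file.path(out_dir, "control.fa")
    Biostrings::writeXStringSet(control, cfa)
    list(result = list(genome = genome, methylome = methylome,
                       control = control, reads = reads),
         files = c(files, fastq = fq, control = cfa))
  })
  if (is.null(sim)) {                   # skipped: rebuild in memory
    genome <- simulate_genome(config)
    methylome <- simulate_methylome(genome, config)
    control <- simulate_control_genome(seed = config$seed + 9L)
    reads <- simulate_bisulfite_reads(genome, methylome, config, control)
    sim <- list(genome = genome, methylome = methylome, control = control,
                reads = reads)
  }
  results$simulate <- sim

  ## 2. align + cytosine reports -----------------------------------------
  aln_digest <- paste(sim_digest, "align")
  aln <- run_stage("align", aln_digest, function() {
    res <- align_stage(sim$reads$reads, sim$genome, sim$control)
    rp <- file.path(out_dir, "cytosine_report.tsv")
    write_cytosine_report(res$report, rp)
    cp <- file.path(out_dir, "control_report.tsv")
    write_cytosine_report(res$control_report, cp)
    sam <- file.path(out_dir, "alignments.sam")
    write_sam(res$placed, sim$genome, sam)
    list(result = res, files = c(report = rp, control_report = cp, sam = sam))
  })
  if (is.null(aln)) aln <- align_stage(sim$reads$reads, sim$genome,
                                       sim$control)
  results$align <- aln

  ## 3. features ----------------------------------------------------------
  feat <- run_stage("features", paste(aln_digest, "features"), function() {
    isl <- detect_cpg_islands(sim$genome)
    calls <- classify_mcpg(aln$report)
    cl <- detect_mcpg_clusters(aln$report, calls)
    f1 <- file.path(out_dir, "cpg_islands.tsv")
    utils::write.table(isl, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out_dir, "mcpg_clusters.tsv")
    utils::write.table(cl, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(result = list(islands = isl, calls = calls, clusters = cl,
                       summary = attr(calls, "summary")),
         files = c(islands = f1, clusters = f2))
  })
  if (is.null(feat)) {
    calls <- classify_mcpg(aln$report)
    feat <- list(islands = detect_cpg_islands(sim$genome), calls = calls,
                 clusters = detect_mcpg_clusters(aln$report, calls),
                 summary = attr(calls, "summary"))
  }
  results$features <- feat

  ## 4. gene status -------------------------------------------------------
  gs <- run_stage("gene_status", paste(aln_digest, "gene_status"), function() {
    st <- call_gene_status(aln$report, sim$genome)
    f <- file.path(out_dir, "gene_status.tsv")
    utils::write.table(st, f, sep = "\t", quote = FALSE, row.names = FALSE)
    list(result = st, files = c(status = f))
  })
  if (is.null(gs)) gs <- call_gene_status(aln$report, sim$genome)
  results$gene_status <- gs

  ## 5. clustering statistics ---------------------------------------------
  cl <- run_stage("cluster_stats", paste(aln_digest, "cluster"), function() {
    np <- neighbor_pair_analysis(gs, sim$genome, n_perm = n_perm,
                                 seed = config$seed)
    rl <- run_length_analysis(gs, sim$genome, null = "analytic")
    oe <- orientation_enrichment(gs, sim$genome)
    f <- file.path(out_dir, "cluster_stats.json")
    jsonlite::write_json(list(
      class_counts = as.list(np$class_counts),
      mean_distance = as.list(np$mean_distance),
      perm_p = lapply(np$perm, `[[`, "p"),
      mean_run_length = rl$mean_run_length,
      run_chisq_p = rl$chisq_p), f, auto_unbox = TRUE, digits = NA)
    list(result = list(pairs = np, runs = rl, orientation = oe),
         files = c(stats = f))
  })
  if (is.null(cl))
    cl <- list(pairs = neighbor_pair_analysis(gs, sim$genome,
                                              n_perm = n_perm,
                                              seed = config$seed),
               runs = run_length_analysis(gs, sim$genome, null = "analytic"),
               orientation = orientation_enrichment(gs, sim$genome))
  results$cluster_stats <- cl

  ## 6. expression + association -----------------------------------------
  ex <- run_stage("expression", paste(sim_digest, "expression"), function() {
    em <- simulate_expression(sim$genome, config)
    sm <- expression_summary(em)
    sp <- splicing_calls(em$transcripts, em$adult_fpkm)
    ab <- association_battery(gs, sm, sp, dip_B = dip_B, seed = config$seed)
    f1 <- file.path(out_dir, "expression_summary.tsv")
    utils::write.table(sm, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    list(result = list(matrix = em, summary = sm, splicing = sp,
                       association = ab),
         files = c(summary = f1))
  })
  if (is.null(ex)) {
    em <- simulate_expression(sim$genome, config)
    sm <- expression_summary(em)
    sp <- splicing_calls(em$transcripts, em$adult_fpkm)
    ex <- list(matrix = em, summary = sm, splicing = sp,
               association = association_battery(gs, sm, sp, dip_B = dip_B,
                                                 seed = config$seed))
  }
  results$expression <- ex

  ## 7. comparative --------------------------------------------------------
  cp <- run_stage("comparative", paste(upstream, "comparative"), function() {
    ot <- simulate_ortholog_table(seed = config$seed)
    cons <- assign_conservation(ot$table[, !(names(ot$table) %in%
                                               "true_category")],
                                focal = "focal", sister = "sister")
    conc <- concordance_analysis(ot$status_focal, ot$status_sister)
    pp <- simulate_paralog_pairs(seed = config$seed)
    par <- paralog_analysis(pp)
    f <- file.path(out_dir, "comparative.json")
    jsonlite::write_json(list(
      category_counts = as.list(table(cons$category)),
      concordance_excess = conc$excess,
      paralog_median_p = par$median$p), f, auto_unbox = TRUE, digits = NA)
    list(result = list(conservation = cons, concordance = conc,
                       paralogs = par),
         files = c(comparative = f))
  })
  if (is.null(cp)) {
    ot <- simulate_ortholog_table(seed = config$seed)
    cp <- list(conservation = assign_conservation(
                 ot$table[, !(names(ot$table) %in% "true_category")],
                 focal = "focal", sister = "sister"),
               concordance = concordance_analysis(ot$status_focal,
                                                  ot$status_sister),
               paralogs = paralog_analysis(simulate_paralog_pairs(
                 seed = config$seed)))
  }
  results$comparative <- cp

  ## recovery against truth
  truth <- sim$genome$genes
  st <- gs[gs$status %in% c("methylated", "non_methylated"), ]
  m <- match(st$gene_id, truth$gene_id)
  results$recovery <- mean((st$status == "methylated") == truth$methylated[m])

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  structure(list(results = results, manifest = manifest,
                 manifest_path = manifest_path),
            class = "run_manifest")
}

## Align reads: control spike-in first, remainder to the genome.
align_stage <- function(reads, genome, control, max_mismatches = 4L) {
  ctrl_refs <- build_converted_references(control)
  ctrl_placed <- align_bisulfite_reads(reads, ctrl_refs,
                                       max_mismatches = max_mismatches)
  ctrl_report <- extract_cytosine_report(ctrl_placed, control)
  rest <- reads[!(names(reads) %in% ctrl_placed$qname)]
  refs <- build_converted_references(genome)
  placed <- align_bisulfite_reads(rest, refs, max_mismatches = max_mismatches)
  report <- extract_cytosine_report(placed, genome)
  conv <- estimate_conversion_efficiency(ctrl_report, placed = ctrl_placed,
                                         genome = control)
  list(placed = placed, report = report,
       control_placed = ctrl_placed, control_report = ctrl_report,
       conversion = conv,
       lambda_fraction = nrow(ctrl_placed) / length(reads))
}

object_digest <- function(x) {
  tf <- tempfile(); on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

outputs_ok <- function(rec) {
  all(vapply(rec$outputs, function(o)
    file.exists(o$path) && identical(unname(tools::md5sum(o$path)), o$md5),
    TRUE))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", length(x$manifest$stages), "stages; status recovery",
      sprintf("%.1f%%", 100 * x$results$recovery), "\n")
  invisible(x)
}
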