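#' Run the full panel pipeline on a simulated or supplied cohort
#'
#' Orchestrates the stages end to end: obtain a coverage matrix and a
#' variant cohort (either simulated from a `simulation` config block or
#' loaded from files named in an `inputs` block), run coverage QC, call
#' exonic deletions, run the patient-mode filter cascade, assign
#' molecular diagnoses and compute cohort statistics. All intermediates
#' are written as plain TSV so each stage is independently inspectable,
#' together with a Markdown summary report and a JSON run manifest
#' (config snapshot, seed, file checksums, per-stage row counts).
#' Re-running with the same config and seed reproduces identical files.
#'
#' Config blocks (YAML file or an equivalent nested list):
#' * `seed`: integer, drives every random stage.
#' * `simulation`: `n_patients`, optional class `fractions`, coverage
#'   parameters (`depth_mean`, `depth_dispersion`, ...); or
#' * `inputs`: paths `coverage`, `variants`, `patients`.
#' * `filter`: optional `maf_threshold`, `hwe_alpha`.
#' * `cnv`: optional `threshold`, `min_run`.
#'
#' @param config Path to a YAML config or a nested list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`qc`, `cnv`, `filter`, `diagnoses`, `yield`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config is missing required block: seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  genes <- hlh_panel_genes()
  amplicons <- default_amplicons(genes)

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    n_pat <- if (is.null(sim$n_patients)) 58L else as.integer(sim$n_patients)
    cc_args <- list(seed = seed, n_patients = n_pat)
    if (!is.null(sim$fractions)) cc_args$fractions <- sim$fractions
    cohort <- simulate_cohort(genes, amplicons,
                              do.call(cohort_sim_config, cc_args))
    cov_args <- list(seed = seed, n_samples = n_pat)
    for (nm in c("depth_mean", "depth_dispersion", "amplicon_efficiency_sd",
                 "sample_factor_sd", "n_failed_amplicons")) {
      if (!is.null(sim[[nm]])) cov_args[[nm]] <- sim[[nm]]
    }
    cov <- simulate_coverage(amplicons, do.call(coverage_sim_config, cov_args),
                             sample_ids = cohort$patients$patient_id)
    matrix <- cov$matrix
    patients <- cohort$patients
    variants <- cohort$variants
    genotypes <- cohort$genotypes
    external <- NULL
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (nm in c("coverage", "variants", "patients")) {
      if (is.null(inp[[nm]])) stop("config inputs block is missing: ", nm)
    }
    matrix <- read_coverage_matrix(inp$coverage)
    vl <- read_variants_tsv(inp$variants)
    variants <- vl$variants; genotypes <- vl$genotypes
    patients <- readr::read_tsv(inp$patients, show_col_types = FALSE)
    external <- NULL
  } else {
    stop("config is missing required block: simulation or inputs")
  }

  # stage: coverage QC
  qc <- coverage_summary(matrix, amplicons)
  write_report(qc$per_amplicon, file.path(out_dir, "coverage_qc.tsv"))
  write_report(qc$gene_coverage, file.path(out_dir, "gene_coverage.tsv"))

  # stage: CNV calling
  cnv_thr <- if (!is.null(config$cnv$threshold)) config$cnv$threshold else 0.1
  cnv_run <- if (!is.null(config$cnv$min_run)) config$cnv$min_run else 2L
  norm <- normalize_coverage(matrix, failed = qc$failed)
  sexes <- setNames(patients$sex, patients$patient_id)
  cnv <- call_deletions(norm$ratios, amplicons, genes, sexes,
                        threshold = cnv_thr, min_run = cnv_run)
  write_report(cnv$calls, file.path(out_dir, "cnv_calls.tsv"))

  # stage: patient-mode filter cascade
  fc_args <- list()
  if (!is.null(config$filter$maf_threshold)) {
    fc_args$maf_threshold <- config$filter$maf_threshold
  }
  if (!is.null(config$filter$hwe_alpha)) {
    fc_args$hwe_alpha <- config$filter$hwe_alpha
  }
  fc <- do.call(filter_config, fc_args)
  casc <- run_cascade(variants, fc, mode = "patient")
  write_report(casc$survivors[, setdiff(names(casc$survivors), "by_consequence")],
               file.path(out_dir, "filtered_variants.tsv"))
  trace_flat <- casc$trace[, c("step", "n_in", "n_out")]
  write_report(trace_flat, file.path(out_dir, "filter_trace.tsv"))

  # stage: diagnosis
  diagnoses <- diagnose_cohort(patients, casc$survivors, genotypes,
                               deletion_calls = cnv$calls,
                               external_alleles = external, genes = genes)
  write_report(diagnoses, file.path(out_dir, "diagnoses.tsv"))

  # stage: cohort statistics
  yield <- cohort_yield(diagnoses, patients)
  tab <- trigger_table(diagnoses, patients)
  trig_p <- fisher_2x2(tab)
  write_report(yield$by_age_bin, file.path(out_dir, "yield_by_age.tsv"))

  report <- c(
    "# Panel pipeline report", "",
    sprintf("- Patients: %d", nrow(patients)),
    sprintf("- Failed amplicons: %d (%s)", length(qc$failed),
            paste(qc$failed, collapse = ", ")),
    sprintf("- Deletion calls: %d", nrow(cnv$calls)),
    sprintf("- Filter cascade: %s",
            paste(sprintf("%s %d->%d", trace_flat$step, trace_flat$n_in,
                          trace_flat$n_out), collapse = "; ")),
    sprintf("- Diagnosed: %d of %d (%.1f%%)", yield$overall$diagnosed,
            yield$overall$n, yield$overall$pct),
    sprintf("- Monoallelic VUS among undiagnosed: %d of %d (%.1f%%)",
            yield$vus_among_undiagnosed$vus_only,
            yield$vus_among_undiagnosed$n, yield$vus_among_undiagnosed$pct),
    sprintf("- Trigger-by-diagnosis Fisher p: %.4g", trig_p)
  )
  writeLines(report, file.path(out_dir, "report.md"))

  outputs <- list.files(out_dir, pattern = "\\.(tsv|md)$", full.names = TRUE)
  manifest <- list(
    tool = paste0("hlhpanel ", as.character(utils::packageVersion("hlhpanel"))),
    seed = seed,
    config = config,
    row_counts = list(patients = nrow(patients), variants = nrow(variants),
                      genotypes = nrow(genotypes),
                      cascade_survivors = nrow(casc$survivors),
                      cnv_calls = nrow(cnv$calls),
                      diagnosed = yield$overall$diagnosed),
    checksums = as.list(setNames(unname(tools::md5sum(sort(outputs))),
                                 basename(sort(outputs))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qc, cnv = cnv, filter = casc, diagnoses = diagnoses,
                 yield = yield, trigger_p = trig_p, manifest = manifest))
}
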