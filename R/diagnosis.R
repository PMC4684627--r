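#' Age bin used for cohort yield stratification
#'
#' Bins: `[0,1)`, `[1,5)`, `[5,12)`, `[12,18)`, `[18,Inf)`, labelled
#' `0-1`, `1-5`, `5-12`, `12-18`, `18+`. `NA` ages map to `NA`.
#'
#' @param age Age at diagnosis in years (fractional allowed).
#' @return Character vector of bin labels.
#' @export
age_bin <- function(age) {
  labs <- c("0-1", "1-5", "5-12", "12-18", "18+")
  as.character(cut(age, breaks = c(0, 1, 5, 12, 18, Inf), right = FALSE,
                   labels = labs, include.lowest = TRUE))
}

.damaging_or_lof <- function(variants) {
  (!is.na(variants$sift_pred) & variants$sift_pred == "deleterious") |
    (!is.na(variants$polyphen_pred) &
       variants$polyphen_pred %in% c("probably_damaging", "possibly_damaging")) |
    variants$consequence %in% .lof_consequences
}

#' Assign a molecular diagnosis to one patient
#'
#' Applies the zygosity/inheritance logic of the panel: a patient is
#' `diagnosed` when one gene carries
#' * in an AR gene: a homozygous qualifying variant, a homozygous
#'   exonic-deletion call, or two or more distinct heterozygous
#'   qualifying alleles at different positions (presumed compound
#'   heterozygous, in trans; externally typed structural alleles such
#'   as a known inversion count as one allele), or
#' * in an XL gene, in a male: a hemizygous qualifying variant or a
#'   hemizygous deletion call.
#'
#' Two heterozygous variants at the same position are treated as one
#' allele candidate (possible same-allele artifact) and flagged. A
#' female heterozygous for an XL variant is a carrier, never diagnosed.
#' Patients not diagnosed but carrying at least one damaging-predicted
#' monoallelic variant are `vus_only`; otherwise `undiagnosed`.
#'
#' @param patient One-row tibble with `patient_id` and `sex`.
#' @param variants Qualifying variants (post patient-mode cascade and
#'   any curation), tibble as from [read_variants_tsv()].
#' @param genotypes This patient's genotype calls (`variant_id`,
#'   `zygosity`).
#' @param deletion_calls Deletion calls for this patient (may be empty),
#'   as from [call_deletions()].
#' @param external_alleles Externally typed alleles: tibble with `gene`,
#'   `allele`, `zygosity` (e.g. an inversion typed by a dedicated PCR
#'   assay).
#' @param genes Panel gene tibble (inheritance and disease labels).
#' @return One-row tibble: `patient_id`, `status`, `causal_gene`,
#'   `disease_label`, `causal_variants` (semicolon-joined), `flagged`.
#' @export
classify_patient <- function(patient, variants, genotypes,
                             deletion_calls = NULL,
                             external_alleles = NULL,
                             genes = hlh_panel_genes()) {
  pv <- dplyr::inner_join(genotypes, variants, by = "variant_id")
  male <- identical(patient$sex, "M")
  flagged <- FALSE
  result <- NULL

  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    inh <- genes$inheritance[gi]
    vg <- pv[pv$gene == g, ]
    dg <- if (!is.null(deletion_calls) && nrow(deletion_calls) > 0) {
      deletion_calls[deletion_calls$gene == g, ]
    } else NULL
    eg <- if (!is.null(external_alleles) && nrow(external_alleles) > 0) {
      external_alleles[external_alleles$gene == g, ]
    } else NULL

    if (inh == "AR") {
      hom_vars <- vg[vg$zygosity == "hom", ]
      het_vars <- vg[vg$zygosity == "het", ]
      # distinct het allele candidates: one per position
      if (nrow(het_vars) > 0 && anyDuplicated(het_vars$position)) {
        flagged <- TRUE
        het_vars <- het_vars[!duplicated(het_vars$position), ]
      }
      hom_del <- !is.null(dg) && any(dg$zygosity == "homozygous")
      n_ext_het <- if (!is.null(eg)) sum(eg$zygosity == "het") else 0L
      ext_hom <- !is.null(eg) && any(eg$zygosity == "hom")
      n_alleles <- nrow(het_vars) + n_ext_het
      if (nrow(hom_vars) > 0 || hom_del || ext_hom || n_alleles >= 2) {
        causal <- c(
          hom_vars$variant_id[seq_len(min(1, nrow(hom_vars)))],
          if (hom_del) paste0(g, ":exonic_deletion(hom)"),
          if (ext_hom) paste0(g, ":", eg$allele[eg$zygosity == "hom"][1], "(hom)")
        )
        if (length(causal) == 0 && n_alleles >= 2) {
          causal <- c(head(het_vars$variant_id, 2),
                      if (n_ext_het > 0) paste0(g, ":", eg$allele[eg$zygosity == "het"]))
          causal <- head(causal, 2)
        }
        result <- list(gene = g, disease = genes$disease[gi], causal = causal)
        break
      }
    } else {  # XL
      hemi_vars <- vg[vg$zygosity == "hemi", ]
      hemi_del <- !is.null(dg) && any(dg$zygosity == "hemizygous")
      ext_hemi <- !is.null(eg) && any(eg$zygosity == "hemi")
      if (male && (nrow(hemi_vars) > 0 || hemi_del || ext_hemi)) {
        causal <- c(head(hemi_vars$variant_id, 1),
                    if (hemi_del) paste0(g, ":exonic_deletion(hemi)"),
                    if (ext_hemi) paste0(g, ":", eg$allele[eg$zygosity == "hemi"][1]))
        result <- list(gene = g, disease = genes$disease[gi],
                       causal = head(causal, 2))
        break
      }
    }
  }

  if (!is.null(result)) {
    return(tibble::tibble(patient_id = patient$patient_id,
                          status = "diagnosed",
                          causal_gene = result$gene,
                          disease_label = result$disease,
                          causal_variants = paste(result$causal, collapse = ";"),
                          flagged = flagged))
  }
  het_dam <- pv[pv$zygosity %in% c("het") & .damaging_or_lof(pv), ]
  status <- if (nrow(het_dam) > 0) "vus_only" else "undiagnosed"
  tibble::tibble(patient_id = patient$patient_id, status = status,
                 causal_gene = NA_character_, disease_label = NA_character_,
                 causal_variants = if (status == "vus_only") {
                   paste(het_dam$variant_id, collapse = ";")
                 } else "",
                 flagged = flagged)
}

#' Classify every patient in a cohort
#'
#' @param patients Patient metadata tibble (`patient_id`, `sex`, ...).
#' @param variants Qualifying variant tibble.
#' @param genotypes Genotype calls (`sample_id`, `variant_id`,
#'   `zygosity`).
#' @param deletion_calls Deletion calls tibble (column `sample_id`).
#' @param external_alleles Tibble with `patient_id`, `gene`, `allele`,
#'   `zygosity`.
#' @param genes Panel gene tibble.
#' @return Tibble of per-patient [classify_patient()] rows.
#' @export
diagnose_cohort <- function(patients, variants, genotypes,
                            deletion_calls = NULL, external_alleles = NULL,
                            genes = hlh_panel_genes()) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    g <- genotypes[genotypes$sample_id == p$patient_id, ]
    d <- if (!is.null(deletion_calls) && nrow(deletion_calls) > 0) {
      deletion_calls[deletion_calls$sample_id == p$patient_id, ]
    } else NULL
    e <- if (!is.null(external_alleles) && nrow(external_alleles) > 0) {
      external_alleles[external_alleles$patient_id == p$patient_id, ]
    } else NULL
    classify_patient(p, variants, g, d, e, genes)
  })
  dplyr::bind_rows(rows)
}

#' Diagnostic yield overall, per age bin, and in the pediatric subset
#'
#' Fractions are reported with exact numerators and denominators.
#' Patients with unknown age are excluded from the binned yields and
#' from the infant/older split but included in the overall yield (the
#' denominators differ and both are reported). The pediatric subset
#' excludes known adult cases (age >= 18); a patient of unknown age
#' stays in it. `older` aggregates every patient with onset at or after
#' one year of age. Also reports the fraction of patients without a
#' diagnosis who carry at least one monoallelic damaging-predicted
#' variant (`vus_only`).
#'
#' @param results Diagnosis tibble from [diagnose_cohort()].
#' @param patients Patient metadata with `age_at_diagnosis`.
#' @return List of class `yield_report`: `overall` (n, diagnosed,
#'   pct), `by_age_bin` tibble, `older`, `pediatric`,
#'   `vus_among_undiagnosed`.
#' @export
cohort_yield <- function(results, patients) {
  df <- dplyr::inner_join(results, patients, by = "patient_id")
  if (nrow(df) == 0) {
    return(structure(list(
      overall = tibble::tibble(n = 0L, diagnosed = 0L, pct = NA_real_),
      by_age_bin = tibble::tibble(age_bin = character(), n = integer(),
                                  diagnosed = integer(), pct = double()),
      older = tibble::tibble(n = 0L, diagnosed = 0L, pct = NA_real_),
      pediatric = tibble::tibble(n = 0L, diagnosed = 0L, pct = NA_real_),
      vus_among_undiagnosed = tibble::tibble(n = 0L, vus_only = 0L,
                                             pct = NA_real_)
    ), class = "yield_report"))
  }
  df$bin <- age_bin(df$age_at_diagnosis)
  dx <- df$status == "diagnosed"

  overall <- tibble::tibble(n = nrow(df), diagnosed = sum(dx),
                            pct = 100 * mean(dx))
  known <- !is.na(df$bin)
  by_bin <- dplyr::summarise(
    dplyr::group_by(df[known, ], .data$bin),
    n = dplyr::n(), diagnosed = sum(.data$status == "diagnosed"),
    pct = 100 * .data$diagnosed / .data$n, .groups = "drop")
  by_bin <- by_bin[order(match(by_bin$bin, c("0-1", "1-5", "5-12", "12-18", "18+"))), ]
  names(by_bin)[1] <- "age_bin"

  old <- known & df$age_at_diagnosis >= 1
  older <- tibble::tibble(n = sum(old), diagnosed = sum(dx[old]),
                          pct = if (sum(old) > 0) 100 * mean(dx[old]) else NA_real_)
  ped <- !(known & df$age_at_diagnosis >= 18)
  pediatric <- tibble::tibble(n = sum(ped), diagnosed = sum(dx[ped]),
                              pct = if (sum(ped) > 0) 100 * mean(dx[ped]) else NA_real_)
  und <- !dx
  vus <- tibble::tibble(
    n = sum(und), vus_only = sum(df$status[und] == "vus_only"),
    pct = if (sum(und) > 0) 100 * mean(df$status[und] == "vus_only") else NA_real_)

  structure(list(overall = overall, by_age_bin = by_bin, older = older,
                 pediatric = pediatric, vus_among_undiagnosed = vus),
            class = "yield_report")
}

#' Trigger-by-diagnosis contingency table
#'
#' 2x2 counts of (undiagnosed / diagnosed) x (known secondary-HLH
#' trigger present / absent), ready for [fisher_2x2()]. By default
#' `none` counts as absent and `unknown` patients are excluded;
#' `unknown_as_absent = TRUE` keeps them as absent instead.
#'
#' @param results Diagnosis tibble.
#' @param patients Patient metadata with `trigger`.
#' @param unknown_as_absent Treat `unknown` trigger as absent rather
#'   than excluding the patient.
#' @return 2x2 integer matrix, rows `undiagnosed`/`diagnosed`, columns
#'   `trigger`/`no_trigger`.
#' @export
trigger_table <- function(results, patients, unknown_as_absent = FALSE) {
  df <- dplyr::inner_join(results, patients, by = "patient_id")
  if (!unknown_as_absent) df <- df[df$trigger != "unknown", ]
  present <- !(df$trigger %in% c("none", "unknown"))
  dx <- df$status == "diagnosed"
  tab <- matrix(c(sum(!dx & present), sum(!dx & !present),
                  sum(dx & present), sum(dx & !present)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("undiagnosed", "diagnosed"),
                                c("trigger", "no_trigger")))
  tab
}
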