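genes <- hlh_panel_genes()

pv <- function(...) mk_variants(
  ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence, ~sift_pred, ~polyphen_pred,
  ...)

test_that("homozygous AR variants and compound hets diagnose correctly", {
  vars <- pv(
    "chr10", 659L, "G", "A", "PRF1", "missense", "deleterious", "probably_damaging",
    "chr10", 272L, "C", "T", "PRF1", "missense", "deleterious", "possibly_damaging",
    "chr10", 1288L, "G", "T", "PRF1", "missense", "deleterious", "probably_damaging"
  )
  p <- tibble::tibble(patient_id = "A", sex = "F")

  hom <- classify_patient(p, vars, tibble::tibble(
    sample_id = "A", variant_id = vars$variant_id[1], zygosity = "hom"),
    genes = genes)
  expect_equal(hom$status, "diagnosed")
  expect_equal(hom$causal_gene, "PRF1")
  expect_equal(hom$disease_label, "FHL2")

  comp <- classify_patient(p, vars, tibble::tibble(
    sample_id = "A", variant_id = vars$variant_id[2:3], zygosity = "het"),
    genes = genes)
  expect_equal(comp$status, "diagnosed")
  expect_equal(comp$disease_label, "FHL2")
  expect_equal(length(strsplit(comp$causal_variants, ";")[[1]]), 2)

  # single damaging het: VUS only
  single <- classify_patient(p, vars, tibble::tibble(
    sample_id = "A", variant_id = vars$variant_id[2], zygosity = "het"),
    genes = genes)
  expect_equal(single$status, "vus_only")
})

test_that("two hets at one position are a single allele candidate", {
  vars <- pv(
    "chr10", 272L, "C", "T", "PRF1", "missense", "deleterious", "probably_damaging",
    "chr10", 272L, "C", "G", "PRF1", "missense", "deleterious", "probably_damaging"
  )
  p <- tibble::tibble(patient_id = "A", sex = "F")
  out <- classify_patient(p, vars, tibble::tibble(
    sample_id = "A", variant_id = vars$variant_id, zygosity = "het"),
    genes = genes)
  expect_false(out$status == "diagnosed")
  expect_true(out$flagged)
})

test_that("X-linked logic requires hemizygosity in a male", {
  vars <- pv("chrX", 877L, "G", "A", "XIAP", "missense", "deleterious", "probably_damaging")
  gt <- function(z) tibble::tibble(sample_id = "A", variant_id = vars$variant_id,
                                   zygosity = z)
  male <- tibble::tibble(patient_id = "A", sex = "M")
  female <- tibble::tibble(patient_id = "A", sex = "F")
  expect_equal(classify_patient(male, vars, gt("hemi"), genes = genes)$status,
               "diagnosed")
  expect_equal(classify_patient(male, vars, gt("hemi"), genes = genes)$disease_label,
               "XLP2")
  # female heterozygous carrier is never diagnosed through an XL gene
  expect_equal(classify_patient(female, vars, gt("het"), genes = genes)$status,
               "vus_only")
})

test_that("deletion calls and external alleles complete diagnoses", {
  p_m <- tibble::tibble(patient_id = "A", sex = "M")
  empty_vars <- mk_variants(~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence)
  no_gt <- tibble::tibble(sample_id = character(), variant_id = character(),
                          zygosity = character())
  hemi_del <- tibble::tibble(sample_id = "A", gene = "XIAP",
                             first_amplicon_id = "XIAP_001",
                             last_amplicon_id = "XIAP_013",
                             n_amplicons = 13L, zygosity = "hemizygous",
                             mean_ratio = 0.01)
  out <- classify_patient(p_m, empty_vars, no_gt, deletion_calls = hemi_del,
                          genes = genes)
  expect_equal(out$status, "diagnosed")
  expect_equal(out$disease_label, "XLP2")

  hom_del <- tibble::tibble(sample_id = "A", gene = "STX11",
                            first_amplicon_id = "STX11_005",
                            last_amplicon_id = "STX11_012",
                            n_amplicons = 8L, zygosity = "homozygous",
                            mean_ratio = 0.005)
  out2 <- classify_patient(tibble::tibble(patient_id = "A", sex = "F"),
                           empty_vars, no_gt, deletion_calls = hom_del,
                           genes = genes)
  expect_equal(out2$disease_label, "FHL4")

  # one het SNV plus an externally typed allele forms a compound het
  vars <- pv("chr17", 569L, "G", "A", "UNC13D", "splice_region", NA, NA)
  ext <- tibble::tibble(patient_id = "A", gene = "UNC13D",
                        allele = "intron1_inversion", zygosity = "het")
  out3 <- classify_patient(p_m, vars, tibble::tibble(
    sample_id = "A", variant_id = vars$variant_id, zygosity = "het"),
    external_alleles = ext, genes = genes)
  expect_equal(out3$status, "diagnosed")
  expect_equal(out3$disease_label, "FHL3")
})

test_that("planted truth labels are recovered from simulated cohorts", {
  sim <- simulate_cohort(genes, config = cohort_sim_config(
    seed = 19, n_patients = 40,
    fractions = list(biallelic = 0.4, hemizygous = 0.1,
                     monoallelic_vus = 0.2, benign_only = 0.3)))
  casc <- run_cascade(sim$variants, filter_config(), mode = "patient")
  dx <- diagnose_cohort(sim$patients, casc$survivors, sim$genotypes,
                        genes = genes)
  joined <- dplyr::inner_join(dx, sim$truth, by = "patient_id")
  expected <- c(biallelic = "diagnosed", hemizygous = "diagnosed",
                monoallelic_vus = "vus_only", benign_only = "undiagnosed")
  expect_equal(joined$status, unname(expected[joined$class]))
  dxed <- joined[joined$status == "diagnosed", ]
  expect_equal(dxed$causal_gene, dxed$gene)
})

test_that("fully biallelic cohorts are fully diagnosed", {
  sim <- simulate_cohort(genes, config = cohort_sim_config(
    seed = 23, n_patients = 10, fractions = list(biallelic = 1.0)))
  casc <- run_cascade(sim$variants, filter_config(), mode = "patient")
  dx <- diagnose_cohort(sim$patients, casc$survivors, sim$genotypes,
                        genes = genes)
  expect_equal(sum(dx$status == "diagnosed"), 10)
})

test_that("removing a background polymorphism never changes a status", {
  sim <- simulate_cohort(genes, config = cohort_sim_config(
    seed = 29, n_patients = 20,
    fractions = list(biallelic = 0.5, monoallelic_vus = 0.2)))
  casc <- run_cascade(sim$variants, filter_config(), mode = "patient")
  base <- diagnose_cohort(sim$patients, casc$survivors, sim$genotypes,
                          genes = genes)
  # drop one common background call from every patient carrying one
  bg_ids <- sim$variants$variant_id[!is.na(sim$variants$maf) &
                                      sim$variants$maf >= 0.05]
  pruned <- sim$genotypes[!(sim$genotypes$variant_id %in% bg_ids[1]), ]
  after <- diagnose_cohort(sim$patients, casc$survivors, pruned, genes = genes)
  expect_equal(after$status, base$status)
})

test_that("yields and age bins follow the documented edges", {
  expect_equal(age_bin(c(0, 0.99, 1, 4.9, 5, 11.9, 12, 17.9, 18, 70)),
               c("0-1", "0-1", "1-5", "1-5", "5-12", "5-12", "12-18",
                 "12-18", "18+", "18+"))
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:6),
    age_at_diagnosis = c(0.5, 0.6, 2, 19, NA, 3),
    sex = "F", trigger = c("EBV", "none", "none", "EBV", "none", "unknown"))
  results <- tibble::tibble(
    patient_id = patients$patient_id,
    status = c("diagnosed", "diagnosed", "undiagnosed", "undiagnosed",
               "vus_only", "undiagnosed"),
    causal_gene = NA, disease_label = NA, causal_variants = "", flagged = FALSE)
  y <- cohort_yield(results, patients)
  expect_equal(y$overall$n, 6)
  expect_equal(y$overall$diagnosed, 2)
  bin01 <- y$by_age_bin[y$by_age_bin$age_bin == "0-1", ]
  expect_equal(c(bin01$n, bin01$diagnosed), c(2, 2))
  # unknown age excluded from bins, kept overall and in pediatric
  expect_equal(sum(y$by_age_bin$n), 5)
  expect_equal(y$pediatric$n, 5)
  expect_equal(y$older$n, 3)
  expect_equal(y$vus_among_undiagnosed$pct, 25)

  # empty cohort: no division errors
  y0 <- cohort_yield(results[0, ], patients[0, ])
  expect_equal(y0$overall$n, 0)
})

test_that("trigger table is order invariant with configurable unknowns", {
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:5), age_at_diagnosis = 1, sex = "F",
    trigger = c("EBV", "none", "unknown", "malignancy", "none"))
  results <- tibble::tibble(
    patient_id = patients$patient_id,
    status = c("undiagnosed", "diagnosed", "undiagnosed", "undiagnosed",
               "undiagnosed"))
  tab <- trigger_table(results, patients)
  expect_equal(unname(tab["undiagnosed", ]), c(2, 1))
  expect_equal(unname(tab["diagnosed", ]), c(0, 1))
  # permuting rows leaves the table unchanged
  ord <- c(4, 2, 5, 1, 3)
  expect_equal(trigger_table(results[ord, ], patients[ord, ]), tab)
  # unknown as absent inflates the no-trigger column
  tab2 <- trigger_table(results, patients, unknown_as_absent = TRUE)
  expect_equal(unname(tab2["undiagnosed", ]), c(2, 2))
  # all-none triggers empty the first column
  patients$trigger <- "none"
  expect_equal(unname(trigger_table(results, patients)[, "trigger"]), c(0, 0))
})
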