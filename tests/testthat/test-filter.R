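fc <- filter_config()

test_that("consequence filter keeps impact classes, drops silent ones", {
  vars <- mk_variants(
    ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence,
    "chr10", 1L, "C", "T", "PRF1", "synonymous",
    "chr17", 2L, "G", "A", "UNC13D", "splice_acceptor",
    "chr17", 3L, "G", "A", "UNC13D", "intronic",
    "chr19", 4L, "C", "G", "STXBP2", "missense",
    "chr1", 5L, "T", "C", "LYST", "UTR",
    "chr1", 6L, "T", "C", "LYST", "weird_term"
  )
  out <- consequence_filter(vars, fc) |> suppressWarnings()
  expect_setequal(out$consequence, c("splice_acceptor", "missense", "weird_term"))
  expect_true(out$consequence_flag[out$consequence == "weird_term"])
  expect_warning(consequence_filter(vars, fc), "unrecognised")

  # empty input passes through
  expect_equal(nrow(consequence_filter(vars[0, ], fc)), 0)

  # regulatory allow-list rescues a deep-intronic regulatory allele
  reg <- mk_variants(
    ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence, ~hgvs_c,
    "chr17", 7L, "G", "A", "UNC13D", "regulatory", "c.118-307G>A")
  expect_equal(nrow(consequence_filter(reg, fc)), 0)
  fc_allow <- filter_config(regulatory_allowlist = "c.118-307G>A")
  expect_equal(nrow(consequence_filter(reg, fc_allow)), 1)
})

test_that("MAF filter is strict-less-than with missing treated as zero", {
  vars <- mk_variants(
    ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence, ~maf,
    "chr10", 1L, "C", "T", "PRF1", "missense", 0.05,
    "chr10", 2L, "C", "T", "PRF1", "missense", NA,
    "chr10", 3L, "C", "T", "PRF1", "missense", 0.004,
    "chr10", 4L, "C", "T", "PRF1", "missense", 0.3
  )
  out <- maf_filter(vars, fc)
  expect_setequal(out$position, c(2L, 3L))
})

test_that("damaging filter honours either-tool rule and LoF bypass", {
  vars <- mk_variants(
    ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence, ~sift_pred, ~polyphen_pred,
    "chr10", 1L, "C", "T", "PRF1", "missense", "tolerated", "benign",
    "chr10", 2L, "C", "T", "PRF1", "missense", "deleterious", "benign",
    "chr10", 3L, "C", "T", "PRF1", "missense", "tolerated", "possibly_damaging",
    "chr10", 4L, "C", "T", "PRF1", "frameshift", NA, NA,
    "chr10", 5L, "C", "T", "PRF1", "missense", NA, NA
  )
  pop <- damaging_filter(vars, fc, mode = "population")
  expect_setequal(pop$position, c(2L, 3L, 4L))
  pat <- damaging_filter(vars, fc, mode = "patient")
  expect_setequal(pat$position, c(2L, 3L, 4L, 5L))
  expect_true(pat$prediction_flag[pat$position == 5L])
  expect_false(any(pat$prediction_flag[pat$position != 5L]))
})

test_that("exact HWE test matches enumeration oracles", {
  # worked example: one hom-ref, one hom-alt individual
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # modal configuration: p = 1
  expect_equal(hwe_exact_p(0, 2, 0), 1.0, tolerance = 1e-12)
  # monomorphic convention
  expect_equal(hwe_exact_p(10, 0, 0), 1.0)

  # exhaustive agreement with the individual-level oracle, n <= 6
  for (n_AA in 0:4) for (n_Aa in 0:4) for (n_aa in 0:4) {
    n <- n_AA + n_Aa + n_aa
    if (n < 1 || n > 6) next
    expect_equal(hwe_exact_p(n_AA, n_Aa, n_aa),
                 hwe_oracle_small(n_AA, n_Aa, n_aa),
                 tolerance = 1e-9,
                 label = sprintf("hwe(%d,%d,%d)", n_AA, n_Aa, n_aa))
  }
  # exhaustive agreement with the closed-form choose() oracle, n <= 20
  for (n in c(10, 15, 20)) {
    for (n_aa in 0:floor(n / 2)) for (n_Aa in 0:(n - 2 * n_aa)) {
      n_AA <- n - n_Aa - n_aa
      expect_equal(hwe_exact_p(n_AA, n_Aa, n_aa),
                   hwe_oracle_choose(n_AA, n_Aa, n_aa),
                   tolerance = 1e-9)
    }
  }
})

test_that("exact HWE test is symmetric under allele relabeling", {
  set.seed(1)
  for (i in 1:50) {
    x <- sample(0:30, 3, replace = TRUE)
    if (sum(x) == 0) next
    expect_equal(hwe_exact_p(x[1], x[2], x[3]), hwe_exact_p(x[3], x[2], x[1]),
                 tolerance = 1e-12)
  }
})

test_that("cascade trace is arithmetically consistent and order fixed", {
  vars <- mk_variants(
    ~chromosome, ~position, ~ref, ~alt, ~gene, ~consequence, ~maf, ~sift_pred, ~polyphen_pred,
    "chr10", 1L, "C", "T", "PRF1", "missense", 0.2, "deleterious", "benign",
    "chr10", 2L, "C", "T", "PRF1", "synonymous", 0.01, NA, NA,
    "chr10", 3L, "C", "T", "PRF1", "missense", 0.001, "deleterious", "probably_damaging",
    "chr10", 4L, "C", "T", "PRF1", "missense", 0.001, "tolerated", "benign"
  )
  out <- run_cascade(vars, fc, mode = "patient")
  expect_equal(out$trace$step, c("consequence", "maf", "damaging"))
  expect_true(all(out$trace$n_out <= out$trace$n_in))
  expect_equal(out$trace$n_in[-1], out$trace$n_out[-nrow(out$trace)])
  expect_setequal(out$survivors$position, 3L)

  # population mode inserts the HWE step
  vars$n_AA <- c(50, 50, 10, 50)
  vars$n_Aa <- c(10, 10, 0, 10)
  vars$n_aa <- c(0, 0, 10, 0)
  out_pop <- run_cascade(vars, fc, mode = "population")
  expect_equal(out_pop$trace$step, c("consequence", "maf", "hwe", "damaging"))
  # the HWE-deviant site (10/0/10) is removed
  expect_false(3L %in% out_pop$survivors$position)
})

test_that("consequence and MAF filters commute", {
  set.seed(7)
  cons <- c(consequence_vocabulary(), "odd_term")
  for (i in 1:20) {
    n <- 30
    vars <- tibble::tibble(
      chromosome = "chr10", position = seq_len(n), ref = "C", alt = "T",
      gene = "PRF1", consequence = sample(cons, n, TRUE),
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      maf = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.2)),
      sift_pred = NA_character_, polyphen_pred = NA_character_,
      cadd = NA_real_)
    vars$variant_id <- as.character(vars$position)
    a <- suppressWarnings(maf_filter(consequence_filter(vars, fc), fc))
    b <- suppressWarnings(consequence_filter(maf_filter(vars, fc), fc))
    expect_setequal(a$variant_id, b$variant_id)
  }
})

test_that("an all-benign cohort is emptied by the damaging step", {
  genes <- hlh_panel_genes()
  sim <- simulate_cohort(genes, config = cohort_sim_config(
    seed = 13, n_patients = 12, fractions = list(benign_only = 1.0)))
  out <- run_cascade(sim$variants, fc, mode = "population")
  expect_equal(nrow(out$survivors), 0)
})
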