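test_that("Wilson interval reproduces known values and limits", {
  ci <- wilson_ci(72, 74)
  expect_equal(unname(ci["low"]), 0.907, tolerance = 5e-4)
  expect_equal(round(unname(ci["low"]), 3), 0.907)
  expect_equal(round(unname(ci["high"]), 4), 0.9926)
  expect_equal(unname(wilson_ci(0, 10)["low"]), 0)
  expect_equal(unname(wilson_ci(10, 10)["high"]), 1)
  expect_error(wilson_ci(1, 0), "positive")
})

test_that("Wilson interval contains the point estimate, narrows with n", {
  for (p in c(0.1, 0.5, 0.9)) {
    widths <- vapply(c(10, 40, 160, 640), function(n) {
      ci <- wilson_ci(round(p * n), n)
      expect_true(ci["low"] <= p + 1e-9 && p - 1e-9 <= ci["high"])
      unname(ci["high"] - ci["low"])
    }, double(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("sensitivity evaluation counts recovered truth variants", {
  truth <- tibble::tibble(sample_id = rep("S1", 4), chromosome = "chr10",
                          position = 1:4, ref = "C", alt = "T")
  called <- truth[1:3, ]
  rep1 <- sensitivity_eval(truth, called)
  expect_equal(rep1$sensitivity, 0.75)
  # extra calls do not change sensitivity
  extra <- dplyr::bind_rows(called, tibble::tibble(
    sample_id = "S1", chromosome = "chr10", position = 99L, ref = "A", alt = "G"))
  expect_equal(sensitivity_eval(truth, extra)$sensitivity, 0.75)
  # perfect recovery
  full <- sensitivity_eval(truth, truth)
  expect_equal(full$sensitivity, 1)
  expect_equal(full$ci_high, 1)
  expect_error(sensitivity_eval(truth[0, ], called), "empty truth")
})

test_that("Fisher 2x2 matches enumeration oracle and known examples", {
  expect_equal(fisher_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3,
               tolerance = 1e-12)
  # proportional rows: independence, p = 1
  expect_equal(fisher_2x2(matrix(c(3, 5, 3, 5), 2, byrow = TRUE)), 1.0)
  expect_equal(fisher_2x2(matrix(0, 2, 2)), 1.0)

  # exhaustive grid against the enumeration oracle and fisher.test
  set.seed(2)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_2x2(tab)
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-9)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher 2x2 is invariant under transposition and swaps", {
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_2x2(tab)
    expect_equal(fisher_2x2(t(tab)), p, tolerance = 1e-9)
    expect_equal(fisher_2x2(tab[2:1, 2:1]), p, tolerance = 1e-9)
  }
})

test_that("rank-sum test: exact small-sample values and tie handling", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1.0)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)

  # agreement with wilcox.test exact p when there are no ties
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:1000, 6); y <- sample(2000:3000, 7)
    expect_equal(wilcoxon_rank_sum(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
    x2 <- runif(5); y2 <- runif(8)
    expect_equal(wilcoxon_rank_sum(x2, y2),
                 wilcox.test(x2, y2, exact = TRUE)$p.value, tolerance = 1e-9)
  }
})

test_that("exact and approximate rank-sum branches agree at moderate n", {
  set.seed(5)
  diffs <- replicate(100, {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    wilcoxon_rank_sum(x, y, exact = TRUE) -
      wilcoxon_rank_sum(x, y, exact = FALSE)
  })
  expect_lt(max(abs(diffs)), 0.02)
})

test_that("carrier burden counts individuals, homozygotes and genes", {
  sites <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    gene = c("PRF1", "PRF1", "UNC13D"),
    maf = c(0.01, 0.02, 0.01))
  g <- matrix(0L, 5, 3, dimnames = list(paste0("I", 1:5), sites$variant_id))
  g["I1", "v1"] <- 1L
  g["I2", "v1"] <- 2L           # homozygous carrier
  g["I3", "v3"] <- 1L
  rep1 <- carrier_burden(g, sites, qualifying = c("v1", "v2", "v3"))
  expect_equal(rep1$n_carriers, 3)
  expect_equal(rep1$n_homozygous_carriers, 1)
  expect_equal(rep1$carrier_fraction, 0.6)
  expect_equal(rep1$per_gene$n_variants[rep1$per_gene$gene == "PRF1"], 2)

  # restriction to a gene subset
  rep2 <- carrier_burden(g, sites, qualifying = c("v1", "v2", "v3"),
                         gene_subset = "UNC13D")
  expect_equal(rep2$n_carriers, 1)

  # nobody carries anything
  rep0 <- carrier_burden(g * 0L, sites, qualifying = "v1")
  expect_equal(rep0$n_carriers, 0)
  expect_equal(rep0$carrier_fraction, 0)

  # unknown qualifying id is a hard error
  expect_error(carrier_burden(g, sites, qualifying = "nope"), "absent")
})

test_that("simulated population recovers a planted carrier fraction", {
  # ~25 % carriers from 3 independent rare sites:
  # 1 - prod(1 - 2q(1-q) - q^2) = 0.25 at q ~ 0.0468
  q <- 1 - (1 - 0.25)^(1 / 3)
  q <- 1 - sqrt(1 - q)   # per-allele frequency so P(carrier/site) matches
  sites <- tibble::tibble(variant_id = paste0("v", 1:3),
                          gene = c("PRF1", "UNC13D", "STX11"),
                          maf = rep(q, 3))
  pop <- simulate_population(sites, n_individuals = 2000, seed = 8)
  rep1 <- carrier_burden(pop$genotypes, pop$sites, qualifying = sites$variant_id)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(rep1$carrier_fraction - 0.25), 3 * se)
})

test_that("burden comparison is symmetric and flags no false enrichment", {
  counts <- tibble::tibble(label = "PRF1",
                           cohort_carriers = 3, cohort_n = 36,
                           pop_carriers = 50, pop_n = 2504)
  out <- compare_burden(counts)
  tab <- matrix(c(3, 33, 50, 2454), 2, byrow = TRUE)
  expect_equal(out$p, fisher_oracle(tab), tolerance = 1e-9)

  # identical proportions give p = 1
  eq <- compare_burden(tibble::tibble(label = "x", cohort_carriers = 5,
                                      cohort_n = 50, pop_carriers = 50,
                                      pop_n = 500))
  expect_equal(eq$p, 1.0)

  # swapping the group labels leaves the two-sided p unchanged
  sw <- compare_burden(tibble::tibble(label = "PRF1", cohort_carriers = 50,
                                      cohort_n = 2504, pop_carriers = 3,
                                      pop_n = 36))
  expect_equal(sw$p, out$p, tolerance = 1e-9)
})

test_that("exact tests hold their size under null simulations", {
  set.seed(6)
  n_rep <- 400
  # HWE-true sites
  rej_hwe <- mean(replicate(n_rep, {
    q <- runif(1, 0.05, 0.5)
    g <- sample(0:2, 60, TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.05
  }))
  # equal-proportion groups
  rej_fis <- mean(replicate(n_rep, {
    a <- rbinom(1, 30, 0.3); b <- rbinom(1, 30, 0.3)
    fisher_2x2(matrix(c(a, 30 - a, b, 30 - b), 2, byrow = TRUE)) < 0.05
  }))
  expect_gte(rej_hwe, 0.0); expect_lte(rej_hwe, 0.06)
  expect_gte(rej_fis, 0.0); expect_lte(rej_fis, 0.06)
})
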