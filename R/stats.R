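#' Wilson score confidence interval for a binomial proportion
#'
#' The interval obtained by inverting the score test, without
#' continuity correction: centre `(p + z^2/2n) / (1 + z^2/n)`,
#' half-width `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Both
#' bounds are reported at full precision.
#'
#' @param successes Number of successes.
#' @param n Number of trials (> 0).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(successes >= 0, successes <= n)
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Variant-calling sensitivity against a truth set
#'
#' Variants are identified by (sample, chromosome, position, ref, alt).
#' Sensitivity is the fraction of truth variants recovered among the
#' calls; extra calls do not enter (false-positive accounting is out of
#' scope here). The 95 % Wilson score interval quantifies uncertainty.
#'
#' @param truth,called Tibbles with columns `sample_id`, `chromosome`,
#'   `position`, `ref`, `alt`.
#' @param confidence Confidence level for the Wilson interval.
#' @return List of class `sensitivity_report`: `n_expected`, `n_called`,
#'   `sensitivity`, `ci_low`, `ci_high`.
#' @export
sensitivity_eval <- function(truth, called, confidence = 0.95) {
  if (nrow(truth) == 0) stop("empty truth set")
  key <- function(df) paste(df$sample_id, df$chromosome, df$position,
                            df$ref, df$alt, sep = ":")
  tk <- unique(key(truth))
  ck <- unique(key(called))
  hit <- sum(tk %in% ck)
  ci <- wilson_ci(hit, length(tk), confidence)
  structure(list(n_expected = length(tk), n_called = hit,
                 sensitivity = hit / length(tk),
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"])),
            class = "sensitivity_report")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p under the "probability mass" rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (the
#' usual convention; two-sided definitions differ between tools, so the
#' rule is fixed here and checked against an enumeration oracle in the
#' test suite). An all-zero table returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (sum(table) == 0) return(1.0)
  m <- rowSums(table)
  k <- colSums(table)[1]
  x <- max(0, k - m[2]):min(m[1], k)
  d <- dhyper(x, m[1], m[2], k)
  d_obs <- dhyper(table[1, 1], m[1], m[2], k)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

#' Two-sided Wilcoxon rank-sum test with midranks
#'
#' Ranks the pooled sample with midranks for ties. For small samples
#' (smaller group <= 10 and combined n <= 20) the null distribution of
#' the rank sum is enumerated exactly over all group assignments;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Two identical multisets give p = 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact
#'   enumeration; `NULL` (default) selects by sample size as above.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) > 0, length(y) > 0)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1.0)
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); n <- nx + ny
  w <- sum(r[seq_len(nx)])
  if (is.null(exact)) exact <- min(nx, ny) <= 10 && n <= 20
  if (exact) {
    if (n > 24) stop("exact enumeration not feasible for combined n > 24")
    idx <- utils::combn(n, nx)
    sums <- colSums(matrix(r[idx], nrow = nx))
    p_lo <- mean(sums <= w + 1e-9)
    p_hi <- mean(sums >= w - 1e-9)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Carrier burden of qualifying variants in a population
#'
#' Counts individuals carrying at least one allele of a qualifying
#' variant (those surviving the population-mode cascade), per-gene
#' variant tallies, and homozygous carriers. Optionally restricted to a
#' gene subset (e.g. the familial-HLH genes PRF1, UNC13D, STX11,
#' STXBP2).
#'
#' @param genotypes Integer matrix individuals x variant ids (alt
#'   allele counts 0/1/2), as from [simulate_population()].
#' @param sites Site tibble with `variant_id` and `gene`.
#' @param qualifying Character vector of qualifying `variant_id`s.
#' @param gene_subset Optional character vector of genes to restrict to.
#' @return List of class `burden_report`: `n_individuals`, `n_carriers`,
#'   `carrier_fraction`, `n_homozygous_carriers`, `per_gene` (tibble of
#'   qualifying-variant and carrier counts per gene).
#' @export
carrier_burden <- function(genotypes, sites, qualifying,
                           gene_subset = NULL) {
  missing_ids <- setdiff(qualifying, colnames(genotypes))
  if (length(missing_ids) > 0) {
    stop("qualifying variant(s) absent from genotype table: ",
         paste(head(missing_ids, 3), collapse = ", "))
  }
  keep <- qualifying
  if (!is.null(gene_subset)) {
    keep <- intersect(keep, sites$variant_id[sites$gene %in% gene_subset])
  }
  g <- genotypes[, keep, drop = FALSE]
  n_ind <- nrow(genotypes)
  carriers <- rowSums(g > 0) > 0
  hom <- rowSums(g == 2) > 0
  site_sub <- sites[sites$variant_id %in% keep, ]
  per_gene <- dplyr::count(site_sub, .data$gene, name = "n_variants")
  per_gene$n_carriers <- vapply(per_gene$gene, function(gg) {
    ids <- site_sub$variant_id[site_sub$gene == gg]
    sum(rowSums(g[, ids, drop = FALSE] > 0) > 0)
  }, integer(1))
  structure(list(n_individuals = n_ind,
                 n_carriers = sum(carriers),
                 carrier_fraction = if (n_ind > 0) mean(carriers) else 0,
                 n_homozygous_carriers = sum(hom),
                 per_gene = per_gene),
            class = "burden_report")
}

#' Compare carrier counts between a cohort and a population
#'
#' One 2x2 Fisher test per row (carrier / non-carrier x group). Raw
#' p-values are reported together with a Bonferroni-adjusted column.
#'
#' @param counts Tibble with columns `label`, `cohort_carriers`,
#'   `cohort_n`, `pop_carriers`, `pop_n`.
#' @return Input with `p` and `p_bonferroni` columns appended.
#' @export
compare_burden <- function(counts) {
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$cohort_carriers[i],
                    counts$cohort_n[i] - counts$cohort_carriers[i],
                    counts$pop_carriers[i],
                    counts$pop_n[i] - counts$pop_carriers[i]),
                  nrow = 2, byrow = TRUE)
    fisher_2x2(tab)
  }, double(1))
  counts$p <- p
  counts$p_bonferroni <- p.adjust(p, method = "bonferroni")
  counts
}
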