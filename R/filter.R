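#' Filter cascade configuration
#'
#' @param maf_threshold Variants with reference-population minor allele
#'   frequency at or above this are removed (strict `<`, default 0.05).
#' @param impact_consequences Consequence terms regarded as having a
#'   possible impact at the protein (or splicing) level.
#' @param hwe_alpha Significance level for the exact Hardy-Weinberg
#'   deviation filter (population mode only).
#' @param apply_hwe Whether the HWE step runs (population mode).
#' @param regulatory_allowlist Character vector of `variant_id`s (or
#'   HGVS c. strings) of known regulatory mutations that the
#'   consequence filter must keep even though a consequence-based rule
#'   would drop them (deep-intronic regulatory alleles).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.05,
                          impact_consequences = c(
                            "missense", "stop_gained", "stop_lost",
                            "start_lost", "frameshift", "inframe_indel",
                            "splice_donor", "splice_acceptor", "splice_region"),
                          hwe_alpha = 0.05,
                          apply_hwe = TRUE,
                          regulatory_allowlist = character()) {
  stopifnot(maf_threshold > 0, maf_threshold < 1,
            length(impact_consequences) > 0,
            hwe_alpha > 0, hwe_alpha < 1)
  structure(list(maf_threshold = maf_threshold,
                 impact_consequences = impact_consequences,
                 hwe_alpha = hwe_alpha, apply_hwe = apply_hwe,
                 regulatory_allowlist = regulatory_allowlist),
            class = "filter_config")
}

# loss-of-function consequences bypass the in-silico damaging filter:
# SIFT/PolyPhen-2 score only missense changes, so nonsense, frameshift
# and canonical splice variants would otherwise all be discarded
.lof_consequences <- c("stop_gained", "stop_lost", "start_lost",
                       "frameshift", "splice_donor", "splice_acceptor")

.trace_step <- function(trace, step, n_in, variants) {
  bd <- table(variants$consequence)
  tibble::add_row(trace, step = step, n_in = n_in, n_out = nrow(variants),
                  by_consequence = list(bd))
}

.empty_trace <- function() {
  tibble::tibble(step = character(), n_in = integer(), n_out = integer(),
                 by_consequence = list())
}

#' Consequence (impact) filter
#'
#' Retains variants with a possible impact at the protein or splicing
#' level; drops synonymous, non-splice intronic, UTR and regulatory-only
#' annotations (unless on the regulatory allow-list). Unknown terms are
#' retained and flagged (`consequence_flag`), conservatively.
#'
#' @param variants Variant tibble (see [read_variants_tsv()]).
#' @param config A [filter_config()].
#' @return Surviving variants.
#' @export
consequence_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  known <- variants$consequence %in% consequence_vocabulary()
  if (any(!known)) {
    warning(sum(!known), " variant(s) with unrecognised consequence ",
            "term retained and flagged")
  }
  allow <- variants$variant_id %in% config$regulatory_allowlist |
    (!is.na(variants$hgvs_c) & variants$hgvs_c %in% config$regulatory_allowlist)
  keep <- (variants$consequence %in% config$impact_consequences) | !known | allow
  out <- variants[keep, ]
  out$consequence_flag <- !(out$consequence %in% consequence_vocabulary())
  out
}

#' Minor-allele-frequency filter
#'
#' Retains variants with `maf` strictly below the threshold. A missing
#' MAF means the variant is absent from the reference population and is
#' treated as 0 (retained) — rare-variant semantics.
#'
#' @inheritParams consequence_filter
#' @return Surviving variants.
#' @export
maf_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  maf <- ifelse(is.na(variants$maf), 0, variants$maf)
  variants[maf < config$maf_threshold, ]
}

#' In-silico damaging filter
#'
#' Retains variants predicted damaging by either tool: SIFT
#' `deleterious` or PolyPhen-2 `probably_damaging`/`possibly_damaging`.
#' Loss-of-function consequences (nonsense, frameshift, canonical
#' splice) always pass, since the predictors only score missense
#' changes. Missense variants with both predictions missing are dropped
#' in population mode and retained with `prediction_flag = TRUE` in
#' patient mode (a patient variant is kept for manual review).
#'
#' @inheritParams consequence_filter
#' @param mode `"patient"` or `"population"`.
#' @return Surviving variants.
#' @export
damaging_filter <- function(variants, config = filter_config(),
                            mode = c("patient", "population")) {
  mode <- match.arg(mode)
  if (nrow(variants) == 0) return(variants)
  sift_dam <- !is.na(variants$sift_pred) & variants$sift_pred == "deleterious"
  poly_dam <- !is.na(variants$polyphen_pred) &
    variants$polyphen_pred %in% c("probably_damaging", "possibly_damaging")
  both_missing <- is.na(variants$sift_pred) & is.na(variants$polyphen_pred)
  lof <- variants$consequence %in% .lof_consequences
  keep <- sift_dam | poly_dam | lof
  flag <- rep(FALSE, nrow(variants))
  if (mode == "patient") {
    keep <- keep | both_missing
    flag <- both_missing & !lof
  }
  out <- variants[keep, ]
  out$prediction_flag <- flag[keep]
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, enumerate
#' every compatible heterozygote count, compute its probability under
#' the conditional null distribution, and sum the probabilities of all
#' configurations no more probable than the observed one. Monomorphic
#' sites return p = 1 by convention. Symmetric under allele relabeling.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors recycle together).
#' @return Vector of exact p-values.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- cbind(n_AA, n_Aa, n_aa)
  if (any(n < 0)) stop("negative genotype count")
  if (any(rowSums(n) == 0)) stop("empty genotype table")
  apply(n, 1, function(x) .hwe_exact_one(x[1], x[2], x[3]))
}

.hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa           # minor-allele count (either allele works)
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1.0)
  # heterozygote counts share the parity of the minor-allele count
  h <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(h | n, n_a) = log n! - log prod(genotype counts!) + h log 2
  #                     - log C(2n, n_a)  (normalized over h below)
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  lp <- lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) -
    lgamma(hom_maj + 1) + h * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg deviation filter (population mode)
#'
#' Removes variants whose genotype counts deviate from Hardy-Weinberg
#' equilibrium at the configured significance level — a variant-quality
#' filter: in a large outbred cohort, gross HWE departure at a rare
#' site usually signals a genotyping artifact.
#'
#' @param variants Variant tibble carrying `n_AA`, `n_Aa`, `n_aa`.
#' @param config A [filter_config()].
#' @return Surviving variants with an `hwe_p` column appended.
#' @export
hwe_filter <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) { variants$hwe_p <- double(0); return(variants) }
  stopifnot(all(c("n_AA", "n_Aa", "n_aa") %in% names(variants)))
  variants$hwe_p <- hwe_exact_p(variants$n_AA, variants$n_Aa, variants$n_aa)
  variants[variants$hwe_p >= config$hwe_alpha, ]
}

#' Run the full filter cascade
#'
#' Applies, in fixed order: consequence (impact) filter, MAF filter,
#' exact HWE filter (population mode only), then the in-silico damaging
#' filter with the mode-specific missing-prediction rule. A
#' `FilterTrace` records input/output counts and the per-consequence
#' breakdown at every step.
#'
#' @param variants Variant tibble; population mode requires genotype
#'   count columns `n_AA`, `n_Aa`, `n_aa`.
#' @param config A [filter_config()].
#' @param mode `"patient"` or `"population"`.
#' @return List with `survivors` and `trace` (tibble: `step`, `n_in`,
#'   `n_out`, `by_consequence` list-column).
#' @export
run_cascade <- function(variants, config = filter_config(),
                        mode = c("patient", "population")) {
  mode <- match.arg(mode)
  trace <- .empty_trace()

  n0 <- nrow(variants)
  v <- consequence_filter(variants, config)
  trace <- .trace_step(trace, "consequence", n0, v)

  n1 <- nrow(v)
  v <- maf_filter(v, config)
  trace <- .trace_step(trace, "maf", n1, v)

  if (mode == "population" && isTRUE(config$apply_hwe)) {
    n2 <- nrow(v)
    v <- hwe_filter(v, config)
    trace <- .trace_step(trace, "hwe", n2, v)
  }

  n3 <- nrow(v)
  v <- damaging_filter(v, config, mode)
  trace <- .trace_step(trace, "damaging", n3, v)

  list(survivors = v, trace = trace)
}
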