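# Shared fixtures and independent oracles, built in code at test time.

# small 3-gene panel for fast coverage/CNV tests
small_panel <- function() {
  genes <- hlh_panel_genes()
  genes[genes$gene %in% c("PRF1", "STX11", "XIAP"), ]
}

small_amplicons <- function() default_amplicons(small_panel())

# hand-built coverage matrix with dimnames
cov_matrix <- function(values, samples, amplicon_ids) {
  m <- matrix(values, nrow = length(samples), byrow = TRUE,
              dimnames = list(samples, amplicon_ids))
  m
}

# independent exact-HWE oracle: enumerate every individual-level
# genotype vector (0/1/2 per individual), weight each by 2^(#het)
# (the number of allele arrangements producing it), condition on the
# observed alt-allele count, and sum the masses of het counts whose
# conditional probability does not exceed the observed one.
# Feasible for n <= 6 individuals.
hwe_oracle_small <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(n <= 6)
  n_alt <- 2 * n_aa + n_Aa
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  keep <- rowSums(grid) == n_alt
  grid <- grid[keep, , drop = FALSE]
  w <- 2^rowSums(grid == 1)
  het <- rowSums(grid == 1)
  mass <- tapply(w, het, sum)
  mass <- mass / sum(mass)
  obs <- mass[as.character(n_Aa)]
  sum(mass[mass <= obs + 1e-12])
}

# exact-HWE oracle via the closed-form conditional distribution,
# computed with exact choose()/factorial arithmetic (independent of
# the lgamma path in the implementation); n <= 20 individuals.
hwe_oracle_choose <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  if (n_a == 0) return(1.0)
  h <- seq(n_a %% 2, n_a, by = 2)
  prob <- vapply(h, function(hh) {
    hmin <- (n_a - hh) / 2
    hmaj <- n - hh - hmin
    factorial(n) / (factorial(hmin) * factorial(hh) * factorial(hmaj)) *
      2^hh / choose(2 * n, n_a)
  }, double(1))
  obs <- prob[match(n_Aa, h)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# Fisher 2x2 oracle: enumerate all tables with the observed margins,
# probabilities from products of binomial coefficients.
fisher_oracle <- function(tab) {
  r <- rowSums(tab); k <- colSums(tab)[1]
  x <- max(0, k - r[2]):min(r[1], k)
  prob <- choose(r[1], x) * choose(r[2], k - x) / choose(sum(r), k)
  obs <- prob[x == tab[1, 1]]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# variant tibble builder for filter/diagnosis tests
mk_variants <- function(...) {
  df <- tibble::tribble(...)
  defaults <- list(hgvs_c = NA_character_, hgvs_p = NA_character_,
                   maf = NA_real_, sift_pred = NA_character_,
                   polyphen_pred = NA_character_, cadd = NA_real_)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df$variant_id <- paste(df$chromosome, df$position, df$ref, df$alt, sep = ":")
  df
}
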