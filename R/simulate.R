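#' Configuration for the synthetic coverage generator
#'
#' Depths are drawn as negative-binomial counts with mean
#' `depth_mean * amplicon_factor * sample_factor`, where the two factors
#' are log-normal with the given log-scale SDs (amplicon efficiency and
#' library size). `depth_dispersion` is the NB overdispersion
#' (variance = mu + dispersion * mu^2); 0 gives the Poisson limit.
#' `n_failed_amplicons` amplicons are forced to a low mean
#' (`failed_depth_mean`, <= 10) in every sample, emulating assay
#' dropouts. `deletions` plants homozygous/hemizygous exonic deletions:
#' a tibble with columns `sample_id`, `gene`, `first_amplicon` (index
#' within the gene, 1-based), `n_amplicons`, `zygosity` (`hom`/`hemi`);
#' deleted cells are drawn with mean `deletion_residual_mean`
#' (mispriming background, default 1 read).
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_samples Number of samples.
#' @param depth_mean Grand mean read depth.
#' @param depth_dispersion NB dispersion (>= 0).
#' @param amplicon_efficiency_sd,sample_factor_sd Log-scale SDs.
#' @param n_failed_amplicons Number of planted failed amplicons.
#' @param failed_depth_mean Mean depth of failed amplicons (<= 10).
#' @param deletion_residual_mean Residual mean depth in deleted cells.
#' @param deletions Deletion spec tibble (see above), or `NULL`.
#' @param failed_amplicon_ids Optional explicit designation of the
#'   failed amplicons (overrides `n_failed_amplicons`); designating an
#'   amplicon inside a planted deletion run is a config error.
#' @return A list of class `coverage_sim_config`.
#' @export
coverage_sim_config <- function(seed = 1L, n_samples = 60L, depth_mean = 200,
                                depth_dispersion = 0.15,
                                amplicon_efficiency_sd = 0.3,
                                sample_factor_sd = 0.25,
                                n_failed_amplicons = 2L,
                                failed_depth_mean = 3,
                                deletion_residual_mean = 1,
                                deletions = NULL,
                                failed_amplicon_ids = NULL) {
  stopifnot(depth_dispersion >= 0, amplicon_efficiency_sd >= 0,
            sample_factor_sd >= 0, n_samples >= 1,
            failed_depth_mean <= 10, deletion_residual_mean >= 0)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 amplicon_efficiency_sd = amplicon_efficiency_sd,
                 sample_factor_sd = sample_factor_sd,
                 n_failed_amplicons = as.integer(n_failed_amplicons),
                 failed_depth_mean = failed_depth_mean,
                 deletion_residual_mean = deletion_residual_mean,
                 deletions = deletions,
                 failed_amplicon_ids = failed_amplicon_ids),
            class = "coverage_sim_config")
}

# NB draw with Poisson limit at dispersion 0
.rdepth <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate an amplicon coverage matrix with known truth
#'
#' @param amplicons Amplicon tibble ([default_amplicons()] shape).
#' @param config A [coverage_sim_config()].
#' @param sample_ids Optional character vector of sample names (length
#'   `n_samples`); defaults to `S001`, `S002`, ...
#' @return List with `matrix` (samples x amplicons mean depth), and
#'   `truth`: `failed` (amplicon ids forced to fail) and `deletions`
#'   (the planted deletion records expanded with amplicon id runs).
#' @export
simulate_coverage <- function(amplicons, config = coverage_sim_config(),
                              sample_ids = NULL) {
  stopifnot(inherits(config, "coverage_sim_config"))
  set.seed(config$seed)
  n_s <- config$n_samples
  n_a <- nrow(amplicons)
  samples <- if (is.null(sample_ids)) sprintf("S%03d", seq_len(n_s))
             else { stopifnot(length(sample_ids) == n_s); sample_ids }

  amp_factor <- exp(rnorm(n_a, 0, config$amplicon_efficiency_sd))
  samp_factor <- exp(rnorm(n_s, 0, config$sample_factor_sd))

  # expand deletion specs to (sample, amplicon index) cells
  del_truth <- NULL
  del_cells <- matrix(FALSE, n_s, n_a)
  del_idx <- integer(0)
  if (!is.null(config$deletions) && nrow(config$deletions) > 0) {
    specs <- config$deletions
    recs <- list()
    for (k in seq_len(nrow(specs))) {
      sp <- specs[k, ]
      gi <- which(amplicons$gene == sp$gene)
      if (length(gi) == 0) stop("deletion spec names unknown gene: ", sp$gene)
      run <- gi[sp$first_amplicon:(sp$first_amplicon + sp$n_amplicons - 1L)]
      if (anyNA(run)) stop("deletion run exceeds amplicons of gene ", sp$gene)
      si <- match(sp$sample_id, samples)
      if (is.na(si)) stop("deletion spec names unknown sample: ", sp$sample_id)
      del_cells[si, run] <- TRUE
      del_idx <- union(del_idx, run)
      recs[[k]] <- tibble::tibble(
        sample_id = sp$sample_id, gene = sp$gene,
        first_amplicon_id = amplicons$amplicon_id[run[1]],
        last_amplicon_id = amplicons$amplicon_id[run[length(run)]],
        n_amplicons = length(run), zygosity = sp$zygosity
      )
    }
    del_truth <- dplyr::bind_rows(recs)
  }

  # failed amplicons: explicit designation errors on overlap with a
  # planted deletion (the truth would be confounded); random placement
  # simply avoids deletion runs
  if (!is.null(config$failed_amplicon_ids)) {
    failed_idx <- match(config$failed_amplicon_ids, amplicons$amplicon_id)
    if (anyNA(failed_idx)) stop("unknown failed amplicon id designated")
    if (any(failed_idx %in% del_idx)) {
      stop("designated failed amplicon overlaps a planted deletion; ",
           "truth would be confounded")
    }
  } else {
    failed_idx <- integer(0)
    if (config$n_failed_amplicons > 0) {
      eligible <- setdiff(seq_len(n_a), del_idx)
      failed_idx <- sort(sample(eligible, config$n_failed_amplicons))
    }
  }

  mu <- outer(samp_factor, amp_factor) * config$depth_mean
  mu[, failed_idx] <- config$failed_depth_mean
  mu[del_cells] <- config$deletion_residual_mean
  depth <- matrix(.rdepth(length(mu), as.vector(mu), config$depth_dispersion),
                  n_s, n_a)
  dimnames(depth) <- list(samples, amplicons$amplicon_id)

  list(matrix = depth,
       truth = list(failed = amplicons$amplicon_id[failed_idx],
                    deletions = del_truth))
}

#' Configuration for the synthetic patient-cohort generator
#'
#' Patients are assigned one of four ground-truth classes with the given
#' fractions: `biallelic` (one homozygous or two heterozygous qualifying
#' variants in a single AR gene), `hemizygous` (one qualifying variant
#' on chrX in a male), `monoallelic_vus` (exactly one damaging-predicted
#' heterozygous variant), `benign_only` (background variation only).
#' Any remainder is `benign_only`. All patients additionally receive
#' common background polymorphisms (MAF >= 0.05, benign predictions)
#' and synonymous variants. Metadata (age bin, sex, consanguinity,
#' albinism, family history, trigger) is sampled from categorical
#' distributions whose defaults mirror a typical prospective HLH cohort
#' (about a third of onsets in infancy, roughly even sex ratio, frequent
#' consanguinity, secondary triggers concentrated among patients without
#' a cytotoxicity-gene defect).
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size.
#' @param fractions Named list of class fractions (must sum to <= 1).
#' @param n_background_mean Mean number of background polymorphisms per
#'   patient (Poisson).
#' @param age_bin_probs Probabilities for bins 0-1, 1-5, 5-12, 12-18, 18+.
#' @param trigger_probs Named probabilities over trigger categories.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed = 1L, n_patients = 58L,
                              fractions = list(biallelic = 0.33,
                                               hemizygous = 0.05,
                                               monoallelic_vus = 0.15,
                                               benign_only = 0.47),
                              n_background_mean = 4,
                              age_bin_probs = c(0.35, 0.21, 0.16, 0.14, 0.14),
                              trigger_probs = c(none = 0.55, EBV = 0.17,
                                                other_infection = 0.10,
                                                malignancy = 0.05,
                                                autoimmune = 0.05,
                                                unknown = 0.08)) {
  fr <- fractions
  for (nm in c("biallelic", "hemizygous", "monoallelic_vus", "benign_only")) {
    if (is.null(fr[[nm]])) fr[[nm]] <- 0
  }
  tot <- fr$biallelic + fr$hemizygous + fr$monoallelic_vus + fr$benign_only
  if (tot > 1 + 1e-9) stop("cohort class fractions sum to more than 1")
  stopifnot(abs(sum(age_bin_probs) - 1) < 1e-6, abs(sum(trigger_probs) - 1) < 1e-6)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 fractions = fr, n_background_mean = n_background_mean,
                 age_bin_probs = age_bin_probs, trigger_probs = trigger_probs),
            class = "cohort_sim_config")
}

# deterministic catalogue of plantable qualifying variants per gene:
# rare (maf ~ 0), damaging or loss-of-function
.pathogenic_pool <- function(genes, amplicons) {
  cons <- c("missense", "stop_gained", "frameshift", "splice_donor",
            "splice_acceptor", "missense")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    amp <- amplicons[amplicons$gene == g$gene, ]
    n <- 6L
    pos <- amp$start[1] + seq_len(n) * 37L  # arbitrary fixed offsets
    cq <- rep_len(cons, n)
    tibble::tibble(
      chromosome = g$chromosome, position = as.integer(pos),
      ref = "C", alt = "T", gene = g$gene, consequence = cq,
      hgvs_c = sprintf("c.%d%s>%s", seq_len(n) * 37L, "C", "T"),
      hgvs_p = NA_character_,
      maf = c(0, 1e-4, 0, 5e-4, 0, 1e-3)[seq_len(n)],
      sift_pred = ifelse(cq == "missense", "deleterious", NA),
      polyphen_pred = ifelse(cq == "missense", "probably_damaging", NA),
      cadd = 28
    )
  })
  pool <- dplyr::bind_rows(out)
  pool$variant_id <- paste(pool$chromosome, pool$position, pool$ref, pool$alt,
                           sep = ":")
  pool
}

# common benign background variants per gene
.benign_pool <- function(genes, amplicons) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    amp <- amplicons[amplicons$gene == g$gene, ]
    n <- 4L
    pos <- amp$start[1] + seq_len(n) * 53L + 11L
    cq <- rep_len(c("missense", "synonymous", "intronic", "UTR"), n)
    tibble::tibble(
      chromosome = g$chromosome, position = as.integer(pos),
      ref = "G", alt = "A", gene = g$gene, consequence = cq,
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      maf = c(0.12, 0.31, 0.22, 0.08)[seq_len(n)],
      sift_pred = ifelse(cq == "missense", "tolerated", NA),
      polyphen_pred = ifelse(cq == "missense", "benign", NA),
      cadd = 2
    )
  })
  pool <- dplyr::bind_rows(out)
  pool$variant_id <- paste(pool$chromosome, pool$position, pool$ref, pool$alt,
                           sep = ":")
  pool
}

#' Simulate a patient cohort with planted diagnostic genotypes
#'
#' @param genes Panel gene tibble.
#' @param amplicons Amplicon tibble (positions anchor synthetic variants).
#' @param config A [cohort_sim_config()].
#' @return List with `variants`, `genotypes`, `patients` and `truth`
#'   (tibble `patient_id`, `class`, `gene`: the planted ground truth).
#' @export
simulate_cohort <- function(genes, amplicons = default_amplicons(genes),
                            config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_patients
  fr <- config$fractions
  n_bi <- round(n * fr$biallelic)
  n_hemi <- round(n * fr$hemizygous)
  n_vus <- round(n * fr$monoallelic_vus)
  if (n_bi + n_hemi + n_vus > n) stop("class counts exceed cohort size")
  classes <- c(rep("biallelic", n_bi), rep("hemizygous", n_hemi),
               rep("monoallelic_vus", n_vus),
               rep("benign_only", n - n_bi - n_hemi - n_vus))

  ids <- sprintf("PT%03d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[classes == "hemizygous"] <- "M"
  if (n_hemi > 0 && !any(sex == "M")) {
    stop("hemizygous genotypes requested in an all-female cohort")
  }
  bins <- c("0-1", "1-5", "5-12", "12-18", "18+")
  bin_lo <- c(0, 1, 5, 12, 18); bin_hi <- c(1, 5, 12, 18, 70)
  bin_idx <- sample.int(5L, n, replace = TRUE, prob = config$age_bin_probs)
  age <- runif(n, bin_lo[bin_idx], bin_hi[bin_idx])

  patients <- tibble::tibble(
    patient_id = ids, age_at_diagnosis = round(age, 2),
    age_bin = bins[bin_idx], sex = sex,
    consanguinity = sample(c("yes", "no", "unknown"), n, TRUE, c(0.4, 0.5, 0.1)),
    albinism = sample(c("yes", "no"), n, TRUE, c(0.12, 0.88)),
    family_history = sample(c("yes", "no", "unknown"), n, TRUE, c(0.15, 0.75, 0.10)),
    trigger = sample(names(config$trigger_probs), n, TRUE, config$trigger_probs)
  )

  path_pool <- .pathogenic_pool(genes, amplicons)
  ben_pool <- .benign_pool(genes, amplicons)
  ar_genes <- genes$gene[genes$inheritance == "AR"]
  xl_genes <- genes$gene[genes$inheritance == "XL"]

  geno <- list()
  truth_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls == "biallelic") {
      g <- sample(ar_genes, 1)
      truth_gene[i] <- g
      vars_g <- path_pool[path_pool$gene == g, ]
      if (runif(1) < 0.5) {
        v <- vars_g[sample.int(nrow(vars_g), 1), ]
        geno[[length(geno) + 1L]] <- tibble::tibble(
          sample_id = ids[i], variant_id = v$variant_id, zygosity = "hom")
      } else {
        v <- vars_g[sample.int(nrow(vars_g), 2), ]
        geno[[length(geno) + 1L]] <- tibble::tibble(
          sample_id = ids[i], variant_id = v$variant_id, zygosity = "het")
      }
    } else if (cls == "hemizygous") {
      g <- sample(xl_genes, 1)
      truth_gene[i] <- g
      vars_g <- path_pool[path_pool$gene == g, ]
      v <- vars_g[sample.int(nrow(vars_g), 1), ]
      geno[[length(geno) + 1L]] <- tibble::tibble(
        sample_id = ids[i], variant_id = v$variant_id, zygosity = "hemi")
    } else if (cls == "monoallelic_vus") {
      g <- sample(ar_genes, 1)
      truth_gene[i] <- g
      vars_g <- path_pool[path_pool$gene == g & path_pool$consequence == "missense", ]
      v <- vars_g[sample.int(nrow(vars_g), 1), ]
      geno[[length(geno) + 1L]] <- tibble::tibble(
        sample_id = ids[i], variant_id = v$variant_id, zygosity = "het")
    }
    # background polymorphisms for everyone
    n_bg <- rpois(1, config$n_background_mean)
    if (n_bg > 0) {
      bg <- ben_pool[sample.int(nrow(ben_pool), min(n_bg, nrow(ben_pool))), ]
      on_x <- bg$chromosome == "chrX"
      zyg <- ifelse(runif(nrow(bg)) < 0.7, "het", "hom")
      zyg[on_x & sex[i] == "M"] <- "hemi"
      geno[[length(geno) + 1L]] <- tibble::tibble(
        sample_id = ids[i], variant_id = bg$variant_id, zygosity = zyg)
    }
  }
  genotypes <- dplyr::bind_rows(geno)
  used <- unique(genotypes$variant_id)
  variants <- dplyr::bind_rows(path_pool, ben_pool)
  variants <- variants[variants$variant_id %in% used, ]

  list(variants = tibble::as_tibble(variants),
       genotypes = genotypes,
       patients = patients,
       truth = tibble::tibble(patient_id = ids, class = classes,
                              gene = truth_gene))
}

#' Simulate population genotypes at panel sites
#'
#' Each site has a minor allele frequency `maf` and a distortion
#' parameter `f` (an inbreeding-like coefficient): genotype
#' probabilities are `(1-q)^2 + f q(1-q)`, `2q(1-q)(1-f)`,
#' `q^2 + f q(1-q)`. `f = 0` gives exact Hardy-Weinberg proportions;
#' `f = 1` removes all heterozygotes.
#'
#' @param sites Tibble with at least `variant_id`, `maf` and optionally
#'   `distortion` (default 0); extra annotation columns pass through.
#' @param n_individuals Number of diploid individuals.
#' @param seed Integer seed.
#' @return List with `genotypes` (integer matrix individuals x sites of
#'   alt-allele counts 0/1/2) and `sites` (input plus genotype counts
#'   `n_AA`, `n_Aa`, `n_aa`).
#' @export
simulate_population <- function(sites, n_individuals = 2504L, seed = 1L) {
  stopifnot(all(sites$maf > 0), all(sites$maf < 1))
  if (!"distortion" %in% names(sites)) sites$distortion <- 0
  set.seed(seed + 2L)
  n <- as.integer(n_individuals)
  m <- nrow(sites)
  gmat <- matrix(0L, n, m, dimnames = list(sprintf("I%04d", seq_len(n)),
                                           sites$variant_id))
  if (n > 0) {
    for (j in seq_len(m)) {
      q <- sites$maf[j]; f <- sites$distortion[j]
      p_aa <- (1 - q)^2 + f * q * (1 - q)
      p_het <- 2 * q * (1 - q) * (1 - f)
      p_alt <- q^2 + f * q * (1 - q)
      gmat[, j] <- sample(c(0L, 1L, 2L), n, TRUE, prob = c(p_aa, p_het, p_alt))
    }
  }
  sites$n_AA <- unname(colSums(gmat == 0L))
  sites$n_Aa <- unname(colSums(gmat == 1L))
  sites$n_aa <- unname(colSums(gmat == 2L))
  list(genotypes = gmat, sites = tibble::as_tibble(sites))
}
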