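#' Internal consequence vocabulary
#'
#' The filter cascade operates on a fixed controlled vocabulary of
#' consequence terms. Annotation tools emit dialect-specific strings
#' (Sequence Ontology terms, legacy names); [normalize_consequence()]
#' maps the common dialects onto this vocabulary.
#'
#' @return Character vector of recognised consequence terms.
#' @export
consequence_vocabulary <- function() {
  c("missense", "stop_gained", "stop_lost", "start_lost", "frameshift",
    "inframe_indel", "splice_donor", "splice_acceptor", "splice_region",
    "synonymous", "intronic", "UTR", "regulatory")
}

# mapping table from common annotation dialects to the internal enum
.consequence_map <- c(
  missense = "missense", missense_variant = "missense",
  stop_gained = "stop_gained", nonsense = "stop_gained",
  stop_lost = "stop_lost", start_lost = "start_lost",
  frameshift = "frameshift", frameshift_variant = "frameshift",
  inframe_indel = "inframe_indel",
  inframe_insertion = "inframe_indel", inframe_deletion = "inframe_indel",
  splice_donor = "splice_donor", splice_donor_variant = "splice_donor",
  splice_acceptor = "splice_acceptor", splice_acceptor_variant = "splice_acceptor",
  splice_region = "splice_region", splice_region_variant = "splice_region",
  synonymous = "synonymous", synonymous_variant = "synonymous",
  intronic = "intronic", intron_variant = "intronic",
  UTR = "UTR", `5_prime_UTR_variant` = "UTR", `3_prime_UTR_variant` = "UTR",
  utr = "UTR",
  regulatory = "regulatory", regulatory_region_variant = "regulatory",
  upstream_gene_variant = "regulatory", downstream_gene_variant = "regulatory"
)

#' Normalize consequence terms to the internal vocabulary
#'
#' Unrecognised terms are passed through unchanged (the cascade treats
#' them conservatively: retained and flagged).
#'
#' @param x Character vector of consequence terms in any common dialect.
#' @return Character vector in the internal vocabulary where mappable.
#' @export
normalize_consequence <- function(x) {
  mapped <- unname(.consequence_map[x])
  ifelse(is.na(mapped), x, mapped)
}

#' Read annotated variants and genotype calls from a TSV
#'
#' Expected columns: `chromosome`, `position` (1-based), `ref`, `alt`,
#' `gene`, `consequence`, plus per-call `sample_id` and `zygosity`
#' (`het`/`hom`/`hemi`). Optional: `hgvs_c`, `hgvs_p`, `maf`,
#' `sift_pred`, `polyphen_pred`, `cadd`. One row per (variant, sample)
#' call; the unique variant table is derived by collapsing. Rows with a
#' missing consequence are skipped with a warning giving the count.
#'
#' @param path TSV path.
#' @return List with `variants` (one row per unique variant, with a
#'   `variant_id` key `chrom:pos:ref:alt`) and `genotypes` (columns
#'   `sample_id`, `variant_id`, `zygosity`).
#' @export
read_variants_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chromosome", "position", "ref", "alt", "gene", "consequence",
           "sample_id", "zygosity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("variant TSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n_bad <- sum(is.na(df$consequence) | df$consequence == "")
  if (n_bad > 0) {
    warning(n_bad, " record(s) skipped: missing consequence annotation")
    df <- df[!(is.na(df$consequence) | df$consequence == ""), ]
  }
  for (col in c("hgvs_c", "hgvs_p", "sift_pred", "polyphen_pred")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"maf" %in% names(df)) df$maf <- NA_real_
  if (!"cadd" %in% names(df)) df$cadd <- NA_real_
  df$consequence <- normalize_consequence(df$consequence)
  df$variant_id <- paste(df$chromosome, df$position, df$ref, df$alt, sep = ":")
  variants <- dplyr::distinct(
    df, .data$variant_id, .data$chromosome, .data$position, .data$ref,
    .data$alt, .data$gene, .data$consequence, .data$hgvs_c, .data$hgvs_p,
    .data$maf, .data$sift_pred, .data$polyphen_pred, .data$cadd
  )
  if (any(variants$ref == variants$alt)) stop("ref == alt in variant table")
  bad_maf <- !is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1)
  if (any(bad_maf)) stop("maf outside [0, 1]")
  genotypes <- df[, c("sample_id", "variant_id", "zygosity")]
  list(variants = tibble::as_tibble(variants),
       genotypes = tibble::as_tibble(genotypes))
}

#' Write variants + genotypes back to the flat TSV dialect
#'
#' Inverse of [read_variants_tsv()]: one row per genotype call joined to
#' its variant annotation. Deterministic row order (variant_id, sample).
#'
#' @param calls List with `variants` and `genotypes` tibbles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(calls, path) {
  df <- dplyr::inner_join(calls$genotypes, calls$variants, by = "variant_id")
  df <- dplyr::arrange(df, .data$variant_id, .data$sample_id)
  df <- df[, c("chromosome", "position", "ref", "alt", "gene", "consequence",
               "hgvs_c", "hgvs_p", "maf", "sift_pred", "polyphen_pred",
               "cadd", "sample_id", "zygosity")]
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read annotated variants from a VCF
#'
#' Annotations are read from INFO keys `GENE`, `CSQ` (consequence),
#' `MAF`, `SIFT`, `POLYPHEN`, `CADD`. Genotypes come from the GT field;
#' multi-allelic records are split into one variant per ALT allele, and
#' genotype zygosity is assigned per split allele. On chrX, calls in
#' male samples are reported as `hemi` (a haploid GT, or a diploid
#' hom-alt call collapsed to hemizygous); X calls in samples of unknown
#' sex keep their diploid zygosity and are flagged in `x_zygosity_flag`.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sex Optional named character vector, sample id -> `"M"`/`"F"`.
#' @return Same shape as [read_variants_tsv()].
#' @export
read_variants_vcf <- function(path, sex = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  info_get <- function(key) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_get("GENE")
  csq <- info_get("CSQ")
  maf <- suppressWarnings(as.numeric(info_get("MAF")))
  sift <- info_get("SIFT")
  polyphen <- info_get("POLYPHEN")
  cadd <- suppressWarnings(as.numeric(info_get("CADD")))

  rows <- list()
  geno <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    csq_i <- if (is.na(csq[i])) NA else strsplit(csq[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      cq <- if (length(csq_i) >= j) csq_i[j] else csq_i[1]
      if (is.na(cq) || cq == "") { n_skipped <- n_skipped + 1L; next }
      vid <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[j], sep = ":")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variant_id = vid, chromosome = fix$CHROM[i],
        position = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[j],
        gene = gene[i], consequence = normalize_consequence(cq),
        hgvs_c = NA_character_, hgvs_p = NA_character_,
        maf = maf[i], sift_pred = sift[i], polyphen_pred = polyphen[i],
        cadd = cadd[i]
      )
      if (!is.null(dim(gt))) {
        for (s in colnames(gt)) {
          z <- .gt_zygosity(gt[i, s], allele = j, chrom = fix$CHROM[i],
                            sample_sex = if (!is.null(sex)) sex[[s]] else NA)
          if (!is.null(z)) {
            geno[[length(geno) + 1L]] <- tibble::tibble(
              sample_id = s, variant_id = vid, zygosity = z$zygosity,
              x_zygosity_flag = z$flag)
          }
        }
      }
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) skipped: missing consequence annotation")
  }
  variants <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  genotypes <- if (length(geno)) dplyr::bind_rows(geno) else
    tibble::tibble(sample_id = character(), variant_id = character(),
                   zygosity = character(), x_zygosity_flag = logical())
  list(variants = variants, genotypes = genotypes)
}

# zygosity of one GT string w.r.t. a given alt allele index (1-based)
.gt_zygosity <- function(gt, allele, chrom, sample_sex = NA) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  alleles <- strsplit(gt, "[/|]")[[1]]
  n_alt <- sum(alleles == as.character(allele))
  if (n_alt == 0) return(NULL)
  on_x <- chrom %in% c("X", "chrX")
  male <- identical(sample_sex, "M")
  if (length(alleles) == 1L) {
    # haploid call: hemizygous only valid on X in a male
    zyg <- if (on_x && male) "hemi" else "hom"
    return(list(zygosity = zyg, flag = on_x && !male))
  }
  zyg <- if (n_alt == length(alleles)) "hom" else "het"
  flag <- FALSE
  if (on_x) {
    if (male && zyg == "hom") zyg <- "hemi"
    if (!male && !identical(sample_sex, "F")) flag <- TRUE  # unknown sex: keep, flag
  }
  list(zygosity = zyg, flag = flag)
}

#' Read / write a coverage matrix TSV
#'
#' Layout: first column `sample_id`, then one column per amplicon id;
#' cells are mean read depth per (sample, amplicon).
#'
#' @param path TSV path.
#' @return Numeric matrix, rows = samples, columns = amplicons.
#' @export
read_coverage_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative depth in coverage matrix")
  m
}

#' @rdname read_coverage_matrix
#' @param matrix Coverage matrix (samples x amplicons, dimnames set).
#' @export
write_coverage_matrix <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a result table as deterministic TSV plus Markdown
#'
#' Every tabular result of the pipeline (QC summaries, deletion calls,
#' diagnoses, burden reports) is written the same way: a plain TSV and,
#' optionally, a Markdown rendering of the same rows. Identical inputs
#' give byte-identical files.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "tsv") {
    readr::write_tsv(results, path)
  } else {
    cols <- names(results)
    fmt_cell <- function(x) {
      if (is.numeric(x)) formatC(x, format = "g", digits = 10) else as.character(x)
    }
    cells <- vapply(results, fmt_cell, character(nrow(results)))
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(results))
    body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    lines <- c(
      paste0("| ", paste(cols, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
      body
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#' @param path TSV path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
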