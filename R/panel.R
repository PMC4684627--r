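#' The default 12-gene HLH panel
#'
#' Genes in which biallelic (autosomal recessive, AR) or hemizygous
#' (X-linked, XL) mutations cause hemophagocytic lymphohistiocytosis
#' (HLH) or related lymphoproliferative disease. One mutated allele is
#' sufficient for disease only in the XL genes (`SH2D1A`, `XIAP`,
#' `MAGT1`); all other panel genes follow an AR model. `n_amplicons`
#' records the number of PCR amplicons the default synthetic panel
#' geometry assigns to each gene, roughly proportional to coding size.
#'
#' @return A tibble with columns `gene`, `chromosome`, `inheritance`
#'   (`"AR"` or `"XL"`), `disease` (the disease label a causal finding
#'   in that gene receives), `transcript_id` and `n_amplicons`.
#' @examples
#' hlh_panel_genes()
#' @export
hlh_panel_genes <- function() {
  tibble::tribble(
    ~gene,      ~chromosome, ~inheritance, ~disease, ~transcript_id, ~n_amplicons,
    "PRF1",     "chr10", "AR", "FHL2",  "ENST00000373209", 11L,
    "UNC13D",   "chr17", "AR", "FHL3",  "ENST00000207549", 51L,
    "STX11",    "chr6",  "AR", "FHL4",  "ENST00000367568", 28L,
    "STXBP2",   "chr19", "AR", "FHL5",  "ENST00000441779", 25L,
    "SH2D1A",   "chrX",  "XL", "XLP1",  "ENST00000371139", 5L,
    "XIAP",     "chrX",  "XL", "XLP2",  "ENST00000371199", 13L,
    "RAB27A",   "chr15", "AR", "GS2",   "ENST00000396307", 10L,
    "LYST",     "chr1",  "AR", "CHS",   "ENST00000389794", 120L,
    "AP3B1",    "chr5",  "AR", "HPS2",  "ENST00000255194", 50L,
    "BLOC1S6",  "chr15", "AR", "HPS9",  "ENST00000220531", 8L,
    "MAGT1",    "chrX",  "XL", "XMEN",  "ENST00000358075", 18L,
    "ITK",      "chr5",  "AR", "ITKD",  "ENST00000422843", 22L
  )
}

#' Synthetic amplicon geometry for a gene panel
#'
#' Builds a deterministic set of tiled amplicons for each panel gene:
#' consecutive intervals whose lengths cycle through the assay's design
#' range (125-175 bp), placed on the gene's chromosome at arbitrary but
#' fixed loci. Coordinates are 0-based half-open, BED convention.
#'
#' @param genes Panel gene tibble, see [hlh_panel_genes()].
#' @return A tibble of amplicons with columns `amplicon_id`, `gene`,
#'   `chromosome`, `start`, `end`, `length`, in genomic order within
#'   each gene.
#' @export
default_amplicons <- function(genes = hlh_panel_genes()) {
  lengths_cycle <- c(150L, 125L, 160L, 140L, 175L, 135L, 165L, 130L, 155L, 145L)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n <- g$n_amplicons
    len <- rep_len(lengths_cycle, n)
    # fixed per-gene offset keeps genes apart even on a shared chromosome
    origin <- 1e6L + i * 2e6L
    gap <- 10L
    start <- origin + cumsum(c(0L, head(len + gap, -1L)))
    tibble::tibble(
      amplicon_id = sprintf("%s_%03d", g$gene, seq_len(n)),
      gene = g$gene,
      chromosome = g$chromosome,
      start = start,
      end = start + len,
      length = len
    )
  })
  dplyr::bind_rows(out)
}

#' Load a panel from a BED file plus a gene configuration table
#'
#' The BED file (4+ columns, tab separated, 0-based half-open) gives the
#' amplicon intervals; the fourth column must be `<GENE>_<suffix>` or a
#' plain gene symbol identifying the parent gene. The gene configuration
#' is a TSV with columns `gene`, `chromosome`, `inheritance`, `disease`
#' and optionally `transcript_id`, listing every gene the BED refers to.
#'
#' @param bed_path Path to the amplicon BED file.
#' @param gene_config_path Path to the gene configuration TSV.
#' @return A list with elements `genes` and `amplicons` (tibbles in the
#'   same shape as [hlh_panel_genes()] and [default_amplicons()]).
#' @export
load_panel <- function(bed_path, gene_config_path) {
  genes <- readr::read_tsv(gene_config_path, show_col_types = FALSE)
  req <- c("gene", "chromosome", "inheritance", "disease")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene config is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"transcript_id" %in% names(genes)) genes$transcript_id <- NA_character_
  bad_inh <- genes$inheritance[(genes$chromosome == "chrX") != (genes$inheritance == "XL")]
  if (length(bad_inh) > 0) {
    stop("inheritance must be XL exactly for chrX genes in the gene config")
  }

  bed_lines <- readr::read_lines(bed_path)
  bed_lines <- bed_lines[!grepl("^(#|track|browser)", bed_lines) & nzchar(bed_lines)]
  if (length(bed_lines) == 0) {
    amp <- tibble::tibble(
      amplicon_id = character(), gene = character(), chromosome = character(),
      start = integer(), end = integer(), length = integer()
    )
    return(list(genes = genes, amplicons = amp))
  }
  fields <- strsplit(bed_lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop("BED must have at least 4 columns on every line")
  }
  amp <- tibble::tibble(
    chromosome = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    amplicon_id = vapply(fields, `[[`, "", 4L)
  )
  bad <- which(!(amp$end > amp$start))
  if (length(bad) > 0) {
    stop("malformed BED interval (end <= start) on line ", bad[1],
         ": ", bed_lines[bad[1]])
  }
  if (anyDuplicated(amp$amplicon_id)) {
    stop("duplicate amplicon id in BED: ",
         amp$amplicon_id[duplicated(amp$amplicon_id)][1])
  }
  amp$gene <- sub("_[^_]*$", "", amp$amplicon_id)
  unknown <- !(amp$gene %in% genes$gene)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("BED line ", i, " names unknown gene '", amp$gene[i],
         "' (amplicon '", amp$amplicon_id[i], "')")
  }
  amp$length <- amp$end - amp$start
  amp <- amp[, c("amplicon_id", "gene", "chromosome", "start", "end", "length")]
  list(genes = genes, amplicons = amp)
}

#' Write amplicons to BED
#'
#' @param amplicons Amplicon tibble ([default_amplicons()] shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(amplicons, path) {
  df <- amplicons[, c("chromosome", "start", "end", "amplicon_id")]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write a gene configuration TSV
#' @param genes Gene tibble ([hlh_panel_genes()] shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_config <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}
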