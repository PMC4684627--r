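#' Depth display categories
#'
#' Assigns each depth to one of the three display categories used in
#' coverage heatmaps: `<10x` for depths in `[0, 10)`, `10-50x` for
#' `[10, 50]` and `>50x` above 50. Note the display boundary at 10 is
#' exclusive while the failed-amplicon cut-off in [failed_amplicons()]
#' is inclusive (mean <= 10): a depth of exactly 10 displays as
#' `10-50x` yet an amplicon whose mean is 10 counts as failed. Whether
#' 50 belongs to the middle category is a package convention
#' (inclusive); the boundary is documented, not assay-derived.
#'
#' @param depth Numeric vector of non-negative depths.
#' @return Factor with levels `<10x`, `10-50x`, `>50x`.
#' @export
categorize_depth <- function(depth) {
  if (any(depth < 0)) stop("negative depth")
  cut(depth, breaks = c(-Inf, 10, 50, Inf), right = FALSE,
      labels = c("<10x", "10-50x", ">50x")) -> f
  # [10,50] inclusive at 50: cut(right = FALSE) puts 50 in ">50x"; fix
  f[depth == 50] <- "10-50x"
  f
}

#' Failed amplicons by mean-coverage cut-off
#'
#' An amplicon fails when its mean depth across all samples is at or
#' below `cutoff` (inclusive, default 10x).
#'
#' @param matrix Coverage matrix, samples x amplicons.
#' @param amplicons Optional amplicon tibble; when given, the returned
#'   ids are sorted by genomic position, otherwise by column order.
#' @param cutoff Mean-depth cut-off (inclusive).
#' @return Character vector of failed amplicon ids.
#' @export
failed_amplicons <- function(matrix, amplicons = NULL, cutoff = 10) {
  if (length(matrix) == 0) stop("empty coverage matrix")
  mn <- colMeans(matrix)
  ids <- colnames(matrix)[mn <= cutoff]
  if (!is.null(amplicons)) {
    ord <- amplicons[amplicons$amplicon_id %in% ids, ]
    ord <- ord[order(ord$chromosome, ord$start), ]
    ids <- ord$amplicon_id
  }
  ids
}

#' Effective coverage of the initial target
#'
#' The designed panel covers `designed_bp` of the `total_target_bp`
#' regions of interest; amplicons that fail sequencing remove another
#' `failed_bp`. Effective coverage is the bp-weighted fraction of the
#' initial target that remains usable, as a percentage.
#'
#' @param total_target_bp Total bp of the regions of interest.
#' @param designed_bp Target bp covered by designed amplicons.
#' @param failed_bp Designed bp lost to failed amplicons.
#' @return Percentage in `[0, 100]`.
#' @export
effective_coverage <- function(total_target_bp, designed_bp, failed_bp) {
  if (total_target_bp <= 0) stop("total_target_bp must be positive")
  stopifnot(designed_bp <= total_target_bp, failed_bp <= designed_bp,
            failed_bp >= 0)
  100 * (designed_bp - failed_bp) / total_target_bp
}

# union bp of a set of half-open intervals
.union_bp <- function(start, end) {
  if (length(start) == 0) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

#' Per-gene targeted-bp coverage
#'
#' For each gene, the percentage of its targeted bp (union of all its
#' amplicons) that lies in non-failed amplicons. Genes with zero
#' targeted bp are reported with `NA`, not 0. The unweighted mean
#' across genes is attached as attribute `mean_gene_coverage`.
#'
#' @param amplicons Amplicon tibble.
#' @param failed Character vector of failed amplicon ids.
#' @return Tibble `gene`, `targeted_bp`, `covered_bp`, `coverage_pct`.
#' @export
gene_coverage <- function(amplicons, failed = character()) {
  out <- lapply(split(amplicons, amplicons$gene), function(a) {
    tot <- .union_bp(a$start, a$end)
    ok <- a[!(a$amplicon_id %in% failed), ]
    cov <- .union_bp(ok$start, ok$end)
    tibble::tibble(gene = a$gene[1], targeted_bp = tot, covered_bp = cov,
                   coverage_pct = if (tot > 0) 100 * cov / tot else NA_real_)
  })
  res <- dplyr::bind_rows(out)
  res <- res[order(match(res$gene, unique(amplicons$gene))), ]
  attr(res, "mean_gene_coverage") <- mean(res$coverage_pct, na.rm = TRUE)
  res
}

#' Coverage of known mutation sites
#'
#' Percentage of known sites (1-based point positions, e.g. previously
#' reported disease mutations) that fall inside at least one non-failed
#' amplicon. Amplicon intervals are 0-based half-open, so a site whose
#' 0-based coordinate equals an amplicon `end` is outside it. Sites on
#' contigs absent from the panel count as uncovered.
#'
#' @param sites Tibble with `chromosome` and `position` (1-based).
#' @param amplicons Amplicon tibble.
#' @param failed Failed amplicon ids to exclude.
#' @return Percentage of covered sites.
#' @export
site_coverage <- function(sites, amplicons, failed = character()) {
  if (nrow(sites) == 0) stop("no sites supplied")
  ok <- amplicons[!(amplicons$amplicon_id %in% failed), ]
  pos0 <- sites$position - 1L
  covered <- vapply(seq_len(nrow(sites)), function(i) {
    any(ok$chromosome == sites$chromosome[i] &
          ok$start <= pos0[i] & pos0[i] < ok$end)
  }, logical(1))
  off_panel <- !(sites$chromosome %in% amplicons$chromosome)
  if (any(off_panel)) {
    message(sum(off_panel), " site(s) on contigs absent from the panel ",
            "counted as uncovered")
  }
  100 * mean(covered)
}

#' Full coverage QC summary
#'
#' Per-amplicon mean depth and display-category counts, failed
#' amplicons, per-gene coverage and (optionally) known-site coverage.
#'
#' @param matrix Coverage matrix.
#' @param amplicons Amplicon tibble.
#' @param sites Optional known-site tibble for [site_coverage()].
#' @param cutoff Failure cut-off passed to [failed_amplicons()].
#' @return List of class `coverage_summary` with elements
#'   `per_amplicon` (tibble: id, mean depth, category counts), `failed`,
#'   `gene_coverage`, `mean_gene_coverage`, `site_coverage_pct`.
#' @export
coverage_summary <- function(matrix, amplicons, sites = NULL, cutoff = 10) {
  failed <- failed_amplicons(matrix, amplicons, cutoff)
  cats <- apply(matrix, 2, function(d) table(categorize_depth(d)))
  per_amp <- tibble::tibble(
    amplicon_id = colnames(matrix),
    mean_depth = colMeans(matrix),
    n_below_10 = cats["<10x", ],
    n_10_50 = cats["10-50x", ],
    n_above_50 = cats[">50x", ]
  )
  gc <- gene_coverage(amplicons, failed)
  structure(list(
    per_amplicon = per_amp,
    failed = failed,
    gene_coverage = gc,
    mean_gene_coverage = attr(gc, "mean_gene_coverage"),
    site_coverage_pct = if (!is.null(sites)) {
      site_coverage(sites, amplicons, failed)
    } else NA_real_
  ), class = "coverage_summary")
}
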