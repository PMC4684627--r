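#' Median-of-ratios normalization of a coverage matrix
#'
#' Two-step normalization that makes depths comparable across libraries
#' and amplicons: each sample's depths are first divided by that
#' sample's median across amplicons (library-size correction), then
#' each amplicon's library-corrected values are divided by the
#' per-amplicon median across samples (amplicon-efficiency reference).
#' A diploid cell therefore sits near ratio 1 and a homozygous or
#' hemizygous deletion near 0. Medians rather than means keep the
#' reference robust to the failed-amplicon tail and to the deletions
#' themselves.
#'
#' Failed amplicons must be excluded first (they carry no copy-number
#' signal). Samples whose median depth is 0 cannot be normalized and
#' are excluded from calling, reported as uncallable.
#'
#' @param matrix Coverage matrix, samples x amplicons (>= 3 samples).
#' @param failed Amplicon ids to drop before normalizing.
#' @return List with `ratios` (matrix, callable samples only) and
#'   `uncallable` (character vector of excluded sample ids).
#' @export
normalize_coverage <- function(matrix, failed = character()) {
  m <- matrix[, !(colnames(matrix) %in% failed), drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 samples for a stable reference")
  samp_med <- apply(m, 1, median)
  uncallable <- rownames(m)[samp_med == 0]
  m <- m[samp_med > 0, , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 callable samples after excluding ",
                        "zero-median libraries")
  r1 <- m / apply(m, 1, median)
  ref <- apply(r1, 2, median)
  ratios <- sweep(r1, 2, ref, "/")
  ratios[, ref == 0] <- NA_real_
  list(ratios = ratios, uncallable = uncallable)
}

#' Call large homozygous/hemizygous exonic deletions from coverage
#'
#' Scans each sample for maximal runs of at least `min_run` consecutive
#' same-gene amplicons (genomic order) whose normalized ratio falls
#' below `threshold`. Only near-total losses are called: a homozygous
#' deletion leaves ratio near 0 while a heterozygous carrier sits near
#' 0.5, which the default threshold 0.1 deliberately excludes —
#' mispriming background is tolerated, single-copy losses are out of
#' scope. Calls in X-linked genes in male samples are labelled
#' `hemizygous`, all others `homozygous`. Isolated single-amplicon dips
#' are reported separately as unconfirmed possibles, never as calls.
#'
#' @param ratios Normalized ratio matrix from [normalize_coverage()].
#' @param amplicons Amplicon tibble (gives gene and genomic order).
#' @param genes Panel gene tibble (inheritance model for labelling).
#' @param sex Named character vector sample id -> `"M"`/`"F"`.
#' @param threshold Ratio below which an amplicon counts as deleted
#'   (must be < 1).
#' @param min_run Minimum number of consecutive amplicons for a call.
#' @return List with `calls` and `unconfirmed` tibbles (`sample_id`,
#'   `gene`, `first_amplicon_id`, `last_amplicon_id`, `n_amplicons`,
#'   `zygosity`, `mean_ratio`).
#' @export
call_deletions <- function(ratios, amplicons, genes, sex,
                           threshold = 0.1, min_run = 2L) {
  if (threshold >= 1) stop("threshold must be < 1")
  amp <- amplicons[amplicons$amplicon_id %in% colnames(ratios), ]
  amp <- amp[order(match(amp$gene, genes$gene), amp$start), ]
  xl <- genes$gene[genes$inheritance == "XL"]

  calls <- list(); unconf <- list()
  for (s in rownames(ratios)) {
    for (g in unique(amp$gene)) {
      ids <- amp$amplicon_id[amp$gene == g]
      r <- ratios[s, ids]
      low <- !is.na(r) & r < threshold
      rl <- rle(low)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        run <- starts[k]:ends[k]
        zyg <- if (g %in% xl && identical(sex[[s]], "M")) "hemizygous"
               else "homozygous"
        rec <- tibble::tibble(
          sample_id = s, gene = g,
          first_amplicon_id = ids[run[1]],
          last_amplicon_id = ids[run[length(run)]],
          n_amplicons = length(run), zygosity = zyg,
          mean_ratio = mean(r[run])
        )
        if (length(run) >= min_run) {
          calls[[length(calls) + 1L]] <- rec
        } else {
          rec$zygosity <- paste0(rec$zygosity, " (unconfirmed)")
          unconf[[length(unconf) + 1L]] <- rec
        }
      }
    }
  }
  empty <- tibble::tibble(
    sample_id = character(), gene = character(),
    first_amplicon_id = character(), last_amplicon_id = character(),
    n_amplicons = integer(), zygosity = character(), mean_ratio = double()
  )
  list(calls = if (length(calls)) dplyr::bind_rows(calls) else empty,
       unconfirmed = if (length(unconf)) dplyr::bind_rows(unconf) else empty)
}
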