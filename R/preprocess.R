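#' Filter transcripts per subject pair and take the union
#'
#' The single-subject preprocessing rule: within each subject's baseline/case
#' pair, a transcript is flagged for removal when its within-pair mean count
#' falls below the threshold; the retained gene list is the union across pairs
#' of transcripts kept in at least one pair; finally a pseudocount is added to
#' every retained count so later log fold changes are defined.
#'
#' @param matrix Numeric genes x samples count matrix.
#' @param pairs Data frame with columns `subject_id`, `baseline_sample`,
#'   `case_sample`; samples must be columns of `matrix`.
#' @param min_mean Within-pair mean threshold. With `strict = FALSE` a gene is
#'   dropped in a pair when its mean is `<= min_mean` (the real-data rule at 5
#'   counts); with `strict = TRUE` when it is `< min_mean` (the simulation rule
#'   at 30 counts).
#' @param pseudocount Value added to every retained count (default 1).
#' @param strict Use strict inequality for removal (see `min_mean`).
#' @return Filtered, pseudocounted count matrix (same samples, subset of genes).
#' @export
filter_pairs_union <- function(matrix, pairs, min_mean = 5, pseudocount = 1,
                               strict = FALSE) {
  check_pairs(matrix, pairs)
  keep <- rep(FALSE, nrow(matrix))
  for (i in seq_len(nrow(pairs))) {
    m <- (matrix[, pairs$baseline_sample[i]] + matrix[, pairs$case_sample[i]]) / 2
    keep_i <- if (strict) m >= min_mean else m > min_mean
    keep <- keep | keep_i
  }
  if (!any(keep)) stop("no gene survives the pair-mean filter in any pair")
  matrix[keep, , drop = FALSE] + pseudocount
}

#' Retain the most variable transcripts by coefficient of variation
#'
#' Transcripts with a zero count in any sample are removed first, the rest are
#' ranked by coefficient of variation (sd/mean across all samples) in
#' descending order, and the top `ceiling(top_fraction * n)` are kept. This is
#' the cohort-analysis preprocessing used ahead of GLM fits (top 70% by CV).
#'
#' @param matrix Numeric genes x samples count matrix.
#' @param top_fraction Fraction in (0, 1] of zero-free transcripts to keep.
#' @return Filtered count matrix.
#' @export
cv_filter <- function(matrix, top_fraction = 0.7) {
  stopifnot(top_fraction > 0, top_fraction <= 1, nrow(matrix) >= 1)
  zero_free <- rowSums(matrix == 0) == 0
  if (!any(zero_free)) stop("all genes removed by the zero-count rule")
  m <- matrix[zero_free, , drop = FALSE]
  cv <- apply(m, 1, stats::sd) / rowMeans(m)
  n_keep <- ceiling(top_fraction * nrow(m))
  ord <- order(cv, decreasing = TRUE)
  m[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

#' Simulation-mode transcript filtering
#'
#' Reproduces the preprocessing applied to simulated datasets: in `glm` mode,
#' genes with overall mean expression below `min_mean` (strictly) are dropped
#' and a pseudocount added; in `s3` mode the per-pair rule of
#' [filter_pairs_union()] is applied with a strict threshold.
#'
#' @param matrix Numeric genes x samples count matrix.
#' @param pairs Subject pairs (required for `mode = "s3"`).
#' @param mode `"glm"` or `"s3"`.
#' @param min_mean Mean-count threshold (default 30, strict `<`).
#' @param pseudocount Value added to retained counts.
#' @return Filtered, pseudocounted count matrix.
#' @export
sim_filter <- function(matrix, pairs = NULL, mode = c("s3", "glm"),
                       min_mean = 30, pseudocount = 1) {
  mode <- match.arg(mode)
  if (mode == "glm") {
    keep <- rowMeans(matrix) >= min_mean
    if (!any(keep)) stop("no gene survives the mean filter")
    matrix[keep, , drop = FALSE] + pseudocount
  } else {
    filter_pairs_union(matrix, pairs, min_mean = min_mean,
                       pseudocount = pseudocount, strict = TRUE)
  }
}

check_pairs <- function(matrix, pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("subject_id", "baseline_sample", "case_sample") %in%
                  names(pairs)))
  if (anyDuplicated(pairs$subject_id)) stop("duplicate subject_id in pairs")
  if (any(pairs$baseline_sample == pairs$case_sample)) {
    stop("baseline and case sample must differ within a subject")
  }
  missing <- setdiff(c(pairs$baseline_sample, pairs$case_sample),
                     colnames(matrix))
  if (length(missing) > 0L) {
    stop("sample(s) not in count matrix: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
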