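#' Cohort summary of per-subject log odds ratios
#'
#' Averages the per-subject continuity-corrected log odds ratios within a
#' cohort, per gene set: `mean_Q` is the unweighted mean of `Q` over the S
#' subjects and `var_mean_Q = sum(varQ) / S^2` its variance under the normal
#' approximation for each subject's `Q`.
#'
#' @param stats Per-subject stat tibble (rows of [subject_profile()] output
#'   for one cohort), with columns `set_id`, `subject_id`, `Q`, `varQ`.
#' @return Tibble with one row per `set_id`: `mean_Q`, `var_mean_Q`,
#'   `n_subjects`.
#' @export
cohort_summary <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0L) stop("empty per-subject stats")
  stats |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(mean_Q = mean(.data$Q),
                     var_mean_Q = sum(.data$varQ) / dplyr::n()^2,
                     n_subjects = dplyr::n(), .groups = "drop")
}

#' W statistic contrasting two cohort summaries for one gene set
#'
#' `W = (mean_Q_A - mean_Q_B) / sqrt(var_mean_Q_A + var_mean_Q_B)`, which is
#' approximately standard normal when the two cohorts share the same expected
#' log odds ratio; the two-sided p-value is `2 P(Z > |W|)`.
#'
#' @param a,b One-row summaries (from [cohort_summary()]) for the same set.
#' @return Named vector `c(W, p)`.
#' @export
w_statistic <- function(a, b) {
  stopifnot(a$set_id == b$set_id)
  v <- a$var_mean_Q + b$var_mean_Q
  if (!is.finite(v) || v <= 0) stop("non-finite or nonpositive variance")
  W <- (a$mean_Q - b$mean_Q) / sqrt(v)
  c(W = W, p = 2 * stats::pnorm(-abs(W)))
}

#' Cross-cohort comparison of gene-set responsiveness
#'
#' The cross-cohort test: per gene set, cohort means of the per-subject log
#' odds ratios are contrasted with the W statistic, two-sided p-values are
#' Benjamini-Hochberg adjusted across all N sets tested, and then the
#' negative-means rule overwrites the adjusted value with 1.0 for any set
#' whose mean log odds ratio is negative in both cohorts (strictly below
#' zero), so that discoveries are restricted to sets enriched in at least one
#' cohort. Suppression is applied after BH, on the adjusted values; the other
#' q-values are not recomputed.
#'
#' @param stats_a,stats_b Per-subject stat tibbles for cohorts A and B over
#'   the same gene-set collection (see [subject_profile()]).
#' @param fdr_level FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble with one row per set: `set_id`, `mean_Q_A`, `var_mean_Q_A`,
#'   `mean_Q_B`, `var_mean_Q_B`, `W`, `p`, `q`, `suppressed`, `significant`.
#' @export
compare_cohorts <- function(stats_a, stats_b, fdr_level = 0.05) {
  shared <- intersect(unique(stats_a$subject_id), unique(stats_b$subject_id))
  shared <- shared[!is.na(shared)]
  if (length(shared) > 0L) {
    stop("cohorts share subject_id(s): ", paste(shared, collapse = ", "),
         " (cohorts must be independent)")
  }
  sa <- cohort_summary(stats_a)
  sb <- cohort_summary(stats_b)
  if (!setequal(sa$set_id, sb$set_id)) {
    stop("cohorts were scored on different gene-set collections")
  }
  out <- dplyr::inner_join(sa, sb, by = "set_id",
                           suffix = c("_A", "_B")) |>
    dplyr::mutate(
      W = (.data$mean_Q_A - .data$mean_Q_B) /
        sqrt(.data$var_mean_Q_A + .data$var_mean_Q_B),
      p = 2 * stats::pnorm(-abs(.data$W)),
      q = stats::p.adjust(.data$p, method = "BH"),
      suppressed = .data$mean_Q_A < 0 & .data$mean_Q_B < 0,
      q = ifelse(.data$suppressed, 1.0, .data$q),
      significant = .data$q < fdr_level & !.data$suppressed
    )
  out[c("set_id", "mean_Q_A", "var_mean_Q_A", "mean_Q_B", "var_mean_Q_B",
        "W", "p", "q", "suppressed", "significant")]
}
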