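#' TMM normalization factors
#'
#' Per-sample scale factors via the trimmed mean of M-values (30% trim on
#' M-values, 5% on A-values, weighted by asymptotic variances), computed with
#' edgeR. Factors are normalized to a unit geometric mean; multiplying by the
#' library sizes gives effective library sizes.
#'
#' @param matrix Numeric genes x samples count matrix.
#' @param ref_sample Reference sample id, or `NULL` for edgeR's automatic
#'   choice (the sample whose 75th percentile is closest to the mean).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(matrix, ref_sample = NULL) {
  lib <- colSums(matrix)
  if (any(lib <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(matrix)[lib <= 0], collapse = ", "))
  }
  ref <- if (is.null(ref_sample)) NULL else match(ref_sample, colnames(matrix))
  f <- edgeR::calcNormFactors(matrix, method = "TMM", refColumn = ref)
  stats::setNames(f, colnames(matrix))
}

#' log2 counts per million with TMM-effective library sizes
#'
#' @param matrix Count matrix.
#' @param prior_count Offset added before the log (default 0.5).
#' @return log2-CPM matrix.
#' @keywords internal
log_cpm <- function(matrix, prior_count = 0.5) {
  eff <- colSums(matrix) * tmm_factors(matrix)
  log2(t((t(matrix) + prior_count) / (eff + 1)) * 1e6)
}

#' Moderated paired interaction contrast between two cohorts
#'
#' The GLM comparator's interaction design `(A_case - A_baseline) -
#' (B_case - B_baseline)`: counts are TMM-normalized and log2-CPM
#' transformed, each subject is reduced to its within-pair log-ratio (which
#' realizes subject blocking exactly), and the two cohorts' subject-level
#' log-ratios are compared per gene with limma's empirical-Bayes moderated
#' t-statistic, followed by Benjamini-Hochberg adjustment across genes.
#'
#' @param matrix Count matrix covering all samples of both cohorts.
#' @param cohort_a,cohort_b Pair tibbles (`subject_id`, `baseline_sample`,
#'   `case_sample`); at least two subjects per cohort.
#' @return Tibble with one row per gene: `gene`, `log2fc` (A minus B),
#'   `t`, `p`, `q`.
#' @export
paired_interaction_test <- function(matrix, cohort_a, cohort_b) {
  if (nrow(cohort_a) < 2L || nrow(cohort_b) < 2L) {
    stop("design not estimable: need >= 2 subjects per cohort")
  }
  check_pairs(matrix, dplyr::bind_rows(cohort_a, cohort_b))
  lc <- log_cpm(matrix)
  ratios <- cbind(
    lc[, cohort_a$case_sample, drop = FALSE] -
      lc[, cohort_a$baseline_sample, drop = FALSE],
    lc[, cohort_b$case_sample, drop = FALSE] -
      lc[, cohort_b$baseline_sample, drop = FALSE]
  )
  grp <- rep(c(1, 0), c(nrow(cohort_a), nrow(cohort_b)))
  moderated_two_group(ratios, grp)
}

#' Moderated simple contrast on case samples
#'
#' The comparator's simple design `A_case - B_case`: case samples only, no
#' pairing; TMM + log2-CPM then a moderated two-group comparison across
#' samples with BH adjustment.
#'
#' @inheritParams paired_interaction_test
#' @return Tibble as in [paired_interaction_test()].
#' @export
simple_contrast_test <- function(matrix, cohort_a, cohort_b) {
  if (nrow(cohort_a) < 2L || nrow(cohort_b) < 2L) {
    stop("design not estimable: need >= 2 subjects per cohort")
  }
  samples <- c(cohort_a$case_sample, cohort_b$case_sample)
  lc <- log_cpm(matrix[, samples, drop = FALSE])
  grp <- rep(c(1, 0), c(nrow(cohort_a), nrow(cohort_b)))
  moderated_two_group(lc, grp)
}

moderated_two_group <- function(y, grp) {
  design <- cbind(Intercept = 1, groupA = grp)
  fit <- limma::eBayes(limma::lmFit(y, design))
  p <- fit$p.value[, "groupA"]
  tibble::tibble(gene = rownames(y),
                 log2fc = fit$coefficients[, "groupA"],
                 t = fit$t[, "groupA"],
                 p = unname(p),
                 q = stats::p.adjust(p, method = "BH"))
}

#' Gene-set enrichment of GLM interaction DEGs (GLM+EGS)
#'
#' Declares DEGs from a transcript-level comparator result (simulation rule:
#' `q < 0.05`; real-data rule additionally `|log2FC| > lfc_threshold`), then
#' tests each gene set for overrepresentation with the two-sided Fisher exact
#' test over the comparator's gene universe, BH-adjusting across sets. An
#' empty DEG list yields no enriched sets (not an error).
#'
#' @param result Tibble from [paired_interaction_test()].
#' @param sets Gene-set tibble.
#' @param deg_rule `"sim"` (q-only) or `"real"` (q and fold-change gates).
#' @param fdr_level FDR threshold for DEG calling and set enrichment
#'   (default 0.05, strict `<`).
#' @param lfc_threshold Fold-change gate for `deg_rule = "real"`.
#' @return Tibble with one row per set: `set_id`, `g`, `g_not`, `h`, `h_not`,
#'   `fet_p`, `fet_q`, `enriched`, plus `n_degs` as an attribute.
#' @export
glm_egs <- function(result, sets, deg_rule = c("sim", "real"),
                    fdr_level = 0.05, lfc_threshold = log2(1.2)) {
  deg_rule <- match.arg(deg_rule)
  deg <- result$q < fdr_level
  if (deg_rule == "real") deg <- deg & abs(result$log2fc) > lfc_threshold
  degs <- external_deg_call(result$gene, deg)
  out <- subject_profile(degs, sets, fdr_level = fdr_level,
                         subject_id = "glm_egs")
  out <- out[setdiff(names(out), c("subject_id", "Q", "varQ"))]
  attr(out, "n_degs") <- sum(deg)
  out
}
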