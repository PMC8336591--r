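#' Per-subject enrichment profiles for a cohort
#'
#' Runs the single-subject stage for every subject of a cohort over a shared,
#' already preprocessed (pseudocounted) count matrix: per-gene log2 fold
#' change, two-component mixture fit on |log2FC|, DEG calls, and gene-set
#' profiles with Fisher p, BH q and the continuity-corrected log odds ratio.
#'
#' @param matrix Pseudocounted genes x samples count matrix (output of
#'   [filter_pairs_union()] or [sim_filter()]).
#' @param pairs Pair tibble for the cohort (`subject_id`, `baseline_sample`,
#'   `case_sample`).
#' @param sets Gene-set tibble filtered to the matrix's gene universe.
#' @param posterior_threshold,lfc_threshold DEG gates (see [call_degs()]).
#' @param fdr_level Per-subject FDR level for the enriched flag.
#' @return Tibble of stacked [subject_profile()] rows, one block per subject.
#' @export
cohort_profiles <- function(matrix, pairs, sets, posterior_threshold = 0.99,
                            lfc_threshold = NULL, fdr_level = 0.05) {
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    fc <- compute_log2fc(matrix, pairs[i, ])
    fit <- fit_mixture(abs(fc$log2fc))
    degs <- call_degs(fc, fit, posterior_threshold, lfc_threshold)
    subject_profile(degs, sets, fdr_level = fdr_level,
                    subject_id = pairs$subject_id[i])
  })
}

#' Cross-cohort differential gene-set responsiveness, end to end
#'
#' The full pipeline on raw counts: per-pair mean filtering with the union
#' rule and a pseudocount, single-subject mixture-model DEG calling, Fisher
#' enrichment with log odds ratios per subject, and the cross-cohort W test
#' with BH adjustment and the negative-means rule.
#'
#' @param counts Raw genes x samples count matrix covering both cohorts.
#' @param cohort_a,cohort_b Pair tibbles for the two cohorts (disjoint
#'   subjects).
#' @param sets Gene-set tibble; sets are intersected with the post-filter
#'   gene universe and those emptied by the intersection are dropped.
#' @param posterior_threshold,lfc_threshold DEG gates (see [call_degs()]).
#' @param min_mean,strict,pseudocount Pair-mean filter settings (see
#'   [filter_pairs_union()]); real-data analyses use `min_mean = 5,
#'   strict = FALSE`, simulated data `min_mean = 30, strict = TRUE`.
#' @param min_set_size,max_set_size Post-intersection set-size bounds.
#' @param fdr_level FDR level for the comparison (default 0.05).
#' @return The [compare_cohorts()] tibble, with the per-subject profiles of
#'   both cohorts attached as attributes `profiles_a` and `profiles_b`.
#' @export
inter_nof1 <- function(counts, cohort_a, cohort_b, sets,
                       posterior_threshold = 0.99, lfc_threshold = NULL,
                       min_mean = 5, strict = FALSE, pseudocount = 1,
                       min_set_size = 1L, max_set_size = Inf,
                       fdr_level = 0.05) {
  pairs_all <- dplyr::bind_rows(cohort_a, cohort_b)
  mat <- filter_pairs_union(counts, pairs_all, min_mean = min_mean,
                            pseudocount = pseudocount, strict = strict)
  sets_f <- filter_genesets(sets, min_size = min_set_size,
                            max_size = max_set_size,
                            universe = rownames(mat))
  prof_a <- cohort_profiles(mat, cohort_a, sets_f, posterior_threshold,
                            lfc_threshold, fdr_level)
  prof_b <- cohort_profiles(mat, cohort_b, sets_f, posterior_threshold,
                            lfc_threshold, fdr_level)
  out <- compare_cohorts(prof_a, prof_b, fdr_level = fdr_level)
  attr(out, "profiles_a") <- prof_a
  attr(out, "profiles_b") <- prof_b
  out
}

#' GLM+EGS comparator, end to end
#'
#' Comparator pipeline on raw counts: overall mean filter with pseudocount,
#' TMM + log2-CPM, moderated paired interaction contrast between cohorts,
#' DEGs at `q < fdr_level` (plus a fold-change gate in real-data mode), then
#' Fisher enrichment of the gene sets with BH across sets.
#'
#' @inheritParams inter_nof1
#' @param deg_rule `"sim"` or `"real"` (see [glm_egs()]).
#' @param min_mean Overall-mean filter threshold (default 30, strict `<`).
#' @return The [glm_egs()] tibble; the transcript-level result is attached as
#'   attribute `glm_result`.
#' @export
run_glm_egs <- function(counts, cohort_a, cohort_b, sets,
                        deg_rule = "sim", min_mean = 30, pseudocount = 1,
                        fdr_level = 0.05, lfc_threshold = log2(1.2)) {
  mat <- sim_filter(counts, mode = "glm", min_mean = min_mean,
                    pseudocount = pseudocount)
  res <- paired_interaction_test(mat, cohort_a, cohort_b)
  sets_f <- filter_genesets(sets, min_size = 1L, max_size = Inf,
                            universe = res$gene)
  out <- glm_egs(res, sets_f, deg_rule = deg_rule, fdr_level = fdr_level,
                 lfc_threshold = lfc_threshold)
  attr(out, "glm_result") <- res
  out
}
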