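#' Confusion counts over an evaluated set universe
#'
#' @param predicted Character vector of predicted-positive set ids.
#' @param truth Character vector of truly positive set ids.
#' @param universe All evaluated set ids.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted, truth, universe) {
  if (length(setdiff(predicted, universe)) > 0L) {
    stop("predicted set(s) outside universe")
  }
  if (length(setdiff(truth, universe)) > 0L) {
    stop("truth set(s) outside universe")
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(predicted) - tp
  fn <- length(truth) - tp
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 tn = length(universe) - tp - fp - fn)
}

#' Precision and recall with the zero rule
#'
#' When no positive predictions were made (`tp + fp = 0`), both scores are
#' defined as zero in either mode. Otherwise, `traditional` uses `tp/(tp+fp)`
#' and `tp/(tp+fn)`; `adjusted` uses the small-sample adjustment adding 0.5
#' to numerators and 1.0 to denominators, avoiding divisions by zero.
#' Simulated-data accuracy uses the traditional mode; real-cohort analyses
#' use the adjusted mode.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `fn` (see
#'   [confusion()]).
#' @param mode `"traditional"` or `"adjusted"`.
#' @return Named vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts, mode = c("traditional", "adjusted")) {
  mode <- match.arg(mode)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0) return(c(precision = 0, recall = 0))
  if (mode == "traditional") {
    c(precision = tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn))
  } else {
    c(precision = (tp + 0.5) / (tp + fp + 1.0),
      recall = (tp + 0.5) / (tp + fn + 1.0))
  }
}

#' Similarity-matched precision and recall
#'
#' Counts a predicted set as a true positive when it is identical to, or has
#' a pairwise similarity of at least `threshold` with, any reference set (and
#' symmetrically for recall), while the denominators remain all predictions
#' and all reference sets. With the default identity similarity this reduces
#' to exact matching. Intended for semantic similarity scores between
#' ontology terms, supplied as a symmetric matrix with set ids as dimnames.
#'
#' @param predicted,reference Character vectors of set ids.
#' @param similarity Symmetric numeric matrix of pairwise similarities in
#'   \[0, 1\] with dimnames, or `NULL` for identity.
#' @param threshold Match threshold (default 0.70, inclusive).
#' @param mode Passed to [precision_recall()].
#' @return Named vector `c(precision, recall)`.
#' @export
similarity_matched_pr <- function(predicted, reference, similarity = NULL,
                                  threshold = 0.70,
                                  mode = c("traditional", "adjusted")) {
  mode <- match.arg(mode)
  if (length(predicted) == 0L) return(c(precision = 0, recall = 0))
  sim <- function(x, y) {
    if (x == y) return(1)
    if (is.null(similarity)) return(0)
    if (!(x %in% rownames(similarity)) || !(y %in% colnames(similarity))) {
      stop("missing similarity entry for pair (", x, ", ", y, ")")
    }
    similarity[x, y]
  }
  matched_pred <- vapply(predicted, function(x) {
    any(vapply(reference, function(y) sim(x, y) >= threshold, logical(1)))
  }, logical(1))
  matched_ref <- vapply(reference, function(y) {
    any(vapply(predicted, function(x) sim(x, y) >= threshold, logical(1)))
  }, logical(1))
  tp_p <- sum(matched_pred)
  tp_r <- sum(matched_ref)
  if (mode == "traditional") {
    c(precision = tp_p / length(predicted),
      recall = if (length(reference) == 0L) 0 else tp_r / length(reference))
  } else {
    c(precision = (tp_p + 0.5) / (length(predicted) + 1.0),
      recall = (tp_r + 0.5) / (length(reference) + 1.0))
  }
}

#' Random subsamples of two cohorts
#'
#' Draws `n_draws` pairs of sub-cohorts of `s` subjects each, sampled without
#' replacement within each cohort per draw; redundancy across draws is
#' allowed.
#'
#' @param cohort_a,cohort_b Pair tibbles.
#' @param s Sub-cohort size, at most the smaller cohort size.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return List of `n_draws` lists, each with elements `a` and `b`.
#' @export
subsample_cohorts <- function(cohort_a, cohort_b, s, n_draws, seed = 1L) {
  if (s > min(nrow(cohort_a), nrow(cohort_b))) {
    stop("s exceeds a cohort size")
  }
  set.seed(seed)
  lapply(seq_len(n_draws), function(i) {
    list(a = cohort_a[sample(nrow(cohort_a), s), ],
         b = cohort_b[sample(nrow(cohort_b), s), ])
  })
}

#' Benchmark methods across a simulation grid
#'
#' Runs each method end to end on every dataset of the grid, evaluates the
#' predicted positive sets against the ground-truth enriched sets over the
#' four simulated sets (BH at `fdr_level` within each method), and records
#' per-replicate confusion counts plus traditional precision/recall with the
#' zero rule. A method failure on a dataset is recorded as no positive
#' predictions, with a warning.
#'
#' @param grid A `sim_grid` from [generate_grid()].
#' @param methods Subset of `c("inter_mixenrich", "glm_egs", "external")`.
#' @param fdr_level FDR level used by every method (default 0.05).
#' @param posterior_threshold Posterior gate of the mixture-model DEG caller.
#' @param min_mean Simulation-mode mean filter (default 30).
#' @param external_caller For `methods = "external"`: a
#'   `function(dataset, fdr_level)` returning predicted-positive set ids
#'   (plug-in point for alternative single-subject DEG callers).
#' @param verbose Print one line per dataset.
#' @return An `inter_benchmark` tibble: `method`, `cohort_size`,
#'   `prop_coordinated`, `rep`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`.
#' @export
run_benchmark <- function(grid,
                          methods = c("inter_mixenrich", "glm_egs"),
                          fdr_level = 0.05, posterior_threshold = 0.99,
                          min_mean = 30, external_caller = NULL,
                          verbose = FALSE) {
  methods <- match.arg(methods, c("inter_mixenrich", "glm_egs", "external"),
                       several.ok = TRUE)
  manifest <- grid$manifest
  rows <- vector("list", nrow(manifest) * length(methods))
  ri <- 0L
  for (i in seq_len(nrow(manifest))) {
    ds <- grid_dataset(grid, manifest$index[i])
    truth <- ds$truth_sets$set_id[ds$truth_sets$enriched]
    universe <- ds$truth_sets$set_id
    cohort_a <- ds$pairs[ds$pairs$cohort == "A", ]
    cohort_b <- ds$pairs[ds$pairs$cohort == "B", ]
    for (m in methods) {
      predicted <- tryCatch({
        switch(m,
          inter_mixenrich = {
            cmp <- inter_nof1(ds$counts, cohort_a, cohort_b, ds$sets,
                              posterior_threshold = posterior_threshold,
                              lfc_threshold = NULL, min_mean = min_mean,
                              strict = TRUE, fdr_level = fdr_level)
            cmp$set_id[cmp$significant]
          },
          glm_egs = {
            egs <- run_glm_egs(ds$counts, cohort_a, cohort_b, ds$sets,
                               deg_rule = "sim", min_mean = min_mean,
                               fdr_level = fdr_level)
            egs$set_id[egs$enriched]
          },
          external = external_caller(ds, fdr_level)
        )
      }, error = function(e) {
        warning("method ", m, " failed on dataset ", manifest$index[i],
                ": ", conditionMessage(e))
        character(0)
      })
      cc <- confusion(predicted, truth, universe)
      pr <- precision_recall(cc, mode = "traditional")
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        method = m, cohort_size = manifest$cohort_size[i],
        prop_coordinated = manifest$prop_coordinated[i],
        rep = manifest$rep[i], tp = cc$tp, fp = cc$fp, fn = cc$fn,
        tn = cc$tn, precision = pr[["precision"]], recall = pr[["recall"]])
    }
    if (verbose) {
      message(sprintf("dataset %d/%d (S=%d, p=%.2f) done", i,
                      nrow(manifest), manifest$cohort_size[i],
                      manifest$prop_coordinated[i]))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("inter_benchmark", class(out))
  attr(out, "fdr_level") <- fdr_level
  out
}

#' Summarize a benchmark run per method and configuration
#'
#' Reports both per-replicate score summaries (median and quartiles of
#' precision and recall) and the pooled confusion counts across replicates
#' with their pooled precision/recall.
#'
#' @param bench An `inter_benchmark` tibble from [run_benchmark()].
#' @return Tibble with one row per (method, cohort_size, prop_coordinated).
#' @export
summarize_benchmark <- function(bench) {
  bench |>
    dplyr::group_by(.data$method, .data$cohort_size,
                    .data$prop_coordinated) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      precision_median = stats::median(.data$precision),
      precision_q1 = stats::quantile(.data$precision, 0.25, names = FALSE),
      precision_q3 = stats::quantile(.data$precision, 0.75, names = FALSE),
      recall_median = stats::median(.data$recall),
      recall_q1 = stats::quantile(.data$recall, 0.25, names = FALSE),
      recall_q3 = stats::quantile(.data$recall, 0.75, names = FALSE),
      tp = sum(.data$tp), fp = sum(.data$fp),
      fn = sum(.data$fn), tn = sum(.data$tn),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      precision_pooled = ifelse(.data$tp + .data$fp == 0, 0,
                                .data$tp / (.data$tp + .data$fp)),
      recall_pooled = ifelse(.data$tp + .data$fn == 0, 0,
                             .data$tp / (.data$tp + .data$fn))
    )
}
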