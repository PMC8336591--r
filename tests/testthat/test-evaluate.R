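test_that("confusion counts cross-classify predictions against truth", {
  u <- c("A", "B", "C", "D")
  expect_equal(confusion("A", "A", u),
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L, tn = 3L))
  expect_equal(confusion(character(), "A", u)$tp, 0L)
  expect_equal(confusion(character(), "A", u)$fp, 0L)
  expect_equal(confusion(u, character(), u)$fp, 4L)
  expect_error(confusion("Z", "A", u), "outside universe")
  expect_error(confusion("A", "Z", u), "outside universe")
})

test_that("precision/recall formulas and the zero rule", {
  pr <- precision_recall(list(tp = 3, fp = 1, fn = 1), "traditional")
  expect_equal(unname(pr), c(0.75, 0.75))

  adj <- precision_recall(list(tp = 5, fp = 0, fn = 0), "adjusted")
  expect_equal(adj[["precision"]], 5.5 / 6)
  expect_equal(adj[["recall"]], 5.5 / 6)

  # no positive predictions: zero in both modes
  expect_equal(unname(precision_recall(list(tp = 0, fp = 0, fn = 2),
                                       "traditional")), c(0, 0))
  expect_equal(unname(precision_recall(list(tp = 0, fp = 0, fn = 2),
                                       "adjusted")), c(0, 0))
})

test_that("adjusted scores stay strictly inside (0,1) when predictions exist", {
  set.seed(51)
  for (i in 1:30) {
    cc <- list(tp = rpois(1, 2), fp = rpois(1, 2), fn = rpois(1, 2))
    if (cc$tp + cc$fp == 0) next
    pr <- precision_recall(cc, "adjusted")
    expect_true(all(pr > 0 & pr < 1))
  }
})

test_that("similarity matching generalizes exact matching", {
  # identity similarity reduces to exact matching
  pr <- similarity_matched_pr(c("A", "B"), c("A", "C"))
  expect_equal(unname(pr), c(0.5, 0.5))

  sim <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  sim["X", "Y"] <- sim["Y", "X"] <- 0.70
  hit <- similarity_matched_pr("X", "Y", sim, threshold = 0.70)
  expect_equal(unname(hit), c(1, 1))  # 0.70 matches under the >= rule

  sim["X", "Y"] <- sim["Y", "X"] <- 0.69
  miss <- similarity_matched_pr("X", "Y", sim, threshold = 0.70)
  expect_equal(unname(miss), c(0, 0))

  # threshold 1 with identity diagonal is exact matching again
  diag(sim) <- 1
  expect_equal(similarity_matched_pr(c("X", "Y"), c("Y"), sim, threshold = 1),
               similarity_matched_pr(c("X", "Y"), c("Y")))

  expect_error(similarity_matched_pr("X", "Q", sim), "missing similarity")
})

test_that("cohort subsampling draws without replacement, reproducibly", {
  a <- toy_pairs(paste0("a", 1:6), paste0("a", 1:6, "N"), paste0("a", 1:6, "T"))
  b <- toy_pairs(paste0("b", 1:5), paste0("b", 1:5, "N"), paste0("b", 1:5, "T"))
  draws <- subsample_cohorts(a, b, 3, 50, seed = 4)
  expect_length(draws, 50)
  for (d in draws[1:10]) {
    expect_equal(anyDuplicated(d$a$subject_id), 0L)
    expect_equal(nrow(d$b), 3L)
  }
  expect_identical(subsample_cohorts(a, b, 3, 5, seed = 4),
                   subsample_cohorts(a, b, 3, 5, seed = 4))
  full <- subsample_cohorts(a, b, 5, 3, seed = 4)
  expect_setequal(full[[2]]$b$subject_id, b$subject_id)
  expect_error(subsample_cohorts(a, b, 7, 1), "exceeds")
})

test_that("an oracle method scores perfectly and a null grid scores zero", {
  grid <- generate_grid(quick_config(seed = 19L), cohort_sizes = 2L,
                        props = 0.5, reps = 1L)
  oracle <- function(ds, fdr_level) ds$truth_sets$set_id[ds$truth_sets$enriched]
  bench <- run_benchmark(grid, methods = "external", external_caller = oracle)
  expect_equal(bench$precision, 1)
  expect_equal(bench$recall, 1)

  nothing <- function(ds, fdr_level) character(0)
  bench0 <- run_benchmark(grid, methods = "external", external_caller = nothing)
  expect_equal(bench0$precision, 0)
  expect_equal(bench0$recall, 0)
  expect_equal(bench0$tp + bench0$fp, 0L)
})

test_that("a failing method is recorded as no positives with a warning", {
  grid <- generate_grid(quick_config(seed = 21L), cohort_sizes = 2L,
                        props = 0.5, reps = 1L)
  boom <- function(ds, fdr_level) stop("plugin exploded")
  expect_warning(bench <- run_benchmark(grid, methods = "external",
                                        external_caller = boom),
                 "plugin exploded")
  expect_equal(bench$precision, 0)
  expect_equal(bench$recall, 0)
})

test_that("benchmark summaries report per-rep medians, quartiles and pooled counts", {
  bench <- tibble::tibble(
    method = "m", cohort_size = 3, prop_coordinated = 0.5, rep = 1:4,
    tp = c(2, 2, 1, 0), fp = c(0, 0, 1, 0), fn = c(0, 0, 1, 2),
    tn = c(2, 2, 1, 2),
    precision = c(1, 1, 0.5, 0), recall = c(1, 1, 0.5, 0))
  class(bench) <- c("inter_benchmark", class(bench))
  s <- summarize_benchmark(bench)
  expect_equal(s$precision_median, 0.75)
  expect_equal(s$tp, 5)
  expect_equal(s$precision_pooled, 5 / 6)
  expect_equal(s$recall_pooled, 5 / 8)
  p <- ggplot2::autoplot(bench)
  expect_s3_class(p, "ggplot")
})
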