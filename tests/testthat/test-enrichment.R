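test_that("make_table cross-classifies DEG status by set membership", {
  universe <- sprintf("u%03d", 1:100)
  set_genes <- universe[1:10]
  degs <- c(universe[6:10], universe[11:25])  # 5 in set, 15 outside
  expect_equal(make_table(degs, set_genes, universe),
               c(g = 5, g_not = 5, h = 15, h_not = 75))
  expect_equal(make_table(character(), set_genes, universe),
               c(g = 0, g_not = 10, h = 0, h_not = 90))
  expect_equal(make_table(degs, universe, universe),
               c(g = 20, g_not = 80, h = 0, h_not = 0))
  expect_error(make_table(c(degs, "alien"), set_genes, universe), "outside")
  expect_error(make_table(degs, "alien", universe), "empty intersection")
})

test_that("two-sided Fisher p matches hand enumeration on (3,1,1,3)", {
  # margins 4/4, 4 DEGs: P(k) over k = 0..4 is (1,16,36,16,1)/70;
  # observed k = 3 has 16/70, so the two-sided sum is (16+16+1+1)/70
  expect_equal(fisher_two_sided(c(g = 3, g_not = 1, h = 1, h_not = 3)), 34 / 70)
  expect_equal(fisher_two_sided(c(g = 0, g_not = 7, h = 0, h_not = 9)), 1)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(21)
  pick1 <- function(v) v[sample.int(length(v), 1)]
  for (i in 1:400) {
    N <- pick1(4:60)
    m <- pick1(0:N); k <- pick1(0:N)
    g <- pick1(max(0, k - (N - m)):min(k, m))
    tab <- c(g = g, g_not = m - g, h = k - g, h_not = (N - m) - (k - g))
    ft <- stats::fisher.test(matrix(tab[c("g", "h", "g_not", "h_not")], 2))
    expect_equal(fisher_two_sided(tab), ft$p.value, tolerance = 1e-10)
  }
})

test_that("log odds ratio and variance follow the continuity-corrected formulas", {
  expect_equal(log_odds(c(g = 0, g_not = 0, h = 0, h_not = 0)),
               c(Q = 0, varQ = 8))
  lo <- log_odds(c(g = 10, g_not = 90, h = 100, h_not = 800))
  expect_equal(lo[["Q"]], log((10.5 * 800.5) / (100.5 * 90.5)))
  expect_equal(lo[["varQ"]], 1 / 10.5 + 1 / 90.5 + 1 / 100.5 + 1 / 800.5)
  # swapping the DEG and non-DEG columns negates Q and keeps varQ
  sw <- log_odds(c(g = 90, g_not = 10, h = 800, h_not = 100))
  expect_equal(sw[["Q"]], -lo[["Q"]])
  expect_equal(sw[["varQ"]], lo[["varQ"]])
})

test_that("Q and varQ depend only on counts; varQ shrinks as counts grow", {
  set.seed(22)
  for (i in 1:20) {
    tab <- c(g = rpois(1, 5), g_not = rpois(1, 20), h = rpois(1, 50),
             h_not = rpois(1, 500))
    lo <- log_odds(tab)
    expect_gt(lo[["varQ"]], 0)
    for (cell in names(tab)) {
      bumped <- tab; bumped[cell] <- bumped[cell] + 5
      expect_lt(log_odds(bumped)[["varQ"]], lo[["varQ"]])
    }
  }
})

test_that("subject_profile scores all sets with BH across the collection", {
  universe <- sprintf("u%03d", 1:60)
  # 13 DEGs: the "hit" set is saturated, the "miss" set holds its fair share
  degs <- external_deg_call(universe, universe %in% universe[c(1:10, 41:43)])
  sets <- tibble::tibble(set_id = c("hit", "miss"), name = "x",
                         genes = list(universe[1:10], universe[41:55]))
  prof <- subject_profile(degs, sets, fdr_level = 0.05, subject_id = "s1")
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$g[prof$set_id == "hit"], 10)
  expect_true(all(prof$fet_q >= prof$fet_p))
  expect_true(prof$enriched[prof$set_id == "hit"])
  expect_false(prof$enriched[prof$set_id == "miss"])
  expect_error(subject_profile(degs, sets[0, ]), "empty")

  # single set: q equals p
  one <- subject_profile(degs, sets[1, ])
  expect_equal(one$fet_q, one$fet_p)
})

test_that("BH adjustment reproduces the step-up values and ignores order", {
  # hand BH for p = (0.01, 0.02, 0.03, 0.04): all q = 0.04
  universe <- sprintf("u%03d", 1:40)
  degs <- external_deg_call(universe, universe %in% universe[1:8])
  sets <- tibble::tibble(set_id = paste0("s", 1:4), name = "x",
                         genes = list(universe[1:6], universe[3:12],
                                      universe[20:30], universe[31:40]))
  prof <- subject_profile(degs, sets)
  byhand <- {
    o <- order(prof$fet_p)
    q <- prof$fet_p[o] * 4 / seq_len(4)
    q <- rev(cummin(rev(pmin(q, 1))))
    q[order(o)]
  }
  expect_equal(prof$fet_q, byhand)

  shuffled <- subject_profile(degs, sets[c(3, 1, 4, 2), ])
  expect_equal(shuffled$fet_q[match(prof$set_id, shuffled$set_id)],
               prof$fet_q)
})

test_that("with no DEGs every Fisher p is 1 and nothing is enriched", {
  universe <- sprintf("u%03d", 1:50)
  degs <- external_deg_call(universe, rep(FALSE, 50))
  sets <- tibble::tibble(set_id = c("a", "b"), name = "x",
                         genes = list(universe[1:10], universe[11:40]))
  prof <- subject_profile(degs, sets)
  expect_true(all(prof$fet_p == 1))
  expect_false(any(prof$enriched))
  expect_true(all(prof$g == 0 & prof$h == 0))
})
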