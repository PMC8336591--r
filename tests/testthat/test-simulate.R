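test_that("sim_config validates its parameters and round-trips through YAML", {
  cfg <- quick_config(seed = 3L)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(n_genes = 10), "n_genes")
  expect_error(quick_config(prop_coordinated = 1.5), "prop_coordinated")
  expect_error(sim_config(enriched_sets = data.frame(
    set_id = "E", size = 10L, prop_deg = 0.5),
    control_sets = data.frame(set_id = "E", size = 10L)), "distinct")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$gamma_scale, cfg$gamma_scale)
  expect_equal(back$enriched_sets$size, cfg$enriched_sets$size)
  expect_equal(back$seed, cfg$seed)
})

test_that("synthetic baselines are seeded, nonnegative integer counts", {
  cfg <- quick_config(seed = 5L)
  b1 <- synth_baseline(cfg)
  b2 <- synth_baseline(cfg)
  expect_identical(b1, b2)
  expect_true(all(b1$normals >= 0))
  expect_true(all(b1$normals == round(b1$normals)))
  expect_equal(ncol(b1$normals), 2 * cfg$cohort_size)
  expect_equal(nrow(b1$replicate_pairs), cfg$n_replicate_pairs)

  # replicate-pair fold changes are centred at zero by construction
  pool_lfc <- unlist(lapply(seq_len(nrow(b1$replicate_pairs)), function(i) {
    log2(b1$replicates[, b1$replicate_pairs$case_sample[i]] + 1) -
      log2(b1$replicates[, b1$replicate_pairs$baseline_sample[i]] + 1)
  }))
  expect_lt(abs(stats::median(pool_lfc)), 0.05)
})

test_that("the null pool bins by baseline deciles and draws from the right bin", {
  cfg <- quick_config(seed = 6L)
  b <- synth_baseline(cfg)
  pool <- build_null_pool(b$replicates, b$replicate_pairs)
  expect_true(all(lengths(pool$pools) > 0))

  set.seed(1)
  draws <- draw_null_lfc(pool)
  # every drawn value exists in the pool of the gene's own bin
  for (g in sample(names(pool$gene_bin), 50)) {
    bin <- as.character(pool$gene_bin[[g]])
    expect_true(draws[[g]] %in% pool$pools[[bin]])
  }

  # constant replicates give an all-zero pool and zero draws
  const <- matrix(7, nrow = nrow(b$replicates), ncol = 4,
                  dimnames = list(rownames(b$replicates), paste0("r", 1:4)))
  cpool <- build_null_pool(const, toy_pairs(c("p1", "p2"), c("r1", "r3"),
                                            c("r2", "r4")))
  expect_true(all(unlist(cpool$pools) == 0))
  expect_true(all(draw_null_lfc(cpool) == 0))
  expect_error(build_null_pool(const, toy_pairs(character(), character(),
                                                character())), "empty")
})

test_that("DEG fold changes are positive gamma draws with the configured mean", {
  set.seed(7)
  x <- sample_deg_lfc(1e5, 0.55, 6.06)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 0.55 * 6.06) / (0.55 * 6.06), 0.02)
  set.seed(8); a <- sample_deg_lfc(10)
  set.seed(8); b <- sample_deg_lfc(10)
  expect_identical(a, b)
})

test_that("truth assignment seeds the configured DEG counts per subject", {
  genes <- sprintf("g%05d", 1:2000)
  cfg <- sim_config(n_genes = 2000, cohort_size = 5, prop_coordinated = 1,
                    enriched_sets = data.frame(set_id = "E40", size = 40L,
                                               prop_deg = 0.10),
                    control_sets = data.frame(set_id = "C41", size = 41L),
                    seed = 9)
  set.seed(9)
  tr <- assign_truth(cfg, genes)
  # round(0.10 * 40) = 4 DEGs for every subject
  expect_true(all(lengths(tr$subject_degs) == 4L))
  # fully coordinated: identical selections
  expect_length(unique(lapply(tr$subject_degs, sort)), 1L)
  # memberships are disjoint between enriched and control sets
  expect_length(intersect(tr$sets$genes[[1]], tr$sets$genes[[2]]), 0L)

  cfg0 <- cfg; cfg0$prop_coordinated <- 0
  set.seed(10)
  tr0 <- assign_truth(cfg0, genes)
  expect_false(any(tr0$coordinated$coordinated))

  cfg_bad <- cfg
  cfg_bad$enriched_sets$prop_deg <- 0.001
  expect_error(assign_truth(cfg_bad, genes), "rounds to 0")
})

test_that("generated datasets carry coherent truth labels and reproduce exactly", {
  cfg <- quick_config(seed = 11L, cohort_size = 3L)
  ds <- generate_dataset(cfg)
  expect_identical(ds$counts, generate_dataset(cfg)$counts)
  expect_equal(dim(ds$counts), c(cfg$n_genes, 4 * cfg$cohort_size))
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))

  # cohort B is never enriched; cohort A enriched sets are exactly as configured
  expect_setequal(ds$truth_sets$set_id[ds$truth_sets$enriched],
                  cfg$enriched_sets$set_id)
  expect_null(ds$truth_degs[["B01"]])

  # every cohort-A subject holds round(prop * size) truth DEGs inside each set
  for (sid in names(ds$truth_degs)) {
    for (i in seq_len(nrow(cfg$enriched_sets))) {
      members <- ds$sets$genes[[match(cfg$enriched_sets$set_id[i], ds$sets$set_id)]]
      expect_length(intersect(ds$truth_degs[[sid]], members),
                    round(cfg$enriched_sets$prop_deg[i] * cfg$enriched_sets$size[i]))
    }
  }
})

test_that("a zero-enriched configuration yields a global-null dataset", {
  cfg <- sim_config(n_genes = 1200, cohort_size = 2,
                    enriched_sets = data.frame(set_id = character(),
                                               size = integer(),
                                               prop_deg = numeric()),
                    control_sets = data.frame(set_id = c("C50", "C45"),
                                              size = c(50L, 45L)),
                    seed = 13)
  ds <- generate_dataset(cfg)
  expect_false(any(ds$truth_sets$enriched))
  expect_true(all(lengths(ds$truth_degs) == 0L))
})

test_that("the default grid manifest enumerates the full factorial", {
  grid <- generate_grid(quick_config(seed = 15L), reps = 1L)
  expect_equal(nrow(grid$manifest), 15L)  # 5 sizes x 3 proportions

  g1 <- generate_grid(quick_config(seed = 15L), cohort_sizes = c(2L, 3L),
                      props = 0.48, reps = 2L)
  g2 <- generate_grid(quick_config(seed = 15L), cohort_sizes = c(2L, 3L),
                      props = 0.48, reps = 2L)
  expect_identical(g1$manifest, g2$manifest)
  expect_identical(grid_dataset(g1, 2)$counts, grid_dataset(g2, 2)$counts)
  # per-size rep thinning
  g3 <- generate_grid(quick_config(seed = 15L), cohort_sizes = c(2L, 30L),
                      props = 0.48, reps = c(3L, 1L))
  expect_equal(nrow(g3$manifest), 4L)
})

test_that("simulated datasets serialize to plain-text files", {
  ds <- generate_dataset(quick_config(seed = 17L))
  prefix <- file.path(withr::local_tempdir(), "ds")
  files <- write_sim_dataset(ds, prefix)
  expect_true(all(file.exists(files)))
  back <- read_counts(files[["counts"]])
  expect_equal(back, ds$counts)
  expect_equal(read_gmt(files[["gmt"]])$set_id, ds$sets$set_id)
})
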