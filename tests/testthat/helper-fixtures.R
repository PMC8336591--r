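# Shared fixture builders; everything is generated in code at test time.

# small genes x samples matrix with dimnames
toy_counts <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

write_counts_file <- function(df, delimiter = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  path
}

write_gmt_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_pairs <- function(subjects, baseline, case) {
  tibble::tibble(subject_id = subjects, baseline_sample = baseline,
                 case_sample = case)
}

# minimal simulation config for fast end-to-end tests
quick_config <- function(seed = 1L, n_genes = 1200L, cohort_size = 2L,
                         prop_coordinated = 0.5, ...) {
  sim_config(n_genes = n_genes, cohort_size = cohort_size,
             prop_coordinated = prop_coordinated,
             enriched_sets = data.frame(set_id = c("E60", "E40"),
                                        size = c(60L, 40L),
                                        prop_deg = c(0.2, 0.2)),
             control_sets = data.frame(set_id = c("C50", "C45"),
                                       size = c(50L, 45L)),
             seed = seed, ...)
}

# a fake mixture fit with chosen posteriors, for threshold tests
fake_fit <- function(posteriors) {
  structure(list(mix_props = c(0.9, 0.1), means = c(0.1, 3), sds = c(0.1, 1),
                 posteriors = posteriors, loglik_trace = c(-1, 0),
                 converged = TRUE, n_iter = 2L),
            class = "mixenrich_fit")
}
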