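#' Simulation configuration for paired two-cohort count datasets
#'
#' Bundles the six simulation parameters describing two cohorts of paired
#' tumour-normal RNA-seq profiles: cohort size, the expected proportion of
#' cohort-A subjects with coordinated (shared) DEGs, the gamma distribution of
#' positive DEG log2 fold changes, the enriched and control gene-set layouts,
#' and the synthetic baseline-count model. Two enriched sets (sizes 200 and
#' 40, DEG proportion 0.10 each) and two control sets (196 and 41 genes) are
#' seeded by default; cohort B never receives DEGs, setting up the
#' responsive-versus-unresponsive interaction the cross-cohort test looks for.
#'
#' @param n_genes Number of genes in the simulated universe (default 17414).
#' @param cohort_size Subjects per cohort (both cohorts balanced).
#' @param prop_coordinated Probability that a cohort-A subject uses the shared
#'   DEG selection rather than an independent one.
#' @param gamma_shape,gamma_scale Gamma parameters of DEG log2 fold changes
#'   (defaults 0.55 and 6.06).
#' @param enriched_sets Data frame with `set_id`, `size`, `prop_deg`.
#' @param control_sets Data frame with `set_id`, `size`.
#' @param baseline List describing the synthetic normal-count generator:
#'   `meanlog`/`sdlog` of the log-normal gene means and `disp_intercept`/
#'   `disp_slope` of the mean-dependent negative-binomial dispersion
#'   `phi(mu) = disp_intercept + disp_slope / mu`.
#' @param n_replicate_pairs Same-condition replicate pairs used to build the
#'   empirical null fold-change pool (default 7).
#' @param normals Optional user-supplied real normal count matrix; when given,
#'   subject normals are sampled from its columns without replacement.
#' @param replicates Optional user-supplied replicate count matrix (columns
#'   paired consecutively) for the null pool.
#' @param seed Integer seed; every random draw in the simulator flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 17414L,
                       cohort_size = 3L,
                       prop_coordinated = 0.48,
                       gamma_shape = 0.55,
                       gamma_scale = 6.06,
                       enriched_sets = data.frame(
                         set_id = c("SET:E200", "SET:E40"),
                         size = c(200L, 40L),
                         prop_deg = c(0.10, 0.10)),
                       control_sets = data.frame(
                         set_id = c("SET:C196", "SET:C41"),
                         size = c(196L, 41L)),
                       baseline = list(meanlog = log(300), sdlog = 1.6,
                                       disp_intercept = 0.02, disp_slope = 2),
                       n_replicate_pairs = 7L,
                       normals = NULL,
                       replicates = NULL,
                       seed = 1L) {
  stopifnot(n_genes >= 1000, cohort_size >= 1,
            prop_coordinated >= 0, prop_coordinated <= 1,
            gamma_shape > 0, gamma_scale > 0, n_replicate_pairs >= 1,
            all(enriched_sets$prop_deg > 0), all(enriched_sets$prop_deg < 1))
  ids <- c(enriched_sets$set_id, control_sets$set_id)
  if (anyDuplicated(ids)) stop("enriched and control set ids must be distinct")
  structure(list(n_genes = as.integer(n_genes),
                 cohort_size = as.integer(cohort_size),
                 prop_coordinated = prop_coordinated,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 enriched_sets = tibble::as_tibble(enriched_sets),
                 control_sets = tibble::as_tibble(control_sets),
                 baseline = baseline,
                 n_replicate_pairs = as.integer(n_replicate_pairs),
                 normals = normals, replicates = replicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(sim_config)))]
  if (!is.null(args$enriched_sets)) {
    args$enriched_sets <- as.data.frame(do.call(rbind, lapply(args$enriched_sets, as.data.frame)))
  }
  if (!is.null(args$control_sets)) {
    args$control_sets <- as.data.frame(do.call(rbind, lapply(args$control_sets, as.data.frame)))
  }
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  y$normals <- NULL; y$replicates <- NULL
  y$enriched_sets <- lapply(seq_len(nrow(y$enriched_sets)),
                            function(i) as.list(y$enriched_sets[i, ]))
  y$control_sets <- lapply(seq_len(nrow(y$control_sets)),
                           function(i) as.list(y$control_sets[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}

round_half_up <- function(x) floor(x + 0.5)

#' Synthetic baseline (normal-tissue) counts and replicate pairs
#'
#' Draws gene-level mean expression from a log-normal distribution and
#' per-sample counts from a negative binomial with mean-dependent dispersion,
#' emulating a pool of normal-tissue RNA-seq profiles. Also emits
#' same-condition replicate sample pairs from the same generator, from which
#' the empirical null fold-change pool is built. When the configuration
#' carries a real normal matrix, subject normals are drawn from its columns
#' without replacement instead.
#'
#' Sets the RNG from `config$seed`; downstream draws in [generate_dataset()]
#' continue the same stream, so a dataset is fully reproducible from its
#' configuration.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subject normal samples to draw (default twice
#'   the cohort size, one per subject in both cohorts).
#' @return List with `normals` (genes x subjects matrix), `replicates`
#'   (genes x 2*n_replicate_pairs matrix) and `replicate_pairs` (tibble with
#'   `baseline_sample`, `case_sample` column names into `replicates`).
#' @export
synth_baseline <- function(config, n_subjects = 2L * config$cohort_size) {
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  npair <- config$n_replicate_pairs
  rep_names <- sprintf("rep%02d", seq_len(2L * npair))
  if (!is.null(config$normals)) {
    if (ncol(config$normals) < n_subjects) {
      stop("supplied normal matrix has fewer columns than subjects")
    }
    cols <- sample(ncol(config$normals), n_subjects)
    normals <- config$normals[, cols, drop = FALSE]
    if (is.null(config$replicates)) stop("replicates must accompany normals")
    replicates <- config$replicates
    colnames(replicates) <- sprintf("rep%02d", seq_len(ncol(replicates)))
    rep_names <- colnames(replicates)
  } else {
    b <- config$baseline
    mu <- stats::rlnorm(config$n_genes, b$meanlog, b$sdlog)
    phi <- b$disp_intercept + b$disp_slope / mu
    draw <- function(n) {
      matrix(stats::rnbinom(config$n_genes * n, mu = mu, size = 1 / phi),
             nrow = config$n_genes)
    }
    normals <- draw(n_subjects)
    replicates <- draw(2L * npair)
    rownames(normals) <- rownames(replicates) <- genes
    colnames(replicates) <- rep_names
  }
  colnames(normals) <- sprintf("subj%02d", seq_len(ncol(normals)))
  pairs <- tibble::tibble(
    baseline_sample = rep_names[seq(1, length(rep_names), by = 2)],
    case_sample = rep_names[seq(2, length(rep_names), by = 2)]
  )
  list(normals = normals, replicates = replicates, replicate_pairs = pairs)
}

#' Empirical null log2 fold-change pool binned by baseline expression
#'
#' Computes gene-wise log2 fold changes between same-condition replicate
#' pairs, bins genes into deciles of baseline expression (the mean across
#' replicate samples), and merges any decile whose expression range includes
#' zero into a single category. Sampling from the pool returns, for each
#' gene, a fold change drawn (with replacement) from the bin that contains
#' that gene's baseline expression, so the null fold-change spread keeps its
#' dependence on expression level.
#'
#' @param replicates Genes x replicate-samples count matrix.
#' @param replicate_pairs Tibble pairing replicate columns
#'   (`baseline_sample`, `case_sample`).
#' @param pseudocount Added before the log ratio (default 1).
#' @return A `null_fc_pool`: list with `breaks`, `gene_bin` (named integer),
#'   `pools` (list of numeric vectors) and `baseline`.
#' @export
build_null_pool <- function(replicates, replicate_pairs, pseudocount = 1) {
  if (nrow(replicate_pairs) == 0L) stop("empty replicate-pair list")
  baseline <- rowMeans(replicates)
  br <- unique(stats::quantile(baseline, probs = seq(0, 1, 0.1), names = FALSE))
  bin <- findInterval(baseline, br, rightmost.closed = TRUE, all.inside = TRUE)
  # merge every decile whose expression range includes 0 into one category
  lo <- br[-length(br)]
  zero_bins <- which(lo <= 0)
  if (length(zero_bins) > 1L) bin[bin %in% zero_bins] <- zero_bins[1]
  lfc <- unlist(lapply(seq_len(nrow(replicate_pairs)), function(i) {
    log2(replicates[, replicate_pairs$case_sample[i]] + pseudocount) -
      log2(replicates[, replicate_pairs$baseline_sample[i]] + pseudocount)
  }), use.names = FALSE)
  bins_rep <- rep(bin, nrow(replicate_pairs))
  pools <- split(lfc, bins_rep)
  if (any(lengths(pools) == 0L)) stop("empty null fold-change pool bin")
  structure(list(breaks = br, gene_bin = stats::setNames(bin, rownames(replicates)),
                 pools = pools, baseline = baseline),
            class = "null_fc_pool")
}

#' Draw null log2 fold changes for genes from their expression bins
#'
#' @param pool A `null_fc_pool` from [build_null_pool()].
#' @param genes Gene identifiers (default: all genes in the pool).
#' @return Named numeric vector of log2 fold changes.
#' @export
draw_null_lfc <- function(pool, genes = names(pool$gene_bin)) {
  bin <- pool$gene_bin[genes]
  out <- numeric(length(genes))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    p <- pool$pools[[as.character(b)]]
    out[idx] <- p[sample.int(length(p), length(idx), replace = TRUE)]
  }
  stats::setNames(out, genes)
}

#' Gamma-distributed positive DEG log2 fold changes
#'
#' @param n Number of draws.
#' @param gamma_shape,gamma_scale Gamma parameters (defaults 0.55 and 6.06,
#'   as estimated from tumour-normal DEG fold changes).
#' @return Strictly positive numeric vector of length `n`.
#' @export
sample_deg_lfc <- function(n, gamma_shape = 0.55, gamma_scale = 6.06) {
  stopifnot(gamma_shape > 0, gamma_scale > 0)
  stats::rgamma(n, shape = gamma_shape, scale = gamma_scale)
}

#' Assign ground-truth gene-set memberships and per-subject DEG selections
#'
#' Lays the four gene sets (two enriched, two control) over disjoint random
#' gene selections, fixes the per-set DEG count as `round(prop_deg * size)`
#' (half-up), draws one shared DEG selection per enriched set, and flags each
#' cohort-A subject as coordinated with probability `prop_coordinated`
#' (Bernoulli). Coordinated subjects use the shared selections; the rest draw
#' independent selections of the same size. Cohort B subjects and control
#' sets receive no DEGs. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of the simulated gene universe.
#' @return List with `sets` (gene-set tibble with `enriched` flag),
#'   `subject_degs` (named list: cohort-A subject id -> DEG gene vector),
#'   `coordinated` (tibble `subject_id`, `coordinated`).
#' @export
assign_truth <- function(config, genes) {
  es <- config$enriched_sets
  cs <- config$control_sets
  sizes <- c(es$size, cs$size)
  ids <- c(es$set_id, cs$set_id)
  stopifnot(sum(sizes) <= length(genes))
  picked <- sample(genes, sum(sizes))
  members <- split(picked, rep(seq_along(sizes), sizes))
  names(members) <- ids
  deg_counts <- round_half_up(es$prop_deg * es$size)
  if (any(deg_counts < 1)) {
    stop("prop_deg * size rounds to 0 for set(s): ",
         paste(es$set_id[deg_counts < 1], collapse = ", "))
  }
  shared <- lapply(seq_len(nrow(es)), function(i) {
    sample(members[[es$set_id[i]]], deg_counts[i])
  })
  subjects_a <- sprintf("A%02d", seq_len(config$cohort_size))
  coord <- stats::rbinom(config$cohort_size, 1, config$prop_coordinated) == 1
  subject_degs <- lapply(seq_along(subjects_a), function(j) {
    if (coord[j]) {
      unlist(shared, use.names = FALSE)
    } else {
      unlist(lapply(seq_len(nrow(es)), function(i) {
        sample(members[[es$set_id[i]]], deg_counts[i])
      }), use.names = FALSE)
    }
  })
  names(subject_degs) <- subjects_a
  list(
    sets = tibble::tibble(
      set_id = ids,
      name = c(sprintf("enriched size %d", es$size),
               sprintf("control size %d", cs$size)),
      genes = unname(members),
      enriched = c(rep(TRUE, nrow(es)), rep(FALSE, nrow(cs)))
    ),
    subject_degs = subject_degs,
    coordinated = tibble::tibble(subject_id = subjects_a, coordinated = coord)
  )
}

#' Generate one simulated two-cohort paired dataset
#'
#' End-to-end generator: synthetic normal counts for every subject, an
#' empirical null fold-change pool from replicate pairs, ground-truth DEG
#' selections in cohort A's enriched sets, and tumour counts formed as
#' `round(normal * 2^log2FC)` with null-pool fold changes for unaltered genes
#' and positive gamma fold changes for DEGs. Cohort B receives null fold
#' changes everywhere, so none of the four sets is enriched there.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `counts` (genes x 4*S matrix), `pairs`
#'   (tibble `subject_id`, `baseline_sample`, `case_sample`, `cohort`),
#'   `sets` (gene-set tibble), `truth_sets` (tibble `set_id`, `enriched`),
#'   `truth_degs`, `coordinated`, `config`.
#' @export
generate_dataset <- function(config) {
  S <- config$cohort_size
  base <- synth_baseline(config, n_subjects = 2L * S)  # seeds the stream
  genes <- rownames(base$normals)
  pool <- build_null_pool(base$replicates, base$replicate_pairs)
  truth <- assign_truth(config, genes)

  subjects <- c(sprintf("A%02d", seq_len(S)), sprintf("B%02d", seq_len(S)))
  cohorts <- rep(c("A", "B"), each = S)
  counts <- matrix(0, nrow = length(genes), ncol = 2L * length(subjects),
                   dimnames = list(genes, NULL))
  cn <- character(ncol(counts))
  for (j in seq_along(subjects)) {
    normal <- base$normals[, j]
    lfc <- draw_null_lfc(pool)
    degs <- truth$subject_degs[[subjects[j]]]
    if (!is.null(degs) && length(degs) > 0L) {
      lfc[degs] <- sample_deg_lfc(length(degs), config$gamma_shape,
                                  config$gamma_scale)
    }
    tumor <- round_half_up(normal * 2^lfc)
    counts[, 2L * j - 1L] <- normal
    counts[, 2L * j] <- tumor
    cn[2L * j - 1L] <- paste0(subjects[j], "_N")
    cn[2L * j] <- paste0(subjects[j], "_T")
  }
  colnames(counts) <- cn  # integer-valued; stored as double (counts can exceed 2^31)
  pairs <- tibble::tibble(subject_id = subjects,
                          baseline_sample = paste0(subjects, "_N"),
                          case_sample = paste0(subjects, "_T"),
                          cohort = cohorts)
  structure(list(
    counts = counts,
    pairs = pairs,
    sets = truth$sets[c("set_id", "name", "genes")],
    truth_sets = truth$sets[c("set_id", "enriched")],
    truth_degs = truth$subject_degs,
    coordinated = truth$coordinated,
    config = config
  ), class = "sim_dataset")
}

#' Deterministic grid of simulated datasets
#'
#' Enumerates the full factorial of cohort sizes and coordination proportions
#' with a fixed number of replicate datasets per configuration and a
#' deterministic seed schedule derived from the base seed, so the same base
#' seed always yields identical manifests and datasets. The default grid
#' (5 sizes x 3 proportions x 30 reps) enumerates 450 datasets.
#'
#' @param base_config A [sim_config()] providing all non-varied parameters
#'   and the base seed.
#' @param cohort_sizes Cohort sizes to cross (default `c(2, 3, 7, 10, 30)`).
#' @param props Coordination proportions (default `c(0.25, 0.48, 0.75)`).
#' @param reps Replicate datasets per configuration; a scalar, or a vector
#'   parallel to `cohort_sizes` to thin expensive sizes.
#' @return A `sim_grid` list with `manifest` (tibble `index`, `cohort_size`,
#'   `prop_coordinated`, `rep`, `seed`) and `base_config`.
#' @export
generate_grid <- function(base_config = sim_config(),
                          cohort_sizes = c(2L, 3L, 7L, 10L, 30L),
                          props = c(0.25, 0.48, 0.75),
                          reps = 30L) {
  reps <- rep_len(reps, length(cohort_sizes))
  rows <- list()
  cfg_idx <- 0L
  for (ip in seq_along(props)) {
    for (is in seq_along(cohort_sizes)) {
      cfg_idx <- cfg_idx + 1L
      rows[[cfg_idx]] <- tibble::tibble(
        cohort_size = cohort_sizes[is],
        prop_coordinated = props[ip],
        rep = seq_len(reps[is]),
        seed = as.integer((as.numeric(base_config$seed) * 7919 +
                             cfg_idx * 104729 + seq_len(reps[is]) * 331) %%
                            2147483647L) + 1L
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$index <- seq_len(nrow(manifest))
  structure(list(manifest = manifest[c("index", "cohort_size",
                                       "prop_coordinated", "rep", "seed")],
                 base_config = base_config),
            class = "sim_grid")
}

#' Realize one dataset of a simulation grid
#'
#' @param grid A `sim_grid` from [generate_grid()].
#' @param index Row of the manifest to realize.
#' @return A `sim_dataset`.
#' @export
grid_dataset <- function(grid, index) {
  row <- grid$manifest[grid$manifest$index == index, ]
  stopifnot(nrow(row) == 1L)
  cfg <- grid$base_config
  cfg$cohort_size <- as.integer(row$cohort_size)
  cfg$prop_coordinated <- row$prop_coordinated
  cfg$seed <- as.integer(row$seed)
  generate_dataset(cfg)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the counts as TSV, the subject pairs and truth labels as TSV, the
#' four gene sets as GMT and the configuration echo as JSON, under a common
#' file prefix.
#'
#' @param dataset A `sim_dataset`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_sim_dataset <- function(dataset, prefix) {
  files <- c(counts = paste0(prefix, "_counts.tsv"),
             pairs = paste0(prefix, "_pairs.tsv"),
             truth = paste0(prefix, "_truth.tsv"),
             gmt = paste0(prefix, "_sets.gmt"),
             config = paste0(prefix, "_config.json"))
  write_counts(dataset$counts, files[["counts"]])
  utils::write.table(dataset$pairs, files[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth_sets, files[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(dataset$sets, files[["gmt"]])
  cfg <- dataset$config
  cfg$normals <- NULL; cfg$replicates <- NULL
  jsonlite::write_json(unclass(cfg), files[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
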