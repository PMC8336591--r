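#' Per-gene log2 fold change for one subject pair
#'
#' Computes `log2(case) - log2(baseline)` per gene for a single subject's
#' paired samples. The matrix must already be pseudocounted (strictly
#' positive), as guaranteed by the preprocessing functions.
#'
#' @param matrix Strictly positive genes x samples matrix.
#' @param pair One-row data frame (or list) with `baseline_sample` and
#'   `case_sample`.
#' @return Tibble with columns `gene`, `log2fc`.
#' @export
compute_log2fc <- function(matrix, pair) {
  b <- matrix[, pair$baseline_sample[[1]]]
  a <- matrix[, pair$case_sample[[1]]]
  if (any(b <= 0) || any(a <= 0)) {
    stop("nonpositive values: matrix must be pseudocounted before log2fc")
  }
  tibble::tibble(gene = rownames(matrix), log2fc = unname(log2(a) - log2(b)))
}

#' Fit a two-component Gaussian mixture to absolute log2 fold changes
#'
#' The single-subject stage models |log2FC| as a mixture of a low-mean "null"
#' component and a high-mean "differentially expressed" component, fitted by
#' EM. Components are ordinary Gaussians on the absolute-value scale (no
#' folded-normal correction), and are relabeled so means are ascending.
#' Initialization is deterministic: values are split at their 90th percentile
#' and component moments estimated from the two groups, so identical data give
#' identical fits.
#'
#' @param values Nonnegative numeric vector of |log2FC| (length >= 50).
#' @param seed Accepted for interface stability; the fit consumes no
#'   randomness, so it is unused.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood change (default
#'   1e-8).
#' @param sd_floor Lower bound on component standard deviations, preventing
#'   collapse onto single points (default 1e-3).
#' @return An object of class `mixenrich_fit`: a list with `mix_props`,
#'   `means`, `sds`, `posteriors` (per-value probability of the high-mean
#'   component), `loglik_trace`, `converged` and `n_iter`.
#' @export
fit_mixture <- function(values, seed = NULL, max_iter = 500L, tol = 1e-8,
                        sd_floor = 1e-3) {
  stopifnot(is.numeric(values), length(values) >= 50, all(values >= 0))
  if (stats::sd(values) == 0) stop("mixture unidentifiable: all values identical")
  x <- as.numeric(values)
  q90 <- stats::quantile(x, 0.9, names = FALSE)
  hi <- x > q90
  if (!any(hi) || all(hi)) {  # heavy ties at the quantile: split by rank
    hi <- rank(x, ties.method = "first") > 0.9 * length(x)
  }
  mu <- c(mean(x[!hi]), mean(x[hi]))
  sg <- pmax(c(stats::sd(x[!hi]), stats::sd(x[hi])), sd_floor)
  sg[is.na(sg)] <- sd_floor
  w <- c(mean(!hi), mean(hi))

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sg[1], log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sg[2], log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
    r2 <- 1 / (1 + exp(l1 - l2))          # responsibility of component 2
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    w <- pmax(c(n1, n2) / length(x), 1e-12)  # guard against component death
    w <- w / sum(w)
    n1 <- max(n1, 1e-12); n2 <- max(n2, 1e-12)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sg <- pmax(sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                      sum(r2 * (x - mu[2])^2) / n2)), sd_floor)
  }
  # relabel so the null component has the smaller mean
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  l1 <- log(w[1]) + stats::dnorm(x, mu[1], sg[1], log = TRUE)
  l2 <- log(w[2]) + stats::dnorm(x, mu[2], sg[2], log = TRUE)
  post <- 1 / (1 + exp(l1 - l2))
  structure(list(mix_props = w, means = mu, sds = sg, posteriors = post,
                 loglik_trace = trace, converged = converged, n_iter = it),
            class = "mixenrich_fit")
}

#' @export
print.mixenrich_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture on |log2FC|\n")
  cat(sprintf("  null: prop %.3f, mean %.3f, sd %.3f\n",
              x$mix_props[1], x$means[1], x$sds[1]))
  cat(sprintf("  DE:   prop %.3f, mean %.3f, sd %.3f\n",
              x$mix_props[2], x$means[2], x$sds[2]))
  cat(sprintf("  %d iterations, converged: %s\n", x$n_iter, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture fit
#'
#' @param x A `mixenrich_fit`.
#' @param ... Unused.
#' @return Tibble with one row per component: `component`, `mix_prop`,
#'   `mean`, `sd`.
#' @exportS3Method generics::tidy
tidy.mixenrich_fit <- function(x, ...) {
  tibble::tibble(component = c("null", "de"), mix_prop = x$mix_props,
                 mean = x$means, sd = x$sds)
}

#' One-row fit summary
#'
#' @param x A `mixenrich_fit`.
#' @param ... Unused.
#' @return Tibble with `loglik`, `n_iter`, `converged`, `n`.
#' @exportS3Method generics::glance
glance.mixenrich_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik_trace[length(x$loglik_trace)],
                 n_iter = x$n_iter, converged = x$converged,
                 n = length(x$posteriors))
}

#' Call per-subject differentially expressed genes
#'
#' A gene is called DE when its posterior probability of membership in the
#' high-mean mixture component exceeds `posterior_threshold` and, when
#' `lfc_threshold` is set, its |log2FC| exceeds that threshold. Both
#' comparisons are strict. Analyses of real cohorts typically gate at
#' posterior > 0.99 and |log2FC| > log2(1.2); simulated data use the posterior
#' gate alone (`lfc_threshold = NULL`).
#'
#' @param fc Fold-change tibble from [compute_log2fc()].
#' @param fit `mixenrich_fit` computed on `abs(fc$log2fc)`.
#' @param posterior_threshold Posterior gate in \[0, 1\] (default 0.99).
#' @param lfc_threshold Optional |log2FC| gate; `NULL` disables it.
#' @return Tibble with columns `gene`, `abs_log2fc`, `posterior`, `is_deg`.
#' @export
call_degs <- function(fc, fit, posterior_threshold = 0.99,
                      lfc_threshold = NULL) {
  if (posterior_threshold < 0 || posterior_threshold > 1) {
    stop("posterior_threshold must lie in [0, 1]")
  }
  stopifnot(length(fit$posteriors) == nrow(fc))
  abs_lfc <- abs(fc$log2fc)
  deg <- fit$posteriors > posterior_threshold
  if (!is.null(lfc_threshold)) deg <- deg & (abs_lfc > lfc_threshold)
  tibble::tibble(gene = fc$gene, abs_log2fc = abs_lfc,
                 posterior = fit$posteriors, is_deg = deg)
}

#' Wrap an externally produced DEG vector
#'
#' Plug-in point for alternative single-subject DEG callers (e.g. a
#' noise-simulation caller): any boolean DEG vector over the analysis universe
#' can be fed into the enrichment stage in place of the mixture-model calls.
#'
#' @param genes Character vector of gene identifiers (the universe).
#' @param is_deg Logical vector aligned with `genes`.
#' @return Tibble shaped like the output of [call_degs()] (posterior is `NA`).
#' @export
external_deg_call <- function(genes, is_deg) {
  stopifnot(length(genes) == length(is_deg), is.logical(is_deg))
  tibble::tibble(gene = genes, abs_log2fc = NA_real_, posterior = NA_real_,
                 is_deg = is_deg)
}
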