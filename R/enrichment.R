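#' Build the 2x2 DEG-by-gene-set contingency table
#'
#' Cross-classifies DEG status with gene-set membership over the analysis
#' universe: `g` DEGs inside the set, `g_not` non-DEGs inside the set, `h`
#' DEGs outside, `h_not` genes that are neither.
#'
#' @param deg_genes Character vector of DEG identifiers.
#' @param set_genes Character vector of gene-set members.
#' @param universe Character vector of all analysed genes.
#' @return Named integer vector `c(g, g_not, h, h_not)` summing to
#'   `length(universe)`.
#' @export
make_table <- function(deg_genes, set_genes, universe) {
  outside <- setdiff(deg_genes, universe)
  if (length(outside) > 0L) {
    stop("DEG gene(s) outside universe: ", paste(utils::head(outside, 5), collapse = ", "))
  }
  set_genes <- intersect(set_genes, universe)
  if (length(set_genes) == 0L) stop("gene set has empty intersection with universe")
  g <- length(intersect(deg_genes, set_genes))
  g_not <- length(set_genes) - g
  h <- length(deg_genes) - g
  h_not <- length(universe) - length(set_genes) - h
  c(g = g, g_not = g_not, h = h, h_not = h_not)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the two-sided p-value by summing hypergeometric probabilities not
#' exceeding that of the observed table, with a small relative tolerance
#' (1 + 1e-7) guarding against floating-point ties. The test runs on the
#' uncorrected integer counts; the continuity correction applies only to the
#' odds ratio (see [log_odds()]).
#'
#' @param table Named vector `c(g, g_not, h, h_not)` from [make_table()].
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_two_sided <- function(table) {
  g <- table[["g"]]; g_not <- table[["g_not"]]
  h <- table[["h"]]; h_not <- table[["h_not"]]
  m <- g + g_not            # genes in the set
  n <- h + h_not            # genes outside the set
  k <- g + h                # DEGs drawn
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(g, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Continuity-corrected log odds ratio and its variance
#'
#' The single-subject effect size for a gene set: 0.5 is added to each cell of
#' the 2x2 table, giving the natural-log odds ratio
#' `Q = ln((g+1/2)(h'+1/2) / ((h+1/2)(g'+1/2)))` with Woolf-type variance
#' `var(Q) = 1/(g+1/2) + 1/(g'+1/2) + 1/(h+1/2) + 1/(h'+1/2)`. The correction
#' keeps both finite for any table, including all-zero tables.
#'
#' @param table Named vector `c(g, g_not, h, h_not)`.
#' @return Named vector `c(Q, varQ)`.
#' @export
log_odds <- function(table) {
  g <- table[["g"]] + 0.5; gn <- table[["g_not"]] + 0.5
  h <- table[["h"]] + 0.5; hn <- table[["h_not"]] + 0.5
  c(Q = log((g * hn) / (h * gn)), varQ = 1 / g + 1 / gn + 1 / h + 1 / hn)
}

#' Per-subject gene-set enrichment profile
#'
#' For one subject's DEG calls, scores every gene set in the collection:
#' contingency table, two-sided Fisher exact p, Benjamini-Hochberg q across
#' all sets in the collection, the continuity-corrected log odds ratio `Q` and
#' its variance `varQ`. A set is flagged enriched when `fet_q < fdr_level`.
#'
#' @param degs DEG-call tibble (from [call_degs()] or [external_deg_call()]);
#'   its `gene` column defines the analysis universe.
#' @param sets Gene-set tibble (see [read_gmt()]), already filtered to the
#'   universe of interest.
#' @param fdr_level FDR threshold for the enriched flag (default 0.05).
#' @param subject_id Optional subject identifier carried into the output.
#' @return Tibble with one row per gene set: `subject_id`, `set_id`, `g`,
#'   `g_not`, `h`, `h_not`, `Q`, `varQ`, `fet_p`, `fet_q`, `enriched`.
#' @export
subject_profile <- function(degs, sets, fdr_level = 0.05, subject_id = NA_character_) {
  if (nrow(sets) == 0L) stop("empty gene-set collection")
  universe <- degs$gene
  deg_genes <- degs$gene[degs$is_deg]
  rows <- purrr::map2(sets$set_id, sets$genes, function(sid, members) {
    tab <- make_table(deg_genes, members, universe)
    lo <- log_odds(tab)
    tibble::tibble(set_id = sid, g = tab[["g"]], g_not = tab[["g_not"]],
                   h = tab[["h"]], h_not = tab[["h_not"]],
                   Q = lo[["Q"]], varQ = lo[["varQ"]],
                   fet_p = fisher_two_sided(tab))
  })
  out <- dplyr::bind_rows(rows)
  # stable tie-break: BH on p, ties resolved by set_id order
  ord <- order(out$fet_p, out$set_id)
  out$fet_q <- NA_real_
  out$fet_q[ord] <- stats::p.adjust(out$fet_p[ord], method = "BH")
  out$enriched <- out$fet_q < fdr_level
  dplyr::bind_cols(tibble::tibble(subject_id = subject_id, .rows = nrow(out)), out)
}
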