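#' Read a genes-by-samples count matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers, and returns a numeric matrix
#' with gene rownames and sample colnames. Counts may be non-integer
#' (normalized data are accepted); negative values are rejected.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return Numeric matrix, genes x samples.
#' @export
read_counts <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample identifiers in header")
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !is.na(raw) & raw != "NA")
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(raw)) + 1L
    stop("non-numeric value '", raw[bad[1]], "' at gene '", genes[i],
         "', sample '", samples[j], "'")
  }
  mat <- matrix(vals, nrow = nrow(raw), dimnames = list(genes, samples))
  if (any(mat < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  mat
}

#' Write a count matrix as TSV
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_counts <- function(matrix, path, delimiter = "\t") {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `set_id TAB description TAB gene1 TAB gene2 ...`.
#' Genes repeated within a line are de-duplicated with a warning. Gene
#' identifiers are compared case-sensitively as exact strings.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `name` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(genes, anyDuplicated, integer(1)) > 0L)
  if (ndup > 0L) {
    warning(ndup, " gene set(s) contained repeated genes; de-duplicated")
    genes <- lapply(genes, unique)
  }
  tibble::tibble(
    set_id = ids,
    name = vapply(fields, `[[`, character(1), 2L),
    genes = genes
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Tibble with columns `set_id`, `name`, `genes` (list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets[c("set_id", "name", "genes")],
                           function(set_id, name, genes) {
                             paste(c(set_id, name, genes), collapse = "\t")
                           })
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by post-intersection size
#'
#' Each set is intersected with the analysis universe; sets whose intersected
#' size falls inside `[min_size, max_size]` are retained with their intersected
#' memberships. The operation is idempotent.
#'
#' @param sets Gene-set tibble (see [read_gmt()]).
#' @param min_size,max_size Inclusive size bounds after intersection; the
#'   conventional Gene Ontology screen keeps sets of 15 to 500 genes.
#' @param universe Character vector of gene identifiers defining the analysis
#'   universe.
#' @return Filtered gene-set tibble with intersected `genes`.
#' @export
filter_genesets <- function(sets, min_size = 15L, max_size = 500L,
                            universe = NULL) {
  if (is.null(universe) || length(universe) == 0L) {
    stop("universe must be a non-empty vector of gene identifiers")
  }
  stopifnot(min_size <= max_size)
  out <- sets
  out$genes <- lapply(out$genes, intersect, y = universe)
  sz <- lengths(out$genes)
  out[sz >= min_size & sz <= max_size, , drop = FALSE]
}
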