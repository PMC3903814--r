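#' Genotype matrices of mutation sites by single cells
#'
#' A `genotype_matrix` is an integer matrix of called genotypes with mutation
#' sites as rows and single cells as columns. Entries are 0 (homozygous
#' wildtype), 1 (heterozygous mutation), 2 (homozygous mutation) or `NA`
#' (missing call, typically a cell that failed the assay's quality criteria
#' at that site). Missingness is a first-class state, never conflated with
#' wildtype.
#'
#' @param calls integer matrix with entries in `{0, 1, 2, NA}`.
#' @param site_labels character vector of unique site identifiers (defaults
#'   to the rownames of `calls`).
#' @param sample_ids character vector of unique cell identifiers (defaults to
#'   the colnames of `calls`).
#' @return An object of class `genotype_matrix`.
#' @examples
#' m <- genotype_matrix(rbind(A = c(0, 1, NA), B = c(1, 1, 0)))
#' missing_count(m)
#' @export
genotype_matrix <- function(calls, site_labels = rownames(calls),
                            sample_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(site_labels)) site_labels <- paste0("site", seq_len(nrow(calls)))
  if (is.null(sample_ids)) sample_ids <- paste0("cell", seq_len(ncol(calls)))
  site_labels <- as.character(site_labels)
  sample_ids <- as.character(sample_ids)
  if (length(site_labels) != nrow(calls))
    stop("`site_labels` length (", length(site_labels),
         ") does not match the number of rows (", nrow(calls), ")")
  if (length(sample_ids) != ncol(calls))
    stop("`sample_ids` length (", length(sample_ids),
         ") does not match the number of columns (", ncol(calls), ")")
  if (anyDuplicated(site_labels))
    stop("duplicate site labels: ",
         paste(unique(site_labels[duplicated(site_labels)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!is.na(calls) & !(calls %in% 0:2))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(calls)) + 1L
    stop("invalid genotype ", calls[bad[1]], " at site ", site_labels[i],
         ", sample ", sample_ids[j], " (entries must be 0, 1, 2 or missing)")
  }
  dimnames(calls) <- list(site_labels, sample_ids)
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x), " sites x ", ncol(x), " cells, ",
      missing_count(x), " missing (",
      round(100 * missing_count(x) / length(x), 1), "%)\n", sep = "")
  utils::str(unclass(x))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = c("genotype_matrix", "matrix", "array"))
}

#' Tidy long view of a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with columns `site`, `sample`, `genotype` (integer, `NA`
#'   for missing).
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    site = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    genotype = as.integer(x)
  )
}

#' Read a genotype matrix from delimited text
#'
#' Reads the tab/comma-separated dialect used throughout this package: one
#' header row of sample (cell) identifiers, one label column of site
#' identifiers, and genotype calls 0/1/2 with a configurable token for
#' missing entries.
#'
#' @param path file path.
#' @param orientation `"sites"` if rows are mutation sites (the default and
#'   the internal orientation) or `"cells"` if rows are cells; the latter is
#'   transposed on read.
#' @param missing token representing a missing call (default `"-"`).
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, orientation = c("sites", "cells"),
                                 missing = "-", sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           strip.white = TRUE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("no genotype entries in ", path)
  mat <- as.matrix(raw)
  ok <- mat %in% c("0", "1", "2", missing)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    i <- ((bad - 1L) %% nrow(mat)) + 1L
    j <- ((bad - 1L) %/% nrow(mat)) + 1L
    stop("unparseable genotype token \"", mat[bad], "\" at row ",
         rownames(mat)[i], ", column ", colnames(mat)[j],
         " (expected 0, 1, 2 or \"", missing, "\")")
  }
  mat[mat == missing] <- NA_character_
  storage.mode(mat) <- "integer"
  if (orientation == "cells") mat <- t(mat)
  genotype_matrix(mat)
}

#' Write a genotype matrix to delimited text
#'
#' Inverse of [read_genotype_matrix()]; `read(write(m))` is the identity,
#' including missing entries.
#'
#' @param m a [genotype_matrix()].
#' @param path output file path.
#' @param missing token to write for missing calls.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(m, path, missing = "-", sep = "\t") {
  stopifnot(inherits(m, "genotype_matrix"))
  out <- matrix(as.character(unclass(m)), nrow = nrow(m),
                dimnames = dimnames(m))
  out[is.na(out)] <- missing
  lines <- c(
    paste(c("site", colnames(out)), collapse = sep),
    vapply(seq_len(nrow(out)),
           function(i) paste(c(rownames(out)[i], out[i, ]), collapse = sep),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' The 18-site, 58-cell essential thrombocythemia genotype table
#'
#' The transformed single-cell genotype calls for the 18 nonsynonymous
#' mutation sites that Hou et al. (2012) flagged as important in their
#' essential thrombocythemia (ET) tumor, across the 58 sequenced single
#' cells. Entries: 0 wildtype, 1 heterozygous, 2 homozygous mutant, `NA`
#' missing (45% of calls failed quality criteria). This is the worked
#' dataset for the whole package.
#'
#' Provenance: transcribed from the published transformed genotype table.
#' Row tallies of the transcription (DLEC1 mutated fraction 0.857, PABPC1
#' 0.100) differ from the originally printed per-site rates (0.864 and
#' 0.122) by roughly one call per row, consistent with minor differences
#' between the journal's rendered table and the underlying data; the rank
#' order of per-site mutation rates is unaffected.
#'
#' @return A 18 x 58 [genotype_matrix()].
#' @examples
#' m <- et_genotypes()
#' dim(m)
#' @export
et_genotypes <- function() {
  path <- system.file("extdata", "hou2012_18site_genotypes.tsv",
                      package = "mutorder", mustWork = TRUE)
  read_genotype_matrix(path)
}

#' Count missing genotype calls
#'
#' @param m a [genotype_matrix()].
#' @return Integer count of missing entries.
#' @export
missing_count <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  sum(is.na(m))
}

#' Per-site mutation rates
#'
#' The mutated fraction of each site: the proportion of its non-missing
#' calls that are heterozygous (1) or homozygous (2) mutant. Under the
#' one-mutation-per-site model, sites mutating earlier are carried by more
#' sampled cells, so higher rates suggest earlier events.
#'
#' @param m a [genotype_matrix()].
#' @return A tibble with columns `site`, `n_obs` (non-missing calls),
#'   `n_mut` (calls in \{1, 2\}) and `rate` (`n_mut / n_obs`; `NaN` for a
#'   fully missing site), ordered by decreasing rate.
#' @examples
#' mutation_rates(et_genotypes())
#' @export
mutation_rates <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  n_obs <- rowSums(!is.na(m))
  n_mut <- rowSums(m >= 1L, na.rm = TRUE)
  tibble::tibble(site = rownames(m), n_obs = as.integer(n_obs),
                 n_mut = as.integer(n_mut), rate = n_mut / n_obs) |>
    dplyr::arrange(dplyr::desc(.data$rate))
}

#' Per-site summary, exportable as JSON
#'
#' @param m a [genotype_matrix()].
#' @return A tibble with one row per site: counts of each genotype, missing
#'   count, and mutation rate.
#' @export
genotype_summary <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  tibble::tibble(
    site = rownames(m),
    n_wildtype = as.integer(rowSums(m == 0L, na.rm = TRUE)),
    n_het = as.integer(rowSums(m == 1L, na.rm = TRUE)),
    n_hom = as.integer(rowSums(m == 2L, na.rm = TRUE)),
    n_missing = as.integer(rowSums(is.na(m))),
    rate = rowSums(m >= 1L, na.rm = TRUE) / rowSums(!is.na(m))
  )
}

#' Write the per-site summary as JSON
#'
#' @param m a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_summary_json <- function(m, path) {
  jsonlite::write_json(genotype_summary(m), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
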