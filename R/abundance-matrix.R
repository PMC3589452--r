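#' Protein-by-sample abundance matrix with a processing-level tag
#'
#' The quantification pipeline passes a single container through its fixed
#' sequence of transformations: raw spectral counts, length-normalized
#' counts, log-transformed values, row Z-scores, and Z-scores after the
#' presence/absence imputation rule.  The `level` tag records where in that
#' sequence a matrix sits, and each transformation refuses input at the wrong
#' level, so the stages cannot be permuted silently.
#'
#' Cells with no observation (a protein without any surviving peptide in a
#' sample) are `NA` in `values` and `TRUE` in the `missing` mask.  The mask
#' is fixed when the counts matrix is built and is carried unchanged through
#' every later level, including imputation: after [impute_missing()] the
#' values are filled in but the mask still records which cells were never
#' observed.
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   `NA` in unobserved cells.  Must have row and column names.
#' @param level processing level, one of `"counts"`, `"normalized"`,
#'   `"log"`, `"zscore"`, `"zscore_imputed"`.
#' @param missing optional logical matrix marking unobserved cells; defaults
#'   to `is.na(values)`.
#'
#' @return An object of class `abund_matrix`: the values matrix with
#'   attributes `level` and `missing`.
#' @seealso [rollup_counts()], [normalize_by_length()], [log_transform()],
#'   [zscore_rows()], [impute_missing()]
#' @export
abund_matrix <- function(values,
                         level = c("counts", "normalized", "log",
                                   "zscore", "zscore_imputed"),
                         missing = NULL) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_corequant("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_corequant("`values` must carry protein row names and sample column names")
  }
  if (is.null(missing)) missing <- is.na(values)
  if (!identical(dim(missing), dim(values))) {
    stop_corequant("`missing` mask must match the dimensions of `values`")
  }
  if (level == "counts") {
    obs <- values[!missing]
    if (any(obs < 0, na.rm = TRUE) || any(obs != floor(obs), na.rm = TRUE)) {
      stop_corequant("counts-level values must be non-negative integers")
    }
  }
  structure(values,
            level = level,
            missing = missing,
            class = c("abund_matrix", "matrix", "array"))
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("<abund_matrix> %d proteins x %d samples, level = '%s', %d missing cell(s)\n",
              nrow(x), ncol(x), attr(x, "level"), sum(attr(x, "missing"))))
  hdr <- utils::head(x, 5L)
  print(matrix(as.numeric(hdr), nrow = nrow(hdr),
               dimnames = dimnames(hdr)), ...)
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Processing level of an abundance matrix
#'
#' @param m an [abund_matrix()].
#' @return The level string.
#' @export
matrix_level <- function(m) {
  if (!inherits(m, "abund_matrix")) stop_corequant("not an abund_matrix")
  attr(m, "level")
}

#' Missing-observation mask of an abundance matrix
#'
#' @param m an [abund_matrix()].
#' @return Logical matrix, `TRUE` where no observation was made.
#' @export
missing_mask <- function(m) {
  if (!inherits(m, "abund_matrix")) stop_corequant("not an abund_matrix")
  attr(m, "missing")
}

# internal: demand a specific input level for a pipeline step
require_level <- function(m, wanted, op) {
  if (!inherits(m, "abund_matrix")) {
    stop_corequant(sprintf("%s() expects an abund_matrix", op))
  }
  lvl <- attr(m, "level")
  if (!lvl %in% wanted) {
    stop_corequant(sprintf(
      "%s() expects a matrix at level %s, got '%s' (pipeline order is counts -> normalized -> log -> zscore -> zscore_imputed)",
      op, paste(sprintf("'%s'", wanted), collapse = " or "), lvl))
  }
  invisible(m)
}

# internal: rebuild with new values but the same preserved mask
relabel_matrix <- function(values, template, level) {
  abund_matrix(values, level = level, missing = missing_mask(template))
}
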