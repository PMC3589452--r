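#' Normalize spectral counts by protein length
#'
#' Divides each protein's counts by its amino-acid length, the usual
#' correction for longer proteins yielding more observable peptides.
#' Missing cells stay missing.
#'
#' @param counts an [abund_matrix()] at level `"counts"`.
#' @param catalog protein catalog data frame with `protein_id` and positive
#'   `length` columns covering every matrix row.
#' @return An [abund_matrix()] at level `"normalized"`.
#' @export
normalize_by_length <- function(counts, catalog) {
  require_level(counts, "counts", "normalize_by_length")
  assert_columns(catalog, c("protein_id", "length"), "protein catalog")
  idx <- match(rownames(counts), catalog$protein_id)
  if (anyNA(idx)) {
    stop_corequant(sprintf("protein id(s) missing from catalog: %s",
                           paste(utils::head(rownames(counts)[is.na(idx)], 10L),
                                 collapse = ", ")))
  }
  len <- catalog$length[idx]
  if (any(!is.finite(len) | len <= 0)) {
    stop_corequant("protein lengths must be positive and finite")
  }
  relabel_matrix(unclass(counts) / len, counts, "normalized")
}

#' Log-transform normalized abundances
#'
#' @param m an [abund_matrix()] at level `"normalized"`.
#' @param policy a [z_policy()]; `log_base` (default 10) is used.
#' @return An [abund_matrix()] at level `"log"`.
#' @export
log_transform <- function(m, policy = z_policy()) {
  require_level(m, "normalized", "log_transform")
  vals <- unclass(m)
  if (any(vals[!is.na(vals)] <= 0)) {
    stop_corequant("log_transform() requires strictly positive present values (counts of at least 1 are guaranteed upstream by the single-count discard)")
  }
  relabel_matrix(log(vals, base = policy$log_base), m, "log")
}

#' Row-standardize log abundances to Z-scores
#'
#' Standardizes each protein across its observed conditions: the row mean is
#' subtracted and the result divided by the row standard deviation, both
#' computed over present cells only.  Under the default
#' `sign = "standard"` a sample above the protein's mean scores positive;
#' `"paper_literal"` flips the sign (see [z_policy()]).  Rows with zero
#' standard deviation -- including rows with a single present value -- get
#' Z = 0 rather than `NaN`.  Missing cells stay missing and are handled by
#' [impute_missing()].
#'
#' @param m an [abund_matrix()] at level `"log"`.
#' @param policy a [z_policy()].
#' @return An [abund_matrix()] at level `"zscore"`.
#' @export
zscore_rows <- function(m, policy = z_policy()) {
  require_level(m, "log", "zscore_rows")
  vals <- unclass(m)
  out <- vals
  for (i in seq_len(nrow(vals))) {
    x <- vals[i, ]
    pres <- !is.na(x)
    n <- sum(pres)
    if (n == 0L) next
    mu <- mean(x[pres])
    if (n >= 2L) {
      ss <- sum((x[pres] - mu)^2)
      s <- sqrt(ss / (if (policy$sd_mode == "sample") n - 1L else n))
    } else {
      s <- 0
    }
    z <- if (s > 0) (x - mu) / s else ifelse(pres, 0, NA_real_)
    if (policy$sign == "paper_literal") z <- -z
    out[i, ] <- z
  }
  relabel_matrix(out, m, "zscore")
}

#' Apply the presence/absence missing-value rule
#'
#' Implements the bespoke imputation that turns partially observed proteins
#' into a presence/absence pattern: using the global extremes of the Z
#' matrix (computed once, over present cells, before any assignment), every
#' missing cell of a gapped row is set to `min(Z)/impute_low_divisor` and
#' every *present* cell of that row is overwritten with
#' `max(Z) * impute_high_multiplier`.  Fully observed rows are untouched.
#'
#' Note the literal arithmetic: when `min(Z) < 0`, dividing by 1.5 moves the
#' imputed low *towards* zero, so imputed-low cells are not guaranteed to lie
#' below every observed value.  This behaviour is intentional and covered by
#' a property test.
#'
#' @param z an [abund_matrix()] at level `"zscore"`.
#' @param policy a [z_policy()].
#' @return An [abund_matrix()] at level `"zscore_imputed"`; the original
#'   missing mask is preserved for provenance.
#' @export
impute_missing <- function(z, policy = z_policy()) {
  require_level(z, "zscore", "impute_missing")
  vals <- unclass(z)
  if (all(is.na(vals))) {
    stop_corequant("cannot impute an all-missing matrix")
  }
  gmin <- min(vals, na.rm = TRUE)
  gmax <- max(vals, na.rm = TRUE)
  low <- gmin / policy$impute_low_divisor
  high <- gmax * policy$impute_high_multiplier
  gap <- rowSums(is.na(vals)) > 0L
  for (i in which(gap)) {
    miss <- is.na(vals[i, ])
    vals[i, miss] <- low
    vals[i, !miss] <- high
  }
  relabel_matrix(vals, z, "zscore_imputed")
}

#' Average a matrix over the samples of each stage
#'
#' Collapses a per-sample matrix to stage level by the arithmetic mean of
#' each protein's values over the samples assigned to a stage.  Accepts log,
#' Z-score or imputed-Z matrices; any remaining missing cells are ignored in
#' the mean (a stage with no observation yields `NA`).
#'
#' @param m an [abund_matrix()] at level `"log"`, `"zscore"` or
#'   `"zscore_imputed"`.
#' @param stages a [stage_assignment()] or a data frame with `sample_id` and
#'   `stage` columns covering every matrix column.
#' @return A plain numeric matrix, proteins by stages, stages in temporal
#'   order, with the source level kept in attribute `level`.
#' @export
stage_aggregate <- function(m, stages) {
  require_level(m, c("log", "zscore", "zscore_imputed"), "stage_aggregate")
  map <- stage_table(stages)
  idx <- match(colnames(m), map$sample_id)
  if (anyNA(idx)) {
    stop_corequant(sprintf("sample(s) without a stage assignment: %s",
                           paste(colnames(m)[is.na(idx)], collapse = ", ")))
  }
  lv <- stage_levels(map$stage)
  fac <- factor(map$stage[idx], levels = lv)
  if (any(tabulate(fac, nbins = length(lv)) == 0L)) {
    stop_corequant("every stage must contain at least one sample")
  }
  vals <- unclass(m)
  out <- sapply(lv, function(s) {
    rowMeans(vals[, fac == s, drop = FALSE], na.rm = TRUE)
  })
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(rownames(vals), lv))
  attr(out, "level") <- attr(m, "level")
  out
}

# canonical temporal ordering of stage labels
stage_levels <- function(stages) {
  known <- c("early", "middle", "late")
  u <- unique(stages)
  if (all(u %in% known)) known[known %in% u] else sort(u)
}

# coerce a stage_assignment or bare data frame to {sample_id, stage}
stage_table <- function(stages) {
  if (inherits(stages, "stage_assignment")) {
    data.frame(sample_id = stages$assignment$sample_id,
               stage = stages$assignment$stage,
               stringsAsFactors = FALSE)
  } else {
    assert_columns(stages, c("sample_id", "stage"), "stage table")
    stages[c("sample_id", "stage")]
  }
}

#' Call significant abundance shifts between adjacent stages
#'
#' For each ordered pair of adjacent stages (early to middle, middle to
#' late) and each protein, computes `delta_z = z(to) - z(from)` on the
#' stage-aggregated matrix and flags the shift as significant when
#' `|delta_z|` reaches the threshold (inclusive: a difference of exactly 2
#' is significant under the default policy).
#'
#' @param stage_matrix proteins-by-stages matrix from [stage_aggregate()]
#'   (imputed Z level for the standard pipeline).
#' @param policy a [z_policy()].
#' @return Data frame with columns `protein_id`, `from`, `to`, `delta_z`,
#'   `direction` (`"increased"`/`"decreased"`, `NA` at delta 0), and
#'   `significant`.
#' @export
call_significance <- function(stage_matrix, policy = z_policy()) {
  if (!is.matrix(stage_matrix) || ncol(stage_matrix) < 2L) {
    stop_corequant("need a proteins-by-stages matrix with at least 2 stages")
  }
  st <- colnames(stage_matrix)
  out <- do.call(rbind, lapply(seq_len(ncol(stage_matrix) - 1L), function(j) {
    dz <- stage_matrix[, j + 1L] - stage_matrix[, j]
    data.frame(protein_id = rownames(stage_matrix),
               from = st[j], to = st[j + 1L],
               delta_z = as.numeric(dz),
               direction = ifelse(dz > 0, "increased",
                                  ifelse(dz < 0, "decreased", NA_character_)),
               significant = abs(dz) >= policy$delta_z_threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$significant[is.na(out$significant)] <- FALSE
  out
}

#' Heuristic normal-tail p-value for a delta-Z
#'
#' The source procedure attaches no formal test to its delta-Z calls.  As a
#' labelled heuristic only, this treats `delta_z / sqrt(2)` as a standard
#' normal deviate (the difference of two unit-variance scores) and returns
#' the two-sided tail probability.  It is provided for ranking convenience
#' and should not be reported as an inferential p-value.
#'
#' @param delta_z numeric vector of stage differences.
#' @return Two-sided tail probabilities.
#' @export
delta_z_pvalue <- function(delta_z) {
  2 * stats::pnorm(-abs(delta_z) / sqrt(2))
}
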