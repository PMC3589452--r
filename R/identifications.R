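#' Filter peptide-spectrum matches on Xcorr and MSGF scores
#'
#' Applies the conservative two-stage identification filter: a row is kept
#' when its Xcorr meets the charge-specific minimum **and** its MSGF spectral
#' probability is at or below the cutoff.  Both comparisons are inclusive
#' (`xcorr >= threshold`, `msgf <= msgf_max`); row order is preserved.
#'
#' @param records data frame of peptide-spectrum matches with columns
#'   `peptide`, `protein_id`, `charge`, `xcorr`, `msgf`, `sample_id`,
#'   `count`.
#' @param policy a [filter_policy()].
#' @return The surviving rows of `records`, in their original order.
#' @export
#' @examples
#' psms <- data.frame(peptide = c("PEPTIDEK", "AAAK"),
#'                    protein_id = "P1", charge = c(2L, 1L),
#'                    xcorr = c(2.2, 0.5), msgf = c(1e-12, 1e-12),
#'                    sample_id = "s1", count = c(3L, 2L))
#' filter_psms(psms, filter_policy())
filter_psms <- function(records, policy = filter_policy()) {
  assert_columns(records, c("peptide", "protein_id", "charge", "xcorr",
                            "msgf", "sample_id", "count"), "PSM table")
  if (!inherits(policy, "filter_policy")) {
    stop_corequant("`policy` must be a filter_policy")
  }
  if (nrow(records) == 0L) return(records)
  if (any(records$charge < 1L)) {
    stop_corequant("charge states must be >= 1")
  }
  charges <- as.integer(names(policy$xcorr_min_by_charge))
  thr <- policy$xcorr_min_by_charge[match(records$charge, charges)]
  over <- is.na(thr)
  if (any(over)) {
    if (policy$charge_overflow == "error") {
      stop_corequant(sprintf(
        "no Xcorr threshold for charge state(s) %s (rows %s); set charge_overflow = 'use_max' or extend the policy",
        paste(unique(records$charge[over]), collapse = ", "),
        paste(utils::head(which(over), 5L), collapse = ", ")))
    }
    thr[over] <- policy$xcorr_min_by_charge[which.max(charges)]
  }
  keep <- records$xcorr >= thr & records$msgf <= policy$msgf_max
  records[keep, , drop = FALSE]
}

#' Discard peptides identified by only one spectral count
#'
#' Removes peptides whose summed spectral count falls below the policy's
#' `min_total_count` (default 2, i.e. single-count peptides are discarded).
#' Under the default `"global"` scope the sum runs over all samples, so a
#' peptide seen once in each of two samples (total 2) survives; under
#' `"per_sample"` the test is applied within each sample separately.
#'
#' @inheritParams filter_psms
#' @return The surviving rows, original order preserved.
#' @export
drop_single_count_peptides <- function(records, policy = filter_policy()) {
  assert_columns(records, c("peptide", "sample_id", "count"), "PSM table")
  if (nrow(records) == 0L) return(records)
  if (policy$single_count_scope == "global") {
    # dedupe rows that restate the same observation for multiple mapped
    # proteins so a shared peptide is not double-counted in its own total
    obs <- !duplicated(records[c("peptide", "sample_id")])
    totals <- tapply(records$count[obs], records$peptide[obs], sum)
    keep <- totals[records$peptide] >= policy$min_total_count
  } else {
    key <- paste(records$peptide, records$sample_id, sep = "\r")
    obs <- !duplicated(key)
    totals <- tapply(records$count[obs], key[obs], sum)
    keep <- totals[key] >= policy$min_total_count
  }
  records[as.vector(keep), , drop = FALSE]
}

#' Roll surviving peptides up to a protein-by-sample count matrix
#'
#' Each cell sums the spectral counts of a protein's surviving peptides in a
#' sample.  Proteins with no surviving peptide in a sample are *missing*
#' (`NA`), not zero -- absence of an identification is not evidence of zero
#' abundance, and the distinction drives the imputation rule downstream.
#' A peptide mapping to several proteins is credited once to each mapped
#' protein (set `shared_peptides = "drop"` to exclude such peptides instead).
#' Only proteins with at least one surviving observation appear as rows.
#'
#' @inheritParams filter_psms
#' @param catalog protein catalog data frame with columns `protein_id`,
#'   `length`, and optionally `cog`; every `protein_id` in `records` must
#'   resolve here.
#' @param shared_peptides `"credit_all"` (default) or `"drop"`.
#' @return An [abund_matrix()] at level `"counts"`.
#' @export
rollup_counts <- function(records, catalog,
                          shared_peptides = c("credit_all", "drop")) {
  shared_peptides <- match.arg(shared_peptides)
  assert_columns(records, c("peptide", "protein_id", "sample_id", "count"),
                 "PSM table")
  assert_columns(catalog, c("protein_id", "length"), "protein catalog")
  unknown <- setdiff(unique(records$protein_id), catalog$protein_id)
  if (length(unknown)) {
    stop_corequant(sprintf(
      "protein id(s) not in catalog: %s%s",
      paste(utils::head(unknown, 10L), collapse = ", "),
      if (length(unknown) > 10L) sprintf(" (and %d more)", length(unknown) - 10L) else ""))
  }
  if (nrow(records) == 0L) {
    stop_corequant("no surviving peptide records to roll up")
  }
  if (shared_peptides == "drop") {
    nmap <- tapply(records$protein_id, records$peptide,
                   function(p) length(unique(p)))
    records <- records[nmap[records$peptide] == 1L, , drop = FALSE]
    if (nrow(records) == 0L) {
      stop_corequant("all peptides were shared and dropped; nothing to roll up")
    }
  }
  proteins <- sort(unique(records$protein_id))
  samples <- sort(unique(records$sample_id))
  values <- matrix(NA_real_, nrow = length(proteins), ncol = length(samples),
                   dimnames = list(proteins, samples))
  sums <- tapply(records$count,
                 list(factor(records$protein_id, levels = proteins),
                      factor(records$sample_id, levels = samples)),
                 sum)
  values[] <- as.numeric(sums)
  abund_matrix(values, level = "counts")
}
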