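#' Peptide-spectrum filter policy
#'
#' Thresholds for the conservative SEQUEST/MSGF identification filters:
#' charge-dependent minimum Xcorr, a maximum MSGF spectral probability, and
#' the minimum total spectral count a peptide needs to be retained.  Both
#' score thresholds are boundary-inclusive: a row passes with
#' `xcorr >= threshold` and `msgf <= msgf_max`.
#'
#' @param xcorr_min_by_charge named numeric vector mapping charge state to
#'   its minimum Xcorr.  Defaults to the conventional `1.9 (+1)`, `2.2 (+2)`,
#'   `3.5 (+3)` cutoffs.
#' @param charge_overflow how to treat charges above the largest key:
#'   `"use_max"` applies the highest-charge threshold, `"error"` rejects the
#'   record.
#' @param msgf_max maximum MSGF spectral probability (smaller is more
#'   confident); default `1e-10`.
#' @param min_total_count minimum summed spectral count for a peptide to
#'   survive [drop_single_count_peptides()]; default 2 (i.e. single-count
#'   peptides are discarded).
#' @param single_count_scope whether the total in the single-count rule is
#'   summed across all samples (`"global"`, default) or tested per sample
#'   (`"per_sample"`).
#'
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(xcorr_min_by_charge = c(`1` = 1.9, `2` = 2.2, `3` = 3.5),
                          charge_overflow = c("use_max", "error"),
                          msgf_max = 1e-10,
                          min_total_count = 2L,
                          single_count_scope = c("global", "per_sample")) {
  charge_overflow <- match.arg(charge_overflow)
  single_count_scope <- match.arg(single_count_scope)
  if (is.null(names(xcorr_min_by_charge)) ||
      anyNA(suppressWarnings(as.integer(names(xcorr_min_by_charge))))) {
    stop_corequant("`xcorr_min_by_charge` must be named by integer charge states")
  }
  if (any(xcorr_min_by_charge <= 0)) {
    stop_corequant("Xcorr thresholds must be positive")
  }
  assert_number(msgf_max, "msgf_max", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(min_total_count, "min_total_count", lower = 1)
  structure(list(xcorr_min_by_charge = xcorr_min_by_charge,
                 charge_overflow = charge_overflow,
                 msgf_max = msgf_max,
                 min_total_count = as.integer(min_total_count),
                 single_count_scope = single_count_scope),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy>\n")
  cat("  Xcorr minima:",
      paste(sprintf("%s+:%.2f", names(x$xcorr_min_by_charge),
                    x$xcorr_min_by_charge), collapse = "  "), "\n")
  cat(sprintf("  charge overflow: %s; MSGF max: %g\n",
              x$charge_overflow, x$msgf_max))
  cat(sprintf("  single-count discard: total < %d, scope %s\n",
              x$min_total_count, x$single_count_scope))
  invisible(x)
}

#' Z-score and differential-call policy
#'
#' Controls the row-standardization, the presence/absence imputation rule and
#' the delta-Z significance threshold.
#'
#' The sign convention deserves a note.  Read literally, "subtract the
#' individual abundance from the row mean" computes `(mean - x)/sd`, which
#' inverts the usual Z-score so that abundant samples score negative.  The
#' default here is the standard orientation `(x - mean)/sd`, under which
#' "abundance increase" and positive delta-Z agree; the literal form is
#' available as `sign = "paper_literal"`.
#'
#' @param log_base base of the logarithm applied to normalized counts;
#'   default 10.
#' @param sd_mode `"sample"` uses the n-1 denominator (default),
#'   `"population"` uses n.
#' @param sign `"standard"` for `(x - mean)/sd`, `"paper_literal"` for
#'   `(mean - x)/sd`.
#' @param impute_low_divisor missing cells are set to the global minimum
#'   Z divided by this value (default 1.5).
#' @param impute_high_multiplier present cells of a gapped row are set to the
#'   global maximum Z multiplied by this value (default 1.5).
#' @param delta_z_threshold minimum absolute stage-to-stage Z difference for
#'   a significant call; inclusive, default 2.
#' @param condition_unit whether Z-scores are taken over the individual
#'   samples (default) or over stage means.
#'
#' @return An object of class `z_policy`.
#' @export
z_policy <- function(log_base = 10,
                     sd_mode = c("sample", "population"),
                     sign = c("standard", "paper_literal"),
                     impute_low_divisor = 1.5,
                     impute_high_multiplier = 1.5,
                     delta_z_threshold = 2,
                     condition_unit = c("samples", "stages")) {
  sd_mode <- match.arg(sd_mode)
  sign <- match.arg(sign)
  condition_unit <- match.arg(condition_unit)
  assert_number(log_base, "log_base", lower = 1, strict_lower = TRUE)
  assert_number(impute_low_divisor, "impute_low_divisor", lower = 0,
                strict_lower = TRUE)
  assert_number(impute_high_multiplier, "impute_high_multiplier", lower = 0,
                strict_lower = TRUE)
  assert_number(delta_z_threshold, "delta_z_threshold", lower = 0,
                strict_lower = TRUE)
  structure(list(log_base = log_base, sd_mode = sd_mode, sign = sign,
                 impute_low_divisor = impute_low_divisor,
                 impute_high_multiplier = impute_high_multiplier,
                 delta_z_threshold = delta_z_threshold,
                 condition_unit = condition_unit),
            class = "z_policy")
}

#' @export
print.z_policy <- function(x, ...) {
  cat("<z_policy>\n")
  cat(sprintf("  log base %g; SD mode %s; sign %s\n",
              x$log_base, x$sd_mode, x$sign))
  cat(sprintf("  imputation: missing <- min/% .2f, present <- max x %.2f\n",
              x$impute_low_divisor, x$impute_high_multiplier))
  cat(sprintf("  |delta Z| >= %.2f (inclusive); conditions = %s\n",
              x$delta_z_threshold, x$condition_unit))
  invisible(x)
}
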