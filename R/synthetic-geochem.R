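#' Generate a three-phase geochemical time series
#'
#' Produces per-day concentrations of the five analytes used for sample
#' staging, following the canonical acetate-amendment trajectory: ferrous
#' iron rises from a ~50 uM background during the early phase, plateaus at
#' elevated levels through the middle phase, and declines while sulfide
#' first appears late; acetate tracks the amendment, uranium(VI) falls after
#' stimulation, and sulfate is drawn down late.  Within each stage the
#' analyte moves linearly between stage-specific anchor values; days before
#' the first planned day sit at background.  Gaussian measurement noise
#' (per-analyte SD from the config) is added and clipped at zero.
#'
#' @param config a [sim_config()]; the phases align with its `stage_plan`.
#' @param days optional day vector at which to evaluate the series; default
#'   the planned sampling days.
#' @param noise_sd optional override of `config$geochem_noise_sd`; use 0
#'   for a noiseless series.
#' @param seed RNG seed for the measurement noise; [simulate_dataset()]
#'   passes the experiment seed plus three.
#' @return Data frame with columns `day`, `fe2`, `sulfide`, `u6` (uM),
#'   `acetate`, `sulfate` (mM).
#' @export
gen_geochem <- function(config, days = NULL, noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  days <- days %||% unlist(config$stage_plan, use.names = FALSE)
  noise <- noise_sd %||% config$geochem_noise_sd
  if (length(noise) == 1L) {
    noise <- stats::setNames(rep(noise, 5L),
                             c("fe2", "sulfide", "u6", "acetate", "sulfate"))
  }
  base <- geochem_template(days, config)
  with_seed(seed %||% (config$seed + 3L), {
    for (an in c("fe2", "sulfide", "u6", "acetate", "sulfate")) {
      base[[an]] <- pmax(0, base[[an]] +
                           stats::rnorm(nrow(base), 0, noise[[an]]))
    }
    base
  })
}

# anchor values per stage: each analyte moves linearly from `from` to `to`
# across the stage's planned days
geochem_anchors <- function(fe2_background) {
  list(
    fe2     = list(pre = fe2_background,
                   early = c(60, 100), middle = c(160, 190),
                   late = c(130, 90)),
    acetate = list(pre = 0, early = c(1, 3.5), middle = c(4.5, 5),
                   late = c(3.5, 2)),
    u6      = list(pre = 1.5, early = c(1.8, 1.6), middle = c(0.7, 0.4),
                   late = c(0.06, 0.05)),
    sulfate = list(pre = 8.5, early = c(8.5, 8.3), middle = c(8.1, 7.8),
                   late = c(5.5, 3.5)),
    sulfide = list(pre = 0, early = c(0, 0), middle = c(0, 0),
                   late = c(5, 10)))
}

geochem_template <- function(days, config) {
  plan <- config$stage_plan
  anchors <- geochem_anchors(config$fe2_background)
  stage_names <- names(plan)
  # map each requested day to a stage and a within-stage position in [0,1]
  pos <- vapply(days, function(d) {
    for (s in stage_names) {
      rng <- range(plan[[s]])
      if (d <= rng[2]) {
        if (d < min(plan[[stage_names[1]]])) return(c(NA_real_, NA_real_))
        t <- if (diff(rng) > 0) (min(max(d, rng[1]), rng[2]) - rng[1]) / diff(rng) else 0
        return(c(match(s, stage_names), t))
      }
    }
    c(length(stage_names), 1)  # beyond the last planned day: hold the end
  }, numeric(2))
  out <- data.frame(day = days)
  for (an in names(anchors)) {
    a <- anchors[[an]]
    out[[an]] <- vapply(seq_along(days), function(i) {
      si <- pos[1, i]
      if (is.na(si)) return(a$pre)  # pre-amendment background
      v <- a[[stage_names[si]]]
      v[1] + pos[2, i] * (v[2] - v[1])
    }, numeric(1))
  }
  out
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper running every generator under one seed: catalogs and
#' ground truth, the focal-genome PSM table, pairwise similarity tables and
#' the geochemical series.
#'
#' @param config a [sim_config()].
#' @param noise_level bitscore noise for the similarity tables; default 0.
#' @param sequences generate synthetic protein sequences; default `FALSE`.
#' @return An object of class `corequant_sim`: list with `config`,
#'   `catalogs`, `truth`, `psms`, `similarity`, `geochem`.
#' @export
simulate_dataset <- function(config = sim_config(), noise_level = 0,
                             sequences = FALSE) {
  cat_truth <- gen_catalogs(config, sequences = sequences)
  focal <- cat_truth$truth$focal_genome
  psms <- gen_psm_table(cat_truth$catalogs[[focal]], cat_truth$truth, config)
  sim <- gen_similarity_tables(cat_truth$catalogs, cat_truth$truth,
                               noise_level = noise_level,
                               n_decoys = config$n_decoys,
                               seed = config$seed + 1L)
  geo <- gen_geochem(config)
  structure(list(config = config, catalogs = cat_truth$catalogs,
                 truth = cat_truth$truth, psms = psms,
                 similarity = sim, geochem = geo),
            class = "corequant_sim")
}

#' @export
print.corequant_sim <- function(x, ...) {
  cat(sprintf("<corequant_sim> seed %d: %d genomes, %d PSM rows, %d similarity rows, %d geochem days\n",
              x$config$seed, length(x$catalogs), nrow(x$psms),
              nrow(x$similarity), nrow(x$geochem)))
  invisible(x)
}
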