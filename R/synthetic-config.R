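#' Configuration for the synthetic experiment generator
#'
#' Bundles every tunable of the simulated acetate-amendment experiment.  The
#' defaults reproduce the study design the package targets: eight
#' *Geobacter*-like genomes at their published protein-coding sizes, nine
#' samples over three geochemical stages (days 5/8/10, 13/15/17, 29/36/43),
#' a core proteome sized as a fraction of the smallest genome, and planted
#' stage-specific abundance shifts concentrated in chosen COG categories.
#'
#' @param n_genomes number of genomes.
#' @param genome_sizes named integer vector of protein-coding gene counts
#'   per genome; names become genome labels and the first genome is the
#'   focal (searched) genome.
#' @param core_fraction fraction of the smallest genome allocated to
#'   ortholog groups spanning **all** genomes; the number of core groups is
#'   `round(core_fraction * min(genome_sizes))`.  Default 0.32, the
#'   observed share of an eight-genome core in the smallest genome.
#' @param n_samples number of samples; must equal the total days in
#'   `stage_plan`.
#' @param stage_plan named list of sampling days per stage, in temporal
#'   order.
#' @param effect_log_fold magnitude of planted stage shifts, in log10 units
#'   of spectral abundance.  A planted protein follows a two-sided contrast
#'   (`-effect/2` in one stage, `+effect/2` in another, baseline in the
#'   third), the pattern with the largest attainable stage-to-stage Z
#'   difference.  Default 2 (a 100-fold swing).
#' @param dropout_rate probability that a truly expressed protein yields no
#'   identification in a stage, *evaluated at the detection limit*; scalar
#'   or per-stage named vector.  The realized per-protein probability is
#'   `dropout_rate ^ (mu_stage / detection_limit)`, so abundant proteins are
#'   essentially always detected, proteins at the detection limit drop at
#'   `dropout_rate`, and `dropout_rate = 1` silences a stage completely.
#'   Dropout removes the whole stage (all of its samples) for the affected
#'   protein, matching the condition-level presence/absence notion the
#'   downstream imputation rule assumes.  Default 0.1.
#' @param seed integer seed; all generator randomness flows from it.
#' @param expressed_fraction fraction of the focal genome expressed at all
#'   (emitting identifications); default 0.23.
#' @param diff_fraction fraction of expressed proteins carrying a planted
#'   shift; default 0.15.
#' @param baseline_count median per-sample spectral count of an expressed
#'   protein at baseline; default 30.
#' @param baseline_log_sd between-protein SD of baseline abundance, log10
#'   units; default 0.35.
#' @param nb_size negative-binomial dispersion parameter (`size`) of the
#'   count model; counts are zero-truncated so absence arises only through
#'   the dropout mask.  Default 10.
#' @param detection_limit count level at which `dropout_rate` applies;
#'   default 5.
#' @param filter_fail_rate fraction of emitted PSM rows constructed to fail
#'   at least one identification filter; default 0.3.
#' @param single_hit_rate fraction (relative to passing rows) of extra
#'   single-spectral-count peptide rows, exercising the single-count
#'   discard; default 0.05.
#' @param count_noise `"nb"` for stochastic counts (default) or `"none"`
#'   for deterministic `round(mu)` counts (noiseless end-to-end checks).
#' @param p_singleton probability that an accessory ortholog group is a
#'   singleton rather than a proper multi-genome subset; default 0.4.
#' @param n_decoys off-group similarity rows emitted per query protein;
#'   default 2.
#' @param geochem_noise_sd named vector of additive measurement noise SDs
#'   for `fe2`, `sulfide`, `u6` (micromolar), `acetate`, `sulfate`
#'   (millimolar).
#' @param fe2_background pre-amendment Fe(II) concentration, micromolar;
#'   default 50.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 8L,
                       genome_sizes = c(Gbem = 4034L, GM21 = 4152L,
                                        GM18 = 4523L, Gura = 4430L,
                                        GFRC32 = 3839L, Gsul = 3465L,
                                        Gmet = 3576L, Glov = 3725L),
                       core_fraction = 0.32,
                       n_samples = 9L,
                       stage_plan = list(early = c(5, 8, 10),
                                         middle = c(13, 15, 17),
                                         late = c(29, 36, 43)),
                       effect_log_fold = 2,
                       dropout_rate = 0.1,
                       seed = 1L,
                       expressed_fraction = 0.23,
                       diff_fraction = 0.15,
                       baseline_count = 30,
                       baseline_log_sd = 0.35,
                       nb_size = 10,
                       detection_limit = 5,
                       filter_fail_rate = 0.3,
                       single_hit_rate = 0.05,
                       count_noise = c("nb", "none"),
                       p_singleton = 0.4,
                       n_decoys = 2L,
                       geochem_noise_sd = c(fe2 = 6, sulfide = 0.3,
                                            u6 = 0.05, acetate = 0.15,
                                            sulfate = 0.2),
                       fe2_background = 50) {
  count_noise <- match.arg(count_noise)
  if (length(genome_sizes) != n_genomes) {
    genome_sizes <- genome_sizes[seq_len(n_genomes)]
  }
  if (is.null(names(genome_sizes))) {
    names(genome_sizes) <- paste0("G", seq_along(genome_sizes))
  }
  if (any(!is.finite(genome_sizes) | genome_sizes <= 0)) {
    stop_corequant("genome sizes must be positive")
  }
  assert_number(core_fraction, "core_fraction", lower = 0, upper = 1)
  if (is.null(names(stage_plan)) || any(names(stage_plan) == "")) {
    stop_corequant("`stage_plan` must be a named list of day vectors")
  }
  if (sum(lengths(stage_plan)) != n_samples) {
    stop_corequant("`n_samples` must equal the total number of days in `stage_plan`")
  }
  days <- unlist(stage_plan, use.names = FALSE)
  if (is.unsorted(days, strictly = TRUE)) {
    stop_corequant("stage_plan days must be strictly increasing across stages")
  }
  stages <- names(stage_plan)
  if (length(dropout_rate) == 1L && is.null(names(dropout_rate))) {
    dropout_rate <- stats::setNames(rep(dropout_rate, length(stages)), stages)
  }
  if (!all(stages %in% names(dropout_rate))) {
    stop_corequant("per-stage `dropout_rate` must name every stage")
  }
  if (any(dropout_rate < 0 | dropout_rate > 1)) {
    stop_corequant("dropout_rate must lie in [0, 1]")
  }
  assert_number(effect_log_fold, "effect_log_fold", lower = 0)
  assert_number(seed, "seed")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_sizes = genome_sizes,
                 core_fraction = core_fraction,
                 n_samples = as.integer(n_samples),
                 stage_plan = stage_plan,
                 effect_log_fold = effect_log_fold,
                 dropout_rate = dropout_rate[stages],
                 seed = as.integer(seed),
                 expressed_fraction = expressed_fraction,
                 diff_fraction = diff_fraction,
                 baseline_count = baseline_count,
                 baseline_log_sd = baseline_log_sd,
                 nb_size = nb_size,
                 detection_limit = detection_limit,
                 filter_fail_rate = filter_fail_rate,
                 single_hit_rate = single_hit_rate,
                 count_noise = count_noise,
                 p_singleton = p_singleton,
                 n_decoys = as.integer(n_decoys),
                 geochem_noise_sd = geochem_noise_sd,
                 fe2_background = fe2_background),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d genomes (focal %s), %d samples, seed %d\n",
              x$n_genomes, names(x$genome_sizes)[1], x$n_samples, x$seed))
  cat("  stages:", paste(sprintf("%s{%s}", names(x$stage_plan),
                                 vapply(x$stage_plan, paste,
                                        character(1), collapse = ",")),
                         collapse = " "), "\n")
  cat(sprintf("  core fraction %.2f; effect %.1f log10; dropout %s; counts %s\n",
              x$core_fraction, x$effect_log_fold,
              paste(sprintf("%s=%.2g", names(x$dropout_rate), x$dropout_rate),
                    collapse = ","),
              x$count_noise))
  invisible(x)
}

# twenty-letter COG alphabet with rough prevalence weights; J, C, E are of
# particular interest because planted shifts concentrate there
cog_alphabet <- function() {
  c(J = 5, K = 6, L = 5, D = 2, V = 2, T = 4, M = 5, N = 2, U = 2, O = 4,
    C = 6, G = 5, E = 7, F = 2, H = 4, I = 3, P = 4, Q = 2, R = 8, S = 6)
}

# evaluate code under a local, restorable RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}
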