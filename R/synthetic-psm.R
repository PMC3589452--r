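#' Generate a synthetic peptide-spectrum match table
#'
#' Emits search-engine-style PSM rows for the focal genome: per sample and
#' expressed protein, a spectral count drawn from a zero-truncated negative
#' binomial whose log10 mean combines the protein's baseline abundance with
#' its planted stage contrast, split over 1-5 persistent tryptic-like
#' peptides.  Missingness follows the detection-limit dropout model of
#' [sim_config()]: a protein fails detection in an entire stage with
#' probability `dropout_rate ^ (mu_stage / detection_limit)`, and dropped
#' protein-stage combinations emit no rows at all.
#'
#' To exercise the identification filters, a `filter_fail_rate` share of
#' rows is constructed to fail at least one threshold (low Xcorr, high MSGF
#' probability, or both), and a `single_hit_rate` share of
#' single-spectral-count peptides is added to exercise the single-count
#' discard; neither class survives the filtering stage, so the filtered
#' roll-up reflects the planted signal exactly.
#'
#' @param catalog the focal genome's catalog from [gen_catalogs()].
#' @param truth the matching `ground_truth`.
#' @param config the same [sim_config()].
#' @return Data frame with columns `peptide`, `protein_id`, `charge`,
#'   `xcorr`, `msgf`, `sample_id`, `count`.
#' @export
gen_psm_table <- function(catalog, truth, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "ground_truth"))
  if (!all(truth$expressed %in% catalog$protein_id)) {
    stop_corequant("`catalog` must be the focal genome catalog matching `truth`")
  }
  with_seed(config$seed + 2L, gen_psm_impl(catalog, truth, config))
}

gen_psm_impl <- function(catalog, truth, config) {
  stages <- names(config$stage_plan)
  labels <- truth$stage_labels
  samples <- labels$sample_id
  stage_of <- stats::setNames(labels$stage, samples)
  off <- planted_offsets(truth, stages)
  thr <- c(`1` = 1.9, `2` = 2.2, `3` = 3.5)
  used_peptides <- new.env(parent = emptyenv())

  rows <- vector("list", length(truth$expressed))
  for (pi in seq_along(truth$expressed)) {
    prot <- truth$expressed[pi]
    mu_stage <- 10^(truth$baseline[prot] + off[prot, stages])
    names(mu_stage) <- stages
    p_drop <- config$dropout_rate[stages] ^
      (mu_stage / config$detection_limit)
    dropped <- stats::runif(length(stages)) < p_drop
    names(dropped) <- stages
    if (all(dropped)) next
    npep <- sample(1:5, 1L, prob = c(0.10, 0.20, 0.30, 0.25, 0.15))
    peps <- make_peptides(npep, used_peptides)
    w <- stats::runif(npep, 0.5, 1.5)
    w <- w / sum(w)
    charge <- sample(1:3, npep, replace = TRUE, prob = c(0.2, 0.5, 0.3))
    out <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      st <- stage_of[[samples[si]]]
      if (dropped[[st]]) next
      total <- draw_count(mu_stage[[st]], config)
      split <- if (config$count_noise == "nb") {
        as.integer(stats::rmultinom(1L, total, w))
      } else {
        apportion(total, w)
      }
      keep <- split > 0L
      if (!any(keep)) next
      nk <- sum(keep)
      out[[si]] <- data.frame(
        peptide = peps[keep],
        protein_id = prot,
        charge = charge[keep],
        xcorr = thr[as.character(charge[keep])] + stats::runif(nk, 0, 2),
        msgf = 10^-stats::runif(nk, 10, 20),
        sample_id = samples[si],
        count = split[keep],
        stringsAsFactors = FALSE)
    }
    rows[[pi]] <- do.call(rbind, out)
  }
  psms <- do.call(rbind, rows)
  if (is.null(psms)) {
    psms <- data.frame(peptide = character(), protein_id = character(),
                       charge = integer(), xcorr = numeric(),
                       msgf = numeric(), sample_id = character(),
                       count = integer(), stringsAsFactors = FALSE)
  }
  n_pass <- nrow(psms)

  # deliberately failing rows (filter exercise): n chosen so that the
  # failing share of all emitted rows is filter_fail_rate
  fr <- config$filter_fail_rate
  n_fail <- if (fr > 0 && n_pass > 0) round(fr / (1 - fr) * n_pass) else 0L
  if (n_fail > 0) {
    fail_charge <- sample(1:3, n_fail, replace = TRUE)
    mode <- sample(c("xcorr", "msgf", "both"), n_fail, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    x_ok <- thr[as.character(fail_charge)] + stats::runif(n_fail, 0, 2)
    x_bad <- stats::runif(n_fail, 0.1,
                          thr[as.character(fail_charge)] - 0.05)
    m_ok <- 10^-stats::runif(n_fail, 10, 20)
    m_bad <- 10^-stats::runif(n_fail, 0, 9.5)
    fail <- data.frame(
      peptide = make_peptides(n_fail, used_peptides),
      protein_id = sample(catalog$protein_id, n_fail, replace = TRUE),
      charge = fail_charge,
      xcorr = ifelse(mode == "msgf", x_ok, x_bad),
      msgf = ifelse(mode == "xcorr", m_ok, m_bad),
      sample_id = sample(samples, n_fail, replace = TRUE),
      count = sample(1:3, n_fail, replace = TRUE),
      stringsAsFactors = FALSE)
    psms <- rbind(psms, fail)
  }

  # single-spectral-count peptides that pass the score filters but are
  # discarded by the single-count rule
  n_single <- if (n_pass > 0) round(config$single_hit_rate * n_pass) else 0L
  if (n_single > 0) {
    s_charge <- sample(1:3, n_single, replace = TRUE)
    singles <- data.frame(
      peptide = make_peptides(n_single, used_peptides),
      protein_id = sample(truth$expressed, n_single, replace = TRUE),
      charge = s_charge,
      xcorr = thr[as.character(s_charge)] + stats::runif(n_single, 0, 2),
      msgf = 10^-stats::runif(n_single, 10, 20),
      sample_id = sample(samples, n_single, replace = TRUE),
      count = 1L,
      stringsAsFactors = FALSE)
    psms <- rbind(psms, singles)
  }
  psms <- psms[order(psms$sample_id, psms$protein_id, psms$peptide), ]
  rownames(psms) <- NULL
  psms
}

# zero-truncated negative binomial (or deterministic) spectral count
draw_count <- function(mu, config) {
  if (config$count_noise == "none") {
    return(max(1L, as.integer(round(mu))))
  }
  for (i in 1:50) {
    x <- stats::rnbinom(1L, mu = mu, size = config$nb_size)
    if (x > 0L) return(x)
  }
  1L
}

# largest-remainder apportionment of `total` over weights (deterministic)
apportion <- function(total, w) {
  q <- total * w
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# globally unique tryptic-like peptide strings (end in K or R)
make_peptides <- function(n, used) {
  aa <- c("A","G","S","T","V","L","I","P","F","D","E","N","Q","H","Y","M","W","C")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      L <- 7L + stats::rpois(1L, 5L)
      pep <- paste0(paste(sample(aa, L, replace = TRUE), collapse = ""),
                    sample(c("K", "R"), 1L))
      if (!exists(pep, envir = used, inherits = FALSE)) {
        assign(pep, TRUE, envir = used)
        out[i] <- pep
        break
      }
    }
  }
  out
}
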