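#' Generate pairwise inter-genome similarity tables
#'
#' Emits BLAST-tabular-style rows for every ordered genome pair.  True
#' ortholog pairs (from the ground-truth groups) receive high bitscores
#' around 500 with percent identities around 94; every query additionally
#' receives `n_decoys` off-group rows with strictly lower bitscores (50 to
#' 400).  Score noise is clamped to four standard deviations, so the
#' reciprocal-top property of true pairs is guaranteed for
#' `noise_level < 12.5` (the 100-point score gap divided by the 8 combined
#' clamped deviations); beyond that the guarantee lapses by design.
#'
#' @param catalogs named list of catalogs from [gen_catalogs()].
#' @param truth the matching `ground_truth`.
#' @param noise_level standard deviation of Gaussian bitscore perturbation;
#'   default 0 (noiseless: every true pair is the mutual best hit in both
#'   directions).
#' @param n_decoys off-group rows per query protein; default 2.
#' @param seed RNG seed for scores and decoy choice; [simulate_dataset()]
#'   passes the experiment seed plus one.
#' @return Data frame in long form: `query_genome`, `subject_genome`, plus
#'   the twelve standard tabular alignment columns `query_id`, `subject_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
gen_similarity_tables <- function(catalogs, truth, noise_level = 0,
                                  n_decoys = 2L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  bad <- vapply(names(catalogs), function(g) {
    !all(truth$membership$protein_id[truth$membership$genome == g] %in%
           catalogs[[g]]$protein_id)
  }, logical(1))
  if (any(bad)) {
    stop_corequant("catalogs are not consistent with the ground truth membership")
  }
  with_seed(seed, gen_similarity_impl(catalogs, truth, noise_level, n_decoys))
}

gen_similarity_impl <- function(catalogs, truth, noise_level, n_decoys) {
  genomes <- names(catalogs)
  mem <- truth$membership
  out <- list()
  clamp_noise <- function(n) {
    if (noise_level == 0) return(numeric(n))
    pmin(pmax(stats::rnorm(n, 0, noise_level), -4 * noise_level),
         4 * noise_level)
  }
  for (a in genomes) for (b in setdiff(genomes, a)) {
    qa <- catalogs[[a]]
    qb <- catalogs[[b]]
    if (nrow(qa) == 0L || nrow(qb) == 0L) next
    # true pairs: groups with members in both genomes
    ma <- mem[mem$genome == a, c("group_id", "protein_id")]
    mb <- mem[mem$genome == b, c("group_id", "protein_id")]
    tp <- merge(ma, mb, by = "group_id", suffixes = c("_a", "_b"))
    lens <- stats::setNames(qa$length, qa$protein_id)
    blocks <- list()
    if (nrow(tp)) {
      L <- as.integer(lens[tp$protein_id_a])
      pid <- pmin(100, pmax(50, 94 + stats::rnorm(nrow(tp), 0, 2)))
      bs <- 500 + clamp_noise(nrow(tp))
      blocks[[1]] <- sim_rows(a, b, tp$protein_id_a, tp$protein_id_b,
                              pid, L, bs)
    }
    nd <- min(nrow(qb) - 1L, n_decoys)
    if (nd > 0) {
      true_of <- split(tp$protein_id_b, factor(tp$protein_id_a,
                                               levels = qa$protein_id))
      # decoy subjects are restricted to proteins anchored by a true pair of
      # their own, so two partner-less proteins can never become a spurious
      # mutual best hit through decoy rows
      anchored <- unique(tp$protein_id_b)
      picks <- lapply(qa$protein_id, function(q) {
        pool <- setdiff(anchored, true_of[[q]])
        if (!length(pool)) pool <- setdiff(qb$protein_id, true_of[[q]])
        sample(pool, min(nd, length(pool)))
      })
      qid <- rep(qa$protein_id, lengths(picks))
      sid <- unlist(picks, use.names = FALSE)
      L <- as.integer(lens[qid])
      pid <- stats::runif(length(sid), 30, 70)
      bs <- stats::runif(length(sid), 50, 400) + clamp_noise(length(sid))
      blocks[[length(blocks) + 1L]] <- sim_rows(a, b, qid, sid, pid, L, bs)
    }
    out[[paste(a, b)]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, c(out, list(empty_sim_table())))
  rownames(res) <- NULL
  res
}

sim_rows <- function(a, b, qid, sid, pident, len, bitscore) {
  data.frame(query_genome = a, subject_genome = b,
             query_id = qid, subject_id = sid,
             pident = pident, length = len,
             mismatch = as.integer(round(len * (1 - pident / 100))),
             gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len,
             evalue = pmax(10^(-bitscore / 10), 1e-180),
             bitscore = bitscore,
             stringsAsFactors = FALSE)
}

empty_sim_table <- function() {
  data.frame(query_genome = character(), subject_genome = character(),
             query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}
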