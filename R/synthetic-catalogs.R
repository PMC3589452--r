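#' Generate protein catalogs with planted ortholog structure
#'
#' Builds one protein catalog per genome together with the ground truth the
#' rest of the generator (and every recovery test) is scored against.
#' Ortholog groups are constructed first: a core share spanning every
#' genome -- exactly `round(core_fraction * min(genome_sizes))` groups --
#' then accessory groups over random *proper* genome subsets and singletons
#' until each genome reaches its size.  Every group carries one protein per
#' member genome, a shared COG category (drawn from a 20-letter alphabet,
#' with a fraction left unannotated) and a log-normal length (median about
#' 300 amino acids).  Protein identifiers are locus-tag style
#' (`<genome>_<number>`) and are shuffled within each genome so identifier
#' order carries no information about group structure.
#'
#' Expression and differential ground truth for the focal genome (the first
#' one) is planted here as well: an `expressed_fraction` share of focal
#' proteins is expressed, and a `diff_fraction` share of those receives a
#' stage contrast.  Planted shifts are concentrated by category --
#' early-to-middle decreases preferentially in translation (J),
#' early-to-middle increases in energy production (C) and amino-acid
#' metabolism (E) -- mirroring the biological structure the analysis is
#' meant to detect.
#'
#' @param config a [sim_config()].
#' @param sequences logical; also generate synthetic amino-acid sequences
#'   (group members share a template with ~6% substitutions).  Default
#'   `FALSE`; sequences are only needed for FASTA export.
#' @return List with `catalogs` (named list of data frames `protein_id`,
#'   `length`, `cog`, plus `sequence` when requested) and `truth` (class
#'   `ground_truth`; see Details).
#'
#' @details The `ground_truth` object carries `membership` (`group_id`,
#'   `genome`, `protein_id`), `core_groups`, `stage_labels` (`day`,
#'   `sample_id`, `stage`), `expressed`, `differential` (`protein_id`,
#'   `from`, `to`, `direction`, `log_fold`), per-protein `baseline` log10
#'   abundances, `genomes` and `focal_genome`.
#' @export
gen_catalogs <- function(config, sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, gen_catalogs_impl(config, sequences))
}

gen_catalogs_impl <- function(config, sequences) {
  sizes <- config$genome_sizes
  genomes <- names(sizes)
  n <- length(genomes)
  n_core <- as.integer(round_half_up(config$core_fraction * min(sizes)))

  # group construction: core first, then accessory proper subsets/singletons
  members <- vector("list", n_core)
  for (i in seq_len(n_core)) members[[i]] <- genomes
  remaining <- sizes - n_core
  while (any(remaining > 0)) {
    avail <- genomes[remaining > 0]
    smax <- min(n - 1L, length(avail))
    if (smax < 2L || stats::runif(1) < config$p_singleton) {
      grp <- sample(avail, 1L)
    } else {
      grp <- sample(avail, sample(2:smax, 1L))
    }
    members[[length(members) + 1L]] <- grp
    remaining[grp] <- remaining[grp] - 1L
  }
  n_groups <- length(members)
  group_id <- sprintf("TG%06d", seq_len(n_groups))

  # per-group annotation: shared COG (or unannotated) and a template length
  alpha <- cog_alphabet()
  cog <- sample(names(alpha), n_groups, replace = TRUE,
                prob = alpha / sum(alpha))
  cog[stats::runif(n_groups) < 0.2] <- NA_character_
  glen <- pmax(50L, as.integer(round(stats::rlnorm(n_groups,
                                                   meanlog = log(300),
                                                   sdlog = 0.35))))

  # materialize per-genome catalogs with shuffled locus numbers
  sizes_by_genome <- as.integer(sizes)
  names(sizes_by_genome) <- genomes
  counts <- unlist(lapply(members, length))
  flat_genome <- unlist(members)
  flat_group <- rep(group_id, counts)
  flat_cog <- rep(cog, counts)
  flat_len <- pmax(50L, rep(glen, counts) +
                     as.integer(round(stats::rnorm(length(flat_genome), 0, 10))))
  membership <- NULL
  catalogs <- list()
  for (g in genomes) {
    idx <- which(flat_genome == g)
    perm <- sample.int(sizes_by_genome[g])
    pid <- sprintf("%s_%04d", g, perm)
    catalogs[[g]] <- data.frame(protein_id = pid,
                                length = flat_len[idx],
                                cog = flat_cog[idx],
                                stringsAsFactors = FALSE)
    membership <- rbind(membership,
                        data.frame(group_id = flat_group[idx], genome = g,
                                   protein_id = pid,
                                   stringsAsFactors = FALSE))
  }
  membership <- membership[order(membership$group_id, membership$genome), ]
  rownames(membership) <- NULL

  if (sequences) {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    templates <- lapply(glen, function(L) sample(aa, L, replace = TRUE))
    seq_of <- character(length(flat_genome))
    tpl_idx <- rep(seq_len(n_groups), counts)
    for (i in seq_along(seq_of)) {
      s <- templates[[tpl_idx[i]]]
      L <- flat_len[i]
      s <- if (length(s) >= L) s[seq_len(L)] else c(s, sample(aa, L - length(s), replace = TRUE))
      mut <- which(stats::runif(L) < 0.06)
      if (length(mut)) s[mut] <- sample(aa, length(mut), replace = TRUE)
      seq_of[i] <- paste(s, collapse = "")
    }
    for (g in genomes) {
      catalogs[[g]]$sequence <- seq_of[flat_genome == g]
    }
  }

  focal <- genomes[1]
  focal_ids <- catalogs[[focal]]$protein_id
  focal_cog <- stats::setNames(catalogs[[focal]]$cog, focal_ids)
  n_expr <- max(1L, as.integer(round(config$expressed_fraction *
                                       length(focal_ids))))
  expressed <- sort(sample(focal_ids, n_expr))
  differential <- plant_differentials(expressed, focal_cog, config)

  days <- unlist(config$stage_plan, use.names = FALSE)
  stage_labels <- data.frame(
    day = days,
    sample_id = paste0("d", days),
    stage = rep(names(config$stage_plan), lengths(config$stage_plan)),
    stringsAsFactors = FALSE)

  baseline <- stats::setNames(
    stats::rnorm(n_expr, mean = log10(config$baseline_count),
                 sd = config$baseline_log_sd),
    expressed)

  truth <- structure(list(membership = membership,
                          core_groups = group_id[seq_len(n_core)],
                          stage_labels = stage_labels,
                          expressed = expressed,
                          differential = differential,
                          baseline = baseline,
                          genomes = genomes,
                          focal_genome = focal),
                     class = "ground_truth")
  list(catalogs = catalogs, truth = truth)
}

# planted contrasts: a bucket mix over adjacent stage pairs and directions,
# preferentially drawn from the target COG categories
plant_differentials <- function(expressed, focal_cog, config) {
  stages <- names(config$stage_plan)
  n_diff <- as.integer(round(config$diff_fraction * length(expressed)))
  empty <- data.frame(protein_id = character(), from = character(),
                      to = character(), direction = character(),
                      log_fold = numeric(), stringsAsFactors = FALSE)
  if (n_diff == 0L || length(stages) < 2L) return(empty)
  buckets <- data.frame(
    from = c(stages[1], stages[1], stages[2], stages[2]),
    to = c(stages[2], stages[2], stages[3], stages[3]),
    direction = c("decreased", "increased", "decreased", "increased"),
    share = c(0.30, 0.30, 0.25, 0.15),
    pref = c("J", "C|E", "", ""),
    stringsAsFactors = FALSE)
  n_by <- diff(c(0, round(cumsum(buckets$share) * n_diff)))
  pool <- expressed
  rows <- empty
  for (b in seq_len(nrow(buckets))) {
    nb <- min(n_by[b], length(pool))
    if (nb == 0L) next
    w <- rep(1, length(pool))
    if (nzchar(buckets$pref[b])) {
      hit <- !is.na(focal_cog[pool]) &
        grepl(paste0("^(", buckets$pref[b], ")$"), focal_cog[pool])
      w[hit] <- 8
    }
    pick <- sample(pool, nb, prob = w)
    pool <- setdiff(pool, pick)
    rows <- rbind(rows, data.frame(protein_id = pick,
                                   from = buckets$from[b],
                                   to = buckets$to[b],
                                   direction = buckets$direction[b],
                                   log_fold = config$effect_log_fold,
                                   stringsAsFactors = FALSE))
  }
  rows[order(rows$protein_id), , drop = FALSE]
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genomes (focal %s), %d groups (%d core)\n",
              length(x$genomes), x$focal_genome,
              length(unique(x$membership$group_id)), length(x$core_groups)))
  cat(sprintf("  %d expressed focal proteins, %d with planted shifts\n",
              length(x$expressed), nrow(x$differential)))
  invisible(x)
}

#' Per-stage log10 abundance offsets of the planted contrasts
#'
#' A planted shift between stages A and B places the protein at
#' `-log_fold/2` in the stage it is low in, `+log_fold/2` in the stage it is
#' high in, and baseline elsewhere -- the two-sided contrast with the
#' largest attainable stage-to-stage difference of row Z-scores.
#'
#' @param truth a `ground_truth` object.
#' @param stages character vector of stage names in temporal order.
#' @return Matrix (expressed proteins x stages) of log10 offsets.
#' @export
planted_offsets <- function(truth, stages = unique(truth$stage_labels$stage)) {
  off <- matrix(0, nrow = length(truth$expressed), ncol = length(stages),
                dimnames = list(truth$expressed, stages))
  d <- truth$differential
  for (i in seq_len(nrow(d))) {
    e <- d$log_fold[i] / 2
    if (d$direction[i] == "increased") {
      off[d$protein_id[i], d$from[i]] <- -e
      off[d$protein_id[i], d$to[i]] <- e
    } else {
      off[d$protein_id[i], d$from[i]] <- e
      off[d$protein_id[i], d$to[i]] <- -e
    }
  }
  off
}
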