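#' Run the full quantification and orthology pipeline
#'
#' Orchestrates every stage of the analysis on in-memory inputs: peptide
#' filtering and single-count discard, protein roll-up, geochemistry-driven
#' stage assignment, length normalization, log transform, row Z-scores, the
#' presence/absence imputation, stage aggregation, delta-Z significance
#' calls, COG shift summaries, and -- when similarity tables are supplied --
#' reciprocal-best-hit ortholog groups, the all-genome core and its
#' detected-fraction summaries.
#'
#' @param psms PSM data frame (see [filter_psms()]).
#' @param catalog focal-genome catalog (`protein_id`, `length`, `cog`).
#' @param geochem geochemistry data frame (see [sqrt_transform()]), or
#'   `NULL` to supply `stages` directly.
#' @param stages optional precomputed [stage_assignment()]; overrides
#'   `geochem`.
#' @param similarity optional long-format similarity table covering all
#'   genome pairs (see [reciprocal_best_hits()]).
#' @param catalogs optional named list of all genome catalogs (required for
#'   orthology; the focal genome must be first).
#' @param filter a [filter_policy()].
#' @param zpol a [z_policy()].
#' @param k number of stages to cut the geochemistry tree into; default 3.
#' @return An object of class `corequant_run` with components `counts`,
#'   `stages`, `contiguity`, `log_matrix`, `z_matrix` (imputed), `stage_z`,
#'   `calls`, `detection`, `shift_summary`, and (with similarity input)
#'   `groups`, `core`, `fraction_table`, `detected_core_pct`.
#' @export
run_corequant <- function(psms, catalog, geochem = NULL, stages = NULL,
                          similarity = NULL, catalogs = NULL,
                          filter = filter_policy(), zpol = z_policy(),
                          k = 3L) {
  kept <- filter_psms(psms, filter)
  kept <- drop_single_count_peptides(kept, filter)
  counts <- rollup_counts(kept, catalog)
  if (is.null(stages)) {
    if (is.null(geochem)) {
      stop_corequant("supply either `geochem` or a precomputed `stages`")
    }
    stages <- cluster_stages(sqrt_transform(geochem), k = k)
  }
  detection <- detection_set(counts)
  norm <- normalize_by_length(counts, catalog)
  logm <- log_transform(norm, zpol)
  z <- zscore_rows(logm, zpol)
  zi <- impute_missing(z, zpol)
  stage_z <- stage_aggregate(zi, stages)
  calls <- call_significance(stage_z, zpol)
  cogs <- if ("cog" %in% names(catalog)) {
    stats::setNames(catalog$cog, catalog$protein_id)
  } else {
    stats::setNames(rep(NA_character_, nrow(catalog)), catalog$protein_id)
  }
  shifts <- summarize_shifts(calls, cogs, detection)
  out <- list(counts = counts, stages = stages,
              contiguity = validate_contiguity(stages),
              log_matrix = logm, z_matrix = zi, stage_z = stage_z,
              calls = calls, detection = detection, shift_summary = shifts,
              filter = filter, zpol = zpol)
  if (!is.null(similarity)) {
    if (is.null(catalogs)) {
      stop_corequant("orthology needs `catalogs` (all genomes) alongside `similarity`")
    }
    genomes <- names(catalogs)
    pairs <- utils::combn(genomes, 2L, simplify = FALSE)
    rbh <- do.call(rbind, lapply(pairs, function(p) {
      reciprocal_best_hits(similarity, p)
    }))
    groups <- build_ortholog_groups(rbh, catalogs)
    core <- core_set(groups, genomes)
    out$groups <- groups
    out$core <- core
    out$fraction_table <- fraction_table(groups, catalogs, core, detection,
                                         focal_genome = genomes[1])
    out$detected_core_pct <- detected_core_percent(core, detection, groups,
                                                   genomes[1])
  }
  structure(out, class = "corequant_run")
}

#' @export
print.corequant_run <- function(x, ...) {
  cat("<corequant_run>\n")
  cat(sprintf("  %d proteins x %d samples; %d detected in every sample\n",
              nrow(x$counts), ncol(x$counts), length(x$detection$all_samples)))
  st <- x$stages$assignment
  for (s in stage_levels(st$stage)) {
    cat(sprintf("  %-7s days %s\n", s,
                paste(sort(st$day[st$stage == s]), collapse = ", ")))
  }
  sig <- x$calls[x$calls$significant, ]
  agg <- stats::aggregate(protein_id ~ from + to + direction, sig, length)
  cat(sprintf("  %d significant stage shifts\n", nrow(sig)))
  if (nrow(agg)) {
    for (i in seq_len(nrow(agg))) {
      cat(sprintf("    %s -> %s: %d %s\n", agg$from[i], agg$to[i],
                  agg$protein_id[i], agg$direction[i]))
    }
  }
  if (!is.null(x$core)) {
    cat(sprintf("  %d ortholog groups, %d all-genome core, %.1f%% of core detected in every sample\n",
                length(x$groups$span), length(x$core), x$detected_core_pct))
  }
  invisible(x)
}

#' @export
summary.corequant_run <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$fraction_table)) {
    cat("\nPer-genome core and expressed fractions:\n")
    print(x$fraction_table, row.names = FALSE)
  }
  top <- x$shift_summary[order(-(x$shift_summary$n_increased +
                                   x$shift_summary$n_decreased)), ]
  cat("\nLargest COG-category shifts:\n")
  print(utils::head(top, 8L), row.names = FALSE)
  invisible(x)
}
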