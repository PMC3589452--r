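#' Summarize significant shifts by COG functional category
#'
#' Bins significant stage-to-stage calls into COG categories and reports,
#' per stage pair, category and direction, both percentage conventions in
#' use for such summaries: (i) the share of *all* proteins detected across
#' the experiment (the convention behind "displayed as a percentage of the
#' total number of proteins detected"), and (ii) the share of detected
#' proteins *within the category* (the convention behind statements like
#' "34% of the detected ribosomal proteins increased").  Proteins without an
#' annotation are pooled into the pseudo-category `"-"` so counts conserve.
#'
#' @param calls data frame from [call_significance()].
#' @param cogs COG annotation: data frame with `protein_id` and `cog`
#'   columns (one primary letter per protein, `NA` allowed) or a named
#'   character vector.
#' @param detected a [detection_set()]; the overall denominator is the set
#'   of proteins detected in at least one sample.
#' @return Data frame with columns `from`, `to`, `cog`, `n_detected`,
#'   `n_increased`, `n_decreased`, `pct_increased_total`,
#'   `pct_decreased_total`, `pct_increased_category`,
#'   `pct_decreased_category`; attribute `n_detected_total` carries the
#'   overall denominator.
#' @export
summarize_shifts <- function(calls, cogs, detected) {
  assert_columns(calls, c("protein_id", "from", "to", "delta_z",
                          "direction", "significant"), "calls table")
  cog_map <- as_cog_map(cogs)
  universe <- detected$any_sample
  n_total <- length(universe)
  if (n_total == 0L) stop_corequant("no detected proteins")
  cat_of <- function(ids) {
    x <- unname(cog_map[ids])
    x[is.na(x) | x == ""] <- "-"
    x
  }
  det_cat <- table(cat_of(universe))
  pairs <- unique(calls[c("from", "to")])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sub <- calls[calls$from == pairs$from[i] & calls$to == pairs$to[i] &
                   calls$significant, , drop = FALSE]
    cats <- sort(unique(c(names(det_cat), cat_of(sub$protein_id))))
    inc <- table(factor(cat_of(sub$protein_id[sub$direction == "increased"]),
                        levels = cats))
    dec <- table(factor(cat_of(sub$protein_id[sub$direction == "decreased"]),
                        levels = cats))
    ndet <- as.integer(det_cat[cats]); ndet[is.na(ndet)] <- 0L
    data.frame(from = pairs$from[i], to = pairs$to[i], cog = cats,
               n_detected = ndet,
               n_increased = as.integer(inc),
               n_decreased = as.integer(dec),
               pct_increased_total = 100 * as.integer(inc) / n_total,
               pct_decreased_total = 100 * as.integer(dec) / n_total,
               pct_increased_category =
                 ifelse(ndet > 0, 100 * as.integer(inc) / ndet, 0),
               pct_decreased_category =
                 ifelse(ndet > 0, 100 * as.integer(dec) / ndet, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  attr(out, "n_detected_total") <- n_total
  out
}

# accept a data frame or a named vector of single-letter categories
as_cog_map <- function(cogs) {
  if (is.data.frame(cogs)) {
    assert_columns(cogs, c("protein_id", "cog"), "COG annotation")
    stats::setNames(as.character(cogs$cog), cogs$protein_id)
  } else if (!is.null(names(cogs))) {
    stats::setNames(as.character(cogs), names(cogs))
  } else {
    stop_corequant("`cogs` must be a data frame or a named vector")
  }
}

#' Extract an ordered pathway matrix for heat-map export
#'
#' Pulls a named list of proteins (for example the central-metabolism
#' enzymes of interest) out of the quantification matrices, stage-aggregated
#' at both the log and Z levels, in the given order, with a flag marking
#' proteins whose ortholog group belongs to the core proteome (rendered bold
#' in heat maps).
#'
#' @param log_m an [abund_matrix()] at level `"log"`.
#' @param z_m an [abund_matrix()] at level `"zscore_imputed"` (or
#'   `"zscore"`).
#' @param proteins character vector of protein ids, in display order; an
#'   empty vector yields empty matrices without error.
#' @param stages a [stage_assignment()] or `{sample_id, stage}` data frame.
#' @param core_proteins optional character vector of core-proteome protein
#'   ids used to set the `core` flag.
#' @return List with `log` and `z` (proteins-by-stages matrices in request
#'   order) and `core` (named logical vector).
#' @export
pathway_matrix <- function(log_m, z_m, proteins, stages, core_proteins = NULL) {
  require_level(log_m, "log", "pathway_matrix")
  require_level(z_m, c("zscore", "zscore_imputed"), "pathway_matrix")
  if (length(proteins) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(list(log = empty, z = empty,
                core = stats::setNames(logical(0), character(0))))
  }
  unknown <- setdiff(proteins, rownames(log_m))
  if (length(unknown)) {
    stop_corequant(sprintf("protein id(s) not in matrix: %s",
                           paste(unknown, collapse = ", ")))
  }
  log_stage <- stage_aggregate(log_m, stages)
  z_stage <- stage_aggregate(z_m, stages)
  list(log = log_stage[proteins, , drop = FALSE],
       z = z_stage[proteins, , drop = FALSE],
       core = stats::setNames(proteins %in% (core_proteins %||% character(0)),
                              proteins))
}

#' Central-metabolism locus tags used for the default pathway export
#'
#' Locus tags of the *Geobacter bemidjiensis* enzymes tracked in the central
#' carbon/energy metabolism heat map: acetyl-CoA transferase (Gbem_0468,
#' Gbem_0795), phosphotransacetylase and acetate kinase (Gbem_2276,
#' Gbem_2277), pyruvate ferredoxin oxidoreductase (Gbem_0209), citrate
#' synthase (Gbem_3905, Gbem_1652), isocitrate dehydrogenase (Gbem_2901),
#' aconitate hydratase (Gbem_1294), succinate dehydrogenase (Gbem_3332),
#' pyruvate carboxylase (Gbem_0273), superoxide dismutase (Gbem_2204),
#' phosphate-uptake components (Gbem_4031, Gbem_1847, Gbem_1710) and NiFe
#' hydrogenase subunits (Gbem_3139, Gbem_3136, Gbem_3884).
#'
#' @format Character vector of 18 locus tags.
#' @export
central_metabolism_loci <- c(
  "Gbem_0468", "Gbem_0795", "Gbem_2276", "Gbem_2277", "Gbem_0209",
  "Gbem_3905", "Gbem_1652", "Gbem_2901", "Gbem_1294", "Gbem_3332",
  "Gbem_0273", "Gbem_2204", "Gbem_4031", "Gbem_1847", "Gbem_1710",
  "Gbem_3139", "Gbem_3136", "Gbem_3884")
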