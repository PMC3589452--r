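#' Read and write the pipeline's tabular formats
#'
#' Plain-text readers/writers for the formats the pipeline consumes and
#' emits: tab-separated PSM tables and protein catalogs, comma-separated
#' geochemistry, BLAST-outfmt-6-style similarity tables with a two-column
#' genome map, abundance matrices (level recorded in a `# level:` header
#' comment, missing cells as `NA`, the missing mask in a sibling file),
#' stage assignments, significance calls and ground-truth JSON.
#'
#' @param path file path.
#' @param x object to write.
#' @name corequant_io
NULL

#' @rdname corequant_io
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("peptide", "protein_id", "charge", "xcorr", "msgf",
                       "sample_id", "count"), basename(path))
  df
}

#' @rdname corequant_io
#' @export
write_psm_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("protein_id", "length"), basename(path))
  df
}

#' @rdname corequant_io
#' @export
write_catalog <- function(x, path) {
  utils::write.table(x[setdiff(names(x), "sequence")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
read_geochem <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("day", "fe2", "sulfide", "u6", "acetate", "sulfate"),
                 basename(path))
  df
}

#' @rdname corequant_io
#' @export
write_geochem <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @param genome_map data frame `protein_id`, `genome` (or path to a
#'   two-column TSV) attaching genomes to the 12-column table.
#' @export
read_similarity <- function(path, genome_map) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L) {
    stop_corequant(sprintf("%s: expected 12 tab-separated columns, found %d",
                           basename(path), ncol(df)))
  }
  names(df) <- cols
  if (is.character(genome_map)) {
    genome_map <- utils::read.delim(genome_map, stringsAsFactors = FALSE)
  }
  assert_columns(genome_map, c("protein_id", "genome"), "genome map")
  map <- stats::setNames(genome_map$genome, genome_map$protein_id)
  df$query_genome <- unname(map[df$query_id])
  df$subject_genome <- unname(map[df$subject_id])
  if (anyNA(df$query_genome) || anyNA(df$subject_genome)) {
    stop_corequant("similarity table contains protein ids absent from the genome map")
  }
  df[c("query_genome", "subject_genome", cols)]
}

#' @rdname corequant_io
#' @export
write_similarity <- function(x, path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
write_abund_matrix <- function(x, path) {
  stopifnot(inherits(x, "abund_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# level: %s", matrix_level(x)), con)
  utils::write.table(data.frame(protein_id = rownames(x),
                                unclass(x), check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  mask_path <- paste0(path, ".mask")
  utils::write.table(data.frame(protein_id = rownames(x),
                                missing_mask(x) * 1L, check.names = FALSE),
                     mask_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
read_abund_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  level <- sub("^# level:\\s*", "", first)
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[-1])
  rownames(vals) <- df$protein_id
  mask_path <- paste0(path, ".mask")
  mask <- NULL
  if (file.exists(mask_path)) {
    md <- utils::read.delim(mask_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    mask <- as.matrix(md[-1]) == 1L
    rownames(mask) <- md$protein_id
  }
  abund_matrix(vals, level = level, missing = mask)
}

#' @rdname corequant_io
#' @export
write_stage_assignment <- function(x, path) {
  stopifnot(inherits(x, "stage_assignment"))
  utils::write.table(x$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
read_stage_assignment <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stage_assignment(df)
}

#' @rdname corequant_io
#' @export
write_calls <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corequant_io
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname corequant_io
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$membership <- as.data.frame(raw$membership, stringsAsFactors = FALSE)
  raw$stage_labels <- as.data.frame(raw$stage_labels, stringsAsFactors = FALSE)
  raw$differential <- as.data.frame(raw$differential, stringsAsFactors = FALSE)
  raw$baseline <- unlist(raw$baseline)
  structure(raw, class = "ground_truth")
}

#' @rdname corequant_io
#' @param catalog catalog data frame carrying a `sequence` column.
#' @export
write_catalog_fasta <- function(catalog, path) {
  if (is.null(catalog$sequence)) {
    stop_corequant("catalog has no sequences; regenerate with gen_catalogs(..., sequences = TRUE)")
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_corequant("Biostrings is required for FASTA export")
  }
  aa <- Biostrings::AAStringSet(stats::setNames(catalog$sequence,
                                                catalog$protein_id))
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Write every component of a simulated experiment to a directory
#'
#' @param sim a `corequant_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dir <- function(sim, dir) {
  stopifnot(inherits(sim, "corequant_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$catalogs)) {
    write_catalog(sim$catalogs[[g]], file.path(dir, paste0("catalog_", g, ".tsv")))
    if (!is.null(sim$catalogs[[g]]$sequence)) {
      write_catalog_fasta(sim$catalogs[[g]], file.path(dir, paste0(g, ".faa")))
    }
  }
  write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
  write_similarity(sim$similarity, file.path(dir, "similarity.tsv"))
  gm <- do.call(rbind, lapply(names(sim$catalogs), function(g) {
    data.frame(protein_id = sim$catalogs[[g]]$protein_id, genome = g,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gm, file.path(dir, "genome_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_geochem(sim$geochem, file.path(dir, "geochem.csv"))
  write_ground_truth(sim$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
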