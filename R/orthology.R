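#' Reciprocal best hits between two genomes
#'
#' Declares proteins `a` (genome A) and `b` (genome B) orthologous when `b`
#' is `a`'s highest-scoring subject in the A-to-B table **and** `a` is `b`'s
#' highest-scoring subject in the B-to-A table.  Best hits are ranked by
#' bitscore; ties are broken by higher percent identity, then by
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param rows similarity table (long format) with columns `query_id`,
#'   `subject_id`, `query_genome`, `subject_genome`, `pident`, `bitscore`;
#'   must contain rows for both directions of the pair.
#' @param genome_pair character vector of the two genome labels.
#' @return Data frame of ortholog pairs with columns `genome_a`,
#'   `protein_a`, `genome_b`, `protein_b`, `bitscore` (mean of the two
#'   directions' best scores).  `genome_a`/`genome_b` follow the order of
#'   `genome_pair`.
#' @export
reciprocal_best_hits <- function(rows, genome_pair) {
  assert_columns(rows, c("query_id", "subject_id", "query_genome",
                         "subject_genome", "pident", "bitscore"),
                 "similarity table")
  if (length(genome_pair) != 2L || genome_pair[1] == genome_pair[2]) {
    stop_corequant("`genome_pair` must name two distinct genomes")
  }
  a <- genome_pair[1]; b <- genome_pair[2]
  ab <- rows[rows$query_genome == a & rows$subject_genome == b, , drop = FALSE]
  ba <- rows[rows$query_genome == b & rows$subject_genome == a, , drop = FALSE]
  if (nrow(ab) == 0L && nrow(ba) == 0L) {
    return(data.frame(genome_a = character(), protein_a = character(),
                      genome_b = character(), protein_b = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    stop_corequant(sprintf(
      "similarity table covers only one direction of (%s, %s); both are required",
      a, b))
  }
  best_ab <- best_hits(ab)
  best_ba <- best_hits(ba)
  m <- merge(best_ab, best_ba,
             by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_ab", "_ba"))
  if (nrow(m) == 0L) {
    return(data.frame(genome_a = character(), protein_a = character(),
                      genome_b = character(), protein_b = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(genome_a = a, protein_a = m$query_id,
                    genome_b = b, protein_b = m$subject_id,
                    bitscore = (m$bitscore_ab + m$bitscore_ba) / 2,
                    stringsAsFactors = FALSE)
  out[order(out$protein_a), , drop = FALSE]
}

# top subject per query: bitscore desc, pident desc, subject id asc
best_hits <- function(tab) {
  ord <- order(tab$query_id, -tab$bitscore, -tab$pident, tab$subject_id)
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$query_id), c("query_id", "subject_id", "bitscore"),
      drop = FALSE]
}

#' Build ortholog groups from pairwise reciprocal best hits
#'
#' Groups are the connected components of the graph whose vertices are
#' `(genome, protein)` pairs and whose edges are the RBH pairs pooled over
#' all genome pairs.  A component that acquires two proteins of the same
#' genome (possible once similarity tables are noisy) is resolved by
#' repeatedly deleting its lowest-bitscore edge until every component is
#' genome-unique; the deletion order is deterministic.
#'
#' @param pairs data frame as returned by [reciprocal_best_hits()], rows
#'   pooled over genome pairs (zero rows allowed).
#' @param catalogs optional list of catalog data frames (one per genome,
#'   names = genome labels); when supplied, catalog proteins that joined no
#'   pair are added as singleton groups.
#' @return An `ortholog_groups` object: list with `membership` (data frame
#'   `group_id`, `genome`, `protein_id`) and `span` (list mapping group id
#'   to its genome set).
#' @export
build_ortholog_groups <- function(pairs, catalogs = NULL) {
  vertex_id <- function(genome, protein) paste(genome, protein, sep = "\r")
  if (nrow(pairs)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = vertex_id(pairs$genome_a, pairs$protein_a),
                 to = vertex_id(pairs$genome_b, pairs$protein_b),
                 weight = pairs$bitscore, stringsAsFactors = FALSE),
      directed = FALSE)
    g <- resolve_genome_conflicts(g)
    comp <- igraph::components(g)$membership
    verts <- names(comp)
  } else {
    comp <- integer(0)
    verts <- character(0)
  }
  if (!is.null(catalogs)) {
    extra <- unlist(lapply(names(catalogs), function(gn) {
      vertex_id(gn, catalogs[[gn]]$protein_id)
    }))
    extra <- setdiff(extra, verts)
    if (length(extra)) {
      comp <- c(comp, stats::setNames(max(comp, 0L) + seq_along(extra), extra))
      verts <- c(verts, extra)
    }
  }
  if (!length(verts)) {
    stop_corequant("no pairs and no catalogs; nothing to group")
  }
  parts <- do.call(rbind, strsplit(verts, "\r", fixed = TRUE))
  ord <- order(comp, parts[, 1], parts[, 2])
  gid <- sprintf("OG%05d", match(comp[ord], unique(comp[ord])))
  membership <- data.frame(group_id = gid,
                           genome = parts[ord, 1],
                           protein_id = parts[ord, 2],
                           stringsAsFactors = FALSE)
  ortholog_groups(membership)
}

# drop weakest in-component edges until no component holds two proteins of
# the same genome
resolve_genome_conflicts <- function(g) {
  repeat {
    comp <- igraph::components(g)$membership  # named by vertex
    genome_of <- vapply(strsplit(names(comp), "\r", fixed = TRUE),
                        `[[`, character(1), 1L)
    dup <- tapply(genome_of, comp, anyDuplicated)
    bad <- names(dup)[dup > 0]
    if (!length(bad)) return(g)
    cid <- as.integer(bad[1])
    ends <- igraph::ends(g, igraph::E(g))
    in_comp <- which(comp[ends[, 1]] == cid & comp[ends[, 2]] == cid)
    w <- igraph::E(g)$weight[in_comp]
    # deterministic: lowest bitscore first, then lexicographic endpoints
    pick <- in_comp[order(w, ends[in_comp, 1], ends[in_comp, 2])[1]]
    g <- igraph::delete_edges(g, pick)
  }
}

#' Construct an ortholog group set
#'
#' @param membership data frame with `group_id`, `genome`, `protein_id`;
#'   a protein may belong to at most one group.
#' @return An object of class `ortholog_groups`.
#' @export
ortholog_groups <- function(membership) {
  assert_columns(membership, c("group_id", "genome", "protein_id"),
                 "group membership")
  key <- paste(membership$genome, membership$protein_id)
  if (anyDuplicated(key)) {
    stop_corequant("a protein may belong to at most one group")
  }
  span <- lapply(split(membership$genome, membership$group_id), unique)
  structure(list(membership = membership, span = span),
            class = "ortholog_groups")
}

#' @export
print.ortholog_groups <- function(x, ...) {
  sizes <- lengths(x$span)
  cat(sprintf("<ortholog_groups> %d groups over %d genomes; span histogram:\n",
              length(x$span), length(unique(x$membership$genome))))
  print(table(span = sizes))
  invisible(x)
}

#' Groups spanning every genome (the core proteome)
#'
#' @param groups an [ortholog_groups()] object.
#' @param genomes character vector of all genome labels that must be covered.
#' @return Character vector of core group ids.
#' @export
core_set <- function(groups, genomes) {
  if (!length(genomes)) stop_corequant("`genomes` must be non-empty")
  keep <- vapply(groups$span, function(s) all(genomes %in% s), logical(1))
  names(groups$span)[keep]
}

#' Per-sample detection sets from a counts matrix
#'
#' @param counts an [abund_matrix()] at level `"counts"` (focal genome).
#' @return A `detection_set`: list with `per_sample` (named list of detected
#'   protein ids), `all_samples` (proteins detected in every sample) and
#'   `any_sample` (proteins detected at least once).
#' @export
detection_set <- function(counts) {
  require_level(counts, "counts", "detection_set")
  miss <- missing_mask(counts)
  per_sample <- lapply(seq_len(ncol(counts)), function(j) {
    rownames(counts)[!miss[, j]]
  })
  names(per_sample) <- colnames(counts)
  structure(list(per_sample = per_sample,
                 all_samples = Reduce(intersect, per_sample),
                 any_sample = sort(unique(unlist(per_sample)))),
            class = "detection_set")
}

#' Table-1-style per-genome core and expressed fractions
#'
#' For each genome: the protein-coding count, the percentage of its proteins
#' belonging to all-genome core groups, and the "expressed fraction" -- the
#' focal genome's core proteins detected in **all** samples, expressed as a
#' percentage of each genome's size (the original analysis extrapolates the
#' focal detection set across genomes, which is reproduced literally).
#' Percentages are rounded to the nearest integer, ties away from zero.
#'
#' @param groups an [ortholog_groups()] object.
#' @param catalogs named list of catalog data frames (or bare protein-id
#'   vectors), one per genome; names give the genome order of the table.
#' @param core character vector of core group ids from [core_set()].
#' @param detection a [detection_set()] for the focal genome.
#' @param focal_genome label of the genome the detections refer to; default
#'   the first catalog.
#' @return Data frame with one row per genome: `genome`, `n_proteins`,
#'   `n_core`, `core_pct`, `n_expressed_core`, `expressed_pct`.
#' @export
fraction_table <- function(groups, catalogs, core, detection,
                           focal_genome = names(catalogs)[1]) {
  sizes <- vapply(catalogs, function(x) {
    n <- if (is.data.frame(x)) nrow(x) else length(x)
    if (n == 0L) stop_corequant("empty catalog supplied")
    n
  }, integer(1))
  mem <- groups$membership
  core_focal <- mem$protein_id[mem$group_id %in% core &
                                 mem$genome == focal_genome]
  n_core <- length(core)
  n_expr <- length(intersect(core_focal, detection$all_samples))
  data.frame(genome = names(catalogs),
             n_proteins = as.integer(sizes),
             n_core = n_core,
             core_pct = as.integer(round_half_up(100 * n_core / sizes)),
             n_expressed_core = n_expr,
             expressed_pct = as.integer(round_half_up(100 * n_expr / sizes)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of the core proteome detected in every sample
#'
#' @param core character vector of core group ids.
#' @param detection a [detection_set()] for the focal genome.
#' @param groups an [ortholog_groups()] object (to map groups to focal
#'   proteins).
#' @param focal_genome focal genome label.
#' @return Percentage (0-100) of core groups whose focal protein is in the
#'   all-samples intersection.
#' @export
detected_core_percent <- function(core, detection, groups, focal_genome) {
  if (!length(core)) stop_corequant("core set is empty")
  mem <- groups$membership
  core_focal <- mem$protein_id[mem$group_id %in% core &
                                 mem$genome == focal_genome]
  100 * length(intersect(core_focal, detection$all_samples)) / length(core)
}

#' Detected focal proteins shared between two genomes
#'
#' Counts the focal genome's detected proteins (detected in at least one
#' sample) whose ortholog group spans both named genomes.
#'
#' @param groups an [ortholog_groups()] object.
#' @param detection a [detection_set()] for the focal genome.
#' @param genome_a,genome_b genome labels; `genome_a` is the focal genome.
#' @return Integer count.
#' @export
shared_detected <- function(groups, detection, genome_a, genome_b) {
  mem <- groups$membership
  known <- unique(mem$genome)
  for (g in c(genome_a, genome_b)) {
    if (!g %in% known) stop_corequant(sprintf("unknown genome '%s'", g))
  }
  spans_both <- vapply(groups$span, function(s) {
    genome_a %in% s && genome_b %in% s
  }, logical(1))
  gids <- names(groups$span)[spans_both]
  focal <- mem$protein_id[mem$group_id %in% gids & mem$genome == genome_a]
  length(intersect(focal, detection$any_sample))
}

#' Histogram of group span sizes
#'
#' Number of ortholog groups by the number of genomes they cover; the
#' counts sum to the total number of groups.
#'
#' @param groups an [ortholog_groups()] object.
#' @return Named integer vector indexed by span size.
#' @export
span_histogram <- function(groups) {
  table(factor(lengths(groups$span)))
}
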