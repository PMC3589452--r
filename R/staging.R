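#' Square-root transform a geochemistry series into a feature matrix
#'
#' Takes the five analyte columns (ferrous iron, sulfide, uranium(VI),
#' acetate, sulfate), applies an element-wise square root -- the variance-
#' stabilizing transform used before sample clustering -- and returns a
#' features matrix with one row per sampling day.  The day column is kept as
#' row names, not as a feature.  Analytes stay in their native units
#' (micromolar for Fe(II), sulfide and U(VI); millimolar for acetate and
#' sulfate); set `standardize = TRUE` to z-scale the transformed columns if
#' unit harmonization is wanted.
#'
#' @param samples data frame with columns `day`, `fe2`, `sulfide`, `u6`,
#'   `acetate`, `sulfate`; days strictly increasing, concentrations
#'   non-negative.
#' @param standardize logical; scale each transformed column to zero mean and
#'   unit variance.  Default `FALSE`.
#' @return Numeric matrix of square-rooted analyte values, row names the
#'   sampling days.
#' @export
sqrt_transform <- function(samples, standardize = FALSE) {
  analytes <- c("fe2", "sulfide", "u6", "acetate", "sulfate")
  assert_columns(samples, c("day", analytes), "geochemistry series")
  if (is.unsorted(samples$day, strictly = TRUE)) {
    stop_corequant("days must be strictly increasing")
  }
  vals <- as.matrix(samples[analytes])
  if (any(vals < 0)) {
    stop_corequant("negative concentration encountered; all analytes must be >= 0")
  }
  feats <- sqrt(vals)
  if (standardize) feats <- scale(feats)
  rownames(feats) <- as.character(samples$day)
  feats[, , drop = FALSE]
}

#' Bin samples into experiment stages by hierarchical clustering
#'
#' Clusters the sampling days on Euclidean distances between their
#' (square-root transformed) geochemical profiles with average-linkage
#' (UPGMA) agglomeration -- `stats::dist()` plus `stats::hclust()` -- and
#' cuts the tree into `k` groups.  Groups are labelled by ascending mean
#' sampling day: with the default `k = 3` they become `early`, `middle`,
#' `late`; other `k` get `S1 ... Sk`.  Equal-distance merges are resolved by
#' `hclust`'s internal ordering; with continuous geochemical measurements
#' exact ties do not arise in practice.
#'
#' @param features numeric matrix from [sqrt_transform()] (rows = days).
#' @param k number of stages; default 3.
#' @param sample_ids optional sample labels parallel to the feature rows;
#'   default `"d<day>"`.
#' @return A `stage_assignment`: list with `assignment` (data frame `day`,
#'   `sample_id`, `stage`), `tree` (the `hclust` object) and `k`.
#' @export
cluster_stages <- function(features, k = 3L, sample_ids = NULL) {
  if (!is.matrix(features) || is.null(rownames(features))) {
    stop_corequant("`features` must be a matrix with day row names (see sqrt_transform())")
  }
  n <- nrow(features)
  if (k > n) stop_corequant(sprintf("k = %d exceeds the %d samples", k, n))
  if (k < 1L) stop_corequant("k must be >= 1")
  days <- as.numeric(rownames(features))
  sample_ids <- sample_ids %||% paste0("d", rownames(features))
  tree <- stats::hclust(stats::dist(features, method = "euclidean"),
                        method = "average")
  cut <- stats::cutree(tree, k = k)
  mean_day <- tapply(days, cut, mean)
  ord <- order(mean_day)  # temporal labelling: earliest mean day first
  labels <- if (k == 3L) c("early", "middle", "late") else paste0("S", seq_len(k))
  stage <- labels[match(cut, as.integer(names(mean_day))[ord])]
  stage_assignment(data.frame(day = days, sample_id = sample_ids,
                              stage = stage, stringsAsFactors = FALSE),
                   tree = tree, k = k)
}

#' Construct a stage assignment
#'
#' @param assignment data frame with columns `day`, `sample_id`, `stage`.
#' @param tree optional `hclust` object that produced the assignment.
#' @param k number of stages.
#' @return An object of class `stage_assignment`.
#' @export
stage_assignment <- function(assignment, tree = NULL, k = length(unique(assignment$stage))) {
  assert_columns(assignment, c("day", "sample_id", "stage"), "stage assignment")
  if (anyDuplicated(assignment$sample_id)) {
    stop_corequant("each sample must be assigned exactly once")
  }
  structure(list(assignment = assignment, tree = tree, k = k),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("<stage_assignment> %d samples in %d stage(s)\n",
              nrow(x$assignment), x$k))
  for (s in stage_levels(x$assignment$stage)) {
    d <- x$assignment$day[x$assignment$stage == s]
    cat(sprintf("  %-7s days %s\n", s, paste(sort(d), collapse = ", ")))
  }
  invisible(x)
}

#' Check that each stage covers a contiguous run of sampling days
#'
#' A stage is contiguous when its member days occupy an unbroken block of
#' the time-ordered sampling days (no interleaving with another stage).
#' Contiguity is reported, not enforced: an assignment produced by the
#' clustering is returned as-is even when a stage straddles another.
#'
#' @param assignment a [stage_assignment()].
#' @return List with `contiguous` (logical) and `offending` (character
#'   vector of non-contiguous stage labels, empty when clean).
#' @export
validate_contiguity <- function(assignment) {
  a <- assignment$assignment
  a <- a[order(a$day), ]
  runs <- rle(a$stage)$values
  offending <- unique(runs[duplicated(runs)])
  list(contiguous = length(offending) == 0L, offending = offending)
}

#' Export the stage tree in Newick format
#'
#' @param assignment a [stage_assignment()] whose `tree` is set.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
stage_tree_newick <- function(assignment, file = NULL) {
  if (is.null(assignment$tree)) {
    stop_corequant("assignment carries no clustering tree")
  }
  phy <- ape::as.phylo(assignment$tree)
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
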