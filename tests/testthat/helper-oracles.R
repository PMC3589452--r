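# Independent oracles and shared fixtures for the test suite.
# These deliberately re-derive results by brute force, not by calling the
# package's own code paths.

# O(n^3) UPGMA: at every step scan all cluster pairs and merge the one with
# the smallest mean pairwise member distance.
brute_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    m <- length(clusters)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best) {
          best <- dij
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    members[[length(members) + 1L]] <- merged
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  list(heights = heights, members = members)
}

# member sets after each hclust merge step
hclust_members <- function(hc) {
  n <- length(hc$height)
  sets <- vector("list", n)
  for (k in seq_len(n)) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  sets
}

# brute-force reciprocal best hits on dense score/pident matrices:
# (i, j) is a pair iff j beats every other subject of i and i beats every
# other query of j, under (bitscore desc, pident desc, name asc)
brute_rbh <- function(score_ab, pident_ab, score_ba, pident_ba) {
  beats <- function(s1, p1, n1, s2, p2, n2) {
    s1 > s2 || (s1 == s2 && (p1 > p2 || (p1 == p2 && n1 < n2)))
  }
  qa <- rownames(score_ab)
  qb <- colnames(score_ab)
  pairs <- NULL
  for (i in seq_along(qa)) {
    for (j in seq_along(qb)) {
      top_for_i <- all(vapply(seq_along(qb)[-j], function(j2) {
        beats(score_ab[i, j], pident_ab[i, j], qb[j],
              score_ab[i, j2], pident_ab[i, j2], qb[j2])
      }, logical(1)))
      top_for_j <- all(vapply(seq_along(qa)[-i], function(i2) {
        beats(score_ba[j, i], pident_ba[j, i], qa[i],
              score_ba[j, i2], pident_ba[j, i2], qa[i2])
      }, logical(1)))
      if (top_for_i && top_for_j) {
        pairs <- rbind(pairs, data.frame(protein_a = qa[i], protein_b = qb[j],
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(protein_a = character(), protein_b = character(),
                        stringsAsFactors = FALSE)
  }
  pairs[order(pairs$protein_a), , drop = FALSE]
}

# long-format similarity table from dense matrices (both directions)
sim_table_from_matrices <- function(score_ab, pident_ab, score_ba, pident_ba,
                                    genome_a = "A", genome_b = "B") {
  long <- function(score, pident, ga, gb) {
    data.frame(query_genome = ga, subject_genome = gb,
               query_id = rep(rownames(score), ncol(score)),
               subject_id = rep(colnames(score), each = nrow(score)),
               pident = as.vector(pident), bitscore = as.vector(score),
               stringsAsFactors = FALSE)
  }
  rbind(long(score_ab, pident_ab, genome_a, genome_b),
        long(score_ba, pident_ba, genome_b, genome_a))
}

# small, quick simulation configuration used across tests
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_genomes = 3L,
             genome_sizes = c(Gbem = 80L, GM21 = 90L, GM18 = 70L),
             core_fraction = 0.3, seed = seed, ...)
}

# stage table matching the default nine-day plan without clustering
planned_stages <- function(truth) {
  stage_assignment(truth$stage_labels)
}

expected_default_stages <- rep(c("early", "middle", "late"), each = 3L)

# independent nearest-integer (ties up) rounding used to check reported
# percentages
round_half_up_oracle <- function(x) floor(x + 0.5)

# printed-scale orthology fixture: `n_core` groups spanning every genome
# (one protein each), with the first `n_detected` focal core proteins
# detected in all nine samples
build_printed_scale_fixture <- function(sizes, n_core, n_detected) {
  genomes <- names(sizes)
  catalogs <- lapply(genomes, function(g) {
    data.frame(protein_id = sprintf("%s_%04d", g, seq_len(sizes[[g]])),
               length = 300L, stringsAsFactors = FALSE)
  })
  names(catalogs) <- genomes
  mem <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(group_id = sprintf("OG%05d", seq_len(n_core)), genome = g,
               protein_id = sprintf("%s_%04d", g, seq_len(n_core)),
               stringsAsFactors = FALSE)
  }))
  groups <- ortholog_groups(mem)
  det_ids <- sprintf("%s_%04d", genomes[1], seq_len(n_detected))
  samples <- paste0("d", 1:9)
  detection <- structure(list(per_sample = stats::setNames(rep(list(det_ids), 9),
                                                           samples),
                              all_samples = det_ids, any_sample = det_ids),
                         class = "detection_set")
  list(catalogs = catalogs, groups = groups,
       core = sprintf("OG%05d", seq_len(n_core)), detection = detection)
}
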