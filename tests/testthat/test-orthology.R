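test_that("mutual top hits are paired and one-sided preferences are not", {
  # a1<->b1 mutual; a2's best is b1 but b1 prefers a1, so a2 stays unpaired
  score_ab <- rbind(a1 = c(b1 = 500, b2 = 100),
                    a2 = c(b1 = 400, b2 = 150))
  score_ba <- rbind(b1 = c(a1 = 500, a2 = 390),
                    b2 = c(a1 = 90, a2 = 160))
  tab <- sim_table_from_matrices(score_ab, score_ab * 0 + 50,
                                 score_ba, score_ba * 0 + 50)
  pairs <- reciprocal_best_hits(tab, c("A", "B"))
  expect_equal(pairs$protein_a, "a1")
  expect_equal(pairs$protein_b, "b1")
  # b2<->a2 are each other's best by elimination
  score_ba["b2", "a2"] <- 160
  score_ab["a2", "b2"] <- 450
  tab2 <- sim_table_from_matrices(score_ab, score_ab * 0 + 50,
                                  score_ba, score_ba * 0 + 50)
  pairs2 <- reciprocal_best_hits(tab2, c("A", "B"))
  expect_equal(pairs2$protein_a, c("a1", "a2"))
  expect_equal(pairs2$protein_b, c("b1", "b2"))
})

test_that("one-directional similarity tables are rejected, empty input yields no pairs", {
  score <- rbind(a1 = c(b1 = 500))
  tab <- sim_table_from_matrices(score, score * 0 + 90, t(score), t(score) * 0 + 90)
  one_way <- tab[tab$query_genome == "A", ]
  expect_error(reciprocal_best_hits(one_way, c("A", "B")), "both")
  empty <- tab[0, ]
  expect_equal(nrow(reciprocal_best_hits(empty, c("A", "B"))), 0L)
})

test_that("RBH matches brute-force enumeration on 100 random score matrices", {
  for (seed in 1:100) {
    set.seed(seed)
    na <- sample(4:6, 1); nb <- sample(4:6, 1)
    score_ab <- matrix(sample(50:500, na * nb), na, nb,
                       dimnames = list(paste0("a", seq_len(na)),
                                       paste0("b", seq_len(nb))))
    score_ba <- matrix(sample(50:500, na * nb), nb, na,
                       dimnames = list(colnames(score_ab), rownames(score_ab)))
    pid_ab <- matrix(round(runif(na * nb, 30, 100), 1), na, nb,
                     dimnames = dimnames(score_ab))
    pid_ba <- matrix(round(runif(na * nb, 30, 100), 1), nb, na,
                     dimnames = dimnames(score_ba))
    tab <- sim_table_from_matrices(score_ab, pid_ab, score_ba, pid_ba)
    got <- reciprocal_best_hits(tab, c("A", "B"))
    want <- brute_rbh(score_ab, pid_ab, score_ba, pid_ba)
    expect_equal(got$protein_a, want$protein_a)
    expect_equal(got$protein_b, want$protein_b)
    # symmetry in genome order
    rev <- reciprocal_best_hits(tab, c("B", "A"))
    expect_setequal(paste(got$protein_a, got$protein_b),
                    paste(rev$protein_b, rev$protein_a))
  }
})

test_that("bitscore ties fall back to pident and then subject id", {
  score_ab <- rbind(a1 = c(b1 = 300, b2 = 300))
  score_ba <- rbind(b1 = c(a1 = 300), b2 = c(a1 = 300))
  pid_ab <- rbind(a1 = c(b1 = 60, b2 = 90))
  pid_ba <- rbind(b1 = c(a1 = 80), b2 = c(a1 = 80))
  tab <- sim_table_from_matrices(score_ab, pid_ab, score_ba, pid_ba)
  expect_equal(reciprocal_best_hits(tab, c("A", "B"))$protein_b, "b2")
  # equal pident too: lexicographically smaller subject wins
  pid_ab["a1", "b2"] <- 60
  tab <- sim_table_from_matrices(score_ab, pid_ab, score_ba, pid_ba)
  expect_equal(reciprocal_best_hits(tab, c("A", "B"))$protein_b, "b1")
})

test_that("groups are connected components; chains span genomes; no pairs means singletons", {
  pairs <- data.frame(genome_a = c("A", "B"), protein_a = c("a1", "b1"),
                      genome_b = c("B", "C"), protein_b = c("b1", "c1"),
                      bitscore = c(500, 480), stringsAsFactors = FALSE)
  groups <- build_ortholog_groups(pairs)
  expect_equal(length(groups$span), 1L)
  expect_setequal(groups$span[[1]], c("A", "B", "C"))
  cats <- list(A = data.frame(protein_id = c("a1", "a2")),
               B = data.frame(protein_id = "b1"))
  lone <- build_ortholog_groups(pairs[0, ], cats)
  expect_equal(length(lone$span), 3L)
  expect_true(all(lengths(lone$span) == 1L))
})

test_that("same-genome conflicts are resolved by dropping the weakest edge", {
  # a1-b1 (500) and a2-b1 (300): one component with two A proteins; the
  # 300 edge goes, leaving {a1, b1} and singleton a2
  pairs <- data.frame(genome_a = c("A", "A"), protein_a = c("a1", "a2"),
                      genome_b = c("B", "B"), protein_b = c("b1", "b1"),
                      bitscore = c(500, 300), stringsAsFactors = FALSE)
  cats <- list(A = data.frame(protein_id = c("a1", "a2")),
               B = data.frame(protein_id = "b1"))
  groups <- build_ortholog_groups(pairs, cats)
  multi <- groups$membership[groups$membership$group_id %in%
                               names(groups$span)[lengths(groups$span) > 1], ]
  expect_setequal(paste(multi$genome, multi$protein_id), c("A a1", "B b1"))
})

test_that("core extraction, monotonicity and the span histogram accounting hold", {
  mem <- data.frame(
    group_id = c("g1", "g1", "g1", "g2", "g2", "g3"),
    genome = c("A", "B", "C", "A", "B", "C"),
    protein_id = c("a1", "b1", "c1", "a2", "b2", "c2"),
    stringsAsFactors = FALSE)
  groups <- ortholog_groups(mem)
  expect_equal(core_set(groups, c("A", "B", "C")), "g1")
  expect_setequal(core_set(groups, c("A", "B")), c("g1", "g2"))
  # adding a required genome can only shrink the core
  expect_lte(length(core_set(groups, c("A", "B", "C"))),
             length(core_set(groups, c("A", "B"))))
  h <- span_histogram(groups)
  expect_equal(sum(h), length(groups$span))
  expect_equal(as.integer(h[c("1", "2", "3")]), c(1L, 1L, 1L))
})

test_that("noiseless synthetic recovery: groups, core and summaries equal the ledger", {
  cfg <- tiny_config(seed = 21, dropout_rate = 0, count_noise = "none")
  sim <- simulate_dataset(cfg)
  genomes <- names(sim$catalogs)
  pairs <- do.call(rbind, lapply(utils::combn(genomes, 2, simplify = FALSE),
                                 function(p) reciprocal_best_hits(sim$similarity, p)))
  groups <- build_ortholog_groups(pairs, sim$catalogs)
  part <- function(mem) {
    sp <- lapply(split(paste(mem$genome, mem$protein_id), mem$group_id), sort)
    sort(unname(vapply(sp[lengths(sp) > 1], paste, "", collapse = "|")))
  }
  expect_identical(part(groups$membership), part(sim$truth$membership))
  core <- core_set(groups, genomes)
  expect_equal(length(core), length(sim$truth$core_groups))
  expect_equal(length(groups$span), length(unique(sim$truth$membership$group_id)))
})

test_that("detection-based summaries reproduce brute-force set arithmetic", {
  cfg <- tiny_config(seed = 22, dropout_rate = 0, count_noise = "none")
  sim <- simulate_dataset(cfg)
  run <- run_corequant(sim$psms, sim$catalogs[[1]],
                       stages = planned_stages(sim$truth),
                       similarity = sim$similarity, catalogs = sim$catalogs)
  truth <- sim$truth
  focal <- truth$focal_genome
  # noiseless, dropout-free: detected-in-any == detected-in-all == expressed
  expect_identical(sort(run$detection$all_samples), truth$expressed)
  # shared_detected against a brute-force intersection over the ledger
  mem <- truth$membership
  for (other in setdiff(names(sim$catalogs), focal)) {
    gids <- intersect(mem$group_id[mem$genome == focal],
                      mem$group_id[mem$genome == other])
    want <- length(intersect(mem$protein_id[mem$genome == focal &
                                              mem$group_id %in% gids],
                             truth$expressed))
    expect_equal(shared_detected(run$groups, run$detection, focal, other), want)
  }
  expect_error(shared_detected(run$groups, run$detection, focal, "nope"),
               "unknown genome")
  # detected core percent equals the ledger-based hand count
  core_focal_ids <- mem$protein_id[mem$genome == focal &
                                     mem$group_id %in% truth$core_groups]
  want_pct <- 100 * length(intersect(core_focal_ids, truth$expressed)) /
    length(run$core)
  expect_equal(detected_core_percent(run$core, run$detection, run$groups, focal),
               want_pct)
})

test_that("fraction_table reproduces the printed per-genome percentage grid", {
  # genomes at their published protein-coding sizes; a core of 1116 groups
  # and 530 focal core proteins detected in every sample
  sizes <- c(Gbem = 4034L, GM21 = 4152L, GM18 = 4523L, Gura = 4430L,
             GFRC32 = 3839L, Gsul = 3465L, Gmet = 3576L, Glov = 3725L)
  built <- build_printed_scale_fixture(sizes, n_core = 1116L, n_detected = 530L)
  ft <- fraction_table(built$groups, built$catalogs, built$core,
                       built$detection, focal_genome = "Gbem")
  expect_equal(ft$core_pct,
               c(28L, 27L, 25L, 25L, 29L, 32L, 31L, 30L))
  expect_equal(ft$expressed_pct,
               c(13L, 13L, 12L, 12L, 14L, 15L, 15L, 14L))
  # empty core: all-zero percentages
  ft0 <- fraction_table(built$groups, built$catalogs, character(0),
                        built$detection, focal_genome = "Gbem")
  expect_true(all(ft0$core_pct == 0L))
  expect_error(fraction_table(built$groups,
                              c(built$catalogs[1], list(X = built$catalogs[[1]][0, ])),
                              built$core, built$detection),
               "empty catalog")
})
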