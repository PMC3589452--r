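test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genomes = 2, genome_sizes = c(A = 0, B = 10)),
               "positive")
  expect_error(sim_config(core_fraction = 1.2), "core_fraction")
  expect_error(sim_config(dropout_rate = -0.1), "dropout_rate")
  expect_error(sim_config(n_samples = 8), "n_samples")
  # per-stage dropout must cover every stage
  expect_error(sim_config(dropout_rate = c(early = 0.1)), "every stage")
  expect_s3_class(tiny_config(), "sim_config")
})

test_that("full-core and empty-core constructions bracket the group structure", {
  cfg <- sim_config(n_genomes = 2, genome_sizes = c(A = 10L, B = 10L),
                    core_fraction = 1.0, seed = 5)
  ct <- gen_catalogs(cfg)
  mem <- ct$truth$membership
  spans <- lengths(lapply(split(mem$genome, mem$group_id), unique))
  expect_true(all(spans == 2L))  # every protein has exactly one ortholog
  expect_equal(nrow(ct$catalogs$A), 10L)
  cfg0 <- sim_config(n_genomes = 3, genome_sizes = c(A = 30L, B = 30L, C = 30L),
                     core_fraction = 0, seed = 5)
  mem0 <- gen_catalogs(cfg0)$truth$membership
  spans0 <- lengths(lapply(split(mem0$genome, mem0$group_id), unique))
  expect_true(all(spans0 < 3L))  # zero all-genome groups
  expect_equal(length(gen_catalogs(cfg0)$truth$core_groups), 0L)
})

test_that("the all-genome core count equals round(core_fraction x smallest genome)", {
  cfg <- sim_config(seed = 1, core_fraction = 0.28,
                    genome_sizes = c(Gbem = 403L, GM21 = 415L, GM18 = 452L,
                                     Gura = 443L, GFRC32 = 384L, Gsul = 347L,
                                     Gmet = 358L, Glov = 372L))
  truth <- gen_catalogs(cfg)$truth
  expect_equal(length(truth$core_groups), round(0.28 * 347))
  mem <- truth$membership
  spans <- lengths(lapply(split(mem$genome, mem$group_id), unique))
  expect_equal(sum(spans == 8L), round(0.28 * 347))
  # catalog sizes honour the configuration exactly
  cats <- gen_catalogs(cfg)$catalogs
  expect_equal(unname(vapply(cats, nrow, 1L)), unname(cfg$genome_sizes))
  expect_error(gen_catalogs(sim_config(n_genomes = 2,
                                       genome_sizes = c(A = -5, B = 10))),
               "positive")
})

test_that("generators are deterministic: same seed, identical output", {
  cfg <- tiny_config(seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$catalogs, s2$catalogs)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$psms, s2$psms)
  expect_identical(s1$similarity, s2$similarity)
  expect_identical(s1$geochem, s2$geochem)
  s3 <- simulate_dataset(tiny_config(seed = 78))
  expect_false(identical(s1$psms, s3$psms))
})

test_that("catalog lengths are log-normal around ~300 aa and COGs use the 20-letter alphabet", {
  cfg <- sim_config(n_genomes = 2, genome_sizes = c(A = 2000L, B = 2000L),
                    core_fraction = 0.3, seed = 9)
  cat_a <- gen_catalogs(cfg)$catalogs$A
  expect_true(all(cat_a$length >= 50L))
  expect_gt(median(cat_a$length), 250)
  expect_lt(median(cat_a$length), 350)
  expect_true(all(is.na(cat_a$cog) |
                    cat_a$cog %in% strsplit("JKLDVTMNUOCGEFHIPQRS", "")[[1]]))
})

test_that("noiseless similarity tables make every planted pair the mutual best hit", {
  cfg <- tiny_config(seed = 13)
  ct <- gen_catalogs(cfg)
  sim <- gen_similarity_tables(ct$catalogs, ct$truth, noise_level = 0)
  mem <- ct$truth$membership
  for (pair in list(c("Gbem", "GM21"), c("GM21", "GM18"))) {
    got <- reciprocal_best_hits(sim, pair)
    gids <- intersect(mem$group_id[mem$genome == pair[1]],
                      mem$group_id[mem$genome == pair[2]])
    want_a <- sort(mem$protein_id[mem$genome == pair[1] & mem$group_id %in% gids])
    expect_identical(got$protein_a, want_a)
  }
  # scores of true pairs strictly dominate decoys
  expect_gt(min(sim$bitscore[sim$pident > 80]), max(sim$bitscore[sim$pident < 80]))
})

test_that("a two-genome, three-protein hand-written truth yields the enumerated table", {
  mem <- data.frame(group_id = c("TG1", "TG1", "TG2", "TG2", "TG3"),
                    genome = c("A", "B", "A", "B", "A"),
                    protein_id = c("A_1", "B_1", "A_2", "B_2", "A_3"),
                    stringsAsFactors = FALSE)
  truth <- structure(list(membership = mem, genomes = c("A", "B")),
                     class = "ground_truth")
  cats <- list(A = data.frame(protein_id = paste0("A_", 1:3),
                              length = c(100L, 200L, 300L)),
               B = data.frame(protein_id = paste0("B_", 1:2),
                              length = c(100L, 200L)))
  tab <- gen_similarity_tables(cats, truth, noise_level = 0, n_decoys = 1,
                               seed = 4)
  # true rows: A_1->B_1 and A_2->B_2 at bitscore 500, plus reverse direction
  true_rows <- tab[tab$bitscore == 500, ]
  expect_setequal(paste(true_rows$query_id, true_rows$subject_id),
                  c("A_1 B_1", "A_2 B_2", "B_1 A_1", "B_2 A_2"))
  # every query gets exactly one decoy below 400 (anchored subjects only)
  decoys <- tab[tab$bitscore < 450, ]
  expect_true(all(decoys$bitscore <= 400))
  expect_true(all(table(decoys$query_id, decoys$query_genome) <= 1))
  # A_3 has no ortholog: it must not appear as a subject of true rows
  expect_false("A_3" %in% true_rows$subject_id)
  # empty catalogs produce an empty table
  empty <- gen_similarity_tables(list(A = cats$A[0, ], B = cats$B[0, ]),
                                 structure(list(membership = mem[0, ],
                                                genomes = c("A", "B")),
                                           class = "ground_truth"),
                                 seed = 4)
  expect_equal(nrow(empty), 0L)
})

test_that("a fully silenced stage emits no PSM rows for its samples", {
  cfg <- tiny_config(seed = 31,
                     dropout_rate = c(early = 0, middle = 0, late = 1),
                     filter_fail_rate = 0, single_hit_rate = 0)
  ct <- gen_catalogs(cfg)
  psms <- gen_psm_table(ct$catalogs$Gbem, ct$truth, cfg)
  late_samples <- ct$truth$stage_labels$sample_id[
    ct$truth$stage_labels$stage == "late"]
  expect_gt(nrow(psms), 0L)
  expect_false(any(psms$sample_id %in% late_samples))
})

test_that("about the configured fraction of PSM rows fails at least one filter", {
  cfg <- sim_config(n_genomes = 2, genome_sizes = c(A = 1500L, B = 1500L),
                    core_fraction = 0.3, seed = 41, filter_fail_rate = 0.3)
  ct <- gen_catalogs(cfg)
  psms <- gen_psm_table(ct$catalogs$A, ct$truth, cfg)
  thr <- c(1.9, 2.2, 3.5)[pmin(psms$charge, 3)]
  fails <- psms$xcorr < thr | psms$msgf > 1e-10
  expect_equal(mean(fails), 0.3 * (1 / (1 + 0.05 * 0.7)), tolerance = 0.05)
})

test_that("planted up-shifts recover a positive delta-Z sign in nearly all replicates", {
  hits <- 0L
  total <- 0L
  for (s in 1:200) {
    cfg <- sim_config(n_genomes = 2, genome_sizes = c(A = 60L, B = 60L),
                      core_fraction = 0.5, seed = 9000 + s,
                      expressed_fraction = 0.5, diff_fraction = 0.2)
    ct <- gen_catalogs(cfg)
    d <- ct$truth$differential
    d <- d[d$direction == "increased" & d$from == "early", ]
    if (nrow(d) == 0) next
    psms <- gen_psm_table(ct$catalogs$A, ct$truth, cfg)
    run <- run_corequant(psms, ct$catalogs$A, stages = planned_stages(ct$truth))
    calls <- run$calls
    sub <- calls[calls$protein_id %in% d$protein_id &
                   calls$from == "early" & calls$to == "middle", ]
    hits <- hits + sum(sub$delta_z > 0)
    total <- total + nrow(sub)
  }
  expect_gt(total, 50)
  expect_gt(hits / total, 0.95)
})

test_that("geochemistry starts at background before amendment and is seed-stable", {
  cfg <- tiny_config(seed = 15)
  day0 <- gen_geochem(cfg, days = 0, noise_sd = 0)
  expect_equal(day0$fe2, 50)
  expect_equal(day0$acetate, 0)
  expect_equal(day0$sulfide, 0)
  custom <- gen_geochem(sim_config(fe2_background = 80), days = 0, noise_sd = 0)
  expect_equal(custom$fe2, 80)
  g1 <- gen_geochem(cfg)
  g2 <- gen_geochem(cfg)
  expect_identical(g1, g2)
  expect_true(all(unlist(g1[-1]) >= 0))
})

test_that("emitted files re-derive the ground-truth ledger exactly", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 55, dropout_rate = 0, count_noise = "none")
  sim <- simulate_dataset(cfg, sequences = FALSE)
  write_sim_dir(sim, dir)
  truth2 <- read_ground_truth(file.path(dir, "ground_truth.json"))
  expect_equal(truth2$membership, sim$truth$membership)
  expect_equal(truth2$core_groups, sim$truth$core_groups)
  expect_equal(truth2$expressed, sim$truth$expressed)
  # membership re-derived from the written similarity table matches the ledger
  gm <- utils::read.delim(file.path(dir, "genome_map.tsv"))
  tab <- read_similarity(file.path(dir, "similarity.tsv"), gm)
  pairs <- do.call(rbind, lapply(utils::combn(names(sim$catalogs), 2,
                                              simplify = FALSE),
                                 function(p) reciprocal_best_hits(tab, p)))
  groups <- build_ortholog_groups(pairs, sim$catalogs)
  part <- function(mem) {
    sp <- lapply(split(paste(mem$genome, mem$protein_id), mem$group_id), sort)
    sort(unname(vapply(sp[lengths(sp) > 1], paste, "", collapse = "|")))
  }
  expect_identical(part(groups$membership), part(sim$truth$membership))
  # PSM table round-trips through disk
  psms2 <- read_psm_table(file.path(dir, "psms.tsv"))
  expect_equal(nrow(psms2), nrow(sim$psms))
  expect_equal(sum(psms2$count), sum(sim$psms$count))
})
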