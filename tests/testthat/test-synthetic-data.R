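test_that("zero-density, no-planting config yields empty tables and a full TF registry", {
  cfg <- sim_config(n_tf = 5, n_mirna = 5, n_lncrna = 10, n_mrna = 10,
                    edge_density = 0,
                    n_planted_ffl = c(tf_mediated = 0, mirna_mediated = 0,
                                      mixed = 0),
                    n_planted_cerna = 0, seed = 1)
  bg <- generate_background(cfg)
  expect_named(bg$tables, c("tf_mrna", "tf_lncrna", "tf_mirna",
                            "mirna_mrna", "mirna_lncrna"))
  expect_true(all(vapply(bg$tables, nrow, integer(1)) == 0L))
  expect_length(bg$tf_registry, 5L)
})

test_that("generation is deterministic: same seed twice gives identical files", {
  cfg <- small_sim_config(seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("per-class edge counts match an independent recount of the emitted files", {
  cfg <- sim_config(n_tf = 5, n_mirna = 5, n_lncrna = 10, n_mrna = 10,
                    edge_density = 0.2,
                    n_planted_ffl = c(tf_mediated = 2, mirna_mediated = 2,
                                      mixed = 1),
                    n_planted_cerna = 2, seed = 7)
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir, with_expression = FALSE,
                        with_survival = FALSE)
  for (cls in names(sim$background$tables)) {
    # recount with base read.delim, independent of the generator's bookkeeping
    tab <- read.delim(file.path(dir, paste0("associations_", cls, ".tsv")))
    n_unique <- nrow(unique(tab[, c("source_id", "target_id")]))
    expect_identical(n_unique,
                     unname(sim$background$ground_truth$edge_counts[cls]),
                     info = cls)
    expect_true(all(tab$source_id != tab$target_id), info = cls)
  }
})

test_that("planted motif edges are present in the background tables", {
  sim <- simulate_study(small_sim_config(seed = 5), out_dir = NULL,
                        with_expression = FALSE, with_survival = FALSE)
  gt <- sim$background$ground_truth$planted_ffls
  all_edges <- rbindlist(lapply(sim$background$tables, function(tb) {
    tb[, .(source_id, target_id)]
  }))
  key <- function(s, t) paste(s, t)
  ek <- key(all_edges$source_id, all_edges$target_id)
  tm <- gt[ffl_type %in% c("tf_mediated", "mixed")]
  expect_true(all(key(tm$tf, tm$mirna) %in% ek))
  mt <- gt[ffl_type %in% c("mirna_mediated", "mixed")]
  expect_true(all(key(mt$mirna, mt$tf) %in% ek))
  expect_true(all(key(gt$tf, gt$target) %in% ek))
  expect_true(all(key(gt$mirna, gt$target) %in% ek))
})

test_that("DE tables separate planted/drawn DE genes from the rest at the thresholds", {
  cfg <- small_sim_config(seed = 9)
  bg <- generate_background(cfg)
  de <- generate_de_tables(cfg, bg)
  thr <- threshold_config()
  tab <- de$de_tables[[1L]]
  expect_setequal(tab$gene_id, unlist(rnaloops:::sim_node_ids(cfg)))

  planted <- unique(c(bg$ground_truth$planted_ffls$tf,
                      bg$ground_truth$planted_ffls$mirna,
                      bg$ground_truth$planted_ffls$target))
  prec <- tab[gene_id %in% planted]
  expect_true(all(prec$fdr < thr$fdr_max))
  fc_min <- ifelse(prec$biotype %in% c("TF", "mRNA"),
                   thr$fc_min_mrna, thr$fc_min_ncrna)
  expect_true(all(abs(prec$log2fc) > fc_min))

  de_ids <- de$de_genes[[1L]]
  expect_true(all(tab[!gene_id %in% de_ids, fdr] >= thr$fdr_max))
})

test_that("null DE config (fraction 0, no planting) leaves every FDR at or above 0.05", {
  cfg <- sim_config(n_tf = 5, n_mirna = 5, n_lncrna = 10, n_mrna = 10,
                    edge_density = 0.1,
                    n_planted_ffl = c(tf_mediated = 0, mirna_mediated = 0,
                                      mixed = 0),
                    n_planted_cerna = 0,
                    de_fraction = c(TF = 0, mRNA = 0, miRNA = 0, lncRNA = 0),
                    seed = 3)
  bg <- generate_background(cfg)
  de <- generate_de_tables(cfg, bg)
  expect_true(all(de$de_tables[[1L]]$fdr >= 0.05))
  desets <- filter_degs(de$de_tables[[1L]])
  expect_identical(nrow(desets[[1L]]$members), 0L)
})

test_that("planted demand beyond the node universe is a configuration error", {
  expect_error(
    sim_config(n_tf = 2, n_mirna = 2, n_lncrna = 2, n_mrna = 2,
               n_planted_ffl = c(tf_mediated = 10, mirna_mediated = 0,
                                 mixed = 0), n_planted_cerna = 0),
    "planted FFL demand")
  expect_error(
    sim_config(n_tf = 2, n_mirna = 1, n_lncrna = 1, n_mrna = 1,
               n_planted_ffl = c(tf_mediated = 0, mirna_mediated = 0,
                                 mixed = 0), n_planted_cerna = 5),
    "ceRNA demand")
})

test_that("planted ceRNA partners share a latent factor; noise-free weight-1 pair has r = 1", {
  cfg <- sim_config(n_tf = 2, n_mirna = 3, n_lncrna = 5, n_mrna = 5,
                    edge_density = 0,
                    n_planted_ffl = c(tf_mediated = 1, mirna_mediated = 0,
                                      mixed = 0),
                    n_planted_cerna = 1,
                    n_samples = 10, expr_factor_weight = 1,
                    expr_noise_sd = 0, seed = 21)
  bg <- generate_background(cfg)
  expr <- generate_expression(cfg, bg)
  pair <- bg$ground_truth$planted_cerna
  expect_equal(cor(expr[pair$lncrna, ], expr[pair$mrna, ]), 1)
})

test_that("unplanted genes are essentially uncorrelated at large sample size", {
  cfg <- sim_config(n_tf = 2, n_mirna = 2, n_lncrna = 30, n_mrna = 30,
                    edge_density = 0,
                    n_planted_ffl = c(tf_mediated = 0, mirna_mediated = 0,
                                      mixed = 0),
                    n_planted_cerna = 0, n_samples = 200, seed = 13)
  bg <- generate_background(cfg)
  expr <- generate_expression(cfg, bg)
  set.seed(99)
  g <- rownames(expr)
  rs <- replicate(200, {
    p <- sample(g, 2)
    cor(expr[p[1], ], expr[p[2], ])
  })
  expect_gte(mean(abs(rs) < 0.2), 0.95)
})

test_that("too few expression samples is a configuration error", {
  cfg <- small_sim_config(seed = 2)
  cfg$n_samples <- 2L
  bg <- generate_background(cfg)
  expect_error(generate_expression(cfg, bg), "n_samples")
})

test_that("survival generator plants a recoverable hazard effect", {
  cfg <- small_sim_config(seed = 17)
  cfg$survival_n <- 400L
  cfg$survival_hr <- 4
  sv <- generate_survival(cfg, gene_ids = c("LNC_00001", "LNC_00002"),
                          effect_genes = "LNC_00001")
  expect_identical(sv$effect_direction,
                   c(LNC_00001 = 1L, LNC_00002 = 0L))
  res <- survival_screen(sv$cohort, "LNC_00001")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$hazard_ratio, 1)
})

test_that("a fully censored cohort is rejected by the survival screen", {
  cohort <- data.table(sample_id = sprintf("P%02d", 1:20),
                       time = runif(20, 1, 10), event = 0L,
                       G1 = rnorm(20))
  expect_error(survival_screen(cohort, "G1"), "zero events")
})
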