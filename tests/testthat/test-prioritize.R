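test_that("expression-presence filter keeps genes positive in every sample", {
  expr <- rbind(A = c(1, 2, 3), B = c(1, 0, 2), C = c(5, 5, 5))
  colnames(expr) <- sprintf("S%d", 1:3)
  expect_identical(expressed_in_all(expr, c("A", "B", "C")), c("A", "C"))
  expect_warning(res <- expressed_in_all(expr, c("A", "missing")), "absent")
  expect_identical(res, "A")
})

test_that("a 22-candidate fixture with 8 always-expressed genes keeps exactly those 8", {
  set.seed(4)
  genes <- sprintf("LNC_%02d", 1:22)
  expr <- matrix(rlnorm(22 * 10), nrow = 22, dimnames = list(genes, NULL))
  always <- genes[1:8]
  dropped <- genes[9:22]
  for (g in dropped) expr[g, sample(10, 1)] <- 0   # each fails in >= 1 sample
  expect_setequal(expressed_in_all(expr, genes), always)
})

test_that("correlation selection reproduces closed-form values and rankings", {
  # hand-computed Pearson on 4-sample toy vectors: r = 4 / sqrt(5 * 5) = 0.8
  expr <- rbind(L1 = c(1, 2, 3, 4), G1 = c(1, 3, 2, 4),
                G2 = c(1, 2, 3, 4), G3 = c(4, 3, 2, 1))
  colnames(expr) <- sprintf("S%d", 1:4)
  cc <- correlate_lncrna_mrna(expr, "L1", c("G1", "G2", "G3"), top_n = 3)
  expect_equal(cc[mrna == "G1", r], 0.8)
  expect_equal(cc[mrna == "G2", r], 1)
  expect_equal(cc[mrna == "G3", r], -1)
  # ranking is by |r|: the perfect pairs come first
  expect_setequal(cc$mrna[1:2], c("G2", "G3"))

  top1 <- correlate_lncrna_mrna(expr, "L1", c("G1", "G2", "G3"), top_n = 1)
  expect_identical(nrow(top1), 1L)
  sel <- correlate_lncrna_mrna(expr, "L1", c("G1", "G2", "G3"), r_min = 0.9)
  expect_setequal(sel$mrna, c("G2", "G3"))
})

test_that("constant expression rows are excluded from correlation with a warning", {
  expr <- rbind(L1 = c(1, 2, 3, 4), G1 = c(2, 2, 2, 2))
  colnames(expr) <- sprintf("S%d", 1:4)
  expect_warning(cc <- correlate_lncrna_mrna(expr, "L1", "G1"), "constant")
  expect_identical(nrow(cc), 0L)
})

test_that("ORA p-values are exact hypergeometric tails", {
  # fully contained list: universe 100, set 10, list 5 => C(10,5)/C(100,5)
  universe <- sprintf("u%03d", 1:100)
  gs <- gene_set_collection(list(pathA = universe[1:10]), universe)
  res <- hypergeometric_ora(universe[1:5], gs)
  expect_equal(res$p_value, choose(10, 5) / choose(100, 5))

  # full enumeration oracle on small universes
  set.seed(12)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(2:(N - 2), 1)
    k <- sample(2:(N - 2), 1)
    set <- sample(uni, K)
    lst <- sample(uni, k)
    ov <- length(intersect(set, lst))
    gsc <- gene_set_collection(list(s = set), uni)
    got <- hypergeometric_ora(lst, gsc)
    expect_equal(got$overlap, ov)
    expect_equal(got$p_value, ora_enum_p(N, K, k, ov), tolerance = 1e-12)
  }
})

test_that("zero overlap gives p = 1 and set order does not matter", {
  uni <- c(sprintf("a%d", 1:10), sprintf("b%d", 1:10))
  sets <- list(s1 = sprintf("a%d", 1:5), s2 = sprintf("a%d", 6:10))
  gs12 <- gene_set_collection(sets, uni)
  gs21 <- gene_set_collection(rev(sets), uni)
  lst <- sprintf("b%d", 1:4)
  r12 <- hypergeometric_ora(lst, gs12)
  expect_true(all(r12$p_value == 1))
  expect_identical(r12, hypergeometric_ora(lst, gs21))
})

test_that("BH adjustment is monotone with max adjusted equal to max raw", {
  set.seed(3)
  uni <- sprintf("g%03d", 1:200)
  sets <- lapply(1:12, function(i) sample(uni, 25))
  names(sets) <- sprintf("p%02d", 1:12)
  gs <- gene_set_collection(sets, uni)
  res <- hypergeometric_ora(sample(uni, 30), gs)
  expect_true(all(diff(res$fdr_bh) >= -1e-12))   # sorted by p => monotone
  expect_equal(max(res$fdr_bh), max(res$p_value))
  expect_identical(res$fdr_bh,
                   p.adjust(res$p_value, method = "BH"))
})

test_that("query genes outside the universe are dropped with a warning", {
  gs <- gene_set_collection(list(s = c("a", "b")), c("a", "b", "c"))
  expect_warning(res <- hypergeometric_ora(c("a", "zzz"), gs), "outside")
  expect_identical(res$overlap, 1L)
  expect_identical(nrow(hypergeometric_ora(character(), gs)), 0L)
})

test_that("GMT files round-trip into a gene-set collection", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3",
               "pathB\tdesc\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_named(gs$sets, c("pathA", "pathB"))
  expect_setequal(gs$universe, c("g1", "g2", "g3", "g4"))
  expect_error(gene_set_collection(list(empty = character())), "empty")
})

test_that("the log-rank screen matches a hand-worked 6-subject table", {
  cohort <- data.table(
    sample_id = sprintf("P%d", 1:6),
    time = c(2, 4, 6, 1, 3, 5),
    event = c(1, 1, 0, 1, 1, 1),
    # expression above the median for the (1, 3, 5) subjects
    G1 = c(1, 2, 3, 10, 11, 12))
  res <- survival_screen(cohort, "G1")
  oracle <- hand_logrank(cohort$time, cohort$event, cohort$G1 > 5)
  # frozen values from the explicit O/E tabulation
  expect_equal(oracle$chi2, 0.4848763, tolerance = 1e-6)
  expect_equal(oracle$hr, 1.858209, tolerance = 1e-6)
  expect_equal(res$logrank_chi2, oracle$chi2, tolerance = 1e-8)
  expect_equal(res$hazard_ratio, oracle$hr, tolerance = 1e-8)
  expect_equal(res$p_value, 0.4862218, tolerance = 1e-6)
  expect_identical(c(res$n_low, res$n_high), c(3L, 3L))
})

test_that("identical survival in both groups gives chi2 = 0 and p = 1", {
  cohort <- data.table(
    sample_id = sprintf("P%d", 1:6),
    time = c(1, 2, 3, 1, 2, 3),
    event = c(1, 1, 1, 1, 1, 1),
    G1 = c(1, 1, 1, 5, 5, 5))
  res <- survival_screen(cohort, "G1")
  expect_equal(res$logrank_chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("expression values equal to the median go to the low group", {
  cohort <- data.table(
    sample_id = sprintf("P%d", 1:5),
    time = c(1, 2, 3, 4, 5),
    event = c(1, 1, 1, 1, 1),
    G1 = c(1, 1, 1, 2, 2))     # median = 1; the three 1s all go low
  res <- survival_screen(cohort, "G1")
  expect_identical(res$n_low, 3L)
  expect_identical(res$n_high, 2L)
})

test_that("screen_survival reports genes with a zero-event group as NA", {
  cohort <- data.table(
    sample_id = sprintf("P%d", 1:6),
    time = c(2, 4, 6, 1, 3, 5),
    event = c(1, 1, 1, 1, 0, 0),
    G1 = c(1, 2, 3, 10, 11, 12),
    # G2's above-median half is exactly the two censored subjects
    G2 = c(1, 1, 1, 1, 10, 10))
  expect_warning(res <- screen_survival(cohort, c("G1", "G2")), "skipped")
  expect_true(is.na(res[gene == "G2", hazard_ratio]))
  expect_false(is.na(res[gene == "G1", hazard_ratio]))
})

test_that("guilt-by-association annotation enriches the truly linked pathway", {
  set.seed(10)
  n_s <- 40
  f <- rnorm(n_s)
  mrnas <- sprintf("G%02d", 1:40)
  expr <- matrix(rnorm(41 * n_s, 8, 1), nrow = 41,
                 dimnames = list(c("L1", mrnas), NULL))
  linked <- mrnas[1:10]
  expr["L1", ] <- expr["L1", ] + 2 * f
  for (g in linked) expr[g, ] <- expr[g, ] + 2 * f
  gs <- gene_set_collection(list(linked_path = linked,
                                 other_path = mrnas[21:30]),
                            universe = mrnas)
  res <- annotate_lncrnas(expr, "L1", mrnas, gs, top_n = 12)
  expect_identical(res$pathway[1], "linked_path")
  expect_lt(res[pathway == "linked_path", p_value], 0.001)
})
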