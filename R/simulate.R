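#' Generate a synthetic background regulatory universe
#'
#' Draws the five regulator-target association tables (TF->mRNA, TF->lncRNA,
#' TF->miRNA, miRNA->mRNA, miRNA->lncRNA) as independent Bernoulli edge
#' samples within each class, plants the configured feed-forward loops and
#' ceRNA triples by adding their edges, and returns the tables together with
#' the TF registry and the ground truth. miRNA->TF regulations are emitted
#' inside the miRNA->mRNA table with a TF-registry id as target, mirroring
#' how CLIP-derived tables list TF-coding genes among plain gene targets;
#' downstream assembly relabels them via the registry.
#'
#' For planted loops of the strictly one-directional types, the random draw
#' is pruned of the single reverse regulator edge that would upgrade the
#' loop to the mixed class, so planted types are stable under the exclusive
#' classification.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_background`: `tables` (named list of
#'   data.tables with columns `source_id`, `target_id`, `source_db`),
#'   `tf_registry` (character), `ground_truth` (planted loops and triples,
#'   per-class unique-pair counts), `node_ids`, and the `config`.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  ids <- sim_node_ids(config)

  planted_ffls <- plant_ffls(config, ids)
  planted_cerna <- plant_cerna(config, ids, planted_ffls)

  planted_edges <- planted_edge_tables(planted_ffls, planted_cerna)

  # reverse regulator edges that would reclassify a planted one-way loop
  forbid_mt <- planted_ffls[ffl_type == "tf_mediated",
                            edge_key(mirna, tf)]          # no miRNA->TF
  forbid_tm <- planted_ffls[ffl_type == "mirna_mediated",
                            edge_key(tf, mirna)]          # no TF->miRNA

  pools <- list(
    tf_mrna      = list(src = ids$TF,    tgt = ids$mRNA),
    tf_lncrna    = list(src = ids$TF,    tgt = ids$lncRNA),
    tf_mirna     = list(src = ids$TF,    tgt = ids$miRNA),
    # TF ids in the target pool supply miRNA->TF regulations
    mirna_mrna   = list(src = ids$miRNA, tgt = c(ids$mRNA, ids$TF)),
    mirna_lncrna = list(src = ids$miRNA, tgt = ids$lncRNA)
  )
  primary_db <- c(tf_mrna = "chipbase_sim", tf_lncrna = "chipbase_sim",
                  tf_mirna = "chipbase_sim", mirna_mrna = "starbase_sim",
                  mirna_lncrna = "starbase_sim")

  tables <- list()
  for (cls in EDGE_CLASSES) {
    rnd <- sample_class_edges(pools[[cls]]$src, pools[[cls]]$tgt,
                              config$edge_density[[cls]])
    all_e <- unique(rbind(planted_edges[[cls]], rnd))
    if (nrow(all_e)) {
      keys <- edge_key(all_e$source_id, all_e$target_id)
      drop <- switch(cls,
                     mirna_mrna = keys %chin% forbid_mt,
                     tf_mirna   = keys %chin% forbid_tm,
                     rep(FALSE, nrow(all_e)))
      all_e <- all_e[!drop]
    }
    all_e[, source_db := primary_db[[cls]]]
    if (cls == "mirna_lncrna" && nrow(all_e) && config$dup_fraction > 0) {
      n_dup <- floor(nrow(all_e) * config$dup_fraction)
      if (n_dup > 0) {
        dup <- all_e[sample.int(nrow(all_e), n_dup)]
        dup[, source_db := "mircode_sim"]
        all_e <- rbind(all_e, dup)
      }
    }
    setorder(all_e, source_id, target_id, source_db)
    tables[[cls]] <- all_e
  }

  edge_counts <- vapply(tables, function(tb) {
    length(unique(edge_key(tb$source_id, tb$target_id)))
  }, integer(1))

  structure(list(
    tables = tables,
    tf_registry = ids$TF,
    ground_truth = list(
      planted_ffls = planted_ffls,
      planted_cerna = planted_cerna,
      edge_counts = edge_counts,
      n_edges_total = sum(edge_counts)
    ),
    node_ids = ids,
    config = config
  ), class = "sim_background")
}

# exact G(n, p) per class: binomial edge count, then uniform distinct pairs
sample_class_edges <- function(src_ids, tgt_ids, p) {
  n_pairs <- as.numeric(length(src_ids)) * length(tgt_ids)
  empty <- data.table(source_id = character(), target_id = character())
  if (n_pairs == 0 || p <= 0) return(empty)
  m <- rbinom(1L, as.integer(n_pairs), p)
  if (m == 0L) return(empty)
  idx <- sample.int(as.integer(n_pairs), m)
  nc <- length(tgt_ids)
  data.table(source_id = src_ids[(idx - 1L) %/% nc + 1L],
             target_id = tgt_ids[(idx - 1L) %% nc + 1L])
}

sample_unique_triples <- function(k, a, b, c_pool) {
  out <- data.table(x = character(), y = character(), z = character())
  guard <- 0L
  while (nrow(out) < k) {
    need <- k - nrow(out)
    out <- unique(rbind(out, data.table(
      x = sample(a, need, replace = TRUE),
      y = sample(b, need, replace = TRUE),
      z = sample(c_pool, need, replace = TRUE))))
    guard <- guard + 1L
    if (guard > 1000L) stop("unable to draw distinct planted triples",
                            call. = FALSE)
  }
  out[seq_len(k)]
}

# every planted loop gets a distinct (TF, miRNA) regulator pair: a pair
# shared between a one-way and a mixed loop would silently upgrade the
# one-way loop's classification
plant_ffls <- function(config, ids) {
  k_total <- sum(config$n_planted_ffl)
  if (k_total == 0L) {
    return(data.table(tf = character(), mirna = character(),
                      target = character(), target_biotype = character(),
                      ffl_type = character()))
  }
  pairs <- sample_unique_pairs(k_total, ids$TF, ids$miRNA)
  targets <- c(ids$lncRNA, ids$mRNA)
  tgt <- sample(targets, k_total, replace = TRUE)
  data.table(
    tf = pairs$x, mirna = pairs$y, target = tgt,
    target_biotype = fifelse(tgt %chin% ids$lncRNA, "lncRNA", "mRNA"),
    ffl_type = rep(names(config$n_planted_ffl), config$n_planted_ffl))
}

sample_unique_pairs <- function(k, a, b) {
  out <- data.table(x = character(), y = character())
  guard <- 0L
  while (nrow(out) < k) {
    need <- k - nrow(out)
    out <- unique(rbind(out, data.table(x = sample(a, need, replace = TRUE),
                                        y = sample(b, need, replace = TRUE))))
    guard <- guard + 1L
    if (guard > 1000L) stop("unable to draw distinct planted pairs",
                            call. = FALSE)
  }
  out[seq_len(k)]
}

plant_cerna <- function(config, ids, planted_ffls) {
  k <- config$n_planted_cerna
  if (k == 0L) {
    return(data.table(mirna = character(), lncrna = character(),
                      mrna = character()))
  }
  mir_pool <- unique(planted_ffls$mirna)
  if (!length(mir_pool)) mir_pool <- ids$miRNA
  tri <- sample_unique_triples(k, mir_pool, ids$lncRNA, ids$mRNA)
  setnames(tri, c("mirna", "lncrna", "mrna"))
  tri
}

planted_edge_tables <- function(ffls, cerna) {
  e <- lapply(EDGE_CLASSES, function(x) {
    data.table(source_id = character(), target_id = character())
  })
  names(e) <- EDGE_CLASSES
  add <- function(cls, s, t) {
    if (length(s)) e[[cls]] <<- rbind(e[[cls]], data.table(source_id = s,
                                                           target_id = t))
  }
  if (nrow(ffls)) {
    tm <- ffls[ffl_type %in% c("tf_mediated", "mixed")]
    add("tf_mirna", tm$tf, tm$mirna)
    mt <- ffls[ffl_type %in% c("mirna_mediated", "mixed")]
    add("mirna_mrna", mt$mirna, mt$tf)     # miRNA->TF rides the gene table
    lnc <- ffls[target_biotype == "lncRNA"]
    add("tf_lncrna", lnc$tf, lnc$target)
    add("mirna_lncrna", lnc$mirna, lnc$target)
    mr <- ffls[target_biotype == "mRNA"]
    add("tf_mrna", mr$tf, mr$target)
    add("mirna_mrna", mr$mirna, mr$target)
  }
  if (nrow(cerna)) {
    add("mirna_lncrna", cerna$mirna, cerna$lncrna)
    add("mirna_mrna", cerna$mirna, cerna$mrna)
  }
  lapply(e, unique)
}

#' Generate per-condition differential-expression tables
#'
#' Every node of the universe receives one row per condition with a log2
#' fold change and an FDR. Genes drawn as differentially expressed get an
#' FDR uniform on (0, 0.05) and a log2 fold change of random sign with
#' magnitude `threshold + |Normal(0, lfc_effect_size)|`, so they clear the
#' biotype-specific thresholds strictly; all other genes get an FDR uniform
#' on (0.05, 1). All planted-structure nodes are forced into the first
#' condition's DE set.
#'
#' @param config A [sim_config()].
#' @param background A `sim_background` from [generate_background()].
#' @param thresholds A [threshold_config()] defining the separation the DE
#'   draw must respect.
#' @return List with `de_tables` (named list of data.tables, columns
#'   `gene_id`, `biotype`, `log2fc`, `fdr`, `condition`) and `de_genes`
#'   (named list of DE id vectors, the ground truth).
#' @export
generate_de_tables <- function(config, background,
                               thresholds = threshold_config()) {
  stopifnot(inherits(background, "sim_background"))
  set.seed(config$seed + 1L)
  ids <- background$node_ids
  universe <- data.table(
    gene_id = unlist(ids, use.names = FALSE),
    biotype = rep(names(ids), lengths(ids)))

  planted_nodes <- unique(c(
    background$ground_truth$planted_ffls$tf,
    background$ground_truth$planted_ffls$mirna,
    background$ground_truth$planted_ffls$target,
    background$ground_truth$planted_cerna$mirna,
    background$ground_truth$planted_cerna$lncrna,
    background$ground_truth$planted_cerna$mrna))

  conds <- names(config$de_fraction)
  de_tables <- list()
  de_genes <- list()
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    frac <- config$de_fraction[[i]]
    de_ids <- unlist(lapply(names(ids), function(bt) {
      pool <- ids[[bt]]
      n_de <- round((frac[[bt]] %||% 0) * length(pool))
      if (n_de > 0) sample(pool, n_de) else character()
    }), use.names = FALSE)
    if (i == 1L) de_ids <- union(de_ids, planted_nodes)

    tab <- copy(universe)
    tab[, condition := cond]
    is_de <- tab$gene_id %chin% de_ids
    thr <- fifelse(tab$biotype %chin% c("TF", "mRNA"),
                   thresholds$fc_min_mrna, thresholds$fc_min_ncrna)
    if (thresholds$fc_scale == "linear") thr <- log2(thr)
    n <- nrow(tab)
    sign_draw <- sample(c(-1, 1), n, replace = TRUE)
    tab[, log2fc := fifelse(is_de,
                            sign_draw * (thr + abs(rnorm(n, 0, config$lfc_effect_size))),
                            rnorm(n, 0, 0.3))]
    tab[, fdr := fifelse(is_de,
                         runif(n, 0, thresholds$fdr_max),
                         runif(n, thresholds$fdr_max, 1))]
    de_tables[[cond]] <- tab
    de_genes[[cond]] <- sort(de_ids)
  }
  list(de_tables = de_tables, de_genes = de_genes)
}

#' Generate an expression matrix with correlated planted ceRNA partners
#'
#' Every node gets a non-negative expression profile over `n_samples`
#' samples: a baseline plus independent Gaussian noise. The lncRNA and mRNA
#' of each planted ceRNA triple additionally load on a shared latent factor
#' with weight `expr_factor_weight`, giving an expected Pearson correlation
#' of `w^2 / (w^2 + sd^2)` between the partners.
#'
#' @param config A [sim_config()]; `n_samples` must be at least 3.
#' @param background A `sim_background` (source of node ids and planted
#'   triples).
#' @param baseline Additive baseline expression level.
#' @return Numeric matrix, genes in rows (rownames set), samples in columns.
#' @export
generate_expression <- function(config, background, baseline = 8) {
  stopifnot(inherits(background, "sim_background"))
  if (config$n_samples < 3L) {
    stop("n_samples must be >= 3 for downstream correlations", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  genes <- unlist(background$node_ids, use.names = FALSE)
  ns <- config$n_samples
  mat <- matrix(rnorm(length(genes) * ns, 0, config$expr_noise_sd),
                nrow = length(genes), dimnames = list(genes, sprintf("S%02d", seq_len(ns))))
  cerna <- background$ground_truth$planted_cerna
  if (nrow(cerna)) {
    for (t in seq_len(nrow(cerna))) {
      f <- rnorm(ns)
      for (g in c(cerna$lncrna[[t]], cerna$mrna[[t]])) {
        mat[g, ] <- mat[g, ] + config$expr_factor_weight * f
      }
    }
  }
  pmax(mat + baseline, 0)
}

#' Generate a survival cohort with expression-linked hazard
#'
#' Event times are exponential with baseline hazard `base_hazard`; samples
#' in the above-median expression half of each effect gene have their hazard
#' multiplied by `survival_hr`. Censoring is uniform and independent.
#'
#' @param config A [sim_config()]; `survival_n` must be >= 10.
#' @param gene_ids Genes to include as expression columns.
#' @param effect_genes Genes whose expression drives the hazard (default:
#'   the first of `gene_ids`). Multiple effect genes act multiplicatively.
#' @param base_hazard Baseline exponential hazard (events per time unit).
#' @param censor_max Upper bound of the uniform censoring time.
#' @return List with `cohort` (data.table: `sample_id`, `time`, `event`, one
#'   column per gene) and `effect_direction` (named +1/0 per gene).
#' @export
generate_survival <- function(config, gene_ids,
                              effect_genes = gene_ids[1],
                              base_hazard = 0.1,
                              censor_max = 15) {
  if (config$survival_n < 10L) stop("survival_n must be >= 10", call. = FALSE)
  stopifnot(length(gene_ids) >= 1L, all(effect_genes %in% gene_ids))
  set.seed(config$seed + 3L)
  n <- config$survival_n
  expr <- sapply(gene_ids, function(g) rlnorm(n), simplify = FALSE)
  hazard <- rep(base_hazard, n)
  for (g in effect_genes) {
    high <- expr[[g]] > median(expr[[g]])   # ties go low, matching the screen
    hazard <- hazard * config$survival_hr^high
  }
  t_event <- rexp(n, rate = hazard)
  t_cens <- runif(n, 0, censor_max)
  cohort <- data.table(sample_id = sprintf("P%04d", seq_len(n)),
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens))
  for (g in gene_ids) cohort[, (g) := expr[[g]]]
  direction <- setNames(as.integer(gene_ids %in% effect_genes), gene_ids)
  list(cohort = cohort, effect_direction = direction)
}

#' Run the whole synthetic-study generator and optionally write its files
#'
#' Convenience wrapper chaining [generate_background()],
#' [generate_de_tables()], [generate_expression()] and
#' [generate_survival()]. With `out_dir` set, writes the plain-text files
#' every downstream stage reads: one association TSV per edge class, the TF
#' registry, one DE TSV per condition, the expression TSV, the survival TSV
#' and the ground-truth JSON.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param with_expression,with_survival Generate the optional matrices.
#' @return List with `background`, `de`, `expression`, `survival`, `files`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL,
                           with_expression = TRUE, with_survival = TRUE) {
  background <- generate_background(config)
  de <- generate_de_tables(config, background)
  expression <- if (with_expression && config$n_samples >= 3L) {
    generate_expression(config, background)
  }
  surv <- if (with_survival && config$survival_n >= 10L) {
    gt <- background$ground_truth$planted_cerna
    genes <- unique(c(gt$lncrna, head(background$node_ids$lncRNA, 5L)))
    generate_survival(config, genes)
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_simulation(background, de, expression, surv, out_dir)
  }
  invisible(list(background = background, de = de, expression = expression,
                 survival = surv, files = files, config = config))
}

write_simulation <- function(background, de, expression, surv, out_dir) {
  files <- character()
  for (cls in names(background$tables)) {
    p <- file.path(out_dir, paste0("associations_", cls, ".tsv"))
    fwrite(background$tables[[cls]], p, sep = "\t")
    files[cls] <- p
  }
  reg <- file.path(out_dir, "tf_registry.txt")
  writeLines(background$tf_registry, reg)
  files["tf_registry"] <- reg

  for (cond in names(de$de_tables)) {
    p <- file.path(out_dir, paste0("de_", cond, ".tsv"))
    fwrite(de$de_tables[[cond]], p, sep = "\t")
    files[paste0("de_", cond)] <- p
  }
  if (!is.null(expression)) {
    p <- file.path(out_dir, "expression.tsv")
    fwrite(data.table(gene_id = rownames(expression), expression), p, sep = "\t")
    files["expression"] <- p
  }
  if (!is.null(surv)) {
    p <- file.path(out_dir, "survival.tsv")
    fwrite(surv$cohort, p, sep = "\t")
    files["survival"] <- p
  }
  gt <- background$ground_truth
  gt$de_genes <- de$de_genes
  p <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, p, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  files["ground_truth"] <- p
  files
}
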