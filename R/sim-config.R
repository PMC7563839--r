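#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module: the size of the node
#' universe per biotype, per-class edge densities of the random background,
#' the number of planted feed-forward loops and ceRNA triples, per-condition
#' differential-expression fractions, effect sizes, expression-matrix and
#' survival-cohort parameters, and the master seed.
#'
#' Defaults emulate the glioblastoma temozolomide-response study the package
#' models: a background universe of 107 TFs, 1851 mature miRNAs, 10,970
#' lncRNAs and 18,812 mRNAs, with a uniform per-class edge density of 0.0196
#' chosen so that the expected background holds about 1.15 million
#' regulations. The two default conditions mirror a drug-sensitive line with
#' a broad response (about 614 mRNAs, 51 miRNAs, 206 lncRNAs differentially
#' expressed) and a resistant line with a minimal one (about 25/12/1).
#'
#' @param n_tf,n_mirna,n_lncrna,n_mrna Size of each biotype universe.
#' @param edge_density Named numeric of Bernoulli edge probabilities, one per
#'   edge class (`tf_mrna`, `tf_lncrna`, `tf_mirna`, `mirna_mrna`,
#'   `mirna_lncrna`). A single unnamed value is recycled to all classes.
#' @param n_planted_ffl Named counts of planted feed-forward loops per type
#'   (`tf_mediated`, `mirna_mediated`, `mixed`). Planted loops are forced
#'   into the first condition's DE set with all edges present.
#' @param n_planted_cerna Number of planted (miRNA, lncRNA, mRNA) ceRNA
#'   triples. Their miRNAs are drawn from the planted-loop miRNAs when any
#'   loops are planted, so the triples survive the loop-miRNA restriction
#'   applied downstream.
#' @param de_fraction Either a single named-per-biotype probability vector
#'   (names among `TF`, `mRNA`, `miRNA`, `lncRNA`) applied to every
#'   condition, or a named list of such vectors, one per condition; list
#'   names become condition labels.
#' @param lfc_effect_size Standard deviation of the half-normal margin added
#'   above the biotype fold-change threshold for DE genes (log2 units).
#' @param n_samples Number of expression samples (columns); must be >= 3 for
#'   correlations downstream.
#' @param expr_factor_weight Loading of the shared latent factor on planted
#'   ceRNA partners; with unit noise the expected pair correlation is
#'   `w^2 / (w^2 + 1)`.
#' @param expr_noise_sd Standard deviation of per-gene expression noise.
#' @param survival_n Cohort size for the survival generator (>= 10).
#' @param survival_hr Hazard-ratio multiplier applied to the high-expression
#'   half of effect genes (> 0; 1 = no effect).
#' @param dup_fraction Fraction of miRNA-lncRNA edges also emitted under a
#'   second simulated source database, to exercise deduplication.
#' @param seed Master seed; each generator stage derives its own stream from
#'   it, so equal seeds give byte-identical outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_tf = 5, n_mirna = 5, n_lncrna = 10, n_mrna = 10,
#'                   edge_density = 0.2, seed = 7)
sim_config <- function(n_tf = 107L,
                       n_mirna = 1851L,
                       n_lncrna = 10970L,
                       n_mrna = 18812L,
                       edge_density = 0.0196,
                       n_planted_ffl = c(tf_mediated = 20L,
                                         mirna_mediated = 20L,
                                         mixed = 20L),
                       n_planted_cerna = 10L,
                       de_fraction = list(
                         line_sensitive = c(TF = 0.0326, mRNA = 0.0326,
                                            miRNA = 0.0276, lncRNA = 0.0188),
                         line_resistant = c(TF = 0.0013, mRNA = 0.0013,
                                            miRNA = 0.0065, lncRNA = 0.0001)),
                       lfc_effect_size = 1,
                       n_samples = 24L,
                       expr_factor_weight = 2,
                       expr_noise_sd = 1,
                       survival_n = 600L,
                       survival_hr = 2,
                       dup_fraction = 0.05,
                       seed = 1L) {
  if (length(edge_density) == 1L && is.null(names(edge_density))) {
    edge_density <- setNames(rep(edge_density, length(EDGE_CLASSES)), EDGE_CLASSES)
  }
  missing_cls <- setdiff(EDGE_CLASSES, names(edge_density))
  if (length(missing_cls)) {
    stop("edge_density missing classes: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  edge_density <- edge_density[EDGE_CLASSES]

  full_ffl <- c(tf_mediated = 0L, mirna_mediated = 0L, mixed = 0L)
  full_ffl[names(n_planted_ffl)] <- as.integer(n_planted_ffl)
  n_planted_ffl <- full_ffl

  if (!is.list(de_fraction)) de_fraction <- list(condition_1 = de_fraction)
  if (is.null(names(de_fraction)) || any(!nzchar(names(de_fraction)))) {
    names(de_fraction) <- paste0("condition_", seq_along(de_fraction))
  }

  cfg <- structure(list(
    n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
    n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
    edge_density = edge_density,
    n_planted_ffl = n_planted_ffl,
    n_planted_cerna = as.integer(n_planted_cerna),
    de_fraction = de_fraction,
    lfc_effect_size = lfc_effect_size,
    n_samples = as.integer(n_samples),
    expr_factor_weight = expr_factor_weight,
    expr_noise_sd = expr_noise_sd,
    survival_n = as.integer(survival_n),
    survival_hr = survival_hr,
    dup_fraction = dup_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_tf, cfg$n_mirna, cfg$n_lncrna, cfg$n_mrna,
              cfg$n_planted_ffl, cfg$n_planted_cerna, cfg$n_samples,
              cfg$survival_n)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all counts must be non-negative", call. = FALSE)
  }
  probs <- c(cfg$edge_density, unlist(cfg$de_fraction), cfg$dup_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$survival_hr <= 0) stop("survival_hr must be > 0", call. = FALSE)

  bad_bt <- setdiff(unlist(lapply(cfg$de_fraction, names)), BIOTYPES)
  if (length(bad_bt)) {
    stop("unknown biotype in de_fraction: ", paste(bad_bt, collapse = ", "),
         call. = FALSE)
  }

  # each planted loop receives its own regulator pair so that exclusive
  # mixed/one-way classification of planted loops is unambiguous
  n_targets <- cfg$n_lncrna + cfg$n_mrna
  demand <- sum(cfg$n_planted_ffl)
  if (demand > 0 &&
      (cfg$n_tf < 1L || cfg$n_mirna < 1L || n_targets < 1L ||
       demand > as.numeric(cfg$n_tf) * cfg$n_mirna)) {
    stop("planted FFL demand exceeds the node universe", call. = FALSE)
  }
  if (cfg$n_planted_cerna > 0 &&
      (cfg$n_mirna < 1L || cfg$n_lncrna < 1L || cfg$n_mrna < 1L ||
       cfg$n_planted_cerna > as.numeric(cfg$n_mirna) * cfg$n_lncrna * cfg$n_mrna)) {
    stop("planted ceRNA demand exceeds the node universe", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  universe: %d TF, %d miRNA, %d lncRNA, %d mRNA\n",
              x$n_tf, x$n_mirna, x$n_lncrna, x$n_mrna))
  cat("  edge density:", paste(sprintf("%s=%g", names(x$edge_density),
                                       x$edge_density), collapse = ", "), "\n")
  cat("  planted FFLs:", paste(sprintf("%s=%d", names(x$n_planted_ffl),
                                       x$n_planted_ffl), collapse = ", "),
      sprintf("; ceRNA=%d\n", x$n_planted_cerna))
  cat("  conditions:", paste(names(x$de_fraction), collapse = ", "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

sim_node_ids <- function(cfg) {
  list(
    TF     = if (cfg$n_tf) sprintf("TF_%04d", seq_len(cfg$n_tf)) else character(),
    miRNA  = if (cfg$n_mirna) sprintf("MIR_%05d", seq_len(cfg$n_mirna)) else character(),
    lncRNA = if (cfg$n_lncrna) sprintf("LNC_%05d", seq_len(cfg$n_lncrna)) else character(),
    mRNA   = if (cfg$n_mrna) sprintf("MRNA_%05d", seq_len(cfg$n_mrna)) else character()
  )
}
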