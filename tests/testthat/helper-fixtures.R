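# build a subnetwork-like object directly from a typed edge table; nodes are
# inferred from edge endpoints plus any extra isolated nodes
make_subnetwork <- function(edges, extra_nodes = NULL, condition = "test") {
  edges <- as.data.table(edges)
  if (!"sign" %in% names(edges)) edges[, sign := "unsigned"]
  nodes <- unique(rbind(
    edges[, .(id = source_id, biotype = source_biotype)],
    edges[, .(id = target_id, biotype = target_biotype)]))
  if (!is.null(extra_nodes)) nodes <- unique(rbind(nodes, as.data.table(extra_nodes)))
  nodes[, direction := "up"]
  setorder(nodes, id)
  structure(list(condition = condition, nodes = nodes, edges = edges),
            class = "subnetwork")
}

typed_edge <- function(s, sbt, t, tbt) {
  data.table(source_id = s, source_biotype = sbt,
             target_id = t, target_biotype = tbt)
}

# random typed regulatory graph for oracle-equivalence checks
random_typed_graph <- function(seed, n_tf = 6, n_mir = 8, n_lnc = 12,
                               n_mrna = 14, p = 0.15) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  mirs <- sprintf("M%02d", seq_len(n_mir))
  lncs <- sprintf("L%02d", seq_len(n_lnc))
  mrnas <- sprintf("G%02d", seq_len(n_mrna))
  pick <- function(src, sbt, tgt, tbt) {
    grid <- CJ(s = src, t = tgt)
    grid <- grid[runif(nrow(grid)) < p]
    if (!nrow(grid)) return(NULL)
    typed_edge(grid$s, sbt, grid$t, tbt)
  }
  edges <- rbindlist(list(
    pick(tfs, "TF", mirs, "miRNA"),
    pick(tfs, "TF", lncs, "lncRNA"),
    pick(tfs, "TF", mrnas, "mRNA"),
    pick(mirs, "miRNA", tfs, "TF"),
    pick(mirs, "miRNA", lncs, "lncRNA"),
    pick(mirs, "miRNA", mrnas, "mRNA")))
  make_subnetwork(edges)
}

# association TSV on disk
write_assoc_file <- function(rows, path, header = c("source_id", "target_id")) {
  dt <- as.data.table(rows)
  setnames(dt, seq_along(header), header)
  fwrite(dt, path, sep = "\t")
  path
}

small_sim_config <- function(seed = 7, ...) {
  sim_config(n_tf = 10, n_mirna = 12, n_lncrna = 20, n_mrna = 30,
             edge_density = 0.05,
             n_planted_ffl = c(tf_mediated = 3, mirna_mediated = 3, mixed = 3),
             n_planted_cerna = 3,
             de_fraction = list(A = c(TF = 0.3, mRNA = 0.3, miRNA = 0.3,
                                      lncRNA = 0.3),
                                B = c(TF = 0.1, mRNA = 0.1, miRNA = 0.1,
                                      lncRNA = 0.1)),
             n_samples = 12, survival_n = 80, survival_hr = 2, seed = seed,
             ...)
}

# endpoint biotypes per association class, restated independently of the
# package's internal mapping
edge_class_biotypes_for_test <- function(cls) {
  switch(cls,
    tf_mrna      = c("TF", "mRNA"),
    tf_lncrna    = c("TF", "lncRNA"),
    tf_mirna     = c("TF", "miRNA"),
    mirna_mrna   = c("miRNA", "mRNA"),
    mirna_lncrna = c("miRNA", "lncRNA"))
}
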