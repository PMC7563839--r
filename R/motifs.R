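#' Enumerate 3-node feed-forward loops in a subnetwork
#'
#' Finds every (TF, miRNA, target) triple in which both regulators target
#' the same mRNA or lncRNA and the regulators are themselves connected, and
#' classifies it:
#'
#' * `tf_mediated` — TF->miRNA, TF->target and miRNA->target present;
#' * `mirna_mediated` — miRNA->TF, miRNA->target and TF->target present;
#' * `mixed` — TF->miRNA and miRNA->TF both present, plus both
#'   regulator->target edges.
#'
#' Under the default exclusive classification a mutually regulated pair
#' yields a single `mixed` motif per target; with `exclusive = FALSE` such a
#' triple is additionally reported under `tf_mediated` and `mirna_mediated`.
#' Targets are restricted to biotypes mRNA and lncRNA, so the three nodes of
#' a motif are always distinct. Output is sorted by (tf, mirna, target).
#'
#' @param subnetwork A `subnetwork` (or any object with typed `edges`).
#' @param exclusive Logical; report mutually regulated triples as `mixed`
#'   only (default `TRUE`).
#' @return data.table of motifs: `tf`, `mirna`, `target`, `target_biotype`,
#'   `ffl_type`.
#' @export
enumerate_ffls <- function(subnetwork, exclusive = TRUE) {
  edges <- subnetwork$edges
  empty <- data.table(tf = character(), mirna = character(),
                      target = character(), target_biotype = character(),
                      ffl_type = character())
  if (!nrow(edges)) return(empty)

  tm <- unique(edges[source_biotype == "TF" & target_biotype == "miRNA",
                     .(tf = source_id, mirna = target_id)])
  mt <- unique(edges[source_biotype == "miRNA" & target_biotype == "TF",
                     .(tf = target_id, mirna = source_id)])
  t_tgt <- unique(edges[source_biotype == "TF" &
                        target_biotype %chin% c("mRNA", "lncRNA"),
                        .(tf = source_id, target = target_id, target_biotype)])
  m_tgt <- unique(edges[source_biotype == "miRNA" &
                        target_biotype %chin% c("mRNA", "lncRNA"),
                        .(mirna = source_id, target = target_id)])
  if (!nrow(t_tgt) || !nrow(m_tgt) || (!nrow(tm) && !nrow(mt))) return(empty)

  co <- merge(t_tgt, m_tgt, by = "target", allow.cartesian = TRUE)
  if (!nrow(co)) return(empty)
  pair_key <- function(a, b) paste(a, b, sep = "\r")
  co[, has_tm := pair_key(tf, mirna) %chin% pair_key(tm$tf, tm$mirna)]
  co[, has_mt := pair_key(tf, mirna) %chin% pair_key(mt$tf, mt$mirna)]
  co <- co[has_tm | has_mt]
  if (!nrow(co)) return(empty)

  if (exclusive) {
    co[, ffl_type := fifelse(has_tm & has_mt, "mixed",
                             fifelse(has_tm, "tf_mediated", "mirna_mediated"))]
    out <- co[, .(tf, mirna, target, target_biotype, ffl_type)]
  } else {
    out <- rbind(
      co[(has_tm), .(tf, mirna, target, target_biotype,
                     ffl_type = "tf_mediated")],
      co[(has_mt), .(tf, mirna, target, target_biotype,
                     ffl_type = "mirna_mediated")],
      co[has_tm & has_mt, .(tf, mirna, target, target_biotype,
                            ffl_type = "mixed")])
  }
  setorder(out, tf, mirna, target)
  out[]
}

#' Summarize enumerated motifs
#'
#' Counts per (loop type, target biotype) and per-node participation.
#'
#' @param motifs data.table from [enumerate_ffls()].
#' @return List with `type_counts` (data.table `ffl_type`,
#'   `target_biotype`, `N`), `n_motifs`, and `participation` (data.table
#'   `id`, `role`, `N`).
#' @export
motif_summary <- function(motifs) {
  type_counts <- motifs[, .N, by = .(ffl_type, target_biotype)]
  setorder(type_counts, ffl_type, target_biotype)
  participation <- rbind(
    motifs[, .(N = .N, role = "tf"), by = .(id = tf)],
    motifs[, .(N = .N, role = "mirna"), by = .(id = mirna)],
    motifs[, .(N = .N, role = "target"), by = .(id = target)])
  setcolorder(participation, c("id", "role", "N"))
  setorder(participation, id, role)
  list(type_counts = type_counts, n_motifs = nrow(motifs),
       participation = participation)
}

#' Summary of lncRNA-containing loops
#'
#' Restricts a motif table to loops whose target is a lncRNA and reports
#' the distinct lncRNAs, the loop count, and the rosters of TFs and miRNAs
#' regulating them.
#'
#' @param motifs data.table from [enumerate_ffls()].
#' @return List with `n_lncrnas`, `n_loops`, `lncrnas`, `tfs`, `mirnas`,
#'   `loops` (the restricted motif table).
#' @export
lncrna_loop_summary <- function(motifs) {
  loops <- motifs[target_biotype == "lncRNA"]
  list(n_lncrnas = length(unique(loops$target)),
       n_loops = nrow(loops),
       lncrnas = sort(unique(loops$target)),
       tfs = sort(unique(loops$tf)),
       mirnas = sort(unique(loops$mirna)),
       loops = loops)
}

#' Export lncRNA-containing loops as hive-plot tables
#'
#' Assigns the nodes of lncRNA-target motifs to three axes (TF, miRNA,
#' lncRNA) and lists every loop edge once; a mixed motif contributes both
#' mutual regulator edges. When a signed edge table (e.g. from a subnetwork
#' after [assign_edge_signs()]) is supplied, signs are attached.
#'
#' @param motifs data.table from [enumerate_ffls()]; only
#'   `target_biotype == "lncRNA"` rows are used.
#' @param signed_edges Optional edge data.table with `source_id`,
#'   `target_id`, `sign`.
#' @return List of data.tables: `nodes` (`id`, `axis`) and `edges`
#'   (`source_id`, `target_id`, `sign`), deterministically ordered.
#' @export
export_hive <- function(motifs, signed_edges = NULL) {
  loops <- motifs[target_biotype == "lncRNA"]
  if (!nrow(loops)) {
    return(list(nodes = data.table(id = character(), axis = character()),
                edges = data.table(source_id = character(),
                                   target_id = character(),
                                   sign = character())))
  }
  nodes <- unique(rbind(
    data.table(id = loops$tf, axis = "TF"),
    data.table(id = loops$mirna, axis = "miRNA"),
    data.table(id = loops$target, axis = "lncRNA")))
  setorder(nodes, axis, id)

  edges <- unique(rbind(
    loops[ffl_type %chin% c("tf_mediated", "mixed"),
          .(source_id = tf, target_id = mirna)],
    loops[ffl_type %chin% c("mirna_mediated", "mixed"),
          .(source_id = mirna, target_id = tf)],
    loops[, .(source_id = tf, target_id = target)],
    loops[, .(source_id = mirna, target_id = target)]))
  if (!is.null(signed_edges)) {
    edges <- merge(edges,
                   unique(signed_edges[, .(source_id, target_id, sign)]),
                   by = c("source_id", "target_id"), all.x = TRUE)
    edges[is.na(sign), sign := "unsigned"]
  } else {
    edges[, sign := "unsigned"]
  }
  setorder(edges, source_id, target_id)
  list(nodes = nodes, edges = edges[])
}
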