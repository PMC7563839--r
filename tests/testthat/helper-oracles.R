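library(data.table)

# ---- independent brute-force FFL oracle ------------------------------------
# O(n^3) triple scan over (TF, miRNA, target) with explicit edge lookups;
# kept deliberately naive and separate from the package's join-based path.
bf_enumerate_ffls <- function(edges, exclusive = TRUE) {
  has <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    assign(paste(edges$source_id[i], edges$target_id[i], sep = "->"),
           TRUE, envir = has)
  }
  e <- function(a, b) !is.null(has[[paste(a, b, sep = "->")]])
  node_bt <- unique(rbind(
    data.frame(id = edges$source_id, bt = edges$source_biotype),
    data.frame(id = edges$target_id, bt = edges$target_biotype)))
  tfs <- unique(node_bt$id[node_bt$bt == "TF"])
  mirs <- unique(node_bt$id[node_bt$bt == "miRNA"])
  tgts <- node_bt[node_bt$bt %in% c("mRNA", "lncRNA"), ]
  tgts <- tgts[!duplicated(tgts$id), ]
  rows <- list()
  for (tf in tfs) for (mi in mirs) {
    tm <- e(tf, mi); mt <- e(mi, tf)
    if (!tm && !mt) next
    for (j in seq_len(nrow(tgts))) {
      tg <- tgts$id[j]
      if (!e(tf, tg) || !e(mi, tg)) next
      if (exclusive) {
        type <- if (tm && mt) "mixed" else if (tm) "tf_mediated" else "mirna_mediated"
        rows[[length(rows) + 1L]] <-
          data.frame(tf = tf, mirna = mi, target = tg,
                     target_biotype = tgts$bt[j], ffl_type = type)
      } else {
        if (tm) rows[[length(rows) + 1L]] <-
          data.frame(tf = tf, mirna = mi, target = tg,
                     target_biotype = tgts$bt[j], ffl_type = "tf_mediated")
        if (mt) rows[[length(rows) + 1L]] <-
          data.frame(tf = tf, mirna = mi, target = tg,
                     target_biotype = tgts$bt[j], ffl_type = "mirna_mediated")
        if (tm && mt) rows[[length(rows) + 1L]] <-
          data.frame(tf = tf, mirna = mi, target = tg,
                     target_biotype = tgts$bt[j], ffl_type = "mixed")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), mirna = character(), target = character(),
               target_biotype = character(), ffl_type = character())
  out[order(out$tf, out$mirna, out$target, out$ffl_type), ]
}

motif_keys <- function(m) {
  sort(paste(m$tf, m$mirna, m$target, m$ffl_type, sep = "|"))
}

# ---- exact hypergeometric tail by combinatorial enumeration ----------------
ora_enum_p <- function(N, K, k, ov) {
  js <- ov:min(K, k)
  sum(choose(K, js) * choose(N - K, k - js)) / choose(N, k)
}

# ---- log-rank by explicit hand tabulation ----------------------------------
# standard O/E tabulation over distinct event times; group 1 = "high"
hand_logrank <- function(time, event, is_high) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & is_high)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & is_high)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O2 <- sum(event[!is_high]); E2 <- sum(event) - E1
  list(chi2 = (O1 - E1)^2 / V,
       hr = (O1 / E1) / (O2 / E2))
}
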