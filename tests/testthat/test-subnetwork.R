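toy_net <- function() {
  edges <- rbind(typed_edge("T1", "TF", "M1", "miRNA"),
                 typed_edge("T1", "TF", "L1", "lncRNA"),
                 typed_edge("M1", "miRNA", "L1", "lncRNA"),
                 typed_edge("T1", "TF", "G9", "mRNA"))
  edges[, source_db := "db"]
  build_interactome(edges)
}

toy_deset <- function(ids, bts, cond = "c1") {
  recs <- data.table(gene_id = ids, biotype = bts, log2fc = 3, fdr = 0.01,
                     condition = cond)
  if (!length(ids)) {
    # a record failing both gates gives a real but empty DE set
    recs <- data.table(gene_id = "dummy", biotype = "mRNA", log2fc = 0,
                       fdr = 0.99, condition = cond)
  }
  filter_degs(recs)[[cond]]
}

test_that("extraction keeps exactly the induced edges and isolated DE nodes", {
  net <- toy_net()
  ds <- toy_deset(c("T1", "M1", "L1", "X7"),
                  c("TF", "miRNA", "lncRNA", "mRNA"))
  sn <- extract_subnetwork(net, ds)
  expect_identical(nrow(sn$edges), 3L)
  expect_false("G9" %in% c(sn$edges$source_id, sn$edges$target_id))
  # X7 is DE but unknown to the background: kept isolated
  expect_true("X7" %in% sn$nodes$id)
  deg <- degree_report(sn)
  expect_identical(deg$degrees[id == "X7", in_degree + out_degree], 0L)
})

test_that("an empty DE set gives an empty subnetwork", {
  sn <- extract_subnetwork(toy_net(), toy_deset(character(), character()))
  expect_identical(nrow(sn$nodes), 0L)
  expect_identical(nrow(sn$edges), 0L)
})

test_that("subnetwork equals the brute-force double loop on random instances", {
  net_edges <- random_typed_graph(101, p = 0.2)$edges
  net_edges[, source_db := "db"]
  net <- build_interactome(net_edges)
  set.seed(55)
  de_ids <- sample(net$nodes$id, 25)
  ds <- toy_deset(sort(de_ids), net$nodes[id %in% de_ids][order(id), biotype])
  sn <- extract_subnetwork(net, ds)
  # brute force: every background edge with both endpoints DE
  expected <- net$edges[source_id %in% de_ids & target_id %in% de_ids]
  expect_setequal(paste(sn$edges$source_id, sn$edges$target_id),
                  paste(expected$source_id, expected$target_id))
})

test_that("adding DE members never removes subnetwork edges", {
  net_edges <- random_typed_graph(77, p = 0.2)$edges
  net_edges[, source_db := "db"]
  net <- build_interactome(net_edges)
  ids <- net$nodes$id
  small_ids <- sort(ids[seq(1, length(ids), by = 3)])
  big_ids <- sort(union(small_ids, ids[seq(1, length(ids), by = 2)]))
  sn_small <- extract_subnetwork(net, toy_deset(small_ids,
                                                net$nodes[id %in% small_ids][order(id), biotype]))
  sn_big <- extract_subnetwork(net, toy_deset(big_ids,
                                              net$nodes[id %in% big_ids][order(id), biotype]))
  expect_true(all(paste(sn_small$edges$source_id, sn_small$edges$target_id) %in%
                  paste(sn_big$edges$source_id, sn_big$edges$target_id)))
})

test_that("degree conservation holds and degrees match a brute-force recount", {
  sn <- random_typed_graph(303, p = 0.25)
  deg <- degree_report(sn)$degrees
  expect_identical(sum(deg$in_degree), nrow(sn$edges))
  expect_identical(sum(deg$out_degree), nrow(sn$edges))
  for (v in deg$id) {
    expect_identical(deg[id == v, out_degree], sum(sn$edges$source_id == v))
    expect_identical(deg[id == v, in_degree], sum(sn$edges$target_id == v))
  }
})

test_that("a miRNA star has the expected degrees and hub ordering", {
  edges <- typed_edge("M1", "miRNA", sprintf("x%d", 1:5), "mRNA")
  sn <- make_subnetwork(edges)
  rep_ <- degree_report(sn, top_k = 3)
  expect_identical(rep_$degrees[id == "M1", out_degree], 5L)
  expect_true(all(rep_$degrees[id != "M1", in_degree] == 1L))
  expect_identical(rep_$hubs$id[1], "M1")
  # ties broken lexicographically
  expect_identical(rep_$hubs$id[2:3], c("x1", "x2"))
})

test_that("edge signs follow endpoint correlation with the miRNA default", {
  edges <- rbind(typed_edge("T1", "TF", "G1", "mRNA"),
                 typed_edge("T1", "TF", "G2", "mRNA"),
                 typed_edge("M1", "miRNA", "G3", "mRNA"),
                 typed_edge("T1", "TF", "G4", "mRNA"))
  sn <- make_subnetwork(edges)
  base <- c(1, 2, 3, 4, 5, 6)
  expr <- rbind(T1 = base, G1 = base * 2, G2 = -base, G3 = base,
                G4 = rep(1, 6))
  colnames(expr) <- sprintf("S%d", 1:6)
  expect_warning(signed <- assign_edge_signs(sn, expr), "constant")
  e <- signed$edges
  expect_identical(e[target_id == "G1", sign], "stimulatory")
  expect_identical(e[target_id == "G2", sign], "inhibitory")
  expect_identical(e[target_id == "G4", sign], "unsigned")

  # miRNA-source edges default to inhibitory without expression
  signed2 <- assign_edge_signs(sn, NULL)
  expect_identical(signed2$edges[source_id == "M1", sign], "inhibitory")
  expect_identical(signed2$edges[source_id == "T1" & target_id == "G1", sign],
                   "unsigned")
})

test_that("the optional correlation filter drops weakly correlated edges only", {
  net <- toy_net()
  ds <- toy_deset(c("T1", "M1", "L1"), c("TF", "miRNA", "lncRNA"))
  s <- c(1, 2, 3, 4, 5, 6)
  expr <- rbind(T1 = s, M1 = s + rnorm(6, 0, 0.01), L1 = c(2, 1, 2, 1, 2, 1))
  colnames(expr) <- sprintf("S%d", 1:6)
  sn <- extract_subnetwork(net, ds, expression = expr, corr_min = 0.8)
  expect_true("M1" %in% sn$edges$target_id)      # T1->M1 strongly correlated
  expect_false("L1" %in% sn$edges$target_id)     # both L1 edges fail |r|

  # genes missing from the matrix leave their edges in place with a warning
  expr2 <- expr[c("T1", "M1"), ]
  expect_warning(sn2 <- extract_subnetwork(net, ds, expression = expr2,
                                           corr_min = 0.8),
                 "absent")
  expect_true("L1" %in% sn2$edges$target_id)
})
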