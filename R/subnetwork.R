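#' Extract a condition-specific subnetwork
#'
#' Maps a DE set onto the background interactome and keeps exactly the
#' background edges whose two endpoints are both DE in this condition (the
#' induced subgraph). DE genes absent from the interactome, or present but
#' unconnected among DE genes, are retained as isolated nodes. Optionally,
#' edges can additionally be required to pass an absolute expression
#' correlation threshold between their endpoints.
#'
#' @param interactome An `interactome` from [build_interactome()].
#' @param deset A `deset` from [filter_degs()].
#' @param expression Optional genes-by-samples matrix enabling the
#'   correlation filter.
#' @param corr_min Optional minimum `|Pearson r|` an edge must reach when
#'   `expression` is given; `NULL` (default) disables the filter, so base
#'   behavior is pure induced-subgraph extraction.
#' @return Object of class `subnetwork`: `condition`, `nodes` (data.table
#'   `id`, `biotype`, `direction`), `edges` (background edge subset, with a
#'   `sign` column of `"unsigned"` until [assign_edge_signs()] is applied).
#' @export
extract_subnetwork <- function(interactome, deset, expression = NULL,
                               corr_min = NULL) {
  stopifnot(inherits(interactome, "interactome"), inherits(deset, "deset"))
  de_ids <- deset$members$gene_id

  edges <- interactome$edges[source_id %chin% de_ids &
                             target_id %chin% de_ids]
  edges <- copy(edges)
  edges[, sign := "unsigned"]

  if (!is.null(corr_min)) {
    if (is.null(expression)) {
      stop("corr_min given without an expression matrix", call. = FALSE)
    }
    have <- rownames(expression)
    missing_g <- setdiff(unique(c(edges$source_id, edges$target_id)), have)
    if (length(missing_g)) {
      warning(length(missing_g), " subnetwork gene(s) absent from the ",
              "expression matrix; their edges are kept unsigned",
              call. = FALSE)
    }
    if (nrow(edges)) {
      r <- mapply(function(s, t) {
        if (s %in% have && t %in% have) {
          suppressWarnings(cor(expression[s, ], expression[t, ]))
        } else NA_real_
      }, edges$source_id, edges$target_id)
      edges <- edges[is.na(r) | abs(r) >= corr_min]
    }
  }

  # interactome biotype wins where available (TF relabeling), DE biotype
  # covers ids outside the background
  nodes <- merge(deset$members[, .(id = gene_id, biotype, direction)],
                 interactome$nodes, by = "id", all.x = TRUE,
                 suffixes = c("_de", ""))
  nodes[, biotype := fifelse(is.na(biotype), biotype_de, biotype)]
  nodes <- nodes[, .(id, biotype, direction)]
  setorder(nodes, id)

  structure(list(condition = deset$condition, nodes = nodes, edges = edges),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> condition %s: %d nodes, %d edges\n",
              x$condition, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Annotate subnetwork edges as stimulatory or inhibitory
#'
#' An edge is `stimulatory` when the Pearson correlation of its endpoints'
#' expression is positive and `inhibitory` when negative. Edges whose
#' endpoints lack expression stay `unsigned`, except miRNA-source edges,
#' which default to `inhibitory` (miRNA regulation is repressive). Constant
#' expression rows leave the edge unsigned with a warning.
#'
#' @param subnetwork A `subnetwork`.
#' @param expression Optional genes-by-samples matrix; `NULL` applies only
#'   the miRNA default.
#' @return The subnetwork with its `sign` edge column filled in.
#' @export
assign_edge_signs <- function(subnetwork, expression = NULL) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  edges <- copy(subnetwork$edges)
  if (nrow(edges)) {
    signs <- rep("unsigned", nrow(edges))
    if (!is.null(expression)) {
      have <- rownames(expression)
      n_const <- 0L
      for (i in seq_len(nrow(edges))) {
        s <- edges$source_id[i]; t <- edges$target_id[i]
        if (s %in% have && t %in% have) {
          xs <- expression[s, ]; xt <- expression[t, ]
          if (stats::sd(xs) == 0 || stats::sd(xt) == 0) {
            n_const <- n_const + 1L
            next
          }
          r <- cor(xs, xt)
          if (r > 0) signs[i] <- "stimulatory"
          else if (r < 0) signs[i] <- "inhibitory"
        }
      }
      if (n_const > 0L) {
        warning(n_const, " edge(s) left unsigned (constant expression row)",
                call. = FALSE)
      }
    }
    signs[signs == "unsigned" & edges$source_biotype == "miRNA"] <- "inhibitory"
    edges[, sign := signs]
  }
  subnetwork$edges <- edges
  subnetwork
}

#' Per-node degrees and hub list of a subnetwork
#'
#' @param subnetwork A `subnetwork`.
#' @param top_k Number of hubs to report (by out-degree, ties broken
#'   lexicographically by id).
#' @return List with `degrees` (data.table `id`, `biotype`, `in_degree`,
#'   `out_degree`) and `hubs` (head of `degrees` ordered by decreasing
#'   out-degree).
#' @export
degree_report <- function(subnetwork, top_k = 10L) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  degrees <- copy(subnetwork$nodes[, .(id, biotype)])
  outd <- subnetwork$edges[, .N, by = .(id = source_id)]
  ind <- subnetwork$edges[, .N, by = .(id = target_id)]
  degrees <- merge(degrees, setnames(outd, "N", "out_degree"),
                   by = "id", all.x = TRUE)
  degrees <- merge(degrees, setnames(ind, "N", "in_degree"),
                   by = "id", all.x = TRUE)
  degrees[is.na(out_degree), out_degree := 0L]
  degrees[is.na(in_degree), in_degree := 0L]
  setcolorder(degrees, c("id", "biotype", "in_degree", "out_degree"))
  setorder(degrees, id)
  hubs <- degrees[order(-out_degree, id)][seq_len(min(top_k, nrow(degrees)))]
  if (nrow(degrees) == 0L) hubs <- degrees
  list(degrees = degrees[], hubs = hubs)
}
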