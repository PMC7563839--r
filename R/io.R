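#' Convert an interactome or subnetwork to an igraph graph
#'
#' Nodes carry `biotype` (and `direction` for subnetworks); edges carry
#' `evidence` and/or `sign` where available.
#'
#' @param x An `interactome` or `subnetwork`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, c("interactome", "subnetwork")))
  vertices <- as.data.frame(x$nodes)
  names(vertices)[1L] <- "name"
  edge_cols <- intersect(c("source_id", "target_id", "evidence", "sign"),
                         names(x$edges))
  edges <- as.data.frame(x$edges[, edge_cols, with = FALSE])
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Write a network as GraphML
#'
#' @param x An `interactome` or `subnetwork`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(as_igraph(x), path, format = "graphml")
  invisible(path)
}

#' Write a network in SIF format
#'
#' One line per edge: `source <TAB> relation <TAB> target`, the relation
#' being the `sourceBiotype-targetBiotype` class. Isolated nodes are listed
#' on their own line, as SIF allows.
#'
#' @param x An `interactome` or `subnetwork`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, c("interactome", "subnetwork")))
  e <- x$edges
  lines <- if (nrow(e)) {
    paste(e$source_id, paste0(e$source_biotype, "-", e$target_biotype),
          e$target_id, sep = "\t")
  } else character()
  isolated <- setdiff(x$nodes$id, unique(c(e$source_id, e$target_id)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a DE statistics table
#'
#' Expects the header `gene_id`, `biotype`, `log2fc`, `fdr` and optionally
#' `condition` (as written by the synthetic generator).
#'
#' @param path TSV file.
#' @return data.table.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t")
  need <- c("gene_id", "biotype", "log2fc", "fdr")
  missing_col <- setdiff(need, names(dt))
  if (length(missing_col)) {
    stop("DE table ", path, " missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  dt
}

#' Read an expression matrix TSV (first column gene ids)
#' @param path TSV file.
#' @return Numeric matrix with rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  dt <- fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- dt[[1L]]
  m
}

#' Read a survival cohort TSV
#' @param path TSV with columns `sample_id`, `time`, `event`, one column
#'   per gene.
#' @return data.table.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path,
                               call. = FALSE)
  dt <- fread(path, sep = "\t")
  missing_col <- setdiff(c("time", "event"), names(dt))
  if (length(missing_col)) {
    stop("survival table missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  dt
}
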