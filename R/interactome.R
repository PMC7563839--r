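#' Load a regulator-target association table
#'
#' Reads one tab-separated association file of a declared edge class. The
#' first two columns are taken as source and target id; an optional
#' `source_db` column (or the `source_db` argument) records evidence
#' provenance. The declared class fixes the endpoint biotypes. Rows with an
#' empty id are a parse error (reported with line numbers); self-loop rows
#' are dropped with a warning.
#'
#' @param path TSV file with at least two columns.
#' @param edge_class One of `"tf_mrna"`, `"tf_lncrna"`, `"tf_mirna"`,
#'   `"mirna_mrna"`, `"mirna_lncrna"`.
#' @param source_db Evidence label for every row; defaults to the file's
#'   `source_db` column, else the file name.
#' @return data.table of edges: `source_id`, `source_biotype`, `target_id`,
#'   `target_biotype`, `source_db`.
#' @export
load_associations <- function(path, edge_class, source_db = NULL) {
  if (!file.exists(path)) {
    stop("association file not found: ", path, call. = FALSE)
  }
  bts <- edge_class_biotypes(edge_class)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("association file needs >= 2 columns: ", path, call. = FALSE)
  }
  db_label <- if (!is.null(source_db)) source_db
              else if ("source_db" %in% names(raw)) raw[["source_db"]]
              else basename(path)
  dt <- data.table(source_id = raw[[1L]], target_id = raw[[2L]],
                   source_db = db_label)

  bad <- which(!nzchar(dt$source_id) | !nzchar(dt$target_id) |
               is.na(dt$source_id) | is.na(dt$target_id))
  if (length(bad)) {
    stop("empty id in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  loops <- dt$source_id == dt$target_id
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped from ", basename(path),
            " (lines ", paste(which(loops) + 1L, collapse = ", "), ")",
            call. = FALSE)
    dt <- dt[!loops]
  }
  dt[, `:=`(source_biotype = bts[[1L]], target_biotype = bts[[2L]])]
  setcolorder(dt, c("source_id", "source_biotype", "target_id",
                    "target_biotype", "source_db"))
  dt[]
}

#' Assemble the background RNA interactome
#'
#' Merges edge lists from all association classes into one deduplicated
#' heterogeneous directed graph. Duplicate (source, target) pairs are merged
#' and their evidence databases unioned. Any target id present in the TF
#' registry is relabeled to biotype TF (TF-coding genes arrive through
#' mRNA-class tables); a registry id declared as lncRNA or miRNA in an edge
#' file is a biotype conflict and an error, as is any id appearing with two
#' different biotypes across files.
#'
#' @param edge_lists List of edge data.tables from [load_associations()]
#'   (or a single one).
#' @param tf_registry Character vector of TF ids (see [read_tf_registry()]).
#' @return Object of class `interactome`: `nodes` (data.table `id`,
#'   `biotype`), `edges` (deduplicated, with `evidence` the sorted
#'   `;`-joined database union), and `provenance` (edge count per database).
#' @export
build_interactome <- function(edge_lists, tf_registry = character()) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edges <- rbindlist(edge_lists, use.names = TRUE, fill = TRUE)
  if (!nrow(edges)) {
    edges <- data.table(source_id = character(), source_biotype = character(),
                        target_id = character(), target_biotype = character(),
                        source_db = character())
  }
  if (!"source_db" %in% names(edges)) edges[, source_db := "unknown"]

  # TF registry relabeling; conflicting declarations are errors
  conflict <- unique(c(
    edges[target_biotype %chin% c("lncRNA", "miRNA") &
          target_id %chin% tf_registry, target_id],
    edges[source_biotype == "miRNA" & source_id %chin% tf_registry, source_id]))
  if (length(conflict)) {
    stop("id(s) in TF registry but declared lncRNA/miRNA in edge files: ",
         paste(sort(conflict), collapse = ", "), call. = FALSE)
  }
  edges[target_id %chin% tf_registry, target_biotype := "TF"]
  edges[source_id %chin% tf_registry, source_biotype := "TF"]

  loops <- edges$source_id == edges$target_id
  if (any(loops)) edges <- edges[!loops]

  merged <- edges[, .(
    source_biotype = source_biotype[1L],
    target_biotype = target_biotype[1L],
    evidence = paste(sort(unique(source_db)), collapse = ";")
  ), by = .(source_id, target_id)]
  setorder(merged, source_id, target_id)

  nodes <- unique(rbind(
    merged[, .(id = source_id, biotype = source_biotype)],
    merged[, .(id = target_id, biotype = target_biotype)]))
  if (length(tf_registry)) {
    nodes <- unique(rbind(nodes,
                          data.table(id = tf_registry, biotype = "TF")))
  }
  dup <- nodes[, .N, by = id][N > 1L, id]
  if (length(dup)) {
    stop("inconsistent biotype declarations for id(s): ",
         paste(sort(dup), collapse = ", "), call. = FALSE)
  }
  setorder(nodes, id)

  provenance <- edges[, .N, by = source_db][order(source_db)]
  setnames(provenance, "N", "n_edges")

  structure(list(nodes = nodes, edges = merged, provenance = provenance,
                 tf_registry = sort(unique(tf_registry))),
            class = "interactome")
}

#' Read a TF registry file (one id per line)
#' @param path Text file.
#' @return Character vector of ids.
#' @export
read_tf_registry <- function(path) {
  if (!file.exists(path)) stop("TF registry not found: ", path, call. = FALSE)
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Summarize interactome composition
#'
#' Node counts per biotype and edge counts per (source biotype, target
#' biotype) class.
#'
#' @param interactome An `interactome`.
#' @return List with `node_counts` (named integer over all four biotypes),
#'   `edge_counts` (data.table `source_biotype`, `target_biotype`,
#'   `n_edges`), `n_nodes`, `n_edges`.
#' @export
summarize_interactome <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  node_counts <- setNames(integer(length(BIOTYPES)), BIOTYPES)
  if (nrow(interactome$nodes)) {
    tab <- interactome$nodes[, .N, by = biotype]
    node_counts[tab$biotype] <- tab$N
  }
  edge_counts <- interactome$edges[, .(n_edges = .N),
                                   by = .(source_biotype, target_biotype)]
  setorder(edge_counts, source_biotype, target_biotype)
  list(node_counts = node_counts,
       edge_counts = edge_counts,
       n_nodes = nrow(interactome$nodes),
       n_edges = nrow(interactome$edges))
}

#' @export
print.interactome <- function(x, ...) {
  s <- summarize_interactome(x)
  cat(sprintf("<interactome> %d nodes, %d edges\n", s$n_nodes, s$n_edges))
  cat("  nodes:", paste(sprintf("%s=%d", names(s$node_counts), s$node_counts),
                        collapse = ", "), "\n")
  if (nrow(s$edge_counts)) {
    cat("  edges:", paste(sprintf("%s->%s=%d", s$edge_counts$source_biotype,
                                  s$edge_counts$target_biotype,
                                  s$edge_counts$n_edges), collapse = ", "), "\n")
  }
  invisible(x)
}
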