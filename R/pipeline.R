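#' Pipeline configuration
#'
#' Collects the file paths and options of a full end-to-end run. The
#' association and DE paths are required; expression, survival and gene-set
#' inputs switch the optional prioritization steps on.
#'
#' @param associations Named list of association TSV paths; names are edge
#'   classes (`tf_mrna`, `tf_lncrna`, `tf_mirna`, `mirna_mrna`,
#'   `mirna_lncrna`).
#' @param tf_registry Path to the TF registry file.
#' @param de_tables Named list (condition -> path) of DE statistic TSVs.
#' @param expression,survival,gene_sets Optional paths (expression TSV,
#'   survival TSV, GMT).
#' @param thresholds A [threshold_config()].
#' @param exclusive_mixed Exclusive motif classification flag (default
#'   `TRUE`).
#' @param corr_min Optional subnetwork edge correlation filter.
#' @param top_n_assoc mRNAs kept per lncRNA in guilt-by-association.
#' @param top_pathways Pathways reported per lncRNA.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(associations, tf_registry, de_tables,
                            expression = NULL, survival = NULL,
                            gene_sets = NULL,
                            thresholds = threshold_config(),
                            exclusive_mixed = TRUE, corr_min = NULL,
                            top_n_assoc = 200L, top_pathways = 10L,
                            out_dir, seed = 1L) {
  stopifnot(is.list(associations), !is.null(names(associations)),
            is.list(de_tables), !is.null(names(de_tables)))
  bad_cls <- setdiff(names(associations), EDGE_CLASSES)
  if (length(bad_cls)) {
    stop("unknown association class(es): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  structure(list(associations = associations, tf_registry = tf_registry,
                 de_tables = de_tables, expression = expression,
                 survival = survival, gene_sets = gene_sets,
                 thresholds = thresholds, exclusive_mixed = exclusive_mixed,
                 corr_min = corr_min, top_n_assoc = top_n_assoc,
                 top_pathways = top_pathways, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a simulation output directory
#'
#' @param sim_dir Directory written by [simulate_study()].
#' @param out_dir Pipeline output directory (default `sim_dir/results`).
#' @param ... Passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_sim <- function(sim_dir,
                                     out_dir = file.path(sim_dir, "results"),
                                     ...) {
  assoc <- setNames(
    as.list(file.path(sim_dir, paste0("associations_", EDGE_CLASSES, ".tsv"))),
    EDGE_CLASSES)
  de_files <- list.files(sim_dir, pattern = "^de_.*\\.tsv$",
                         full.names = TRUE)
  de <- setNames(as.list(de_files),
                 sub("^de_(.*)\\.tsv$", "\\1", basename(de_files)))
  expr <- file.path(sim_dir, "expression.tsv")
  surv <- file.path(sim_dir, "survival.tsv")
  pipeline_config(associations = assoc,
                  tf_registry = file.path(sim_dir, "tf_registry.txt"),
                  de_tables = de,
                  expression = if (file.exists(expr)) expr,
                  survival = if (file.exists(surv)) surv,
                  out_dir = out_dir, ...)
}

#' Validate pipeline input files
#'
#' Report-only schema check: existence, required headers, numeric columns,
#' id syntax and biotype vocabulary, with line-level diagnostics where
#' applicable.
#'
#' @param config A `pipeline_config`.
#' @return data.table of diagnostics: `file`, `line` (`NA` for file-level
#'   issues), `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(config) {
  diags <- list()
  note <- function(file, line, msg) {
    diags[[length(diags) + 1L]] <<- data.table(file = file,
                                               line = as.integer(line),
                                               message = msg)
  }
  for (cls in names(config$associations)) {
    p <- config$associations[[cls]]
    if (!file.exists(p)) { note(p, NA, "file missing"); next }
    raw <- fread(p, sep = "\t", header = TRUE, colClasses = "character")
    if (ncol(raw) < 2L) { note(p, NA, "needs >= 2 columns"); next }
    bad <- which(!nzchar(raw[[1L]]) | !nzchar(raw[[2L]]))
    for (b in bad) note(p, b + 1L, "empty id")
    loops <- which(raw[[1L]] == raw[[2L]])
    for (b in loops) note(p, b + 1L, "self-loop")
  }
  if (!file.exists(config$tf_registry)) note(config$tf_registry, NA,
                                             "file missing")
  for (cond in names(config$de_tables)) {
    p <- config$de_tables[[cond]]
    if (!file.exists(p)) { note(p, NA, "file missing"); next }
    raw <- fread(p, sep = "\t", header = TRUE, colClasses = "character")
    missing_col <- setdiff(c("gene_id", "biotype", "log2fc", "fdr"),
                           names(raw))
    if (length(missing_col)) {
      note(p, NA, paste("missing column(s):",
                        paste(missing_col, collapse = ", ")))
      next
    }
    bad_bt <- which(!raw$biotype %chin% BIOTYPES)
    for (b in head(bad_bt, 20L)) {
      note(p, b + 1L, paste("unknown biotype:", raw$biotype[b]))
    }
    num_fdr <- suppressWarnings(as.numeric(raw$fdr))
    for (b in head(which(is.na(num_fdr)), 20L)) {
      note(p, b + 1L, "non-numeric fdr")
    }
    num_fc <- suppressWarnings(as.numeric(raw$log2fc))
    for (b in head(which(is.na(num_fc)), 20L)) {
      note(p, b + 1L, "non-numeric log2fc")
    }
  }
  for (p in c(config$expression, config$survival, config$gene_sets)) {
    if (!is.null(p) && !file.exists(p)) note(p, NA, "file missing")
  }
  if (!length(diags)) {
    return(data.table(file = character(), line = integer(),
                      message = character()))
  }
  rbindlist(diags)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: background network assembly, per-condition DEG
#' filtering and intersection, subnetwork extraction with degree reports,
#' feed-forward loop enumeration with lncRNA-loop summaries and hive
#' tables, ceRNA triple derivation, and — when expression / gene-set /
#' survival inputs are configured — lncRNA prioritization. Every stage
#' writes plain-text artifacts into `out_dir` and the run closes with a
#' manifest (package version, seed, input checksums, per-stage row counts).
#' A failing stage aborts with the stage named and leaves a `FAILED` marker
#' alongside any partial outputs.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "rnaloops",
    version = as.character(utils::packageVersion("rnaloops")),
    seed = config$seed,
    inputs = input_checksums(config),
    stages = list())
  rows <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  missing_in <- Filter(Negate(file.exists),
                       unlist(c(config$associations, config$tf_registry,
                                config$de_tables, config$expression,
                                config$survival, config$gene_sets)))
  if (length(missing_in)) {
    writeLines(paste("missing input:", missing_in), file.path(out, "FAILED"))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }

  # -- build-net ------------------------------------------------------------
  net <- stage("build-net", function() {
    edge_lists <- lapply(names(config$associations), function(cls) {
      load_associations(config$associations[[cls]], cls)
    })
    build_interactome(edge_lists, read_tf_registry(config$tf_registry))
  })
  s <- summarize_interactome(net)
  comp <- data.table(metric = c(paste0("nodes_", names(s$node_counts)),
                                "nodes_total", "edges_total"),
                     value = c(s$node_counts, s$n_nodes, s$n_edges))
  fwrite(comp, file.path(out, "interactome_summary.tsv"), sep = "\t")
  fwrite(s$edge_counts, file.path(out, "interactome_edge_classes.tsv"),
         sep = "\t")
  write_graphml(net, file.path(out, "interactome.graphml"))
  write_sif(net, file.path(out, "interactome.sif"))
  manifest$stages[["build-net"]] <- list(nodes = s$n_nodes,
                                         edges = s$n_edges)

  # -- filter-degs ----------------------------------------------------------
  desets <- stage("filter-degs", function() {
    recs <- rbindlist(lapply(names(config$de_tables), function(cond) {
      dt <- read_de_table(config$de_tables[[cond]])
      if (!"condition" %in% names(dt)) dt[, condition := cond]
      dt
    }), fill = TRUE)
    filter_degs(recs, config$thresholds, net$tf_registry)
  })
  for (cond in names(desets)) {
    fwrite(desets[[cond]]$members,
           file.path(out, paste0("degs_", cond, ".tsv")), sep = "\t")
  }
  if (length(desets) >= 2L) {
    ix <- intersect_desets(desets)
    fwrite(ix$region_counts, file.path(out, "deg_intersections.tsv"),
           sep = "\t")
  }
  manifest$stages[["filter-degs"]] <-
    lapply(desets, function(d) nrow(d$members))

  expression <- if (!is.null(config$expression)) {
    read_expression(config$expression)
  }

  # -- per-condition network stages ----------------------------------------
  subnets <- list(); motifs <- list(); cernas <- list()
  for (cond in names(desets)) {
    sn <- stage(paste0("subnet:", cond), function() {
      sn <- extract_subnetwork(net, desets[[cond]],
                               expression = expression,
                               corr_min = config$corr_min)
      assign_edge_signs(sn, expression)
    })
    subnets[[cond]] <- sn
    fwrite(sn$edges, file.path(out, paste0("subnetwork_", cond, "_edges.tsv")),
           sep = "\t")
    write_graphml(sn, file.path(out, paste0("subnetwork_", cond, ".graphml")))
    write_sif(sn, file.path(out, paste0("subnetwork_", cond, ".sif")))
    deg <- degree_report(sn)
    fwrite(deg$degrees, file.path(out, paste0("degrees_", cond, ".tsv")),
           sep = "\t")

    mf <- stage(paste0("ffl:", cond), function() {
      enumerate_ffls(sn, exclusive = config$exclusive_mixed)
    })
    motifs[[cond]] <- mf
    fwrite(mf, file.path(out, paste0("ffl_", cond, ".tsv")), sep = "\t")
    ms <- motif_summary(mf)
    fwrite(ms$type_counts, file.path(out, paste0("ffl_summary_", cond, ".tsv")),
           sep = "\t")
    hive <- export_hive(mf, sn$edges)
    fwrite(hive$nodes, file.path(out, paste0("hive_nodes_", cond, ".tsv")),
           sep = "\t")
    fwrite(hive$edges, file.path(out, paste0("hive_edges_", cond, ".tsv")),
           sep = "\t")

    ce <- stage(paste0("cerna:", cond), function() {
      find_cerna(sn, mirna_allowlist = unique(mf$mirna),
                 expression = expression)
    })
    cernas[[cond]] <- ce
    fwrite(ce, file.path(out, paste0("cerna_", cond, ".tsv")), sep = "\t")
    fwrite(cerna_network_export(ce, sn),
           file.path(out, paste0("cerna_network_", cond, ".tsv")), sep = "\t")

    manifest$stages[[paste0("network:", cond)]] <- list(
      subnetwork_nodes = nrow(sn$nodes), subnetwork_edges = nrow(sn$edges),
      ffls = nrow(mf), cerna_triples = nrow(ce))
  }

  # -- prioritize (optional) ------------------------------------------------
  prioritization <- NULL
  loop_lncrnas <- sort(unique(unlist(
    lapply(motifs, function(m) m[target_biotype == "lncRNA", target]))))
  if (!is.null(expression) && length(loop_lncrnas)) {
    prioritization <- stage("prioritize", function() {
      res <- list()
      res$expressed <- expressed_in_all(expression, loop_lncrnas)
      if (!is.null(config$gene_sets) && length(res$expressed)) {
        gs <- read_gmt(config$gene_sets)
        mrna_pool <- intersect(net$nodes[biotype == "mRNA", id],
                               rownames(expression))
        res$enrichment <- annotate_lncrnas(
          expression, res$expressed, mrna_pool, gs,
          top_n = config$top_n_assoc, top_pathways = config$top_pathways)
      }
      if (!is.null(config$survival)) {
        cohort <- read_survival(config$survival)
        genes <- intersect(loop_lncrnas, names(cohort))
        if (length(genes)) {
          res$survival <- suppressWarnings(screen_survival(cohort, genes))
        }
      }
      res
    })
    writeLines(prioritization$expressed,
               file.path(out, "lncrna_expressed_in_all.txt"))
    if (!is.null(prioritization$enrichment)) {
      fwrite(prioritization$enrichment,
             file.path(out, "lncrna_enrichment.tsv"), sep = "\t")
    }
    if (!is.null(prioritization$survival)) {
      fwrite(prioritization$survival,
             file.path(out, "lncrna_survival_screen.tsv"), sep = "\t")
    }
    manifest$stages[["prioritize"]] <- list(
      candidates = length(loop_lncrnas),
      expressed_in_all = length(prioritization$expressed),
      enrichment_rows = rows(prioritization$enrichment %||% list()),
      survival_rows = rows(prioritization$survival %||% list()))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(interactome = net, desets = desets, subnetworks = subnets,
                 motifs = motifs, cerna = cernas,
                 prioritization = prioritization, manifest = manifest))
}

input_checksums <- function(config) {
  paths <- unlist(c(config$associations, tf_registry = config$tf_registry,
                    config$de_tables, expression = config$expression,
                    survival = config$survival, gene_sets = config$gene_sets))
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `associations`
#' (mapping edge class -> path), `tf_registry`, `de_tables` (condition ->
#' path), optional `expression`, `survival`, `gene_sets`, `out_dir`,
#' `seed`, `exclusive_mixed`, `corr_min`, `top_n_assoc`, `top_pathways`,
#' and an optional `thresholds` mapping passed to [threshold_config()].
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  thr <- do.call(threshold_config, y$thresholds %||% list())
  pipeline_config(
    associations = lapply(y$associations, resolve),
    tf_registry = resolve(y$tf_registry),
    de_tables = lapply(y$de_tables, resolve),
    expression = resolve(y$expression),
    survival = resolve(y$survival),
    gene_sets = resolve(y$gene_sets),
    thresholds = thr,
    exclusive_mixed = y$exclusive_mixed %||% TRUE,
    corr_min = y$corr_min,
    top_n_assoc = y$top_n_assoc %||% 200L,
    top_pathways = y$top_pathways %||% 10L,
    out_dir = resolve(y$out_dir %||% "results"),
    seed = y$seed %||% 1L)
}
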