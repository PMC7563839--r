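#' Differential-expression thresholds
#'
#' Encodes the biotype-specific selection rule for differential expression:
#' a gene is called DE when its FDR is strictly below `fdr_max` and its
#' absolute fold change is strictly above the biotype threshold — `fc_min_mrna`
#' for mRNAs (and TF-coding genes), `fc_min_ncrna` for miRNAs and lncRNAs.
#' `fc_scale` states the scale on which the thresholds are compared against
#' the table's `log2fc` column: `"log2"` compares `|log2fc| > fc_min`,
#' `"linear"` compares `2^|log2fc| > fc_min`. Both inequalities are strict,
#' so records sitting exactly at a threshold are excluded.
#'
#' @param fdr_max Maximum FDR (exclusive), default 0.05.
#' @param fc_min_mrna Fold-change threshold for mRNA/TF, default 2.
#' @param fc_min_ncrna Fold-change threshold for miRNA/lncRNA, default 1.5.
#' @param fc_scale `"log2"` (default) or `"linear"`.
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(fdr_max = 0.05, fc_min_mrna = 2,
                             fc_min_ncrna = 1.5,
                             fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(fdr_max >= 0, fdr_max <= 1, fc_min_mrna > 0, fc_min_ncrna > 0)
  structure(list(fdr_max = fdr_max, fc_min_mrna = fc_min_mrna,
                 fc_min_ncrna = fc_min_ncrna, fc_scale = fc_scale),
            class = "threshold_config")
}

#' Filter differentially expressed genes per condition
#'
#' Applies the biotype-specific FDR and fold-change thresholds to a DE
#' statistics table and returns one DE set per condition. mRNA records whose
#' id is in the TF registry are relabeled TF and filtered at the mRNA
#' threshold. The regulation direction (`up`/`down`) is the sign of the
#' admitting record's log2 fold change.
#'
#' @param records data.table/data.frame with columns `gene_id`, `biotype`,
#'   `log2fc`, `fdr` and (optionally) `condition`; one row per
#'   (gene, condition).
#' @param thresholds A [threshold_config()].
#' @param tf_registry Character vector of TF ids for relabeling.
#' @return Named list of `deset` objects, one per condition, each a list
#'   with `condition` and `members` (data.table `gene_id`, `biotype`,
#'   `direction`).
#' @export
filter_degs <- function(records, thresholds = threshold_config(),
                        tf_registry = character()) {
  stopifnot(inherits(thresholds, "threshold_config"))
  dt <- as.data.table(records)
  need <- c("gene_id", "biotype", "log2fc", "fdr")
  missing_col <- setdiff(need, names(dt))
  if (length(missing_col)) {
    stop("DE table missing column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  if (!"condition" %in% names(dt)) dt[, condition := "condition_1"]
  unknown <- setdiff(unique(dt$biotype), BIOTYPES)
  if (length(unknown)) {
    stop("unknown biotype(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dups <- dt[, .N, by = .(gene_id, condition)][N > 1L]
  if (nrow(dups)) {
    stop("duplicate (gene, condition) rows, e.g. ",
         dups$gene_id[1L], " in ", dups$condition[1L], call. = FALSE)
  }
  if (any(!is.finite(dt$log2fc)) || any(dt$fdr < 0 | dt$fdr > 1)) {
    stop("log2fc must be finite and fdr in [0, 1]", call. = FALSE)
  }

  dt <- copy(dt)
  dt[biotype == "mRNA" & gene_id %chin% tf_registry, biotype := "TF"]
  fc_min <- fifelse(dt$biotype %chin% c("TF", "mRNA"),
                    thresholds$fc_min_mrna, thresholds$fc_min_ncrna)
  fc_obs <- if (thresholds$fc_scale == "log2") abs(dt$log2fc)
            else 2^abs(dt$log2fc)
  keep <- dt$fdr < thresholds$fdr_max & fc_obs > fc_min

  sel <- dt[keep]
  sel[, direction := fifelse(log2fc > 0, "up", "down")]
  out <- lapply(split(sel, by = "condition", sorted = TRUE), function(s) {
    members <- s[, .(gene_id, biotype, direction)]
    setorder(members, gene_id)
    structure(list(condition = s$condition[1L], members = members),
              class = "deset")
  })
  # conditions whose every record failed still get an (empty) DE set
  for (cond in setdiff(unique(dt$condition), names(out))) {
    out[[cond]] <- structure(
      list(condition = cond,
           members = data.table(gene_id = character(), biotype = character(),
                                direction = character())),
      class = "deset")
  }
  out[sort(names(out))]
}

#' @export
print.deset <- function(x, ...) {
  cat(sprintf("<deset> condition %s: %d members\n", x$condition,
              nrow(x$members)))
  if (nrow(x$members)) {
    tab <- x$members[, .N, by = biotype]
    cat(" ", paste(sprintf("%s=%d", tab$biotype, tab$N), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Intersect DE sets across conditions
#'
#' Builds the per-gene membership matrix over conditions and counts every
#' intersection region (the cells of the Venn diagram), per biotype and
#' overall.
#'
#' @param desets List of `deset` objects (>= 2).
#' @return List with `membership` (data.table: `gene_id`, `biotype`, one
#'   logical column per condition, `region` label) and `region_counts`
#'   (data.table `region`, `biotype`, `N`).
#' @export
intersect_desets <- function(desets) {
  stopifnot(length(desets) >= 2L)
  conds <- vapply(desets, function(d) d$condition, character(1))
  all_members <- rbindlist(lapply(desets, function(d) {
    cbind(d$members[, .(gene_id, biotype)], condition = d$condition)
  }))
  if (!nrow(all_members)) {
    membership <- data.table(gene_id = character(), biotype = character())
    for (cond in conds) membership[, (cond) := logical()]
    membership[, region := character()]
    return(list(membership = membership,
                region_counts = data.table(region = character(),
                                           biotype = character(),
                                           N = integer())))
  }
  membership <- dcast(all_members, gene_id + biotype ~ condition,
                      fun.aggregate = length, value.var = "condition")
  for (cond in setdiff(conds, names(membership))) membership[, (cond) := 0L]
  for (cond in conds) membership[, (cond) := get(cond) > 0L]
  membership[, region := apply(.SD, 1L, function(row) {
    paste(conds[as.logical(row)], collapse = "&")
  }), .SDcols = conds]
  setorder(membership, gene_id)
  region_counts <- membership[, .N, by = .(region, biotype)]
  setorder(region_counts, region, biotype)
  list(membership = membership[], region_counts = region_counts)
}
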