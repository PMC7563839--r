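#' Keep genes expressed in every sample
#'
#' @param expression Genes-by-samples matrix.
#' @param genes Candidate gene ids; ids absent from the matrix are dropped
#'   with a warning.
#' @param min_value Exclusive lower bound a gene must exceed in every
#'   sample (default 0).
#' @return Character vector of retained gene ids (input order).
#' @export
expressed_in_all <- function(expression, genes, min_value = 0) {
  missing_g <- setdiff(genes, rownames(expression))
  if (length(missing_g)) {
    warning(length(missing_g), " gene(s) absent from the expression matrix: ",
            paste(head(missing_g, 5L), collapse = ", "),
            if (length(missing_g) > 5L) ", ...", call. = FALSE)
  }
  present <- intersect(genes, rownames(expression))
  keep <- vapply(present, function(g) all(expression[g, ] > min_value),
                 logical(1))
  present[keep]
}

#' Guilt-by-association: correlate lncRNAs with mRNAs
#'
#' For each lncRNA, ranks mRNAs by absolute expression correlation and
#' returns the selection, either the `top_n` strongest or all pairs with
#' `|r| >= r_min`. Constant expression rows are excluded with a warning.
#'
#' @param expression Genes-by-samples matrix (>= 3 samples).
#' @param lncrnas,mrnas Row ids to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param top_n Number of mRNAs kept per lncRNA (default 200).
#' @param r_min If given, overrides `top_n`: keep all mRNAs with
#'   `|r| >= r_min`.
#' @return data.table: `lncrna`, `mrna`, `r`, ordered by lncRNA then
#'   decreasing `|r|`.
#' @export
correlate_lncrna_mrna <- function(expression, lncrnas, mrnas,
                                  method = c("pearson", "spearman"),
                                  top_n = 200L, r_min = NULL) {
  method <- match.arg(method)
  if (ncol(expression) < 3L) {
    stop("need >= 3 samples for correlation", call. = FALSE)
  }
  lncrnas <- intersect(lncrnas, rownames(expression))
  mrnas <- intersect(mrnas, rownames(expression))
  sds <- apply(expression[c(lncrnas, mrnas), , drop = FALSE], 1L, stats::sd)
  const <- names(sds)[sds == 0]
  if (length(const)) {
    warning(length(const), " constant expression row(s) excluded: ",
            paste(head(const, 5L), collapse = ", "), call. = FALSE)
    lncrnas <- setdiff(lncrnas, const)
    mrnas <- setdiff(mrnas, const)
  }
  if (!length(lncrnas) || !length(mrnas)) {
    return(data.table(lncrna = character(), mrna = character(),
                      r = numeric()))
  }
  cm <- cor(t(expression[lncrnas, , drop = FALSE]),
            t(expression[mrnas, , drop = FALSE]), method = method)
  out <- rbindlist(lapply(lncrnas, function(l) {
    dt <- data.table(lncrna = l, mrna = mrnas, r = cm[l, ])
    dt <- dt[order(-abs(r), mrna)]
    if (!is.null(r_min)) dt[abs(r) >= r_min]
    else dt[seq_len(min(top_n, nrow(dt)))]
  }))
  out[]
}

#' Hypergeometric over-representation analysis
#'
#' Tests a gene list against each set of a collection with the one-sided
#' hypergeometric tail (probability of an overlap at least as large as
#' observed, given the universe), then applies Benjamini-Hochberg
#' correction across the sets.
#'
#' @param genes Character vector of query genes; ids outside the universe
#'   are dropped with a warning.
#' @param gene_sets A `gene_set_collection` from [gene_set_collection()] or
#'   [read_gmt()].
#' @param top_n Keep the `top_n` most significant sets (default all).
#' @return data.table sorted by p-value: `pathway`, `set_size`, `overlap`,
#'   `p_value`, `fdr_bh`.
#' @export
hypergeometric_ora <- function(genes, gene_sets, top_n = Inf) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  empty <- data.table(pathway = character(), set_size = integer(),
                      overlap = integer(), p_value = numeric(),
                      fdr_bh = numeric())
  if (!length(genes)) return(empty)
  outside <- setdiff(genes, gene_sets$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
  }
  genes <- unique(intersect(genes, gene_sets$universe))
  if (!length(genes)) return(empty)

  N <- length(gene_sets$universe)
  k <- length(genes)
  res <- rbindlist(lapply(names(gene_sets$sets), function(nm) {
    set <- gene_sets$sets[[nm]]
    K <- length(set)
    ov <- length(intersect(genes, set))
    # P(X >= ov), X ~ Hypergeom(N, K, k)
    p <- phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
    data.table(pathway = nm, set_size = K, overlap = ov, p_value = p)
  }))
  res[, fdr_bh := p.adjust(p_value, method = "BH")]
  setorder(res, p_value, pathway)
  res[seq_len(min(top_n, nrow(res)))]
}

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (no empty sets).
#' @param universe Background gene ids; defaults to the union of the sets.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(universe)
  outside <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(outside)) {
    stop("gene set member(s) outside the universe: ",
         paste(head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' GMT is line-oriented: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file.
#' @param universe Optional background; defaults to the union of all sets.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed GMT line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(sets, universe)
}

#' Median-split log-rank survival screen for one gene
#'
#' Splits the cohort at the gene's median expression (values equal to the
#' median go to the low group), compares the two Kaplan-Meier curves with
#' the log-rank test, and reports the observed/expected hazard-ratio
#' approximation `HR = (O_high / E_high) / (O_low / E_low)` for high versus
#' low expression.
#'
#' @param cohort data.frame/data.table with columns `time`, `event` (0/1)
#'   and one expression column per gene.
#' @param gene Gene (column) to screen.
#' @return List of class `survival_screen`: `gene`, `hazard_ratio`,
#'   `logrank_chi2`, `p_value`, `n_low`, `n_high`, `events`
#'   (observed/expected per group) and `km` (a [survival::survfit] object
#'   with both group curves).
#' @export
survival_screen <- function(cohort, gene) {
  cohort <- as.data.table(cohort)
  need <- c("time", "event", gene)
  missing_col <- setdiff(need, names(cohort))
  if (length(missing_col)) {
    stop("cohort missing column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  expr <- cohort[[gene]]
  group <- factor(fifelse(expr > median(expr), "high", "low"),
                  levels = c("low", "high"))
  dat <- data.frame(time = cohort$time, event = cohort$event, group = group)
  ev <- tapply(dat$event, dat$group, sum)
  if (any(is.na(ev)) || any(ev == 0)) {
    stop("degenerate survival input for gene ", gene,
         ": a median-split group has zero events", call. = FALSE)
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = dat)
  chi2 <- sd_fit$chisq
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  # survdiff orders groups by factor level: 1 = low, 2 = high
  obs <- setNames(as.numeric(sd_fit$obs), c("low", "high"))
  exp_ <- setNames(as.numeric(sd_fit$exp), c("low", "high"))
  hr <- (obs[["high"]] / exp_[["high"]]) / (obs[["low"]] / exp_[["low"]])
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  structure(list(gene = gene, hazard_ratio = unname(hr),
                 logrank_chi2 = unname(chi2), p_value = unname(p),
                 n_low = sum(group == "low"), n_high = sum(group == "high"),
                 events = list(observed = obs, expected = exp_),
                 km = km),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("<survival_screen> %s: HR(high/low) = %.3f, chi2 = %.3f, p = %.3g (n = %d/%d)\n",
              x$gene, x$hazard_ratio, x$logrank_chi2, x$p_value,
              x$n_low, x$n_high))
  invisible(x)
}

#' Screen many genes with the median-split log-rank test
#'
#' @param cohort As in [survival_screen()].
#' @param genes Gene columns to screen. Genes with a zero-event group are
#'   reported with `NA` statistics and a warning rather than aborting the
#'   screen.
#' @return data.table: `gene`, `hazard_ratio`, `logrank_chi2`, `p_value`,
#'   `n_low`, `n_high`.
#' @export
screen_survival <- function(cohort, genes) {
  rows <- lapply(genes, function(g) {
    res <- tryCatch(survival_screen(cohort, g), error = function(e) e)
    if (inherits(res, "error")) {
      warning("gene ", g, " skipped: ", conditionMessage(res), call. = FALSE)
      data.table(gene = g, hazard_ratio = NA_real_, logrank_chi2 = NA_real_,
                 p_value = NA_real_, n_low = NA_integer_,
                 n_high = NA_integer_)
    } else {
      data.table(gene = g, hazard_ratio = res$hazard_ratio,
                 logrank_chi2 = res$logrank_chi2, p_value = res$p_value,
                 n_low = res$n_low, n_high = res$n_high)
    }
  })
  rbindlist(rows)
}

#' Annotate lncRNAs by association and pathway enrichment
#'
#' Full guilt-by-association step: for each candidate lncRNA, pick its
#' associated mRNAs by expression correlation, run hypergeometric
#' over-representation on them, and keep the top pathways.
#'
#' @param expression Genes-by-samples matrix.
#' @param lncrnas Candidate lncRNAs.
#' @param mrnas mRNA universe to correlate against.
#' @param gene_sets A `gene_set_collection`.
#' @inheritParams correlate_lncrna_mrna
#' @param top_pathways Pathways reported per lncRNA (default 10).
#' @return data.table: `lncrna` plus the [hypergeometric_ora()] columns.
#' @export
annotate_lncrnas <- function(expression, lncrnas, mrnas, gene_sets,
                             method = "pearson", top_n = 200L, r_min = NULL,
                             top_pathways = 10L) {
  assoc <- correlate_lncrna_mrna(expression, lncrnas, mrnas,
                                 method = method, top_n = top_n,
                                 r_min = r_min)
  out <- rbindlist(lapply(unique(assoc$lncrna), function(l) {
    enr <- hypergeometric_ora(assoc[lncrna == l, mrna], gene_sets,
                              top_n = top_pathways)
    if (nrow(enr)) cbind(lncrna = l, enr) else NULL
  }))
  if (!nrow(out)) {
    out <- data.table(lncrna = character(), pathway = character(),
                      set_size = integer(), overlap = integer(),
                      p_value = numeric(), fdr_bh = numeric())
  }
  out[]
}
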