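#' Find shared-miRNA ceRNA candidate triples
#'
#' A candidate triple is a (miRNA, lncRNA, mRNA) such that the subnetwork
#' contains both the miRNA->lncRNA and the miRNA->mRNA edge: the lncRNA and
#' the mRNA compete for the same miRNA, so the lncRNA may act as a sponge.
#' The default miRNA allowlist is the set of miRNAs participating in the
#' subnetwork's feed-forward loops, mirroring the restriction to
#' loop-involved miRNAs; pass an explicit vector, or `allow_all = TRUE` to
#' consider every subnetwork miRNA.
#'
#' @param subnetwork A `subnetwork`.
#' @param mirna_allowlist Optional character vector of miRNAs to consider;
#'   default: miRNAs in [enumerate_ffls()] of this subnetwork.
#' @param allow_all If `TRUE`, consider every miRNA in the subnetwork.
#' @param expression Optional genes-by-samples matrix; adds an
#'   `r_lnc_mrna` column with the Pearson correlation of each pair.
#' @return data.table of triples: `mirna`, `lncrna`, `mrna` (and optionally
#'   `r_lnc_mrna`), ordered deterministically.
#' @export
find_cerna <- function(subnetwork, mirna_allowlist = NULL, allow_all = FALSE,
                       expression = NULL) {
  edges <- subnetwork$edges
  if (is.null(mirna_allowlist) && !allow_all) {
    mirna_allowlist <- unique(enumerate_ffls(subnetwork)$mirna)
  }
  m_lnc <- unique(edges[source_biotype == "miRNA" & target_biotype == "lncRNA",
                        .(mirna = source_id, lncrna = target_id)])
  m_mrna <- unique(edges[source_biotype == "miRNA" & target_biotype == "mRNA",
                         .(mirna = source_id, mrna = target_id)])
  if (!allow_all) {
    m_lnc <- m_lnc[mirna %chin% mirna_allowlist]
    m_mrna <- m_mrna[mirna %chin% mirna_allowlist]
  }
  triples <- merge(m_lnc, m_mrna, by = "mirna", allow.cartesian = TRUE)
  setorder(triples, mirna, lncrna, mrna)
  if (!is.null(expression) && nrow(triples)) {
    have <- rownames(expression)
    triples[, r_lnc_mrna := mapply(function(l, g) {
      if (l %in% have && g %in% have) {
        suppressWarnings(cor(expression[l, ], expression[g, ]))
      } else NA_real_
    }, lncrna, mrna)]
  }
  triples[]
}

#' Export ceRNA triples as per-miRNA star edge tables
#'
#' Each miRNA becomes a hub with one edge to every distinct lncRNA and mRNA
#' partner, annotated with biotype and, when a subnetwork is supplied, the
#' DE direction of each partner.
#'
#' @param triples data.table from [find_cerna()].
#' @param subnetwork Optional `subnetwork` supplying DE directions.
#' @return data.table: `mirna`, `partner`, `partner_biotype`, `direction`.
#' @export
cerna_network_export <- function(triples, subnetwork = NULL) {
  if (!nrow(triples)) {
    return(data.table(mirna = character(), partner = character(),
                      partner_biotype = character(), direction = character()))
  }
  stars <- unique(rbind(
    triples[, .(mirna, partner = lncrna, partner_biotype = "lncRNA")],
    triples[, .(mirna, partner = mrna, partner_biotype = "mRNA")]))
  if (!is.null(subnetwork)) {
    stars <- merge(stars,
                   subnetwork$nodes[, .(partner = id, direction)],
                   by = "partner", all.x = TRUE)
  } else {
    stars[, direction := NA_character_]
  }
  setcolorder(stars, c("mirna", "partner", "partner_biotype", "direction"))
  setorder(stars, mirna, partner)
  stars[]
}
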