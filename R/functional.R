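## Virulence-factor gene quantification from homology hits, and functional
## differential analysis of KO / VF abundance matrices.

#' Filter homology hits on the similarity criterion
#'
#' Keeps hits with e-value strictly below `e_max`, percent identity strictly
#' above `min_identity`, and alignment coverage strictly above
#' `min_coverage` of the reference gene length (the coverage denominator is
#' the VF reference gene; use `coverage` computed on the query to apply the
#' criterion query-side). The filter is idempotent and monotone: tightening
#' any threshold never adds a surviving hit.
#'
#' @param hits a [hit_table()].
#' @param e_max maximum e-value (exclusive).
#' @param min_identity minimum percent identity (exclusive).
#' @param min_coverage minimum coverage fraction (exclusive).
#' @return the surviving rows as a [hit_table()].
#' @export
filter_hits <- function(hits, e_max = 1e-5, min_identity = 80,
                        min_coverage = 0.8) {
  keep <- hits$evalue < e_max &
    hits$percent_identity > min_identity &
    hits$coverage_fraction > min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Aggregate gene abundances onto virulence-factor reference genes
#'
#' The relative abundance of each VF reference gene is the per-sample sum of
#' the abundances of all catalogue genes with a surviving hit against it. A
#' catalogue gene hitting several VF genes contributes its full abundance to
#' each of them (no splitting), so VF column totals can exceed 100 when
#' multi-hits exist. Catalogue genes absent from the gene abundance matrix
#' are skipped with a warning.
#'
#' @param hits a filtered [hit_table()] (see [filter_hits()]).
#' @param gene_abund a gene-level [abundance_matrix()].
#' @return a VF-gene x sample numeric matrix of class `vf_abundance` with
#'   attribute `contributors` (a named list of catalogue gene ids per VF
#'   gene).
#' @export
vf_aggregate <- function(hits, gene_abund) {
  if (nrow(hits) == 0) {
    warning("empty filtered hit table; VF abundance matrix is empty")
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(gene_abund),
                  dimnames = list(character(0), colnames(gene_abund)))
    return(structure(out, contributors = list(),
                     class = c("vf_abundance", class(out))))
  }
  known <- hits$catalogue_gene_id %in% rownames(gene_abund)
  if (any(!known)) {
    warning(sprintf("hit(s) for catalogue gene(s) absent from abundances, skipped: %s",
                    paste(unique(hits$catalogue_gene_id[!known]), collapse = ", ")))
    hits <- hits[known, , drop = FALSE]
  }
  hits <- unique(hits[, c("catalogue_gene_id", "vf_gene_id")])
  m <- unclass(gene_abund)
  groups <- split(hits$catalogue_gene_id, hits$vf_gene_id)
  out <- t(vapply(groups,
                  function(g) colSums(m[g, , drop = FALSE]),
                  numeric(ncol(m))))
  colnames(out) <- colnames(m)
  structure(out, contributors = groups,
            class = c("vf_abundance", class(out)))
}

#' Differential analysis of functional (KO or VF) abundances
#'
#' Delegates to [differential_features()] with no prevalence filter (none is
#' applied at the functional level) and a default significance threshold of
#' adjusted p < 0.05. Adds a readable `change` column
#' (increased/decreased in `groupA` relative to `groupB`).
#'
#' @param abund a KO- or VF-level abundance matrix (any feature x sample
#'   numeric matrix with dimnames).
#' @param metadata a [sample_metadata()] data.frame.
#' @param groupA,groupB group labels.
#' @param q_threshold significance threshold on the adjusted p-value.
#' @return a `differential_result` data.frame with an extra `change`
#'   column.
#' @export
functional_differential <- function(abund, metadata, groupA, groupB,
                                    q_threshold = 0.05) {
  out <- differential_features(abund, metadata, groupA, groupB,
                               q_threshold = q_threshold,
                               filter_spec = NULL)
  out$change <- ifelse(out$direction > 0, "increased",
                       ifelse(out$direction < 0, "decreased", "none"))
  out
}
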