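## Normalization of read counts to relative abundances and aggregation to
## higher-level features (taxa, KO groups).

#' Gene-level relative abundance from read counts
#'
#' The relative abundance of a catalogue gene in a sample is the number of
#' reads mapped to it, normalized by the gene length and by the total of the
#' length-normalized counts over all catalogue genes in that sample:
#'
#' \deqn{a_{gs} = 100 \cdot \frac{c_{gs}/L_g}{\sum_{g'} c_{g's}/L_{g'}}}
#'
#' Columns of the result sum to 100 (percent).
#'
#' @param counts a [count_table()].
#' @param annotation a [gene_annotation()] covering every gene in `counts`.
#' @return an [abundance_matrix()] at gene level.
#' @export
gene_relative_abundance <- function(counts, annotation) {
  genes <- rownames(counts)
  idx <- match(genes, annotation$gene_id)
  if (anyNA(idx)) {
    missing <- genes[is.na(idx)]
    stop(sprintf("genes without annotation: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  len <- annotation$length_bp[idx]
  rate <- unclass(counts) / len
  tot <- colSums(rate)
  if (any(tot <= 0))
    stop(sprintf("sample '%s' has no mapped reads",
                 colnames(counts)[which(tot <= 0)[1]]))
  vals <- 100 * sweep(rate, 2, tot, "/")
  abundance_matrix(vals, level = "gene")
}

#' Aggregate abundances by a feature-to-group labelling
#'
#' Each output row is the per-sample sum of the abundances of its member
#' features (e.g. genes of one KO group, species of one genus). The sum is
#' exact; no renormalization is performed, so unlabeled features remain in
#' the per-sample totals but are dropped from the output.
#'
#' @param abund an [abundance_matrix()].
#' @param labels named character vector mapping feature id to group label;
#'   features missing from `labels` (or labelled `NA`) are dropped.
#' @param level level label for the output matrix.
#' @return an [abundance_matrix()] at `level`.
#' @export
aggregate_abundance <- function(abund, labels, level = "ko") {
  lab <- labels[rownames(abund)]
  keep <- !is.na(lab) & nzchar(lab)
  if (!any(keep)) {
    warning("empty label set: aggregation produced no features")
    out <- matrix(numeric(0), nrow = 0, ncol = ncol(abund),
                  dimnames = list(character(0), colnames(abund)))
    return(abundance_matrix(out, level = level))
  }
  agg <- rowsum(unclass(abund)[keep, , drop = FALSE], group = lab[keep])
  ## summing percentages may overshoot 100 by accumulated float error
  agg <- pmin(agg, 100)
  abundance_matrix(agg, level = level)
}

#' Prevalence filter on relative abundances
#'
#' Keep a feature if its abundance exceeds `threshold_percent` (strictly) in
#' at least one sample. Applied before group comparisons: genera are
#' filtered at > 1% and species at > 0.1%.
#'
#' @param abund an [abundance_matrix()].
#' @param threshold_percent strictly positive threshold in percent.
#' @return an [abundance_matrix()] with the retained rows, order preserved.
#' @export
prevalence_filter <- function(abund, threshold_percent) {
  stopifnot(is.numeric(threshold_percent), threshold_percent > 0)
  keep <- apply(unclass(abund), 1, max) > threshold_percent
  abundance_matrix(unclass(abund)[keep, , drop = FALSE],
                   level = abundance_level(abund))
}

#' Subset a KO abundance matrix to a configured KO list
#'
#' Returns one row per requested KO label in list order. KO groups absent
#' from the matrix are kept as all-zero rows (with a warning) so that
#' fixed-size gene-group panels, such as the alcohol-metabolism set, keep
#' their shape.
#'
#' @param abund an [abundance_matrix()] at KO level.
#' @param ko_list character vector of KO labels.
#' @return an [abundance_matrix()] at KO level with `length(ko_list)` rows.
#' @export
subset_ko <- function(abund, ko_list) {
  ko_list <- as.character(ko_list)
  out <- matrix(0, nrow = length(ko_list), ncol = ncol(abund),
                dimnames = list(ko_list, colnames(abund)))
  present <- ko_list %in% rownames(abund)
  if (any(present))
    out[ko_list[present], ] <- unclass(abund)[ko_list[present], ]
  if (any(!present))
    warning(sprintf("KO group(s) absent from matrix, kept as zero rows: %s",
                    paste(ko_list[!present], collapse = ", ")))
  abundance_matrix(out, level = "ko")
}
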