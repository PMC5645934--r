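## Rank-based test for enrichment of oral (buccal) species in one cohort.
##
## Gut colonization by mouth-resident species is a hallmark of liver
## cirrhosis. Because their absolute abundances are small and zero-inflated,
## enrichment is assessed on within-sample abundance ranks rather than on
## the abundances themselves.

#' Rank-transform a species abundance matrix
#'
#' Let N be the number of species detected (abundance > 0) in at least one
#' sample; species never detected are dropped first. Within each sample the
#' detected species are ranked by decreasing abundance (1 = most abundant);
#' species undetected in that sample receive the sentinel rank N + 1.
#' Within-sample ties take the average rank rounded half-up, so tied species
#' share an integer rank; the transform is deterministic.
#'
#' @param abund a species-level [abundance_matrix()].
#' @return an integer species x sample matrix of class `rank_matrix` with
#'   attribute `N`.
#' @export
rank_transform <- function(abund) {
  m <- unclass(abund)
  detected_any <- rowSums(m > 0) > 0
  m <- m[detected_any, , drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]   # lexicographic determinism
  N <- nrow(m)
  out <- matrix(N + 1L, nrow = N, ncol = ncol(m),
                dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    det <- m[, j] > 0
    if (!any(det)) next
    r <- rank(-m[det, j], ties.method = "average")
    out[det, j] <- as.integer(floor(r + 0.5))   # half-up to integer ranks
  }
  structure(out, N = N, class = c("rank_matrix", class(out)))
}

#' One-tailed rank comparison of oral species between two cohorts
#'
#' For each designated oral species, the vectors of within-sample ranks (see
#' [rank_transform()]) of the two groups are compared with a one-tailed
#' Mann-Whitney test. The alternative is that the species is more abundant
#' — i.e. has numerically smaller ranks — in `groupA`. Sentinel ranks of
#' undetected species enter as ties; no multiple-testing adjustment is
#' applied.
#'
#' @param ranks a `rank_matrix` from [rank_transform()].
#' @param metadata a [sample_metadata()] data.frame.
#' @param species character vector of oral species labels; labels missing
#'   from the rank matrix are warned about and reported with `p = 1` and
#'   `detected = FALSE`.
#' @param groupA,groupB group labels; the test is for enrichment in
#'   `groupA`.
#' @return data.frame with columns `species`, `p`, `median_rank_A`,
#'   `median_rank_B`, `detected`.
#' @export
oral_rank_test <- function(ranks, metadata, species, groupA, groupB) {
  sa <- intersect(metadata$sample_id[metadata$group == groupA], colnames(ranks))
  sb <- intersect(metadata$sample_id[metadata$group == groupB], colnames(ranks))
  if (length(sa) == 0 || length(sb) == 0)
    stop("both groups must be non-empty")
  N <- attr(ranks, "N")
  missing <- setdiff(species, rownames(ranks))
  if (length(missing) > 0)
    warning(sprintf("oral species not in the rank matrix: %s",
                    paste(missing, collapse = ", ")))
  res <- lapply(species, function(sp) {
    if (!sp %in% rownames(ranks))
      return(data.frame(species = sp, p = 1, median_rank_A = NA_real_,
                        median_rank_B = NA_real_, detected = FALSE,
                        stringsAsFactors = FALSE))
    ra <- unclass(ranks)[sp, sa]
    rb <- unclass(ranks)[sp, sb]
    if (all(ra == N + 1) && all(rb == N + 1)) {
      p <- 1
      detected <- FALSE
    } else {
      ## smaller rank = more abundant, so enrichment in A means ranks_A < ranks_B
      p <- mann_whitney(ra, rb, alternative = "less")$p
      detected <- TRUE
    }
    data.frame(species = sp, p = p,
               median_rank_A = stats::median(ra),
               median_rank_B = stats::median(rb),
               detected = detected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ordered enrichment table of oral species detections
#'
#' Lists every (sample, oral species) pair whose relative abundance strictly
#' exceeds `min_percent`, sorted by decreasing abundance — the tabular view
#' of which patients carry substantial loads of mouth-resident species.
#'
#' @param abund a species-level [abundance_matrix()].
#' @param species character vector of oral species labels.
#' @param min_percent inclusion threshold in percent (strict `>`).
#' @return data.frame with columns `sample`, `species`, `abundance`.
#' @export
enrichment_table <- function(abund, species, min_percent = 1.0) {
  present <- intersect(species, rownames(abund))
  m <- unclass(abund)[present, , drop = FALSE]
  idx <- which(m > min_percent, arr.ind = TRUE)
  out <- data.frame(sample = colnames(m)[idx[, 2]],
                    species = rownames(m)[idx[, 1]],
                    abundance = m[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
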