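## Two-group differential abundance: Mann-Whitney rank test with
## Benjamini-Hochberg FDR control, and pathway-level calling on KO results.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by enumeration when the pooled sample size is at most 12
#' and the data are tie-free; otherwise the normal approximation with tie
#' correction (and continuity correction). The `U` statistic counts pairs
#' won by `a`; `alternative = "greater"` tests whether `a` is stochastically
#' greater than `b`.
#'
#' @param a,b non-empty numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (of `a`
#'   relative to `b`).
#' @return a list with elements `U` and `p`.
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  if (length(unique(c(a, b))) == 1)   # no separation at all
    return(list(U = length(a) * length(b) / 2, p = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alt, exact = exact,
                       correct = !exact)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output keeps
#' the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Feature-wise two-group differential abundance
#'
#' Each retained feature is compared between the two groups with a
#' two-sided Mann-Whitney test; Benjamini-Hochberg adjustment is applied
#' across the retained features only (after the prevalence filter), so the
#' filter must precede testing. Direction is the sign of the group-A minus
#' group-B median difference (mean difference when the medians tie).
#'
#' @param abund an [abundance_matrix()].
#' @param metadata a [sample_metadata()] data.frame covering the samples.
#' @param groupA,groupB group labels from `metadata$group`.
#' @param q_threshold significance threshold on the adjusted p-value.
#' @param filter_spec optional list `list(threshold_percent = ...)`; when
#'   given, [prevalence_filter()] is applied before testing.
#' @return a data.frame of class `differential_result` with one row per
#'   retained feature: `feature`, `U`, `p`, `q`, `direction`, per-group
#'   medians and means, and `significant`.
#' @export
differential_features <- function(abund, metadata, groupA, groupB,
                                  q_threshold = 0.01, filter_spec = NULL) {
  if (!is.null(filter_spec))
    abund <- prevalence_filter(abund, filter_spec$threshold_percent)
  sa <- metadata$sample_id[metadata$group == groupA]
  sb <- metadata$sample_id[metadata$group == groupB]
  sa <- intersect(sa, colnames(abund))
  sb <- intersect(sb, colnames(abund))
  if (length(sa) == 0 || length(sb) == 0)
    stop("both groups must contain samples present in the abundance matrix")
  if (length(sa) < 3 || length(sb) < 3)
    warning("a group has fewer than 3 samples; tests still run")
  m <- unclass(abund)
  res <- lapply(rownames(m), function(f) {
    xa <- m[f, sa]
    xb <- m[f, sb]
    mw <- mann_whitney(xa, xb, alternative = "two_sided")
    dmed <- stats::median(xa) - stats::median(xb)
    dir <- sign(if (dmed != 0) dmed else mean(xa) - mean(xb))
    data.frame(feature = f, U = mw$U, p = mw$p, direction = dir,
               median_A = stats::median(xa), median_B = stats::median(xb),
               mean_A = mean(xa), mean_B = mean(xb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_threshold
  out <- out[, c("feature", "U", "p", "q", "direction", "median_A",
                 "median_B", "mean_A", "mean_B", "significant")]
  rownames(out) <- NULL
  attr(out, "groupA") <- groupA
  attr(out, "groupB") <- groupB
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Pathway-level calls from KO differential results
#'
#' A pathway is retained when at least half of its member KO terms are
#' differentially abundant. Membership counts only the KOs present in the
#' supplied KO results (i.e. detected in the data), not every KO annotated
#' to the pathway. The majority direction of the differential members is
#' reported; an exact split is flagged `"mixed"`.
#'
#' @param ko_results a `differential_result` table at KO level (typically
#'   computed at q < 0.05).
#' @param pathway_map data.frame with columns `ko`, `pathway`.
#' @return a data.frame of class `pathway_result` with columns `pathway`,
#'   `n_members`, `n_diff`, `fraction`, `retained`, `direction`.
#' @export
pathway_calls <- function(ko_results, pathway_map) {
  stopifnot(all(c("ko", "pathway") %in% names(pathway_map)))
  pm <- pathway_map[, c("ko", "pathway")]
  pm$ko <- as.character(pm$ko)
  pm$pathway <- as.character(pm$pathway)
  rows <- lapply(split(pm$ko, pm$pathway), unique)
  res <- lapply(names(rows), function(pw) {
    kos <- intersect(rows[[pw]], ko_results$feature)
    if (length(kos) == 0) {
      warning(sprintf("pathway '%s' has no KO mapped in the results; skipped",
                      pw))
      return(NULL)
    }
    sub <- ko_results[ko_results$feature %in% kos, , drop = FALSE]
    diff <- sub[sub$significant, , drop = FALSE]
    n_up <- sum(diff$direction > 0)
    n_dn <- sum(diff$direction < 0)
    direction <- if (nrow(diff) == 0) NA_character_
                 else if (n_up > n_dn) "increased"
                 else if (n_dn > n_up) "decreased"
                 else "mixed"
    frac <- nrow(diff) / length(kos)
    data.frame(pathway = pw, n_members = length(kos), n_diff = nrow(diff),
               fraction = frac, retained = frac >= 0.5,
               direction = direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(pathway = character(0), n_members = integer(0),
                      n_diff = integer(0), fraction = numeric(0),
                      retained = logical(0), direction = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pathway_result", "data.frame")
  out
}
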