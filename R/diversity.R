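## Alpha diversity, Bray-Curtis dissimilarity, classical MDS ordination,
## dendrogram-based outlier detection and dominance reporting.

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the nonzero entries of a sample's
#' composition, in nats. Abundances are renormalized internally, so the
#' index is invariant to the scale of the input column.
#'
#' @param x a non-negative vector (one sample) or an [abundance_matrix()]
#'   (one index per sample column).
#' @return a numeric value, or a named vector for a matrix input.
#' @export
shannon_index <- function(x) {
  if (is.matrix(x)) {
    return(vapply(colnames(x), function(s) shannon_index(unclass(x)[, s]),
                  numeric(1)))
  }
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("all-zero composition has no Shannon index")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Welch's unequal-variance t-test between two groups
#'
#' @param a,b numeric vectors, each of length >= 2 with nonzero variance.
#' @return a list with elements `t` and `p` (two-sided).
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("Welch's test requires n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1))
    stop("degenerate zero-variance groups")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)},
#' bounded in \[0, 1\]. Bray-Curtis is not a metric (the triangle inequality
#' can fail); it is used here for ordination, clustering and PERMANOVA, none
#' of which require metricity.
#'
#' @param abund an [abundance_matrix()] (samples in columns).
#' @return a sample x sample matrix of class `dissimilarity_matrix` with a
#'   `metric` attribute.
#' @export
bray_curtis <- function(abund) {
  m <- unclass(abund)
  tot <- colSums(m)
  if (any(tot <= 0))
    stop(sprintf("sample '%s' has zero total abundance",
                 colnames(m)[which(tot <= 0)[1]]))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dissimilarity_matrix(d, metric = "braycurtis")
}

#' Construct a dissimilarity matrix container
#' @param d symmetric numeric matrix with zero diagonal and dimnames.
#' @param metric metric label, e.g. `"braycurtis"` or `"euclidean"`.
#' @return a matrix of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(d, metric = "braycurtis") {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("dissimilarity matrix requires sample ids")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("dissimilarity matrix must have zero diagonal")
  structure(d, metric = metric,
            class = c("dissimilarity_matrix", class(d)))
}

#' Classical (metric) multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared-dissimilarity matrix;
#' coordinate axes are ordered by decreasing eigenvalue and axes with
#' non-positive eigenvalues are dropped. If fewer than `k` positive
#' eigenvalues exist, the result is truncated with a warning.
#'
#' @param d a [dissimilarity_matrix()].
#' @param k number of requested dimensions (>= 1).
#' @return a sample x k' coordinate matrix (k' <= k) with an `eig`
#'   attribute holding the eigenvalues.
#' @export
mds_ordinate <- function(d, k = 2) {
  stopifnot(k >= 1)
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(unclass(d)), k = min(k, n - 1),
                         eig = TRUE)
  pos <- sum(fit$eig > 1e-8)
  if (pos < k) {
    warning(sprintf("only %d positive eigenvalue(s); coordinates truncated",
                    pos))
  }
  keep <- seq_len(min(k, max(pos, 1), ncol(fit$points)))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("MDS", keep)
  attr(coords, "eig") <- fit$eig
  coords
}

#' Detect outlier samples at the dendrogram's top-level cut
#'
#' Samples are hierarchically clustered on the dissimilarity matrix and the
#' tree is cut at the top level into two branches; the members of the
#' smaller branch are reported as outliers. An exact tie in branch sizes
#' yields an empty outlier set with a warning, since "smaller branch" is
#' then undefined.
#'
#' @param d a [dissimilarity_matrix()] over >= 3 samples.
#' @param linkage `"ward"` (Ward's minimum-variance, `hclust` method
#'   `ward.D2`) or `"complete"`.
#' @param genus_abund optional genus-level [abundance_matrix()]; when given,
#'   the report carries each sample's dominant genus, its abundance and the
#'   sample's Shannon index.
#' @return a list of class `outlier_report` with elements `outliers`,
#'   `linkage`, `metric`, `tree` (the `hclust` object) and, when
#'   `genus_abund` is supplied, a `dominance` data.frame.
#' @export
detect_outliers <- function(d, linkage = c("ward", "complete"),
                            genus_abund = NULL) {
  linkage <- match.arg(linkage)
  if (nrow(d) < 3) stop("outlier detection requires >= 3 samples")
  method <- c(ward = "ward.D2", complete = "complete")[[linkage]]
  tree <- stats::hclust(stats::as.dist(unclass(d)), method = method)
  cl <- stats::cutree(tree, k = 2)
  sizes <- table(cl)
  if (sizes[[1]] == sizes[[2]]) {
    warning("top-level branches are equal-sized; no outliers designated")
    out <- character(0)
  } else {
    small <- as.integer(names(sizes)[which.min(sizes)])
    out <- names(cl)[cl == small]
  }
  report <- list(outliers = out, linkage = linkage,
                 metric = attr(d, "metric"), tree = tree)
  if (!is.null(genus_abund) && length(out) > 0) {
    dom <- dominance_report(genus_abund)
    dom <- dom[dom$sample %in% out, , drop = FALSE]
    dom$shannon <- shannon_index(genus_abund)[dom$sample]
    rownames(dom) <- NULL
    report$dominance <- dom
  }
  class(report) <- "outlier_report"
  report
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier report (%s linkage, %s metric): %d outlier(s)\n",
              x$linkage, x$metric, length(x$outliers)))
  if (length(x$outliers) > 0)
    cat(" ", paste(x$outliers, collapse = ", "), "\n")
  if (!is.null(x$dominance)) print(x$dominance)
  invisible(x)
}

#' Per-sample dominance report
#'
#' For each sample, the most abundant genus and its relative abundance; the
#' sample is flagged when that abundance exceeds `threshold_percent`. The
#' threshold is a parameter (the notion of a "dominated" community has no
#' canonical cutoff); 50% by default.
#'
#' @param genus_abund a genus-level [abundance_matrix()].
#' @param threshold_percent dominance flag threshold in percent.
#' @return data.frame with columns `sample`, `top_genus`, `abundance`,
#'   `dominated`.
#' @export
dominance_report <- function(genus_abund, threshold_percent = 50) {
  m <- unclass(genus_abund)
  top <- apply(m, 2, which.max)
  ab <- m[cbind(top, seq_len(ncol(m)))]
  data.frame(sample = colnames(m),
             top_genus = rownames(m)[top],
             abundance = ab,
             dominated = ab > threshold_percent,
             stringsAsFactors = FALSE, row.names = NULL)
}
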