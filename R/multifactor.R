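## Community-level variance partitioning (PERMANOVA) and per-taxon
## multifactor linear association modelling.

#' One-factor PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' is formed from among- and within-group sums of squared dissimilarities
#' and its null distribution obtained by permuting sample labels
#' (vegan's `adonis2` backend). The permutation p-value carries the +1
#' correction, \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}, so it is
#' never zero; \eqn{R^2 = SS_{among}/SS_{total}}.
#'
#' @param d a [dissimilarity_matrix()].
#' @param f per-sample factor (character or factor), >= 2 levels each with
#'   >= 2 samples.
#' @param n_perm number of permutations.
#' @param seed optional integer seed; fixing it makes the p-value
#'   reproducible.
#' @return a list of class `permanova_result` with `R2`, `F`, `p`,
#'   `n_perm`.
#' @export
permanova <- function(d, f, n_perm = 999, seed = NULL) {
  f <- as.factor(f)
  if (nlevels(droplevels(f)) < 2)
    stop("PERMANOVA requires a factor with >= 2 levels")
  if (any(table(droplevels(f)) < 2))
    warning("a factor level has fewer than 2 samples")
  if (length(f) != nrow(d))
    stop("factor length does not match the dissimilarity matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(unclass(d)) ~ f,
                        permutations = n_perm)
  structure(list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1],
                 n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, F = %.3f, p = %.4g (%d permutations)\n",
              x$R2, x$F, x$p, x$n_perm))
  invisible(x)
}

#' PERMANOVA screen over several clinical factors
#'
#' Runs a one-factor PERMANOVA per factor column of the metadata and
#' adjusts the permutation p-values across the factor set with
#' Benjamini-Hochberg. For determinism the seed is re-applied before each
#' factor, so a factor's raw p does not depend on its position in the list.
#'
#' @param d a [dissimilarity_matrix()]; row order must match
#'   `metadata$sample_id`.
#' @param metadata a [sample_metadata()] data.frame.
#' @param factors character vector of metadata column names (e.g.
#'   `c("dependence", "cirrhosis", "gender")`).
#' @param n_perm permutations per factor.
#' @param seed optional integer seed.
#' @return data.frame of class `permanova_screen` with columns `factor`,
#'   `R2`, `F`, `p`, `p_adj`, `n_perm`.
#' @export
permanova_screen <- function(d, metadata, factors, n_perm = 999,
                             seed = NULL) {
  idx <- match(rownames(d), metadata$sample_id)
  if (anyNA(idx)) stop("dissimilarity samples missing from metadata")
  rows <- lapply(factors, function(fc) {
    if (!fc %in% names(metadata))
      stop(sprintf("factor '%s' not in metadata", fc))
    pr <- permanova(d, metadata[[fc]][idx], n_perm = n_perm, seed = seed)
    data.frame(factor = fc, R2 = pr$R2, F = pr$F, p = pr$p,
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[, c("factor", "R2", "F", "p", "p_adj", "n_perm")]
  rownames(out) <- NULL
  class(out) <- c("permanova_screen", "data.frame")
  out
}

#' Multifactor linear association of taxa with clinical factors
#'
#' For every taxon abundant at > `min_abund` percent in at least
#' `min_samples` samples, fits an ordinary least-squares model of the
#' variance-stabilized abundance (arcsine of the square root of the
#' fraction) on the binary covariates jointly:
#'
#' `asin(sqrt(abundance/100)) ~ dependence + cirrhosis + gender`
#'
#' This is a classical plain-OLS approximation of boosted-GLM multivariate
#' association frameworks (MaAsLin-style); no boosting or feature selection
#' is performed, and outputs are labelled accordingly. Coefficient p-values
#' are Benjamini-Hochberg-adjusted jointly across all (taxon, factor)
#' pairs; a positive coefficient denotes a direct association between the
#' factor and the taxon's abundance.
#'
#' @param abund a taxon-level [abundance_matrix()].
#' @param metadata a [sample_metadata()] data.frame.
#' @param factors factor columns to include (yes/no or F/M encoded).
#' @param min_abund,min_samples retain a taxon when its abundance exceeds
#'   `min_abund` percent in at least `min_samples` samples.
#' @param q_threshold significance threshold on the adjusted p-value.
#' @return data.frame of class `association_result` with columns `taxon`,
#'   `factor`, `coefficient`, `p`, `q`, `direction`, `significant`.
#' @export
multifactor_association <- function(abund, metadata,
                                    factors = c("dependence", "cirrhosis",
                                                "gender"),
                                    min_abund = 0.01, min_samples = 10,
                                    q_threshold = 0.05) {
  idx <- match(colnames(abund), metadata$sample_id)
  if (anyNA(idx)) stop("abundance samples missing from metadata")
  meta <- metadata[idx, , drop = FALSE]
  keep <- rowSums(unclass(abund) > min_abund) >= min_samples
  m <- unclass(abund)[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no taxon passes the abundance filter")

  design <- list()
  for (fc in factors) {
    v <- meta[[fc]]
    x <- if (all(v %in% c("yes", "no"))) as.numeric(v == "yes")
         else if (all(v %in% c("F", "M"))) as.numeric(v == "M")
         else as.numeric(as.factor(v)) - 1
    if (length(unique(x)) < 2) {
      warning(sprintf("factor '%s' is constant in the data; dropped", fc))
      next
    }
    design[[fc]] <- x
  }
  if (length(design) == 0) stop("no usable factor remains")
  X <- as.data.frame(design)

  rows <- lapply(rownames(m), function(tx) {
    y <- asin(sqrt(pmin(m[tx, ], 100) / 100))
    fit <- stats::lm(y ~ ., data = X)
    sm <- summary(fit)$coefficients
    fcs <- intersect(names(design), rownames(sm))
    data.frame(taxon = tx, factor = fcs,
               coefficient = sm[fcs, "Estimate"],
               p = sm[fcs, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$direction <- sign(out$coefficient)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  attr(out, "model") <- "OLS on arcsine-sqrt fractions (plain-OLS approximation, no boosting)"
  class(out) <- c("association_result", "data.frame")
  out
}
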