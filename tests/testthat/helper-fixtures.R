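# Shared fixtures and independent oracles used across the test files.

no_species_effects <- function() {
  data.frame(clade = character(0), n = numeric(0), factor = character(0),
             effect = numeric(0), stringsAsFactors = FALSE)
}

no_ko_effects <- function() {
  data.frame(n = numeric(0), factor = character(0), effect = numeric(0),
             stringsAsFactors = FALSE)
}

# A null cohort configuration: no planted structure unless overridden.
null_config <- function(..., seed) {
  simulation_config(n_genes = 0,
                    species_effects = no_species_effects(),
                    ko_effects = no_ko_effects(),
                    oral_spike = list(species = character(0)),
                    outlier_spec = list(n = 0),
                    vf_spec = list(n_vf = 0),
                    seed = seed, ...)
}

# Species-level relative abundance of a cohort, through the normalization path.
cohort_species_abundance <- function(cohort) {
  ab <- gene_relative_abundance(cohort$counts, cohort$annotation)
  if (identical(rownames(ab), cohort$truth$taxonomy$species))
    return(abundance_matrix(unclass(ab), level = "species"))
  aggregate_abundance(
    ab, stats::setNames(cohort$annotation$taxon_species,
                        cohort$annotation$gene_id),
    level = "species")
}

cohort_genus_abundance <- function(cohort) {
  sp <- cohort_species_abundance(cohort)
  aggregate_abundance(
    sp, stats::setNames(cohort$truth$taxonomy$genus,
                        cohort$truth$taxonomy$species),
    level = "genus")
}

# Small abundance matrix from a plain numeric matrix (percent columns).
abund_fixture <- function(m, level = "species") {
  if (is.null(rownames(m))) rownames(m) <- paste0("sp", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  abundance_matrix(m, level = level)
}

# --- independent oracles ----------------------------------------------------

# Exhaustive Mann-Whitney p-value by enumeration of all group labelings.
# U counts pairs won by `a` (with half-credit for ties).
mw_enumeration_oracle <- function(a, b, alternative) {
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  u_all <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  u_obs <- u_stat(a, b)
  m <- na * length(b)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two_sided = if (u_obs > m / 2) min(1, 2 * p_ge) else min(1, 2 * p_le))
}

# Hand step-up Benjamini-Hochberg with running-minimum monotonicity.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Pseudo-F and R2 computed directly from the sums of squared dissimilarities.
permanova_hand_oracle <- function(d, f) {
  f <- as.factor(f)
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (lev in levels(f)) {
    i <- which(f == lev)
    sub <- d[i, i, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(i)
  }
  ss_among <- ss_total - ss_within
  k <- nlevels(f)
  list(F = (ss_among / (k - 1)) / (ss_within / (n - k)),
       R2 = ss_among / ss_total)
}

# Procrustes distance after optimal rotation/reflection/translation.
procrustes_error <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(yc^2)
  max(abs(xc - sc * yc %*% rot))
}
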