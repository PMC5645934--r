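make_bc <- function(m) bray_curtis(abund_fixture(m))

test_that("PERMANOVA pseudo-F and R2 agree with the hand sums-of-squares oracle", {
  set.seed(61)
  m <- matrix(runif(25 * 8, 0, 5), nrow = 25)
  m <- 100 * sweep(m, 2, colSums(m), "/")
  d <- make_bc(m)
  f <- rep(c("a", "b"), each = 4)
  fit <- permanova(d, f, n_perm = 99, seed = 1)
  oracle <- permanova_hand_oracle(unclass(d), f)
  expect_equal(fit$F, oracle$F, tolerance = 1e-9)
  expect_equal(fit$R2, oracle$R2, tolerance = 1e-9)
  expect_gte(fit$p, 1 / 100)
})

test_that("PERMANOVA permutation p converges to the exhaustive value on small fixtures", {
  set.seed(62)
  m <- matrix(runif(20 * 8, 0, 5), nrow = 20)
  m[1:5, 1:4] <- m[1:5, 1:4] * 4
  m <- 100 * sweep(m, 2, colSums(m), "/")
  d <- make_bc(m)
  f <- rep(c("a", "b"), each = 4)
  # exhaustive: all 70 assignments of 4 labels among 8 samples
  obs <- permanova_hand_oracle(unclass(d), f)$F
  idx <- utils::combn(8, 4)
  f_all <- apply(idx, 2, function(i) {
    g <- rep("b", 8); g[i] <- "a"
    permanova_hand_oracle(unclass(d), g)$F
  })
  p_exhaustive <- mean(f_all >= obs - 1e-12)
  fit <- permanova(d, f, n_perm = 9999, seed = 3)
  expect_lt(abs(fit$p - p_exhaustive), 0.01)
})

test_that("PERMANOVA is deterministic under a seed and invariant to duplication", {
  set.seed(63)
  m <- matrix(runif(30 * 12, 0, 5), nrow = 30)
  m <- 100 * sweep(m, 2, colSums(m), "/")
  colnames(m) <- paste0("s", 1:12)
  rownames(m) <- paste0("sp", 1:30)
  d <- make_bc(m)
  f <- rep(c("a", "b"), each = 6)
  p1 <- permanova(d, f, n_perm = 199, seed = 9)
  p2 <- permanova(d, f, n_perm = 199, seed = 9)
  expect_identical(p1$p, p2$p)

  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", 1:24)
  d2 <- bray_curtis(abundance_matrix(m2, "species"))
  p3 <- permanova(d2, c(f, f), n_perm = 99, seed = 9)
  expect_equal(p3$R2, p1$R2, tolerance = 1e-9)

  expect_error(permanova(d, rep("a", 12)), ">= 2 levels")
})

test_that("the factor screen adjusts across factors and is order-deterministic", {
  cfg <- simulation_config(n_ads = 25, n_alc = 0, n_control = 25,
                           n_genes = 0, n_species = 120,
                           ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = list(n = 0),
                           vf_spec = list(n_vf = 0), seed = 640)
  coh <- generate_cohort(cfg)
  sp <- cohort_species_abundance(coh)
  d <- bray_curtis(prevalence_filter(sp, 0.1))
  scr <- permanova_screen(d, coh$metadata, c("dependence", "gender"),
                          n_perm = 199, seed = 11)
  expect_identical(scr$factor, c("dependence", "gender"))
  expect_equal(scr$p_adj, bh_adjust(scr$p))
  # dependence carries the planted structure, gender does not
  expect_lt(scr$p_adj[scr$factor == "dependence"], 0.05)

  scr2 <- permanova_screen(d, coh$metadata, c("gender", "dependence"),
                           n_perm = 199, seed = 11)
  expect_equal(scr2$p[scr2$factor == "dependence"],
               scr$p[scr$factor == "dependence"])
})

test_that("multifactor association assigns planted effects to the right factor and sign", {
  cfg <- simulation_config(n_genes = 0, seed = 650)
  coh <- generate_cohort(cfg)
  sp <- prevalence_filter(cohort_species_abundance(coh), 0.1)
  assoc <- multifactor_association(sp, coh$metadata)
  tr <- coh$truth$species_effects
  correct <- 0
  for (i in seq_len(nrow(tr))) {
    row <- assoc[assoc$taxon == tr$species[i] & assoc$factor == tr$factor[i], ]
    if (nrow(row) == 1 && row$significant &&
        row$direction == sign(log(tr$effect[i]))) correct <- correct + 1
  }
  expect_gte(correct / nrow(tr), 0.8)
})

test_that("a shared enrichment under both factors loads on the dependence term", {
  # one taxon planted higher in both patient groups: the cirrhosis term
  # absorbs the extra ALC effect, dependence carries the shared part
  eff <- data.frame(clade = "Bifidobacterium|Lactobacillus", n = 3,
                    factor = "dependence", effect = 4,
                    stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = 0, species_effects = eff,
                           ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = list(n = 0),
                           vf_spec = list(n_vf = 0), seed = 660)
  coh <- generate_cohort(cfg)
  sp <- prevalence_filter(cohort_species_abundance(coh), 0.1)
  assoc <- multifactor_association(sp, coh$metadata)
  planted <- coh$truth$species_effects$species
  rows <- assoc[assoc$taxon %in% planted & assoc$factor == "dependence", ]
  expect_gte(sum(rows$significant & rows$direction > 0), 2)
})

test_that("null taxa are rarely called and constant factors are dropped", {
  set.seed(670)
  hits <- replicate(40, {
    m <- matrix(rlnorm(60 * 40, 0, 1), nrow = 60)
    m <- 100 * sweep(m, 2, colSums(m), "/")
    rownames(m) <- paste0("sp", 1:60); colnames(m) <- paste0("s", 1:40)
    meta <- sample_metadata(data.frame(
      sample_id = colnames(m),
      group = rep(c("ADS", "Control"), each = 20),
      gender = sample(c("F", "M"), 40, replace = TRUE)))
    a <- multifactor_association(abundance_matrix(m, "species"), meta,
                                 factors = c("dependence", "gender"))
    c(raw = mean(a$p < 0.05), fdr = sum(a$significant))
  })
  expect_equal(mean(hits["raw", ]), 0.05, tolerance = 0.02)
  expect_lte(mean(hits["fdr", ] > 0), 0.1)

  m <- matrix(rlnorm(20 * 12), nrow = 20)
  m <- 100 * sweep(m, 2, colSums(m), "/")
  rownames(m) <- paste0("sp", 1:20); colnames(m) <- paste0("s", 1:12)
  meta <- sample_metadata(data.frame(sample_id = colnames(m),
                                     group = rep(c("ADS", "Control"), 6),
                                     gender = rep("M", 12)))
  expect_warning(
    a <- multifactor_association(abundance_matrix(m, "species"), meta,
                                 factors = c("dependence", "gender"),
                                 min_samples = 3),
    "constant")
  expect_false("gender" %in% a$factor)
})

test_that("single-factor association agrees in direction with the rank test", {
  cfg <- simulation_config(n_ads = 40, n_alc = 0, n_control = 40,
                           n_genes = 0, ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = list(n = 0),
                           vf_spec = list(n_vf = 0), seed = 680)
  coh <- generate_cohort(cfg)
  sp <- prevalence_filter(cohort_species_abundance(coh), 0.1)
  assoc <- multifactor_association(sp, coh$metadata,
                                   factors = "dependence")
  diff <- differential_features(sp, coh$metadata, "ADS", "Control",
                                q_threshold = 0.05)
  tr <- coh$truth$species_effects
  tr <- tr[tr$factor == "dependence" & tr$species %in% rownames(sp), ]
  agree <- 0
  for (s in tr$species) {
    a_dir <- assoc$direction[assoc$taxon == s & assoc$factor == "dependence"]
    d_dir <- diff$direction[diff$feature == s]
    if (length(a_dir) == 1 && length(d_dir) == 1 && a_dir == d_dir)
      agree <- agree + 1
  }
  expect_gte(agree / nrow(tr), 0.95)
})
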