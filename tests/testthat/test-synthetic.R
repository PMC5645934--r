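test_that("identical seeds give bitwise-identical studies", {
  cfg <- simulation_config(n_ads = 10, n_alc = 5, n_control = 8,
                           n_species = 120, n_genes = 3000,
                           reads_per_sample = 2e4, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(unclass(a$counts)[, ], unclass(b$counts)[, ])
  expect_identical(a$hits, b$hits)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$species_effects, b$truth$species_effects)
})

test_that("emitted counts normalize to exact percent columns", {
  cfg <- simulation_config(n_ads = 8, n_alc = 4, n_control = 6,
                           n_species = 100, n_genes = 2000,
                           reads_per_sample = 2e4, seed = 100)
  coh <- generate_cohort(cfg)
  ab <- gene_relative_abundance(coh$counts, coh$annotation)
  expect_equal(unname(colSums(ab)), rep(100, ncol(ab)), tolerance = 1e-9)
})

test_that("metadata encodes the clinical factors by group", {
  coh <- generate_cohort(null_config(n_ads = 3, n_alc = 3, n_control = 3,
                                     n_species = 60, seed = 101))
  md <- coh$metadata
  expect_true(all(md$dependence[md$group == "ALC"] == "yes"))
  expect_true(all(md$cirrhosis[md$group == "ALC"] == "yes"))
  expect_true(all(md$cirrhosis[md$group == "ADS"] == "no"))
  expect_true(all(md$dependence[md$group == "Control"] == "no"))
})

test_that("a 4x cirrhosis effect is realized at about 4x in the emitted data", {
  eff <- data.frame(clade = "Bacteroidales", n = 5, factor = "cirrhosis",
                    effect = 4, stringsAsFactors = FALSE)
  cfg <- simulation_config(n_ads = 0, n_alc = 27, n_control = 60,
                           n_genes = 0, species_effects = eff,
                           ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = list(n = 0),
                           vf_spec = list(n_vf = 0), seed = 102)
  coh <- generate_cohort(cfg)
  sp <- cohort_species_abundance(coh)
  alc <- coh$metadata$sample_id[coh$metadata$group == "ALC"]
  ctl <- coh$metadata$sample_id[coh$metadata$group == "Control"]
  planted <- coh$truth$species_effects$species
  ratios <- rowMeans(unclass(sp)[planted, alc, drop = FALSE]) /
    rowMeans(unclass(sp)[planted, ctl, drop = FALSE])
  expect_true(mean(ratios) > 3 && mean(ratios) < 5)
})

test_that("planted effects carry the planted sign in the emitted data", {
  coh <- generate_cohort(simulation_config(n_genes = 0, seed = 103))
  sp <- cohort_species_abundance(coh)
  md <- coh$metadata
  tr <- coh$truth$species_effects
  for (i in seq_len(nrow(tr))) {
    yes <- md$sample_id[md[[tr$factor[i]]] == "yes"]
    no <- md$sample_id[md[[tr$factor[i]]] == "no"]
    ratio <- mean(unclass(sp)[tr$species[i], yes]) /
      mean(unclass(sp)[tr$species[i], no])
    expect_equal(sign(log(ratio)), sign(log(tr$effect[i])),
                 info = tr$species[i])
  }
})

test_that("dominance spikes hit their target share and depress diversity", {
  spec <- list(n = 1, genera = "Prevotella", fraction = 0.71)
  cfg <- simulation_config(n_ads = 15, n_alc = 0, n_control = 0,
                           n_genes = 0, n_species = 150,
                           species_effects = no_species_effects(),
                           ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = spec, vf_spec = list(n_vf = 0),
                           seed = 104)
  coh <- generate_cohort(cfg)
  ge <- cohort_genus_abundance(coh)
  out <- coh$truth$outliers$sample
  expect_equal(coh$truth$outliers$genus, "Prevotella")
  realized <- unclass(ge)["Prevotella", out]
  expect_true(realized >= 68 && realized <= 74)
  sp <- cohort_species_abundance(coh)
  expect_lt(shannon_index(unclass(sp)[, out]), 2.5)
})

test_that("requesting zero outliers leaves the data untouched", {
  set.seed(105)
  m <- matrix(runif(50 * 6), nrow = 50,
              dimnames = list(paste0("sp", 1:50), paste0("s", 1:6)))
  m <- sweep(m, 2, colSums(m), "/")
  res <- spike_outliers(m, list(n = 0), NULL)
  expect_identical(res$fractions, m)
  expect_equal(nrow(res$truth), 0)
})

test_that("planted outliers in a small cohort are recovered end to end", {
  cfg <- simulation_config(n_ads = 20, n_alc = 0, n_control = 0,
                           n_genes = 0, n_species = 150,
                           species_effects = no_species_effects(),
                           ko_effects = no_ko_effects(),
                           oral_spike = list(species = character(0)),
                           outlier_spec = list(n = 2,
                                               genera = c("Prevotella",
                                                          "Bacteroides"),
                                               fraction = 0.7),
                           vf_spec = list(n_vf = 0), seed = 106)
  coh <- generate_cohort(cfg)
  sp <- prevalence_filter(cohort_species_abundance(coh), 0.1)
  rep <- detect_outliers(bray_curtis(sp), "ward")
  expect_setequal(rep$outliers, coh$truth$outliers$sample)
})

test_that("recovery rate increases with the planted effect size", {
  rates <- vapply(c(1.5, 2.5, 4), function(effect) {
    rec <- vapply(1:12, function(r) {
      eff <- data.frame(clade = "*", n = 8, factor = "dependence",
                        effect = effect, stringsAsFactors = FALSE)
      cfg <- simulation_config(n_ads = 30, n_alc = 0, n_control = 30,
                               n_species = 100, n_genes = 0,
                               species_effects = eff,
                               ko_effects = no_ko_effects(),
                               oral_spike = list(species = character(0)),
                               outlier_spec = list(n = 0),
                               vf_spec = list(n_vf = 0),
                               seed = 107000 + 100 * effect + r)
      coh <- generate_cohort(cfg)
      sp <- prevalence_filter(cohort_species_abundance(coh), 0.1)
      res <- differential_features(sp, coh$metadata, "ADS", "Control",
                                   q_threshold = 0.01)
      mean(coh$truth$species_effects$species %in%
             res$feature[res$significant])
    }, numeric(1))
    mean(rec)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("written studies are consumable by the readers without modification", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_ads = 6, n_alc = 4, n_control = 5,
                           n_species = 100, n_genes = 1500,
                           reads_per_sample = 1e4,
                           vf_spec = list(n_vf = 5, effect = 4,
                                          factor = "dependence"),
                           seed = 108)
  coh <- generate_cohort(cfg)
  write_study(coh, dir)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(unclass(counts)[, ], unclass(coh$counts)[, ])
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_true(all(md$dependence[md$group == "ALC"] == "yes" &
                    md$cirrhosis[md$group == "ALC"] == "yes"))
  ann <- read_gene_annotation(file.path(dir, "gene_annotation.tsv"))
  hits <- read_hits(file.path(dir, "hits.tsv"))
  ab <- gene_relative_abundance(counts, ann)
  expect_equal(unname(colSums(ab)), rep(100, ncol(ab)), tolerance = 1e-9)
  expect_s3_class(hits, "hit_table")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(length(truth$species_effects) > 0)
})
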