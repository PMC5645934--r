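## Synthetic study generator: emits a complete set of pipeline inputs
## (gene read counts, gene annotations, sample metadata, homology hits)
## with a planted effect structure and a truth registry, so every analysis
## stage has a recovery-testable fixture.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: a 72/27/60 cohort
#' (dependence-only patients, cirrhosis patients, controls), ~300 species,
#' 20,000 catalogue genes and 100,000 reads per sample (read depth is
#' scaled down from sequencing scale to desk scale; configurable upward).
#' Baseline species composition is log-normal (heavy-tailed, so a few
#' genera such as Bacteroides/Prevotella dominate at the ~20% level) with
#' per-sample log-normal noise.
#'
#' Planted effects mirror the study's structure: dependence-linked
#' depletion of Clostridiales commensals and enrichment of
#' Enterobacteriaceae (with virulence-factor genes), cirrhosis-linked
#' depletion of Bacteroidales and spike-ins of oral species, and
#' Bifidobacterium/Lactobacillus enrichment under both factors but through
#' disjoint species sets. Effects are multiplicative on the underlying
#' fractions before renormalization.
#'
#' @param n_ads,n_alc,n_control cohort sizes.
#' @param n_species number of species in the pool.
#' @param n_genes number of catalogue genes; `0` generates species-level
#'   counts directly (one pseudo-gene per species).
#' @param reads_per_sample mean mapped reads per sample.
#' @param base_meanlog,base_sdlog log-normal parameters of the baseline
#'   composition.
#' @param sample_sdlog standard deviation of the per-sample, per-species
#'   idiosyncratic log-normal noise.
#' @param n_gradients,gradient_sdlog inter-individual variation is modelled
#'   as `n_gradients` community-wide gradients (enterotype-like axes): each
#'   genus carries a normal loading with standard deviation
#'   `gradient_sdlog` on each axis, each sample a standard-normal score,
#'   and member species inherit their genus loading. Whole genera therefore
#'   covary across individuals, which is what drives the large
#'   between-sample spread of the dominant genera in real cohorts.
#' @param species_effects data.frame of effect rules with columns `clade`
#'   (genus or higher-rank tag, `|`-separated alternatives), `n` (species
#'   drawn from the clade), `factor` (`dependence`/`cirrhosis`), `effect`
#'   (multiplicative, > 0). `NULL` plants the default structure; an empty
#'   data.frame plants nothing (pure null).
#' @param ko_effects like `species_effects` but with column `n` drawn from
#'   the alcohol-metabolism KO panel; `NULL` = default (6 dependence-linked,
#'   9 cirrhosis-linked, 3x), empty data.frame = none.
#' @param oral_spike `NULL` or list(`species`, `group`, `prob`,
#'   `range_percent`): each sample of `group` receives, with probability
#'   `prob` per species, a spike of that oral species at a relative
#'   abundance drawn uniformly from `range_percent`.
#' @param outlier_spec `NULL` or list(`n`, `genera`, `fraction`): `n`
#'   patient samples are turned into dominance outliers, each with one
#'   genus scaled to `fraction` of the community.
#' @param vf_spec `NULL` or list(`n_vf`, `effect`, `factor`): virulence
#'   factor reference genes hit by Enterobacteriaceae-tagged catalogue
#'   genes, boosted multiplicatively in samples positive for `factor`.
#' @param alcohol_kos character vector of KO labels for the
#'   alcohol-metabolism panel; defaults to the packaged 19-KO configuration
#'   ([default_alcohol_kos()]).
#' @param n_filler_kos number of additional (null) KO groups.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_ads = 72, n_alc = 27, n_control = 60,
                              n_species = 300, n_genes = 20000,
                              reads_per_sample = 1e5,
                              base_meanlog = 0, base_sdlog = 2,
                              sample_sdlog = 0.3,
                              n_gradients = 2, gradient_sdlog = 0.15,
                              species_effects = NULL,
                              ko_effects = NULL,
                              oral_spike = NULL,
                              outlier_spec = NULL,
                              vf_spec = NULL,
                              alcohol_kos = default_alcohol_kos(),
                              n_filler_kos = 120,
                              seed = 1) {
  if (is.null(species_effects))
    species_effects <- data.frame(
      clade = c("Clostridiales", "Enterobacteriaceae",
                "Bifidobacterium|Lactobacillus",
                "Bacteroidales", "Bifidobacterium|Lactobacillus"),
      n = c(8, 4, 4, 8, 4),
      factor = c("dependence", "dependence", "dependence",
                 "cirrhosis", "cirrhosis"),
      effect = c(0.25, 4, 4, 0.25, 4),
      stringsAsFactors = FALSE)
  if (is.null(ko_effects))
    ko_effects <- data.frame(
      n = c(6, 9),
      factor = c("dependence", "cirrhosis"),
      effect = c(3, 3),
      stringsAsFactors = FALSE)
  if (is.null(oral_spike))
    oral_spike <- list(species = oral_species_panel(), group = "ALC",
                       prob = 0.9, range_percent = c(0.5, 6))
  if (is.null(outlier_spec))
    outlier_spec <- list(n = 3,
                         genera = c("Prevotella", "Bacteroides",
                                    "Lactobacillus"),
                         fraction = 0.70)
  if (is.null(vf_spec))
    vf_spec <- list(n_vf = 50, effect = 4, factor = "dependence")
  cfg <- list(n_ads = n_ads, n_alc = n_alc, n_control = n_control,
              n_species = n_species, n_genes = n_genes,
              reads_per_sample = reads_per_sample,
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              sample_sdlog = sample_sdlog,
              n_gradients = n_gradients, gradient_sdlog = gradient_sdlog,
              species_effects = species_effects, ko_effects = ko_effects,
              oral_spike = oral_spike, outlier_spec = outlier_spec,
              vf_spec = vf_spec, alcohol_kos = alcohol_kos,
              n_filler_kos = n_filler_kos, seed = seed)
  stopifnot(cfg$n_ads >= 0, cfg$n_alc >= 0, cfg$n_control >= 0,
            cfg$n_species >= 2, cfg$reads_per_sample >= 100,
            all(cfg$species_effects$effect > 0))
  if (!is.null(cfg$outlier_spec) && cfg$outlier_spec$n > 0)
    stopifnot(cfg$outlier_spec$fraction > 0, cfg$outlier_spec$fraction < 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' The five oral (buccal) marker species used by default
#' @return character vector of species labels.
#' @export
oral_species_panel <- function() {
  c("Streptococcus salivarius", "Veillonella atypica",
    "Veillonella dispar", "Veillonella parvula",
    "Lactobacillus salivarius")
}

#' Default alcohol-metabolism KO panel (configuration, not hard-coded truth)
#'
#' Nineteen KEGG orthology labels covering alcohol, aldehyde and
#' acetaldehyde dehydrogenases plus acetate activation, read from the
#' packaged configuration file. Supply your own vector to
#' [simulation_config()] or [subset_ko()] to analyze a different panel.
#'
#' @return character vector of 19 KO labels.
#' @export
default_alcohol_kos <- function() {
  path <- system.file("extdata", "alcohol_metabolism_kos.txt",
                      package = "gutshift")
  if (!nzchar(path)) stop("packaged KO configuration not found")
  x <- readLines(path)
  x <- trimws(sub("\t.*", "", x))
  x[nzchar(x) & !startsWith(x, "#")]
}

## Genus pool with higher-rank clade tags used by the species effect rules.
.genus_pool <- function() {
  data.frame(
    genus = c("Bacteroides", "Prevotella", "Alistipes", "Parabacteroides",
              "Odoribacter", "Paraprevotella",
              "Faecalibacterium", "Roseburia", "Coprococcus", "Blautia",
              "Clostridium", "Ruminococcus", "Eubacterium", "Dorea",
              "Bifidobacterium", "Lactobacillus", "Streptococcus",
              "Enterococcus", "Lactococcus", "Veillonella",
              "Escherichia", "Klebsiella", "Citrobacter",
              "Akkermansia", "Phascolarctobacterium"),
    clade = c(rep("Bacteroidales", 6),
              rep("Clostridiales", 8),
              "Bifidobacteriales", rep("Lactobacillales", 3), "Lactobacillales",
              "Veillonellales",
              rep("Enterobacteriaceae", 3),
              "Verrucomicrobiales", "Veillonellales"),
    weight = c(6, 5, 3, 3, 1, 1,
               5, 3, 3, 4, 4, 4, 3, 2,
               3, 3, 3, 2, 1, 1,
               2, 1, 1,
               1, 1),
    stringsAsFactors = FALSE)
}

.make_taxonomy <- function(n_species) {
  pool <- .genus_pool()
  oral <- data.frame(
    species = oral_species_panel(),
    genus = c("Streptococcus", "Veillonella", "Veillonella", "Veillonella",
              "Lactobacillus"),
    stringsAsFactors = FALSE)
  n_rest <- n_species - nrow(oral)
  if (n_rest < length(pool$genus)) stop("n_species too small for the genus pool")
  ## deterministic weight-proportional allocation (at least one per genus)
  ## so effect and outlier rules can always draw on every clade
  alloc <- diff(c(0, round(cumsum(pool$weight) / sum(pool$weight) * n_rest)))
  alloc <- pmax(alloc, 1)
  while (sum(alloc) > n_rest) {
    i <- which.max(alloc); alloc[i] <- alloc[i] - 1
  }
  g <- rep(pool$genus, alloc)
  cnt <- stats::ave(seq_along(g), g, FUN = seq_along)
  tax <- rbind(oral,
               data.frame(species = sprintf("%s sp%02d", g, cnt), genus = g,
                          stringsAsFactors = FALSE))
  tax$clade <- pool$clade[match(tax$genus, pool$genus)]
  tax$oral <- tax$species %in% oral$species
  rownames(tax) <- NULL
  tax
}

.materialize_species_effects <- function(rules, taxonomy, base) {
  if (nrow(rules) == 0)
    return(data.frame(species = character(0), factor = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE))
  used <- character(0)
  out <- lapply(seq_len(nrow(rules)), function(i) {
    alts <- strsplit(rules$clade[i], "|", fixed = TRUE)[[1]]
    hit <- if (identical(alts, "*")) rep(TRUE, nrow(taxonomy))
           else taxonomy$genus %in% alts | taxonomy$clade %in% alts
    cand <- taxonomy$species[hit & !taxonomy$oral]
    cand <- setdiff(cand, used)
    if (length(cand) < rules$n[i])
      stop(sprintf("not enough species in clade '%s' for the effect rule",
                   rules$clade[i]))
    ## effects represent reported signature taxa: prevalent but not
    ## community-dominating, so draw the clade members closest to a typical
    ## 0.5% baseline share -- detectable after the prevalence filters yet
    ## light enough that renormalization does not distort the fold change
    frac <- base[match(cand, taxonomy$species)] / sum(base)
    cand <- cand[order(abs(log(frac) - log(0.005)))]
    pool <- utils::head(cand, 2 * rules$n[i])
    sel <- sample(pool, rules$n[i])
    used <<- c(used, sel)
    data.frame(species = sel, factor = rules$factor[i],
               effect = rules$effect[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Turn selected samples into single-genus dominance outliers
#'
#' Rescales each target sample so that one genus occupies the requested
#' fraction of the community; the remaining species are renormalized to
#' share the complement. The genus's mass is concentrated on a single
#' member species (a bloom of one opportunist, drawn at random from the
#' genus), reproducing the low species-level alpha diversity (Shannon
#' index around 1.6-2.3 nats) that accompanies single-genus dominance in
#' real dysbiotic communities.
#' Operates on a species x sample matrix of fractions (columns summing
#' to 1).
#'
#' @param fractions species x sample numeric matrix, columns summing to 1.
#' @param spec list(`n`, `genera`, `fraction`) as in
#'   [simulation_config()]; optionally `samples` naming the target columns
#'   (otherwise drawn at random).
#' @param taxonomy data.frame with columns `species`, `genus` covering the
#'   rows of `fractions`.
#' @return list with elements `fractions` (modified matrix) and `truth`
#'   (data.frame `sample`, `genus`, `fraction`).
#' @export
spike_outliers <- function(fractions, spec, taxonomy) {
  if (is.null(spec) || spec$n == 0)
    return(list(fractions = fractions,
                truth = data.frame(sample = character(0),
                                   genus = character(0),
                                   fraction = numeric(0),
                                   stringsAsFactors = FALSE)))
  stopifnot(spec$fraction > 0, spec$fraction < 1)
  samples <- spec$samples
  if (is.null(samples))
    samples <- sample(colnames(fractions), spec$n)
  genera <- rep_len(spec$genera, spec$n)
  for (i in seq_len(spec$n)) {
    rows <- taxonomy$species[taxonomy$genus == genera[i]]
    rows <- intersect(rows, rownames(fractions))
    if (length(rows) == 0)
      stop(sprintf("target genus '%s' absent from the species pool", genera[i]))
    col <- fractions[, samples[i]]
    top <- if (length(rows) == 1) rows else sample(rows, 1)
    ## the bloom displaces its congeners entirely, so the genus share equals
    ## the target up to counting noise
    col[setdiff(rows, top)] <- 0
    others <- setdiff(rownames(fractions), rows)
    col[others] <- col[others] * (1 - spec$fraction) / sum(col[others])
    col[top] <- spec$fraction
    fractions[, samples[i]] <- col
  }
  list(fractions = fractions,
       truth = data.frame(sample = samples, genus = genera,
                          fraction = spec$fraction,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Draws baseline species fractions from a log-normal law, applies
#' per-sample noise, multiplicative factor effects, oral-species spike-ins
#' and dominance outliers, assigns catalogue genes (with lengths, KO labels
#' and taxon labels) to species, and samples per-sample read counts
#' multinomially over genes with probability proportional to
#' species fraction x gene weight x gene length (times any gene-level
#' factor effect). A homology hit table links a subset of
#' Enterobacteriaceae-tagged genes to virulence-factor reference ids.
#' Identical seeds give bitwise-identical outputs.
#'
#' @param config a [simulation_config()].
#' @return a list of class `synthetic_cohort` with elements `counts`
#'   ([count_table()]), `annotation` ([gene_annotation()]), `metadata`
#'   ([sample_metadata()]), `hits` ([hit_table()]), `pathway_map`
#'   (data.frame `ko`, `pathway`), `truth` (planted-effect registry) and
#'   `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  ## --- metadata -------------------------------------------------------------
  groups <- c(rep("ADS", config$n_ads), rep("ALC", config$n_alc),
              rep("Control", config$n_control))
  ids <- c(sprintf("ADS_%d", seq_len(config$n_ads)),
           sprintf("ALC_%d", seq_len(config$n_alc)),
           sprintf("CTRL_%d", seq_len(config$n_control)))
  p_female <- c(ADS = 3 / 72, ALC = 5 / 27, Control = 32 / 60)
  age_mean <- c(ADS = 44, ALC = 49, Control = 36)
  age_sd <- c(ADS = 10, ALC = 7, Control = 11)
  gender <- ifelse(stats::runif(length(ids)) < p_female[groups], "F", "M")
  age <- round(pmin(pmax(stats::rnorm(length(ids), age_mean[groups],
                                      age_sd[groups]), 20), 60))
  metadata <- sample_metadata(data.frame(
    sample_id = ids, group = groups, gender = gender, age = age,
    stringsAsFactors = FALSE))

  ## --- latent species fractions --------------------------------------------
  taxonomy <- .make_taxonomy(config$n_species)
  n_sp <- nrow(taxonomy)
  base <- stats::rlnorm(n_sp, config$base_meanlog, config$base_sdlog)
  base[taxonomy$oral] <- base[taxonomy$oral] * 0.02  # mouth taxa are rare in gut
  sp_eff <- .materialize_species_effects(config$species_effects, taxonomy,
                                         base)

  dep <- metadata$dependence == "yes"
  cir <- metadata$cirrhosis == "yes"

  ## genus-level gradient loadings: whole genera covary between individuals
  genera <- unique(taxonomy$genus)
  n_grad <- config$n_gradients
  loadings <- matrix(stats::rnorm(length(genera) * n_grad, 0,
                                  config$gradient_sdlog),
                     nrow = length(genera), ncol = n_grad,
                     dimnames = list(genera, NULL))
  sp_load <- loadings[taxonomy$genus, , drop = FALSE]

  fr <- matrix(0, nrow = n_sp, ncol = length(ids),
               dimnames = list(taxonomy$species, ids))
  for (j in seq_along(ids)) {
    score <- stats::rnorm(n_grad)
    lognoise <- drop(sp_load %*% score) +
      stats::rnorm(n_sp, 0, config$sample_sdlog)
    f <- base * exp(lognoise)
    if (nrow(sp_eff) > 0) {
      on <- (sp_eff$factor == "dependence" & dep[j]) |
            (sp_eff$factor == "cirrhosis" & cir[j])
      if (any(on)) {
        idx <- match(sp_eff$species[on], taxonomy$species)
        f[idx] <- f[idx] * sp_eff$effect[on]
      }
    }
    fr[, j] <- f / sum(f)
  }

  ## --- oral spike-ins -------------------------------------------------------
  spike <- config$oral_spike
  oral_truth <- data.frame(sample = character(0), species = character(0),
                           target_percent = numeric(0),
                           stringsAsFactors = FALSE)
  if (!is.null(spike) && length(spike$species) > 0) {
    targets <- metadata$sample_id[metadata$group == spike$group]
    for (s in targets) {
      hit <- spike$species[stats::runif(length(spike$species)) < spike$prob]
      if (length(hit) == 0) next
      pct <- stats::runif(length(hit), spike$range_percent[1],
                          spike$range_percent[2])
      if (sum(pct) >= 99)
        stop("oral spike-ins exceed the available community fraction")
      col <- fr[, s]
      col[hit] <- 0
      col <- col * (1 - sum(pct) / 100) / sum(col)
      col[hit] <- pct / 100
      fr[, s] <- col
      oral_truth <- rbind(oral_truth,
                          data.frame(sample = s, species = hit,
                                     target_percent = pct,
                                     stringsAsFactors = FALSE))
    }
  }

  ## --- dominance outliers ---------------------------------------------------
  ospec <- config$outlier_spec
  if (!is.null(ospec) && ospec$n > 0 && is.null(ospec$samples)) {
    patients <- metadata$sample_id[metadata$group != "Control"]
    ospec$samples <- sample(patients, ospec$n)
  }
  sp <- spike_outliers(fr, ospec, taxonomy)
  fr <- sp$fractions
  outlier_truth <- sp$truth

  ## --- gene catalogue -------------------------------------------------------
  gene_level <- config$n_genes > 0
  if (gene_level) {
    n_g <- config$n_genes
    gene_sp <- sample(seq_len(n_sp), n_g, replace = TRUE)
    gene_len <- sample(300:3000, n_g, replace = TRUE)
    gene_w <- stats::rlnorm(n_g, 0, 0.5)
    ## per-species unit weight sum: the pipeline estimates a species' share
    ## by summing its genes' length-normalized abundances, which is f_s
    ## times the species' total gene weight -- so that total must be equal
    ## across species or catalogue gene counts would bias every share
    gene_w <- gene_w / stats::ave(gene_w, gene_sp, FUN = sum)
    gene_id <- sprintf("gene_%05d", seq_len(n_g))

    kos <- c(config$alcohol_kos,
             sprintf("K%05d", 20000 + seq_len(config$n_filler_kos)))
    gene_ko <- rep(NA_character_, n_g)
    genes_per_ko <- 5
    free <- seq_len(n_g)
    for (k in kos) {
      pick <- sample(free, genes_per_ko)
      gene_ko[pick] <- k
      free <- setdiff(free, pick)
    }

    ## KO-level multiplicative effects on member genes
    ko_eff <- config$ko_effects
    ko_truth <- data.frame(ko = character(0), factor = character(0),
                           effect = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(ko_eff) && nrow(ko_eff) > 0) {
      avail <- config$alcohol_kos
      for (i in seq_len(nrow(ko_eff))) {
        sel <- utils::head(avail, ko_eff$n[i])
        avail <- setdiff(avail, sel)
        ko_truth <- rbind(ko_truth,
                          data.frame(ko = sel, factor = ko_eff$factor[i],
                                     effect = ko_eff$effect[i],
                                     stringsAsFactors = FALSE))
      }
    }

    ## virulence-factor hits: Enterobacteriaceae-tagged genes only
    vf <- config$vf_spec
    hits <- hit_table(data.frame(catalogue_gene_id = character(0),
                                 vf_gene_id = character(0),
                                 evalue = numeric(0),
                                 percent_identity = numeric(0),
                                 coverage_fraction = numeric(0),
                                 stringsAsFactors = FALSE))
    vf_truth <- data.frame(vf_gene_id = character(0),
                           catalogue_gene_id = character(0),
                           factor = character(0), effect = numeric(0),
                           stringsAsFactors = FALSE)
    if (!is.null(vf) && vf$n_vf > 0) {
      entero <- which(taxonomy$clade[gene_sp] == "Enterobacteriaceae" &
                        is.na(gene_ko))
      if (length(entero) < vf$n_vf)
        stop("not enough Enterobacteriaceae genes for the VF specification")
      vf_genes <- sample(entero, vf$n_vf)
      vf_ids <- sprintf("VFG%04d", seq_len(vf$n_vf))
      good <- data.frame(
        catalogue_gene_id = gene_id[vf_genes],
        vf_gene_id = vf_ids,
        evalue = 10^stats::runif(vf$n_vf, -40, -6),
        percent_identity = stats::runif(vf$n_vf, 81, 100),
        coverage_fraction = stats::runif(vf$n_vf, 0.81, 1),
        stringsAsFactors = FALSE)
      ## decoys that must not survive the similarity criterion
      n_decoy <- max(10, round(vf$n_vf / 2))
      decoy_genes <- sample(setdiff(seq_len(n_g), vf_genes), n_decoy)
      decoy <- data.frame(
        catalogue_gene_id = gene_id[decoy_genes],
        vf_gene_id = sample(vf_ids, n_decoy, replace = TRUE),
        evalue = 10^stats::runif(n_decoy, -4, 0),
        percent_identity = stats::runif(n_decoy, 30, 79),
        coverage_fraction = stats::runif(n_decoy, 0.1, 0.79),
        stringsAsFactors = FALSE)
      hits <- hit_table(rbind(good, decoy))
      vf_truth <- data.frame(vf_gene_id = vf_ids,
                             catalogue_gene_id = gene_id[vf_genes],
                             factor = vf$factor, effect = vf$effect,
                             stringsAsFactors = FALSE)
    }

    ## per-sample multinomial read counts over genes
    base_w <- gene_w * gene_len
    dep_mult <- rep(1, n_g)
    cir_mult <- rep(1, n_g)
    if (nrow(ko_truth) > 0) {
      for (i in seq_len(nrow(ko_truth))) {
        members <- which(gene_ko == ko_truth$ko[i])
        if (ko_truth$factor[i] == "dependence")
          dep_mult[members] <- dep_mult[members] * ko_truth$effect[i]
        else cir_mult[members] <- cir_mult[members] * ko_truth$effect[i]
      }
    }
    if (nrow(vf_truth) > 0) {
      members <- match(vf_truth$catalogue_gene_id, gene_id)
      if (unique(vf_truth$factor) == "dependence")
        dep_mult[members] <- dep_mult[members] * vf_truth$effect
      else cir_mult[members] <- cir_mult[members] * vf_truth$effect
    }

    counts <- matrix(0L, nrow = n_g, ncol = length(ids),
                     dimnames = list(gene_id, ids))
    for (j in seq_along(ids)) {
      p <- fr[gene_sp, j] * base_w
      if (dep[j]) p <- p * dep_mult
      if (cir[j]) p <- p * cir_mult
      counts[, j] <- stats::rmultinom(1, config$reads_per_sample, p)
    }
    annotation <- gene_annotation(data.frame(
      gene_id = gene_id, length_bp = gene_len, ko = gene_ko,
      taxon_species = taxonomy$species[gene_sp],
      taxon_genus = taxonomy$genus[gene_sp],
      stringsAsFactors = FALSE))
    pathway_map <- .make_pathway_map(config$alcohol_kos,
                                     setdiff(kos, config$alcohol_kos))
  } else {
    ## species-level shortcut: one pseudo-gene of unit length per species
    counts <- matrix(0L, nrow = n_sp, ncol = length(ids),
                     dimnames = list(taxonomy$species, ids))
    for (j in seq_along(ids))
      counts[, j] <- stats::rmultinom(1, config$reads_per_sample, fr[, j])
    annotation <- gene_annotation(data.frame(
      gene_id = taxonomy$species, length_bp = 1000, ko = NA_character_,
      taxon_species = taxonomy$species, taxon_genus = taxonomy$genus,
      stringsAsFactors = FALSE))
    hits <- hit_table(data.frame(catalogue_gene_id = character(0),
                                 vf_gene_id = character(0),
                                 evalue = numeric(0),
                                 percent_identity = numeric(0),
                                 coverage_fraction = numeric(0),
                                 stringsAsFactors = FALSE))
    ko_truth <- data.frame(ko = character(0), factor = character(0),
                           effect = numeric(0), stringsAsFactors = FALSE)
    vf_truth <- data.frame(vf_gene_id = character(0),
                           catalogue_gene_id = character(0),
                           factor = character(0), effect = numeric(0),
                           stringsAsFactors = FALSE)
    pathway_map <- data.frame(ko = character(0), pathway = character(0),
                              stringsAsFactors = FALSE)
  }

  truth <- list(species_effects = sp_eff, ko_effects = ko_truth,
                vf_genes = vf_truth, oral_spikes = oral_truth,
                outliers = outlier_truth, taxonomy = taxonomy,
                latent_fractions = fr)
  structure(list(counts = count_table(counts), annotation = annotation,
                 metadata = metadata, hits = hits,
                 pathway_map = pathway_map, truth = truth, config = config),
            class = "synthetic_cohort")
}

.make_pathway_map <- function(alcohol_kos, filler_kos) {
  ## alcohol KOs are split over three panels, fillers into 6-KO pathways
  alc_pw <- paste0("path:AlcoholMetabolism_",
                   c("I", "II", "III")[ceiling(seq_along(alcohol_kos) /
                                                ceiling(length(alcohol_kos) / 3))])
  fill_pw <- sprintf("path:PW%03d", ceiling(seq_along(filler_kos) / 6))
  data.frame(ko = c(alcohol_kos, filler_kos),
             pathway = c(alc_pw, fill_pw),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d genes x %d samples (%d ADS / %d ALC / %d Control), %d species\n",
    nrow(x$counts), ncol(x$counts), x$config$n_ads, x$config$n_alc,
    x$config$n_control, nrow(x$truth$taxonomy)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits every input the pipeline consumes, as TSV (plus the truth registry
#' as JSON and the oral species panel as a one-label-per-line text file):
#' `counts.tsv`, `gene_annotation.tsv`, `metadata.tsv`, `hits.tsv`,
#' `pathway_map.tsv`, `oral_species.txt`, `truth.json`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_study <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_gene_annotation(cohort$annotation,
                        file.path(dir, "gene_annotation.tsv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_hits(cohort$hits, file.path(dir, "hits.tsv"))
  write_df_tsv(cohort$pathway_map, file.path(dir, "pathway_map.tsv"))
  spike <- cohort$config$oral_spike
  if (!is.null(spike))
    writeLines(spike$species, file.path(dir, "oral_species.txt"))
  truth <- cohort$truth
  truth$latent_fractions <- NULL  # matrix truth stays in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
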