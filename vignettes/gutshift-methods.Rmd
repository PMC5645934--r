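---
title: "Disentangling alcohol dependence and liver cirrhosis in gut metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gutshift methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Alcohol dependence reshapes the gut microbiota, but in patients who progress
to alcoholic liver cirrhosis the liver dysfunction reshapes it again, in a
different direction. Separating the two signals requires a cohort design with
both patient groups (dependence without advanced liver disease, and
dependence with cirrhosis) against an external control group, and a
statistical pipeline that treats the two clinical conditions as separate
binary factors rather than comparing three groups pairwise.

`gutshift` implements that pipeline for shotgun-metagenomic relative
abundance data: normalization of gene-level read counts, taxonomic and
functional aggregation, alpha and beta diversity, abnormal-sample (outlier)
detection, rank-based differential abundance with FDR control, a dedicated
rank statistic for oral (buccal) species in the gut, PERMANOVA screening
with per-taxon multifactor linear modelling, and virulence-factor gene
quantification from homology hits. A synthetic cohort generator with a
planted-effect truth registry makes every stage testable end to end.

## Data model and normalization

The raw quantitative input is a gene × sample matrix of mapped read counts
over a reference gene catalogue, with per-gene annotations (length in bp,
optional KO label, optional species/genus label). The relative abundance of
gene $g$ in sample $s$ is

$$a_{gs} = 100\cdot\frac{c_{gs}/L_g}{\sum_{g'} c_{g's}/L_{g'}},$$

i.e. counts normalized by gene length and by the total of the
length-normalized counts, in percent. Columns sum to 100 exactly; every
aggregation (genes to KO groups or taxa, species to genera) is a plain sum of
member rows with no renormalization, so a full partition preserves column
sums and a subset never exceeds them. Abundances are carried in percent
throughout because the field reports them that way; conversions to fractions
are internal.

Taxon-level matrices may also be supplied directly (as produced by
genome-mapping profilers); aggregation from gene annotations exists for the
synthetic path and for catalogues with taxonomic labels.

Two prevalence filters precede all group comparisons, both strict
inequalities: genera must exceed 1% and species 0.1% in at least one sample.
The multifactor model uses its own inclusion rule, > 0.01% in at least 10
samples.

## Statistical procedures

**Differential abundance.** Feature-wise two-sided Mann-Whitney tests with
Benjamini-Hochberg step-up adjustment across the retained features;
significance at adjusted p below 0.01 for taxa and 0.05 for functional
features (KO groups, virulence-factor genes, where no prevalence filter is
applied). The Mann-Whitney p-value is exact by enumeration when the pooled
sample size is at most 12 and tie-free, and otherwise uses the normal
approximation with tie and continuity corrections. Direction is the sign of
the median difference, falling back to means on a median tie.

**Pathway calls.** KO-level results are lifted to pathways by the explicit
half-membership criterion: a pathway is retained when at least half of its
member KO terms (counting only KOs present in the KO abundance matrix, a
documented choice) are differentially abundant at adjusted p < 0.05. A
gene-set enrichment machinery (reporter features, boosted scoring) is
deliberately not used; the half-of-KOs rule is self-contained and
reproducible.

**Diversity and ordination.** Shannon index $H=-\sum p_i\ln p_i$ in nats
(values near 3.3 for communities of a few hundred species are only consistent
with the natural logarithm), Welch's t-test for group comparisons of $H$,
Bray-Curtis dissimilarity $1-2\sum\min(x_i,y_i)/(\sum x_i+\sum y_i)$, and
classical (metric) MDS via eigendecomposition of the double-centered squared
dissimilarities, dropping non-positive eigenvalue axes. Bray-Curtis is not a
metric; nothing downstream requires the triangle inequality.

**Outlier detection.** Samples are clustered hierarchically (default Ward's
linkage on Bray-Curtis; complete linkage offered to mirror Euclidean heatmap
clustering) and the tree is cut at the top level into two branches; the
smaller branch is the outlier set. An exact tie yields no outliers, since
"smaller" is then undefined. A complementary dominance report flags samples
whose top genus exceeds a threshold; the notion of a "dominated" community
has no canonical cutoff, so the threshold is a parameter defaulting to 50%.

**Oral-species rank statistic.** Let $N$ be the number of species detected
(abundance > 0) in at least one sample; species never detected are dropped.
Within each sample the detected species are ranked by decreasing abundance
(rank 1 = most abundant) and undetected species receive the sentinel rank
$N+1$. For each designated oral species the rank vectors of two cohorts are
compared with a one-tailed Mann-Whitney test, alternative "more abundant
(numerically smaller rank) in the first group", with no multiplicity
adjustment. Sentinels enter as ties and the tie correction applies — ranks,
unlike raw abundances of sparse taxa, give the sentinel mass a well-defined
place in the test. Within-sample ties take the average rank rounded half-up,
and undetected means exactly zero after normalization (no detection
threshold is imposed).

**Multifactor analysis.** A PERMANOVA screen (one factor at a time,
pseudo-F on Bray-Curtis, permutation p with the +1 correction so p is never
zero, BH adjustment across the factor set) selects the clinical factors, and
per-taxon linear models are then fitted jointly on the binary covariates:

`asin(sqrt(abundance/100)) ~ dependence + cirrhosis + gender`

with the fixed encoding dependence-only = (yes, no), cirrhosis = (yes, yes),
control = (no, no). Coefficient p-values are BH-adjusted jointly across all
(taxon, factor) pairs — adjusting per factor was the alternative; joint
adjustment is the more conservative reading and is what the package does. The
fit is ordinary least squares on the variance-stabilized (arcsine square
root) fraction — the classical default of multivariate microbiome
association frameworks; boosting and feature selection are intentionally
omitted and the output is labelled as a plain-OLS approximation. Age is
handled only in the PERMANOVA screen. A factor constant in the data is
dropped with a warning rather than producing a rank-deficient fit.

**Virulence factors.** Homology hits of catalogue genes against a
virulence-factor reference are filtered by the strict similarity criterion
e-value < 1e-5, identity > 80%, coverage > 80% of the reference gene length
(the reference side is the documented reading of the ambiguous "of length";
computing coverage on the query instead simply changes the input column).
Each reference gene's abundance is the per-sample sum of its surviving
catalogue genes' abundances; a catalogue gene hitting several reference
genes contributes fully to each (summing, not splitting, matches the
aggregation rule used everywhere else; the consequence — VF totals can
exceed 100% under multi-hits — is accepted and documented). BLAST itself is
not executed; the package consumes its tabular output with an explicit
coverage column.

## The synthetic cohort generator

The generator emits everything the pipeline consumes — counts, annotations,
metadata, homology hits, a KO-to-pathway map — plus a truth registry of
planted effects, so recovery is measurable. Defaults reproduce the study
conditions: 72/27/60 samples, ~300 species, 20,000 genes, 100,000 reads per
sample (scaled down from sequencing depth to keep runs at desk scale;
configurable upward — the methods are depth-agnostic above the detection
limit).

Baseline species fractions are log-normal (meanlog 0, sdlog 2), heavy-tailed
so a handful of genera dominate at the ~20% level. Inter-individual
variation has two parts: two genus-level community gradients (each genus
carries a normal loading, sd 0.15; each sample a standard-normal score;
species inherit their genus loading), so whole genera covary between
individuals as they do along real enterotype axes, plus per-species
idiosyncratic log-normal noise (sd 0.3). Factor effects are multiplicative
on the underlying fractions before renormalization — the simplest model
consistent with fold-change statements; the resulting compositional
spillover onto non-planted taxa is accepted and visible in the tests.
Planted effects mirror the study's structure: dependence-linked depletion of
Clostridiales commensals with enrichment of Enterobacteriaceae (whose genes
carry the virulence-factor hits), cirrhosis-linked Bacteroidales depletion
with oral-species spike-ins, and Bifidobacterium/Lactobacillus enrichment
under both factors through disjoint species sets. Effect species are drawn
from the clade members closest to a 0.5% baseline share: prevalent enough to
pass the filters, light enough that renormalization does not distort the
planted fold change. Gene-level counts are multinomial with probability
proportional to species fraction × gene weight × gene length, so the
length normalization is genuinely exercised rather than cancelled.

Dominance outliers are realized as a bloom of one randomly drawn member
species of the target genus that displaces its congeners, which reproduces
the low species-level alpha diversity (Shannon ~1.4–2.0 nats) observed in
real single-genus-dominated communities and makes the outlier a distinct
abnormal state rather than an amplified normal profile.

Calibration was anchored, once, to the study's printed summary statistics:
cohort Shannon diversity ~3.3–3.5 with a spread around 0.5 that is largely
carried by the planted low-diversity outliers, and natural (unplanted)
dominance above 50% remaining rare. What the generator deliberately does
**not** emulate: the full marginal spread of the dominant genera in real
cohorts (reported standard deviations on the order of the mean, i.e.
enterotype-scale variation). At that strength of continuous inter-individual
structure the top-level-cut outlier rule itself degrades — the dendrogram's
root split follows the community gradient instead of the outliers — so the
generator keeps continuous variation moderate and concentrates abnormality
in explicitly planted structures. Passing recovery tests therefore
demonstrate the machinery on cohorts with a coherent commensal cloud and
rare abnormal samples; they do not certify the top-level-cut rule on cohorts
with strong enterotype stratification.

## Numerical and design notes

- Thresholds quoted with ">" or "<" are strict everywhere (prevalence
  filters, similarity criterion, enrichment table cutoff).
- Missing annotation for a counted gene is fatal, not a silent drop:
  normalization needs every mapped gene's length.
- KO panels keep their shape: a KO absent from the data stays as an all-zero
  row with a warning, so a 19-group panel is always reported as 19 groups.
  The alcohol-metabolism KO list is configuration (a packaged text file),
  not hard-coded truth.
- PERMANOVA p-values are bit-reproducible under a fixed seed, and the seed
  is re-applied per factor in the screen so results do not depend on factor
  order.
- Problem sizes in the test-suite simulations (e.g. 100 null replicates of a
  200-species 50-vs-50 cohort, 50 outlier-recovery replicates, a single full
  159-sample end-to-end chain) were chosen as the smallest sizes at which the
  binomial/selection noise of the assertions is negligible.
- Ties at the dendrogram root, all-zero samples, empty label sets, empty
  filtered hit tables and constant design factors all have defined, warned
  behaviour rather than errors deep in the stack.

## Limitations

- The multifactor model is plain OLS on arcsine-sqrt fractions; boosted or
  penalized frameworks may assign shared variance differently when factors
  are strongly confounded.
- Raw relative abundances are tested directly (by design, matching the
  source methodology); no log-ratio/compositional transformation is offered,
  and compositional spillover is visible when very abundant taxa shift.
- The generator starts at mapped counts: sequencing error, mapping bias and
  read-level artifacts are out of scope, as is inference of which species
  are "oral" (the panel is user input).
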