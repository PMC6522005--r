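---
title: "Comparing microbiome form and function between host genotype groups"
author: "taxafun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microbiome form and function between host genotype groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxafun)
```

## The question and the design

A recurring question in host-microbiome genetics is whether host genotype
shapes only the *taxonomic composition* of the gut community ("form") or
also its *functional gene content* ("function"). The two can diverge:
when many taxa carry the same gene family, taxa can replace one another
while the community's functional repertoire stays put. That buffering is
functional redundancy, and its signature is a *decoupling* of taxonomic
from functional turnover — samples far apart in taxon space can be close in
function space.

`taxafun` implements the comparison end to end for a congenic-mouse-style
design: two zygosity groups (homozygote/heterozygote at an immune locus) of
three genotypes each, five mice per genotype, 16S OTU tables rarefied to a
common depth, and KO (KEGG Orthology) tables predicted from the taxa. The
pipeline (`runPipeline()`) chains ingest, filtering, diversity, ordination,
group tests, per-group co-occurrence networks, taxonomy-function coupling,
prevalence decay, and differential abundance. Every stage is exported on
its own, and nothing is specific to mice: any two-level grouping over a
count table works.

## Statistics and their conventions

**Alpha and beta diversity.** Shannon entropy is reported in bits (log base
2, the QIIME-1 convention). Faith's PD is the branch length of the minimal
rooted subtree spanning a sample's taxa (computed with `picante`,
root included). Beta diversity uses Bray-Curtis throughout,
`BC(x, y) = sum|x - y| / sum(x + y)`; UniFrac (through `phyloseq`) is
available for phylogenetic sensitivity analyses, with the weighted variant
in its raw, non-normalized form by default (a `normalized` flag switches).
PCoA is classical scaling of `-D^2/2`; axes with non-positive eigenvalues
are discarded without correction, and proportions explained are relative to
the positive-eigenvalue total.

**Permutation tests.** Group separation uses ANOSIM (via `vegan`), whose R
statistic contrasts mean between- vs within-group distance ranks. The
taxonomy-function association uses a Mantel test written in-package because
the conventional implementations are one-sided while the natural question
here ("is coupling different?") is two-sided: r is the Pearson correlation
of corresponding off-diagonal entries and p comes from simultaneous
row/column shuffling of the second matrix. Univariate group contrasts
(alpha diversity, within-group dissimilarities, functional richness) use a
Welch t statistic referred to its Monte Carlo permutation distribution. All
permutation p-values use the add-one estimator `(1 + k)/(1 + B)`, so p is
never zero; defaults are 99 permutations for ANOSIM (its customary figure
default) and 999 for the Mantel and two-sample tests; all are arguments.
Multiple testing is Benjamini-Hochberg step-up everywhere.

**Co-occurrence networks.** Within each sample group, Spearman rho is
computed for all feature pairs on column-normalized relative abundances
(rank-based, so the normalization is a fidelity choice rather than a
numerical one), and an edge is kept only if `|rho| > 0.8` *and* BH-adjusted
`p <= 0.05` — both criteria, audited post hoc in the tests. For groups of
`n <= 8` samples, p-values come from full enumeration of the n! sample
permutations rather than the t approximation, which is invalid at such n.
This has a consequence worth stating plainly: at n = 5 the smallest
achievable two-sided exact p is 2/120, so after BH correction across
~10^5 pairs *no* edge can reach adjusted p <= 0.05, and genotype-level
networks in the default design are empty. Non-empty genotype networks at
n = 5 are an artifact of asymptotic p-values; the pipeline therefore fits
networks at both granularities and the zygosity level (n = 15), where the
t approximation is reasonable, carries the topology comparison.
Betweenness centrality is unweighted shortest-path betweenness normalized
by `(n-1)(n-2)/2` with n the network's node count; hubs are the top-k nodes
with lexicographic tie-breaking for determinism.

**Differential abundance.** `nbWaldTest()` is a deliberately simplified
negative-binomial Wald procedure: median-of-ratios size factors (rescaled
to geometric mean 1; when no feature is positive everywhere the geometric
means fall back to positive counts only), per-feature method-of-moments
dispersion on normalized counts pooled across groups and floored at 1e-8,
`log2FC = log2(mean_num / mean_den)` with a 0.5 pseudo-mean added to both
groups whenever either group mean is zero, a delta-method standard error
`Var(log mu_hat) = (mu + alpha mu^2) / (n mu^2)`, and a two-sided normal
reference for z = log2FC/SE. There is no dispersion shrinkage, no LFC
shrinkage and no independent filtering: the scientific content here is the
comparison design, not estimator refinements, and the simple estimator's
calibration is verified empirically (type-I error within [0.03, 0.07] at
n = 15/15 in the test suite). Positive log2 fold changes mean enrichment in
the numerator group, by default the homozygote label. Features whose total
count falls below `minTotal` are excluded with an explicit reason rather
than propagated as NA.

**Core microbiota and decay.** The core is the set of features present
(count > 0) in at least a prevalence threshold of samples, 100% by default.
The decay curve is the *exact expectation* of the number of features shared
by a random k-subset of samples, `E[shared(k)] = sum_f C(prev_f, k)/C(N, k)`.
The field sometimes plots an ordering-dependent accumulation instead
(cumulative intersection along a sample order); that variant is available
behind `method = "accumulation"` for sensitivity analysis, but the
expectation is the default because it is order-free, reproducible, and
verifiable against brute-force subset enumeration — which the test suite
does for all N <= 8. AUC is the trapezoid rule on the k grid, and group
AUC differences are tested by label permutation (group sizes preserved,
add-one estimator): the literature's AUC comparison methods are tied to
parametric variance formulas we have no basis to assume here, and a
permutation test is consistent with every other test in the package.

**Functional prediction and NSTI.** Full ancestral-state reconstruction
over a reference database is out of scope at desk scale. The predictor
keeps the concept: each OTU inherits the KO copy-number vector of its
nearest *sequenced* reference tip by patristic distance (ties broken
lexicographically), making the taxonomy-to-function map linear in
abundances — the property the redundancy analysis depends on. The weighted
NSTI score, `sum_i a_i d_i / sum_i a_i`, summarizes how far a sample's
community sits from its references; 0 means every observed taxon is itself
a reference. 16S copy-number correction is omitted; a copy-number table can
be folded into the `TaxonFunctionMap` if available.

## What the synthetic generator emulates

`simulationConfig()` defaults *are* the study conditions: 6 genotypes split
3/3 by zygosity, 5 samples each, 700 OTUs, multinomial sampling at a fixed
depth of 16,000 reads (rarefied-table semantics: column sums are exact).
Base relative abundances are log-normal (sdlog 1.0 — a realistic evenness
for 16S gut surveys); within-group sample-to-sample variation is log-normal
with sd 0.7, multiplied by 1.4 in heterozygotes to mimic their higher
beta-dispersion. A core fraction (12%, echoing the ~82-of-692 core
typical of such designs) is present in every sample; peripheral features
get per-sample Bernoulli dropout with uniform prevalence targets, and
rarer features are also less abundant (a 1.5 log-unit penalty scaled by
the dropout probability), as in real surveys.

Planted structure, recorded in a `truth` object for recovery testing:

- **Correlated pairs** (25 by default, |rho| = 0.9, a quarter negative) are
  realized through a Gaussian copula: the latent Pearson correlation is
  `2 sin(pi rho_s / 6)` so the *rank* correlation hits the target through
  any monotone marginal. Planted features are boosted to roughly 1.2 log
  units above baseline so the signal survives multinomial counting noise
  without letting them dominate community dissimilarity. Overlapping pair
  declarations fall back to an explicit correlation matrix with nearest-PSD
  repair.
- **Fold changes** (40 features at |log2FC| = 2, half in each direction)
  enter as symmetric half-shifts of the latent means of the two zygosity
  groups.
- **The redundancy contrast** is the design's centerpiece and needs a
  mechanism, not just a parameter: with independent per-taxon fluctuations,
  summing taxa into KOs never decouples function from taxonomy, because
  Bray-Curtis on both sides is driven by the same abundant-taxa
  fluctuations. The generator therefore models *functional guilds* as
  phylogenetic clades (`phyloGuilds()`, average-linkage clusters of
  patristic distance — functional content is phylogenetically conserved,
  which is also the premise of nearest-taxon prediction). Each group's KO
  carrier sets are the reference members of one clade of its own partition,
  with mean clade size equal to that group's redundancy (20 for
  homozygotes, 2 for heterozygotes by default); and the same clades get
  *compensatory dynamics*: within each guild of m >= 3 members, the
  abundance-weighted mean log fluctuation is shrunk by `1 - 2/m`, buffering
  the guild total (what a KO measures) while members still turn over.
  Guilds of 1–2 taxa have no effective substitutes and are untouched, and
  planted-edge features are exempt (their dynamics are pinned by the
  planted interaction). The result is the expected phenomenon: taxonomic
  turnover with a flat functional profile in the redundant group, hence a
  lower taxonomy-function Mantel r — the direction holds in well over 95%
  of seeded replicates in the acceptance suite.
- The KO universe is 2,000 gene families by default (predicted metagenomes
  carry thousands of KOs; a small universe undersamples the low-redundancy
  group's carriers and distorts the contrast), with `mapOverlap` available
  to share a fraction of carrier sets between the group maps — sharing
  dilutes the planted contrast, so the default is 0.

What the generator does **not** emulate: sequencing error and chimeras
(upstream of this artifact), 16S copy-number variation, compositional
interactions beyond the fixed-depth multinomial, phylogenetic signal in
abundances (the tree is a Yule tree independent of the latent means), and
any KEGG pathway hierarchy. Passing recovery tests therefore demonstrates
that the *estimators* recover planted structure under realistic shapes and
noise, not that real communities satisfy the generator's assumptions.

## Numerical choices and degenerate inputs

Seeds: every stochastic operation takes a `seed` and restores the caller's
RNG state, so pipelines are reproducible and composable; `runPipeline()`
derives fixed offsets from its single seed for each stage. Rarefaction
drops samples below depth (with a message) rather than keeping partial
samples, preserving the exact-column-sum invariant. Constant features are
skipped in network construction (rho undefined); all-zero samples are
rejected where a statistic is undefined (Shannon, Bray-Curtis, NSTI); a
two-group Welch statistic with zero variance in both groups and equal means
yields p = 1 rather than an error. Exact permutation enumeration is capped
at n = 8 (40,320 permutations); beyond that the t approximation on n - 2
degrees of freedom is used, with p = 0 only at |rho| = 1. BH adjustment
validates its inputs and preserves order. Ties in hubs and in
nearest-reference lookups break lexicographically.

Problem sizes in the test and acceptance suites are chosen to keep the
whole suite in the low tens of minutes on one core: oracle comparisons run
at N <= 8 samples or <= 10 nodes where exhaustive enumeration is exact and
instant; calibration uses 300-500 replicates per test; recovery uses 10-20
seeds at the study's own shape (30 samples; 200-700 features); the
redundancy direction uses 50-100 seeds at full defaults.

## Known limitations

- The NB Wald test is anti-conservative in the tails at very small n
  (3-5 per group); its calibration is verified at the design's n = 15/15.
- Exact network inference at n = 5 yields empty networks after BH
  correction (see above); that is a property of honest small-n inference,
  not a bug, but it means per-genotype topology is only informative with
  more samples or a relaxed error criterion.
- The Mantel coupling contrast compares coefficients descriptively; no
  test for the *difference* of two dependent Mantel coefficients is
  provided.
- Functional prediction ignores within-clade gene-content variation by
  construction: an OTU gets exactly its nearest reference's KO vector.
- NSTI magnitudes depend on the tree's branch-length scale and the
  reference fraction; they are comparable within a study, not across
  databases.
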