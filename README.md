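# taxafun

Tools for asking whether host genetics reshapes not just *which* microbes
live in the gut (community "form") but *what those microbes can do*
(community "function"). The motivating design is a congenic-mouse 16S rRNA
survey — groups of host genotypes differing only at an immune locus, with
OTU tables on one side and predicted KEGG Orthology (KO) gene-content
tables on the other — but every function works on any features-by-samples
count table with a two-level sample grouping.

## What it computes

Given an OTU table, sample metadata (genotype, zygosity group, cage), a
rooted phylogeny and a taxon-to-KO copy-number reference, the package runs
the full comparison:

- **Ingest and filtering** — QIIME-classic TSV and classic-BIOM JSON
  readers/writers, singleton removal, and rarefaction to a fixed depth via
  without-replacement subsampling, so every retained sample sums to exactly
  the target depth.
- **Diversity** — Shannon index (bits), Faith's PD, Bray-Curtis and UniFrac
  dissimilarities, PCoA by classical scaling, and the permutation statistics
  used to compare groups: ANOSIM (R in [-1, 1]), a two-sided Mantel test,
  and a nonparametric two-sample test (Welch t with Monte Carlo label
  permutations), all with add-one p-value estimators and BH adjustment.
- **Core microbiota and decay** — core features at a prevalence threshold,
  exact prevalence decay curves
  E[shared(k)] = Σ_f C(prev_f, k) / C(N, k)
  (the expected number of features present in every member of a random
  k-sample subset), trapezoidal AUC, and a label-permutation test for AUC
  differences between groups.
- **Co-occurrence networks** — all-pairs Spearman rho on within-group
  relative abundances; edges kept only when |rho| > 0.8 **and** BH-adjusted
  p <= 0.05. For groups of 8 or fewer samples the p-values come from full
  enumeration of sample permutations (the t approximation is invalid there).
  Topology summaries: nodes, edges, connectivity (edges/nodes), edge-sign
  fractions, normalized betweenness centrality, and top-k hub features.
- **Differential abundance** — a simplified negative-binomial Wald test
  (median-of-ratios size factors, method-of-moments dispersion, delta-method
  SE), with the convention that positive log2 fold changes mean
  homozygote-enriched.
- **Functional prediction** — a desk-scale nearest-sequenced-taxon
  predictor: each OTU inherits the KO copy numbers of its closest reference
  tip by patristic distance, plus the weighted NSTI score
  Σ a_i d_i / Σ a_i per sample.
- **Synthetic data** — a generator with planted ground truth (pairwise
  correlations via a Gaussian copula, between-group fold changes, core
  prevalence structure, a per-group functional-redundancy contrast realized
  through phylogenetic guilds with compensatory dynamics), so every stage
  has a recovery test.

## Worked example

```r
library(taxafun)

cfg <- simulationConfig(nFeatures = 300, nKos = 800, depth = 8000)
sim <- simulateCommunity(cfg, seed = 42)
sim$table
#> FeatureTable (taxon): 300 features x 30 samples
#>   sample depths: 8000 .. 8000

report <- runPipeline(sim$table, sim$metadata, sim$tree, sim$functionMaps,
                      config = runConfig(depth = 8000, seed = 42))
report
#> Analysis report
#>   30 samples, 300 features (90 core)
#>   overall ANOSIM: R = 0.791, P = 0.01
#>   Mantel r (taxa~function): homozygote 0.319, heterozygote 0.650
#>   differentially abundant taxa (BH P < 0.05): 52
```

Reading the output: the two zygosity groups separate strongly in
Bray-Curtis space (ANOSIM R = 0.79 on a 0–1 scale, permutation P = 0.01);
taxonomic and functional turnover are tightly coupled in the heterozygote
group (Mantel r = 0.65) but weakly in the homozygote group (r = 0.32),
exactly the decoupling that high functional redundancy produces — the
generator gave the homozygote group 20 carrier taxa per KO versus 2; and 52
of 300 taxa differ in abundance between groups after BH correction, of
which the generator planted 40. Individual stages are available directly:

```r
report$beta$overall$anosim
#> ANOSIM: R = 0.791, P = 0.01 (99 permutations)
head(report$differential$taxa[order(report$differential$taxa$p_adjusted), ], 3)
#>     feature_id base_mean log2_fold_change standard_error  p_value p_adjusted
#> 122    OTU0122     151.4            -2.94          0.359 2.70e-16   8.11e-14
#> 268    OTU0268      76.6            -2.61          0.362 6.02e-13   9.03e-11
#> 105    OTU0105      58.2            -2.46          0.349 1.79e-12   1.79e-10
```

Negative log2 fold changes mark heterozygote-enriched taxa.
`writeReport(report, "out/")` serializes every stage (distance matrices,
PCoA coordinates, edge lists, decay curves, DA tables, NSTI scores) as
TSV plus a JSON summary embedding the config and seed.

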