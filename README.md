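# organsort

Subcellular protein localization from organelle-fractionation proteomics.

Differential centrifugation enriches membrane-bound organelles without
purifying them: every fraction is a mixture, and every quantified protein
acquires a *fractionation profile* — its relative abundance across the six
enriched fractions (plasma membrane, ER, endosome, lysosome, Golgi,
mitochondria), measured in technical triplicate under two biological
conditions. organsort turns those profiles into localization calls, for
proteomics groups running organelle-enrichment experiments and for
methodologists benchmarking spatial-proteomics classifiers.

## The method

1. **Marker selection.** A four-stage filter keeps proteins with
   reproducible, condition-stable profiles: median normalization; presence
   in both conditions; minimum pairwise replicate Pearson correlation
   r ≥ 0.8 within each condition; cross-condition Pearson r ≥ 0.8 and
   Spearman ρ ≥ 0.6.
2. **Cluster discovery and annotation.** Markers are embedded in 3-D by
   t-SNE (perplexity 50, θ = 0.5) and partitioned by a Gaussian mixture
   with BIC-selected k. Each cluster × compartment pair is scored by the
   fold change

   FC = (b/n) / (B/N)

   (b annotated proteins of the compartment in the cluster of size n; B of
   them among all N annotated markers) and the hypergeometric upper tail
   P(X ≥ b), BH-corrected; a compartment is attached when FC ≥ 2 and
   q < 0.05 in ≥ 3 of 5 reference strategies. Compartments collapse to five
   *neighborhoods*: secretory, mitochondria, nuclear, cytosol, ribosome.
3. **Classification with precision-floor calibration.** Per replicate, an
   RBF-SVM (cost × gamma grid, 10-fold CV) emits per-cluster
   probabilities. Calls require 2-of-3 replicate agreement; probabilities
   are averaged; per-class thresholds are chosen on held-out markers to
   maximize recall subject to precision = TP/(TP+FP) ≥ 0.9 (clusters) or
   ≥ 0.95 (neighborhoods), falling back to the F1 = 2PR/(P+R) optimum
   when the floor is unattainable. Neighborhood probabilities are sums of
   member-cluster probabilities; contradictory cluster/neighborhood calls
   become unclassified at both levels.
4. **Downstream.** Domain–localization enrichment; protein-complex
   colocalization after a member-correlation (PCC ≥ 0.8) prefilter,
   against a random non-complex-pair null.

A seeded synthetic-data generator (`simulate_experiment()`) emulates the
whole design — cluster-specific organelle profiles, replicate noise,
cross-organelle contamination, condition-unstable and multi-localized
proteins, reference annotations, domain and complex tables — with full
ground truth, so every stage is benchmarked against planted labels.

## Worked example

```r
library(organsort)
cfg <- default_pipeline_config(seed = 11)
cfg$simulate$n_proteins <- 1000
run <- run_pipeline(cfg)
run
#> <organsort_run>
#>   proteins: 1000 | markers: 592 | clusters: 14
#>   classified: 924 (92.4%) at cluster level, 981 (98.1%) at neighborhood level
#>   reconciled to unclassified: 12
```

592 of 1000 simulated proteins survive the marker filter; the mixture
model resolves 14 clusters on the embedding (adjacent planted clusters in
the same neighborhood may merge — downstream stages are agnostic to k).
92.4% of proteins receive a cluster-level call and 98.1% a
neighborhood-level call; 12 proteins had contradictory calls at the two
levels and were reset to unclassified.

```r
run$markers$stage_counts
#> # A tibble: 4 × 3
#>   stage description                               retained
#>   <int> <chr>                                        <int>
#> 1     1 normalized input                              1000
#> 2     2 present in both conditions                    1000
#> 3     3 replicate PCC >= 0.80                          641
#> 4     4 cross-condition PCC >= 0.80 & SCC >= 0.60      592

head(run$thresholds, 3)
#> # A tibble: 3 × 9
#>   level   class threshold mode            precision recall    f1 n_true n_predicted
#>   <chr>   <chr>     <dbl> <chr>               <dbl>  <dbl> <dbl>  <int>       <int>
#> 1 cluster 1         0.613 precision-floor         1      1     1     27          27
#> 2 cluster 10        0     precision-floor         1      1     1      6           6
#> 3 cluster 11        0     precision-floor         1      1     1      9           9
```

Each class gets its own operating point: cluster 1 needs an averaged
probability of at least 0.613 for a call (precision 1.0 at recall 1.0 on
the held-out markers); where the precision floor is unattainable the mode
column records the F1 fallback.

```r
run$evaluation
#> <organsort_agreement> n = 880, agreement = 91.1%

run$complex_null
#> <organsort_null> 500 null pairs (mean PCC -0.005) vs 243 complex pairs
#>   (mean PCC 0.814); KS D = 0.796
```

Neighborhood calls agree with the simulated reference annotation for 91.1%
of the 880 overlapping proteins (the annotation itself carries 5% planted
label error), and complex co-members correlate far above random protein
pairs.

Plot helpers: `plot_embedding()`, `autoplot(run$gmm)` (BIC curve),
`plot_threshold_curves()`, `plot_domain_enrichment()`,
`autoplot(run$complex_null)` (cumulative correlation curves).

A thin command-line wrapper lives at `inst/scripts/organsort.R`
(`Rscript organsort.R run --config cfg.yml --outdir out`); a sample
configuration is in `inst/extdata/example_config.yml`.

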