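# ptmDynamics

Quantitative post-translational modification (PTM) dynamics from
multiplexed mass-spectrometry experiments, for proteomics analysts working
with reporter-ion (iTRAQ-style) time courses or SILAC pairs of modified
peptides — lysine acetylation and tyrosine phosphorylation in particular.

Receptor tyrosine kinase stimulation (insulin, IGF-1, EGF) changes lysine
acetylation on many proteins within a minute. Given a peptide-level
quantification table (one row per modified peptide, one intensity column
per reporter channel mapped to condition / timepoint / replicate), the
package:

1. **Normalizes channel loading** by the mean-ratio rule: each channel is
   divided by the mean over peptides of its ratio to the block's reference
   (unstimulated) channel.
2. **Builds temporal profiles** `v_t = log2(mean_reps x_t / x_0)`,
   anchored at exactly 0 for the unstimulated timepoint.
3. **Clusters profiles by affinity propagation** — responsibility /
   availability message passing implemented from first principles, with
   similarity `s(i,k) = -||v_i - v_k||²` — over a sweep of preference
   values, selecting the clustering that minimizes a spherical-Gaussian
   BIC, `BIC = nd ln(σ̂²) + (Kd + 1) ln n` with `σ̂² = RSS / (d(n−K))`.
4. **Classifies early responses** at 1 minute: reduced at least two-fold
   (`v_1 ≤ −1`) or increased more than 1.5-fold (`v_1 > log2 1.5`).
5. **Quantifies deacetylase-inhibitor crosstalk** in paired vehicle/TSA
   designs with the fold-change ratio
   `FCR = fc_TSA / fc_vehicle` of EGF-induced fold changes, categorized at
   the 0.3 / 0.5 / 1.5 / 1.9 thresholds, plus per-site Welch t-tests,
   one-way ANOVA across timepoints, and Benjamini–Hochberg adjustment.

A synthetic-data module generates reporter tables and SILAC pairs with a
full ground-truth ledger (archetype cluster labels, true profiles, planted
FCR effects, channel bias) calibrated to the study design it emulates:
timepoints {0, 1, 5, 30} min, 4 biological replicates, per-site replicate
CV of ~8% (under the <10% reproducibility typical for unstimulated
acetylation sites), 0.15 log2 measurement noise.

## Worked example

```r
library(ptmDynamics)

# simulated insulin-style time course: 200 sites, 4 archetypes
bundle <- runPipeline(list(simulate = list(n_sites = 200), seed = 1))
summarizeRun(bundle)
#> Pipeline run summary
#>   n_peptide_sites          200
#>   n_proteins               99
#>   n_profiles               200
#>   K_selected               4
#>   cluster_sizes            39,65,50,46
#>   bic                      -3356.4383
#>   early_decreased_2fold    30
#>   early_increased_1p5fold  0
#>   early_unclassified       170
```

The sweep over 15 preference values proposed clusterings from coarse to
fine; BIC selected K = 4, matching the four planted temporal archetypes
(sustained decrease, late decrease, unchanged, slight increase), and 30
sites show an at-least-two-fold loss within 1 minute of stimulation.

```r
# paired vehicle / TSA crosstalk design with 10% planted FCR effects
tsa <- runPipeline(list(simulate = list(n_sites = 200, design = "tsa"),
                        seed = 1))
summarizeRun(tsa)
#> Pipeline run summary
#>   n_peptide_sites          200
#>   n_proteins               103
#>   n_profiles               400
#>   fraction_fcr_altered     0.095
#>   n_significant_raw        30

silacFoldChange(5e6, 1e6)
#>   fold_change log2_fold_change
#> 1           5         2.321928
```

`fraction_fcr_altered` is the share of sites whose EGF response was
changed by at least fifty percent by TSA pretreatment (FCR ≤ 0.5 or
≥ 1.5) — 0.095 measured against the 0.10 planted; `n_significant_raw`
counts sites with raw Welch p < 0.05 between conditions. Result tables
(profiles, cluster assignments, FCR records, test results) and a JSON run
manifest are written by `writeResults()` / the `out_dir` config key.

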