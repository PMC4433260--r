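---
title: "Methods: temporal PTM profiling, affinity-propagation clustering and FCR crosstalk"
author: "ptmDynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal PTM profiling, affinity-propagation clustering and FCR crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmDynamics)
```

# The analysis problem

Receptor tyrosine kinase (RTK) activation — insulin, IGF-1 or EGF binding
its receptor — triggers signaling that is classically read out as tyrosine
phosphorylation, but lysine acetylation on non-histone proteins also
responds within minutes. Quantifying that response takes a multiplexed
mass-spectrometry design: cells are stimulated for 0, 1, 5 and 30 minutes,
acetylated (or phosphorylated) peptides are enriched, and each timepoint's
peptides carry a distinct isobaric reporter channel (iTRAQ), so one MS run
yields a per-peptide intensity for every timepoint. A second design asks a
crosstalk question: does blocking lysine deacetylases (one hour of
trichostatin A, TSA) reshape the phosphotyrosine response to a 5-minute EGF
stimulus?

ptmDynamics implements the downstream analysis of both designs: channel
normalization, temporal log2 fold-change profiles, affinity-propagation
(AP) clustering with BIC model selection, early-response classification,
and the fold-change-ratio (FCR) crosstalk screen with per-site tests. A
synthetic generator with a ground-truth ledger reproduces the statistical
structure of such data so every stage is testable without any download.

# Data model

A `ReporterTable` is a `SummarizedExperiment`: one `intensity` assay
(modified peptides x reporter channels), the channel map in `colData`
(condition, timepoint in minutes, replicate, reference flag) and the PTM
site annotation in `rowData`. The site key is
`protein|residue-position list|peptide` — uniqueness is peptide-level, so a
doubly acetylated peptide (e.g. histone H4 K6+K9) is one site. Duplicate
rows collapse by summing per channel (reporter intensities are additive
evidence; `dedup = "max"` is the documented alternative). Protein positions
are 1-based. Each (condition, replicate) labeling block designates exactly
one reference channel — the unstimulated, timepoint-0 sample; ratios are
only meaningful within a block, which makes the single-block 4-plex and
the two-condition 8-plex designs special cases of the same rule.

# Normalization and profiles

Loading differences between channels are corrected by the mean-ratio rule:
for channel $c$ with block reference $r$, the ratio
$\bar{q}_c = \mathrm{mean}_i\, x_{ic}/x_{ir}$ over rows complete in both
channels, and intensities are divided by $\bar{q}_c$. The mean is
arithmetic in linear space (median and geometric-mean variants are
options). Afterwards every recomputed mean ratio is 1 (exactly, for the
mean variant), and the operation is idempotent. Rows here are peptides; the
peptide-level mean stands in for a protein-level mean, an interpretive
choice that is logged. Two identifiability facts shape the tests:

* Injected per-channel bias is recovered exactly **relative to the block's
  reference channel** — the absolute scale of the reference itself cancels
  from every ratio and cannot be estimated from ratio data. Downstream
  profiles are therefore invariant to any per-channel bias.
* Mean-ratio normalization removes the *average biological response* along
  with the bias. That is the intended behaviour for profile heatmaps (most
  sites are assumed unchanged), but it is why the crosstalk stage works on
  the raw table (below).

Profiles are $v_t = \log_2(\mathrm{mean}_\text{reps}\; x_t/x_0)$, pooled
across replicates in linear space before the log; the reference timepoint
is exactly 0, rows with a missing channel or nonpositive reference are
dropped with a logged reason, and no imputation is performed. SILAC pairs
reduce to `silacFoldChange(heavy, light)` = stimulated/unstimulated.

# Affinity propagation and BIC selection

Similarity is the negative **squared** Euclidean distance between profiles
(the cited message-passing algorithm's standard choice; plain negative
distance sits behind a flag). The always-zero reference column is kept: a
constant coordinate cannot affect Euclidean distances. The diagonal carries
the preference; `"median"` resolves to the median off-diagonal similarity.

The implementation iterates the responsibility and availability updates
with damping 0.9 (default), at most 1000 iterations, declaring convergence
when the exemplar set is unchanged for 100 iterations. A seeded jitter of
about $10^{-12}\,\max|s|$ breaks exact ties that make the messages
oscillate; its diagonal component is strictly negative so ties resolve
toward fewer exemplars. The magnitude is ~10 orders below any data noise.
Two numerical special cases are handled outside the message loop:

* **Degenerate geometry** (all off-diagonal similarities equal, e.g.
  identical profiles): message passing has no gradient and oscillates
  around an exact tie, but the optimum is closed-form — every point its
  own exemplar if the preference exceeds the common similarity, otherwise
  one cluster. The closed form is returned directly.
* **No positive self-evidence** after the loop: the point with maximal
  self-responsibility plus self-availability becomes the single exemplar.

After convergence one refinement pass moves each cluster's exemplar to the
member with maximal within-cluster similarity, then points re-assign to
their best exemplar — the standard post-processing of the reference
algorithm. Results are deterministic given the seed. An exhaustive oracle
(`exhaustiveExemplarOracle`, $n \le 12$) enumerates all exemplar subsets
and is the independent optimum the AP tests compare against; on 100
seeded well-separated instances AP matches the oracle's net similarity in
at least 95 and never exceeds it.

Candidate clusterings come from a preference sweep: 15 values log-spaced
between the minimum and the median off-diagonal similarity, the range over
which K typically grows from few to many. Each result is scored by a
spherical-Gaussian BIC with clusters centred on their exemplars and one
pooled variance:

$$\mathrm{BIC} = nd\,\ln\hat\sigma^2 + (Kd + 1)\ln n,
\qquad \hat\sigma^2 = \frac{\mathrm{RSS}}{d\,(n - K)},$$

lower is better, ties break toward smaller K then smaller preference.
Because exemplars are data points that fit themselves exactly, the
variance uses residual degrees of freedom $d(n-K)$ rather than $nd$; with
the naive denominator and a floor, the saturated $K = n$ clustering (RSS
exactly 0) would be the global minimum of the score — a memorized model.
Here $K = n$ is assigned $+\infty$ (no residual degrees of freedom), and
$\hat\sigma^2$ is floored at $10^{-12}$ for exact-duplicate clusters. A
known limitation: near-saturated clusterings ($K$ close to $n$) can still
score deceptively well if a sweep ever proposes them; the default grid
(capped at the median similarity) does not.

The temporal classes of interest are the early responders: a site is
`decreased_2fold` when its 1-minute value is at least a two-fold reduction
($v_1 \le -1$, boundary inclusive — "at least") and `increased_1p5fold`
when more than 1.5-fold up ($v_1 > \log_2 1.5$, strict — "more than").

# FCR crosstalk screen and tests

For the paired design, each condition's 5-minute response is
$f = \mathrm{mean}_\text{reps}(x_5/x_0)$ and the fold-change ratio is
$\mathrm{FCR} = f_\text{TSA}/f_\text{vehicle}$ (the inverse convention is
a flag). Categories: $<0.3$ strongly attenuated, $[0.3, 0.5]$ attenuated,
$(0.5, 1.5)$ unchanged, $[1.5, 1.9]$ amplified, $>1.9$ strongly amplified
— the strong classes open ("FCR < 0.3", "FCR > 1.9"), the ±50% screen
closed ("at least fifty percent"). Note the thresholds are not reciprocal
pairs ($1/0.3 \ne 1.9$), so swapping the two conditions maps
$\mathrm{FCR} \to 1/\mathrm{FCR}$ exactly but mirrors the category only
where arithmetic allows (strong attenuation always inverts into strong
amplification; a 1.9-fold amplification inverts to 0.53, "unchanged").

The crosstalk stage runs on the **raw** table: the FCR is a
within-replicate ratio of ratios, so per-channel loading bias cancels up
to one factor common to all sites, whereas mean-ratio normalization forces
each condition's mean response to 1 and thereby distorts the FCR whenever
a nontrivial fraction of sites respond. Zero-noise planted-FCR recovery
is exact under this choice and provably not under the normalized one.

Per-site significance uses the two-sided Welch (unequal-variance) t-test
on log2 responses (pooled-variance option available; with two groups the
one-way ANOVA equals the pooled t-test via $F = t^2$), raw $p < 0.05$ as
the headline criterion and Benjamini–Hochberg adjusted values emitted
alongside, never silently substituted. Degenerate zero-variance cases
return $p = 1$ for equal means and $p \to 0$ with a warning otherwise;
both tests are invariant under adding a constant to all log2 values.

# The synthetic generator

`generateDataset()` emulates the time-course design. Four archetypes fix
the cluster shapes over {0, 1, 5, 30} min: sustained decrease
$(0, -1.2, -1.2, -1.2)$, late decrease $(0, 0, -0.2, -1.0)$, unchanged
$(0,0,0,0)$, slight increase $(0, 0.3, 0.45, 0.6)$. The shapes follow the
four observed cluster behaviours; the magnitudes are fixed constants
chosen so the at-least-two-fold class is populated by 1 minute. Default
archetype weights (0.25, 0.25, 0.30, 0.20) give a realistic skew toward
unchanged sites. Per site, the true profile is its archetype plus a
per-timepoint Gaussian offset (SD 0.1 log2, `site_offset_sd`) so sites
within an archetype are distinguishable; the reference intensity is
log-normal around $10^6$ arbitrary units; each biological replicate
carries a multiplicative log-normal effect with
$\sigma_{\log} = \sqrt{\ln(1 + \mathrm{cv}^2)}$ so the per-site CV of
reference intensities across replicates targets `cv_target`; non-reference
channels are reference $\times 2^{\mu + \varepsilon}$ with
$\varepsilon \sim N(0, 0.15^2)$ log2 measurement noise, times an optional
per-channel bias. Replicate effects cancel from within-block ratios, so
the zero-noise limit (`noise_sd_log2 = 0`, `site_offset_sd = 0`) recovers
the archetypes exactly regardless of `cv_target`.

Calibration: 4 replicates and `cv_target = 0.08` place the median
measured per-site replicate CV near 7% (the sample CV of 4 draws is
slightly biased low), consistent with the under-10% biological
reproducibility reported for unstimulated acetylation sites; the reported
"<10% variance" is read as a CV. `generateTSAExperiment()` plants
`round(n * fcr_altered_fraction)` sites with true FCR uniform on
$[0.2, 0.5] \cup [1.5, 3.0]$ (probability proportional to interval
length), all others FCR = 1, on top of per-site vehicle responses
$\log_2 f \sim N(0, 0.8)$ — the default planted fraction of 10% mirrors
the scale of crosstalk observed in the motivating screen. All draws flow
from one seed through a generator that restores the caller's RNG state.

What the generator does **not** emulate: isotope-impurity cross-talk
between reporter channels, intensity-dependent (heteroscedastic) noise,
ratio compression from co-isolated peptides, and any informative
missingness. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean multiplicative error model, not
robustness to those instrumental artifacts.

# Problem sizes and reproducibility

The shipped checks use sizes a laptop handles comfortably: clustering
recovery at 200 sites x 10 seeds (K = 4 selected in at least 8, median
adjusted Rand index at least 0.9, exactly 1 at zero noise), normalization
properties at 1000 sites, AP-vs-oracle on 100 instances of up to 10
points, 50,000 null replications for the Welch size (its true size at 4+4
replicates is ~0.041, slightly conservative — a property of the
Satterthwaite approximation, resolvable from the 0.040 band edge only
with that many replications) and 10,000 for the ANOVA. Pipelines are
deterministic: same config and seed give byte-identical result tables,
and a JSON manifest records config, seed, versions and per-stage counts.

```{r example}
bundle <- runPipeline(list(simulate = list(n_sites = 60), seed = 7,
                           clustering = list(nGrid = 8)))
invisible(summarizeRun(bundle))
```
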