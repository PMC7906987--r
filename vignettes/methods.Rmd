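---
title: "Statistical methods behind metaCrosstalk"
author: "metaCrosstalk maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind metaCrosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaCrosstalk)
```

# The problem

Chronic kidney disease injures both of the nephron's profiled compartments
— the tubule and the glomerulus — and the two injuries are not
independent: secreted products of one compartment can act on the other.
`metaCrosstalk` implements a desk-level pipeline for asking two questions
from publicly available case/control expression cohorts:

1. Which genes are differentially expressed between disease and control in
   each compartment, robustly across heterogeneous cohorts?
2. Which (tubule gene, glomerulus gene) pairs co-vary across patients in
   *every* cohort that profiled both compartments in the same patients —
   and which of those pairs involve a secreted protein that could carry the
   signal between compartments?

All inputs are plain text: per-study genes-by-samples log2 expression
matrices, per-sample metadata (group, compartment, patient id), an
optional probe-to-gene map, and a one-gene-per-line secretome list.

# Preprocessing

Matrices are assumed log2-scale on input (`log2Transform()` is provided
for raw-scale data; it is deliberately not idempotent and never applied
automatically). Each dataset is quantile-normalized *within* the study:
every sample is forced onto the common empirical distribution given by the
row means of the column-sorted matrix. Ties receive the mean of the
reference values their rank range spans, which makes the transform fully
deterministic. We normalize within rather than across studies because the
meta-analysis below operates per dataset and never compares raw
intensities across studies; between-study location shifts are absorbed by
the per-study effect sizes.

Genes with missing values are dropped per dataset and reported — the
source studies give no imputation procedure, and inventing one would be a
larger assumption than losing a handful of genes. Probe-level matrices are
collapsed to genes either by keeping the probe with the highest mean
(default, recorded per gene) or by per-sample medians.

A consequence of quantile normalization worth knowing: genes whose rank is
identical in every sample (typically at the extremes) come out with
*exactly* zero variance. Downstream code treats zero-variance genes as
degenerate — they are excluded from effect-size pooling and flagged in the
SAM statistic rather than producing infinities.

# Differential expression: two evidence streams

## Stream 1 — pooled standardized effect sizes

For gene *i* in study *s*, the effect size is Hedges' g: the case-minus-
control mean difference divided by the pooled SD, with the small-sample
bias correction J = 1 − 3/(4·df − 1). Its sampling variance is
(n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂)). Studies are combined with the
fixed-effect inverse-variance model,

  f_meta = Σ wᵢgᵢ / Σ wᵢ,  wᵢ = 1/var(gᵢ),  se = (Σ wᵢ)^(−1/2),

with a two-sided normal p-value on z = f_meta/se and Benjamini–Hochberg
FDR across genes (cutoff: q ≤ 0.05). Heterogeneity (Cochran's Q, I²) is
computed and logged but does not gate calls — with the small numbers of
cohorts typical here, a random-effects model would be estimated from 3–8
points and mostly add noise. Genes must appear, non-degenerate, in at
least `min_datasets_present` (default 2) studies.

## Stream 2 — SAM with cross-study combination

Per study, Tusher's relative difference d = (x̄_case − x̄_control)/(s + s₀)
is computed per gene, with the fudge factor s₀ chosen from the percentile
grid {0, 5, …, 100} of the per-gene standard errors to minimize the
coefficient of variation of windowed median absolute deviations of d
(100 s-quantile windows). Below 100 genes that criterion is unstable, so
the 5th percentile of s is used and the fallback is recorded.

q-values come from label permutations: at each observed |d| threshold, the
estimated FDR is the mean count (over permutations, pooled across genes)
of null |d*| at or above the threshold divided by the number of genes
called, capped at 1 and made monotone in rank. Two deliberate choices:

* **The observed grouping (and its mirror in balanced designs) is excluded
  from the permutation null.** Including it would floor every q at a
  positive value — no gene could ever reach q = 0 even if its statistic
  dwarfed every genuine permutation. With it excluded, a 3-vs-3 design
  enumerates all 18 remaining assignments exactly; larger designs sample
  `n_permutations` (default 1000) assignments from the stage's seed
  stream.
* **The pooled permutation null doubles as a per-gene permutation
  p-value**, giving resolution of about 1/(B·n_genes) rather than 1/B —
  needed by the combination step next.

Per-study calls (q < 0.10) are then combined across studies. The default
combination is **Fisher's combined probability test** on the per-study
permutation p-values, −2Σln pᵢ ~ χ²₂ₘ, with cutoff p ≤ 0.05. An exact
binomial replication tail — P(K ≥ k | m, rate = 0.10), the probability of
the observed number of per-study calls if calls were null at the q cutoff
rate — is implemented and selectable (`sam_combine = "binomial"`). Fisher
is the default because the binomial tail is extremely coarse with few
cohorts: with m = 4, P(K ≥ 2) = 0.052 already misses a 0.05 cutoff, so
only genes called in 3+ of 4 studies can pass, and per-study SAM power at
q < 0.10 for a moderate effect (g = 1, 15v15, 50 true genes in 1000) is
only ~0.2–0.3. The binomial reading therefore discards most genuinely
replicated moderate effects; the Fisher statistic uses the same per-study
permutation evidence without the hard per-study dichotomization.

## The final call

A gene is a final DEG only when **both** streams pass (effect-stream
q ≤ 0.05 AND combined SAM p ≤ 0.05), with its direction taken from the
sign of f_meta. Genes missing from either stream are never final DEGs and
carry an explicit reason. For enrichment hand-off, final DEGs are
additionally filtered to |mean log2 fold change| ≥ log2(1.5), the mean
being an unweighted average of per-study case-minus-control differences
(the sources do not state how fold change was aggregated; equal weights
are the assumption-free choice).

# Compartment comparison

Tubular and glomerular final DEG sets are partitioned into
unique/shared/unique by exact set algebra (`vennPartition()`). A
direction-aware variant counts a gene as shared only when called with the
same sign in both compartments; the identity-only overlap is the default.

# Cross-compartment correlation screen

For each cohort with both compartments profiled in the same patients,
samples are aligned by patient id and every (tubular DEG, glomerular DEG)
pair is tested for correlation across patients with three statistics:
Pearson's r (t reference, df = n−2), Spearman's rho (Pearson on average
ranks, same t approximation), and Kendall's tau-b (tie-corrected, normal
approximation z = 3τ√(n(n−1))/√(2(2n+5))). Constant vectors yield a
flagged "undefined" result, never a silent zero. The implementation uses
`stats::cor` for the coefficients and its own closed-form p-values; the
test suite checks all three coefficients against from-scratch
implementations of the definitions.

A pair is retained in a cohort when |coefficient| > 0.7 and p < 0.001.
**Which coefficients the cutoff applies to is governed by
`corr_consensus`, and the default is `pearson_only`.** The three
coefficients live on different scales: for bivariate Gaussian data,
τ = (2/π)·arcsin(ρ), so a pair with Pearson correlation 0.85 has
population Kendall τ ≈ 0.65 — a 0.7 cutoff applied to τ then sits *above*
the population value, and clearing it in every one of four cohorts
requires four independent upward sampling fluctuations, which is why
joint recovery collapses. Requiring all three coefficients to clear one shared
threshold (`all_three`, available) therefore does not express "three
methods agree"; it silently re-tightens the Pearson cutoff to ≈ 0.93.
Under the default, the cutoffs apply to Pearson's r and all three
statistics are still computed and reported for every retained pair.

Correlation p-values are deliberately **not** multiple-testing corrected —
the screen reproduces a raw p < 0.001 cutoff — but the run log reports the
implied expected number of null pairs (|DEG_tub|·|DEG_glom|·0.001 per
cohort) so users can judge the screen's specificity; the cross-cohort
intersection is what actually controls false pairs.

Consensus pairs must be retained in **all** cohorts with a consistent
Pearson sign; sign-conflicted pairs are rejected. The signed bipartite
network (nodes labelled tubule / glomerulus / both; edges carrying the
consensus sign and median r) is exported in SIF format for
network-visualization tools.

# Secretome annotation

A user-supplied secreted-protein list (ids uppercased, deduplicated, file
hash logged) flags each consensus pair's tubule and glomerulus genes.
Pairs whose tubule-side gene is secreted rank first — a secreted tubular
product correlated with a glomerular transcript is the natural ligand-like
candidate for tubule-to-glomerulus signaling. Summary counts are of
distinct genes, not pairs.

# The synthetic generator

Validation needs data with known answers. The generator emulates the
pipeline's inputs with a Gaussian model on the log2 scale: gene baselines
~ N(8, 2), a scalar per-dataset batch shift ~ N(0, 0.5), within-sample
noise ~ N(0, 1), planted DEGs as a ±1.0·noise-SD case shift (half down-
regulated), so planted genes have true Hedges-scale effect ≈ 1.0
regardless of the noise scale. Paired cohorts plant cross-compartment
pairs through a shared per-patient latent factor with loadings chosen so
the population cross-correlation equals `rho_true`; when DEGs are also
planted, pair genes are drawn from the planted DEG sets with signs matched
to sign(rho_true) so the disease effect reinforces rather than cancels the
latent correlation — the coherent-disease-process scenario the screen is
meant to detect.

Default conditions (the ones the test suite and acceptance script run):
four 15v15 cohorts of 1000 genes with 50 planted DEGs at g = 1.0; four
paired cohorts of 40 patients with 20 planted pairs at ρ = 0.85 in a
300-gene-per-compartment universe. These sizes keep the full validation
suite in the low minutes on one CPU while leaving the statistics in their
asymptotically honest regime.

What the generator does **not** emulate: probe-level artifacts, missing
values, count overdispersion (RNA-seq), outlier samples, and non-Gaussian
tails. Passing tests on synthetic data therefore demonstrate correctness
of the statistical machinery under the model's assumptions, not robustness
to every pathology of real microarray data.

All randomness — permutations and generation — derives from one root seed
through per-stage hashed streams, so adding a stage never perturbs another
stage's draws and whole runs are byte-reproducible.

# Numerical and degenerate-case choices

* Zero pooled SD ⇒ effect size undefined; the gene is excluded from
  pooling in that dataset (not set to 0).
* s + s₀ = 0 ⇒ SAM d undefined; flagged, q = 1.
* Fewer than 10 distinct label assignments ⇒ permutation q-values refuse
  to run rather than return vacuous estimates.
* s₀ candidate ties break toward the smallest candidate.
* Constant expression vectors in the correlation screen are flagged
  undefined and can never pass the cutoffs.
* BH adjustment validates p ∈ [0, 1] and errors on NA rather than
  propagating it.
* Writers refuse to write empty result tables (truth tables are the one
  exception: an empty truth is a legitimate null configuration).

# Known limitations

* Fixed-effect pooling assumes one common effect per gene; heterogeneity
  is reported, not modeled.
* The Kendall normal-approximation p ignores the tie correction in the
  variance (the coefficient itself is tie-corrected tau-b); at the
  screen's n ≥ 30 this is immaterial next to the |r| > 0.7 cutoff.
* The correlation screen is marginal: it cannot distinguish direct
  crosstalk from shared confounding (disease severity correlates
  everything with everything at some level), which is why the secretome
  annotation and sign consistency are filters, not proofs.
* Identifiers are opaque strings; cross-platform id reconciliation must
  happen upstream.
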