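---
title: "Methods: miRNA-mRNA inverse-correlation integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA inverse-correlation integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprop)
```

## The question and the model

In a two-group bulk design — here a caloric-restriction model of fetal
growth restriction (FGR), control vs restricted placentas — miRNAs act by
repressing their predicted mRNA targets. A miRNA that genuinely regulates
its targets should therefore be *inversely* correlated with them across
samples. `mirprop` operationalizes this in four stages, each with an
explicit statistical contract.

**Normalization.** Counts per million, `value(f, s) = counts(f, s) /
(lib_size(s) · factor(s)) · 1e6`. The optional factors are trimmed-mean-of-
M-values (TMM) scaling factors computed in-package: per sample, the
precision-weighted mean of per-feature log2 ratios against a reference
sample, after trimming 30% of the log-ratios (M) and 5% of the average
log-abundances (A) at each tail, excluding features with a zero count in
either member of the pair; factors are rescaled to geometric mean 1, and
the reference defaults to the sample whose 75th-percentile count fraction
is closest to the mean of those fractions. The pipeline default is
`cpm+tmm`: when a handful of highly expressed features move strongly in one
group, pure library-size normalization transfers their shift to every other
feature as a spurious opposite-direction change; TMM is the standard guard
against exactly this composition bias, and the simulator (which plants its
regulators among the most abundant miRNAs) makes the effect visible if TMM
is switched off.

**Differential expression.** Four tests cover the design space: a
pooled-variance two-sided Student *t* and a one-way fixed-effects ANOVA on
`log2(CPM + pseudocount)` for replicated designs, and the Fisher exact and
Pearson chi-squared tests on within-group pooled counts for replicate-free
designs. The default for the 3-vs-3 replicated design is the *t* test.
Significance is driven by the raw p-value at α = 0.05 by default — matching
the style of reporting this analysis mirrors — with Benjamini–Hochberg
adjustment behind a flag for users who want FDR control.

**Selection.** miRNAs are ranked by mean normalized (CPM) count over the
case-group samples; the top 100 are kept, and their intersection with the
significant set is the *focus set*. Ranking uses normalized rather than raw
counts because raw sums are library-size-confounded; mean rather than
median because at n = 3 the median is just the middle order statistic. Ties
break by feature identifier, ascending, so the ordering is total and
deterministic.

**Integration.** For each focus miRNA, each predicted target that is (a)
significantly DE on the mRNA side and (b) present in the mRNA matrix is
Spearman-correlated with the miRNA across *all* samples, both groups
pooled. Pooling maximizes n (6 in the motivating design) and is the only
way target counts of 4 or more significantly correlated genes can arise
from a 3 + 3 design. Each pair is classified inverse / positive /
nonsignificant at α_corr = 0.05. For a miRNA with n_sig ≥ `min_targets`
significantly correlated targets, of which x are inverse, the test is

z = (|x/n_sig − p₀| − 1/(2·n_sig)) / √(p₀(1 − p₀)/n_sig), p₀ = 0.5,

with the continuity-corrected numerator floored at zero and a two-sided
normal p-value — the convention of the widely used online one-proportion
calculators. An exact binomial p is available behind a flag. The reported
interval for x/n_sig is the exact Clopper–Pearson interval (Beta
quantiles), whose boundary closed forms are `(α/2)^(1/n)·100` at x = n and
the mirror image at x = 0; the printed intervals this analysis style
produces (e.g. 19.41–99.37 for 3 of 4, 15.81–100.00 for 2 of 2) identify
the method uniquely against Wald or Wilson intervals. A miRNA is a
*candidate regulator* iff its proportion test is significant at α_prop and
its direction call is YES (majority inverse).

### Why p₀ = 0.5

The null proportion is never stated in the style of analysis this package
implements, but 0.5 is the only null consistent with a Yes/No/= framing:
under no regulation, a significantly correlated target is equally likely to
be inverse or positive. Note that testing the inverse fraction x/n against
0.5 is equivalent to testing its complement (n − x)/n — the two-sided
p-value is identical — so phrasing the statistic as "non-inverse over
total" changes nothing. Both the threshold and p₀ are configuration
options.

## Exact Spearman p-values at small n

With six samples, the usual *t* approximation for Spearman's ρ is invalid:
the permutation null of ρ at n = 6 is discrete with only 720 orderings.
`spearman_pvalue(method = "auto")` therefore enumerates all n! rank
orderings for n ≤ 8 and reports the two-sided fraction of permutations with
|ρ_perm| ≥ |ρ_obs| − 1e-12 (the tolerance absorbs floating-point ties in
the discrete null). Two consequences worth knowing:

* the smallest attainable two-sided p at n = 6 is 2/720 ≈ 0.0028, and
  p < 0.05 requires |ρ| ≥ 0.886 — only rank patterns within one adjacent
  transposition of perfect monotonicity qualify;
* the enumeration is over untied orderings; when the data carry ties the
  p-value approximates the tie-conditional null (which would require the
  rank vectors themselves, not just ρ and n). Pairs with zero rank variance
  are dropped with a logged count rather than given an arbitrary ρ.

## The simulator

`sim_config()` / `simulate_dataset()` generate the two-omics benchmark.
Defaults emulate the motivating study's design: 1546 miRNAs, 5000 mRNAs,
3 biological replicates per group, ~15% DE miRNAs at |log2FC| = 2, 16
regulator miRNAs, 20 predicted targets per miRNA with 75% of a regulator's
targets inversely coupled at strength 1.5 (log2 units per SD of the
regulator's latent log2 expression), negative-binomial counts with
dispersion φ = 0.1 (variance μ + φμ²), log-normal feature means (natural-log
mean 6, sd 1.5, i.e. median ≈ 400 counts), and uniform per-sample library
factors in 0.7–1.3. Library sizes and dispersion are not reported for the
motivating dataset; these values are conventional for bulk small-RNA data.
One master seed drives all draws in a documented order, so identical
configurations are byte-identical.

Design choices that were genuinely open:

* **Coupling acts on the latent mean.** A coupled target's per-sample log2
  mean is shifted by ∓`coupling_strength` × z_s, where z_s is the
  regulator's standardized latent log2 expression. Inverse correlation is
  thus a property of expression, recoverable by Spearman, rather than an
  artifact of shared sampling noise. With 3 + 3 samples the latent is
  two-valued (group structure only), so within-group rank order is pure
  negative-binomial noise — an intentional, conservative choice; the
  alternative (injecting shared per-sample latent noise) would manufacture
  within-group correlation that the generating model has no biological
  reason to contain, and would simultaneously degrade the miRNA's own DE
  detectability.
* **Regulators are abundant in the case group.** The analysis this package
  mirrors only ever examines the top-100-by-count miRNAs of the case group,
  so regulators are planted among features whose case-group latent mean
  reaches the 50th-largest baseline mean. Under the log-normal abundance
  model very few features are abundant enough to remain in the top tier
  after a 4-fold knockdown, so when a regulator is drawn as down-regulated
  but no sufficiently abundant feature remains, its sign is flipped to up —
  the simulator consequently plants more up- than down-regulated
  regulators. Real miRNA abundance distributions are heavier-tailed (a few
  miRNAs capture a large share of reads), which is the main respect in
  which the simulator is *less* favourable to knockdown regulators than
  real data.
* **What the simulator does not model:** sequencing reads, hairpin
  structure, 3′-UTR sequence (targets are abstract pairs), tagwise
  dispersion, batch effects, or sex differences. Passing recovery tests on
  this generator therefore demonstrates internal consistency of the
  pipeline, not performance on real libraries.

## Numerical and reporting conventions

* log2 pseudocount 1 on the CPM scale (bounded fold changes at zero
  counts); a zero pseudocount is rejected whenever a zero value is present.
* Percentages are rounded half-up (14.7477 → 14.7), matching how such
  tables are typically printed; base R's round-half-even would disagree on
  exact .05 boundaries.
* Results tables serialize reals at 6 significant digits with Unix
  newlines; the same table is always byte-identical, and the run manifest
  records MD5 hashes of every artifact.
* Degenerate inputs are defined, not accidental: zero-variance features in
  both groups with equal means give t = 0, p = 1; zero margins give
  Fisher/chi-squared p = 1 with a logged count; miRNAs with fewer than
  `min_targets` (default 2) significantly correlated targets are excluded
  from the proportion test with a logged count; empty called sets score
  precision 1 by convention in recovery reports.

## Power: what three replicates can and cannot show

The package's own acceptance checks quantify a hard limitation. At
n = 6 pooled samples, a planted inversely coupled pair (coupling 1.5,
φ = 0.1) reaches exact-Spearman significance only when its ranks are within
one adjacent transposition of a perfect reversal; within-group order is
noise, so this happens in roughly a quarter of cases. The one-proportion
test then needs nearly *all* of a miRNA's ~20 targets to be significantly
correlated and almost all of those inverse before z exceeds 1.96 (e.g.
15 of 20 inverse of 20 significant is the boundary case, p ≈ 0.044; 6 of 6
is the smallest all-inverse pass). The compound event is rare: candidate
recall against planted regulators is a few percent at the default study
scale, while precision is essentially perfect — the rare calls that do
clear the bar are true regulators. This asymmetry (trustworthy positives,
many missed regulators) is exactly what users should expect from the
corresponding analysis of a real 3-vs-3 dataset, and is why the candidate
list should be read as a high-confidence shortlist rather than an
inventory. At `n_per_group = 10` the same planted couplings are recovered
as significant inverse correlations (the test suite verifies this), which
is the cleanest demonstration that the constraint is the sample size, not
the method's implementation.

Type-I behaviour is verified on null simulations (no DE, no coupling,
1546 miRNAs, 5 replicates per group, 20 seeds): the t-test false-positive
rate at α = 0.05 stays within 99% binomial bounds of its pooled trial
count, and the proportion test — conservative at small n_sig because of the
continuity correction and the discreteness of its inputs — calls well under
10% of tested miRNAs significant.

## Problem sizes used by the test suite

Unit tests run on purpose-built small fixtures. The statistical acceptance
checks use: all 2×2 tables with row margins ≤ 20 for the Fisher oracle;
full n! enumeration up to n = 6 for the Spearman oracle; 20 null seeds at
1546 × 10 for calibration; and the default study-scale simulation
(1546 miRNAs × 5000 mRNAs, 3 vs 3) for recovery and determinism. These
sizes were chosen as the smallest at which each property is meaningfully
exercised.

## Known limitations

* The candidate rule (proportion-test p < α and majority-inverse call) is
  deliberately strict; at three replicates per group its recall is low (see
  above). Users wanting a more inclusive list can lower `min_targets`, use
  the exact binomial option, or simply rank by the inverse fraction and its
  CI rather than thresholding.
* Exact Spearman p-values ignore tie structure (documented above); at CPM
  scale with six samples ties are rare but possible for low counts.
* The mRNA-side significance filter uses the same t-test machinery as the
  miRNA side; external mRNA DE calls can be supplied instead by passing
  their gene list to `integrate_mirna()` directly.
* Functional enrichment of the exported candidate targets is out of scope;
  the `candidates.tsv` hand-off file is the boundary.
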