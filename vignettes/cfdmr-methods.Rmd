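---
title: "cfdmr: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfdmr: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own statistics: the models
each stage assumes, the tunable parameters and why their defaults are
what they are, what the synthetic-cohort generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. Everything quantitative claimed here is computed by the test suite
or by `scripts/acceptance.R`; nothing is asserted that the code does not
verify.

## 1. The average methylation fraction

For a genomic bin $b$ and sample $s$, with $m_{is}$ methylated and
$t_{is}$ total read observations at reference CpG $i \in b$,

$$\mathrm{AMF}(b, s) = \frac{\sum_{i \in b} m_{is}}{\sum_{i \in b} t_{is}}.$$

The denominator counts *read observations*, not distinct CpGs, so deeper
CpGs weigh more. A bin with no covered CpG is *missing* (never zero).
Bins are fixed-width half-open tiles $[kw, (k+1)w)$ with $w = 100$ bp,
and only bins with at least `min_cpgs = 5` reference CpGs are eligible:
at low depth, single-CpG estimates are dominated by binomial noise, and
CpG-dense bins are where regional methylation is coherent enough for a
ratio to be meaningful.

Coordinates are 0-based half-open everywhere; the call-file dialect
(chrom, start, end, percentage, count methylated, count unmethylated) is
parsed by reconstructing totals as methylated + unmethylated and dropping
zero-coverage rows.

**Masking.** Blacklist/repeat intervals are applied at the CpG-call
level: a call at position $p$ is removed when $p$ lies in a masked
interval. For point records, removing masked calls and then binning is
identical to binning against a mask-filtered CpG catalog — the pipeline
uses the latter (one catalog filter instead of one interval query per
sample), and the equivalence is tested. This is an approximation of
read-level masking (a read straddling a blacklist boundary contributes
its unmasked CpGs here, whereas read-level filtering would drop it
entirely); the package's entry point is call files, where read identity
is no longer available.

**Sample QC.** The conversion rate is $1 - \sum m / \sum t$ over CHH
context calls; in human DNA, CHH methylation is negligible, so residual
CHH signal estimates conversion failure. A sample passes when conversion
strictly exceeds 0.99 and the median over eligible bins of the per-bin
average CpG depth ($\sum t / \#\text{covered CpGs}$) is at least 3. Two
open choices were resolved as follows: the 99% gate is strict (a sample
at exactly 99% fails), and the depth statistic averages within bins
first (per-bin average, then the median across bins); the averaging unit
is configurable in `sample_qc()` but per-bin is the default.

**Cohort filter.** After dropping failing samples, a bin is retained
when its missing fraction across retained samples is strictly below
`max_null_fraction = 0.10`; with 10 samples, missing-in-one (exactly
0.10) is dropped.

## 2. Unsupervised structure

The variance screen computes each bin's SD over observed cells only
(imputation would shrink the very variability being screened),
standardizes the SD vector across bins, and keeps bins with $z > 2$.
Missing cells of surviving bins are then imputed with the bin's
group-wise mean — the mildest completion consistent with the two-group
design; a bin with no observed value in a group is an error, not a
silent fill.

PCA is computed by SVD on the centered samples × bins matrix
(unit-variance scaling is available by flag but off by default: AMF
values share a scale, and variance differences are signal here). The
number of reportable components defaults to $k = 30$.

**Permutation cutoff.** To decide which components exceed noise, each
bin's values are independently permuted across samples; for each of
`n_perm = 1000` permuted tables the top component's variance proportion
is recorded, and the cutoff is the maximum over permutations. Observed
components whose variance proportion exceeds the cutoff are significant.
Two design points:

* *Per-bin* shuffling is the only useful reading of "shuffling samples":
  permuting whole sample columns leaves the covariance spectrum exactly
  unchanged, so a whole-column null would reproduce the observed scree
  and declare nothing. Per-bin shuffling preserves every bin's marginal
  distribution while destroying inter-bin correlation — precisely the
  noise model against which real covariance structure should be judged.
* The "maximum total variance" of the permuted tables is interpreted as
  the maximum top-1 variance *proportion*, the only permutation summary
  commensurable with per-component observed proportions on a scree plot
  with a single cutoff line.

Loading signs are fixed (largest-magnitude loading positive) for
reproducibility. Retained components are correlated with clinical
variables: Pearson $r$ with $t$-distribution p-values for continuous
variables, identical machinery on 0/1 coding for binary ones (the
point-biserial coefficient *is* Pearson on 0/1 coding — tested as an
exact identity), and Spearman in parallel. Zero-variance variables give
missing cells rather than errors.

One subtlety the permutation null does not capture: group-mean
imputation makes samples that share a missing cell share its imputed
value, a small within-group correlation that survives in the observed
table but not in permuted ones. At the package's missingness levels
(≤ 10% per bin by construction) this effect is far below the cutoff —
the null-calibration test (100 seeded runs on no-effect cohorts, ≥ 95%
with zero significant components) passes with it included.

## 3. The DMR screen

Samples are split 85:15 into train and test, stratified by group with
per-group training counts rounded half-up — (109 good, 34 poor) yields
exactly (93, 29) training and (16, 5) test samples. Three bootstrap
subsets are drawn from the training set, each full-size and stratified
within group (plain with-replacement bootstrap would occasionally
decimate the 29-sample poor group; stratification preserves the group
composition exactly, which is what the per-bin two-sample test needs).
Duplicated samples count as independent observations — plain bootstrap
semantics.

Per subset, a bin is tested when more than 90% of its bootstrap
observations are non-missing (coverage is evaluated on bootstrap
observations, not unique samples — a flag switches this) and both groups
retain at least two observations. Welch's unequal-variances $t$ is
computed in closed form, vectorized over bins:

$$t = \frac{\bar{x}_g - \bar{x}_p}{\sqrt{s_g^2/n_g + s_p^2/n_p}},$$

with Welch–Satterthwaite degrees of freedom and a two-sided $t$ p-value.
Methylation variance is heteroscedastic across the genome, which is why
Welch rather than the pooled test is the screen's engine; the two agree
exactly when variances and group sizes coincide (tested at 1e-10
against the reference implementation). Degenerate bins (both groups
constant) return $p = 1$ when means agree and a p-value floored at the
smallest positive double when they differ — never a division by zero.

The good-minus-poor mean differences of all tested bins are standardized
into z-scores *within the subset* (the standardization population is the
subset's tested bins); q-values are Benjamini–Hochberg by default. A bin
is a DMR when $q < 0.05$ and $|z| > 2$, labeled hypomethylated
($z < -2$: good below poor) or hypermethylated. An empirical-null
q-value variant is available (`method = "empirical-null"`): BH scaled by
a null-proportion estimate $\hat\pi_0 = \min(1, 2\,\overline{[p > 0.5]})$.
It is this package's own tail-area variant — exact reproduction of
external empirical-null density estimators was deliberately not
attempted, since their q-values depend on estimation internals that are
not part of the method's definition.

**Intersection and ranking.** The cascade keeps bins selected in all
three subsets, then ranks the intersection within each subset by
ascending q (ties by descending $|z|$, then genomic coordinate — the
tie-break is a package decision; ranking is otherwise undefined for tied
q-values) and keeps bins in the top 500 of every subset.

**Why intersect?** Under a no-effect cohort, a *single* bootstrap
subset's Welch p-values are anti-conservative: duplicate observations
understate within-group variance, and measured single-subset false
selection runs at 0.5–3% of tested bins. The subsets' false positives
are largely disjoint, so the three-way intersection suppresses them to
≈ 0–0.2% (the unique-sample screen selects essentially nothing). This
is measured, not assumed — the null-calibration tests assert the ≤ 1%
budget on the cascade's output and on the unique-sample screen.

## 4. Random-forest markers

Candidate-DMR AMF values feed a random-forest classifier. Imputation is
leakage-guarded: training cells use training-group means; test cells use
overall training means (no label information touches the test side).
`mtry` is selected from the grid
$\{\lfloor\sqrt{p}/2\rfloor, \lfloor\sqrt{p}\rfloor, 2\lfloor\sqrt{p}\rfloor\}$
(500 trees) by repeated stratified cross-validation — 10 folds × 10
repeats by default — scored by the AUC of pooled out-of-fold predictions
(accuracy by flag). The grid and tree count are package defaults chosen
to bracket the conventional $\sqrt{p}$ heuristic; the original tooling's
values are not stated anywhere.

The *training* ROC is computed from out-of-fold cross-validation
predictions, not resubstitution: a forest resubstitutes near-perfectly
by construction, so a resubstitution ROC would be uninformative. The
test ROC uses the final forest (refitted on the full training set at the
chosen `mtry`) on the held-out samples. The ROC is the tie-aware
empirical curve with trapezoidal AUC, which equals the normalized
Mann–Whitney U statistic (tested at 1e-12, plus a cross-check against
an independent ROC package).

Markers are the top 20 candidates by mean decrease in Gini, ties broken
by genomic coordinate. Annotation classifies each marker by overlap
priority exon > intron > intergenic (any overlap counts) and attaches
the nearest gene with a signed distance (0 overlapping, negative left of
the gene, positive right). Gene lists are exported deduplicated and
alphabetical for external enrichment tools; enrichment itself is out of
scope.

## 5. External validation

AMF is recomputed over the marker intervals from external per-CpG call
files with the same depth-weighted ratio (verified to agree exactly with
the pipeline's binned AMF when the region equals a bin). Samples with a
covered CpG in fewer than half of the marker regions are excluded — the
threshold makes a qualitative "very low coverage" exclusion explicit and
reproducible. Per region, the external cohort is compared with the study
good group by a two-sided Mann–Whitney test, and a *stringency*
indicator reports whether the external distribution is at least as tight
as the poor group's (external IQR ≤ poor IQR) with a median no more than
0.05 below the poor median. The indicator is a labeled reporting
heuristic — the underlying claim ("similar or more stringent") has no
canonical statistic — and the 0.05 tolerance is on the AMF scale.

## 6. The synthetic cohort generator

The generator emulates the study conditions so that every downstream
stage has recoverable ground truth:

* **Cohort**: 109 good / 34 poor samples. Covariates (age ≈
  N(57.8, 10.6²); male 102/143; hypertension 68/143; diabetes 34/143;
  smoking 19/143) are drawn at the published cohort prevalences,
  independent of group by construction, so association tests between
  group and covariates are null.
* **Genome**: `n_bins` 100-bp bins tiled over two synthetic chromosomes;
  each dense bin carries 5–10 CpGs placed uniformly without collision;
  20% of bins get 1–4 CpGs to exercise the density filter; 1% of bins
  are blacklisted to exercise masking.
* **Methylation**: each bin has a baseline mean $m_b \sim$ Beta(45, 5)
  (mean 0.90, SD ≈ 0.04 — mass concentrated near 1 with narrow spread,
  the empirical signature of the poor group). Per sample, the bin-level
  methylation is Beta-distributed with mean $m_b$ and within-group SD
  0.03, reparameterized from (mean, SD) with the SD clamped to the
  feasible range near the boundaries. In the `n_dmr` planted DMR bins
  (drawn among dense unmasked bins so truth is recoverable), the good
  group's mean drops by `dmr_effect` (default 0.3) and its SD widens by
  `dmr_spread` (default 0.05) — hypomethylated and more variable, the
  direction the study design expects.
* **Coverage**: per-CpG depth is Poisson(`depth_mean`, default 8);
  zero-depth CpGs are emitted as absent records. Poisson depth alone
  cannot produce bin-level missingness at these depths — a bin with
  $k \ge 5$ CpGs is entirely uncovered with probability $e^{-k\lambda}
  \approx 0$ — so the generator adds a per-(bin, sample) dropout event
  (think uneven regional cfDNA representation) with probability
  $$p_0 = \frac{\texttt{missing\_target} - \bar e}{1 - \bar e}, \qquad
  \bar e = \operatorname{mean}_b\, e^{-k_b \lambda},$$
  which calibrates the expected zero-coverage cell fraction to
  `missing_target` (default 0.05); the calibration is tested to ±0.05.
* **Conversion QC**: CHH records are generated with per-read
  false-methylation probability `chh_error` (default 0.002, i.e. true
  conversion 99.8%, comfortably above the 99% gate; set it above 0.01 to
  simulate failing samples).
* **Healthy validation sets**: per-CpG call files over supplied marker
  regions, following the poor-group (near-1) model. Two deliberate
  choices: the healthy between-sample SD is 0.015 — *tighter* than the
  patient poor group, matching the expectation that healthy cfDNA is at
  least as stringent — and the default depth is 30 reads/CpG, since
  published healthy reference sets are sequenced deeper than
  depth-limited patient libraries. `region_means` lets the caller pin
  the healthy means to specific per-region values (the pipeline passes
  the poor-group truth of the marker bins, modeling markers whose
  hypomethylation is disease-specific).

With the same seed the generator is byte-identical across runs; the
pipeline derives per-stage seeds from one global seed via a fixed affine
map (`derive_seed`), so stages are independently reproducible.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: fragment-level correlation of
adjacent CpGs (CpGs are conditionally independent given the bin's
methylation level), genomic covariates of coverage (GC bias, mappability),
realistic CpG spatial clustering (CpG islands), batch and library-prep
effects, age- or cell-composition-associated methylation, and any
correlation between covariates and methylation. The tests demonstrate
that the pipeline recovers the structure it is designed to detect under
its own stated noise model, at the study's sample sizes — not that the
biological findings replicate.

## 7. Problem sizes used by the test suite

Monte-Carlo checks run at the reference scale of 5000 bins and 109/34
samples: 20 seeded planted cohorts (100 DMRs, effect 0.3, depth 8) for
recovery (mean recall ≥ 0.7, precision ≥ 0.8, ≥ 90% hypomethylated) and
for classifier sanity (median held-out AUC ≥ 0.9 planted, within
[0.3, 0.7] with labels permuted at the classifier stage — permuting
before the screen would empty the candidate set and leave no classifier
to test); 100 permutation-PCA runs on no-effect cohorts as 10 fresh
cohorts × 10 procedure seeds at 200 permutations each (the cutoff is a
maximum over permutations, so the zero-significant-components guarantee
does not depend on the permutation count); oracle equivalence on 1000
random Welch instances and 200 q-value vectors at 1e-10. The multi-seed
classifier checks use a reduced cross-validation budget (5 folds × 2
repeats, 300 trees, single-point mtry grid) — the tuned quantity there
is the held-out AUC, which is insensitive to the grid at these feature
counts. The single worked-example and determinism runs use the full
default configuration.

## 8. Known limitations

* Read-level blacklist filtering is approximated at the call level (see
  §1); the difference is confined to reads straddling mask boundaries.
* The empirical-null q-value variant is a π₀-scaled BH, not a density-
  estimated local-fdr; results using that flag are not comparable to
  external empirical-null implementations.
* Single bootstrap subsets are anti-conservative under the null (§3);
  per-subset DMR counts should never be interpreted alone, only through
  the intersection.
* The PCA permutation null ignores the small imputation-induced
  within-group correlation (§2); at ≤ 10% missingness this is
  negligible, but the cutoff is not exact for heavily imputed matrices.
* `stratified_split` guarantees the published split counts only under
  round-half-up; other rounding conventions will disagree by one sample
  per group.
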