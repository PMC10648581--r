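---
title: "Methods: spike-in normalization, permutation screening, and forward-selected subtype classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalization, permutation screening, and forward-selected subtype classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsubtype)
```

`mirsubtype` analyzes RT-qPCR miRNA panels profiled across tumor
subtypes of endometrial carcinoma. This vignette is the package's own
account of the statistical machinery: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and where the
method's known limitations lie.

## Ct normalization against spike-in controls

RT-qPCR reports a quantification cycle (Ct): the PCR cycle at which
fluorescence crosses threshold. Abundance scales as $2^{-\mathrm{Ct}}$,
so Ct differences are log2 expression differences with the sign
flipped. Panels of this kind include synthetic spike-in controls added
at a fixed amount per sample; their Ct read-out absorbs purely
technical per-sample variation (input amount, RT efficiency).

`normalize_ct()` uses the per-sample *median* spike-in Ct as the
technical reference:

$$\mathrm{expr}(m, s) = \operatorname{median}_k \mathrm{Ct}_{\text{spike}}(k, s) - \mathrm{Ct}(m, s).$$

Higher values mean more abundant, and the construction is exactly
invariant under any additive Ct shift applied uniformly to one sample
(the shift enters the reference and the assay Ct alike). The median
over controls is robust to individual control failures. The actual
normalization pipeline shipped with commercial panels of this type is
proprietary and unpublished; this spike-in $\Delta$Ct scheme is the
package's stand-in — standard qPCR practice, deterministic, and
testable through its shift-invariance property.

**Undetected wells.** A Ct at or above the detection limit (default
38 cycles, the conventional qPCR calling limit), or a missing well, is
treated as undetected. A miRNA undetected in more than
`max_missing_frac` (default 20%) of samples is dropped; remaining
undetected wells are imputed at that miRNA's minimum observed
expression minus one cycle — a deterministic floor just below the
observed range that keeps the matrix finite without inventing signal.
Left-censoring of this kind can attenuate estimated fold changes for
miRNAs expressed near the limit; the generator reproduces the mechanism
so the tests exercise it.

## One-vs-rest differential screen

Each subtype level is contrasted against all *other samples with a
known label* of the same variable ("one vs rest"). Samples with an
unknown molecular or CTNNB1 status are excluded from both sides rather
than pooled into the control group: only 102 of 119 samples carry a
molecular call and 92 a CTNNB1 call in the emulated design, and pooling
unknowns would contaminate the null group with unlabelled positives.

Per miRNA the screen reports:

* **Fold change** — the ratio of geometric means,
  $\mathrm{FC} = 2^{\bar{x}_{\text{group}} - \bar{x}_{\text{rest}}}$,
  computed in the same log2 domain as the test statistic.
* **Student *t*** — the two-sample pooled-variance statistic on log2
  expression, positive when the group's mean is higher. Zero pooled
  variance yields $t = 0$ for equal means and a signed-infinity
  sentinel otherwise.
* **Permutation p** — two-sided on $|t|$: group labels are reassigned
  uniformly at random $B = 1000$ times preserving group sizes, and
  $p = (1 + \#\{|t_b| \ge |t_{\text{obs}}|\}) / (B + 1)$. The
  add-one estimator never returns 0 and is mildly conservative, the
  standard choice for sampled permutation tests. When the assignment
  space $\binom{n}{n_1}$ has at most $B$ elements the space is
  enumerated exhaustively and the exact proportion returned instead —
  this makes small contrasts exactly testable against brute-force
  enumeration. All miRNAs of a screen share one permutation set, which
  both matches the single-shuffle-of-labels design and lets the whole
  352-miRNA screen be computed with two dense matrix products.

Significance is `perm_p < alpha` (default 0.05, no multiple-testing
correction — the emulated study applies none; the number of tests is
recorded in `glance()` so users can post-correct). The effect-size
filter keeps $|\mathrm{FC} - 1| > 0.5$ *strictly*, i.e. FC above 1.5 or
below 0.5; the strict inequality matches the published boundary
behavior of the catalogue this package ships (values of 1.51 kept,
1.47–1.50 excluded; 0.49 kept, 0.52 excluded).

## Subtype classification by sequential forward selection

For a one-vs-rest contrast, `sequential_forward_select()` grows a miRNA
panel greedily. The criterion for a candidate panel is stratified
$k$-fold cross-validated AUC: for each of `n_repeats` independent fold
partitions, a scorer is trained on each fold's complement, the held-out
linear scores are pooled across folds, one AUC is computed on the
pooled scores, and the criterion is the mean over repeats. AUC is the
Mann–Whitney probability (ties counted 0.5), so it is rank-invariant
in the scores.

Decisions the design left open, and how the package resolves them:

* **Base scorer.** A ridge-penalized logistic model (IRLS, penalty
  `regularization = 1` on standardized coefficients, intercept
  unpenalized). For cohorts of ~100 samples and panels of ≤ 10
  features a lightly regularized linear scorer is deterministic,
  well-conditioned even with separable features, and its log-odds
  score is rank-equivalent to common alternatives on standardized
  inputs. Standardization parameters are learned on training folds
  only; a constant feature receives weight 0 with a warning.
* **Number of folds.** $k = 5$: the smallest modelled groups
  (8 POLE, 11 p53-abnormal) still place at least one positive in
  every fold under stratification.
* **Repeats.** 50 independent partitions per criterion evaluation;
  the partition-to-partition SD of a 5-fold AUC at $n \approx 100$ is
  ~0.01–0.03, so 50 repeats stabilize the criterion to a few
  thousandths.
* **Stopping.** A candidate is added only if it improves the criterion
  by at least `min_improvement = 0.005` over the current value
  (baseline 0.5), up to `max_features = 10`, which covers the 3- to
  10-feature envelope of the models this package targets. If no
  candidate ever clears the baseline, the single best candidate is
  returned with a warning rather than an empty model.
* **Determinism.** Every fold partition is seeded by a stable hash of
  `(seed, stage, step, repeat)`; candidate ties break toward the
  earlier candidate index. Re-running with the same config reproduces
  models byte-identically.
* **Selection vs evaluation AUC.** The headline `mean_auc` is
  recomputed for the selected panel on `n_repeats` fold partitions
  disjoint from all selection-time partitions. This removes the
  winner's-curse of the *partition* draw, but not of the *sample*
  draw: selection saw all samples, so with many null candidates the
  selected feature's sample-specific artifact survives re-partitioning.
  On pure-noise data with hundreds of candidates the reported AUC can
  therefore sit meaningfully above 0.5; only nested cross-validation
  (selection redone inside every fold) removes that bias, at ~$k\times$
  the cost, and is out of scope here. Fixed feature panels are free of
  the issue and the package's null-band tests assert it for them.

## The synthetic cohort generator

`generate_cohort()` simulates the full measurement chain in the Ct
domain. The defaults *are* the emulated study's conditions: a 352-miRNA
panel with 32 spike-in controls; 119 tumors split 89/8/13/9 across
endometrioid, serous, clear cell and de-differentiated histology; 102
samples molecularly subtyped 48/8/35/11 (MMRd/POLE/p53wt/p53abn),
assigned independently of histology; 19 CTNNB1-mutated samples among 92
sequenced, 17 of them endometrioid (reproducing the catalogue's
confounding without modelling its biology).

Per miRNA $m$, a baseline log2 level
$b(m) \sim N(\texttt{spikein\_ct} - \texttt{baseline\_ct\_mean},\;
\texttt{baseline\_ct\_sd})$ is drawn relative to the spike-in
reference; a sample in a planted effect's group adds
$\log_2 \mathrm{FC}$; biological noise is Gaussian in log2 units
(`noise_sd = 1.0` — log-normal on the linear scale, matching
$\Delta$Ct behavior and making the *t*-test's assumptions hold by
construction; no within-group variance was published, so 1.0 log2 units
is a package default chosen as typical for FFPE qPCR panels, not a
reported value). The read-out is
$\mathrm{Ct} = \texttt{spikein\_ct} - \mathrm{expr} + \delta_s$ with a
per-sample technical shift $\delta_s \sim N(0, 1)$ applied to every
assay including the spike-ins, and wells beyond the detection limit are
emitted as missing. Spike-in levels center at Ct 20 and miRNA baselines
at Ct 28, placing both inside the valid [0, 45] cycle range with mild
detection-limit censoring of low-baseline miRNAs. Generation is a pure
function of the config, seed included.

The default planted-effect set is `subtype_effect_catalogue()`, a
published catalogue of one-vs-rest fold changes for this tumor type
(histology effects up to ~15-fold; molecular effects mostly 1.2–2-fold;
seven CTNNB1 effects). Planting the full catalogue reproduces a
realistic *correlated* structure: the same miRNA may be planted in
several subtypes, so one-vs-rest estimates are diluted or inverted by
effects in the rest group exactly as in real cohorts. Two consequences
worth knowing:

* Catalogue-scale fold changes are only recovered cleanly when a single
  variable's effects are planted (the recovery tests plant the
  endometrioid catalogue alone).
* One-vs-rest molecular classifiers on the default cohort reach AUCs
  well above the published 0.75–0.85 range, because the rest group
  carries its own planted signatures that separate it from the target
  subtype. These model AUCs are properties of the synthetic conditions,
  not estimates of the originals.

What the generator does **not** emulate: plate/batch structure beyond
the per-sample shift, PCR efficiency differences, probe cross-talk,
correlated miRNA co-regulation beyond the planted effects, and
survival/outcome structure. Passing tests therefore demonstrate the
statistical machinery is correct under its stated model, not that the
published biology would be reproduced from raw data.

## Numerical choices

* Permutation extremeness uses $|t_b| \ge |t_{\text{obs}}| - 10^{-8}$
  so exact ties are counted under floating-point noise.
* Pooled variances are clamped at 0 to absorb catastrophic
  cancellation when a group is (numerically) constant; the degenerate
  branches return $t = 0$ (equal means) or signed infinity.
* Fold partitions deal shuffled class members round-robin, so fold
  sizes differ by at most one per class.
* Test problem sizes: unit tests run on trimmed cohorts (40–80 miRNAs,
  36–102 samples) chosen so each property is exercised at the smallest
  scale at which it is meaningful; the calibration, recovery and
  selection-consistency checks run at the full 352 × 119 study
  dimensions.

## Limitations

Beyond the selection-bias caveat above: no Welch or nonparametric
test alternatives; no FDR control; no covariate adjustment; no absolute
quantification or standard-curve efficiency modelling; annotations with
unknown labels are excluded per contrast rather than imputed. The
fold-change filter, being a ratio criterion, is insensitive to absolute
expression differences at high abundance.
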