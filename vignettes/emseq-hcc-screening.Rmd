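---
title: "Conversion QC for enzymatic methyl-seq and stacked cfDNA screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion QC for enzymatic methyl-seq and stacked cfDNA screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical conventions,
and what a green test does and does not establish.

## 1. The conversion failure model

Enzymatic conversion turns unmethylated cytosine into uracil (sequenced as
T) while sparing 5mC/5hmC. Two empirically distinct failure modes exist:

* **Sporadic** failures: isolated unconverted cytosines, modelled as
  independent per-site events at rate `1 - eff` in normal molecules.
* **Clustered** failures: a molecule that largely escapes conversion, so
  many of its cytosines stay unconverted. Modelled as a per-*molecule*
  Bernoulli event with probability `rho_fail`; inside a compromised
  molecule each unmethylated cytosine converts only with probability
  `eff_fail`.

This two-parameter construction reproduces the sporadic/clustered
dichotomy with a bimodal per-read unconverted-CH distribution and is the
basis of every downstream QC property. Crick-origin molecules are
simulated by converting cytosines of the reverse-complement strand; reads
are emitted in forward-reference coordinates with an origin-strand flag
(a converted Crick cytosine appears as G→A in forward coordinates). `N`
bases never convert and never receive calls.

Defaults (`conversion_params()`): `eff = 0.998`, `rho_fail = 0.01`,
`eff_fail = 0.5`, `err = 0.001`. These are implementer-chosen plausible
values — the failure *rates* of real chemistry are not published as
parameters anywhere — and everything downstream treats them as
configurable. Failure is modelled context-independent; real enzymatic
conversion shows sequence-context dependence (deaminase substrate
preference), which is left as an extension point rather than guessed.

## 2. Read-level QC: counting unconverted CH

Per-read call strings use the de-facto methylation-call-tag alphabet
(`Z/z` CpG, `X/x` CHG, `H/h` CHH, uppercase = cytosine retained =
unconverted, `.` = no origin-strand cytosine or unresolvable context).
Context is always taken from the *reference*, using up to two bases
downstream in origin-strand sense, so read-terminal cytosines are
classifiable; a context that runs past the reference end or through an
`N` is unresolvable (`.`). Read bases other than C/T (origin-strand
sense) at a cytosine — sequencing errors — also yield `.`.

The filter statistic is the number of uppercase `X` + `H` symbols: CH
cytosines (CC/CT/CA) that failed to convert. Since non-CpG methylation is
negligible in human DNA, each such site is a conversion failure. Reads
with **≥ 3** unconverted CH sites are removed. The primary description of
this threshold is ambiguous between "more than 3" and "≥ 3" in different
places; this package uses ≥ 3 (the form used in the results that motivate
the filter) and makes the threshold configurable
(`filter_config(ch_threshold = )`).

For a read covering `n` truth-unmethylated CH sites the unconverted count
is a two-component binomial mixture, and the removal probability has the
closed form implemented in `ch_removal_probability()`:

    P(remove) = rho_fail * P(Binom(n, 1 - eff_fail) >= 3)
              + (1 - rho_fail) * P(Binom(n, 1 - eff) >= 3)

Tests compare simulated removal fractions against the mean of this
expression over the realised per-read `n`, within three standard
deviations of the corresponding sum of independent Bernoullis.

Counting is per physical read (mate), not per fragment; deduplication
keeps the first read per (reference, start, end, strand) key. Base
qualities are not used in counting by default. Reads with indels are
rejected rather than approximated.

## 3. Quantification, efficiency, hotspots

`aggregate_cpg()` tallies uppercase/lowercase calls per strand-resolved
cytosine; β = meth/(meth+unmeth); zero-coverage sites are omitted rather
than reported as 0. Watson/Crick CpG merging (onto the Watson C position)
is opt-in, since control-level comparisons are site-level.

Conversion efficiency on an unmethylated control pools all cytosine
contexts: `1 - Σmeth / Σ(meth+unmeth)`, with a normal-approximation
binomial CI. Site classes use strict inequalities: hypomethylated β < 1%,
hypermethylated β > 80%; a β exactly at a threshold is "intermediate"
(boundary convention, documented rather than meaningful).

Incomplete-conversion **hotspots** are CpGs on an unmethylated control
with β above a signal threshold (default 1%) supported by ≥ 1 CH site
with β above the same threshold within ±`window` bp. The source material
says only "adjacent"; the default window of ±50 bp (read-length scale) is
a design choice, configurable and reported in the output.

## 4. Marker selection and probe design

Differential screens use equal-variance two-sample t tests with
Benjamini–Hochberg FDR — the t test because the motivating analysis uses
Student's t throughout, BH as the standard FDR control; zero-variance
rows get p = 1 and a flag so they can never appear significant. Selection
keeps CpGs with Δβ > 0.2 (difference of group mean β; the directional
"hypermethylated in tumor" reading) at FDR < 0.05 whose linked gene has
log2FC < −1 at FDR < 0.05; the gene↔CpG map is an input table. The blood
filter removes a CpG when mean blood β exceeds mean tumor-tissue β by
more than 0.1. Candidates absent from the blood matrix are retained with
a warning (absence of evidence is not evidence of blood methylation).

Probe sets: a 120-bp window centered on the CpG (shifted to fit near
reference edges, with a message), plus four fully converted variants —
methylated/unmethylated × Watson/Crick. In-silico conversion under the
"CpG-methylated" assumption converts every C except C immediately
followed by G; under "unmethylated" every C. Crick variants apply the
same rules to the reverse complement. Two invariants pin the construction:
the methylated-Watson probe differs from the original exactly at non-CpG
C positions, the unmethylated-Watson probe exactly at all C positions.

## 5. The synthetic cohort

Each HCC sample carries a tumor fraction θ; its true marker level is the
mixture `(1 − θ)·β_background + θ·β_tumor`. Observed values are
beta-binomial draws at `depth = 800` reads per marker (the depth scale of
targeted capture at clinical input amounts) with overdispersion
`rho = 0.005`. Liver-disease samples get a background shift (+0.05 on a
random 20% of markers) so the HL model has something real to learn.
Class sizes default to the clinical split the package is patterned on
(training 195/54/168 normal/liver/HCC; test 84/22/73; 283 markers).

Stage-specific θ ranges — I: 0.5–3%, II: 1–6%, III–IV: 3–20% — are
implementer-chosen plausible values (no published tumor fractions exist
for this design) and are labelled as such; the qualitative consequence
(signal intensity increasing with stage) is what tests assert, not the
absolute numbers. Serology (AFP, PIVKA-II) is lognormal with class- and
θ-dependent location so that marker-negative HCC samples exist
(positivity cutoffs 20 and 40 ng/mL).

What the generator does **not** emulate: batch effects, age-related
methylation drift, sequence-context-dependent conversion failure,
capture-efficiency variation, fragment-level correlation between markers.
A green end-to-end test therefore establishes that the pipeline recovers
a planted mixture signal of stated size under stated noise — not that
the clinical AUC of any real assay is reproduced. The headline clinical
quantities (cohort AUCs, the 37/264/283 marker counts) depend on raw
data that is not available and are explicitly out of reach; the
acceptance suite substitutes property-based checks at desk scale.

Fragment lengths follow a Gaussian at 167 bp (sd 10) with optional 10-bp
sub-peaks below the mode (weights 0.035/0.02/0.01, sd 2 — about 20% of
the main-peak height, the scale seen in cfDNA size profiles). The profile
reporter estimates the modal length from a 5-bp moving average of the
1-bp histogram (a single noisy bin should not define the mode) and the
ladder spacing from the autocorrelation peak (lags 5–15) of the
sub-modal histogram detrended by an 11-bp moving average.

## 6. The stacked screening model

Layer 1 is a gradient-boosted decision tree classifier (Newton boosting
on logistic loss, exact greedy splits, no row/column subsampling — hence
fully deterministic), implemented in compiled code because no boosting
library is available in the target environment. Leaf weights are
`-G/(H + λ)` with λ = 1; split gain is the standard second-order
criterion; features are presorted once per fit and nodes scan membership,
keeping recursive feature elimination affordable.

* **HN** (HCC vs normal): features by recursive feature elimination with
  cross-validated AUC. The classical step of 1 feature per iteration is
  quadratic in feature count with CV at every step; the default
  eliminates 10% of remaining features per step (floor one feature),
  which preserves the shape of the method at tractable cost and is
  configurable back to step 1 (`rfe_step_frac`). Scanning from the full
  set down, the first (largest) feature set achieving the maximum CV AUC
  is kept.
* **HL** (HCC vs liver disease): features with importance (total split
  gain) > 0 after an initial fit.
* Hyperparameters per model by cross-validated grid search over a small
  implementer-chosen grid: trees {100, 300}, depth {2, 3}, learning rate
  {0.05, 0.1}; first maximum wins (deterministic tie-break).

The stacker is an L2-penalised logistic regression (IRLS, intercept
unpenalised) on **out-of-fold** layer-1 outputs: per CV fold, HN and HL
are refit without the fold (using the full-training-set feature
selections and hyperparameters) and predict the held-out fold. The
out-of-fold matrix is flagged, and `train_stack()` refuses unflagged
input — the leakage guard. Feature selection itself is performed once on
the full training split (the common, mildly optimistic practice); the
test split is never touched by any stage, which is what the test-set
metrics rely on. "Iterative" cross-validation is a single repetition by
default (`repeats`), with predictions averaged over repeats when larger.

The t-score is `h = w·(HN, HL) + b`. The decision threshold defaults to
the value maximising Youden's J on the training out-of-fold scores
(ties: highest threshold), because the motivating description never
states its operating point; h ≥ threshold is called HCC (boundary counts
as positive). The reported marker panel is the deduplicated union of HN
and HL features.

## 7. Metrics and numerical conventions

* Sensitivity TP/(TP+FN), specificity TN/(TN+FP); zero denominators give
  an explicit `NA` plus an `undefined` marker, never 0. Percent display
  rounds **half up** (`round_half_up()`), which reproduces published
  clinical tables; base R's round-half-even does not.
* Proportion CIs: `p ± 1.96·sqrt(p(1−p)/n)`, clipped to [0, 1].
* AUC is the Mann–Whitney rank statistic with midrank ties; its 95% CI
  uses the DeLong placement variance. Both are implemented in-package
  (no ROC library in the environment) and tested against exhaustive
  pair-counting and an independent placement computation.
* Group tests are equal-variance two-sided t; zero pooled variance is an
  error, not NaN.
* Coordinates are 0-based half-open internally and in BED/bedGraph;
  1-based in the cytosine report, matching the respective conventions.
* Model bundles serialize to versioned JSON with 17 significant digits,
  which round-trips IEEE doubles bit-exactly (15 digits provably does
  not: a tree threshold perturbed by one ulp can reroute a sample).
* The pipeline config is a single JSON file with a fixed key set;
  unknown keys are rejected. JSON rather than YAML because the target
  environment ships no YAML parser for R.

## 8. Degenerate inputs

Zero fragments → empty read set with a warning; zero reads → errors in
report functions (no silent zeros); no CH-containing reads → share
defined as 0 with a warning; empty subgroups → 0/0 with undefined
percent; constant layer-1 outputs → stacker weights shrink to ~0 and
prediction falls to the prior; single-class inputs error everywhere a
two-class quantity is requested.

## 9. Known limitations

Paired-end mate-overlap handling is reduced to a "first mate wins"
policy; indels are rejected rather than realigned; conversion failure is
context-independent (see §1); the cohort simulator's θ ranges and
serology models are plausibility choices, not estimates; the GBDT grid is
small by design and not tuned per dataset; hotspot support uses a fixed
window rather than a learned adjacency scale.
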