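---
title: "Methods: from exposure series to consensus kinase rankings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from exposure series to consensus kinase rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomeRank)
library(dplyr)
library(tibble)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, what the synthetic generator does and does not
emulate, and the places where the design was genuinely open.

## 1. The measurement model

A peptide kinome array reports, for every peptide spot, fluorescence
intensity at a handful of camera exposure times. Within a well-behaved spot
the intensity is affine in exposure time, so the package takes the
ordinary-least-squares slope of intensity on exposure (with intercept) as
the phosphorylation signal. The intercept is retained rather than forcing
the fit through the origin: residual background after washing shifts the
whole series without carrying kinase information, and an intercept absorbs
it. R² of that fit measures linearity.

Two failure modes are screened per sample:

* **nonlinear** spots (R² < 0.90): optical saturation or washing artifacts
  bend the series; the slope no longer summarizes it;
* **undetectable** spots (slope ≤ 0, or maximum intensity under a
  configurable floor, default 0): nothing to quantify.

A peptide must pass both screens in *every* sample of a comparison to be
retained — a per-sample rule rather than a pooled-fit rule, chosen because a
single saturated well already corrupts that replicate's ratio. Internal
controls are excluded from differential calling. Raising the R² threshold
can only shrink the retained set; the tests assert this monotonicity.

## 2. Fold changes and differential calls

Case and control samples are paired by replicate index (replicate *i* case
against replicate *i* control); the pairing is a convention — the replicates
are exchangeable in the generator — but fixing it keeps the arithmetic
reproducible. Per-replicate fold changes of slopes are averaged on the ratio
scale (arithmetic mean of FCs); a geometric alternative is exposed via
`average = "geometric"` in `compute_fold_change()` and is the variant under
which fc(case, control) · fc(control, case) = 1 holds exactly. A peptide is
differential when FC ≥ 1.30 or FC ≤ 0.70, both thresholds inclusive — a 30%
signal change in either direction. Peptides whose control slope is not
positive in some replicate are routed to the exclusion set rather than
raising an error: an undefined ratio is a data-quality fact, not a bug.

## 3. The resampling null

For each kinase family F with peptide set S(F) (the union over member
kinases — family-level scoring gives all members identical values), the
observed statistic is |differential ∩ S(F)|. The null asks: how many hits
would a *random* set of m differential peptides produce? Each of 3000
iterations draws m peptides uniformly **without replacement** from the
196-spot universe and records per-family hit counts; the empirical mean and
SD over iterations give Z = (obs − mean₀)/sd₀.

Numerical and edge choices:

* Sampling without replacement reflects that a differential set contains
  distinct peptides; the empirical moments then converge to the
  hypergeometric closed form, which the tests use as an independent oracle
  (means within 3 Monte-Carlo standard errors, SDs within 10% at 3000
  iterations).
* The universe defaults to all 196 spots including the 3 internal controls;
  `include_controls = FALSE` switches to the 193 assayable peptides. The
  choice barely moves k/N but is exposed because both readings are
  defensible.
* If sd₀ = 0 (e.g. m equals the universe size), Z is 0 when the observed
  count equals the null mean and the family is flagged `degenerate`
  otherwise, rather than producing an infinity.
* Directionality is the arithmetic mean log2FC of the family's differential
  peptides; families with no differential peptides get `NA` and are left
  unranked.
* The default significance annotation is |Z| ≥ 2, configurable; it is an
  annotation, not a filter.
* Family percentiles are computed from |mean log2FC| — the absolute value,
  so strong decreases rank as high as strong increases, mirroring the
  absolute-value rule the upstream-kinase-analysis adapter applies to its
  median final score.

The whole stage is bit-reproducible given the configuration seed; the
resampling is implemented as one membership-matrix cross-product per call,
so 3000 iterations over a 196-peptide universe cost milliseconds.

## 4. Inclusive percentiles and consensus averaging

Heterogeneous pipeline outputs are made comparable by converting each
pipeline's scores (oriented so larger = stronger evidence by the adapters:
absolute median final score; reciprocal of the FDR-scaled enrichment
statistic, with a +Inf sentinel for a zero denominator; −log10 of the
cutoff-then-database-averaged FDR) to **inclusive percentile ranks**: for n
values sorted ascending, the value at rank r gets 100·(r−1)/(n−1); ties
share the mean of their positional percentiles; a single value gets 100.
"Inclusive" is read as endpoint-inclusive — the extremes attain exactly 0
and 100, consistent with the 0% and 100% entries in the published tables the
package ships.

Two consensus statistics combine pipelines:

* **unweighted average** — mean over the pipelines that report the kinase;
  absence is "not reported", never zero;
* **weighted average** — sum of reported percentiles divided by the *total*
  number of pipelines. This is a deliberate re-interpretation: read
  literally, "dividing average percentile rankings by the number of
  pipelines" would shrink a complete four-pipeline consensus fourfold, which
  contradicts every published row where all pipelines report (there the
  printed weighted average equals the unweighted one). The sum/total form
  reproduces every published cell and equals the literal form only when one
  pipeline reports.

Group rankings (e.g. a patient-derived group of two cell lines) average each
kinase's per-cell-line percentiles within each pipeline over the lines where
it is reported, then combine as above. Recomputing from pooled raw scores
would be an alternative; percile-space averaging was chosen because raw
scores are not comparable across chips, while percentiles are.

Display rounding is round-half-to-even to integer percent (base `round()`),
the only convention consistent with all half-integral cells in the shipped
published tables (95.5→96 but 70.5→70). Full precision is kept in `_exact`
columns; ties in the top-10 tables are broken alphabetically by kinase id —
the published tables state their tie order was arbitrary, so exact tie
positions are not expected to match.

Feeding the published per-pipeline percentile columns back through this
arithmetic reproduces all 200 printed Average / Weighted Average cells to
within ±1 percentage point, and 174 exactly. The residual ±1 discrepancies
are expected: the printed inputs are themselves rounded to integer percent,
so a cell computed from unrounded percentiles can land on the other side of
a rounding boundary (e.g. two printed values averaging 93.5 against a
printed 93).

## 5. What the synthetic generator emulates

`simulate_run()` produces intensity series mimicking the study design:
196 peptides (3 internal controls), two conditions × 3 replicates, exposures
{10, 20, 50, 100, 200} ms. Per peptide, intensity(t) = slope·t + intercept +
N(0, noise_sd); differential activity is injected **multiplicatively on the
slope** (case slope = 2^effect_log2fc × control slope), because the slope is
the signal — so the fold change of slopes equals the spiked effect exactly
in the noise-free limit, which is what makes ground-truth recovery tests
sharp. Defaults, chosen once as realistic for a fluorescence-unit scale:
baseline slopes uniform in 1–3 units/ms (peak intensities of a few hundred
units at 200 ms) and noise_sd = 20 units — enough noise that per-sample R²
filtering actually trims peptides, not so much that triplicate fold changes
lose the 30% threshold.

Designated failure modes exercise the filters continuously: a *nonlinear*
fraction receives saturating signal a·(1 − e^(−t/τ)) with τ = 15 ms, which
yields OLS R² ≈ 0.50 on the standard exposure grid, safely below 0.90; an
*undetectable* fraction receives a small negative slope (−0.05 units/ms), an
exact line that fails detectability rather than linearity, keeping the two
exclusion channels separable in tests. Both designations are drawn only from
non-control peptides not mapped to any spiked kinase, so the spiked
ground-truth set remains exactly recoverable; internal controls always carry
condition-independent signal and are never mapped to kinases. Noise is
additive, Gaussian and homoscedastic across exposures — the simplest model
that makes R² a continuous filter.

What the generator does **not** emulate: spot segmentation and image
quantification (upstream of this package), chip-to-chip batch effects and
normalization, heteroscedastic or multiplicative noise, kinetic (pre-wash)
phases, and cross-reactivity between peptides beyond what the
kinase–peptide map encodes. Passing tests therefore demonstrate correctness
of the *analysis* under a clean additive-noise model, not robustness to
every artifact of real chips.

`simulate_pipeline_scores()` extends the same spiked truth to native-format
score tables for the three external pipelines (kinases in spiked families
get larger absolute scores / smaller FDR-type values; each pipeline covers a
random 80% of kinases, emulating differing database coverage). It emulates
the statistical *shape* of those outputs — orientation, FDR scale, partial
coverage — not the tools' algorithms, which are out of scope here; the
package only implements their published output transforms in the adapters.

## 6. Seeds and problem sizes

A single global seed drives everything; each stage derives a fixed substream
(`seed × 1009 + stage` modulo 2³¹) so that stages are decoupled — changing
the number of resampling iterations does not perturb the simulated
intensities. Identical configuration and seed give byte-identical output
files; the manifest records the seed and MD5 digests of everything written.

The shipped analyses use a 40-kinase, 16-family map on the full 196-peptide
chip with 3000 resampling iterations; the spiked-recovery study uses 100
simulated comparisons at effect log2FC = 1.5 on a family with ≥ 5 mapped
peptides and noise_sd = 20 — sizes at which the whole suite runs in a couple
of minutes on a laptop while keeping Monte-Carlo error well inside the
asserted tolerances.

## 7. Known limitations

* The kinase–peptide maps here are synthetic or file-based exports; the
  package deliberately performs no live database queries, so map quality is
  the caller's responsibility (and conflicting family assignments must be
  resolved in the supplied family table).
* Per-pipeline kinase scores from real external tools are accepted via
  adapters but cannot be validated internally beyond schema checks.
* The weighted average penalizes non-reporting pipelines without modelling
  *why* a kinase is absent (database coverage vs. true negative); treat
  weighted rankings as conservative, not probabilistic.
* Replicate pairing by index is arbitrary when replicates are unpaired in
  the lab; with three replicates the ratio-scale average is robust to the
  choice, but heavily unbalanced designs are out of scope.
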