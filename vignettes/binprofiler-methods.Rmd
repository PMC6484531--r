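---
title: "Negative-control binning profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-control binning profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binprofiler)
```

## The problem

High-content screens image hundreds of cells per well and extract hundreds
of morphological parameters per cell (intensities, shapes, textures,
Zernike moments, ...). Two things make this data hard to use directly for
compound profiling. First, well-level averaging throws away the population
structure: a compound that splits a unimodal cell population into a bimodal
one can leave the well mean almost unchanged while half the cells moved up
and half moved down. Second, many parameters are *noisy* — their
distribution drifts from well to well even among untreated (vehicle/DMSO)
wells — and such parameters dilute every downstream similarity computation.

`binprofiler` implements a subpopulation profiling pipeline that addresses
both issues using **negative controls only**:

1. **Quantile binning** (`bin_profile()`): per plate and parameter, the
   pooled DMSO cell values define k equal-occupancy quantile bins
   (k = 5 by default, cutoffs at the 20/40/60/80th percentiles). Every
   well's cells are counted into those bins; counts become percentages of
   the well population; percentages are z-scored against the mean and
   sample sd of the plate's DMSO well percentages. A distribution shift of
   any shape — including unimodal-to-bimodal — moves cells between bins
   and produces large |z| in the affected bins, prominently the two
   *extreme* bins (lowest and highest), because phenotypes push parameters
   down or up.
2. **Stability selection** (`stability()`): in a DMSO well, cells fall into
   the k bins like draws from an urn, so the bin counts are multinomial
   with equal proportions. A chi-square goodness-of-fit test per (control
   well, parameter), Bonferroni-adjusted, flags wells that deviate from
   equal occupancy. The fraction of control wells passing is a per-parameter
   stability score; a ladder of retention thresholds (0.01 to 0.96 in steps
   of 0.05 — 20 nested fingerprints, `stability_ladder()`) trades off
   parameter count against reliability, and `select_best_threshold()` picks
   the rung with the best leave-one-out classification accuracy (ties go to
   the sparser fingerprint). Crucially the selection never sees a treatment
   label, so it cannot overfit the known mechanism classes.
3. **L1 baseline** (`l1_scan()`): the classical supervised alternative — an
   L1-penalized logistic regression of mechanism-of-action (MoA) labels on
   the fingerprint, scanned over a fixed penalty ladder; features with all
   coefficients at zero are dropped. This selection is label-driven by
   construction, which is exactly what the package's held-out-class
   experiment (`holdout_class_experiment()`) probes.
4. **Classification** (`nn_loo_classify()`): cosine distance, 1-nearest
   neighbor, leave-one-out. The default exclusion removes all profiles of
   the query's own compound (not-same-compound), so replicates cannot vote
   for themselves; a query-only exclusion is available because the
   evaluation protocol is a genuine degree of freedom in this literature.

## Model and assumptions

Write $O_{w,p,b}$ for the number of cells of well $w$ falling into bin $b$
of parameter $p$, and $n_{w,p} = \sum_b O_{w,p,b}$. Under exchangeability
of control cells within a plate,

$$ (O_{w,p,1}, \dots, O_{w,p,k}) \sim \mathrm{Multinomial}(n_{w,p}, (1/k, \dots, 1/k)) $$

over the *instantiated* bins, and the test statistic is
$\chi^2 = \sum_b (O_b - E_b)^2/E_b$ with $E_b = n/k$ and $k - 1$ degrees of
freedom. The z-scores are computed on **percentages**, not raw counts, so
wells of different cell number are comparable; their baseline uses the
sample standard deviation (denominator $n-1$) across the plate's DMSO
wells, which makes the control z-population exactly mean 0 / sd 1 by
construction.

The chi-square approximation assumes expected counts that are not tiny;
with 5 bins and the default floor of 50 cells per well, $E_b \ge 10$.
Its power grows with the well population: a drift that 200 cells tolerate
may be flagged with 2000. The stability cutoff therefore has to be read
relative to the screen's cell counts, which is why the cutoff (0.05), the
bin count, the per-well cell floor and the ladder are all arguments, with
the defaults above.

## Tunable parameters

| argument | default | meaning |
|---|---|---|
| `k` | 5 | quantile bins per parameter (cutoffs at multiples of 100/k %) |
| `type` | 7 | quantile type (linear interpolation of order statistics) |
| `cutoff` | 0.05 | adjusted-p cutoff of the per-well stability test |
| `min_cells` | 50 | cells a well needs before it is tested/averaged |
| `thresholds` | 0.01..0.96 by 0.05 | stability retention ladder |
| `alphas` | 0.01, 0.05, 0.1, 0.5, 1, 2, 4, 6, 8, 10 | L1 penalty ladder |
| `exclude` | `same_treatment` | leave-one-out exclusion policy |

The L1 penalty `alpha` multiplies the L1 term of the per-sample-averaged
loss (equivalently `C = 1/alpha` in inverse-regularization conventions);
features are standardized before fitting and intercepts are unpenalized.
On standardized features the upper rungs of the ladder usually shrink every
coefficient to zero; such rungs are skipped with a warning rather than
treated as errors, since an empty fingerprint cannot be classified.

## Numerical choices and degenerate inputs

* **Interval convention.** Bins are half-open $[e_{i-1}, e_i)$ with the
  last bin closed above; a value exactly on a cutoff goes to the upper bin.
  Duplicated cutoffs (discrete parameters — a nuclei count that is almost
  always 1) create zero-width bins that receive no cells. A bin is
  *instantiated* when at least one pooled control cell occupies it; a
  constant parameter instantiates exactly one bin and is untestable
  (treated as unstable, never retained).
* **Renormalized expectation.** For parameters with $2 \le m < k$
  instantiated bins the multinomial expectation is uniform over the $m$
  instantiated bins with $m - 1$ degrees of freedom, so discrete-but-not-
  constant parameters remain testable.
* **Bonferroni family.** All (control well × testable parameter) tests of
  a plate form the family — the scope at which the tests are computed.
  `family = "none"` disables the adjustment.
* **Degenerate scales.** A parameter whose control percentiles coincide
  (linear scaling) or whose control well averages have zero sd (z-scoring)
  is set to missing on that plate with a warning; fingerprint assembly then
  drops every column containing a missing value, because cosine distances
  need complete vectors. Assembly fails loudly if nothing survives.
* **Ties in classification.** Exact distance ties are broken by the
  lexicographically smaller candidate id, making the report independent of
  profile order. Queries with no candidates (e.g. a compound that owns all
  other profiles under the not-same-compound rule) are reported as
  unclassifiable and excluded from the accuracy denominator, not silently
  dropped.

## The synthetic screen generator

`generate_screen()` emulates the data regimes the pipeline must handle,
with a ground-truth role for every parameter:

* **stable uninformative** — i.i.d. per plate from a fixed
  location/scale normal (or log-normal, since real morphology features are
  skewed and the method is distribution-agnostic);
* **stable informative** — shifted in treated wells by `effect_size`
  baseline sd, either *translated* or *bimodally split* (exactly half the
  cells up, half down, so the well mean stays put while the extreme bins
  fill — the subpopulation phenotype that motivates binning);
* **noisy** — an independent per-well offset with sd `noise_drift_sd`
  (default 0.5 baseline sd);
* **degenerate** — the value 1 for ≥ 99% of cells.

The defaults describe the study conditions used throughout the tests and
the acceptance script: 2 plates × 40 wells (20 DMSO each), 500 cells per
well (Poisson-dispersed), 100 parameters with 20 noisy and 5 degenerate,
3 MoA classes × 2 compounds × 3 replicate wells, effect size 2 sd, half of
each 5-parameter signature bimodal. Class signatures are drawn *disjointly*
from the stable pool, so every class owns private informative parameters —
the structure needed to demonstrate the generalization contrast: a
held-out class's private parameters carry no signal for the remaining
labels, so the L1 selection drops them, while the control-based stability
selection keeps them (they are perfectly control-stable). Problem sizes in
the test suite are scaled-down variants of the same design (typically
2 plates × 16 wells × 200 cells × 30 parameters), chosen so the planted
effects remain comfortably detectable at those counts.

What the generator does **not** emulate: correlation structure between
parameters (real morphology features are heavily correlated), spatial
plate effects (edge wells, gradients), segmentation artifacts, and
dose-response structure (every compound appears at one concentration).
Passing tests therefore demonstrate the statistical machinery — not that
any particular real screen will classify at the accuracies the synthetic
benchmark reaches, which are near-perfect by design at the default effect
sizes.

## A worked example

`generate_worked_example()` builds a fully deterministic 2-plate table
(no random numbers) whose binning outcome is known by construction: a
permuted 1..100 parameter bins into exactly 20 cells per bin everywhere
(chi-square 0), a planted +1 sd drift in control well D6 yields a
chi-square of 61.1 and survives Bonferroni, and a ±2 bimodal split in a
treated well produces extreme-bin z-scores above 35 while the middle bins
collapse. These values are frozen (computed by explicit counting and the
closed-form chi-square tail) in `inst/extdata/worked_example_golden.csv`
and checked against the pipeline in the test suite.

```{r example, eval = FALSE}
scr <- generate_screen(synthetic_config(seed = 1))
bp  <- bin_profile(scr$cells)                 # quantile binning + z-scores
st  <- stability(bp)                          # control-only stability test
lad <- stability_ladder(st)                   # 20 nested fingerprints
sel <- select_best_threshold(lad, bp, mode = "extreme_bins")
fm  <- assemble_fingerprints(bp, "extreme_bins", parameters = sel$retained)
nn_loo_classify(fm)                           # cosine 1-NN, leave-one-out
```

## Open design choices, resolved

* **Leave-one-out scope.** Whether historical MoA benchmarks excluded only
  the query or all replicates of its compound is ambiguous; we default to
  the stricter not-same-compound rule and expose `exclude = "self"`.
* **Binning of unnormalized data.** Quantile binning is invariant under
  strictly increasing per-plate transforms, so binned statistics need no
  prior normalization; the linear-percentile and z-score schemes are
  provided for the well-average profiles, where scale does matter.
* **Bin features.** Fingerprints use bin z-scores (not raw percentages):
  z-scores put every (parameter, bin) on the control-dispersion scale,
  which is what cosine similarity should weigh.
* **Multiclass L1.** One-vs-rest binomial fits are the default (the
  historical default of widely used solvers), softmax is available via
  `scheme = "multinomial"`.

## Known limitations

* The equal-occupancy expectation is exact only if control cells are
  exchangeable within a plate; systematic within-plate gradients would
  inflate the noisy classification (arguably correctly so).
* The chi-square test's power depends on the cell count per well, so
  stability fractions are comparable across screens only at similar
  population sizes.
* With very few control wells the percentage baseline sd is itself noisy;
  at least ~8 DMSO wells per plate are advisable (the defaults use 20).
* `best_alpha()`/`select_best_threshold()` evaluate accuracy on the same
  profiles used for selection (matching the original protocol); the
  held-out-class experiment is the guard against the optimism this invites.
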