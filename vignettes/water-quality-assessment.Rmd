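---
title: "Assessing river water quality with weighted grey relational selection and a PSO-tuned multiclass SVM"
author: "aquassess authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing river water quality with weighted grey relational selection and a PSO-tuned multiclass SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Routine river monitoring produces, per sampling event, a handful of
physico-chemical indicators: dissolved oxygen (DO, mg/L), temperature
(°C), turbidity (NTU), ammonia nitrogen (NH3-N, mg/L), permanganate index
(CODMn, mg/L), pH and total dissolved solids (TDS, mg/L). Under the
GB3838-2002 surface-water standard each sample belongs to one of six
ordered quality categories — I (best) through V plus "poor V" — defined by
per-class limits on the band-carrying indicators. Two questions arise in
practice: *which indicators carry the information about the quality class*,
and *how to predict the class of new samples accurately* from those
indicators. `aquassess` answers the first with a weighted grey relational
analysis and the second with a one-vs-one multiclass SVM whose kernel
hyperparameters are tuned by particle swarm optimization.

## Stage 1: weighted grey relational selection

Write $x_0(i)$ for the (ordinal, 1–6) class of sample $i$ and $x_j(i)$ for
indicator $j$. After min–max normalization of every series to $[0,1]$,
the grey relational coefficient between indicator $j$ and the class series
at sample $i$ is

$$ s_j(i) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_j(i) + \rho\,\Delta_{\max}}, \qquad
   \Delta_j(i) = |x_0(i) - x_j'(i)|, $$

with $\Delta_{\min}, \Delta_{\max}$ the global extremes of the difference
matrix over all samples *and* indicators and $\rho = 0.5$ the conventional
distinguishing coefficient. The per-indicator degree is then weighted by a
combined indicator weight $\omega_j$:

$$ r(j) = \omega_j \cdot \frac1m \sum_{i=1}^m s_j(i), \qquad
   \omega_j = \frac{\alpha_j + \beta_j}{\sum_l (\alpha_l + \beta_l)}, $$

where $\alpha$ are subjective AHP weights (row sums of a reciprocal 1–9
pairwise comparison matrix, with a Saaty consistency-ratio check) and
$\beta$ are objective CRITIC weights
$\beta_j \propto \sigma_j \sum_l (1 - r_{jl})$ built from each normalized
column's dispersion and its conflict (one minus Pearson correlation) with
the other indicators. Indicators are ranked by $r(j)$ and the top $q$
(default 4) become the classifier's inputs.

```{r}
library(aquassess)
d <- generate_water_data(synth_config(n_per_class = 100, seed = 1))
select_features(d[c(indicator_ranges()$indicator, "label")], q = 4)
```

### Design choices in this stage

* **Coefficient denominator.** The classical coefficient uses
  $\Delta_j(i) + \rho\Delta_{\max}$; a variant sometimes seen in print
  drops $\rho$ from the denominator. The classical form is the default;
  the variant is available as
  `grey_config(denominator_form = "literal")`. With $\rho = 0.5$ and the
  default form every coefficient lies in $[1/3, 1]$.
* **Scope of the extremes.** $\Delta_{\min}/\Delta_{\max}$ are taken
  globally over the whole difference matrix (the two-level min/max of
  classical grey relational analysis), not per indicator; a per-indicator
  scope would rescale every column to the same effective range and erase
  most of the between-indicator contrast the degree is meant to measure.
* **Severity orientation.** The coefficient measures *proximity*, not
  association: an indicator perfectly anti-tracking the class series gets
  a *low* degree. DO is the one indicator whose severity direction is
  reversed (high DO = good water), so its normalized series is flipped
  ($x' \mapsto 1 - x'$) before the comparison — the standard cost/benefit
  preprocessing of grey relational analysis. Directions are recorded in
  `water_schema()` and can be overridden per column.
* **Reference normalization.** The class series is itself min–max
  normalized before differencing (disable with
  `grey_config(normalize_reference = FALSE)`); mixing a 1–6 integer
  reference with $[0,1]$ indicator series would let the reference's scale
  dominate every difference.
* **Defaults.** The subjective comparison matrix defaults to all ones
  (equal subjective weights), making the subjective half neutral unless
  the analyst supplies domain judgments; $q$ defaults to 4; ranking ties
  are broken by original column order, so results are deterministic.

### What the combined weighting does — and does not — do

A property worth understanding before trusting any weighted relational
ranking: the CRITIC half *rewards indicators that disagree with the
others*. On data where a subset of indicators jointly drives the class
(and is therefore mutually correlated), those informative indicators
receive *smaller* objective weights than independent noise columns —
the conflict term $\sum_l (1 - r_{jl})$ is largest for columns correlated
with nothing. On the package's band-structured synthetic data this effect
is strong enough to overturn the unweighted ranking: the plain
(equal-weight) relational degree ranks the four band-carrying indicators
first in essentially every draw, while the combined-weight degree
promotes the label-independent indicators instead. The acceptance suite
asserts the informative-recovery property at its stated conditions and
documents the measured outcome rather than adjusting the method; users
selecting features for *prediction* should compare the weighted ranking
against the equal-weight one (set the comparison matrix to all ones and
read `mean_s` in the ranking table) before committing to either.

## Stage 2: PSO-tuned one-vs-one SVM

For $k$ classes, $k(k-1)/2$ soft-margin binary SVMs are trained, one per
unordered class pair, on min–max-scaled features whose scaling parameters
are fitted on the training split only. Prediction is by majority vote;
vote ties are broken by the largest sum of signed decision values among
the tied classes, then by the lowest class id — a deterministic rule that
also settles full voting cycles. Kernels follow the usual forms: linear
$(x \cdot y)$, RBF $\exp(-\lVert x-y\rVert^2 / r^2)$ (note the *width*
parameterization: backends expressed in $\gamma$ use $\gamma = 1/r^2$),
polynomial $((x \cdot y) + 1)^d$. The binary quadratic programs are solved
by `e1071` (libsvm); the OVO assembly, scaling, voting and tuning are the
package's own.

Hyperparameters are tuned by a bounded particle swarm: positions are
$(\log_{10} C, \log_{10} r)$ (degree for the polynomial kernel), the
objective is the stratified 5-fold cross-validated error rate on the
training split, and the velocity update uses cognitive/social factors
$c_1 = 1.6 < c_2 = 2.0$ (a notice is logged if a user sets $c_1 > c_2$,
which biases particles toward local search) and a linearly decreasing
inertia weight

$$ \omega(t) = 0.9 - 0.4\,t/T_{\max}, $$

from exploratory 0.9 down to convergent 0.5. Default budgets are 300
particles and 300 iterations for standalone optimization; the pipeline
default is 50 × 50, which reaches the same optima on these 1–2
dimensional search boxes in a fraction of the time.

Numerical hygiene not fixed by the update equations themselves:
velocities are initialized uniformly within ±10% of the box width and
clamped to half the box width; positions are clipped to the box with the
offending velocity component zeroed; the run stops early when the global
best improves by less than `tol` over a 20-iteration patience window
(the iteration cap is the other stopping rule). Minimization is the
canonical direction; maximize by negating the objective. All randomness
flows through a single seed, and identical (objective, config, seed)
triples give bit-identical trajectories.

## Evaluation

`evaluate_classification()` reports accuracy (total true predictions over
samples), per-class precision $TP/(TP+FP)$ and recall $TP/(TP+FN)$ with
macro averages as the headline (micro averages, which coincide with
accuracy here, are also emitted), and RMSE computed on the ordinal class
encoding I→1 … poor V→6 — the only encoding consistent with the severity
order, and the reason a one-class error always contributes exactly 1.
Macro averaging was chosen because class balance matters in this domain
and micro precision would merely duplicate accuracy. A class that is
never predicted gets precision 0 with a logged note; classes absent from
both vectors are excluded from the macro averages.

## The synthetic generator

Real national monitoring data of this kind is not redistributable, so
`generate_water_data()` emulates its structure: for each requested class
$c$, the informative indicators (default: the four band-carrying ones —
DO, NH3-N, CODMn, TDS) are drawn *uniformly inside their class-$c$ band*
(DO in $[\ell_c, \ell_{c-1})$, upper-limited indicators in
$(\ell_{c-1}, \ell_c]$, class 6 beyond the class-V limit), capped at the
observed indicator ranges; the remaining indicators are label-independent
uniform noise over their full ranges. Uniform-within-band sampling (rather
than something more realistic like lognormal mixtures) is a deliberate
trade: it makes the generated label *provably* equal to the single-factor
classification of the sample, which is what lets the test suite assert
exact label recovery. Two quirks are handled explicitly:

* the standard's TDS limits coincide for classes IV and V and exceed the
  observed TDS maximum, so the high-class TDS bands are empty under the
  range cap; the generator then falls back to the highest feasible lower
  band, which cannot raise the sample's class since the other informative
  indicators attain the requested one;
* with `nonlinear = TRUE`, temperature and turbidity are replaced by
  points on class-indexed annuli (common centre, radius growing with
  class position) — a radially separable geometry that defeats a linear
  kernel and exercises the RBF path.

What the generator does *not* emulate: seasonal/temporal autocorrelation,
station-level spatial structure, measurement error (unless `noise_sd > 0`
is set, which adds Gaussian jitter after labelling and deliberately
breaks exact label consistency), correlated noise indicators, and class
imbalance. Tests passing on this generator therefore demonstrate the
correctness of the algorithms under clean class-band structure, not
performance on real monitoring data.

## The pipeline

`run_pipeline()` executes: cleaning (row-wise deletion of incomplete
records, with a logged count — no imputation), a stratified 80/20
train/test split, indicator selection **on the training split only**,
scaling fitted on the training split, PSO tuning, OVO training, and
evaluation on the held-out split. The selection-before-split ordering
sometimes drawn in workflow diagrams is available behind
`select_on_all = TRUE` for comparison, but the default avoids test
leakage; a dedicated test perturbs held-out rows and asserts that
selection and tuned hyperparameters are unchanged. Every run can write a
manifest recording all resolved settings and derived seeds
(split = seed, tuner = seed + 1, CV folds = seed + 2);
`run_from_manifest()` reproduces all artifacts byte-identically. Reports
are plain CSV; numbers are printed at full double precision so byte
identity is meaningful.

## Degenerate inputs and edge rules

* Constant indicator columns cannot be normalized (no scale) and raise a
  degenerate-column error naming the column.
* A comparison matrix must be reciprocal, positive and on the 1–9 scale;
  a consistency ratio above 0.1 warns but does not stop the run.
* All-pairwise-correlation-1 data defeats CRITIC (zero information in
  every column) and errors rather than returning 0/0.
* Grey coefficients where every series equals the reference
  ($\Delta_{\max}=0$) are 1 by convention.
* A decision value of exactly 0 in a binary vote counts for the pair's
  first (lower-id) class, keeping the vote deterministic.
* Cross-validation folds whose training part degenerates to one class are
  skipped with a note; tuning fails only if every fold degenerates.

## Problem sizes used by the checks

The shipped test-suite and acceptance script exercise: weighting
identities on 30 random 200 × 7 datasets; feature recovery on 20 draws of
600 banded samples; the sphere benchmark at the full 300 × 300 swarm
budget over 10 seeds; 200 randomized voting tables against a brute-force
oracle; kernel ordering and the full tuned pipeline on 600 samples with a
50 × 50 swarm; and byte-identity of two manifest-driven runs. These sizes
were chosen as the smallest at which each property is statistically
unambiguous.

## Known limitations

* The combined weighting's conflict term penalizes mutually correlated
  informative indicators (discussed above); the weighted ranking is a
  relevance *diagnostic*, not a guaranteed predictor-selection rule.
* Turbidity and pH never influence the standard class (the standard gives
  them single advisory limits, not class bands), so they can only enter
  the model as covariates, never as labelling indicators.
* RMSE on ordinal encodings treats adjacent classes as equidistant.
* The PSO objective is a CV *error rate*, hence piecewise constant in the
  hyperparameters; the patience rule, not the tolerance, usually ends the
  run.
* Single-factor classification takes the worst indicator; it is
  deliberately conservative and not a composite quality index.
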