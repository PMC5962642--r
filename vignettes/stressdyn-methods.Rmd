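---
title: "Models and methods behind stressdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stressdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stressdyn)
```

stressdyn analyses time-resolved high-content imaging screens of
fluorescent stress-response reporter cell lines.  Four HepG2 reporter
lines are modelled — SRXN1 (Nrf2 oxidative-stress pathway), CHOP (ER
stress / unfolded protein response), P21 (p53 / DNA damage) and ICAM1
(NF-kB inflammatory signalling) — each exposed to a panel of drugs at 1,
5, 10, 50 and 100 multiples of the drug's peak plasma concentration
(C-max), imaged hourly for 24 h with a propidium-iodide (PI) viability
stain at the final frame.  The pipeline turns per-cell feature tables
into well-level descriptor time courses, tests and clusters those
courses, extracts benchmark concentrations (BMC) from fitted
concentration-response curves, and classifies drugs as severe versus
non-severe for drug-induced liver injury (DILI).

This vignette documents the models, the tunable parameters, and the
design decisions taken where the design was genuinely open.

## Compound annotation

The packaged table (`read_compound_table()`) carries 123 compounds: 118
drugs with FDA DILI-concern labels (16 no-concern, 12 ambiguous, 36
less-severe, 54 most-severe) and 5 reference treatments (DMSO, TNFa,
etoposide, thapsigargin, diethyl maleate).  The binary severity used by
the classifier groups most-severe-concern drugs as `severe` and all
other annotated drugs as `non_severe`.  C-max values are stored in
micromolar exactly as transcribed; they range from 0.002 uM
(epinephrine) to 940 uM (betaine, 0.94 mM).  Compounds without a
tabulated hepatotoxicity class (e.g. cyclosporin A) keep their severity
label with a missing class rather than a zero.

## The synthetic screen generator

The deposited image-derived data of the original screen is not bundled;
instead `simulate_screen()` generates per-cell records with the
statistical structure the downstream analysis assumes, so every stage is
testable with known ground truth.

Per compound and reporter, effect parameters are drawn once
(`draw_compound_params()`):

* the true point of departure `bmc_true` (in C-max multiples) is
  log10-normal with class-dependent mean — 0.9 for severe, 1.6 for
  non-severe DILI compounds, sd 0.4, truncated to [0, 2.3] (the tested
  decade range).  Severe compounds therefore activate reporters at
  lower C-max-normalised concentrations, the central class effect the
  dose-response statistics and the classifier are meant to detect.
* responsiveness per reporter is Bernoulli with class-dependent
  probability (defaults 0.8 severe / 0.45 non-severe); the plateau
  `emax` is uniform on [0.5, 0.9], the Hill coefficient uniform on
  [1.2, 3], induction half-time uniform on [6, 14] h and onset rate
  uniform on [0.4, 1] per hour.  These ranges were chosen once as
  typical of live-cell reporter induction kinetics over a 24 h window.
* cytotoxicity: with class-dependent probability (0.6 / 0.3) a compound
  has a finite death-threshold concentration (log10-normal, mean 1.2 /
  1.7, sd 0.3); above it, cells die with hazard
  `0.1 * log10(conc / threshold)` per hour.

The population mean scaled response of a treated well is

    m(t, x) = emax * x^h / (x^h + bmc_true^h) * 1 / (1 + exp(-r (t - t50)))

a Hill occupancy in concentration times a logistic onset in time.  At
`x = bmc_true` the Hill term is exactly 1/2, so with `emax = 0.8` the
late-time response is 0.4 — a convenient analytic anchor used by the
tests.  Per-cell GFP is `baseline * (1 + gain * m)` with multiplicative
lognormal noise (CV 0.3 by default; the same noise model makes the
control-well positive fractions analytically predictable as lognormal
tail masses).

ICAM1 wells follow the TNFa control ramp `r(t) = A t / (t + tau)`
multiplied by `1 + (icam_multiplier - 1) * Hill(x)`: a multiplier below
1 suppresses and above 1 enhances the TNFa-induced response, with the
same Hill-type concentration dependence as induction, so ICAM1
concentration-response curves and BMCs are exercisable.  A multiplier
of exactly 1 reproduces the control ramp, which is how the
null-calibration tests are built.  ICAM1 plates carry TNFa + DMSO
control wells (`control_kind = "TNFa_DMSO"`), the other reporters plain
DMSO, matching the screen's background definitions.

Dead cells stop moving, shrink (x 0.7), condense their Hoechst signal
(x 1.4) and receive a PI overlap of at least 10% of their nuclear area
at the final frame; live cells stay below 5%.  The population grows at
0.02 per hour, reduced under toxicity, and positions follow a random
walk whose step shrinks with the death hazard — this is what gives the
cell-count, nuclear-size, Hoechst and speed slopes their signal.

The defaults emulate the screen design (one reporter and one
concentration per plate, at least two replicates, hourly frames 0-24 h,
PI only at the final frame).  Cells are seeded at 8000 per well in the
modelled experiment; the generator's default `n_cells_0 = 200` (and
smaller in the test suite) is a deliberate scale-down — cell-level
noise averages out quickly in well-level summaries, so the well
descriptor distributions are preserved while keeping tables small.
What the generator does *not* emulate: segmentation artefacts, spatial
well-position effects, plate drift, compound metabolism and
reporter-specific baseline differences.  Passing tests therefore show
the analysis machinery is correct and calibrated, not that real-screen
effect sizes will match.

One master seed drives everything; plates use substreams
`seed + plate_index` so individual plates are independently
reproducible, and compound draws use a disjoint substream offset.

## Well-level descriptors

Backgrounds are computed per plate and timepoint from that plate's
control wells: mean and sd of GFP for the positive-fraction thresholds,
and linear-interpolation quartiles (the standard type-7 convention —
the modelled method names only "IQR") for the ICAM1 fences.  If a
timepoint lacks controls the nearest control timepoint on the same
plate is used; thresholds always use the matched timepoint, not a
time-pooled mean.

Descriptors per well and timepoint:

* `frac_2m`, `frac_3m`: fraction of cells above 2x / 3x the control
  mean; `frac_m3sd`: above mean + 3 sd (SRXN1 / CHOP / P21).
* `icam_up_k` / `icam_down_k` / `icam_diff_k` for k in 1.5, 2, 3:
  fractions outside the TNFa control IQR fences `Q3 + k IQR` /
  `Q1 - k IQR`, and their difference (ICAM1; fences because the ICAM1
  intensity distribution is skewed).
* `intensity_mean`: the population mean GFP.

A cell is dead when PI overlap is at least 10% of nuclear area
(boundary inclusive — "at least").  The PI-positive fraction is
control-subtracted and may be negative.  Cytotoxicity slopes
(cell count as a fraction of the initial count, mean speed from
consecutive positions, nuclear area, Hoechst intensity) are ordinary
least-squares slopes per well, averaged over plates.

Intensity descriptors are min-max scaled to [0, 1] with extremes taken
per descriptor x reporter across all compounds, concentrations and
timepoints within a replicate; fractions are already on a fixed scale
and bypass scaling.  The replicate-wide scope is one reading of the
scaling formula's "replicate" subscript; a per-plate scope is available
behind `scope = "plate"`.  The ICAM1 mean intensity is scaled to
[-1, 1] by mapping the TNFa control trajectory to 0 and the largest
absolute departure from it within the replicate to +/-1 — the target
range is specified by the method, this particular map is the package's
choice.

## Time-course statistics

For condensation, a natural cubic spline with 8 degrees of freedom is
fitted per replicate and evaluated on 24 equidistant timepoints, then
replicates are averaged pointwise.  Splines reproduce constants and
linear courses exactly, which the tests exploit.

For significance testing, each course is linearly interpolated to 100
equidistant points and compared to the pooled control-well courses of
the same reporter with a permutation functional ANOVA.  The statistic
is the grid-mean of the squared group-mean difference divided by the
pooled pointwise variance; induction reporters are tested one-sided for
upregulation by zeroing negative pointwise differences, ICAM1
two-sided.  The permutation null is exhaustive whenever the number of
distinct group assignments does not exceed `n_perm` (default 1999),
otherwise `n_perm` random permutations with the observed assignment
included — this keeps the p-value exact for the replicate counts the
screen actually has.  Control wells from all plates of a reporter are
pooled as the comparison group to enlarge the permutation space, since
two or three replicates alone would make the permutation granularity
useless.  Benjamini-Hochberg correction is applied across tests with a
q < 0.01 significance flag.

Multi-reporter clustering concatenates each compound's condensed
courses over the five concentrations (compound-level items; a
per-compound-and-concentration alternative would cluster exposures
instead), computes the pairwise Manhattan (L1) distance per reporter,
averages the distance matrices over reporters (pairwise-complete when a
compound misses a reporter), and clusters with Ward linkage
(`hclust(method = "ward.D2")`).  Leaf order follows the dendrogram; no
optimal-leaf reordering.  The dendrogram is exported in Newick form.

## Concentration response and BMC

The maximum over time of each scaled descriptor course (signed extreme
for ICAM1 difference descriptors, so suppression registers) is
summarised per replicate, replicate means are fitted against the five
tested concentrations with a four-parameter log-logistic curve

    f(x) = c + (d - c) / (1 + exp(b (log x - log e)))

by bounded multi-start least squares (Levenberg-Marquardt with an
L-BFGS-B fallback; asymptotes bounded to the descriptor's range widened
by half its span, because a fitted plateau may legitimately extrapolate
beyond the observed scaling range when the scaled maximum is set by a
stronger responder; inflection bounded within two decades of the tested
range).  The parameterization is mirror-symmetric — `(b, c, d)` and
`(-b, d, c)` describe the same curve — so fits are canonicalized to
`c <= d`.  Constant
responses return a degenerate fit flagged unidentifiable rather than an
error.

The BMC is the concentration at which the *fitted* curve departs from
its low-concentration asymptote by +0.25 (-0.25 for ICAM1 suppression),
solved in closed form by inverting the log-logistic.  Reading the
"initial response" as the fitted asymptote rather than the observed
response at 1x C-max makes the BMC a property of the curve and robust
to single-point noise.  A result is censored — never extrapolated —
when the plateau falls short of |0.25|, the departure has the wrong
sign, or the solution leaves the tested range [1, 100] x C-max.  For
ICAM1 both departures are tried and the more potent uncensored one is
the headline BMC, with both retained.

Because concentrations are expressed in C-max multiples, the BMC in
those units *is* the C-max-normalised BMC; the absolute BMC in uM is
obtained by multiplying with C-max.  Class statistics: a Welch t-test
on log10(BMC/C-max) between severity classes (the log transform matches
the decade-scaled axes on which these ratios are analysed; it is a
package decision), and a nested linear-model F-test of
`log10(BMC) ~ log10(C-max)` against `+ severity`.  The method
description's phrasing ("a linear model with the BMC and C-max as
explanatory variables") reads BMC as a predictor of itself; it is
implemented here as log-BMC response with log-C-max covariate, the only
reading that makes the nested comparison well-defined.

## DILI severity classification

The feature matrix holds, per compound: for each reporter x descriptor
(headline fraction and mean intensity) x concentration, five condensed-
course features (maximum magnitude, time of maximum, trapezoid AUC,
early 0-8 h and late 8-24 h OLS slopes); per concentration the
cytotoxicity summaries (with the TNFa-background cell death from ICAM1
plates kept separate); per reporter the log10 BMC/C-max and log10
absolute BMC with censored values imputed at the maximum tested
concentration plus a censoring indicator (censoring is informative,
not silent); and log10 C-max.  The modelled analysis reports 273
features from its in-house extractor, whose exact composition is not
recoverable; this catalogue covers every named feature family and the
realized count is written to a manifest rather than forced to 273.

Each of the `n_iter` (default 200) iterations draws a class-stratified
80/20 train/test split and, on the training set only: a two-sample
Kolmogorov-Smirnov test per feature (retain p < 0.05; the alpha is
unstated in the modelled method and exposed in `svm_config()`), a
greedy pairwise correlation filter in order of ascending KS p (drop at
|r| > 0.8, strict), and an RBF-kernel SVM tuned over a small
cost x width grid with 10 repeats of 10-fold stratified
cross-validation scored by pooled out-of-fold ROC-AUC (ties toward the
smaller cost, then width).  The kernel is unspecified in the modelled
method; RBF is the standard choice for a tuned SVM on dense tabular
features.  The SVM is unweighted by default (the modelled
sensitivity/specificity balance suggests no class weighting), with
weights switchable.  Test-set metrics use severe as the positive class;
the reported AUC is the mean of per-iteration test AUCs, not pooled
scores.  Features selected in more than 150 of 200 iterations (strict,
scaled as 0.75 x n_iter) form the stable set; per-compound
correct-prediction fractions are accumulated over test appearances.

AUC is computed internally via the Mann-Whitney identity and
cross-checked against an independent ROC implementation in the tests.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) throughout.
* Min-max scaling of a constant series returns zeros with a warning.
* `fit_4pl` multi-starts 18 initialisations; `rss` ties resolve to the
  first best.  Noiseless 5-point curves are recovered to 1e-3.
* Permutation p-values use a `>=` comparison with a 1e-12 slack so
  exact ties count as extreme.
* The truncated-normal draws use inverse-CDF sampling; their analytic
  means (used as test oracles) come from the standard closed form.
* `ks.test` warnings about ties are expected on fraction-valued
  features and suppressed; the test remains a valid selection
  heuristic.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run scaled-down screens —
typically 6-60 compounds, 2 replicates, 25-60 cells seeded per well,
50 classifier iterations — chosen so the full pipeline is exercised
end-to-end with comfortable statistical margins (e.g. the separable
classifier harness reaches AUC 1.0, far above the 0.95 assertion).
The class-shift, noise and kinetic defaults above are never altered by
the tests; only problem sizes are.

## Known limitations

* The generator draws reporter effects independently per reporter;
  real compounds co-activate pathways, so cross-reporter feature
  correlation structure is optimistic in synthetic data.
* Headline real-screen performance numbers (mean ROC about 0.73)
  depend on the deposited image-derived data and are out of scope; the
  classifier harness demonstrates correctness and calibration, not
  real-data effect sizes.
* The functional ANOVA is a permutation test of an integrated
  standardized mean difference — the same family as basis-expansion
  functional ANOVA methods, but not a reimplementation of any specific
  one.
* No benchmark-dose confidence intervals; BMCs are point estimates, as
  in the modelled analysis.
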