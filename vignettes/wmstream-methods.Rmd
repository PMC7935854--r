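---
title: "Methods: decision-weight mapping and memory-perception crosstalk"
author: "wmstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-weight mapping and memory-perception crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmstream)
```

## The task and the data

`wmstream` analyzes a dual-task psychophysics paradigm. On each trial the
observer memorizes a single colored dot (blue or red) presented at a random
angle on an invisible circle of 3.8 degrees radius around fixation, then
watches a stream of six displays, each containing 20 dots (0.3 degrees
diameter) inside a circular area of 10.6 degrees diameter, and judges whether
the stream contained more blue or red dots overall. Finally the observer
reproduces the memorized dot's color and location. The blue-minus-red count
of each display is drawn from a normal distribution with SD 10 truncated at
one SD around a per-trial mean of +4 or -4, rounded to the even grid the
20-dot display can realize -- eleven levels at even offsets -10..+10 around
the mean. Two control conditions either omit the memory task entirely
("control1") or move it before the stream ("control2").

The unit of data is a tidy trial table (one row per trial: condition, memory
sample color and angle, the six signed counts, choice, recall) plus a long
dot table (trial, display, x, y, signed color). Everything downstream is a
function of these two tables.

## Pixel-wise decision-weight maps

The central quantity is a spatiotemporal map of decision weight obtained by
reverse correlation. Each display is rasterized into a signed pseudo-color
image (blue +1, black 0, red -1) on a G x G grid in which the display circle
is inscribed (the reference grid is 401 pixels; any G is proportionally
equivalent) and smoothed with a unit-sum separable Gaussian kernel. At every
pixel, choices are regressed on the pixel's six per-display values:

$$P(\mathrm{blue}) = L\Big(\beta_0 + \sum_{k=1}^{6}\beta_{x,y,k}\,c_{x,y,k}\Big),$$

fit independently per pixel by ridge-penalized maximum likelihood
(RcppArmadillo IRLS with step-halving; penalty on slopes only). The slope
stack is the map M. A spatially blind psychometric model (below) supplies an
unbiased-observer map M*: the per-pixel regressions are refit with responses
derived from the model's predicted probabilities, and M - M* isolates
regional over- and underweighting. Group inference is a per-pixel one-sample
t-test across subjects with Benjamini-Hochberg FDR correction over in-mask
pixels.

Numerical choices worth knowing:

* **Kernel.** The smoothing support is 20 pixels on the 401 grid, scaled
  proportionally to G and forced odd; sigma is width/4 (so 5 px at the
  reference size), truncated to the support and renormalized. Smoothing
  precedes circular masking. The support convention (+-2 sigma) is the
  common image-processing default; the pipeline exposes `kernel_width`
  for sensitivity checks.
* **Ridge.** The default penalty is 1e-3 on slopes, never on the intercept.
  It exists because near the mask edge predictors are almost constant and
  unpenalized slopes diverge on separable pixels (the divergence is
  monotone as the ridge vanishes; see the test suite). On non-convergence
  the ridge escalates tenfold up to four times; still-failing pixels are
  returned as NaN and counted.
* **M\* responses.** Two variants are implemented. The default draws one
  set of binary choices from the model's predicted probabilities
  (parametric bootstrap). The alternative fits the probabilities directly
  as fractional responses; it is deterministic, but because binary-response
  logistic slopes carry a small away-from-zero finite-sample bias that a
  noiseless fractional fit does not share, the difference M - M* then
  acquires a small positive offset (about +0.15 slope units at 240 trials
  on G = 61 in our simulations) and the group test loses calibration. The
  bootstrap variant cancels the bias by construction, at the cost of one
  extra unit of map-level Monte-Carlo noise, which the between-subject
  t-test absorbs.
* **Grid conventions.** Pixel (0,0) is the top-left corner, x rightward, y
  downward in pixel space; degree coordinates have the origin at the
  display center, x rightward, y upward, angles counterclockwise from +x.

## Rotational alignment and angular tuning

To ask whether decision weight concentrates at the memorized location,
displays are rotated -- on dot coordinates, before rasterization, so the
operation is exact rather than interpolated -- such that each trial's sample
angle lands on a common reference (45 degrees). Trials whose location recall
is displaced more than 40 pixels (401-grid scale, converted proportionally)
from the true sample position are excluded and logged. The display area is
then partitioned into 11 equal pie segments with the target segment centered
on the reference; tuning is the target-segment mean weight minus the mean of
the remaining segments, tested across subjects per display position. Segment
membership follows the pixel center's angle; boundary ties fall to the lower
segment by the floor convention. Control trials can be pseudo-aligned with
angles borrowed at random (without replacement where counts allow) from
memory trials, which must produce null tuning.

Map stability across the six display positions is quantified as the 15
pairwise Pearson correlations over in-mask pixels, minus a baseline obtained
by independently rotating each map by uniform random angles (bilinear
interpolation, 1000 draws by default). Radially symmetric structure -- a
center bias -- survives random rotation and is removed by the subtraction; a
purely radial map has raw correlation near 1 and corrected correlation near
0.

## The psychometric choice model

Sensitivity and bias are quantified with a logistic choice model: color-tied
intercepts (one when the memorized sample was blue, one when red) plus six
slopes on the per-display excess counts; control trials get a single
intercept. The bias magnitude is the intercept contrast
$\beta_b - \beta_r$ (log-odds), and the recency slope is the least-squares
slope of $\beta_1..\beta_6$ against display position.

Two modeling decisions deserve emphasis:

* **Counts enter raw.** The slopes multiply the raw signed counts of each
  display, whose range happens to be the trial mean plus or minus 10. An
  alternative is to demean the counts by the per-trial stream mean; but the
  observer reacts to the dots actually shown, so demeaning without also
  modeling the mean leaves an omitted per-trial offset that attenuates all
  coefficients (we measured 12-28 percent depending on sensitivity). With
  raw counts the model is correctly specified for the generative observers
  and injected biases are recovered without systematic error. The
  reverse-correlation *weighting function*, in contrast, is tabulated on
  the 11-level demeaned grid, which is the natural axis for plotting.
* **Separation handling.** Fits whose coefficients exceed 15 on
  standardized predictors (or that fail to converge) are flagged as
  quasi-separated, and error-free recall makes the recall-report model
  degenerate; flagged subjects are excluded from residual-based analyses
  and counted, mirroring the exclusion of ceiling-performing participants
  from residual analyses in practice. No lapse parameter is fitted: the
  generative observer may lapse, the analysis model never does.
* **Condition structure.** Conditions are fit separately (memory condition
  with color-tied intercepts; the two control conditions pooled with a
  single intercept); both fits are exposed and can be contrasted.

## Crosstalk: does the stream bleed into memory?

Three statistics probe the reverse direction. (1) A logistic regression of
recall color on the per-display excess counts (color-tied intercepts
included; slopes `gamma_1..gamma_6`, plus a pooled fit with the mean count
as a single predictor -- pooling over displays is done on the predictor by
default, with the mean of per-display slopes available as an alternative).
(2) A logistic regression of recall color on the trial's choice residual
(observed choice minus model probability) -- sensitivity of memory reports
to endogenous decision variability unexplained by any stimulus. (3) The
Pearson correlation, within subject, between the residual series of the
choice model applied to choices and to recall reports, tested across
subjects. Location-recall precision is summarized by per-trial Euclidean
error, per-subject medians (for error with isotropic SD sigma the median is
sigma times sqrt(2 ln 2)), and a 2-D histogram of aligned recall positions;
a per-subject median split (ties to the high-precision set) lets any
analysis be rerun on high- versus low-precision trials.

## The synthetic experiment: what it emulates and what it does not

Because the paradigm's real data cannot ship with a package, every stage is
validated by parameter recovery on a generative observer whose parameters
are known:

* stimuli exactly as above (truncated-normal counts on the even grid;
  uniform non-overlapping dot placement by rejection sampling, capped at
  10^4 proposals per dot; the historical one-dot presentation offset is
  reproducible via `shift` but defaults to 0);
* a decision stage $P(\mathrm{blue}) = L\big(\sum_k w_k E_k/\sigma_d +
  b_{wm}\,s/2\big)$ with per-display evidence $E_k$ equal to the signed
  count, modulated by a multiplicative Gaussian gain bump of amplitude $a$
  and width $\sigma_g$ centered $r_g$ degrees from fixation along the
  fixation-to-sample axis in selected displays; logistic (not Gaussian)
  decision noise, so that the color bias $b_{wm}$ is, by construction, the
  log-odds blue-minus-red intercept contrast that the choice model
  estimates -- injected and recovered quantities share a scale;
* a recall stage with isotropic Gaussian location noise and a color-error
  channel: errors occur with probability $\epsilon$ and copy the decision
  response with probability $\kappa$ (the crosstalk dial), otherwise flip
  the true color; on "control2" trials recall precedes the stream and the
  coupling is disabled.

Defaults were chosen once to mimic the published task's operating point:
equal temporal weights with $\sigma_d = 25$ count-units per log-odds, giving
about 71 percent choice accuracy and near-linear weighting functions
spanning roughly 0.4-0.6; $\epsilon = 0.069$ matching the reported 93.1
percent color-recall accuracy; location-recall SD 0.5 degrees, which puts
about 11 percent of trials beyond the 40-pixel exclusion radius (the
Rayleigh tail). For recovery experiments the gain field uses $a = 20$,
$\sigma_g = 1.5$, $r_g = 2$: a deliberately strong synthetic effect, set by
an a-priori power analysis so that a single 20-subject, 240-trial cohort
detects display-limited tuning with subject-level effect size near one SD
(the corresponding human effect, detected in a cohort three times larger,
is about half that size; desk-scale recovery needs the stronger dial). The
recency-recovery experiments follow the same power rule: the injected
temporal-weight gradient (0.4 to 1.6 across the six displays) is set so a
12-subject run detects a positive slope with run-level z near five, making
per-run sign failures negligible.

The generator reproduces the task's stimulus statistics and a plausible
observer, not human idiosyncrasy: there is no session drift, no lapse
correlation with memory load, no anisotropic spatial weighting (the vertical
overweighting seen in humans), and recall errors are isotropic. Passing
recovery tests therefore certifies the estimators -- that the pipeline finds
what is there and nothing when nothing is there -- not any claim about real
observers.

## Problem sizes and statistical conventions of the test suite

The packaged checks run the map pipeline at G = 61 (the inscribed-circle
mask then holds ~2,900 pixels), 240 trials and 12-20 subjects per cohort,
20 replicate cohorts for calibration and recovery rates, 50 groups for the
crosstalk null calibration, and 10^5 draws for stimulus goodness-of-fit;
these sizes make the whole suite run in minutes while leaving each check
well powered. Where a check asserts that a nominal error rate (for example
the 5 percent FDR level) is respected, the assertion uses an exact binomial
consistency bound at the 99.5th percentile rather than the raw expected
count: with 20 replicates an ideal procedure exceeds the expected single
rejection 26 percent of the time, so the raw count would be a coin-flip
test of a correct implementation. Five percent of no-gain display tests are
likewise expected to reject by construction, and are bounded binomially,
not asserted to be zero.

## Orchestration and formats

`run_stage()` chains the stages (simulate, fit-maps, null-map, group-test,
align, tune, stability, psychometrics, crosstalk, report) over plain file
interfaces: trial and dot tables as CSV, tidy statistics as CSV, fitted map
objects as RDS containers, configurations as YAML or JSON, and a JSON
manifest per stage recording the configuration, seed, package version and
md5 hashes of all inputs and outputs. Rerunning a stage with the same
inputs and seed reproduces its outputs bit-identically (exact stages) or to
fitting tolerance (iterative fits). Exclusion counts -- trials beyond the
recall threshold, separated subjects, unconverged pixels -- are surfaced in
logs and object fields because the analyses hinge on these filters.

## Known limitations

* Per-pixel regressions are fit independently (as the mapping model
  specifies); a joint spatial model with explicit pixel covariance is out
  of scope, and no cluster-based or permutation map statistics are
  provided.
* The angular tuning profile is segment-based; continuous tuning-curve
  fits (e.g. circular von Mises regression) are not implemented.
* Location recall is summarized by error radii and histograms; mixture
  modeling of swap/guess components is out of scope.
* The rotation baseline for map stability interpolates bilinearly, so a
  one-to-two-pixel rim of the mask is lost to interpolation in the rotated
  maps; correlations use the pixels finite in both maps of a pair.
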