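---
title: "Methods: FvCB curve fitting and ensemble spectra-trait PLSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FvCB curve fitting and ensemble spectra-trait PLSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectraphys)
```

`spectraphys` implements a two-stage pipeline for leaf photosynthetic
traits. Stage one estimates the parameters of the
Farquhar–von Caemmerer–Berry (FvCB) model — the maximum Rubisco
carboxylation rate $V_{cmax25}$, the maximum electron transport rate
$J_{max25}$, the triose phosphate utilization rate $T_{p25}$ and
respiration — from A-C$_i$ gas-exchange curves, plus dark respiration
$R_{dark25}$ from dark-adapted efflux series. Stage two trains ensemble
partial least-squares regression (PLSR) models that predict those traits
from leaf reflectance spectra (500–2400 nm) and validates them under
three split designs of increasing difficulty. A synthetic-data generator
emulates the joint trait–spectra structure so every stage can be
exercised, tested and calibrated without field data.

## The FvCB model and its temperature normalization

Net CO$_2$ assimilation is the minimum of three potentially limiting
gross rates minus respiration in the light:

$$A_{net} = \min(A_c, A_j, A_p) - R_d,$$

with

$$A_c = V_{cmax}\frac{C_i - \Gamma^*}{C_i + K_c(1 + O/K_o)}, \qquad
  A_j = J\frac{C_i - \Gamma^*}{4C_i + 8\Gamma^*}, \qquad
  A_p = 3T_p.$$

$J$ follows the non-rectangular hyperbola
$\theta J^2 - (\alpha Q + J_{max})J + \alpha Q J_{max} = 0$ (smaller
root), with defaults $\theta = 0.7$ and $\alpha = 0.425$. Because curves
are measured at per-leaf saturating irradiance the fit is insensitive to
these two values; both are arguments everywhere so the assumption is
visible and editable. The export limb uses the simplest standard form
$A_p = 3T_p$ with no glycolate-export term. Gas concentrations are mole
fractions throughout (µmol mol$^{-1}$ for CO$_2$, mmol mol$^{-1}$ for
O$_2$), matching instrument output. Mesophyll conductance is assumed
infinite, so all parameters are *apparent*.

Every parameter is expressed at 25 °C and scaled to each observation's
leaf temperature by the modified (peaked) Arrhenius function

$$f(T) = \exp\!\left[\frac{H_a(T - T_{ref})}{T_{ref}\,R\,T}\right]
  \frac{1 + \exp\!\left[(T_{ref}\Delta S - H_d)/(T_{ref}R)\right]}
       {1 + \exp\!\left[(T\Delta S - H_d)/(TR)\right]},$$

which reduces to pure Arrhenius when $H_d$ and $\Delta S$ are absent
(used for respiration and the kinetic constants). $f(T_{ref}) = 1$
exactly. The numeric values of $H_a/H_d/\Delta S$ per parameter and of
$K_{c25}, K_{o25}, \Gamma^*_{25}$ ship in an editable YAML file
(`inst/extdata/photosynthesis_constants.yml`), loaded by
`fvcb_constants()`. The defaults are the widely used in-vivo tobacco
kinetics of Bernacchi and colleagues and common temperate-default
peaked-Arrhenius parameters; they are configuration, and a study using
different temperature-response sources should substitute its own file.

## Maximum-likelihood curve fitting

`fit_aci()` maximizes a Gaussian likelihood: observed $A$ equals the
forward FvCB prediction plus iid noise with standard deviation
$\sigma$. Numerically, $\sigma$ is concentrated out analytically
($\hat\sigma^2 = RSS/n$) and the resulting profile objective is
minimized by bounded quasi-Newton (L-BFGS-B) from five starts — one
heuristic (Vcmax from inverting the Rubisco limb at the lowest-C$_i$
points, Jmax from the high-C$_i$ plateau, $T_p$ = plateau/3,
$R_d$ = 1), the rest log-normally jittered around it — followed by a
Nelder-Mead polish, because the `min()` kinks between limbs can stall
gradient methods slightly short of the optimum. When the export limb is
fitted, two additional structured starts seed the two basins in which
the high-C$_i$ plateau is explained by $A_j$ saturation or by a flat
$A_p$ cap. The limb limiting each observation falls out of the fitted
parameters; transitions are never assigned by hand.

Standard errors come from the inverse observed information (Hessian) of
the profile objective. Two small-sample conventions matter on 15-point
curves: the covariance is rescaled by $n/(n-p)$ (the concentrated
likelihood's $RSS/n$ variance estimate is biased low), and intervals
use the $t$ critical value at the residual degrees of freedom. Without
these, simulated 95 % interval coverage sits near 88 %; with them it is
91–96 %. A singular Hessian (e.g. a curve with no Rubisco-limited
points, leaving $V_{cmax}$ on a flat likelihood ridge) sets
`reliable = FALSE` rather than failing. Fig-style confidence and
prediction bands (`curve_intervals()`) are parametric-bootstrap
percentile bands: parameter draws from the Wald multivariate normal are
propagated through the forward model, and the prediction band adds
Gaussian residual noise.

The respiration parameter co-estimated during curve fitting is kept in
the fit object but deliberately **not** exported as the $R_{dark25}$
trait: only dark-adapted measurements (`rdark_from_timeseries()`: mean
of one minute of 1 Hz efflux, normalized by the respiration Arrhenius
factor) feed the trait table. The standard error reported for
$R_{dark25}$ is the sample $sd/\sqrt{n}$ of the efflux readings — an
instrument-noise summary; this is a documented assumption, since
repeated readings of one leaf carry no biological replication.

## AIC selection of the export limb

Export (triose-phosphate) limitation is not present in every curve.
Each curve is fitted with and without the $A_p$ limb and the lower-AIC
model is kept ($AIC = 2k - 2\log L$, $k$ counting $\sigma$); exact ties
resolve to the model without the limb. `fit_aci_selected()` wraps the
pair of fits with mutual warm starts — each model is also refit from the
other's optimum, keeping the better likelihood — because the AIC
comparison is only meaningful when both nested models are at their
optima.

A caveat worth stating plainly: when the export limb is truly absent,
the flat $A_p$ cap can still chop noisy high-C$_i$ points, and with
fully optimized fits the probability that this gains more than the
2-unit AIC penalty is roughly 0.15 at a residual noise of
0.5 µmol m$^{-2}$ s$^{-1}$ on the 15-point protocol — higher than the
$\chi^2_1$ intuition suggests, because the cap parameter enters through
a kink rather than smoothly. Simulated false-detection rates of
10–15 % under the null are therefore expected behavior of the AIC rule
itself, not an optimizer defect; we verified that under-optimizing the
with-limb fit lowers the apparent rate, which would be a dishonest fix.
In the simulation suite the "strong plateau" regime is defined as an
export cap at 60 % of the leaf's otherwise attainable gross plateau;
there the correct model is selected in ≈ 95–97 % of replicates.

## Spectra handling

Reflectance enters as wide CSV (leaf, replicate, one column per nm over
350–2500 nm). The 3–4 replicate scans per leaf are averaged per
wavelength; spectra are then linearly interpolated onto an integer
1 nm grid over 500–2400 nm, trimming detector-edge noise at both ends.
The window and step are arguments of `regrid_spectra()` /
`spectra_matrix()` since the exact trim is a modeling choice, and no
smoothing is applied by default. Averaging and regridding are both
linear, so their order does not matter (tested to $10^{-9}$).

## Ensemble PLSR

For each trait separately, the workflow is:

1. **Transformation.** $V_{cmax25}$ and $J_{max25}$ are square-root
   transformed (their distributions are right-skewed); $T_{p25}$ and
   $R_{dark25}$ are modeled untransformed.
2. **Component selection** (`press_profile()` + `select_ncomp()`). The
   training set is resampled 1000 times into random 70/30 splits; a
   PLS1 model (NIPALS, X-only deflation, mean-centering, **no**
   unit-variance scaling — reflectance shares units and scaling would
   distort spectral shape) is fit on the 70 % part and PRESS is
   evaluated on the 30 % part at every component count. The selected
   count is the smallest whose mean PRESS is within one standard error
   of the best; "standard error" defaults to
   $sd/\sqrt{n_{iter}}$ across iterations (a full-$sd$ variant is
   available via `se_rule = "sd"`, since guide texts differ). The count
   chosen on the random split is reused unchanged for the species and
   site splits, so the three designs test transfer, not re-tuning.
3. **Ensemble fitting** (`fit_ensemble()`). 1000 sub-models are each
   fit on a fresh random 70 % subset at the fixed component count; each
   stores its coefficient vector, intercept and the residual sd from
   its own 30 % holdout. Sub-model seeds derive from one master seed by
   a counter scheme, so the whole path is bit-reproducible.
4. **Prediction** (`predict_ensemble()`). Every sub-model predicts on
   the transformed scale and is back-transformed *before* aggregation
   (squaring each prediction, then averaging — this propagates ensemble
   spread through the nonlinearity). The 95 % confidence interval is
   the 2.5/97.5 percentile of the 1000 back-transformed predictions;
   the prediction interval adds one Gaussian draw per sub-model with
   its residual sd before back-transforming. Percentiles (not a normal
   approximation) were chosen because the ensemble distribution is
   already available and possibly skewed after back-transformation;
   prediction intervals are clamped to enclose the confidence interval,
   which the finite-sample percentiles would otherwise violate on rare
   rows.
5. **Interpretation.** VIP scores use the standard PLS1 formula
   ($\sum_j VIP_j^2 = p$); the ensemble VIP is the mean over sub-models,
   accumulated during fitting so the full weight arrays need not be
   stored. `coefficient_summary()` reports the mean and 95 % band of
   the coefficient vectors with the VIP > 1 mask;
   `coefficient_difference()` compares two traits' ensembles through
   paired sub-model differences and reports the wavelengths whose 95 %
   difference band excludes zero, plus the Pearson correlation of the
   mean coefficient vectors.

## Validation designs and metrics

* **Random split**: 80 % of trait-eligible leaves train, 20 % validate.
* **Species split**: "new" species — those present only in the most
  recent campaign — are identified from the composition table; 30 % of
  them (rounded half away from zero, e.g. $0.3 \times 32 = 9.6 \to 10$)
  are drawn and *all* their leaves validate. Species seen in an earlier
  campaign always train.
* **Site split**: deterministic — Panama trains, Brazil validates. The
  split refuses traits absent at the validation site (no Brazilian
  dark-respiration data) and warns when validation support is sparse
  (few Brazilian export-limited curves).

Metrics are RMSE, %RMSE $= 100\,RMSE / (\max - \min)$ with the range
taken over the *whole* dataset (all splits pooled) so the designs are
comparable, and $R^2 = 1 - SS_{res}/SS_{tot}$ on the validation set —
not a squared correlation; it penalizes bias and may be negative, and
is never clipped.

## The synthetic-data generator

`gen_traits()` draws species mean log-traits from a multivariate normal
(log-normal marginals with medians near 40, 75, 5.5 and
0.65 µmol m$^{-2}$ s$^{-1}$ for $V_{cmax25}$, $J_{max25}$, $T_{p25}$,
$R_{dark25}$), with 60 % of log variance at the species level and the
rest between leaves. The log-scale correlation matrix defaults to a
strong $V_{cmax}$–$J_{max}$ correlation of 0.9 with weaker 0.5–0.8
links to $T_p$ and $R_{dark}$; these defaults are stated assumptions
(the field reports correlations in this range but the exact values are
configuration). A "Brazil-like" site receives a −0.45 log-mean shift,
no dark-respiration measurements and almost no export-limited curves,
so the site-split code path — including its refusal branch — is
exercised. $T_{p25}$ is masked to missing for 68 % of the remaining
leaves, matching the observed rate of about one third of curves showing
an export limitation.

`gen_aci_curve()` follows the measurement protocol: the 15-setpoint
chamber CO$_2$ sequence (400 down to 50, back to 400, up to 1800
µmol mol$^{-1}$), leaf temperature constant at 30, 31 or 32 °C,
saturating irradiance, $C_i$ = 0.8 × setpoint (a fixed stomatal
drawdown — the pipeline needs realistic $C_i$ ranges, not stomatal
realism), and Gaussian noise with sd 0.5 µmol m$^{-2}$ s$^{-1}$. That
noise level is calibrated so that single-curve fitting uncertainty is a
few percent of the parameter value, far smaller than the spread across
leaves — the contrast a field survey shows between measurement
uncertainty and biological variation.

`gen_spectra()` builds reflectance as a smooth vegetation-like baseline
(green peak, red absorption, NIR plateau, two water dips, SWIR decline)
minus Gaussian absorption features at 680, 1450, 1940 and 2100 nm whose
depths are linear in the standardized log traits, plus correlated
smooth noise (50 nm length scale) and white noise. Feature positions
echo the visible/water/SWIR regions that spectra-trait models typically
exploit; they are illustrative and configurable. Because depths are
linear in the latent traits, a linear method can recover the map —
which is the point: the generator tests the machinery, not radiative
transfer. What it does **not** emulate: PROSPECT-style physics,
leaf-age trajectories, instrument drift between spectrometers, or
trait–spectra links mediated by unmodeled constituents. Passing tests
on synthetic data therefore demonstrate correctness of the estimation
machinery under the stated statistical structure, not field accuracy.

## Numerical choices and problem sizes

* Optimizer bounds: $V_{cmax25} \in [1, 1000]$,
  $J_{max25} \in [1, 1500]$, $R_{d25} \in [10^{-3}, 50]$,
  $T_{p25} \in [0.1, 200]$ µmol m$^{-2}$ s$^{-1}$; RSS floored at
  $10^{-12}$ so noise-free curves remain finite on the log scale.
* PLS1 stops early when the response is numerically exhausted
  (noiseless low-rank data) and pads the coefficient path, so PRESS
  profiles stay defined past the effective rank.
* The test-suite and example problem sizes are scaled for a laptop:
  spectra at 10–20 nm steps, ensembles of 200 sub-models, 200-curve
  Monte-Carlo batches. The defaults in the package (1 nm grid, 1000
  sub-models) are the full-scale workflow; all conclusions in the test
  suite are invariant to this scaling, and the ensemble-size invariance
  is itself tested (quadrupling sub-models changes mean predictions by
  well under 2 %).

## Known limitations

* Wald/percentile intervals are symmetric-information constructs; a
  profile-likelihood option would be more faithful near parameter
  bounds.
* AIC export-limb detection has the null false-positive behavior
  discussed above; users needing strict control of false $T_p$
  detections should raise the evidence threshold themselves.
* The generator's $C_i$ drawdown is a constant ratio, so curves carry
  no stomatal-closure signature; fitted parameters are unaffected, but
  the curves should not be used to study stomatal behavior.
* $R^2$ on narrow-range validation sets (the Brazil site) is expected
  to drop even at unchanged RMSE, since less total variance is
  available to explain.
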