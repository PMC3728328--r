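---
title: "Decomposing fasting-refeeding calorimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing fasting-refeeding calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagecal)
```

`cagecal` analyses meal-response indirect calorimetry in small animals: an
overnight-fasted animal in a ventilated metabolic cage receives a calibrated
test meal, and gas exchange (VO~2~, VCO~2~) plus spontaneous activity are
recorded at 5-s resolution. From one such session the package derives the
standard energy-budget parameters — basal metabolic rate (BMR), thermic
effect of feeding (TEF), resting and activity-specific respiratory quotients
(Rest-RQ, Act-RQ), the energy cost of activity, and glucose/lipid oxidation
rates — and relates them across a cohort to body-composition trajectories
under sequential high-carbohydrate (HCD) and high-fat (HFD) feeding.

Because raw animal recordings of this kind are rarely shared, the package
includes a first-class synthetic-data generator that emulates both the cage
physics and the cohort's statistical structure, so every stage of the
pipeline can be tested against known ground truth.

## The measurement model

### Chamber washout

The analyzer does not see the animal's instantaneous gas exchange: the cage
behaves as a stirred volume, so the measured signal $y(t)$ is the
first-order low-pass response of the production signal $x(t)$,

$$\tau \dot y(t) = x(t) - y(t), \qquad \tau = V / F,$$

with practical dilution volume $V = 10.5$ L and ventilation flow
$F = 1.5$ L/min by default, i.e. $\tau = 7$ min. `washout_correct()` inverts
this relation using the identity $x = y + \tau\,\dot y$, taking the
derivative on a 30-s moving-average copy with a slope baseline of one
smoothing width on each side, which bounds noise amplification at the price
of band-limiting the inverse.

That band limit has one important consequence. The decomposition regresses
corrected gas on activity, but activity is measured directly (it never
passed through the chamber), so fast activity modulations survive in the
regressor while being attenuated in the corrected gas — an
errors-in-the-operator mismatch that biases the activity-cost estimate
towards zero whenever activity fluctuates on time scales comparable to
$\tau$. `washout_correct()` therefore also emits `activity_matched_au`: the
activity channel passed through the *same* chamber low-pass and then the
same approximate inverse. Regressing corrected gas on the matched regressor
is consistent at all frequencies; on noise-free piecewise-constant test
signals the decomposition then agrees with a windowed least-squares oracle
to better than 1%, which fails badly with the raw regressor.

Missing samples (the acquisition freeze while the meal is introduced)
propagate through the correction with a guard band of one smoothing width;
gaps are always explicit `NA`s, never zeros.

### State-space decomposition

`kalman_decompose()` separates resting from activity-driven gas exchange
with a linear-Gaussian state-space model. The state
$x_k = (r^{O_2}_k, r^{CO_2}_k, c^{O_2}_k, c^{CO_2}_k)$ holds the resting
rates (mL/min) and the activity costs (mL/min per arbitrary activity unit);
both follow random walks, slow for rest and much slower for cost:

$$x_{k+1} = x_k + w_k, \quad w_k \sim N(0, \mathrm{diag}(q_r, q_r, q_c, q_c)),$$

with defaults $q_r = (0.01)^2$ and $q_c = (0.001)^2$ per 5-s sample. The
observations are

$$\mathrm{VO}_{2,k} = r^{O_2}_k + c^{O_2}_k a_k + e_k, \qquad
  \mathrm{VCO}_{2,k} = r^{CO_2}_k + c^{CO_2}_k a_k + f_k,$$

where $a_k$ is the (chamber-matched) activity. Observation noise is
estimated from the first ten minutes of the trace by the MAD of first
differences divided by $\sqrt2$, which is robust to early activity bursts.
Rest states initialise at the 10-min median of the trace start; cost states
at zero with a broad prior. A forward filter is followed by fixed-interval
(Rauch–Tung–Striebel) smoothing by default; `smooth = FALSE` gives the
causal filter for on-line use. Missing samples are predicted through
without an update, so state variance inflates naturally across gaps.
After smoothing, resting rates are floored at a small positive bound and
costs at zero. If activity is identically zero the cost states are not
identifiable; the function warns and flags the result rather than guessing.

Numerical details that matter: the filter runs in C++ (RcppArmadillo) with
the Joseph-form covariance update for numerical symmetry; Act-RQ is masked
wherever activity is below the 5th percentile of non-zero activity, because
a ratio of two near-zero costs is meaningless there.

### Derived parameters

With gas rates in mL/min, energy expenditure follows the Weir form
$\mathrm{EE}\,[\mathrm{W}] = (16.3\,\mathrm{VO}_2 + 4.57\,\mathrm{VCO}_2)/60$,
applied separately to the resting components (REE), the costs (activity
cost in W/AU) and cost × activity (activity EE); the form is linear, so
resting and activity EE sum exactly to the EE of the reconstructed total.
Nitrogen-free glucose and lipid oxidation rates are
$\mathrm{Gox} = (4.57\,\mathrm{VCO}_2 - 3.23\,\mathrm{VO}_2)\cdot 15.6/60$ and
$\mathrm{Lox} = 1.69\,(\mathrm{VO}_2 - \mathrm{VCO}_2)\cdot 39.5/60$ W;
their sum reconstructs Weir EE within 0.5% over RQ 0.70–1.00, and values
beyond the formula roots (RQ below ~0.707 or above 1) are reported as-is.

Series are binned into 15-min windows whose edges align to meal delivery
(time 0); bins more than half missing are flagged. Session parameters then
follow fixed windows: BMR is the mean resting EE over −120..0 min (the
fasted animal near thermoneutrality makes RMR ≈ BMR; the mean rather than a
minimum statistic, since the pre-meal period is stationary by design), and
TEF is the net area of (RMR − BMR) over 0..300 min, integrating bin means
over their width — exact for binned step data — with negative excursions
subtracting, the standard energy-balance reading. TEF is always computed
from absolute RMR: it is a property of the meal, not of body size, so it is
never mass-normalised. BMR (and oxidation rates) can be normalised to
metabolic mass as value × 300/(FFM + 0.2 FM), stated per 300 g to keep
whole-animal magnitudes.

Diet bookkeeping uses 16.7 kJ/g for carbohydrate (starch + sucrose) and
protein and 37.7 kJ/g for fat; minerals, vitamins, cellulose and choline
contribute no energy. The food quotient is the energy-fraction weighted sum
with weights 1 / 0.825 / 0.7 (carbohydrate / protein / fat), giving 0.946
for the reference HCD and 0.847 for the HFD. For the two reference diets
the datasheet's printed energy fractions and densities (15.95 and 19.82
kJ/g) are treated as authoritative — the factor-derived values (15.92,
19.80 kJ/g; HFD quotient 0.8464 from unrounded fractions) differ in the
last digit through rounding and stay available as
`energy_density_kj_g` / `food_quotient_from_masses`.

## Body composition and sensitivity classes

MRI adipose volume converts to fat mass at 0.9 g/cm³ and FFM is body weight
minus FM. FFM and FM are interpolated linearly (and independently) between
bracketing imaging sessions to put a composition on each calorimetry day;
no extrapolation is permitted, and `validate_interpolation()` checks the
assumption by regressing interpolated FFM+FM on weighed body mass — slope
and R² near 1 on synthetic cohorts.

Adiposity is (FM/BW) × 100, and a diet period's "gain" is the difference of
adiposity percentages in percentage points (a relative-change definition is
available as a switch; the percentage-point difference is what feeds the
mixed model as a single slope covariate). `classify_cohort()` median-splits
an even cohort into exactly n/2 resistant and n/2 sensitive animals —
CR/CS under the carbohydrate diet, FR/FS under the fat diet,
cross-classified independently. Ties straddling the median are resolved by
stable animal order with a warning, so the split is deterministic. The
split is invariant under any strictly monotone transform of the gains.
Visceral:subcutaneous fat ratios are summarised as median ± 0.5 IQR
(type-7 linear-interpolation quartiles; the convention is stated because it
is not universal) and compared across timepoints by paired two-sided
Wilcoxon signed-rank tests.

## The meal-response mixed model

The inferential core is

```
mp ~ adchg * mealtime,  random = ~ 1 | rat / session / period
```

fitted by REML with `nlme::lme`: `mp` is a metabolic parameter (Rest-RQ by
default), `adchg` the animal's adiposity change under one diet, and
`mealtime` pre vs post. The four fixed effects are the pre-meal intercept
at zero adiposity change, the pre-meal slope against adiposity change, the
post-meal shift, and the interaction — how the meal response scales with
adiposity gain, the quantity of scientific interest. HC and HF meals, and
HCD vs HFD adiposity changes, are always fitted as separate models, never
pooled.

Two identifiability points. With one aggregated value per pre/post period,
the period-level random intercept is confounded with the residual; and with
one session per animal per meal type, the session level is confounded with
the animal level. `nesting = "auto"` therefore keeps only the identifiable
levels (the full three-level nesting engages when per-bin data are
supplied); fixed-effect estimates are unchanged by this reduction.
P-values are nlme's conditional t-tests, the same machinery a practitioner
would get from `lme` directly. Inestimable configurations (e.g. a constant
covariate) return a flagged, non-converged result rather than a silent
fallback. `adchg` enters uncentred, which affects only the intercept's
interpretation. No multiple-testing correction is applied anywhere;
instead the fixed conventions are P ≤ 0.01 "significant" and
0.01 < P ≤ 0.05 "marginal". Per-timepoint group comparisons
(`pointwise_group_tests()`) run independent two-sided t-tests per 15-min
bin at the 0.01 threshold and report contiguous significant spans.

## What the generator emulates — and what it does not

`generate_cohort()` draws a cohort with the documented statistical
structure: starting body weight 303.3 ± 24.5 g; starting adiposity
10 ± 2.5% (typical for young male Wistar rats); HCD and HFD adiposity gains
bivariate normal at 2.0 ± 1.5 and 5.0 ± 2.0 percentage points with
correlation 0.482 (the loose inter-diet coupling); body-weight gains of
80 ± 15 g (HCD) and 100 ± 20 g (HFD) coupled to the adiposity gains at
Pearson 0.525 and 0.911 respectively, constructed conditionally so the
population correlation is exact; and visceral:subcutaneous ratios
log-normal around medians 1.44 / 1.82 / 1.53 at the three imaging
timepoints, with a persistent per-animal component (sd~log~ 0.15 between,
0.16 within) so the timepoints are genuinely paired. Gains are drawn
jointly with starting adiposity and redrawn for the rare animal whose
trajectory would leave (0.5, 60)% adiposity — a negligible truncation at
these settings. Sensitivity is continuous (the gain itself); class labels
are only ever derived downstream by the median split, never stored as
truth.

`generate_latent_session()` builds the ground-truth physiology on the 5-s
grid: resting EE as a basal 1.35 W plus a slow Ornstein–Uhlenbeck wander
(stationary sd 0.03 W, time constant 80 min) plus, post-meal, a
gamma-kernel (shape 2, scale 60 min) TEF bump scaled so exactly
`tef_fraction` (default 10%) of the 60-kJ meal is dissipated over 0..300
min; resting RQ as basal 0.80 plus a small OU wander plus a gamma-kernel
excursion (scale 90 min, peaking where post-meal substrate shifts are
largest) normalised so its *window-mean* rise is the configured value —
0.035 for HF meals (insensitive to class, as the low food quotient leaves
little room), and for HC meals 0.075 at zero sensitivity plus 0.0086 per
percentage point of HCD gain, so the window-mean pre/post contrast carries
exactly the interaction slope the mixed model should recover, and
clearly sensitive animals peak above the diet's food quotient of 0.946
while resistant ones stay below (never above 1: no net lipogenesis).
Activity is a marked point process — exponential inter-burst times
(8 events/h), log-normal magnitudes, ~60-s exponential decay — costing
0.015 W/AU fasted and 30% more after feeding (smooth ~30-min onset), with
Act-RQ a constant 0.02 above Rest-RQ. `apply_chamber_mixing()` then applies
the exact zero-order-hold discretisation of the 7-min washout, adds
Gaussian analyzer noise (0.05 mL/min), and blanks a 120-s acquisition
freeze at meal delivery.

The full overnight segment (18:00–17:00) is generated even though only
−120..+300 min around the meal is analysed, so window selection is
exercised on realistic context. Features of real data deliberately *not*
emulated: thermoregulatory EE (sessions are defined at ~26 °C precisely so
it is negligible), circadian structure beyond the fast/refeed design,
analyzer drift and calibration steps, and any dependence of BMR, TEF or
activity cost on the sensitivity classes — the generator builds the null
the study reported for those parameters. Passing recovery tests therefore
demonstrates that the pipeline measures what the model generates without
bias at realistic noise; it cannot certify behaviour under artefacts the
generator omits.

The mixed-model simulator (`simulate_meal_response()`) is a separate,
direct generator of the long-format table with explicit fixed effects and
variance components; `re_scales_from_se()` inverts the balanced-design SE
identities so that a 24-animal cohort yields slope and interaction SEs near
0.0041 and 0.0026 (giving rat-intercept sd 0.0264 and residual sd 0.0132 on
the RQ scale). This route checks the inferential layer independently of the
signal-processing layer.

## Problem sizes, tolerances, reproducibility

Routine property checks run on 9-h sessions; full recovery studies use 50
overnight sessions (pre-meal Rest-RQ recovered within ±0.02, HF window-mean
rise within ±0.007), 200 cohorts for correlation calibration (±0.05 and
±0.03), and 200 cohorts for interaction recovery (within one generating SE),
sizes at which Monte-Carlo error is a small fraction of each tolerance. The
type-I-error check of the interaction test uses 400 null replicates with a
3-sigma binomial band around 5%. All generation is seeded and
bit-reproducible; independent streams derive from one master seed through a
fixed integer map, and end-to-end runs write byte-identical CSVs given the
same seed. Degenerate inputs (all-missing traces, zero activity, constant
covariates, ties at the median, sub-threshold activity) return explicit
errors, warnings or flags — never silent guesses.

## A worked session

```{r example, eval = FALSE}
cfg <- session_config(seed = 7, meal_type = "HF")
sim <- simulate_session(rat = list(hcd_gain_pct = 2), config = cfg)
dec <- decompose_session(sim$trace)
summarize_session(dec$binned, rat_id = "R01", meal_type = "HF",
                  ffm_g = 270, fm_g = 30)
```

and a whole synthetic study, from cohort to fitted models:

```{r pipeline, eval = FALSE}
res <- run_full_pipeline(run_config(seed = 1, n_rats = 24))
res$fits$HC_meal_hcd_gain
```

## Known limitations

The washout inverse is band-limited, so gas-exchange structure faster than
about one smoothing width is unrecoverable by design. The activity cost is
identified only from activity variation; long perfectly-still stretches
carry the cost state on its random walk with growing variance. The
substrate-oxidation formulas are nitrogen-free (no protein-oxidation
correction), and TEF uses a fixed 300-min window rather than modelling TEF
duration. Multi-animal multiplexed cages and sub-5-s dynamics are out of
scope.
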