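---
title: "Methods: the fruquintinib vs BSC Markov cohort model"
author: "fruqcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fruquintinib vs BSC Markov cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruqcea)
```

## The decision problem

Fruquintinib is a VEGFR inhibitor approved in China as third-line treatment
for metastatic colorectal cancer (mCRC). In its pivotal phase III trial it
extended median overall survival from 6.6 to 9.3 months versus placebo
(HR 0.65) and median progression-free survival from 1.8 to 3.7 months, at
the price of frequent grade 3/4 adverse events. After China's 2019 national
price negotiation cut the drug's price by over 60%, the question for the
healthcare payer is whether the survival gain is worth the incremental cost.
`fruqcea` implements a cohort-level Markov decision model that answers this
in cost per quality-adjusted life year (QALY), under both the negotiated
price and the earlier market price with its manufacturer donation scheme,
against a willingness-to-pay (WTP) threshold of 27,130 USD/QALY (three times
2018 Chinese per-capita GDP).

## Model structure

Patients enter one of two strategies: fruquintinib (states *on treatment*,
*BSC after discontinuation*, *dead*) or best supportive care alone (*BSC*,
*dead*). Each cycle lasts 28 days — 21 dosing days plus a 7-day break — and
the model runs to a lifetime horizon (260 cycles, about 20 years, or until
less than 0.1% of the cohort remains alive; under the default calibration
the residual alive fraction falls below the threshold after about 4–5
years).

Mortality is driven by each arm's overall-survival curve alone. The
conditional per-cycle death probability is

$$P(t) = 1 - \frac{S\big((t+1)\Delta\big)}{S(t\Delta)},$$

with $\Delta = 28/30.4375$ months per cycle, applied identically to both
alive states: the trial reports arm-level OS, not state-specific hazards, so
assigning differential mortality to the on-treatment and BSC states would
invent information. A consequence we exploit throughout testing is that the
telescoped alive fraction equals $S(t\Delta)$ to machine precision — the
discrete cohort never drifts from the fitted curve.

Overall survival is extrapolated with a two-parameter Weibull,
$S(t) = \exp(-(t/\lambda)^k)$, the family used to fit the trial curves, with
no cure fraction or hazard cap in the tail. Treatment discontinuation
(progression, grade 3/4 toxicity, intolerance) is exponential — a constant
per-cycle probability $1 - e^{-\ln 2 / m \cdot \Delta}$ for a median time on
treatment $m$ — applied to on-treatment survivors after death each cycle.
The within-cycle order (death before discontinuation) is second-order
because mortality is state-independent; `run_cohort()` exposes the
alternative order and the tests confirm the traces coincide.

## Survival calibration

The original analysis fitted Weibull curves to the published trial OS
figures, but neither the fitted parameters nor the curve coordinates are
available, and the model's effective median time on treatment is likewise
unpublished. `fruqcea` therefore treats these as calibration parameters and
states so openly, rather than presenting a pseudo-re-fit:

* each arm's Weibull **scale** is tied to its published median OS
  ($\lambda = \text{median}/(\ln 2)^{1/k}$), so simulated medians match
  9.3 / 6.6 months by construction;
* the BSC arm's **shape** is the single free parameter minimizing the summed
  squared relative error of the arm's discounted cost and QALYs against the
  published values (golden-section search over $k \in [0.8, 2.5]$);
* the treated arm's **shape and discontinuation median** are searched
  jointly (L-BFGS-B, two targets, two parameters), which fits the treated
  arm's published cost and QALYs essentially exactly.

The frozen optimum is $k = 1.285$ (treated), $k = 1.206$ (BSC), and a
discontinuation median of 3.53 months — just below the 3.7-month median PFS,
as expected when toxicity stops some patients before progression. The
implied cumulative-hazard ratio of the calibrated curves at 9.3 months is
0.66, close to the trial HR of 0.65, although the arms are fitted
independently and the HR is used only as this cross-check. An exponential
BSC curve ($k = 1$) would overshoot the published BSC QALYs by ~9%, which is
why the calibrated shapes exceed 1 (rising hazard). Calibration is fully
deterministic; rerunning `calibrate_shapes()` reproduces
`frozen_calibration()` and the residual errors are 0% (treated, both
targets) and ±0.4% (BSC arm).

## Economic accumulation

**QALYs.** Each cycle the standing cohort accrues
$\text{df}(t)\,\cdot\,\text{alive}(t)\,\cdot\,u\,\cdot\,28/365.25$ QALYs with
baseline utility $u = 0.66$. Grade 3/4 adverse events subtract a one-off,
incidence-weighted, duration-adjusted QALY loss at model entry
($\sum_i p_i\, d_i\, \text{days}_i/365.25$); hand-foot syndrome
(disutility 0.116, 14 days) and diarrhea (0.103, 5 days) carry decrements,
hypertension and thrombocytopenia are assigned zero. Disutilities are stored
as positive magnitudes and subtracted, avoiding sign ambiguity. AE
management costs are likewise one-off and incidence-weighted, matching the
trial-level incidence semantics of the inputs (they are whole-trial
incidences, not per-cycle rates).

**Costs.** Per-cycle costs are billed *in arrears*: at the end of each
completed cycle $t = 1, 2, \dots$, the cohort is charged
$\text{df}(t)\,[\text{on}(t)\cdot\text{drug}(t) +
\text{alive}(t)\cdot c_{\text{BSC}}]$, so model entry itself incurs only the
one-off AE cost, while QALYs accrue from cycle 0. This convention is the
package's resolution of an internal constraint of the published results: in
the BSC arm both cost and QALYs are proportional to the same discounted
person-time, so their ratio is fixed at
$1415.4 / (0.66 \cdot 28/365.25) = 27{,}974$ USD/QALY no matter what
survival curve is used — yet the published arm outputs imply 25,214 USD/QALY.
Shifting cost accrual by one cycle relative to QALY accrual (care is paid
for once delivered; life-time is lived from entry) reproduces both published
BSC outputs within 0.4%, and both treated-arm outputs exactly. The
alternative (`cost_cycle0 = TRUE`) is exposed as a flag.

Patients on fruquintinib receive supportive care concurrently
(`concurrent_bsc = TRUE` by default): without the concurrent BSC cost the
treated arm's total falls ~25% short of the published figure, so the
original model evidently charged it; the flag exposes the alternative.

**Drug pricing.** After the negotiation, 21 dosing days at 53.8 USD/5 mg
give 1,129.8 USD per cycle analytically, but the published per-cycle figure
1,128.8 is used as the default — the source's own number wins over its own
arithmetic. Before the negotiation the unit cost was 162.3 USD/5 mg
(3,408.5 per cycle) but, under the donation scheme, patients paid only in
their 1st, 2nd and 5th treatment cycles. The scenarios differ *only* in this
schedule, so their QALYs are bit-identical.

**Discounting.** Costs and QALYs are discounted at 3%/year with the exact
day-fraction exponent $(1+r)^{-t\cdot 28/365.25}$; cycle 0 is undiscounted.
No half-cycle correction is applied — the source model reports none, and the
cost-accrual convention above already settles how the first cycle is
weighted.

## Sensitivity analysis

**One-way.** Every registry parameter is set to its published low and high
bound (±20% of base for most; 0.59–0.735 for utility; 0.00–0.05 for the
discount rate) with all else at base, and the full ICER is recomputed — the
tornado diagram's data. Because all varied parameters are economic, the
survival traces are computed once and reused.

**Probabilistic.** 1000 Monte Carlo draws sample every Beta/Gamma row of the
registry independently; the discount rate (no published distribution) and
the survival parameters (none listed among the varied inputs) are held
fixed. Distributions are built by the method of moments with the published
range treated as a 95% interval (SD = width/3.92; width/4 is available via
the `z` argument): Beta matched to mean and SD for probabilities, utilities
and disutility magnitudes, Gamma for costs and durations. The construction
is mean-preserving, so PSA means converge to the base case, and supports
automatically respect the natural bounds (utilities cannot exceed 1, costs
cannot go negative). No correlation structure is imposed — none is
published. The cost-effectiveness acceptability curve reports, per WTP value
on a 0–120,000 grid, the fraction of draws with positive net monetary
benefit $\text{WTP}\cdot\Delta E - \Delta C$.

## Synthetic survival data

The trial's patient-level data are unavailable, so
`generate_pseudo_ipd()` produces Weibull event times with administrative
censoring at a fixed follow-up — the statistical structure the fitting stage
assumes. `km_from_ipd()` (product-limit, via the survival package) and
`fit_weibull_km()` (least squares on
$\log(-\log S) = k\log t - k\log\lambda$) close the loop: generated data at
$n = 5000$ recover the generating parameters within 5%, and the regression
fit agrees with maximum likelihood on the same data. The generator draws no
dropout process and no covariates; passing these tests shows the fitting
path is correct on clean Weibull data, not that real-world registry data
would be fitted well. The packaged base case does not depend on this path —
it anchors curves on published medians — but users with digitized curve
coordinates can substitute `fit_weibull_km()` output for the frozen shapes.

## Numerical choices

* Time: 1 cycle = 28 days = 28/30.4375 months; the source never states its
  day/month convention, so the constant is exposed via `model_constants()`.
* Horizon: 260 cycles; stop threshold $10^{-3}$ residual alive fraction.
* Calibration search: shape in $[0.8, 2.5]$, discontinuation median in
  $[1.8, 6]$ months, `optimize()` tolerance $10^{-9}$, L-BFGS-B
  `factr = 1e4`; no randomness anywhere in calibration.
* Degenerate inputs: ICERs with non-positive incremental cost or effect are
  reported as `NA` with a cost-effectiveness-plane quadrant label rather
  than thrown; Kaplan–Meier points at survival 0 or 1 are excluded from the
  log–log fit with a reported count; registry rows with `fixed`
  distribution or zero-width ranges are point masses in the PSA.
* Problem sizes used by the test suite: $10^6$ draws for distribution moment
  checks, $n = 5000$ pseudo-IPD with 20 replicates for parameter recovery,
  1000-draw PSA (plus one 4000-draw convergence check).

## Known limitations

* The pre-negotiation scenario's published cost is not exactly recoverable:
  billing the three paid donation-scheme cycles in arrears gives an ICER 7%
  below the published 70,952.6 USD/QALY, billing them upfront 6% above. The
  published value lies between the two conventions; `validate_model()`
  reports these rows as failing rather than widening their bands. The
  post-negotiation base case, the one-way-SA conclusion, and the CEAC
  landmarks are unaffected.
* Proteinuria is named among the grade 3/4 AEs with differential incidence,
  but no incidence, cost or disutility is published for it; the registry
  carries the four costed fruquintinib AEs plus BSC-arm hypertension.
* No background general-population mortality floor, no alternative
  parametric families, no societal costs, and prices are static — all
  inherited from the source analysis' scope.
* Arm OS curves are fitted independently; proportional hazards is not
  imposed and the trial HR serves only as a calibration diagnostic.
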