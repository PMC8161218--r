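---
title: "ETIS: model, calibration and synthetic-data design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ETIS: model, calibration and synthetic-data design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etis)
```

## The index

ETIS scores the thermal load on a sow as an *equivalent dry-bulb
temperature*: the air temperature plus, for each non-temperature factor,
the air-temperature increment with the same effect on heat load,

$$\mathrm{ETIS} = T + T_{rh} + T_u + T_f + T_r.$$

The four increments and their tunable coefficients are

| term | formula | default | meaning |
|------|---------|---------|---------|
| humidity | $a\,(RH-50)\,T$ | $a = 0.0006$ | null at 50 % RH; humid air hinders evaporative loss |
| velocity | $e\,u^{c}(T_s-T)$ | $e=-0.3132$, $c=0.6827$ | convective cooling, zero in still air or at $T=T_s$ |
| conduction | $d\,(f\,T_s-T)$ | $d=-4.79$, $f=1.0086$ | heat lost to the (concrete) floor, taken at air temperature |
| radiation | $r\,((T_s{+}273.15)^4-(T{+}273.15)^4)$ | $r=4.8957\times10^{-8}$ °C K⁻⁴ | long-wave exchange with surrounding surfaces |

with $T_s = 38$ °C a fixed reference skin temperature. Temperatures are
degrees Celsius throughout; the Kelvin shift appears only inside the
radiation term, exactly as in the published form. The velocity exponent
$c = 0.6827$ is the convective power law for a recumbent sow and is held
fixed during calibration.

Assumptions worth making explicit:

* **Indoor substitution.** Floor-surface and mean-radiant temperatures are
  taken equal to air temperature unless supplied (`floor_temp`,
  `radiant_temp` in `etis()`); this is the usual indoor-climate
  assumption for mechanically ventilated barns and is what collapses the
  general conduction/radiation forms onto functions of $T$ alone.
* **Conduction constants stored verbatim.** The fitted conduction pair
  $(-4.79,\,1.0086)$ does not follow from the published per-column
  regression ratios by any stated rule, and the final published equation
  applies a single radiation coefficient where the per-column fit produced
  two. We store the final equation's constants verbatim as the canonical
  default (`etis_params()`), expose the two-coefficient radiation variant
  (`r_rad_skin`, `r_rad_air`), and let `etis_calibrate()` re-derive
  parameters from data when the user prefers; re-deriving the published
  constants from the published ratios is not attempted.
* **Monotonicity envelope.** With the default constants the index is
  strictly increasing in $T$ over the summer-barn envelope
  ($T \in [21.9, 34]$ °C, any $RH \in [40, 90]$, $u \in [0, 0.29]$) and
  non-increasing in $u$ whenever $T < T_s$; both are enforced as tests,
  not assumed.

## Psychrometrics

The wet-bulb and dew-point conversions exist to serve the comparison
indices, not as a full psychrometric chart.

* **Saturation curve.** Magnus–Tetens base-10 constants
  $e_s(t) = 6.1078\cdot 10^{7.5t/(237.3+t)}$ hPa, declared valid on
  $[-20, 60]$ °C. This constant set is also the exponent structure
  printed inside the enthalpy index, which motivated choosing it over the
  (equally defensible) exponential-form Magnus sets; any choice moves
  comparison-index values in the second decimal. The enthalpy row as
  printed uses 273.3 in the exponent denominator where the Magnus form
  requires 237.3; we treat 273.3 as a typographical slip but reproduce it
  under `strict_paper = TRUE`.
* **Dew point** is the analytic inverse of the saturation curve and
  satisfies the round trip $e_s(T_{dp}) = (RH/100)\,e_s(T)$ to $10^{-4}$
  relative by construction.
* **Wet bulb.** The default method solves the Assmann psychrometer
  relation $e = e_s(t_w) - A(t_w)\,P\,(T - t_w)$,
  $A(t_w) = 6.62\times10^{-4}(1 + 0.00115\,t_w)$ °C⁻¹, by a safeguarded
  Newton iteration started from Stull's closed-form approximation, so the
  production value *is* the psychrometer solution (to $10^{-12}$) at any
  pressure, and the ordering $T_{dp} \le T_{wb} \le T$ holds exactly.
  The bare closed form (`method = "stull"`) is kept as the fast
  approximation; against the psychrometer solution it is good to a few
  tenths of a degree at moderate humidity but drifts to about 0.6 °C in
  the hot-dry corner of the barn envelope, which is why the default
  refines it rather than returning it.

## Comparison indices

The registry carries the eleven classical indices used for benchmarking
plus ETIS. Two printed formulas are not evaluable as typeset and were
reconstructed from the structure of their sources, each with a
`strict_paper` toggle preserving the literal grouping: effective
temperature, reconstructed as
$ET = T + 0.0015(RH-50)T - (42-T)(u^{0.66} - 0.2^{0.66})$ (velocity
correction null at the 0.2 m s⁻¹ reference), and the enthalpy index
(Magnus denominator, above). Fahrenheit-based THI variants (`thi_d`,
`thi_f`) convert internally and report on their native scale — their
published stress breakpoints are scale-specific, so silent conversion
would be worse than none. The black-globe index substitutes dry bulb for
a missing globe temperature, mirroring the indoor mean-radiant assumption.

Several THI formulations circulate; the classifier and the synthetic
physiology both default to the $0.8\,T + RH(T-14.4)/100 + 46.4$ variant
(`thi_b`), because the pregnancy-rate breakpoints 74/78/82 that anchor the
stress categories were established on that form. The choice is a
configuration key (`thi_variant`), not a constant.

## Calibration

`etis_calibrate()` regresses skin temperature on the index's own term
structure with $T_s$ frozen at 38 °C:

$$y = b_0 + b_1 T + b_2 (50T) + b_3 (RH\,T) + b_4\,u^{0.6827}(38-T)
      + b_5\,38 + b_6 T + b_7 (38{+}273.15)^4 + b_8 (T{+}273.15)^4.$$

The design is rank-deficient *by construction* — duplicate $T$ columns,
$50T \propto T$, two constant columns besides the intercept — so the
solver must not fail on collinearity: we return the minimum-norm
least-squares solution from an SVD with columns scaled to unit norm first
(the fourth-power column is $\sim 10^{10}$ larger than the others and
would otherwise dominate the rank test), report rank and a condition
indicator, and treat only *fitted values* as unique. $R^2$ is the squared
Pearson correlation between observed and predicted on the evaluated
subset (the scatter-plot definition), reported for both halves of a
seeded 70/30 split (`floor(0.7 n)` training rows; 1029 records give
720/309).

Mapping coefficients back to index parameters (`convention = "direct"`)
uses only identifiable combinations: $a = b_3$, $e = b_4$,
$r = -b_8$; the conduction coefficient comes from the total linear-in-$T$
mass, $d = 1 - 50a - (b_1 + 50 b_2 + b_6)$ — the $-50a$ term because the
humidity term $a(RH-50)T$ itself carries linear-$T$ mass — and the
reference factor from the residual constant mass. On noiseless
index-structured data this recovers the generating parameters to
$10^{-12}$; with a response that is an affine function of the index it
recovers them up to the response slope, which is recorded in the fit's
`mapping` metadata. `convention = "paper"` bypasses the mapping and
returns the published constant set, keeping the regression as
diagnostics. How the original analysis zeroed some collinear columns is
unstated in the source; any solution in the same affine family yields
identical predictions, so nothing downstream depends on the choice.

## Thresholds

Stress categories translate THI breakpoints through the linear map
$\mathrm{ETIS} = 0.3533\,\mathrm{THI} + 6.9249$. The source prints the
intercept with both signs in different places; the positive sign is
canonical here because only it reproduces the published category table
($0.3533 \cdot 74 + 6.9249 \approx 33.1$). Boundaries are rounded to one
decimal *before* comparison (the published table's precision; whether the
original rounded before or after comparing is unstated, so the choice is
documented rather than hidden), and classification uses lower-inclusive
half-open intervals: suitable $< 33.1 \le$ mild $< 34.5 \le$ moderate
$< 35.9 \le$ severe. Breakpoints are configuration — stress thresholds
shift with genotype and region — and `fit_thi_etis_map()` refits the map
from any paired THI/ETIS series.

## Synthetic barn data

The generator emulates a summer farrowing-barn campaign summarized by its
per-variable moments and ranges and by linear physiology-on-THI responses:

* **Marginals.** Truncated normals whose *underlying* location and scale
  are solved numerically so the truncated distribution hits the target
  mean/sd (naive clipping biases both). Targets: $T$ mean 28.7, sd 2.6 on
  $[21.9, 34.0]$ °C; $RH$ mean 65.8, sd 10.0 on $[40.4, 89.8]$ %; $u$
  mean 0.07, sd 0.07 on $[0, 0.29]$ m s⁻¹. The velocity targets are
  infeasible for any truncated normal on that interval (mean and sd that
  large cannot coexist under the left truncation); the solver's
  least-squares optimum — achieved mean ≈ 0.075, sd ≈ 0.067 — is used and
  recorded in the provenance attributes. Draws use inverse-CDF sampling
  on the upper tail, which keeps full precision even when the solved
  marginal is an extreme tail (the velocity marginal's survival
  probabilities are $\sim 10^{-12}$).
* **Dependence.** A Gaussian copula ties $T$ and $RH$ with correlation
  $-0.3$ by default — afternoon warming dries indoor air, so a modest
  negative dependence is the realistic sign — while velocity is
  independent. No joint structure was reported for the original campaign,
  so this is a visible knob (`t_rh_cor`), not a claim.
* **Physiology.** Skin temperature is an index-driven signal plus Gaussian
  noise. By default the index values are centered and scaled so the skin
  series hits mean 34.9 °C, sd 1.4 °C with squared correlation 0.6341 on
  the index — the campaign's skin moments and the training-set $R^2$ of
  the published index–skin regression — which anchors the generated skin
  series to reported quantities rather than to an arbitrary noise scale.
  An explicit `intercept`/`slope`/`sigma` model can be supplied instead
  (the parameter-recovery tests use slope 1, sigma 0). Respiration rate
  is $2.2137\,\mathrm{THI} - 135.98$ and core temperature
  $0.0454\,\mathrm{THI} + 34.873$, with noise standard deviations solved
  from the published squared correlations (0.1386 and 0.0972) and the
  *realized* THI variance via $R^2 = \sigma_s^2/(\sigma_s^2+\sigma^2)$;
  respiration is floored at 12 breaths min⁻¹, the campaign minimum, which
  costs the realized $R^2$ about 0.01.
* **What it does not emulate.** Diurnal and serial autocorrelation,
  spatial gradients along the barn, repeated measures on the same sows,
  and individual-animal effects. Passing tests therefore demonstrate that
  the pipeline recovers known structure from data with the right moments
  and response laws — not that it would do so under real-world
  autocorrelated, animal-clustered noise.

## Numerical choices and problem sizes

Degenerate inputs are errors, not silent values: zero-variance series in
correlations and map fitting, non-finite index values in classification,
infeasible moment targets in the generator, negative velocities, RH
outside its domain. The Newton wet-bulb iteration is clamped to
$[T_{dp}, T]$ each step, so it cannot leave the bracket. Seeds are
explicit everywhere randomness exists (split, generator); the physiology
stream uses `seed + 1` so environment and physiology draws are decoupled
but jointly reproducible.

The test suite exercises the invariants at sizes chosen to keep the whole
suite in a few seconds while leaving Monte-Carlo noise well below the
asserted tolerances: $2\times10^4$ records for generator moment checks,
$10^4$ random states for psychrometric and oracle-agreement properties,
20 seeded replicates for ranking stability, $n = 1000$ for parameter
recovery. The acceptance script uses $10^5$ records for the two
generator means.

## Known limitations

The index was calibrated for crated sows on solid concrete floors in a
mechanically ventilated barn; slatted floors, outdoor radiation and other
postures change the conduction and radiation terms in ways the constants
cannot absorb. The conduction pair $(-4.79, 1.0086)$ is preserved, not
explained; users re-calibrating on their own data should prefer
`convention = "direct"` and inspect the recovered parameters. The
synthetic generator's independence and normality assumptions are stated
above and are the main gap between passing tests and field validity.
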