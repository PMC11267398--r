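---
title: "Simulated paired respirometry: model, endpoints and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated paired respirometry: model, endpoints and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socresp)
```

## The experiment the package emulates

`socresp` models a paired intermittent-flow respirometry experiment on a
group-living fish with a dominance hierarchy. From each of 16 social
groups, the dominant female and the largest subordinate female are placed
in adjacent chambers for a 48 h baseline, split into a 24 h *social* block
(transparent walls, the pair can see each other) and a 24 h *isolation*
block (opaque barrier), in randomized order. At 48 h both fish are chased
to exhaustion for 3 min and air-exposed for 1 min, then returned to their
chambers for 6 h of recovery — 9 pairs recover in visual contact, 7 in
isolation, always matching the treatment of their second baseline block.
Oxygen is recorded on alternating 5 min sealed *measure* periods and
5 min *flush* periods, giving 324 oxygen-consumption measurements per fish
over the 54 h trial, under a 13:11 light:dark photoperiod with a 30 min
sunrise ramp.

Seven endpoints per fish summarise the trial, following standard
respirometry practice:

* **resting MO2** — mean of the 10 lowest QC-passing overnight rates per
  treatment block (µmol O2 h⁻¹);
* **routine MO2** — mean of the five consecutive periods starting 30 min
  after lights reach full intensity;
* **maximum MO2** — largest single-period rate in the first 60 min after
  the chase;
* **aerobic scope** — maximum minus routine MO2, identically;
* **time to AS50** — minutes from chase end until MO2 first falls to
  routine + 50% of aerobic scope;
* **time to 10% routine** — minutes until MO2 first falls to 1.10 ×
  treatment-matched routine;
* **EPOC** — trapezoidal integral of the excess of MO2 over routine across
  the recovery window (µmol O2).

## The generator

### True metabolic process

A fish of mass $m$ g has daytime routine rate
$R = a\,m^{b}$, with allometric coefficient $a = 10$ µmol O2 h⁻¹ g⁻ᵇ and
exponent $b = 0.8$, a typical teleost value; both are configurable. The
circadian cycle is a smoothed square wave: the rate ramps linearly between
$R$ and the overnight floor $0.7R$ over the 30 min sunrise and sunset
transitions. After the chase the rate decays single-exponentially,

$$\mathrm{MO}_2(t) = R + (\mathrm{MMR} - R)\,e^{-k\,(t - t_\mathrm{chase})},$$

from the fish's maximum $\mathrm{MMR} = \mu R$ back towards its
treatment-matched routine. The unaffected cells use $\mu = 6$ (a factorial
aerobic scope of 6, at the athletic end of the teleost range so that the
aerobic-scope contrasts sized below come out at their target magnitude)
and $k = 1.5$ h⁻¹, placing the 50%-scope landmark near 30 min and full
recovery near 2.5–4 h, comfortably inside the 6 h window.

Biological variation is lognormal and deliberately modest, consistent with
body mass explaining the large majority of between-fish variance in these
endpoints: a pair-level level multiplier (sd 0.05 on the log scale, shared
by both fish of a pair — this is what the pair random intercept in the
analysis models), plus fish-level multipliers on routine level, maximum
level and recovery rate (each sd 0.05).

### Observation model

Within each sealed measure period the chamber O2 concentration declines
linearly at rate $\mathrm{MO}_2(t_\mathrm{mid}) / V_\mathrm{eff}$, where
$V_\mathrm{eff}$ is the chamber volume minus the fish's displaced volume
(body density fixed at 1 g mL⁻¹), starting from air saturation
(247 µmol O2 L⁻¹ for 27 °C freshwater; the constant cancels out of every
rate). Each flush restores saturation. Readings are taken every 30 s
(default) with i.i.d. Gaussian noise of sd 0.15 µmol O2 L⁻¹, a typical
post-smoothing optode precision. The 0.5 L chamber keeps the worst-case
per-period O2 drawdown (at MMR) near 20% of saturation — the chamber a
practitioner would select — and gives overnight periods a slope
signal-to-noise that passes the default QC comfortably.

Evaluating the rate at the period midpoint makes the noiseless invariant
exact: every fitted slope equals $-\mathrm{MO}_2(t_\mathrm{mid}) /
V_\mathrm{eff}$ to relative 1e-9, which the test suite checks through the
full observation model.

### Randomness and reproducibility

One global seed; every pair, fish, trace and replicate derives its own
sub-stream via a deterministic hash (`substream_seed`), so any subset of a
study regenerates identically regardless of what else is simulated.

## Calibration of the packaged scenario

The packaged `paper_scenario` encodes a subordinate disadvantage that
appears only when the pair is in visual contact: a 7% deficit in measured
maximum MO2 and a 65% longer measured time to AS50, plus the pooled
aerobic-scope deficit (about 4%) that those parameters imply.

Two measurement facts make this calibration non-trivial. First, the
pipeline's "maximum MO2" is the largest *period* rate, and the first
recovery period's midpoint sits $t_1 = 2.5$ min after the chase ends, so
the measured maximum is $R(1 + (\mu - 1)e^{-k t_1})$ — attenuated below
the true peak by an amount that depends on $k$, and $k$ differs between
the cells being compared. Second, because the AS50 threshold is defined
from the *measured* maximum, the analytic crossing time shifts by exactly
$t_1$: the measured landmark is $t_1 + \ln 2 / k$.

`calibrate_paper_effects()` inverts this closed-form measurement model:
given the dominant-side baselines it returns the subordinate-social
multiplier ($\mu_s \approx 5.458$) and recovery rate
($k_s \approx 0.878$ h⁻¹) that make the *measured* within-pair contrasts
hit 7% and 65% in expectation. The calibration is analytic and runs at
configuration time; nothing is fitted to simulation output.

Two further design choices follow from the same logic:

* **Size-matched pairs.** The published percentages are mass-adjusted
  model contrasts, while the recovery checks use raw within-pair ratios.
  The generator therefore draws the subordinate's mass as the dominant's
  times a lognormal(0, 0.05) ratio — the "largest subordinate female"
  selection rule — so raw and mass-adjusted contrasts coincide.
* **The pooled aerobic-scope deficit is implied, not tuned.** With the
  maximum-MO2 deficit confined to the social cells and the 9/7 recovery
  split, the pooled within-pair aerobic-scope deficit is mechanically
  $\tfrac{9}{16}\cdot 7\% \cdot \mathrm{MMR}/(\mathrm{MMR}-R) \approx
  4.4\text{–}4.8\%$ (the small isolation-side Jensen term pulls it down
  slightly), matching the published 4% within its tolerance. It cannot be
  moved independently once the other conditions are fixed.

The `null_scenario` is identical except that every multiplier is equal:
dominants and subordinates differ only through mass.

## Trace processing and QC

Slopes are ordinary least squares per period after discarding a 30 s
mixing window, computed vectorised over all fish and periods from centred
cross-products (numerically stable at trial-clock time scales, and
identical to `lm()` to 1e-9, which is tested). A period passes QC when
r² ≥ 0.90, the rate is non-negative and at least 3 readings remain.
Degenerate flat periods get slope 0 with r² defined as 0, so they fail QC
rather than passing vacuously. Negative post-QC rates are excluded, not
truncated, with counts logged; a fish losing more than half its periods
raises a warning. The real study's exact QC rules live in its
supplementary materials, so these defaults are declared, configurable
(`qc_config()`) and logged rather than inferred. A constant-rate
background-respiration subtraction is exposed as a hook (default 0); blank
chambers are not part of the design.

## Numerical conventions in the endpoints

* Each period's rate is stamped at the period midpoint; recovery
  thresholds are crossed by linear interpolation between midpoints.
* First crossing counts (with a `sustained_n` option to require N
  consecutive sub-threshold periods); a series starting below its
  threshold yields 0 by convention.
* Recovery times that never cross are recorded as censored at the 360 min
  window end and enter the models as missing, with counts logged — no
  imputation.
* Resting MO2 is the *mean* of the 10 lowest overnight values (the field's
  usual reading of "calculated using the 10 lowest"); "overnight" is
  lights-off to lights-on of the block's dark phase.
* If a QC failure interrupts the routine window, the window slides to the
  first run of five consecutive passing periods after the anchor.
* EPOC clips the excess at zero before integrating, uses the
  treatment-matched routine as its baseline (mirroring the 10%-routine
  metric), integrates from the first observed midpoint (the unobserved
  first 2.5 min are not extrapolated) and stops at the interpolated return
  to routine or the window end, whichever is earlier.
* The maximum-MO2 search window defaults to the first 60 min of recovery;
  with a monotone decay the first period always wins, so the window only
  matters under noise.

## The statistical layer

Each endpoint is analysed with a Gaussian linear mixed model (REML, via
`lme4`/`lmerTest`): status, treatment, their interaction and centred
natural-log body mass as fixed effects, under sum-to-zero contrasts.
Repeated-measures endpoints (resting, routine; two values per fish) start
from fish-within-pair random intercepts, single-measure endpoints from a
pair intercept. A fit with a variance component on the zero boundary is
reduced along the ladder fish-within-pair → pair-only → none, with all
fits retained for side-by-side comparison; the terminal rung is ordinary
least squares. Type-III F tests use Satterthwaite denominator degrees of
freedom (the `lmerTest` default) for mixed fits and residual df for the
OLS fallback. Effect sizes are partial eta-squared,
$\eta_p^2 = F\,df_1 / (F\,df_1 + df_2)$, and cell contrasts are estimated
marginal means at the mean covariate with Tukey-adjusted p values
(`emmeans`). A constant body mass would alias the covariate, so degenerate
inputs drop it rather than fitting a rank-deficient design. No
multiplicity correction is applied across the seven endpoint models, and
α = 0.05 throughout.

In degenerate-variance limits the whole stack collapses to textbook
two-way ANCOVA, which the tests verify against `stats::anova` and OLS
oracles.

## What the simulation experiments show — and what they do not

`effect_recovery_study()` (200 replicate studies, within-period sampling
coarsened to 60 s — attenuation of the measured maximum depends on period
timing, not sampling density) recovers the three injected contrasts at
their target magnitudes, and `interaction_type1_sim()` (1000 metric-level
replicates, bypassing trace synthesis) shows the interaction F test
holding its nominal 5% size under the null. These sizes keep the default
runs to a few minutes; they are stated here as the package's chosen
problem sizes.

The generator emulates the protocol's structure, kinetics and observation
physics, not everything about real fish: no habituation drift after
chamber entry (the real first-block routine window sits before full
habituation), no background microbial respiration, no temperature
dynamics, no activity bursts or spontaneous movement spikes, no two-phase
EPOC, and recovery is exactly single-exponential. Passing parameter
recovery on this generator therefore demonstrates that the pipeline's
estimators are consistent with their definitions under the stated model —
it does not validate the biological model itself, and real traces would
exercise QC paths (outliers, drift) that the synthetic data rarely
trigger.

## Known limitations

* Real published F and p values for this design depend on the deposited
  raw data, which the package does not ingest; its statistical layer is
  validated against arithmetic identities, oracle equivalences and
  simulation instead.
* Censored recovery times are dropped, not modelled; with heavy censoring
  the recovery-time models would lose power and balance.
* The chamber model assumes instant mixing after the 30 s discard window
  and instant re-saturation at each flush.
* Satterthwaite denominator dfs can fall below 1 in very small designs;
  they are reported as computed.
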