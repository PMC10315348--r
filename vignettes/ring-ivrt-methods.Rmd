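---
title: "Methods: release-testing analysis for matrix-type vaginal rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: release-testing analysis for matrix-type vaginal rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringrelease)
```

## The problem

A matrix-type vaginal ring disperses a poorly water-soluble drug (here the
antiretroviral dapivirine, a weak base: pKa 5.30, log P 5.35, 24.4 mg per
ring) through a silicone elastomer torus and releases it over 28 days of
wear. In vitro release testing (IVRT) immerses rings in a release medium,
samples it on a fixed schedule, and quantifies drug by HPLC. Two protocol
families are supported:

* **monophasic** — 100 mL of an isopropanol/water (IPA/water) mixture,
  sampled daily with *complete* discard-and-refill; no sampling on
  weekends, so Friday refills use 200 mL that stays in place for a 3-day
  interval;
* **biphasic** — 100 mL aqueous buffer (pH 7 or pH 4.2) under a 20 mL
  octanol overlay acting as an absorptive "tissue" sink; every day 1.0 mL
  is withdrawn from *each* phase and replaced with drug-free medium
  (octanol samples are diluted 1:20 before injection).

The analysis questions are always the same: how much drug has been
released, at what rate, by what mechanism, and were the measurements made
under sink conditions that make the mechanism interpretable.

## From concentrations to cumulative release

Measured concentrations are the raw signal; cumulative release must be
reconstructed with the protocol's bookkeeping.

**Full replacement.** All drug in the vessel at event $i$ was released
during interval $i$, so the interval amount is $C_i V_i$ and cumulative
release is the running sum (`reconstruct_monophasic()`). Weekend intervals
keep their true 3-day length; daily rates divide by the interval length,
and all regressions use the true event times, so the weekend ambiguity
cannot bias slopes.

**Partial sampling.** With constant phase volume $V$ and daily aliquot
$v_s$ replaced by blank medium, the cumulative amount attributable to a
phase at event $n$ is the drug present plus everything previously removed:

$$A_n = V C_n + \sum_{i<n} v_s C_i$$

(`reconstruct_biphasic()`). Measurement noise can make $A_n$ decrease;
decreases are flagged (`qc_decreasing`), never silently forced monotone.
`invert_to_concentrations()` is the exact inverse of both bookkeeping
schemes and underpins the round-trip tests.

HPLC calibration (`calibration_curve()`) uses weighted least squares with
$1/x^2$ weights by default — the common chromatographic convention when
assay variance grows with concentration — with $1/x$ and unweighted
variants available. Back-calculated concentrations are floored at zero and
below-range responses flagged rather than rejected.

## Kinetic models and inference

Three standard laws are fitted by OLS on transformed axes
(`fit_zero_order()`, `fit_higuchi()`, `fit_peppas()`), all sharing one
regression core (`fit_linear()`) that reports Student-t 95% confidence
intervals on $n-2$ degrees of freedom and $R^2$:

* zero order $Q = at + b$ — partition-controlled (solubility-limited)
  release;
* Higuchi $Q = a\sqrt{t} + b$ — diffusion out of the drug-loaded matrix;
* Korsmeyer–Peppas $M_t/M_\infty = k t^n$, fitted as
  $\log_{10}$ fraction vs $\log_{10} t$ (slope $n$, intercept
  $\log_{10} k$).

Design choices, made once:

* **Time convention.** $t$ is in days, $t=0$ at immersion, samples at
  end-of-interval event times; no $t=0$ point enters any fit.
* **Peppas window.** Default is every point with fraction in $(0,1]$
  (matching how 28-day ring data are conventionally summarised); the
  textbook restriction to fractions $\le 0.6$ is available via
  `max_fraction`. Non-positive fractions are excluded with a warning.
  Fits default to replicate-mean profiles, with per-ring fits available by
  passing individual profiles.
* **Basis selection.** `select_time_basis()` picks the higher $R^2$; exact
  ties resolve to Higuchi because matrix diffusion is the expected
  mechanism for this dosage form. A user override is honoured by the
  pipeline and recorded.
* **Negative intercepts** (e.g. a Higuchi fit with $b < 0$ from a
  suppressed burst) are reported as-is; clamping to zero happens only when
  curves are evaluated for simulation or display.
* **Interval correction.** `correct_interval_with_model()` replaces the
  measured increments inside an anomalous window (e.g. a dip caused by a
  mis-prepared medium batch) with model-predicted increments and reports
  the day-28 delta.
* **Replicate exclusion.** `exclude_replicates()` refits after dropping
  named rings and flags retained rings whose residuals from the pooled fit
  exceed 3 robust (MAD-based) SDs — the signature of a ring that touched
  the octanol layer.

## Sink conditions and mechanism

`assess_sink()` compares each daily sample concentration (not a modelled
peak) with the medium's saturation solubility: strict sink requires all
ratios $< 10\%$, relaxed $< 30\%$. `classify_mechanism()` is a total,
deterministic rule grid: off-sink, a better linear fit means
partition-controlled release and the Peppas exponent is suppressed with a
warning (it is not mechanistically interpretable there); under sink
conditions $n$ is read against a Fickian reference of 0.5 with band
half-width $\delta = 0.05$ — within the band is Fickian matrix diffusion,
$(0.5+\delta, 1)$ anomalous transport, $\ge 1$ case-II, below the band
quasi-Fickian. The reference 0.5 (rather than the thin-film/cylinder
value 0.45) follows the field's usage for these rings; both the reference
and $\delta$ are parameters.

`scale_volume_for_target()` implements the transparent linear-scaling
extrapolation `volume * target / release` for asking what aqueous volume
would match an in vivo 28-day release target; it deliberately makes no
claim beyond that linear assumption.

## Weak-base physicochemistry

For a monoprotic base: protonated fraction
$f = 1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$, total solubility
$S = S_0 (1 + 10^{\mathrm{p}K_a-\mathrm{pH}})$, and distribution
coefficient $\log D = \log P - \log_{10}(1+10^{\mathrm{p}K_a-\mathrm{pH}})$
under the standard assumption that only the neutral species partitions
(no ion-pair term; none is measurable from the available data). All logs
are base 10. Note a documented model deviation: the measured pH 4.2 / pH 7
solubility ratio for dapivirine (about 28×) exceeds the
Henderson–Hasselbalch prediction (about 13.6×), plausibly a buffer-species
effect; the package reports the model value and ships the measured ladder
separately (`dapivirine_properties()`).

Aqueous pKa extrapolation from mixed-solvent titrations
(`yasuda_shedlovsky_extrapolate()`) regresses
$\mathrm{p_sK_a} + \log_{10}[\mathrm{H_2O}]$ on $1/\varepsilon$ and
evaluates at the pure-water point. Instrument vendors differ on the exact
abscissa, so a plain percent-co-solvent extrapolation is available via
`method = "fraction"`. Pure-water constants default to
$\varepsilon = 78.3$ and $[\mathrm{H_2O}] = 55.5$ M and are configurable;
they matter only through the evaluation point. Solubility between
tabulated co-solvent levels is interpolated log-linearly in co-solvent
percent (`cosolvent_solubility()`), because the ladder spans four orders
of magnitude.

## What the simulators emulate

The simulators exist so every pipeline stage is testable end-to-end with
known ground truth; their defaults are the study conditions the analysis
assumes.

**Monophasic** (`simulate_monophasic()`): true release follows the Higuchi
law, but each interval's release is capped at $\varphi S V_i$ — the amount
that would bring the freshly replaced medium to a fraction $\varphi$ of
saturation. The cap reproduces the partition-controlled linear regime in
poor solvents and never binds in good ones, so lowering $S$ through the
measured IPA/water ladder walks the fitted basis from Higuchi to zero
order. The default $\varphi = 0.5$ is a calibration against the measured
ladder — water-only release of 7.55 µg/day vs $S \cdot V = 8.4$ µg/day and
10/90 release of 25.0 vs 55.6 — not a mechanistic claim: it subsumes
boundary-layer hydrodynamics the simulator does not model.

**Biphasic** (`simulate_biphasic()`): two compartments between daily
events,

$$\frac{dM_b}{dt} = k_r (S_{aq} V_b - M_b) - q_t\left(C_b - \frac{C_o}{D}\right),
\qquad \frac{dM_o}{dt} = q_t\left(C_b - \frac{C_o}{D}\right),$$

with $D$ the octanol/buffer distribution ratio from the drug's log D at
the buffer pH. Defaults $k_r = 1$/day and $q_t = 400$ mL/day were chosen
once so that, with the *measured* acetate-buffer solubility
(0.499 µg/mL), steady-state octanol accumulation is ≈ 40 µg/day — the
scale of the adjusted pH 4.2 reference slope (40.94 µg/day). Integration
is classical fixed-step RK4 at 100 substeps/day, doubled automatically
until the day-28 solution is step-converged to 0.1% (fixed-step for
bit-reproducibility; mass balance holds exactly by construction and is
asserted). Daily events remove the aliquot at the pre-removal
concentration and replace it with blank medium. The optional anomaly adds
a constant µg/day directly into octanol from a start day, mimicking
accidental ring–octanol contact, and is what the divergence-flagging in
`exclude_replicates()` is tested against.

**Noise** is multiplicative lognormal on concentrations with unit mean,
default CV 3% (typical HPLC repeatability); the CI-coverage property is
checked at CV 5%. All randomness flows from a single seed.

What the simulators do *not* capture: in-flask hydrodynamics (60 rpm
orbital shaking), matrix depletion physics beyond a loading cap, drug
degradation, octanol–buffer mutual solubility, and the buffer-species
solubility effects noted above. Passing round-trip tests therefore
demonstrates correctness of the *bookkeeping and inference*, not fidelity
of the mechanistic model to any particular experiment.

## Problem sizes and numerical conventions

Tests and the acceptance script run at the study's natural scale: 28-day
schedules (20 monophasic events with the weekend pattern, or 28 daily
events), 4 replicate rings, 500 simulations for the CI-coverage check.
Degenerate inputs are errors, not guesses: fewer than 3 points or constant
abscissae for any fit, mixed replacement modes in one reconstruction,
decreasing inversion targets, excluding every replicate. A constant
response is assigned $R^2 = 1$ only when residuals vanish. Reports print
mg to 3 significant figures; all internal arithmetic is in µg and days.

## Worked example

```{r example, eval = FALSE}
protocol <- monophasic_protocol()
sim <- simulate_monophasic(protocol, a = 2022, b = -238.5,
                           solubility = 645, noise_cv = 0.03, seed = 11)
profiles <- lapply(sim$series, reconstruct_monophasic,
                   protocol = protocol, loading = 24400)
pooled <- pool_replicates(profiles)
select_time_basis(pooled)$basis        # "higuchi"
fit_peppas(pooled, loading = 24400)    # n ~ 0.53, log10 k ~ -1.14
```

The same flow is scripted by `run_pipeline()` (see the README), which
writes the series, pooled profile, fit tables, sink/mechanism report and a
provenance manifest for a configuration block, and is wrapped by the thin
command-line script in `inst/exec/ivrt.R`.

## Known limitations

* The mechanism classifier inherits every caveat of the Peppas exponent:
  it assumes one dominant mechanism over the fit window and a known
  loading.
* Linear volume scaling is an extrapolation device, not a hydrodynamic
  model.
* The biphasic simulator's $k_r$/$q_t$ are effective rates; they are not
  identifiable separately from release data alone and are not meant to be
  fitted.
* Ion-pair partitioning and activity corrections are ignored throughout;
  at ionic strengths far from the titration conditions the pKa-derived
  quantities drift accordingly.
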