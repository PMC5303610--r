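---
title: "Methods: simulating and classifying radial pulse waves with pulseloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying radial pulse waves with pulseloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseloop)
```

## The system being modelled

`pulseloop` is an in-silico counterpart of a bench-top mock circulatory loop
used to study how the four classical pulse qualities of oriental pulse
diagnosis — depth, rate, shape and strength — arise from ordinary
hemodynamics. The physical loop consists of:

* a **piston pump** driven through a slider-crank mechanism (one crank
  revolution = one beat), ejecting through a check valve so that only the
  advancing stroke delivers flow;
* a **two-segment elastic vessel tree**: a silicone "aorta" and a silicone
  "radial artery", much stiffer than human vessels, so waves travel several
  times faster than in vivo;
* an adjustable **peripheral resistance** and constant-head reservoirs
  closing the loop;
* a **glycerin–water working fluid** matched to blood's density and
  viscosity; and
* a **tonometric measurement rig** that loads the radial tube with stacked
  weights and records the transmitted pulse amplitude at each load — the
  applied-pressure/amplitude ("P-H") curve of pulse-taking devices.

Because the tubes are stiff, the loop preserves the *superposition time* of
the reflected wave rather than vessel lengths: a mock tube is lengthened by
the ratio of mock to physiological pulse wave velocity (PWV), so the
reflected wave returns after the same delay as in the body. With an aortic
PWV of 18 m/s versus 5 m/s physiological, the 0.5 m human aorta becomes a
2.0 m tube (`design_mock_length(0.5, 5, 18, "nearest_integer_ratio")`); with
21 m/s versus 10 m/s the ~0.5 m arm path becomes 1.0 m.

## Wave model

The simulator is a linear delay-line (d'Alembert) superposition model. The
pump flow $Q(t)$ is computed from the crank kinematics,

$$x(\theta) = r\cos\theta + \sqrt{l^2 - r^2\sin^2\theta},\qquad
  Q = A_p \max(0, -\dot x),$$

so the ejected volume per beat is exactly the swept volume $2 r A_p$
(60 mL for the default $r = 0.03$ m, $A_p = 10^{-3}$ m²). $Q$ is split into
its cycle mean $\bar Q$ and pulsatile remainder $\tilde Q$. The radial-site
pressure is

$$P(t) = P_{ven} + R_p \bar Q
  + Z_c\Big[\tilde Q(t-\tau_f)
  + \sum_{k=1}^{n} \Gamma^k \Gamma_h^{k-1} \tilde Q(t-\tau_f-k\,\Delta t)\Big]
  + \mathrm{rebound}(t),$$

where $\tau_f$ is the forward transit time to the measurement site,
$\Delta t = 2L_a/c_a$ the aortic round-trip (superposition) delay,
$\Gamma = (R_p - Z_c)/(R_p + Z_c)$ the peripheral reflection coefficient,
$\Gamma_h$ a lumped closed-valve reflection coefficient for re-reflections,
and $Z_c = s\,\rho c_a / A_a$ the (scaled) aortic characteristic impedance.
The rebound term is a damped half-sine injected at each valve closure,
producing the incisura notch and dicrotic wave. The model is linear,
one-dimensional and deterministic; it contains no convective nonlinearity,
no viscoelastic wall, and no venous dynamics (the reservoirs are a constant
back-pressure).

The delay-line solution is validated in the test suite against an
independent finite-difference solution of the linear 1-D wave equation
(Lax–Wendroff transport of the Riemann invariants $p \pm Z_c q$ with a
flow-source inlet and resistive termination); the two agree to about 0.01%
RMS, far inside the 2% acceptance bound. The comparison is run with
$\Gamma_h = 0$: the re-reflection series above is a lumped phenomenology —
an exact partially-reflecting flow inlet would carry coefficients
$(1+\Gamma_h)\Gamma^k\Gamma_h^{k-1}$ — so only the physically exact
single-reflection configuration is compared against the oracle.

### Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `crank_radius_m` | 0.03 m | with `piston_area_m2 = 1e-3` m² realises the 60 mL stroke volume; varied (0.02/0.04) by the strength presets |
| `systole_fraction` | 0.32 | fraction of the beat occupied by ejection (see below) |
| `rpm` | 75 | beats per minute; 60/90 for the rate presets |
| aorta | 2.0 m, 18 m/s | mock aorta; 2.4/1.6 m for the shape presets |
| radial | 1.0 m, 21 m/s | mock arm segment; measurement site 0.8 m along it |
| `n_reflections` | 2 | retained reflected terms (see below) |
| `heart_reflection` | 0.5 | lumped closed-valve re-reflection coefficient |
| `valve_rebound_fraction` | 0.1 | rebound amplitude relative to the forward-wave amplitude |
| `impedance_scale` | 0.3508 | calibration factor on $\rho c/A$ (see below) |
| `transfer_width_mmHg` | 80 | Gaussian width of the tonometric transfer function |

**Systole fraction.** A constant-speed crank would eject for half the beat.
The loop's designed piston motion (its crank profile was derived by inverse
kinematics from a desired motion) is represented by a two-speed cam: the
advancing stroke is completed in a fraction 0.32 of the beat. The value is
constrained by the observed physics: the reflected wave (delay 0.2222 s for
the 2.0 m aorta) must arrive *within* ejection at 60 bpm but *after* it at
90 bpm, which requires the fraction to lie in (0.222, 0.333). 0.32 also
places the normal 75 bpm arrival late in systole and the 2.4 m-aorta
arrival after it, matching the described waveforms.

**Truncation depth and heart-end reflection.** The delay line carries no
per-transit attenuation, so deep re-reflections must be truncated to play
the role of the loop's viscous damping. With three or more retained terms
the third re-reflection (delay $3\Delta t \approx 0.67$ s) wraps around the
beat at 90 bpm and lands on the next systolic peak, inflating pulse pressure
by tens of percent — behaviour the physical loop does not show (its maximum
pulse amplitude is essentially constant across the rate and shape
manipulations). Defaults: two terms, $\Gamma_h = 0.5$.

**Calibration.** The loop's absolute pressures are set by two constants,
chosen once and documented as properties of the simulated bench (not
physiological claims — the stiff loop runs well above physiological
pressure, as its 50–400 mmHg hold-down protocol implies): the normal-state
cycle mean is 145 mmHg (near the centre, ~150.6 mmHg, of hold-down steps
1–5, so the normal P-H curve peaks centrally and its CFS is near zero), and
the normal pulse pressure is 40 mmHg, realised by the frozen
`impedance_scale = 0.3508076` computed with `calibrate_impedance_scale()`.
The floating and sunken presets shift the mean by ∓60 mmHg through the
peripheral resistance alone.

## Tonometry and the P-H curve

The hold-down emulation maps each cumulative weight step to an applied
pressure $k\,mg/A$ (≈50.17 mmHg per 60 g step over 0.88 cm²) and models the
transmitted amplitude as

$$H(P_a) = \mathrm{PP} \cdot \exp\!\big(-(P_a - \bar P)^2 / 2w^2\big),$$

pulse pressure times a unimodal, symmetric transfer of the transmural
pressure. This encodes exactly the three empirically established P-H
behaviours — the peak sits where applied pressure equals mean pressure, a
mean-pressure change slides the curve rigidly, and a pulse-pressure change
scales only the heights — and nothing more. The Gaussian form and its 80
mmHg width are modelling choices; the width trades off how steeply the CFS
statistic responds to mean-pressure shifts and is exposed in the API.

The depth statistic is $\mathrm{CFS} = (Y_1+Y_2)/2 - (Y_4+Y_5)/2$ over the
first five steps, with the conventional ±15 decision threshold. Under the
default calibration the floating/normal/sunken presets score +28.4 / +2.9 /
−25.4 (the physical loop reported +23 / +2 / −17.5; exact magnitudes depend
on that loop's unpublished pressure calibration, so only the threshold
relations are meaningful). Strength is quantified by pulse force (max H)
and pulse power (trapezoidal area of the P-H curve over the measured range,
with no extrapolation outside it).

## Feature extraction and classification

The feature extractor is model-free: it detects the beat period by
autocorrelation (unbiasing the finite-sample taper, refining the peak
parabolically — detected rates are within 0.05% of the crank speed),
phase-averages beats after a two-beat settling window, aligns the average
beat at its foot, and measures the systolic peak, the incisura and the
pulse pressure. The incisura is located as the deepest local minimum
between the systolic peak and the next prominent (>5% of pulse pressure)
local maximum — i.e. the notch preceding the dicrotic/reflected peak. A
plain "deepest minimum before 60% of the beat" rule is used as fallback
when no secondary peak exists; it cannot be the primary rule here because
the loop's strong reflections create late lobe-junction dips deeper than
the true notch. The reflected-wave arrival is taken from the generating
model's known delay when available, otherwise estimated from the most
prominent fourth-derivative maximum after the systolic peak (a coarse
shoulder detector, adequate for waveforms with a distinct reflected bump).

Classification is per axis:

* **depth** — CFS against ±15;
* **rate** — detected bpm rounded to the nearest integer, slow ≤ 60,
  rapid ≥ 90;
* **strength** — pulse force against a reference force (the normal preset's)
  with a ±25% dead-band; the literature for this axis offers no numeric
  criterion, so the dead-band is an explicit configurable stand-in;
* **shape** — string-like when the reflected arrival is advanced by more
  than 10% relative to a reference superposition delay (the normal 2.0 m
  aorta's 0.2222 s), falls within systole and the incisura is high (≥0.5 of
  pulse pressure); slippery when the arrival is delayed by more than 10%,
  falls after systole and the incisura is low (≤0.25).

The reference-delay comparison in the shape rule deserves a note: a short
aorta at normal rate and a normal aorta at slow rate produce waveforms that
are *time-scaled copies* of each other (identical arrival-to-systole
ratios), so no rule based purely on timing relative to the beat can
separate string-like from slow, or slippery from rapid — their shapes
genuinely coincide; they differ only in absolute rate. The classifier
therefore anchors shape to the absolute superposition delay, exactly as
strength is anchored to a reference force.

With these rules every one of the nine presets classifies to its intended
label on its manipulated axis and "normal" on the other three. The margins
worth knowing: the rate presets' CFS values land at +13.7 (slow) and −14.4
(rapid) — inside, but near, the ±15 depth band, because changing the rate at
fixed resistance also moves the mean pressure (the loop's mean is
resistance × mean flow); and the slow preset's pulse force is 78% of the
reference, just above the 75% vacuous boundary, because peak flow scales
with crank speed.

## What the simulation does and does not establish

Passing tests show that the *mechanisms* — mean pressure shifting the P-H
peak (depth), superposition timing reshaping the waveform (shape), pulse
pressure scaling the P-H heights (strength), rate being rate — are
correctly realised and mutually decoupled in a linear wave model with
idealised valves, exact weights and no measurement noise. They do not show
that the model reproduces any particular physical loop quantitatively:
absolute pressures are calibration constants, the tonometric transfer width
is a modelling choice, skin/tissue mechanics are absent, and real devices
add sensor noise and nonlinearity. The optional noise hook
(`measure_ph_curve(..., noise_sd, seed)`) exists for robustness
experiments, not realism.

## Numerical choices

* Sample rate 1000 Hz, duration 8 s (a whole number of beats at 60, 75 and
  90 bpm; ≥6 beats for period detection). All delayed flow terms are
  evaluated analytically from the periodic crank flow — no interpolation.
* Inverse kinematics by `uniroot` to |Δx| < 1e-9 m (tolerance 1e-13 on the
  bracket); the returning branch is the mirror 2π − θ of the advancing root.
* Quadrature checks of ejected volume use trapezoidal sums on 160k-point
  grids (the flow has slope discontinuities at valve events, so spectral
  accuracy is not available; the grid keeps the error below 1e-9 m³).
* The finite-difference oracle runs at Courant number 0.95 with 600 cells;
  the steady-state beat is compared.
* Degenerate inputs: a pulseless waveform yields an all-zero P-H curve (and
  CFS 0, "normal"); waveforms without detectable periodicity or shorter
  than three beats raise analysis errors; impossible geometry (rod shorter
  than crank), out-of-range compositions and non-monotone CSV time axes are
  rejected at construction with specific messages.
* Fluid composition is interpreted as glycerin **mass** fraction. This is
  the only reading under which the two published anchors of the working
  fluid are simultaneously reproducible: Cheng's (2008) correlation gives
  3.20 cP at w = 0.37 and 20 °C, and the empirical (contraction-aware)
  density fit gives 1.092 g/cm³. A volume-fraction reading with ideal
  mixing matches the density (1.095) but puts the viscosity near 4.1 cP,
  far outside the fluid's stated 3.2 cP. Density uses a quadratic in mass
  fraction anchored at handbook values for water, the 50 w/w mixture and
  glycerol at 20 °C, with a linear thermal-expansion correction; viscosity
  uses Cheng's exponential blending rule (stated validity 0–100 °C).
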