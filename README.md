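# pulseloop

An in-silico mock circulatory loop for studying how the four classical pulse
qualities of oriental pulse diagnosis — **depth**, **rate**, **shape** and
**strength** — arise from ordinary hemodynamics.

Clinically these qualities are felt at the radial artery under varying
finger pressure; bench studies quantify them with a pulse-taking device that
records the transmitted pulse amplitude *H* at stepped applied pressures *P*
(the **P-H curve**). `pulseloop` simulates the whole chain:

* a **slider-crank piston pump** (crank radius *r*, rod *l*, piston area
  *A<sub>p</sub>*; one revolution per beat) ejecting through an ideal check
  valve: `Q = A_p · max(0, −dx/dt)` with
  `x(θ) = r cosθ + √(l² − r² sin²θ)`, so exactly `2 r A_p` (60 mL by
  default) is ejected per beat;
* a **two-segment elastic vessel network** (mock aorta 2.0 m at 18 m/s,
  mock radial/arm 1.0 m at 21 m/s) terminated by a peripheral resistance
  *R<sub>p</sub>*, solved as a linear delay-line superposition: the forward
  wave `Z_c Q̃` plus reflections attenuated by
  `Γ = (R_p − Z_c)/(R_p + Z_c)` and delayed by the aortic round trip
  `Δt = 2 L_a / c_a`, plus a valve-closure rebound transient (incisura and
  dicrotic wave);
* a **glycerin–water working fluid** model (37 w/w: 1.09 g/cm³, 3.2 cP at
  20 °C) and **Moens–Korteweg** helpers `c = √(E h / ρ D)`;
* a **tonometric hold-down emulation** (eight cumulative 60 g weights on
  0.88 cm², ≈50 mmHg per step) producing P-H curves via a Gaussian
  transmural transfer `H = PP · exp(−(P_a − P̄)²/2w²)`;
* **quantification and classification**: the coefficient of floating and
  sunken pulse `CFS = (Y₁+Y₂)/2 − (Y₄+Y₅)/2` with the ±15 decision band,
  pulse force (max H) and pulse power (P-H area), autocorrelation beat-rate
  detection, incisura and reflected-arrival features, and per-axis labels.

Nine named presets encode the bench experiments: `normal`, `floating` /
`sunken` (mean pressure via *R<sub>p</sub>*), `slow` / `rapid` (60 / 90
rpm), `slippery` / `string_like` (aorta 2.4 / 1.6 m, i.e. delayed /
advanced reflection), `vacuous` / `replete` (stroke volume via crank radius
at constant mean).

## Worked example

```r
library(pulseloop)

wave <- simulate_preset("floating")
wave
#> <pressure_waveform> 8000 samples at 1000 Hz (8 s), mean 85.15 mmHg, pulse pressure 40 mmHg

round(measure_ph_curve(wave)$amplitude_mmHg, 2)
#> [1] 36.35 39.29 28.65 14.10  4.68  1.05  0.16  0.02

ref <- pulse_force(measure_ph_curve(simulate_preset("normal")))
classify_preset("floating", ref)
#> <pulse_report>
#>   depth   : floating    (CFS 28.4)
#>   rate    : normal      (75.0 bpm)
#>   shape   : normal
#>   strength: normal      (force 39.29 mmHg, power 5324 mmHg^2)
```

The floating preset runs at a low mean pressure (85 mmHg), so its P-H curve
peaks at the second hold-down step (~100 mmHg applied) and decays: the pulse
is felt best under light pressure. Its CFS of 28.4 clears the +15 floating
threshold, while rate, shape and strength remain normal — only the
manipulated axis moves.

The length-scaling design rule and the working fluid:

```r
design_mock_length(0.5, 5, 18, "nearest_integer_ratio")  # mock aorta: 2 m
fluid_spec()
#> <fluid_spec> 37% glycerin (w/w) at 20 C: 1.092 g/cm^3, 3.2 cP
```

## Command line

A thin CLI wraps the same functions (installed at `exec/pulseloop`, or call
`pulse_main()` directly):

```sh
pulseloop simulate --preset normal --out wave.csv --manifest run.json
pulseloop ph --wave wave.csv --out ph.csv
pulseloop classify --wave wave.csv --ph ph.csv --reference normal
pulseloop design --real-length 0.5 --real-pwv 5 --mock-pwv 18 --rounding nearest_integer_ratio
pulseloop presets
```

CSV waveforms use the header `time_s,pressure_mmHg` ('.' decimal, UTF-8);
P-H curves `step,applied_mmHg,amplitude_mmHg`; configs and reports are JSON.
All runs are deterministic given their inputs.

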