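# gravicor

Lumped-parameter cardiopulmonary hemodynamics across gravitational
transitions, with heart-failure phenotypes and a diuretic countermeasure.

## What this package is for

Space tourism exposes passengers with chronic cardiac disease to an
abrupt change from standing in Earth gravity to weightlessness.  That
transition removes the hydrostatic gradients that pool blood in the
dependent veins and shifts volume centrally; cardiac output rises, and
left atrial pressure (LAP) — the upstream pressure of the pulmonary
circulation and the standard surrogate for pulmonary-oedema risk — rises
with it.  A heart already in failure starts from an elevated LAP, so the
same shift can push it toward the ~25 mmHg threshold associated with
acute pulmonary oedema.

`gravicor` quantifies this with a closed-loop, 21-compartment 0D model:
four time-varying elastance cardiac chambers (squared half-sine
activation between `Emin` and `Emax`), 17 vascular compartments with
linear elastances, unstressed volumes, signed hydrostatic column heights
and ideal-diode valves, lymphatic return, and a set-point baroreflex
acting on heart rate, contractility, arteriolar resistance and venous
tone.  Compartment pressure follows

    P = max(0, E (V − Vu)) + P_thoracic + g · s · h · 0.77

(elastance `E` mmHg/mL, unstressed volume `Vu` mL, posture scale `s`,
height `h` cm signed positive above heart level), flows follow
`q = ΔP / R`, and volumes are integrated with fixed-step RK4 at 0.25 ms.
Heart failure with reduced ejection fraction (HFrEF) substitutes the
pooled LV `Emax` 0.99 mmHg/mL plus eccentric dilation of the LV
unstressed volume; heart failure with preserved ejection fraction
(HFpEF) substitutes LV `Emin` 0.21 mmHg/mL plus left-atrial dilation;
the countermeasure removes 9% of total blood volume.  See the methods
vignette (`vignettes/gravicor-methods.Rmd`) for the full model account.

## Worked example

Simulate a healthy subject and an HFrEF patient through the
standing-1G → 0G transition (onset at 125 s, 10-s ramp, samples at 80 s
and 225 s):

```r
library(gravicor)

base  <- default_model()                      # calibrated healthy table
sim   <- simulate_model(base, microgravity_protocol("standing"))
transition_report(sim)
#> <cp_transition_report> scenario: normal
#> pre : beat 78.69-79.35 s: CO 4.1 L/min | HR 91 bpm | MAP 93 (SAP 114 / DAP 82) mmHg
#>   LAP 6.0 / RAP 0.1 mmHg | LVEDV 98 / LVESV 53 mL | EF 46% | Ea 2.54 | Ea/Ees 1.02
#> post: beat 223.51-224.37 s: CO 5.4 L/min | HR 70 bpm | MAP 99 (SAP 131 / DAP 82) mmHg
#>   LAP 11.8 / RAP 2.8 mmHg | LVEDV 144 / LVESV 67 mL | EF 54% | Ea 1.70 | Ea/Ees 0.68
#> delta LAP +5.8 | RAP +2.7 | CO +1.3 | HR -21
#> LAP spike: peak 15.4 mmHg, settles in 11 s

hf    <- apply_hfref(base)                    # Table-substituted phenotype
simhf <- simulate_model(hf, microgravity_protocol("standing"))
rep   <- transition_report(simhf)
rep$post$lap                                  # post-transition plateau LAP
#> [1] 17.5
risk_flags(rep)
#> [1] "chronic_lap_elevation"
```

The healthy transition raises LAP by ~5.8 mmHg to ~11.8 mmHg — benign.
The HFrEF heart starts congested and settles at ~17.5 mmHg, below the
acute 25 mmHg threshold but chronically elevated, which is why the
report is flagged.  A supine-1G baseline (`supine_baseline_protocol()`)
reproduces resting hemodynamics (healthy: CO 5.1 L/min, MAP 97 mmHg,
EF 53%, LAP 9.3 mmHg); `run_paper_suite()` executes all eight study
scenarios and writes per-run metrics, PV-loop data and a summary table.

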