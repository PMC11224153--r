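---
title: "Modelling heart failure across gravitational transitions with gravicor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heart failure across gravitational transitions with gravicor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Commercial spaceflight exposes passengers with chronic cardiovascular
disease to an abrupt transition from standing in Earth gravity to
weightlessness.  Entering microgravity removes the hydrostatic pressure
gradients that pool blood in the dependent veins and triggers a cephalad
fluid shift; cardiac output rises and left atrial pressure (LAP) - the
upstream pressure of the pulmonary veins and the standard surrogate for
pulmonary-oedema risk - rises with it.  For a healthy heart this is
benign.  For a heart in failure, which already operates at elevated
filling pressures, the same shift may push LAP toward the ~25 mmHg
threshold associated with acute pulmonary oedema.

`gravicor` implements a closed-loop, 21-compartment lumped-parameter (0D)
model of the cardiopulmonary system to quantify that risk: it simulates
healthy subjects and heart failure with reduced (HFrEF) or preserved
(HFpEF) ejection fraction through a standing-1G to 0G transition, with
and without a pre-flight diuretic countermeasure.

## Model structure

The circulation is divided into 21 compartments: the four cardiac
chambers (RA, RV, LA, LV), five intrathoracic vascular compartments
(thoracic aorta, pulmonary arteries, pulmonary veins, superior vena cava,
thoracic inferior vena cava), two upper-body compartments (arteries,
veins) and ten lower-body compartments (abdominal aorta, renal,
splanchnic, pelvic and leg artery/vein pairs, abdominal vena cava).
Each compartment `i` is a linear elastic reservoir,

\[ P_i = \max\{0,\; E_i (V_i - V_{u,i})\} + P_{it}\,[\text{thoracic}]
   + g\,s\,h_i\,\rho , \]

with elastance \(E_i\) (mmHg/mL), unstressed volume \(V_{u,i}\) (mL),
intrathoracic pressure \(P_{it}\) (constant, -3.5 mmHg; respiration is
not modelled because all reported outputs are beat averages), and a
hydrostatic term built from the gravity level \(g\), the posture scale
\(s\) (1 standing, 0 supine; supine and 0 G are equivalent in this
framework), the signed effective column height \(h_i\) (cm, positive
above heart level) and the density factor \(\rho = 0.77\) mmHg/cm for
blood of 1.05 g/mL.  Because \(h_i\) is signed positive upward, \(P_i\)
is the piezometric head: differences of \(P_i\) drive flow, a dependent
compartment in equilibrium carries a luminal pressure exceeding a
heart-level one by \(0.77\,|h|\), and blood pools in the legs on
standing, as it should.  The elastic term is clamped at zero below the
unstressed volume - compartments do not generate suction.

Flows follow the linear resistive law \(q = \Delta P / R\); the four
cardiac valves are ideal diodes (zero backflow, no regurgitation or
inertance).  Three low-conductance one-way lymphatic paths return fluid
from the leg, splanchnic and upper-body venous beds to the superior vena
cava.  The cardiac chambers use a squared-half-sine time-varying
elastance between \(E_{min}\) and \(E_{max}\); ventricular systole
occupies \(0.3\sqrt{60/\mathrm{HR}}\) s of each cycle and the atrial kick
is a fixed late-diastolic window (cycle fraction 0.82-1.0), so the
elastance is continuous, periodic and equals \(E_{min}\) at the beat
boundary.

### Venous collapse guard

With a hard clamp at zero elastic pressure, compartments above heart
level would siphon indefinitely when standing: their head stays high
(gravity term) even when empty, so outflow would continue until volumes
went negative.  Real veins collapse.  The model therefore de-rates the
outflow of any vascular compartment smoothly (a smoothstep) from full
flow at 90% of its unstressed volume to zero at 80%, acting as a
Starling-resistor-like flow limiter.  The guard engages only in strongly
drained states (upper-body veins when standing, central veins under
volume depletion) and leaves all normally-filled compartments untouched.

## Baroreflex

Arterial pressure is sensed at the thoracic aorta through a first-order
low-pass (time constant 3.3 s), and four effectors - heart rate,
ventricular contractility (\(E_{max}\) of both ventricles), arteriolar
resistance of the five microcirculatory beds, and venous unstressed
volume of the six large venous beds - each relax with first-order
dynamics toward a saturated linear function of the pressure error.  A
sensed pressure below the set point raises heart rate, contractility and
resistance and lowers venous unstressed volume (venoconstriction
recruits stressed volume).  At the set point every multiplier is 1.

The saturation bounds are deliberately asymmetric for the vascular
effectors: constriction has a large reserve (upper bounds 2.2 and
1/0.72) while dilation below the basal operating point is nearly
exhausted (resistance floor 0.97, venodilation ceiling 1.4).  This
mirrors the physiology - sympathetic tone can rise far more than it can
fall from rest - and it is what lets one controller both defend the
standing posture and not over-respond to the mild hypertension of the
post-transition state.  Gains and time constants (HR 0.05/mmHg, 2 s;
contractility 0.05/mmHg, 5 s; resistance 0.04/mmHg, 12 s; venous tone
0.03/mmHg, 12 s) were calibration outputs, chosen together with the
vascular parameters so that the healthy model reproduces published
supine, standing and post-transition hemodynamics; the published HR pair
(86 bpm standing / 71 bpm in 0 G around a 73 bpm supine baseline)
effectively pins the chronotropic gain and set point.  Heart-failure
scenarios keep the healthy reflex unchanged.

## Protocols

A protocol is a time-ordered list of segments (gravity level, posture,
fluid-shift fraction) with linear entry ramps.  The standing-to-0G
transition holds standing 1G until 125 s, ramps linearly to weightless
supine-equivalent over 10 s, and then holds 0 G; outputs are sampled at
80 s ("pre") and 225 s ("post"), each preceded by a stationarity check
(the last five beats must agree within 1%).  The supine baseline protocol
is a single steady supine-1G segment sampled at 80 s.

Entering microgravity does more than zero the hydrostatic term: capillary
filtration balance and tissue-weight changes shift volume centrally.
This is modelled, as in other lumped treatments of spaceflight, by
ramping per-compartment unstressed-volume offsets in with the
transition: the dependent venous beds lose a modest amount of unstressed
volume (legs -20, pelvis -10, splanchnic -10, abdominal cava -5 mL)
and the pulmonary veins lose 310 mL, concentrating the shift in the
thoracic compartments.  The offsets are calibration outputs pinned to the
published healthy transition response (LAP rise +5.7 mmHg, right atrial
pressure rise +2.7 mmHg, cardiac output rise +1.2 L/min); the
pulmonary-weighted split is what reproduces the observed pattern of a
substantial LAP rise with only a moderate cardiac-output rise.

## Disease parameterization

Profiles substitute pooled literature chamber properties into the
calibrated healthy table and nothing else:

* **HFrEF** (systolic dysfunction): LV \(E_{max}\) drops from 2.50 to
  0.99 mmHg/mL, and eccentric remodeling enters as an increase of the LV
  unstressed volume scaled so that the simulated supine-1G end-systolic
  volume moves from ~66 mL to the pooled 184.2 mL.  A closed-form guess
  assuming conserved end-systolic pressure
  (\(V_u' = 184.2 - (65.9 - V_u)(2.50/0.99)\)) is refined by a short
  deterministic secant iteration on 60-s supine runs, because ejection
  continues past peak elastance and the closed form alone leaves the
  simulated ESV ~15 mL short.
* **HFpEF** (diastolic dysfunction): LV \(E_{min}\) rises from 0.10 to
  0.21 mmHg/mL (the tabulated pooled value, used in preference to the
  narrative "factor of 2"), the left atrium dilates by the pooled volume
  ratio 53.6/32.1, and \(E_{max}\) stays at 2.50.
* **Countermeasure**: thiazide-class diuresis is represented purely as a
  9% reduction of total blood volume (a ~15% plasma-volume reduction
  times the 0.60 plasma fraction), with initial stressed volumes shrunk
  proportionally; no drug pharmacodynamics are modelled.

Profiles are deliberately not composable (applying two is an error), and
applying one to an uncalibrated table warns.

## Calibration

The base-model vascular parameter set behind the published tables is not
reprinted there, so the package ships its own physiologically ordered
table and pins it to published healthy outputs: the twelve supine-1G beat
metrics and the three transition deltas (LAP, RAP, CO).
`calibrate_baseline()` evaluates those residuals and, when any exceeds
10%, runs a bounded Nelder-Mead search over log-scales of a declared
tunable subset (total blood volume, arteriolar resistance scale, venous
elastance and unstressed-volume scales, fluid-shift scale, reflex set
point and gain scale) with a fixed start and iteration budget - fully
deterministic.  The shipped table already satisfies every residual, so
calibration on it returns after zero objective evaluations; the
heart-failure and countermeasure results are then pure predictions
obtained by parameter substitution, never tuned to their published
values.

## Analysis conventions

All reported metrics summarize the last complete beat before the sample
time: MAP is the time-average of aortic pressure (trapezoidal), SAP/DAP
its extremes, LAP/RAP beat-averaged atrial pressures, stroke volume the
LV volume excursion, EF = 100 SV/LVEDV, CO = SV x HR/1000 with HR taken
from the beat length.  Arterial elastance uses the standard non-invasive
approximation Ea = SAP/SV (peak aortic pressure differs from peak LV
pressure only by the small gradient across the ideal valve), and the
coupling ratio divides by the scenario's static LV \(E_{max}\), so the
HFrEF identity Ea/Ees = Ea/0.99 holds exactly.  PV-loop stroke work is
the signed shoelace area, positive counterclockwise, and agrees with the
trapezoidal \(\oint P\,dV\) oracle.

The transition LAP "spike" is measured on the beat-averaged LAP series
(the envelope of the within-beat a/v waves, which is what beat-wise
transition traces display): its peak within 60 s of transition onset,
and its duration as the time until the series re-enters +/-10% of the
post plateau.  Instantaneous LA pressure peaks several mmHg above the
beat mean even in steady state, so an instantaneous maximum would
measure waveform pulsatility rather than the transient.

## Numerics

Volumes are integrated with fixed-step classical RK4 at dt = 0.25 ms;
the reflex state and cardiac phase advance once per step (their time
constants exceed dt by four orders of magnitude).  Ideal-diode valves
make the right-hand side non-smooth, which is why a small fixed step is
preferred over adaptive stiff solvers; halving the step changes every
beat-averaged healthy-baseline metric by well under 1%, and a
one-compartment RC drain matches its closed-form exponential to better
than 0.5%.  Volume is conserved to machine precision by construction
(every flow moves volume between exactly two compartments).  Integration
aborts with the failure time if any volume goes negative or any pressure
magnitude exceeds 500 mmHg.  Output is sampled every 5 ms.  Initial
volumes distribute the stressed volume in proportion to compliance (an
equal-pressure start); both protocols allow 80 s of settling before the
first sample, verified by the stationarity check.

Everything is deterministic: there is no randomness anywhere in the
pipeline, and the toy-circuit fixture generator derives its parameter
jitter from an explicit seed without touching R's global RNG.

## What the toy fixtures do and do not show

`toy_circuit()` builds 1-3 compartment circuits with closed-form
behaviour (exponential RC drainage with time constant R/E, symmetric
two-compartment equilibrium, equal-head ring equilibrium with a diode).
They validate the integrator, the pressure/flow laws and volume
conservation against independent arithmetic - but they contain no
chambers, no reflex and no gravity, so passing them says nothing about
physiological realism; that burden falls on the calibrated baseline and
its comparison with published human data.

## Known limitations

* Elastances are linear.  Real ventricles stiffen exponentially at high
  diastolic volume; without that, the dilated HFrEF ventricle absorbs
  the cephalad fluid shift into its compliant diastolic reservoir, and
  the model under-predicts the published HFrEF congestion during and
  after the transition (post-transition LAP ~17.5 vs ~22 mmHg reported;
  transition spike ~23 vs ~30 mmHg).  The healthy and HFpEF transition
  responses, where this nonlinearity matters less, reproduce the
  published values closely.
* The baroreflex is a single set-point proportional controller; there is
  no cardiopulmonary (low-pressure) receptor loop, no vagal/sympathetic
  split and no neurohormonal axis, and heart-failure autonomic
  dysfunction is deliberately not modelled.
* No respiratory mechanics, gas exchange, inertances or nonlinear
  resistances; no hypergravity phase before the transition; no
  long-duration adaptation (cardiac atrophy, plasma-volume resetting).
* The two heart-failure profiles are pooled, treated, stage-C phenotypes;
  E/A ratios and biphasic diastolic filling are outside the model.

## Problem sizes used by the test-suite

The unit tests integrate the toy circuits for 20-60 s and the full model
for its protocol horizons (90 s supine, 250 s transition) at the default
step, with one half-step refinement run for the convergence check; the
full verification suite completes in a few minutes on a single core.
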