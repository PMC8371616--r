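---
title: "Simulating a bag-based emergency ventilator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a bag-based emergency ventilator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 5)
```

`ventsim` is a closed-loop simulator for an acute-shortage ventilator: a
pneumatic piston compresses a self-inflating bag resuscitator through a
patient circuit built from a mechanical peak-inspiratory-pressure (PIP)
relief valve, an active patient valve, an orifice spirometer and a PEEP
threshold valve, under the control of a 100 Hz microcontroller offering
volume-controlled and pressure-controlled assist-control modes (VC-AC /
PC-AC). The simulator couples that controller to a single-compartment
patient lung and reproduces, per breath, the derived parameters a bench
verification campaign reports: tidal volume (TV), peak inspiratory
pressure (PIP), minimum (end-expiratory) pressure, respiratory rate (RR)
and the inspiratory-to-expiratory (I:E) time ratio, plus missed-trigger
statistics for spontaneously breathing patients.

## The patient model

The lung is a linear one-compartment system: a compliance $C$ (mL/cmH₂O)
filled through phase-dependent resistances ($R_{in}$ on inflow, $R_{ex}$ on
outflow, cmH₂O·s/L). With volume $V$ referenced to functional residual
capacity, applied PEEP as an additive baseline, and muscle pressure
$p_{mus} \le 0$,

$$
p_{alv} = \frac{V}{C} + \mathrm{PEEP} + p_{mus}, \qquad
p_{aw} = p_{alv} + R(q)\,q ,
$$

where $q$ is the flow into the lung (L/s) and $p_{aw}$ the pressure at the
airway opening where the sensors sit. Four presets span the bench lungs: a
normal adult lung ($C=50$, $R=6/6$) and three ARDS severities down to
$C=10$, $R=20/20$. The resistance unit printed by the lung-simulator
vendor is ambiguous; we read it as the standard cmH₂O·s/L, which gives the
normal lung the familiar expiratory time constant
$\tau = R_{ex} C = 0.3$ s. Endotracheal-tube resistance is folded into the
preset resistances rather than modelled separately.

Spontaneous effort follows a half-sinusoidal profile: over each cycle of
length $60/\mathrm{RR}$ the muscle pressure descends sinusoidally to
$-P_{max}$ during the inspiratory fraction (default 20% of the cycle),
releases along a quarter-cosine during the release fraction (default 15%)
and is zero otherwise. The profile is continuous and its minimum is
exactly $-P_{max}$ at the end of the ramp. Patient inspiratory pauses and
active expiration are not modelled.

## The drive and circuit model

The piston compresses the bag at the constant rate
`bag_capacity / stroke_time` (default 750 mL / 0.5 s = 1.5 L/s). The PIP
relief valve is ideal: delivered flow is clamped so that
$p_{alv} + R_{in} q$ never exceeds the valve setting, and the surplus is
vented. The PEEP valve is an ideal threshold check valve: expiratory flow
is $-(p_{alv}-\mathrm{PEEP})/R_{ex}$ when alveolar pressure exceeds the
PEEP setting and zero otherwise, so exhalation alone can never drag the
airway below PEEP (intrinsic PEEP can still build up when the expiratory
window is short). A patient pulling the airway below ambient draws flow in
through the bag's inlet valve, which is what allows breathing through a
disabled device.

The two inspiration modes differ in what the bag does after the stroke:

* **VC-AC** — compression stops as soon as the integrated spirometer
  volume reaches the internal setpoint (or the stroke completes); the bag
  is then *held*, flow stops, and the airway shows the pressure plateau of
  an inspiratory pause until the commanded inspiratory time ends.
* **PC-AC** — the compressed bag acts as a pressure reservoir at the PIP
  valve setting for the whole inspiratory time: delivery continues through
  the hold at the pressure-limited rate, capped by the piston rate and the
  bag capacity. This reproduces first-order charging of the lung toward
  the quasi-static volume $C(\mathrm{PIP}-\mathrm{PEEP})$ with
  $\tau = R_{in} C$, which is the regime in which the severe-ARDS lung
  tops out near 250 mL.

Because the adaptive volume algorithm corrects volume-controlled breaths
breath-by-breath, the internal setpoint moves by half the error between
set and delivered volume each breath
($s' = s + 0.5\,(V_{set} - V_{del})$, clamped to the bag capacity). The
map is a contraction for any plant gain below 2, so convergence to within
2% of the target takes at most a handful of breaths; the gain of 0.5 and
the initial setpoint equal to the set volume are fixed design choices.

## Sensing

Flow is measured by an orifice spirometer: $\mathrm{flow} = k\sqrt{\Delta p}$,
with the coefficient $k$ obtained by a least-squares fit of flow against
$\sqrt{\Delta p}$ through the origin. The hardware coefficient is a
calibration product rather than a published constant; the package default
$k = 45$ (L/min)/√cmH₂O places the drive's ~90 L/min peak flow inside the
5 cmH₂O differential range with headroom. The airway gauge saturates at
50 cmH₂O, the differential channel at ±5 cmH₂O; saturated samples are
clipped and flagged. Optional zero-mean Gaussian noise with configurable
SD and seed can be applied to both channels; it is off by default so that
every run is bit-reproducible.

Both sensors sample at 100 Hz. The recorded stream holds the
instantaneous flow and pressure at each sample instant under the phase
commanded at that tick; the controller consumes each conversion one tick
later — the ordinary read-compute-actuate latency of a sampled control
loop. One consequence worth knowing: because the ideal drive switches
flow in a single plant step, a 100 Hz record of a flow *step* aliases
roughly half a sample interval of volume at every switch edge, so the
cumulative trapezoid of recorded flow slowly drifts from the true lung
volume on mechanically ventilated breaths (the hardware's own
flow-integrating firmware shares this error). On smooth flows — e.g.
spontaneous breathing through the disabled device — the recorded stream
integrates back to the simulated volume to within 0.5%.

## Numerics

The plant integrates by explicit Euler at a fixed 1 ms step inside each
10 ms controller tick (zero-order-hold commands). The smallest time
constant in any preset is 0.2 s, so the scheme is comfortably stable and
converges to well under 0.5% in delivered volume when the step is halved
(this is asserted in the test suite). Negative lung volumes are clamped
to zero, mirroring the circuit's check valves; a hard 60 cmH₂O mechanical
ceiling caps airway pressure under any configuration. Controller
comparisons use strict inequality at the trigger threshold and carry a
200 ms refractory window after release begins, preventing re-triggering
on the exhalation transient (the hardware description is silent here;
the window is far shorter than any tested breath period).

## Scenarios and the verification grid

A scenario bundles lung, effort pattern, ventilator settings, circuit
configuration and run parameters, serialised as a flat key/value YAML file
whose keys follow the control panel's parameter names. Trigger thresholds
are absolute pressures; a negative configured value is interpreted
relative to PEEP at load time. Default durations cover a warm-up (5
breaths passive, 10 spontaneous — spontaneous runs take visibly longer to
settle) plus 20 steady-state breaths, capped at 120 s; summaries flag
themselves invalid below 20 analysed breaths (the 10 brpm point, capped
at 120 s, analyses 14 and is used only for rate accuracy).

The bundled requirements grid holds 29 scenarios — the four lungs crossed
with set volumes 250/400/600 mL in VC-AC, rate and inspiratory-time
sweeps on the normal lung, the four lungs at PIP 25/35 cmH₂O in PC-AC,
and two spontaneous-trigger scenarios (−5 and −2 cmH₂O effort at
30 brpm). ARDS lungs run at PEEP 10 cmH₂O, the normal lung at 5, rate
20 brpm and I:E 1:2 except where swept. The published campaign also used
29 scenarios but does not enumerate them; this grid is the package's
documented reconstruction, so suite-level aggregates (e.g. the highest
per-scenario mean PIP) should be read as approximate reproductions.

## Breath analytics

Breaths are segmented from the flow signal alone — an upward crossing of
+1 L/min (re-armed below 0.5 L/min) opens a breath; the inspiratory
window runs to the first crossing below −1 L/min and therefore includes
the zero-flow inspiratory pause, matching how commanded and measured
inspiratory times agree on the bench. The thresholds sit far above
numeric noise and far below the ~90 L/min peaks. Working from the flow
signal (rather than the controller's phase codes) keeps the analytics
applicable to recorded or third-party waveforms read from CSV. Tidal
volume is the trapezoidal integral of positive flow over the inspiratory
window; PIP and minimum pressure are the airway-pressure extremes within
the breath; RR is 60 over the mean breath duration. Patient efforts are
matched to patient-triggered breaths within a 300 ms window (shorter than
the smallest breath period tested); the missed fraction is the share of
efforts with no matched breath.

## What the simulator does and does not show

Passing the bundled verification grid shows that the *control logic* —
phase machine, triggering, adaptive volume convergence, alarm conditions,
pressure limiting — behaves as specified against an idealised plant. The
idealisations matter in one visible place: with instantaneous valves and
an instantly released drive, circuit pressure collapses to PEEP within a
few expiratory time constants, so a −5 cmH₂O effort always reaches the
trigger threshold and the fast-patient scenario shows essentially no
missed triggers, where the hardware — whose piston retraction, bag refill
and valve dynamics delay the pressure fall — missed roughly one effort in
ten. Reproducing that figure would require actuator dynamics the device
description does not quantify, and is deliberately out of scope. Likewise
absent: nonlinear or multi-compartment lung mechanics, airway collapse,
gas exchange and oxygen blending, leak and humidification effects, and
any real-time or hardware-in-the-loop behaviour.

## A worked example

```{r, eval = FALSE}
library(ventsim)

scn <- load_scenario("normal_vcac_400")
wave <- run_simulation(scn)
plot(wave, window = c(15, 24))

breaths <- segment_breaths(wave)
summarize_breaths(breaths, warmup = 5)
```

The summary prints TV 393 mL (set 400), PIP 21.7 cmH₂O, PEEP 5 cmH₂O,
RR exactly 20 brpm and I:E 1:2.0 — the steady-state operating point of
the volume-controlled reference scenario. The residual ~2% volume error
is the quantisation of the 100 Hz volume integrator that the adaptive
setpoint cannot remove entirely; it sits far inside the 15% verification
band.
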