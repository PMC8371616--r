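# ventsim

Closed-loop simulation of an acute-shortage mechanical ventilator — the
kind of device built in an equipment crisis by mechanically compressing a
self-inflating bag resuscitator through a patient circuit of standard
hospital parts. The package is for engineers and researchers who want to
exercise and verify such a ventilator's *control logic* (modes,
triggering, adaptive volume control, alarms, pressure limiting) against a
configurable simulated patient, without bench hardware.

The simulated system couples three parts:

* **Patient** — a single-compartment lung with compliance *C* and
  phase-dependent airway resistances *R<sub>in</sub>*/*R<sub>ex</sub>*,
  obeying the equation of motion

  *p<sub>aw</sub> = V/C + PEEP + p<sub>mus</sub> + R(q)·q*,

  with optional half-sinusoidal spontaneous muscle effort
  (rate, −P<sub>max</sub>, 20% inspiratory / 15% release fractions).
  Presets cover a normal adult lung (C = 50 mL/cmH₂O, R = 6) and three
  ARDS severities down to C = 10, R = 20.
* **Circuit** — a piston that empties a 750 mL bag in a 0.5 s stroke, an
  ideal PIP relief valve (20–40 cmH₂O), an ideal PEEP threshold valve, a
  60 cmH₂O mechanical ceiling, and a √Δp orifice spirometer plus airway
  gauge sampling at 100 Hz.
* **Controller** — a 100 Hz assist-control state machine
  (COMPRESS → HOLD → RELEASE) in volume-controlled (VC-AC) or
  pressure-controlled (PC-AC) mode, with absolute-pressure patient
  triggering, a breath-to-breath adaptive volume setpoint
  (*s′ = s + 0.5 (V<sub>set</sub> − V<sub>del</sub>)*), a software
  maximum-pressure halt, and the device's volume/pressure alarm table.

Waveform analytics segment the recorded flow into breaths and report the
bench campaign's derived parameters — tidal volume, PIP, minimum
pressure, respiratory rate, I:E ratio — as mean ± SD over steady-state
breaths, plus the fraction of patient efforts that fail to trigger a
breath.

## A worked example

```r
library(ventsim)

scn  <- load_scenario("normal_vcac_400")   # passive normal lung, VC-AC reference
wave <- run_simulation(scn)
summarize_breaths(segment_breaths(wave), warmup = 5)
#> <metrics_summary> 20 breaths
#>   TV     393.0 (SD  7.05) mL
#>   PIP     21.7 (SD  0.14) cmH2O, per-breath max 21.8
#>   PEEP     5.0 (SD  0.00) cmH2O
#>   RR     20.00 (SD  0.00) brpm
#>   I:E  1:2.00 (SD 0.00)
```

Set to 400 mL at 20 breaths/min with PEEP 5 and the PIP valve at 35
cmH₂O, the simulated device delivers 393 mL per breath (the ~2% deficit
is the 100 Hz volume-integrator quantisation the adaptive setpoint cannot
remove), peaks at 21.7 cmH₂O, returns exactly to PEEP each breath, and
holds the commanded 3.0 s breath period and 1:2 inspiratory-to-expiratory
split. `plot(wave, window = c(15, 24))` draws the monitor-style
flow/pressure/volume panels.

A 29-scenario verification grid (all lungs × the settings ranges) is
bundled:

```r
report <- run_suite(requirements_suite(seed = 1))
max(report$pip_max_breath)   # highest per-breath PIP across the grid
```

There is also a small command line:

```sh
Rscript inst/cli/asvsim.R presets
Rscript inst/cli/asvsim.R run --scenario normal_vcac_400 --out wave.csv --metrics metrics.txt
Rscript inst/cli/asvsim.R suite --grid requirements --report report.csv
Rscript inst/cli/asvsim.R calibrate-spirometer --pairs inst/extdata/spirometer_pairs_synthetic.csv
```

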