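---
title: "Methods: a digital twin of a multisensor apnea-detection bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital twin of a multisensor apnea-detection bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneasim)
```

## The problem

Neonatal apnea — a breathing pause of at least 20 s, or more than 10 s when
accompanied by desaturation and bradycardia — must be monitored at home after
discharge, in rooms full of mechanical disturbances a hospital would never
tolerate. Characterising an apnea monitor directly on patients is ethically
constrained, so the field uses mechatronic benches: a motorised stage moves a
plate the way a newborn's abdomen moves, a servo hammer injects impulsive
structural noise, and the candidate sensors watch the plate. `apneasim` is a
software twin of such a bench. Everything the physical rig does — command a
breathing displacement, pause it for apnea events, strike the structure,
sample the sensors — is generated in code, so detection rules and monitoring
logic can be validated reproducibly, at scale, and without hardware.

The package has four layers: signal synthesis (`simulate_recording()`),
episode detection (`detect_recording()`, `run_protocol()`), validation
statistics (`summary_statistics()` against `load_reference_fixture()`), and
the monitoring state machine (`monitor_run()`).

## Motion model

A breath is commanded as a symmetric triangular displacement: the stepper
runs at constant speed to the peak during the first half-cycle and back
during the second. Peak-to-peak amplitude is 500, 1000 or 1500 µm on the
standard grid; the default rate is 40 breaths/min, a typical neonatal
resting rate inside the stage's 0–120 bpm envelope. Positions are quantized
to the stepper quantum (0.11 µm/step). An apnea event freezes the commanded
position — absence of motion — for its scheduled duration (≥ 20 s, the
clinical definition); the standard protocol inserts three such events at
random breath boundaries into a run of 100 breaths, giving a 210 s recording
(150 s breathing + 60 s apnea). Smooth waveform alternatives were considered
and rejected: the bench's motion is literally piecewise-linear, and the
second derivative of a triangle (acceleration impulses at the vertices) is
exactly what an accelerometer on such a stage sees.

The body-worn sensor does not see the raw stage acceleration: clothing and
mattress act as a mechanical low-pass. We model that as a second-order
Butterworth filter, 10 Hz cutoff by default — low enough to smear the vertex
impulses into realistic millig-scale pulses, high enough to pass all
breathing harmonics of interest. The filtered motion acceleration is
projected onto the sensor axes by the body-position angle θ, with the motion
axis `(cos θ, 0, sin θ)` in the x–z plane: 90° (supine analogue) puts all
energy on z; 45° and 135° split it across x and z with opposite x signs.
Whether the angle tilts the sensor or the whole bed plane is equivalent
under this convention. A static 1 g projection is added along the same axis
when gravity is enabled; it is constant and vanishes under the detrended
amplitude metric.

## Noise model

The physical hammer is only specified as "adjustable energy", so the noise
waveform family is a modelling choice: strikes arrive as a Poisson process
(default 0.15 strikes/s), each one a damped sinusoid
\(A e^{-t/\tau}\sin(2\pi f t)\) with ring frequency 50 Hz and decay constant
50 ms — the generic signature of an impact exciting one dominant structural
mode. Peak amplitudes are log-normal (median 0.012 g, sdlog 0.9), because
impact amplitudes are positive, right-skewed, and span an order of
magnitude. The ceiling channel sees the full strike; fixed structural gains
couple it into the bed (0.6) and body (0.3) channels.

The defaults were calibrated once, qualitatively: the log-normal strike
distribution was centred so that its mass straddles the body-channel
amplitudes produced by 500–1500 µm breathing. That placement is what makes
the unusable-data rate fall as displacement rises — small breaths are
overwhelmed by a typical strike, large breaths only by a rare large one —
and it reproduces the reference grid's inverse displacement trend without
per-condition tuning. The absolute simulated rates are not meant to match
the reference counts exactly; the physical hammer energies behind those
counts are unknown.

## Sensor chain

Accelerations are quantized by a uniform mid-tread ADC over ±3 g with 12
bits: zero maps to code 2048, the rails clip to 0 and 4095. The sensitivity
is ⌊2¹²/6⌋ = 682 LSB/g and the scale factor 6000/4096 ≈ 1.46 mg/LSB
(`adc_sensitivity()`); catalogue figures for 10-bit parts (256 LSB/g at
±2 g, 512 at ±1 g) reproduce under the same truncation convention. The
six-channel acquisition mode samples at 4 kHz per channel (a 26 kHz
three-channel mode is supported for diagnostics).

The infrared ranger follows the inverse-distance law \(V = k/(d + d_0)\)
with defaults k = 12 V·cm and d₀ = 0.42 cm — a standard approximation for
short-range analog IR triangulation sensors, configurable and not claimed to
be a device datasheet fit — plus 2 mV additive Gaussian noise. The optical
path also shakes with the structure (`ir_vibration_cm_per_g`, default
0.35 cm/g of ceiling acceleration), so hammer strikes perturb the proximity
reading too.

## Detection rule and fusion

Each commanded breath cycle is one scoring episode. The amplitude metric is
the peak-to-peak of the linearly detrended episode window — insensitive to
gravity offsets and slow drift — taken as the maximum over the three body
axes, so a breath is credited to whichever axis captured it best. An episode
is *unusable* when the noise reference is at least as large as the body
signal; ties go to unusable, the conservative direction for patient safety.
The bed accelerometer is the noise reference (the sensor physically adjacent
to the body sensor); the ceiling channel is kept for diagnostics.

The infrared rescue reclassifies an unusable episode as detected when the
displacement implied by the IR voltage swing (local inversion of the
transfer curve, `ir_implied_displacement_um()`) reaches half the commanded
displacement. The fraction is configurable; 0.5 asks the IR channel to
confirm at least the scale of the commanded motion without demanding an
exact match from a noisy analog sensor.

One divergence from the physical bench is worth stating plainly: in the
simulation the IR rescue is essentially total. A 0.01 g ring at 50 Hz
corresponds to about one micrometre of actual displacement, so a
displacement-domain sensor barely notices vibrations that saturate the
acceleration-domain comparison — every accelerometer-unusable episode still
shows its commanded swing in the IR channel. The physical reference grid
retains 36 unusable episodes out of 88 after fusion, reflecting IR
disturbances (optical interference, electrical pickup, mounting resonances)
the twin does not emulate. Consequently the packaged reference grid, not the
simulation, is the ground for the fusion statistics; the simulation
demonstrates the direction of the fusion benefit, not its size.

## Validation statistics

For each condition the error odds are unusable/detected, as a percentage.
Displacement-level summaries average the three angles (mean ± sample SD,
n − 1); the overall figure is the mean ± sample SD of the three level means,
computed from unrounded values (rounding first changes the second decimal).
Pooling the grid gives a 2 × 2 table (mode × outcome) tested with the
Pearson chi-square without continuity correction,
\(\chi^2 = n(ad-bc)^2/(r_1 r_2 c_1 c_2)\) on 1 df — the correction is
deliberately omitted; with it the reference table's statistic would not be
23.42 — and summarised by the odds ratio \((b/a)/(d/c)\). Reporting rounds
half-up to two decimals; p-values below resolution are reported as bounds.
No confidence intervals or exact tests are attached: one test, one table.

```{r}
ref <- load_reference_fixture()
s <- summary_statistics(ref)
s$pooled
c(chi_square = s$chi_square, odds_ratio = s$odds_ratio)
s$by_displacement_no_ir[, 1:4]
unlist(s$overall_no_ir)
```

## Monitoring state machine

The monitor consumes 0.25 s frames (the cadence is a design choice; all
thresholds are in seconds and independent of it), each summarised by the
same detrended peak-to-peak metric as the detector, in g. A frame is *clear*
when the abdomen channel exceeds the bed reference; a clear frame at or
above the acceleration threshold g_th is a confirmed breath. The timer T
counts seconds since the last confirmed breath and is reset by nothing else
— in particular, unclear frames never reset it. T entering [10, 20) s on a
clear signal raises one apnea alert per pause and requests the caregiver
survey; T reaching 20 s, or a continuously unclear signal exceeding 20 s,
activates the rescue process (with an actuator-enable event for a bed
shaker); rescue latches until the explicit reset.

Choices where the flow narrative is silent: a breath arriving while the
survey is pending resolves the pause (monitoring resumes, no duplicate
alert); a pending pause that outlives the survey window escalates to rescue
at 20 s, consistent with the ≥ 20 s apnea definition; the survey verdict is
critical exactly when *both* saturation and heart rate are below 90, read
strictly (90 itself is not below 90; an inclusive reading is a
configuration flag); missing vitals escalate to rescue rather than resuming
monitoring — fail-safe. Risk colours map red to immediate intervention
(any rescue, or an alert with a critical or missing survey), yellow to a
planned check-up (alert with an ok survey), green to routine
prospective-study records. Every alert carries the eight-question (8Ws)
schema with the computable keys pre-filled (what, where, when) and the rest
left to the operator.

## Numerical choices and degenerate inputs

Zero-phase filtering runs the biquad forward and backward through R's
C-level recursive filter; the series starts and ends at rest so no edge
padding is needed. Episode windows are `[t0, t1)` sample ranges; an empty
window is an error, a constant window has amplitude zero. The quantizer
guarantees `decode(encode(x))` within half a scale factor of the clipped
input. Chi-square requires nonzero margins; the odds ratio refuses zero
reference cells rather than silently adding a continuity constant
(`summary_statistics()` reports it as `NA` in that case). All randomness
flows from one root seed: per-condition streams are `seed + condition
index`, and every generator restores the caller's RNG state.

## Problem sizes

The packaged tests run each property at the scale it needs: unit tests use
short protocols (a handful of breaths at 400 Hz), while the end-to-end suite
simulates the full protocol — nine conditions at 4 kHz with 100 breaths and
three apnea events each — once noise-free, once at default noise, and twenty
seeded replicates of the supine displacement sweep for the trend property.
The whole suite completes in a few minutes on one core.

## Limitations

The twin validates detection logic, not tissue mechanics: it does not model
chest-wall dynamics, obstructive apnea (motion persists there), sensor
drift, temperature effects (metadata placeholders only), or transport-layer
concerns of a deployed monitor. The hammer calibration is qualitative, so
simulated error rates are comparable across conditions but not to the
physical bench's absolute counts; and the IR channel is cleaner than any
physical IR ranger, as discussed above. Passing the simulated-trend tests
therefore shows the pipeline orders conditions correctly under the stated
noise model — it does not certify performance on a real infant.
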