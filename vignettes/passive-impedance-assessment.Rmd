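---
title: "Passive assessment of skin-electrode contact impedance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive assessment of skin-electrode contact impedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuntcheck)
library(ggplot2)
```

## The problem

Biopotential monitoring — EEG, and especially intraoperative
neurophysiological monitoring (IONM) — needs low skin-electrode contact
impedance to keep signals clean: a high contact impedance attenuates the
signal and makes the channel susceptible to mains pickup and motion
artefacts. Practice sets the acceptability limit near 5 kΩ. The common way
to check a contact injects a known current and measures the voltage drop,
which costs power, complicates regulatory certification (current-injecting
devices sit in a stricter class), and abrades the skin when repeated.

`shuntcheck` implements and simulates a *passive* alternative: no current is
ever injected. A resistor of known value $R$ is briefly switched in parallel
with one amplifier input, and the attenuation this causes **on the measured
biosignal itself** reveals the contact resistance.

## The measurement model

Each contact is reduced to a series resistance $R_+$ (or $R_-$) plus a DC
half-cell potential. The DC is blocked by the input high-pass filter
(series $C_{hpf}$, shunt $R_{hpf}$), and in the band of interest the contact
behaves as an averaged-out resistance — the method never needs the reactive
part, because it probes the contact with the very signal being recorded.

With the shunt engaged on the positive input, the input network is a
resistive divider (given $R_{hpf} \gg R$ and signal frequencies well above
the filter cutoff), so the signal is scaled by the attenuation coefficient

$$\alpha = \frac{R}{R + R_+}, \qquad \beta = \frac{R}{R + R_-}.$$

Each three-position input switch selects shunt (1), normal operation (2) or
ground (3). The four-phase protocol measures, in order,
$v_a\,(2,3)$, $v_b\,(1,3)$, $v_c\,(3,2)$, $v_d\,(3,1)$: one terminal is
grounded while the other is observed plain and then shunted. Because the
biosignal is random-like, a statistic $F(\cdot)$ — the RMS — summarises each
phase, and

$$\alpha = \frac{F(v_b)}{F(v_a)}, \qquad
  \beta  = \frac{F(v_d)}{F(v_c)}, \qquad
  R_\pm = R\,\frac{1-\text{coeff}}{\text{coeff}}.$$

Two thresholds (2.5 kΩ and 7.5 kΩ, bracketing the 5 kΩ limit) classify each
estimate as good / middling / unacceptable (green / yellow / red). In
coefficient space the thresholds sit at 0.67 and 0.4. Coefficients above 1,
which noise can produce when the contact is excellent, would imply a
negative resistance; they are clamped to 0 Ω and flagged.

```{r divider}
attenuation_coefficient(c(0, 2500, 5000, 7500), r_shunt = 5000)
as.numeric(contact_from_coefficient(c(0.67, 0.5, 0.4)))
```

## Settling: why the protocol waits 2τ

Every switch event re-charges the HPF capacitor through
$R_{hpf} + R_{eq}$, where $R_{eq}$ is the source-side resistance of the new
configuration (the contact resistance in normal operation, contact ∥ shunt
when shunted, zero when grounded). The protocol waits twice the larger of
the two terminal time constants before opening the RMS window — the
trade-off between measurement duration and residual transient used
throughout the validation experiments. With the default components
(τ ≈ 1 s) a full bipolar assessment takes about 10 s of simulated signal.

```{r settle}
settle_time("b", electrode_contact(5000), electrode_contact(100))
```

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| `r_shunt` | 5 kΩ | equal to the acceptability limit, so a borderline contact reads coefficient 0.5 |
| `r_hpf`, `c_hpf` | 10 MΩ, 100 nF | cutoff ≈ 0.16 Hz; `r_hpf` ≥ 2000 × `r_shunt`, keeping the divider approximation below 0.1% error. These component values are a package design choice; the construction only requires `r_hpf` ≫ `r_shunt`, and configurations violating `r_hpf ≥ 100 r_shunt` are rejected |
| `gain` | 50 V/V | typical first-stage LNA gain for a ±32 mV input range |
| `adc_bits`, `adc_full_scale` | 16, `gain` × 32 mV | the ADC digitises the amplifier output |
| `sample_rate` | 20 kHz | ≥ 20 samples per cycle of the 1 kHz test tone; doubling it changes phase RMS readings by < 0.1% |
| window | 0.2 s | an integer number of both 50 Hz and 1 kHz cycles, so periodic components contribute their exact RMS regardless of phase |
| `white_rms` | 0.5 µV | an input-referred bench-level noise floor. This is a tuning chosen to be realistic for a discrete LNA front end, not a measured figure |
| thresholds | 2.5 / 7.5 kΩ | bracket the 5 kΩ limit; boundaries classify upward (conservative) |

## What the simulator does

`simulate()` integrates each terminal's one-pole input network with the
exact zero-order-hold exponential update — closed-form, so no ODE-solver
tolerance enters — and carries the capacitor voltage across switch events.
Switching transients therefore emerge from physical state continuity rather
than being modelled explicitly, and their envelopes decay with exactly the
τ that `settle_time()` predicts. The differential output gets
input-referred white/impulsive noise, the amplifier gain, and a mid-tread
16-bit quantizer with rail clipping.

The amplifier itself is ideal: infinite input impedance and CMRR, gain
exactly $G$. The derivations assume this, and the floating, high-CMRR bench
the method targets justifies it; consequently a 1 mV 50 Hz common-mode
component contributes less than one ADC step to the output when contacts
are matched.

```{r transient, fig.width = 6.5, fig.height = 3}
b <- bench_config(contact_plus = electrode_contact(100),
                  contact_minus = electrode_contact(51000),
                  quantize_output = FALSE)
m <- run_sequence(b, seed = 1)
autoplot(attr(m, "trace"))
```

## The synthetic biosignal, and what it does not emulate

The laboratory experiments this package reproduces drove the bench from an
arbitrary waveform generator replaying a recorded neurological signal. Two
consequences shape the `signal_synth` design:

* **The surrogate.** `synth_eeg_surrogate()` generates seeded Gaussian
  noise brick-wall-limited to 0.5–100 Hz and rescaled to an exact
  peak-to-peak amplitude (15 µV by default). It matches a real recording in
  amplitude and bandwidth but has none of EEG's nonstationarity, rhythms or
  artefacts — passing tests show the *estimator* works on random-like
  signals, not that real EEG is stationary enough over any particular
  window.
* **Replay.** A generator on loop presents the *same* signal content to
  every phase. The simulator reproduces this: surrogates are regenerated
  identically per phase, and `run_sequence()` rounds the common phase
  duration up to a whole number of analysis windows, so every RMS window
  sees the same source content and the same mains phase. Source content
  then cancels exactly in the RMS ratios. On a live subject the signal does
  not repeat; there the method relies on statistical stationarity, and the
  RMS ratio carries a sampling error that shrinks with window length
  (roughly $1/\sqrt{2BT}$ per phase for bandwidth $B$ and window $T$). The
  0.2 s default window is a bench/simulation choice; live use wants longer
  windows or the repeat-and-median option (`assess(n_repeats = )`).

## Numerical choices and degenerate inputs

* **RMS.** The streaming (single-accumulation) formula is used, matching an
  embedded implementation, with a relative floor of $10^{-13}$ on the mean
  square to absorb the formula's cancellation error on near-constant
  windows. DC removal within the window is on by default: it costs nothing
  for zero-mean signals and suppresses residual settling offsets. Both
  behaviours are exposed.
* **Validity floor.** A phase RMS below 3× the quantization noise RMS
  (LSB/√12) aborts with an "insufficient signal" error rather than
  returning a meaningless ratio; with the ideal (non-quantizing) chain the
  floor is zero.
* **Clamping.** Coefficients > 1 clamp to 0 Ω with a flag; they are kept
  as 0 (not substituted by a small plotting value) everywhere numerical.
* **Boundaries.** Classification intervals are half-open with the upper
  boundary escalating (7 500 Ω is "unacceptable") — deterministic and
  conservative.
* **Initial state.** Capacitors start at the DC operating point of ongoing
  normal recording (source DC + half-cell), the physically settled
  condition from which a real instrument enters the protocol.

## Validation experiments and the problem sizes used

`grid16()` runs the 4 × 4 grid {100 Ω, 1 kΩ, 5 kΩ, 51 kΩ}² through the full
bipolar protocol. With `noise_off = TRUE` it reproduces the
mathematical-model conditions — no noise, ideal ADC, no DC, 1 kHz tone —
under which every contact is recovered within 2% (the residual error is the
$R_{hpf}$ divider approximation, ≈ 0.5% at 51 kΩ) and all sixteen cases land
in the correct scenario. The idealisation matters: at these signal levels
(15 µVpp before a 0.89 attenuation at gain 50) the shunted-phase output at
51 kΩ is about half an LSB of a 16-bit ± 1.6 V ADC, so the *quantized* chain
cannot achieve 2% recovery there; the noisy variant of the experiment is
instead validated on scenario correctness, where errors appear only at the
5 kΩ boundary and only toward higher severity — the conservative failure
mode.

`monopolar_sweep()` (9 resistance values × 10 replicates × both terminals,
full noisy chain) recovers median estimates well within 10%;
`bipolar_grid9()` runs the 3 × 3 bench grid with the replayed surrogate.
Per assessment the simulator integrates ~10 s of signal at 20 kHz
(≈ 2 × 10⁵ samples), so the full sweep (180 assessments) completes in tens
of seconds on one core.

```{r grid, fig.width = 6, fig.height = 4}
g <- grid16(noise_off = TRUE, seed = 1)
summary(abs(g$r_plus_est - g$r_plus_true) / g$r_plus_true)
all(g$scenario_est == g$scenario_true)
```

## Known limitations

* The contact is a pure resistance: polarization reactance and electrode
  drift are out of scope, consistent with the method's premise of an
  in-band averaged resistance.
* The amplifier is ideal; device-level effects (finite CMRR, bias
  currents, slew) are not modelled.
* Real mains interference is neither phase-stable nor exactly 50 Hz; the
  simulator's clean common mode is a best case for the windowing choices
  above.
* Hardware benches report coefficient values a few percent away from the
  divider line (the published asymmetric realization read α = 0.987 and a
  noise-inflated β = 0.124 against divider values 0.980 and 0.089); the
  simulated chain lands within a fraction of a percent of the divider, so
  agreement with hardware is assessed through bands, not point equality.
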