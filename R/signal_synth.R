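#' Signal specification
#'
#' Describes one synthetic monopolar source: a calibration sine, a seeded
#' EEG-like band-limited surrogate, or a constant. Amplitudes are given
#' peak-to-peak in volts, as bench instruments report them.
#'
#' @param kind `"sine"`, `"eeg_surrogate"` or `"constant"`.
#' @param frequency Sine frequency in Hz.
#' @param vpp Peak-to-peak amplitude in volts. A negative value flips the
#'   polarity (the bench convention `v- = -v+`); the realised peak-to-peak
#'   amplitude is `abs(vpp)`.
#' @param dc_offset DC offset in volts.
#' @param band Two-element `c(low, high)` passband in Hz for the surrogate
#'   (default 0.5-100 Hz, the conventional EEG band).
#' @param seed Integer seed making the surrogate reproducible.
#' @return An object of class `signal_spec`.
#' @examples
#' test_tone <- signal_spec("sine", frequency = 1000, vpp = 15e-6,
#'                          dc_offset = 1e-3)
#' @export
signal_spec <- function(kind = c("sine", "eeg_surrogate", "constant"),
                        frequency = 1000, vpp = 15e-6, dc_offset = 0,
                        band = c(0.5, 100), seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(vpp)) abort("vpp must be finite",
                             class = "shuntcheck_domain_error")
  if (kind == "eeg_surrogate" && !(band[1] > 0 && band[1] < band[2])) {
    abort("band must satisfy 0 < low < high", class = "shuntcheck_domain_error")
  }
  structure(
    list(kind = kind, frequency = frequency, vpp = vpp,
         dc_offset = dc_offset, band = band, seed = as.integer(seed)),
    class = "signal_spec"
  )
}

#' Noise specification
#'
#' Additive disturbances of the acquisition chain, referred to the amplifier
#' input: stationary white Gaussian noise plus optional Poisson-timed
#' biphasic impulses (the kind of disturbance that can hit only one phase of
#' the switch sequence and distort a single RMS reading).
#'
#' @param white_rms RMS of the white noise in volts (default 0.5 uV, a
#'   bench-level figure; a tuning, not a measured value).
#' @param impulse_rate Expected impulse events per second (default 0).
#' @param impulse_amplitude Peak amplitude of each biphasic impulse in volts.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_rms = 0.5e-6, impulse_rate = 0,
                       impulse_amplitude = 0, seed = 1L) {
  if (white_rms < 0 || impulse_rate < 0 || impulse_amplitude < 0) {
    abort("noise parameters must be non-negative",
          class = "shuntcheck_domain_error")
  }
  structure(
    list(white_rms = white_rms, impulse_rate = impulse_rate,
         impulse_amplitude = impulse_amplitude, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Construct a signal trace
#'
#' A uniformly sampled voltage sequence stored as a tibble with columns
#' `time` (s) and `voltage` (V) plus `sample_rate` and `start_time`
#' attributes. All generator and simulator outputs use this container.
#'
#' @param voltage Numeric vector of sampled voltages (finite, length >= 1).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return A tibble of class `signal_trace`.
#' @export
signal_trace <- function(voltage, sample_rate, start_time = 0) {
  if (length(voltage) < 1 || any(!is.finite(voltage))) {
    abort("voltage must be a non-empty finite vector",
          class = "shuntcheck_domain_error")
  }
  if (sample_rate <= 0) {
    abort("sample_rate must be > 0", class = "shuntcheck_domain_error")
  }
  out <- tibble(
    time = start_time + (seq_along(voltage) - 1) / sample_rate,
    voltage = as.numeric(voltage)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "start_time") <- start_time
  attr(out, "units") <- "V"
  class(out) <- c("signal_trace", class(out))
  out
}

trace_sample_rate <- function(trace) attr(trace, "sample_rate")

#' Synthesise a sinusoidal test tone
#'
#' `dc_offset + (vpp/2) * sin(2 pi f t)`, sampled uniformly. The default
#' spec mirrors the standard bench stimulus: 1 kHz, 15 uV peak-to-peak,
#' 1 mV DC offset.
#'
#' @param spec A [signal_spec()] with `kind = "sine"` (a `"constant"` spec
#'   yields a constant trace at `dc_offset`).
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz; must exceed twice the tone
#'   frequency.
#' @param start_time Time of the first sample (the tone phase is tied to
#'   absolute time, so consecutive segments are continuous).
#' @return A [signal_trace()].
#' @export
synth_sine <- function(spec, duration, sample_rate = 20000, start_time = 0) {
  if (duration <= 0) abort("duration must be > 0",
                           class = "shuntcheck_domain_error")
  n <- round(duration * sample_rate)
  t <- start_time + (seq_len(n) - 1) / sample_rate
  if (spec$kind == "constant" || spec$vpp == 0) {
    return(signal_trace(rep(spec$dc_offset, n), sample_rate, start_time))
  }
  if (sample_rate < 2 * spec$frequency) {
    abort("sample_rate below the Nyquist rate of the tone: aliasing",
          class = "shuntcheck_domain_error")
  }
  v <- spec$dc_offset + (spec$vpp / 2) * sin(2 * pi * spec$frequency * t)
  signal_trace(v, sample_rate, start_time)
}

#' Synthesise an EEG-like band-limited surrogate
#'
#' A seeded Gaussian process band-limited by a brick-wall Fourier mask to
#' `spec$band`, then rescaled so the realised peak-to-peak amplitude equals
#' `vpp` exactly, and offset by `dc_offset`. It stands in for a replayed
#' recording of a real neurological signal: matched in amplitude and band,
#' reproducible from the seed, but with none of the nonstationary structure
#' of real EEG.
#'
#' @param spec A [signal_spec()] with `kind = "eeg_surrogate"`.
#' @inheritParams synth_sine
#' @return A [signal_trace()].
#' @export
synth_eeg_surrogate <- function(spec, duration, sample_rate = 20000,
                                start_time = 0) {
  if (duration <= 0) abort("duration must be > 0",
                           class = "shuntcheck_domain_error")
  if (spec$band[1] <= 0 || spec$band[2] >= sample_rate / 2) {
    abort("band must lie inside (0, sample_rate / 2)",
          class = "shuntcheck_domain_error")
  }
  n <- round(duration * sample_rate)
  x <- withr::with_seed(spec$seed, rnorm(n))
  # brick-wall band-pass in the frequency domain
  freqs <- (seq_len(n) - 1) * sample_rate / n
  freqs <- pmin(freqs, sample_rate - freqs) # two-sided -> absolute frequency
  mask <- freqs >= spec$band[1] & freqs <= spec$band[2]
  x <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  rng <- range(x)
  if (diff(rng) > 0 && spec$vpp != 0) {
    x <- (x - mean(rng)) * (spec$vpp / diff(rng))
  } else {
    x <- x * 0
  }
  signal_trace(x + spec$dc_offset, sample_rate, start_time)
}

#' Synthesise a source described by a signal spec
#'
#' Dispatches on `spec$kind` to [synth_sine()] or [synth_eeg_surrogate()].
#'
#' @inheritParams synth_sine
#' @param spec A [signal_spec()].
#' @return A [signal_trace()].
#' @export
synth_signal <- function(spec, duration, sample_rate = 20000, start_time = 0) {
  switch(spec$kind,
    sine = ,
    constant = synth_sine(spec, duration, sample_rate, start_time),
    eeg_surrogate = synth_eeg_surrogate(spec, duration, sample_rate, start_time)
  )
}

#' Add white and impulsive noise to a trace
#'
#' Adds seeded white Gaussian noise of the stated RMS and, when
#' `impulse_rate > 0`, Poisson-timed biphasic impulses (one sample at
#' `+impulse_amplitude` immediately followed by one at `-impulse_amplitude`).
#'
#' @param trace A [signal_trace()].
#' @param noise A [noise_spec()].
#' @param seed Optional integer overriding `noise$seed`.
#' @return A [signal_trace()] of the same length.
#' @export
add_noise <- function(trace, noise, seed = NULL) {
  seed <- seed %||% noise$seed
  n <- nrow(trace)
  v <- trace$voltage
  withr::with_seed(seed, {
    if (noise$white_rms > 0) {
      v <- v + rnorm(n, sd = noise$white_rms)
    }
    if (noise$impulse_rate > 0 && noise$impulse_amplitude > 0) {
      duration <- n / trace_sample_rate(trace)
      n_events <- rpois(1, noise$impulse_rate * duration)
      if (n_events > 0) {
        at <- sample.int(max(n - 1, 1), n_events, replace = TRUE)
        v[at] <- v[at] + noise$impulse_amplitude
        v[pmin(at + 1, n)] <- v[pmin(at + 1, n)] - noise$impulse_amplitude
      }
    }
  })
  signal_trace(v, trace_sample_rate(trace), attr(trace, "start_time"))
}

#' Quantize a trace with a mid-tread uniform ADC model
#'
#' Mid-tread uniform quantization over `+/- adc_full_scale` with
#' `adc_bits` of resolution; samples beyond the rails are clipped to the
#' nearest representable code. The fraction of clipped samples is recorded
#' in the `clipped_fraction` attribute; clipping in more than 1% of samples
#' raises a warning.
#'
#' @param trace A [signal_trace()] (voltages at the amplifier output).
#' @param params A [front_end_params()] giving `adc_bits` and
#'   `adc_full_scale`.
#' @return A quantized [signal_trace()] with a `clipped_fraction` attribute.
#' @export
quantize <- function(trace, params = front_end_params()) {
  lsb <- 2 * params$adc_full_scale / 2^params$adc_bits
  kmax <- 2^(params$adc_bits - 1) - 1
  kmin <- -2^(params$adc_bits - 1)
  k <- round(trace$voltage / lsb)
  clipped <- k > kmax | k < kmin
  k <- pmin(pmax(k, kmin), kmax)
  out <- signal_trace(k * lsb, trace_sample_rate(trace),
                      attr(trace, "start_time"))
  frac <- mean(clipped)
  attr(out, "clipped_fraction") <- frac
  for (a in c("phases")) if (!is.null(attr(trace, a))) {
    attr(out, a) <- attr(trace, a)
  }
  if (frac > 0.01) {
    warn(sprintf("ADC clipping in %.1f%% of samples", 100 * frac),
         class = "shuntcheck_clipping")
  }
  out
}

#' ADC least-significant-bit size
#'
#' @param params A [front_end_params()].
#' @return The LSB in volts at the amplifier output.
#' @export
adc_lsb <- function(params) {
  2 * params$adc_full_scale / 2^params$adc_bits
}
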