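#' Analog front-end parameters
#'
#' Bundles the known instrument constants of the acquisition front end: the
#' switched shunt resistor `r_shunt` (the known R of the method), the input
#' high-pass filter components `r_hpf` and `c_hpf`, the differential amplifier
#' gain, the ADC resolution and full scale (referred to the amplifier output),
#' and the sampling rate.
#'
#' The estimator assumes `r_hpf >> r_shunt`, so that the shunt network
#' impedance in the signal band is essentially `r_shunt` and the attenuation
#' reduces to a resistive divider. A configuration with
#' `r_hpf < 100 * r_shunt` breaks that approximation and is rejected.
#'
#' @param r_shunt Shunt resistance in ohms (default 5000).
#' @param r_hpf High-pass filter resistance in ohms (default 10 MOhm).
#' @param c_hpf High-pass filter capacitance in farads (default 100 nF,
#'   giving a cutoff of about 0.16 Hz).
#' @param gain Amplifier differential gain in V/V (default 50).
#' @param adc_bits ADC resolution in bits (default 16).
#' @param adc_full_scale ADC full scale in volts at the amplifier output;
#'   default `gain * 32e-3` (a +/-32 mV input range).
#' @param sample_rate Sampling rate in Hz (default 20 kHz).
#'
#' @return An object of class `front_end_params` (a named list).
#' @examples
#' p <- front_end_params()
#' hpf_cutoff(p)
#' @export
front_end_params <- function(r_shunt = 5000,
                             r_hpf = 1e7,
                             c_hpf = 100e-9,
                             gain = 50,
                             adc_bits = 16L,
                             adc_full_scale = gain * 32e-3,
                             sample_rate = 20000) {
  stopifnot(is.numeric(r_shunt), is.numeric(r_hpf), is.numeric(c_hpf),
            is.numeric(gain), is.numeric(sample_rate))
  if (r_shunt <= 0 || r_hpf <= 0 || c_hpf <= 0 || gain <= 0 ||
      sample_rate <= 0 || adc_full_scale <= 0) {
    abort("all front-end parameters must be strictly positive",
          class = "shuntcheck_domain_error")
  }
  if (adc_bits < 2) {
    abort("adc_bits must be at least 2", class = "shuntcheck_domain_error")
  }
  if (r_hpf < 100 * r_shunt) {
    abort(
      "r_hpf must be at least 100 * r_shunt for the divider approximation to hold",
      class = "shuntcheck_config_error"
    )
  }
  structure(
    list(r_shunt = r_shunt, r_hpf = r_hpf, c_hpf = c_hpf, gain = gain,
         adc_bits = as.integer(adc_bits), adc_full_scale = adc_full_scale,
         sample_rate = sample_rate),
    class = "front_end_params"
  )
}

#' @export
print.front_end_params <- function(x, ...) {
  cat("<front_end_params>\n")
  cat(sprintf("  r_shunt: %g Ohm, r_hpf: %g Ohm, c_hpf: %g F (cutoff %.3g Hz)\n",
              x$r_shunt, x$r_hpf, x$c_hpf, hpf_cutoff(x)))
  cat(sprintf("  gain: %g V/V, ADC: %d bits over +/-%g V, fs: %g Hz\n",
              x$gain, x$adc_bits, x$adc_full_scale, x$sample_rate))
  invisible(x)
}

#' High-pass filter cutoff frequency
#'
#' Nominal -3 dB cutoff of the input high-pass filter in normal operation
#' with a negligible contact resistance, `1 / (2 pi c_hpf r_hpf)`.
#'
#' @param params A [front_end_params()] object.
#' @return Cutoff frequency in Hz.
#' @export
hpf_cutoff <- function(params) {
  1 / (2 * pi * params$c_hpf * params$r_hpf)
}

#' Electrode contact model
#'
#' One electrode's skin contact, reduced to a series contact resistance plus
#' a DC half-cell potential. Polarization reactances are deliberately out of
#' scope: the method probes the contact with the in-band biosignal itself, so
#' the contact acts as an averaged-out resistance in the band of interest.
#'
#' @param r_contact Contact resistance in ohms (>= 0).
#' @param e_half_cell Half-cell DC potential in volts (default 0).
#' @return An object of class `electrode_contact`.
#' @export
electrode_contact <- function(r_contact, e_half_cell = 0) {
  if (!is.numeric(r_contact) || length(r_contact) != 1 || !is.finite(r_contact) ||
      r_contact < 0) {
    abort("r_contact must be a single finite non-negative number",
          class = "shuntcheck_domain_error")
  }
  if (!is.numeric(e_half_cell) || !is.finite(e_half_cell)) {
    abort("e_half_cell must be finite", class = "shuntcheck_domain_error")
  }
  structure(list(r_contact = r_contact, e_half_cell = e_half_cell),
            class = "electrode_contact")
}

# -- switch positions and phases ----------------------------------------------

#' Switch positions and phase configurations
#'
#' Each amplifier input has a three-position switch: `"shunt"` connects the
#' known resistor R in parallel with the electrode (position 1), `"normal"`
#' is plain signal acquisition (position 2), `"ground"` ties the input node
#' to system ground (position 3). A *phase* is a pair of switch positions;
#' the measurement protocol uses the labelled phases
#' a = (normal, ground), b = (shunt, ground), c = (ground, normal),
#' d = (ground, shunt), plus "normal" = (normal, normal) for plain recording.
#'
#' @param x A character scalar naming a position.
#' @return `switch_position()` returns the validated position string.
#' @export
switch_position <- function(x) {
  x <- match.arg(x, c("shunt", "normal", "ground"))
  x
}

phase_table <- function() {
  tibble(
    label = c("a", "b", "c", "d", "normal"),
    pos_plus = c("normal", "shunt", "ground", "ground", "normal"),
    pos_minus = c("ground", "ground", "normal", "shunt", "normal")
  )
}

#' @rdname switch_position
#' @param label One of `"a"`, `"b"`, `"c"`, `"d"`, `"normal"`.
#' @return `phase_config()` returns a one-row tibble with columns `label`,
#'   `pos_plus`, `pos_minus`.
#' @export
phase_config <- function(label) {
  tbl <- phase_table()
  label <- match.arg(label, tbl$label)
  tbl[tbl$label == label, ]
}

# -- divider arithmetic -------------------------------------------------------

#' Attenuation coefficient of the shunted input divider
#'
#' When the known shunt resistor R is switched in parallel with an input, the
#' measured signal is attenuated by the resistive divider formed with the
#' contact resistance: `coeff = r_shunt / (r_shunt + r_contact)`. A perfect
#' contact (0 ohm) gives 1; a contact equal to R gives 0.5.
#'
#' @param r_contact Contact resistance(s) in ohms (>= 0). Vectorised.
#' @param r_shunt Known shunt resistance in ohms (> 0).
#' @return Dimensionless attenuation in (0, 1].
#' @examples
#' attenuation_coefficient(c(0, 2500, 5000, 7500), 5000)
#' @export
attenuation_coefficient <- function(r_contact, r_shunt = 5000) {
  if (any(!is.finite(r_contact)) || any(r_contact < 0)) {
    abort("r_contact must be finite and non-negative",
          class = "shuntcheck_domain_error")
  }
  if (any(!is.finite(r_shunt)) || any(r_shunt <= 0)) {
    abort("r_shunt must be finite and strictly positive",
          class = "shuntcheck_domain_error")
  }
  r_shunt / (r_shunt + r_contact)
}

#' Contact resistance from a measured attenuation coefficient
#'
#' Inverts the divider relation: `r = r_shunt * (1 - coeff) / coeff`.
#' Measured coefficients can exceed 1 because of noise; such values would map
#' to impossible negative resistances and are clamped to 0 ohm, with the
#' `clamped` attribute flagging which elements were affected.
#'
#' @param coeff Measured attenuation coefficient(s), > 0. Vectorised.
#' @param r_shunt Known shunt resistance in ohms.
#' @return Contact resistance(s) in ohms, with a logical attribute
#'   `clamped` marking coefficients that exceeded 1.
#' @examples
#' contact_from_coefficient(c(0.4, 0.5, 1, 1.02), 5000)
#' @export
contact_from_coefficient <- function(coeff, r_shunt = 5000) {
  if (any(!is.finite(coeff)) || any(coeff <= 0)) {
    abort("unmeasurable contact: coefficient must be finite and > 0",
          class = "shuntcheck_insufficient_signal")
  }
  if (any(!is.finite(r_shunt)) || any(r_shunt <= 0)) {
    abort("r_shunt must be finite and strictly positive",
          class = "shuntcheck_domain_error")
  }
  clamped <- coeff > 1
  r <- r_shunt * (1 - coeff) / coeff
  r[clamped] <- 0
  structure(r, clamped = clamped)
}

# -- complex network relations ------------------------------------------------

# impedance of the series HPF branch seen from the electrode node
hpf_branch_impedance <- function(frequency, params) {
  w <- 2 * pi * frequency
  xc <- ifelse(w == 0, Inf, 1 / (1i * w * params$c_hpf))
  params$r_hpf + xc
}

#' Impedance of the shunt network
#'
#' Complex impedance seen from the electrode node when the shunt resistor is
#' engaged: the parallel combination of R with the series HPF branch
#' (`r_hpf + 1/(j w c_hpf)`). At DC the capacitor is open and the impedance
#' is exactly R; at high frequency it tends to `R || r_hpf`, which is within
#' a fraction of a percent of R when `r_hpf >> R`.
#'
#' @param frequency Frequency(ies) in Hz (>= 0). Vectorised.
#' @param params A [front_end_params()] object.
#' @return Complex impedance in ohms.
#' @export
shunt_impedance <- function(frequency, params = front_end_params()) {
  if (any(frequency < 0)) {
    abort("frequency must be non-negative", class = "shuntcheck_domain_error")
  }
  zb <- hpf_branch_impedance(frequency, params)
  out <- (zb * params$r_shunt) / (zb + params$r_shunt)
  # DC limit: capacitor open, shunt branch alone
  out[is.infinite(Re(zb)) | frequency == 0] <- params$r_shunt + 0i
  out
}

#' Per-terminal transfer function of the input network
#'
#' Complex gain from one monopolar source to the corresponding amplifier
#' input, for each switch position:
#' * `"normal"`: `r_hpf / (r_hpf + 1/(j w C) + r_contact)` — a one-pole
#'   high-pass whose passband gain is essentially 1;
#' * `"shunt"`: `(Z / (r_contact + Z)) * (r_hpf / (r_hpf + 1/(j w C)))` with
#'   `Z = shunt_impedance()` — in the passband this converges to the
#'   resistive-divider attenuation coefficient;
#' * `"ground"`: identically 0.
#'
#' @param frequency Frequency(ies) in Hz. Vectorised.
#' @param pos A switch position (see [switch_position()]).
#' @param contact An [electrode_contact()].
#' @param params A [front_end_params()] object.
#' @return Complex gain(s).
#' @export
transfer_function <- function(frequency, pos, contact,
                              params = front_end_params()) {
  if (any(frequency < 0)) {
    abort("frequency must be non-negative", class = "shuntcheck_domain_error")
  }
  pos <- switch_position(pos)
  if (pos == "ground") {
    return(rep(0 + 0i, length(frequency)))
  }
  zb <- hpf_branch_impedance(frequency, params)
  if (pos == "normal") {
    h <- params$r_hpf / (zb + contact$r_contact)
  } else {
    z <- shunt_impedance(frequency, params)
    h <- (z / (contact$r_contact + z)) * (params$r_hpf / zb)
  }
  h[frequency == 0] <- 0 + 0i # HPF blocks DC
  h
}

#' Bode table of the input network
#'
#' Evaluates [transfer_function()] over a frequency grid for one or more
#' contact resistance values and returns a tidy table of magnitude (dB) and
#' phase (degrees). The shunt network does not move the high-pass cutoff:
#' each curve's -3 dB point (relative to its own passband plateau) agrees
#' between normal and shunted configurations to well under 1%.
#'
#' @param frequencies Strictly positive frequency grid in Hz.
#' @param pos Switch position, `"normal"` or `"shunt"`.
#' @param contact_values Contact resistances in ohms.
#' @param params A [front_end_params()] object.
#' @return A tibble with columns `frequency`, `r_contact`, `gain` (complex
#'   modulus), `magnitude_db`, `phase_deg`.
#' @export
bode <- function(frequencies, pos, contact_values,
                 params = front_end_params()) {
  if (length(frequencies) == 0 || any(frequencies <= 0)) {
    abort("frequencies must be a non-empty, strictly positive grid",
          class = "shuntcheck_domain_error")
  }
  pos <- switch_position(pos)
  purrr::map_dfr(contact_values, function(rc) {
    h <- transfer_function(frequencies, pos, electrode_contact(rc), params)
    tibble(
      frequency = frequencies,
      r_contact = rc,
      gain = Mod(h),
      magnitude_db = 20 * log10(Mod(h)),
      phase_deg = Arg(h) * 180 / pi
    )
  })
}

#' -3 dB corner frequency of one configuration
#'
#' Finds the frequency at which the transfer-function magnitude falls 3 dB
#' below its own passband plateau (evaluated at 1000x the nominal cutoff),
#' by root bracketing on the closed-form response.
#'
#' @inheritParams transfer_function
#' @return Corner frequency in Hz.
#' @export
corner_frequency <- function(pos, contact, params = front_end_params()) {
  f_hi <- 1000 * hpf_cutoff(params)
  plateau <- Mod(transfer_function(f_hi, pos, contact, params))
  target <- plateau / sqrt(2)
  f <- stats::uniroot(
    function(f) Mod(transfer_function(f, pos, contact, params)) - target,
    lower = hpf_cutoff(params) / 100, upper = f_hi, tol = 1e-12
  )
  f$root
}

# -- settling -----------------------------------------------------------------

# source-side resistance seen through the capacitor for one switch position
source_side_resistance <- function(pos, r_contact, params) {
  switch(pos,
    normal = r_contact,
    shunt  = r_contact * params$r_shunt / (r_contact + params$r_shunt),
    ground = 0
  )
}

#' Settling time of a switch phase
#'
#' Each switch event re-charges the HPF capacitor through
#' `r_hpf + R_eq`, where `R_eq` is the source-side resistance of the active
#' configuration (contact resistance in normal operation, contact parallel
#' shunt when shunted, zero when grounded). The protocol waits twice the
#' larger of the two terminal time constants before computing the RMS.
#'
#' @param phase A phase label or one-row [phase_config()] tibble.
#' @param contact_plus,contact_minus [electrode_contact()] objects.
#' @param params A [front_end_params()] object.
#' @param settle_factor Multiple of tau to wait (default 2).
#' @return A list with `tau_plus`, `tau_minus`, `tau` (the maximum) and
#'   `wait_time = settle_factor * tau`, all in seconds.
#' @export
settle_time <- function(phase, contact_plus, contact_minus,
                        params = front_end_params(), settle_factor = 2) {
  if (is.character(phase)) phase <- phase_config(phase)
  req_p <- source_side_resistance(phase$pos_plus, contact_plus$r_contact, params)
  req_m <- source_side_resistance(phase$pos_minus, contact_minus$r_contact, params)
  tau_p <- params$c_hpf * (params$r_hpf + req_p)
  tau_m <- params$c_hpf * (params$r_hpf + req_m)
  tau <- max(tau_p, tau_m)
  list(tau_plus = tau_p, tau_minus = tau_m, tau = tau,
       wait_time = settle_factor * tau)
}

# -- classification -----------------------------------------------------------

quality_levels <- c("good", "middling", "unacceptable")

#' Classify a contact resistance estimate
#'
#' Applies the two quality thresholds: estimates below `low_threshold` are
#' `"good"`, estimates in `[low_threshold, high_threshold)` are `"middling"`,
#' and estimates at or above `high_threshold` are `"unacceptable"`. The
#' intervals are half-open and the upper boundary is classified as
#' unacceptable — the conservative convention. The defaults bracket the
#' common 5 kOhm EEG acceptability limit.
#'
#' @param r_estimate Contact resistance estimate(s) in ohms. Vectorised.
#' @param low_threshold,high_threshold Class boundaries in ohms
#'   (defaults 2500 and 7500).
#' @return An ordered factor with levels `good < middling < unacceptable`.
#' @examples
#' classify_contact(c(100, 5000, 51000))
#' @export
classify_contact <- function(r_estimate, low_threshold = 2500,
                             high_threshold = 7500) {
  if (any(!is.finite(r_estimate)) || any(r_estimate < 0)) {
    abort("r_estimate must be finite and non-negative (clamp upstream)",
          class = "shuntcheck_domain_error")
  }
  if (!(low_threshold > 0 && low_threshold < high_threshold)) {
    abort("thresholds must satisfy 0 < low < high",
          class = "shuntcheck_domain_error")
  }
  cls <- ifelse(r_estimate < low_threshold, "good",
                ifelse(r_estimate < high_threshold, "middling", "unacceptable"))
  factor(cls, levels = quality_levels, ordered = TRUE)
}

#' Map quality classes to indicator LED colours
#'
#' @param class A quality class factor or character vector.
#' @return Characters among `"green"`, `"yellow"`, `"red"`.
#' @export
class_to_led <- function(class) {
  unname(c(good = "green", middling = "yellow", unacceptable = "red")[
    as.character(class)
  ])
}

#' The nine contact-quality scenarios
#'
#' Two thresholds split each terminal's contact resistance into three classes;
#' a measurement case (one resistance per terminal) therefore falls into one
#' of 3 x 3 = 9 scenarios. A case is assessed correctly when the true and the
#' estimated pair land in the same scenario.
#'
#' @param low_threshold,high_threshold Class boundaries in ohms.
#' @return A character vector of the 9 scenario labels, `"<plus>/<minus>"`.
#' @export
scenario_labels <- function(low_threshold = 2500, high_threshold = 7500) {
  stopifnot(low_threshold > 0, low_threshold < high_threshold)
  as.vector(outer(quality_levels, quality_levels,
                  function(p, m) paste(p, m, sep = "/")))
}

scenario_of <- function(r_plus, r_minus, low = 2500, high = 7500) {
  paste(as.character(classify_contact(r_plus, low, high)),
        as.character(classify_contact(r_minus, low, high)), sep = "/")
}
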