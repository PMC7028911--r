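#' Bench configuration
#'
#' Describes one complete simulated measurement setup: the front end, the two
#' electrode contacts, the monopolar sources feeding them, the common-mode
#' interference, the noise, and the amplifier configuration. In the monopolar
#' modes the opposite terminal is hard-grounded at the amplifier input
#' (bypassing its switch) and its source is forced to zero.
#'
#' @param params A [front_end_params()].
#' @param contact_plus,contact_minus [electrode_contact()] objects.
#' @param source_plus,source_minus [signal_spec()]s for the monopolar
#'   biopotentials v+ and v-.
#' @param common_mode A [signal_spec()] added identically to both sources
#'   (default: 1 mV peak-to-peak 50 Hz sine, the mains pickup the bench
#'   emulates).
#' @param r_common Common ground-path resistance in ohms (default 0,
#'   negligible for a floating, high-CMRR front end).
#' @param ground_potential DC potential of the ground electrode in volts.
#' @param noise A [noise_spec()].
#' @param mode `"bipolar"`, `"monopolar_plus"` or `"monopolar_minus"`.
#' @param quantize_output If `TRUE` (default) the simulated amplifier output
#'   is passed through the ADC model; `FALSE` gives the ideal analog chain
#'   used for mathematical-model validation.
#' @return An object of class `bench_config`.
#' @export
bench_config <- function(params = front_end_params(),
                         contact_plus = electrode_contact(100),
                         contact_minus = electrode_contact(100),
                         source_plus = signal_spec("sine", frequency = 1000,
                                                   vpp = 15e-6,
                                                   dc_offset = 1e-3),
                         source_minus = signal_spec("sine", frequency = 1000,
                                                    vpp = -15e-6,
                                                    dc_offset = 1e-3),
                         common_mode = signal_spec("sine", frequency = 50,
                                                   vpp = 1e-3),
                         r_common = 0,
                         ground_potential = 0,
                         noise = noise_spec(),
                         mode = c("bipolar", "monopolar_plus",
                                  "monopolar_minus"),
                         quantize_output = TRUE) {
  mode <- match.arg(mode)
  # a negated source is expressed as vpp < 0 internally; normalise here
  structure(
    list(params = params, contact_plus = contact_plus,
         contact_minus = contact_minus, source_plus = source_plus,
         source_minus = source_minus, common_mode = common_mode,
         r_common = r_common, ground_potential = ground_potential,
         noise = noise, mode = mode, quantize_output = quantize_output),
    class = "bench_config"
  )
}

#' Switch schedule
#'
#' An ordered list of phases with durations, as a tibble with columns
#' `label`, `pos_plus`, `pos_minus`, `duration`.
#'
#' @param labels Character vector of phase labels (see [phase_config()]).
#' @param durations Positive durations in seconds, recycled to
#'   `length(labels)`.
#' @return A tibble of class `switch_schedule`.
#' @export
switch_schedule <- function(labels, durations) {
  if (length(labels) == 0) {
    abort("schedule must contain at least one phase",
          class = "shuntcheck_domain_error")
  }
  if (any(durations <= 0)) {
    abort("phase durations must be > 0", class = "shuntcheck_domain_error")
  }
  cfg <- purrr::map_dfr(labels, phase_config)
  cfg$duration <- rep_len(durations, length(labels))
  class(cfg) <- c("switch_schedule", class(cfg))
  cfg
}

# Thevenin equivalent of the electrode-side network seen by the HPF capacitor:
# returns the scale applied to the source voltage and the series resistance.
thevenin_source <- function(pos, r_contact, params) {
  switch(pos,
    normal = list(scale = 1, r = r_contact),
    shunt = list(
      scale = params$r_shunt / (r_contact + params$r_shunt),
      r = r_contact * params$r_shunt / (r_contact + params$r_shunt)
    ),
    ground = list(scale = 0, r = 0)
  )
}

#' Simulate one input terminal through one switch phase
#'
#' Integrates the single-pole input network (source, contact resistance,
#' optional shunt or ground, series HPF capacitor, shunt HPF resistor) with
#' the exact zero-order-hold exponential update, carrying the capacitor
#' voltage as the state variable so that switching transients emerge from
#' state continuity across calls.
#'
#' @param source A [signal_trace()] of the monopolar source (common mode
#'   included), sampled at `params$sample_rate`.
#' @param dc Additional DC in series with the source (half-cell potential),
#'   in volts.
#' @param pos Switch position for this phase.
#' @param contact The terminal's [electrode_contact()].
#' @param params A [front_end_params()].
#' @param initial_capacitor_voltage Capacitor state at entry, in volts.
#' @return A list with `trace` (the amplifier-input voltage v') and
#'   `final_capacitor_voltage`.
#' @export
simulate_terminal <- function(source, dc, pos, contact,
                              params = front_end_params(),
                              initial_capacitor_voltage = 0) {
  fs <- trace_sample_rate(source)
  if (!isTRUE(all.equal(fs, params$sample_rate))) {
    abort("source sample rate must match params$sample_rate",
          class = "shuntcheck_domain_error")
  }
  pos <- switch_position(pos)
  th <- thevenin_source(pos, contact$r_contact, params)
  v_th <- th$scale * (source$voltage + dc)
  tau <- params$c_hpf * (params$r_hpf + th$r)
  a <- exp(-1 / (fs * tau))
  u <- as.numeric(stats::filter((1 - a) * v_th, a, method = "recursive",
                                init = initial_capacitor_voltage))
  k <- params$r_hpf / (th$r + params$r_hpf)
  vprime <- k * (v_th - u)
  list(
    trace = signal_trace(vprime, fs, attr(source, "start_time")),
    final_capacitor_voltage = u[length(u)]
  )
}

# generate the three bench sources for one phase; surrogates are regenerated
# from their own seed for each phase (replay of the same recorded segment,
# as an arbitrary waveform generator on loop would do), while sines and
# constants follow absolute time and stay phase-continuous across switches.
phase_sources <- function(bench, duration, start_time) {
  fs <- bench$params$sample_rate
  synth_one <- function(spec) {
    if (spec$kind == "eeg_surrogate") {
      synth_signal(spec, duration, fs, start_time = 0)$voltage
    } else {
      synth_signal(spec, duration, fs, start_time = start_time)$voltage
    }
  }
  vcm <- synth_one(bench$common_mode) + bench$ground_potential
  list(
    plus = if (bench$mode == "monopolar_minus") 0 * vcm else
      synth_one(bench$source_plus) + vcm,
    minus = if (bench$mode == "monopolar_plus") 0 * vcm else
      synth_one(bench$source_minus) + vcm
  )
}

#' Simulate the full acquisition chain over a switch schedule
#'
#' Runs both input terminals through every phase of the schedule with
#' capacitor-state continuity, forms the differential signal, injects
#' input-referred noise, applies the amplifier gain and (optionally) the ADC
#' model. Switching transients appear in the output exactly as they do on a
#' hardware bench, because the capacitor voltages are carried across switch
#' events.
#'
#' @param bench A [bench_config()].
#' @param schedule A [switch_schedule()].
#' @param seed Integer seed controlling the noise realisation.
#' @return A [signal_trace()] of the (optionally quantized) amplifier output,
#'   with a `phases` attribute: a tibble of `label`, `start`, `end` times in
#'   seconds.
#' @export
simulate <- function(bench, schedule, seed = 1L) {
  if (nrow(schedule) == 0) {
    abort("schedule must be non-empty", class = "shuntcheck_domain_error")
  }
  params <- bench$params
  fs <- params$sample_rate
  # initial capacitor states: the DC operating point of ongoing normal
  # recording (source DC + half-cell), so the first phase starts from the
  # physically settled condition
  dc_p <- bench$contact_plus$e_half_cell +
    if (bench$mode == "monopolar_minus") 0 else bench$source_plus$dc_offset
  dc_m <- bench$contact_minus$e_half_cell +
    if (bench$mode == "monopolar_plus") 0 else bench$source_minus$dc_offset
  u_p <- dc_p + bench$ground_potential
  u_m <- dc_m + bench$ground_potential
  t0 <- 0
  diff_v <- vector("list", nrow(schedule))
  starts <- ends <- numeric(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    dur <- schedule$duration[i]
    n <- round(dur * fs)
    src <- phase_sources(bench, n / fs, t0)
    # hard grounding in monopolar modes bypasses the switch entirely
    if (bench$mode == "monopolar_plus") {
      vpm <- list(trace = signal_trace(rep(0, n), fs, t0),
                  final_capacitor_voltage = u_m)
    } else {
      vpm <- simulate_terminal(
        signal_trace(src$minus, fs, t0),
        bench$contact_minus$e_half_cell, schedule$pos_minus[i],
        bench$contact_minus, params, u_m
      )
    }
    if (bench$mode == "monopolar_minus") {
      vpp <- list(trace = signal_trace(rep(0, n), fs, t0),
                  final_capacitor_voltage = u_p)
    } else {
      vpp <- simulate_terminal(
        signal_trace(src$plus, fs, t0),
        bench$contact_plus$e_half_cell, schedule$pos_plus[i],
        bench$contact_plus, params, u_p
      )
    }
    u_p <- vpp$final_capacitor_voltage
    u_m <- vpm$final_capacitor_voltage
    diff_v[[i]] <- vpp$trace$voltage - vpm$trace$voltage
    starts[i] <- t0
    ends[i] <- t0 + n / fs
    t0 <- ends[i]
  }
  d <- unlist(diff_v)
  d_tr <- signal_trace(d, fs, 0)
  if (bench$noise$white_rms > 0 || bench$noise$impulse_rate > 0) {
    d_tr <- add_noise(d_tr, bench$noise, seed = seed)
  }
  out <- signal_trace(params$gain * d_tr$voltage, fs, 0)
  attr(out, "phases") <- tibble(label = schedule$label,
                                start = starts, end = ends)
  if (bench$quantize_output) {
    out <- quantize(out, params)
  }
  out
}
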