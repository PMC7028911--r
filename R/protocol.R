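#' Streaming RMS
#'
#' Single-pass RMS as a microcontroller computes it: accumulate the sum and
#' the sum of squares once, then take `sqrt(sum(x^2)/n)` or, with
#' `remove_dc`, `sqrt(sum(x^2)/n - mean(x)^2)`. DC removal (the default)
#' protects the phase statistic against residual settling and quantization
#' offsets.
#'
#' @param samples Numeric vector of at least 2 samples.
#' @param remove_dc Subtract the window mean before squaring (default TRUE).
#' @return The RMS in the units of `samples`.
#' @examples
#' streaming_rms(sin(2 * pi * seq(0, 1, length.out = 1001)[-1]),
#'               remove_dc = FALSE) # ~ 1/sqrt(2)
#' @export
streaming_rms <- function(samples, remove_dc = TRUE) {
  n <- length(samples)
  if (n < 2) {
    abort("need at least 2 samples", class = "shuntcheck_domain_error")
  }
  s1 <- sum(samples)
  s2 <- sum(samples^2)
  ms <- s2 / n - if (remove_dc) (s1 / n)^2 else 0
  # guard the cancellation of the one-pass formula: below the floating-point
  # noise floor of s2/n the residual is roundoff, not signal
  if (ms < 1e-13 * s2 / n) ms <- 0
  sqrt(max(ms, 0))
}

#' Four-phase measurement record
#'
#' Holds the settled RMS statistic of each protocol phase. Monopolar runs
#' fill only their pair (a, b for the positive terminal; c, d for the
#' negative), leaving the others `NA`.
#'
#' @param f_va,f_vb,f_vc,f_vd Phase statistics in volts (>= 0 or NA).
#' @param window_duration Analysis window length in seconds.
#' @param settle_used Settling time applied before each window, seconds.
#' @param statistic_name Name of the statistic (default `"rms"`).
#' @param mode Amplifier configuration the phases were run in.
#' @return An object of class `four_phase_measurement`.
#' @export
four_phase_measurement <- function(f_va = NA_real_, f_vb = NA_real_,
                                   f_vc = NA_real_, f_vd = NA_real_,
                                   window_duration, settle_used,
                                   statistic_name = "rms",
                                   mode = "bipolar") {
  vals <- c(f_va, f_vb, f_vc, f_vd)
  if (any(!is.na(vals) & (vals < 0 | !is.finite(vals)))) {
    abort("phase statistics must be finite and non-negative",
          class = "shuntcheck_domain_error")
  }
  if (window_duration <= 0) {
    abort("window_duration must be > 0", class = "shuntcheck_domain_error")
  }
  structure(
    list(f_va = f_va, f_vb = f_vb, f_vc = f_vc, f_vd = f_vd,
         window_duration = window_duration, settle_used = settle_used,
         statistic_name = statistic_name, mode = mode),
    class = "four_phase_measurement"
  )
}

#' @export
print.four_phase_measurement <- function(x, ...) {
  cat("<four_phase_measurement>", x$mode, "\n")
  cat(sprintf("  F(va)=%.4g F(vb)=%.4g F(vc)=%.4g F(vd)=%.4g V (%s)\n",
              x$f_va, x$f_vb, x$f_vc, x$f_vd, x$statistic_name))
  cat(sprintf("  window %.3g s after %.3g s settling\n",
              x$window_duration, max(x$settle_used)))
  invisible(x)
}

protocol_labels <- function(mode) {
  switch(mode,
    bipolar = c("a", "b", "c", "d"),
    monopolar_plus = c("a", "b"),
    monopolar_minus = c("c", "d")
  )
}

#' Run the switched-shunt measurement sequence
#'
#' Sequences the protocol phases (a = (normal, ground), b = (shunt, ground),
#' c = (ground, normal), d = (ground, shunt); monopolar modes run only their
#' pair), waits `settle_factor` time constants after each switch event, and
#' computes the RMS of the amplifier output over the trailing analysis
#' window of each phase. All phases share a common duration (the largest
#' settling requirement plus the window) so that a replayed surrogate source
#' presents identical content to every phase.
#'
#' @param bench A [bench_config()].
#' @param window Analysis window in seconds (default 0.2 s: an integer
#'   number of both 50 Hz and 1 kHz cycles).
#' @param seed Integer seed for the noise realisation.
#' @param settle_factor Multiples of tau to wait before the window
#'   (default 2).
#' @param remove_dc Passed to [streaming_rms()].
#' @param signal_floor Minimum acceptable phase RMS in volts at the
#'   amplifier output; defaults to three times the quantization noise RMS
#'   (`3 * lsb / sqrt(12)`) when the ADC model is active, else 0. A phase
#'   below the floor aborts with an insufficient-signal error.
#' @return A [four_phase_measurement()], with the simulated output trace in
#'   the `trace` attribute.
#' @export
run_sequence <- function(bench, window = 0.2, seed = 1L, settle_factor = 2,
                         remove_dc = TRUE, signal_floor = NULL) {
  if (window <= 0) abort("window must be > 0",
                         class = "shuntcheck_domain_error")
  labels <- protocol_labels(bench$mode)
  taus <- purrr::map_dbl(labels, function(lb) {
    settle_time(lb, bench$contact_plus, bench$contact_minus,
                bench$params, settle_factor)$wait_time
  })
  fs <- bench$params$sample_rate
  # common phase duration, rounded up to a whole number of analysis windows:
  # every phase then cuts its window at the same offset modulo the window
  # length, so periodic interference (mains) and a replayed source present
  # identical content to every window and cancel exactly in the RMS ratios
  duration <- ceiling((max(taus) + window) / window) * window
  duration <- round(duration * fs) / fs
  sched <- switch_schedule(labels, duration)
  out <- simulate(bench, sched, seed = seed)
  phases <- attr(out, "phases")
  n_win <- round(window * fs)
  f <- purrr::map_dbl(seq_len(nrow(phases)), function(i) {
    i_end <- round(phases$end[i] * fs)
    streaming_rms(out$voltage[(i_end - n_win + 1):i_end], remove_dc)
  })
  names(f) <- phases$label
  floor_v <- signal_floor %||%
    if (bench$quantize_output) 3 * adc_lsb(bench$params) / sqrt(12) else 0
  if (any(f < floor_v)) {
    abort(sprintf("insufficient signal: phase RMS below floor (%.3g V)",
                  floor_v),
          class = "shuntcheck_insufficient_signal")
  }
  meas <- four_phase_measurement(
    f_va = unname(f["a"]), f_vb = unname(f["b"]),
    f_vc = unname(f["c"]), f_vd = unname(f["d"]),
    window_duration = window, settle_used = duration - window,
    mode = bench$mode
  )
  attr(meas, "trace") <- out
  meas
}

#' Attenuation coefficients from a four-phase measurement
#'
#' `alpha = F(vb) / F(va)` for the positive terminal and
#' `beta = F(vd) / F(vc)` for the negative; the shunted-phase statistic over
#' the normal-phase statistic.
#'
#' @param meas A [four_phase_measurement()].
#' @return A named list with `alpha` and `beta` (NA for a terminal the
#'   measurement did not cover).
#' @export
protocol_coefficients <- function(meas) {
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den <= 0) {
      abort("insufficient signal: zero reference-phase RMS",
            class = "shuntcheck_insufficient_signal")
    }
    num / den
  }
  list(alpha = ratio(meas$f_vb, meas$f_va),
       beta = ratio(meas$f_vd, meas$f_vc))
}

#' Assess electrode contact quality
#'
#' The full passive measurement pipeline: run the switch sequence, form the
#' RMS-ratio attenuation coefficients, invert them to contact resistances
#' (clamping coefficients above 1 to 0 ohm), and classify each terminal
#' against the quality thresholds.
#'
#' @inheritParams run_sequence
#' @param thresholds Two class boundaries in ohms,
#'   `c(low, high)` (default `c(2500, 7500)`).
#' @param n_repeats Number of protocol repetitions; the per-terminal median
#'   coefficient is used when `n_repeats > 1` (robustness against impulsive
#'   noise hitting a single phase). Default 1.
#' @return An object of class `impedance_assessment`; see [tidy()] and
#'   [glance()] methods for tabular views.
#' @examples
#' \donttest{
#' b <- bench_config(contact_plus = electrode_contact(100),
#'                   contact_minus = electrode_contact(51000))
#' a <- assess(b, seed = 7)
#' tidy(a)
#' }
#' @export
assess <- function(bench, window = 0.2, seed = 1L,
                   thresholds = c(2500, 7500), settle_factor = 2,
                   remove_dc = TRUE, n_repeats = 1L) {
  meas_list <- purrr::map(seq_len(n_repeats), function(k) {
    run_sequence(bench, window = window, seed = seed + k - 1L,
                 settle_factor = settle_factor, remove_dc = remove_dc)
  })
  reps <- purrr::map(meas_list, protocol_coefficients)
  meas <- meas_list[[1]]
  alpha <- stats::median(purrr::map_dbl(reps, "alpha"))
  beta <- stats::median(purrr::map_dbl(reps, "beta"))

  one_side <- function(coeff) {
    if (is.na(coeff)) {
      return(list(r = NA_real_, class = factor(NA, quality_levels,
                                               ordered = TRUE),
                  clamped = NA))
    }
    r <- contact_from_coefficient(coeff, bench$params$r_shunt)
    list(r = as.numeric(r),
         class = classify_contact(as.numeric(r), thresholds[1], thresholds[2]),
         clamped = attr(r, "clamped"))
  }
  p <- one_side(alpha)
  m <- one_side(beta)
  structure(
    list(alpha = alpha, beta = beta,
         r_plus_est = p$r, r_minus_est = m$r,
         class_plus = p$class, class_minus = m$class,
         clamped_plus = p$clamped, clamped_minus = m$clamped,
         mode = bench$mode, thresholds = thresholds,
         window = window, settle_used = meas$settle_used,
         measurement = meas),
    class = "impedance_assessment"
  )
}

#' Assess contact quality from a recorded trace
#'
#' The bridge to real hardware: consumes an externally recorded amplifier
#' output trace plus phase annotations (which switch phase was active when)
#' and runs the estimation stages only — per-phase RMS, coefficients,
#' inversion, classification.
#'
#' @param trace A [signal_trace()] of the recorded amplifier output, or a
#'   path to a two-column delimited text file (see [read_signal_trace()]).
#' @param phases A tibble/data.frame with columns `label`, `start_s`,
#'   `end_s`, or a path to a delimited text file with those columns.
#' @param params A [front_end_params()] describing the recording instrument
#'   (the shunt value is what matters here).
#' @param window Optional trailing window in seconds within each annotated
#'   phase; default uses the whole annotated span.
#' @param thresholds Quality thresholds in ohms.
#' @param remove_dc Passed to [streaming_rms()].
#' @return An `impedance_assessment`.
#' @export
assess_trace <- function(trace, phases, params = front_end_params(),
                         window = NULL, thresholds = c(2500, 7500),
                         remove_dc = TRUE) {
  if (is.character(trace)) trace <- read_signal_trace(trace)
  if (is.character(phases)) {
    phases <- readr::read_delim(phases, delim = "\t", show_col_types = FALSE)
  }
  stopifnot(all(c("label", "start_s", "end_s") %in% names(phases)))
  fs <- trace_sample_rate(trace)
  f <- rep(NA_real_, 4)
  names(f) <- c("a", "b", "c", "d")
  win_lens <- numeric(0)
  for (i in seq_len(nrow(phases))) {
    lab <- phases$label[i]
    sel <- trace$time >= phases$start_s[i] & trace$time < phases$end_s[i]
    x <- trace$voltage[sel]
    if (!is.null(window)) {
      nw <- min(length(x), round(window * fs))
      x <- tail(x, nw)
    }
    f[lab] <- streaming_rms(x, remove_dc)
    win_lens <- c(win_lens, length(x) / fs)
  }
  mode <- if (all(!is.na(f))) "bipolar"
          else if (all(!is.na(f[c("a", "b")]))) "monopolar_plus"
          else "monopolar_minus"
  f <- unname(f)
  names(f) <- NULL
  meas <- four_phase_measurement(f[1], f[2], f[3], f[4],
                                 window_duration = min(win_lens),
                                 settle_used = 0, mode = mode)
  co <- protocol_coefficients(meas)
  one_side <- function(coeff) {
    if (is.na(coeff)) {
      return(list(r = NA_real_, class = factor(NA, quality_levels,
                                               ordered = TRUE),
                  clamped = NA))
    }
    r <- contact_from_coefficient(coeff, params$r_shunt)
    list(r = as.numeric(r),
         class = classify_contact(as.numeric(r), thresholds[1], thresholds[2]),
         clamped = attr(r, "clamped"))
  }
  p <- one_side(co$alpha)
  m <- one_side(co$beta)
  structure(
    list(alpha = co$alpha, beta = co$beta,
         r_plus_est = p$r, r_minus_est = m$r,
         class_plus = p$class, class_minus = m$class,
         clamped_plus = p$clamped, clamped_minus = m$clamped,
         mode = mode, thresholds = thresholds,
         window = meas$window_duration, settle_used = 0,
         measurement = meas),
    class = "impedance_assessment"
  )
}

#' @export
print.impedance_assessment <- function(x, ...) {
  cat("<impedance_assessment>", x$mode, "\n")
  fmt <- function(coeff, r, cls, clamped) {
    if (is.na(coeff)) return("  (not measured)\n")
    sprintf("  coeff = %.4f -> %s Ohm [%s, LED %s]%s\n", coeff,
            format(round(r, 1), big.mark = ","), as.character(cls),
            class_to_led(cls), if (isTRUE(clamped)) " (clamped)" else "")
  }
  cat("  positive terminal:\n")
  cat(fmt(x$alpha, x$r_plus_est, x$class_plus, x$clamped_plus))
  cat("  negative terminal:\n")
  cat(fmt(x$beta, x$r_minus_est, x$class_minus, x$clamped_minus))
  invisible(x)
}

#' Serialize an assessment to JSON
#'
#' @param x An `impedance_assessment`.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
assessment_json <- function(x, path = NULL) {
  obj <- list(
    alpha = x$alpha, beta = x$beta,
    r_plus_ohm = x$r_plus_est, r_minus_ohm = x$r_minus_est,
    class_plus = as.character(x$class_plus),
    class_minus = as.character(x$class_minus),
    led_plus = class_to_led(x$class_plus),
    led_minus = class_to_led(x$class_minus),
    clamped_plus = x$clamped_plus, clamped_minus = x$clamped_minus,
    mode = x$mode, window_s = x$window, settle_s = max(x$settle_used)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
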