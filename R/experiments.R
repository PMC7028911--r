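#' @keywords internal
#' @noRd
new_experiment_report <- function(cases, name, seed, config) {
  out <- as_tibble(cases)
  attr(out, "experiment_name") <- name
  attr(out, "seed") <- seed
  attr(out, "config_snapshot") <- config
  class(out) <- c("experiment_report", class(out))
  out
}

report_config_snapshot <- function(params, extra = list()) {
  as.character(jsonlite::toJSON(c(unclass(params), extra),
                                auto_unbox = TRUE, digits = NA))
}

# bench for the validation experiments; `ideal` reproduces the
# mathematical-model conditions (no noise, no ADC, no DC), otherwise the
# full laboratory chain (50 Hz common mode, DC offsets, noise, ADC)
experiment_bench <- function(params, r_plus, r_minus, ideal,
                             source_kind = "sine", source_seed = 1L,
                             mode = "bipolar") {
  dc <- if (ideal) 0 else 1e-3
  mk_source <- function(sign) {
    if (source_kind == "sine") {
      signal_spec("sine", frequency = 1000, vpp = sign * 15e-6,
                  dc_offset = dc)
    } else {
      signal_spec("eeg_surrogate", vpp = sign * 15e-6, dc_offset = dc,
                  seed = source_seed)
    }
  }
  bench_config(
    params = params,
    contact_plus = electrode_contact(r_plus),
    contact_minus = electrode_contact(r_minus),
    source_plus = mk_source(1),
    source_minus = mk_source(-1),
    common_mode = if (ideal) signal_spec("constant", vpp = 0) else
      signal_spec("sine", frequency = 50, vpp = 1e-3),
    noise = if (ideal) noise_spec(white_rms = 0) else noise_spec(),
    mode = mode,
    quantize_output = !ideal
  )
}

assess_row <- function(bench, rep_id, seed, window = 0.2,
                       thresholds = c(2500, 7500)) {
  a <- assess(bench, window = window, seed = seed, thresholds = thresholds)
  r_p <- bench$contact_plus$r_contact
  r_m <- bench$contact_minus$r_contact
  tibble(
    r_plus_true = r_p, r_minus_true = r_m, replicate = rep_id,
    alpha = a$alpha, beta = a$beta,
    r_plus_est = a$r_plus_est, r_minus_est = a$r_minus_est,
    class_plus = as.character(a$class_plus),
    class_minus = as.character(a$class_minus),
    scenario_true = scenario_of(r_p, r_m, thresholds[1], thresholds[2]),
    scenario_est = scenario_of(a$r_plus_est, a$r_minus_est,
                               thresholds[1], thresholds[2])
  )
}

#' Sixteen-case validation grid
#'
#' Runs the full bipolar assessment over the 4 x 4 grid of contact
#' resistances \{100, 1000, 5000, 51000\} ohm for each terminal and tabulates
#' estimated against true values and scenarios. With `noise_off = TRUE` the
#' chain runs under mathematical-model conditions (no noise, ideal ADC, no
#' DC offsets, 1 kHz test tone) and every case recovers its contact
#' resistance to within a couple of percent; with `noise_off = FALSE` the
#' full laboratory chain (50 Hz common mode, white noise, quantization, DC
#' offsets) is simulated.
#'
#' @param params A [front_end_params()].
#' @param noise_off Run the idealised mathematical-model chain.
#' @param replicates Repetitions per grid point (default 1).
#' @param seed Integer seed; replicate seeds are derived deterministically.
#' @param values Grid of contact resistances in ohms.
#' @return An `experiment_report` tibble with one row per (case, replicate).
#' @export
grid16 <- function(params = front_end_params(), noise_off = TRUE,
                   replicates = 1L, seed = 1L,
                   values = c(100, 1000, 5000, 51000)) {
  stopifnot(replicates >= 1)
  grid <- tidyr::expand_grid(r_plus = values, r_minus = values,
                             replicate = seq_len(replicates))
  cases <- purrr::pmap_dfr(grid, function(r_plus, r_minus, replicate) {
    b <- experiment_bench(params, r_plus, r_minus, ideal = noise_off)
    assess_row(b, replicate,
               seed = seed + 131L * replicate +
                 match(r_plus, values) + 7L * match(r_minus, values))
  })
  new_experiment_report(
    cases, "grid16", seed,
    report_config_snapshot(params, list(noise_off = noise_off,
                                        values = values))
  )
}

#' Monopolar sweep of contact resistance
#'
#' Repeats the monopolar assessment (one terminal hard-grounded) over a
#' sweep of contact resistances, for both terminals, producing a
#' boxplot-ready replicate table together with the theoretical
#' divider-attenuation curve.
#'
#' @param params A [front_end_params()].
#' @param values Contact resistances in ohms (default: the nine-point bench
#'   sweep 100, 200, 500, 1 k, 2.4 k, 5 k, 10 k, 20 k, 51 k).
#' @param replicates Measurements per value (default 10).
#' @param seed Integer seed.
#' @param terminals Which terminals to sweep (default both).
#' @return An `experiment_report` with columns `terminal`, `r_true`,
#'   `replicate`, `coefficient`, `coeff_theory`, `r_est`, `class`.
#' @export
monopolar_sweep <- function(params = front_end_params(),
                            values = c(100, 200, 500, 1000, 2400, 5000,
                                       10000, 20000, 51000),
                            replicates = 10L, seed = 1L,
                            terminals = c("plus", "minus")) {
  stopifnot(all(values > 0), replicates >= 1)
  grid <- tidyr::expand_grid(terminal = terminals, r_true = values,
                             replicate = seq_len(replicates))
  cases <- purrr::pmap_dfr(grid, function(terminal, r_true, replicate) {
    mode <- paste0("monopolar_", terminal)
    b <- experiment_bench(
      params,
      r_plus = if (terminal == "plus") r_true else 0,
      r_minus = if (terminal == "minus") r_true else 0,
      ideal = FALSE, mode = mode
    )
    a <- assess(b, seed = seed + 977L * replicate +
                  17L * match(r_true, values) +
                  1000L * match(terminal, c("plus", "minus")))
    coeff <- if (terminal == "plus") a$alpha else a$beta
    r_est <- if (terminal == "plus") a$r_plus_est else a$r_minus_est
    cls <- if (terminal == "plus") a$class_plus else a$class_minus
    tibble(
      terminal = terminal, r_true = r_true, replicate = replicate,
      coefficient = coeff,
      coeff_theory = attenuation_coefficient(r_true, params$r_shunt),
      r_est = r_est, class = as.character(cls)
    )
  })
  new_experiment_report(
    cases, "monopolar_sweep", seed,
    report_config_snapshot(params, list(values = values,
                                        replicates = replicates))
  )
}

#' Nine-case bipolar sequential grid
#'
#' Sequential bipolar assessment over the 3 x 3 grid of three widely spaced
#' contact resistances (100 ohm, 5 kohm, 51 kohm) per terminal, with an
#' EEG-like replayed surrogate as the biosignal — the laboratory bench
#' experiment. Coefficient-space thresholds (0.4 and 0.67, the images of the
#' 7.5 kohm and 2.5 kohm resistance thresholds) are recorded in the report
#' attributes for plotting.
#'
#' @param params A [front_end_params()].
#' @param replicates Repetitions per case (default 10).
#' @param seed Integer seed.
#' @param values Contact resistances in ohms.
#' @param noise_off Run under idealised conditions (default FALSE).
#' @return An `experiment_report` with the 16-column case schema plus
#'   attributes `coeff_thresholds` and `r_thresholds`.
#' @export
bipolar_grid9 <- function(params = front_end_params(), replicates = 10L,
                          seed = 1L, values = c(100, 5000, 51000),
                          noise_off = FALSE) {
  stopifnot(replicates >= 1)
  grid <- tidyr::expand_grid(r_plus = values, r_minus = values,
                             replicate = seq_len(replicates))
  cases <- purrr::pmap_dfr(grid, function(r_plus, r_minus, replicate) {
    b <- experiment_bench(params, r_plus, r_minus, ideal = noise_off,
                          source_kind = "eeg_surrogate",
                          source_seed = seed + replicate)
    assess_row(b, replicate,
               seed = seed + 211L * replicate +
                 match(r_plus, values) + 5L * match(r_minus, values))
  })
  out <- new_experiment_report(
    cases, "bipolar_grid9", seed,
    report_config_snapshot(params, list(values = values,
                                        replicates = replicates,
                                        noise_off = noise_off))
  )
  attr(out, "coeff_thresholds") <- c(
    attenuation_coefficient(7500, params$r_shunt),
    attenuation_coefficient(2500, params$r_shunt)
  )
  attr(out, "r_thresholds") <- c(2500, 7500)
  out
}

#' Bode report table
#'
#' Thin wrapper over [bode()] that optionally writes the table as delimited
#' text.
#'
#' @param params A [front_end_params()].
#' @param contact_values Contact resistances in ohms.
#' @param pos Switch position, `"normal"` or `"shunt"`.
#' @param frequencies Frequency grid in Hz (default log-spaced
#'   0.01 Hz - 10 kHz).
#' @param path Optional output file (tab-delimited).
#' @return The bode tibble, invisibly when written to `path`.
#' @export
bode_report <- function(params = front_end_params(),
                        contact_values = c(100, 1000, 5000, 51000),
                        pos = "normal",
                        frequencies = 10^seq(-2, 4, length.out = 241),
                        path = NULL) {
  tbl <- bode(frequencies, pos, contact_values, params)
  if (!is.null(path)) {
    readr::write_tsv(tbl, path)
    return(invisible(tbl))
  }
  tbl
}

#' Summarise replicate statistics of an experiment report
#'
#' Median and quartiles of the resistance estimates (and coefficients, when
#' present) per case — the numbers a boxplot would draw.
#'
#' @param report An `experiment_report`.
#' @return A tibble of per-case summary statistics.
#' @export
report_summary <- function(report) {
  if ("r_est" %in% names(report)) {
    dplyr::summarise(
      dplyr::group_by(report, .data$terminal, .data$r_true),
      coeff_median = stats::median(.data$coefficient),
      r_median = stats::median(.data$r_est),
      r_q1 = stats::quantile(.data$r_est, 0.25),
      r_q3 = stats::quantile(.data$r_est, 0.75),
      .groups = "drop"
    )
  } else {
    dplyr::summarise(
      dplyr::group_by(report, .data$r_plus_true, .data$r_minus_true),
      alpha_median = stats::median(.data$alpha),
      beta_median = stats::median(.data$beta),
      r_plus_median = stats::median(.data$r_plus_est),
      r_minus_median = stats::median(.data$r_minus_est),
      n_correct = sum(.data$scenario_est == .data$scenario_true),
      n = dplyr::n(),
      .groups = "drop"
    )
  }
}
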