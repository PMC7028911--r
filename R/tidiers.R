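#' Tidy an impedance assessment
#'
#' One row per terminal: the measured attenuation coefficient, the contact
#' resistance estimate, the quality class and its LED colour, and whether
#' the coefficient was clamped.
#'
#' @param x An `impedance_assessment`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy impedance_assessment
#' @export
tidy.impedance_assessment <- function(x, ...) {
  tibble(
    terminal = c("plus", "minus"),
    coefficient = c(x$alpha, x$beta),
    r_est = c(x$r_plus_est, x$r_minus_est),
    class = c(as.character(x$class_plus), as.character(x$class_minus)),
    led = c(class_to_led(x$class_plus), class_to_led(x$class_minus)),
    clamped = c(x$clamped_plus, x$clamped_minus)
  )
}

#' Glance at an impedance assessment
#'
#' @param x An `impedance_assessment`.
#' @param ... Unused.
#' @return A one-row tibble of the headline quantities.
#' @method glance impedance_assessment
#' @export
glance.impedance_assessment <- function(x, ...) {
  tibble(
    alpha = x$alpha, beta = x$beta,
    r_plus_est = x$r_plus_est, r_minus_est = x$r_minus_est,
    class_plus = as.character(x$class_plus),
    class_minus = as.character(x$class_minus),
    mode = x$mode, window_s = x$window, settle_s = max(x$settle_used)
  )
}
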