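test_that("streaming RMS equals the closed forms and the batch oracle", {
  # unit-amplitude sine over integer periods
  t <- seq(0, 1, length.out = 20001)[-1]
  expect_equal(streaming_rms(sin(2 * pi * 10 * t), remove_dc = FALSE),
               1 / sqrt(2), tolerance = 1e-6)
  # constants vanish under DC removal
  expect_equal(streaming_rms(rep(3.7, 100), remove_dc = TRUE), 0)
  expect_equal(streaming_rms(rep(3.7, 100), remove_dc = FALSE), 3.7)
  # single-pass accumulation against the two-pass batch computation
  withr::with_seed(5, x <- rnorm(10000, mean = 2, sd = 3))
  batch_centered <- sqrt(mean((x - mean(x))^2))
  batch_raw <- sqrt(mean(x^2))
  expect_equal(streaming_rms(x, remove_dc = TRUE), batch_centered,
               tolerance = 1e-12)
  expect_equal(streaming_rms(x, remove_dc = FALSE), batch_raw,
               tolerance = 1e-12)
  expect_error(streaming_rms(1), class = "shuntcheck_domain_error")
})

test_that("the four-phase sequence follows the prescribed switch order", {
  b <- ideal_bench(100, 1000)
  m <- run_sequence(b, window = 0.2, seed = 1)
  tr <- attr(m, "trace")
  ph <- attr(tr, "phases")
  expect_equal(ph$label, c("a", "b", "c", "d"))
  # labels map to switch positions (SW+, SW-) = (2,3),(1,3),(3,2),(3,1)
  cfg <- purrr::map_dfr(ph$label, phase_config)
  expect_equal(cfg$pos_plus, c("normal", "shunt", "ground", "ground"))
  expect_equal(cfg$pos_minus, c("ground", "ground", "normal", "shunt"))
  # monopolar runs keep only their pair
  mp <- run_sequence(ideal_bench(100, 0, mode = "monopolar_plus"), seed = 1)
  expect_false(is.na(mp$f_va) || is.na(mp$f_vb))
  expect_true(is.na(mp$f_vc) && is.na(mp$f_vd))
})

test_that("noise-free phase ratios reproduce the divider attenuation", {
  # perfect contacts: no attenuation in either pair
  m0 <- run_sequence(ideal_bench(0, 0), seed = 1)
  expect_equal(m0$f_vb / m0$f_va, 1, tolerance = 5e-3)
  expect_equal(m0$f_vd / m0$f_vc, 1, tolerance = 5e-3)
  # a contact equal to the shunt halves the signal
  m5 <- run_sequence(ideal_bench(5000, 0), seed = 1)
  expect_equal(m5$f_vb / m5$f_va, 0.5, tolerance = 0.01)
})

test_that("coefficients are the phase-RMS ratios", {
  m <- four_phase_measurement(f_va = 2, f_vb = 2, f_vc = 4, f_vd = 1,
                              window_duration = 0.2, settle_used = 2)
  co <- protocol_coefficients(m)
  expect_equal(co$alpha, 1)
  expect_equal(co$beta, 0.25)
  bad <- four_phase_measurement(f_va = 0, f_vb = 1, f_vc = 1, f_vd = 1,
                                window_duration = 0.2, settle_used = 2)
  expect_error(protocol_coefficients(bad),
               class = "shuntcheck_insufficient_signal")
})

test_that("a symmetric bench yields matching coefficients", {
  b <- ideal_bench(5000, 5000, kind = "eeg_surrogate")
  co <- protocol_coefficients(run_sequence(b, seed = 3))
  expect_equal(co$alpha, co$beta, tolerance = 0.02)
})

test_that("coefficient estimates do not depend on the test signal", {
  # the method's premise: the measured signal itself suffices, whatever it is
  a_sine <- assess(lab_bench(5000, 1000, kind = "sine"), seed = 2)
  a_sur <- assess(lab_bench(5000, 1000, kind = "eeg_surrogate"), seed = 2)
  expect_equal(a_sur$alpha, a_sine$alpha, tolerance = 0.01)
  expect_equal(a_sur$beta, a_sine$beta, tolerance = 0.01)
})

test_that("assess runs the full pipeline and classifies both terminals", {
  a <- assess(ideal_bench(100, 51000), seed = 1)
  expect_s3_class(a, "impedance_assessment")
  expect_equal(as.character(a$class_plus), "good")
  expect_equal(as.character(a$class_minus), "unacceptable")
  expect_equal(a$r_plus_est, 100, tolerance = 0.02)
  expect_equal(a$r_minus_est, 51000, tolerance = 0.02)
  expect_false(a$clamped_plus || a$clamped_minus)
  td <- tidy(a)
  expect_equal(td$terminal, c("plus", "minus"))
  expect_equal(td$led, c("green", "red"))
  expect_equal(nrow(glance(a)), 1)
})

test_that("assessment is deterministic given the seed", {
  b <- lab_bench(1000, 5000)
  a1 <- assess(b, seed = 11)
  a2 <- assess(b, seed = 11)
  expect_identical(glance(a1), glance(a2))
})

test_that("coefficients above one clamp to a zero-ohm estimate", {
  # craft a recorded trace whose shunted phase reads louder than normal
  fs <- 2000
  mk <- function(amp) amp * sin(2 * pi * 50 * seq(1 / fs, 1, by = 1 / fs))
  tr <- signal_trace(c(mk(1), mk(1.02), mk(1), mk(0.5)), fs)
  ann <- tibble::tibble(label = c("a", "b", "c", "d"),
                        start_s = c(0, 1, 2, 3), end_s = c(1, 2, 3, 4))
  a <- assess_trace(tr, ann, front_end_params())
  expect_equal(a$alpha, 1.02, tolerance = 1e-6)
  expect_true(a$clamped_plus)
  expect_equal(a$r_plus_est, 0)
  expect_equal(as.character(a$class_plus), "good")
  expect_equal(a$r_minus_est, 5000, tolerance = 1e-6)
  # exact boundary estimates classify conservatively
  expect_equal(as.character(classify_contact(7500)), "unacceptable")
})

test_that("phases too weak to measure raise an insufficient-signal error", {
  b <- lab_bench(100, 100)
  b$source_plus <- signal_spec("sine", frequency = 1000, vpp = 1e-7)
  b$source_minus <- signal_spec("sine", frequency = 1000, vpp = -1e-7)
  b$common_mode <- signal_spec("constant", vpp = 0)
  b$noise <- noise_spec(white_rms = 0)
  expect_error(run_sequence(b, seed = 1),
               class = "shuntcheck_insufficient_signal")
})

test_that("repeat-and-median resists an impulse hitting one phase", {
  b <- lab_bench(5000, 5000)
  b$noise <- noise_spec(white_rms = 0.5e-6, impulse_rate = 0.5,
                        impulse_amplitude = 5e-4, seed = 3L)
  a <- assess(b, seed = 3, n_repeats = 5)
  expect_equal(a$r_plus_est, 5000, tolerance = 0.15)
  expect_equal(a$r_minus_est, 5000, tolerance = 0.15)
})

test_that("assessment serializes to the documented JSON schema", {
  a <- assess(ideal_bench(100, 51000), seed = 1)
  js <- jsonlite::fromJSON(assessment_json(a))
  expect_equal(js$alpha, a$alpha, tolerance = 1e-12)
  expect_equal(js$r_minus_ohm, a$r_minus_est, tolerance = 1e-12)
  expect_equal(js$led_plus, "green")
  expect_equal(js$class_minus, "unacceptable")
  expect_equal(js$mode, "bipolar")
})
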