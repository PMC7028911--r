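test_that("front-end parameter validation enforces the divider assumptions", {
  expect_s3_class(front_end_params(), "front_end_params")
  expect_error(front_end_params(r_shunt = -5), class = "shuntcheck_domain_error")
  expect_error(front_end_params(gain = 0), class = "shuntcheck_domain_error")
  expect_error(front_end_params(adc_bits = 1), class = "shuntcheck_domain_error")
  # r_hpf must dominate the shunt for the method's approximations
  expect_error(front_end_params(r_hpf = 5000 * 50),
               class = "shuntcheck_config_error")
  expect_error(electrode_contact(-1), class = "shuntcheck_domain_error")
  expect_error(electrode_contact(100, Inf), class = "shuntcheck_domain_error")
})

test_that("attenuation coefficient matches the resistive divider", {
  expect_identical(attenuation_coefficient(5000, 5000), 0.5)
  expect_identical(attenuation_coefficient(0, 5000), 1)
  expect_identical(attenuation_coefficient(7500, 5000), 0.4)
  expect_equal(attenuation_coefficient(2500, 5000), 2 / 3, tolerance = 1e-12)
  expect_equal(round(attenuation_coefficient(2500, 5000), 2), 0.67)
  # strictly decreasing in contact resistance
  rc <- seq(0, 1e5, length.out = 200)
  expect_true(all(diff(attenuation_coefficient(rc, 5000)) < 0))
  expect_error(attenuation_coefficient(-1, 5000),
               class = "shuntcheck_domain_error")
})

test_that("coefficient inversion recovers resistance and clamps above 1", {
  expect_equal(as.numeric(contact_from_coefficient(0.5, 5000)), 5000)
  expect_equal(as.numeric(contact_from_coefficient(1, 5000)), 0)
  expect_equal(as.numeric(contact_from_coefficient(0.4, 5000)), 7500)
  # direct evaluation of the divider inverse at a measured bench value
  expect_equal(as.numeric(contact_from_coefficient(0.987, 5000)),
               5000 * (1 - 0.987) / 0.987, tolerance = 1e-12)
  expect_equal(as.numeric(contact_from_coefficient(0.987, 5000)), 65.86,
               tolerance = 1e-4)
  r <- contact_from_coefficient(1.02, 5000)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))
  expect_error(contact_from_coefficient(0, 5000),
               class = "shuntcheck_insufficient_signal")
  expect_error(contact_from_coefficient(NaN, 5000),
               class = "shuntcheck_insufficient_signal")
})

test_that("divider arithmetic round-trips over the physical range", {
  withr::with_seed(11, {
    rc <- 10^runif(200, 0, 6)
    rs <- 10^runif(200, 3, 5)
  })
  back <- as.numeric(contact_from_coefficient(
    attenuation_coefficient(rc, rs), rs
  ))
  expect_equal(back, rc, tolerance = 1e-9)
  # inversion strictly decreasing in the coefficient
  co <- seq(0.01, 1, length.out = 100)
  expect_true(all(diff(as.numeric(contact_from_coefficient(co, 5000))) < 0))
})

test_that("shunt network impedance has the right limits", {
  p <- front_end_params()
  expect_equal(shunt_impedance(0, p), 5000 + 0i)
  z_inf <- 5000 * 1e7 / (5000 + 1e7) # R || r_hpf
  expect_equal(Mod(shunt_impedance(1e9, p)), z_inf, tolerance = 1e-6)
  expect_equal(Mod(shunt_impedance(1000, p)), z_inf, tolerance = 1e-3)
  expect_error(shunt_impedance(-1, p), class = "shuntcheck_domain_error")
})

test_that("per-terminal transfer functions match their closed forms", {
  p <- front_end_params()
  # normal operation in the passband is transparent
  h <- transfer_function(1000, "normal", electrode_contact(100), p)
  expect_equal(Mod(h), 0.99999, tolerance = 1e-5)
  # grounding nulls the input
  expect_identical(transfer_function(c(0, 10, 1e4), "ground",
                                     electrode_contact(100), p),
                   rep(0 + 0i, 3))
  # shunted gain converges to the divider coefficient in the passband
  h51 <- Mod(transfer_function(1000, "shunt", electrode_contact(51000), p))
  expect_equal(h51, attenuation_coefficient(51000, 5000), tolerance = 5e-3)
  # DC is blocked in every configuration
  expect_equal(Mod(transfer_function(0, "normal", electrode_contact(100), p)),
               0)
  expect_equal(Mod(transfer_function(0, "shunt", electrode_contact(100), p)),
               0)
})

test_that("shunted passband gain tracks the divider within 0.5% broadly", {
  p <- front_end_params()
  for (rc in c(100, 1000, 5000, 51000, 2e5)) {
    h <- Mod(transfer_function(1000, "shunt", electrode_contact(rc), p))
    expect_equal(h, attenuation_coefficient(rc, p$r_shunt), tolerance = 5e-3)
  }
})

test_that("bode tables reproduce plateau behaviour and cutoff invariance", {
  p <- front_end_params()
  freqs <- 10^seq(-2, 4, length.out = 121)
  nb <- bode(freqs, "normal", c(100, 1000, 5000, 51000), p)
  # passband flatness: normal-mode plateau within 0.05 dB of 0 dB
  plateau <- dplyr::filter(nb, frequency > 100)
  expect_true(all(abs(plateau$magnitude_db) < 0.05))
  # shunted plateau at Rc = R sits at 20 log10(0.5)
  sb <- bode(freqs, "shunt", 5000, p)
  expect_equal(max(sb$magnitude_db), 20 * log10(0.5), tolerance = 1e-2)
  # plateau magnitude monotone decreasing in contact resistance
  sb_all <- bode(1000, "shunt", c(100, 1000, 5000, 51000), p)
  expect_true(all(diff(sb_all$gain) < 0))
  # -3 dB corner is not moved by the shunt (<= 1% shift in any scenario)
  for (rc in c(100, 1000, 5000, 51000)) {
    fc_n <- corner_frequency("normal", electrode_contact(rc), p)
    fc_s <- corner_frequency("shunt", electrode_contact(rc), p)
    expect_equal(fc_s, fc_n, tolerance = 1e-2)
  }
  expect_error(bode(numeric(0), "normal", 100, p),
               class = "shuntcheck_domain_error")
})

test_that("settling times follow the source-side resistance", {
  p <- front_end_params() # r_hpf = 10 MOhm, c_hpf = 100 nF
  st <- settle_time("c", electrode_contact(0), electrode_contact(0), p)
  expect_equal(st$tau_plus, 1.0) # grounded terminal: c_hpf * r_hpf
  st2 <- settle_time("a", electrode_contact(100), electrode_contact(0), p)
  expect_equal(st2$tau_plus, 1e-7 * (1e7 + 100)) # ~ 1.00001 s
  expect_equal(st2$wait_time, 2 * st2$tau)
  # shunting can only reduce the source-side resistance
  tn <- settle_time("a", electrode_contact(5000), electrode_contact(0), p)
  ts <- settle_time("b", electrode_contact(5000), electrode_contact(0), p)
  expect_lt(ts$tau_plus, tn$tau_plus)
  # phase tau is the max of the two terminals
  st3 <- settle_time("a", electrode_contact(100), electrode_contact(51000), p)
  expect_equal(st3$tau, max(st3$tau_plus, st3$tau_minus))
})

test_that("quality classification applies half-open conservative intervals", {
  expect_equal(as.character(classify_contact(100)), "good")
  expect_equal(as.character(classify_contact(5000)), "middling")
  expect_equal(as.character(classify_contact(51000)), "unacceptable")
  # boundaries: low -> middling, high -> unacceptable
  expect_equal(as.character(classify_contact(c(2500, 7500))),
               c("middling", "unacceptable"))
  expect_true(is.ordered(classify_contact(100)))
  expect_true(classify_contact(100) < classify_contact(5000))
  expect_error(classify_contact(-1), class = "shuntcheck_domain_error")
  expect_equal(class_to_led(classify_contact(c(100, 5000, 51000))),
               c("green", "yellow", "red"))
})

test_that("two thresholds induce exactly nine scenarios", {
  labs <- scenario_labels(2500, 7500)
  expect_length(labs, 9)
  expect_length(unique(labs), 9)
  expect_true("good/unacceptable" %in% labs)
})
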