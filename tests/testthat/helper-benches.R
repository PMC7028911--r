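# standard bench fixtures, built in code

# idealised chain: no noise, no ADC, no DC -- the mathematical-model
# conditions under which the estimator is exact up to the r_hpf >> R
# approximation
ideal_bench <- function(r_plus, r_minus, kind = "sine", seed = 42L,
                        mode = "bipolar", cm = FALSE) {
  bench_config(
    contact_plus = electrode_contact(r_plus),
    contact_minus = electrode_contact(r_minus),
    source_plus = signal_spec(kind, frequency = 1000, vpp = 15e-6,
                              seed = seed),
    source_minus = signal_spec(kind, frequency = 1000, vpp = -15e-6,
                               seed = seed),
    common_mode = if (cm) signal_spec("sine", frequency = 50, vpp = 1e-3)
                  else signal_spec("constant", vpp = 0),
    noise = noise_spec(white_rms = 0),
    mode = mode,
    quantize_output = FALSE
  )
}

# full laboratory chain: 50 Hz common mode, DC offsets, white noise, ADC
lab_bench <- function(r_plus, r_minus, kind = "eeg_surrogate", seed = 42L,
                      mode = "bipolar") {
  bench_config(
    contact_plus = electrode_contact(r_plus),
    contact_minus = electrode_contact(r_minus),
    source_plus = signal_spec(kind, frequency = 1000, vpp = 15e-6,
                              dc_offset = 1e-3, seed = seed),
    source_minus = signal_spec(kind, frequency = 1000, vpp = -15e-6,
                               dc_offset = 1e-3, seed = seed),
    common_mode = signal_spec("sine", frequency = 50, vpp = 1e-3),
    noise = noise_spec(white_rms = 0.5e-6),
    mode = mode,
    quantize_output = TRUE
  )
}

severity <- function(class) {
  match(as.character(class), c("good", "middling", "unacceptable"))
}
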