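# clean periodic fixture: no noise, no wander, no RR jitter
clean_config <- function(duration_s = 10, fs = 360, heart_rate = 60,
                         seed = 1L, beat_classes = "regular") {
  synth_config(fs = fs, duration_s = duration_s, heart_rate = heart_rate,
               noise_std = 0, baseline_wander_amp = 0,
               rr_jitter_frac = 0, seed = seed,
               beat_classes = beat_classes)
}

# detection-chain preprocessing used across tests
preprocess_detect <- function(record) {
  remove_baseline_dwt(bandpass_filter(record, bandpass_spec()),
                      wavelet_plan())
}

unitary_dft <- function(x) stats::fft(x) / sqrt(length(x))
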