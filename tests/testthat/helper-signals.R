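# small signal builders used across tests

sine_wave <- function(n, freq, fs = 500, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# a quick valid 16-channel recording from a channel-building function
toy_recording <- function(n = 2000, fs = 500, build = function(ch) rnorm(n),
                          labels = canonical_channels(),
                          subject_id = "T01", condition = "eyes_closed") {
  data <- t(vapply(seq_len(16), build, numeric(n)))
  eeg_recording(subject_id, condition, fs, labels, data)
}

tiny_cohort_args <- function(n_uws = 3, n_mcs = 3, epoch_len = 1024,
                             seed = 42, ...) {
  list(n_uws = n_uws, n_mcs = n_mcs, epoch_len = epoch_len,
       recording_margin_s = 0, seed = seed, ...)
}
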