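# Shared fixture builders. Everything is generated in code at test time.

# A nine-lead recording where every channel is the same pure tone.
tone_recording <- function(freq_hz, amp_pp_uv, fs = 250, duration_s = 16.4,
                           phase = 0, leads = nine_leads()) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- (amp_pp_uv / 2) * sin(2 * pi * freq_hz * t + phase)
  recording(matrix(rep(sig, each = length(leads)), nrow = length(leads)),
            fs = fs, labels = leads, subject = "tone")
}

# One epoch (vector) holding a sum of tones; freqs snapped to the fft grid
# when `snap` is TRUE.
tone_epoch <- function(freqs_hz, amps_pp_uv, fs = 250, n = 2050,
                       snap = TRUE, phases = NULL) {
  if (snap) freqs_hz <- round(freqs_hz * n / fs) * fs / n
  if (is.null(phases)) phases <- rep(pi / 4, length(freqs_hz))
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (i in seq_along(freqs_hz)) {
    sig <- sig + (amps_pp_uv[i] / 2) * sin(2 * pi * freqs_hz[i] * t + phases[i])
  }
  sig
}

# Band-table tibble from a named lead -> amplitude vector for one band.
one_band_table <- function(band, amplitudes, subject = "S01") {
  tibble::tibble(subject = subject, lead = names(amplitudes), band = band,
                 amplitude_uv = unname(amplitudes))
}

# Group-mean band table from the reference cohort statistics.
reference_mean_table <- function() {
  ref <- reference_cohort_stats()
  tibble::tibble(subject = "group", lead = ref$lead, band = ref$band,
                 amplitude_uv = ref$mean)
}
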