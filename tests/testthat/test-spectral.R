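test_that("calculation resolution is fs/N and matches the printed buffer arithmetic", {
  expect_equal(calculation_resolution(1000, 1000), 1)
  # 2048-point buffer spanning 8.2 s -> 0.12 Hz at two decimals
  expect_equal(round(calculation_resolution(2048 / 8.2, 2048), 2), 0.12)
  # r = 1/T for any fs = N/T
  expect_equal(calculation_resolution(512 / 4, 512), 0.25)
  expect_equal(calculation_resolution(128, 128), 1)
  expect_error(calculation_resolution(-1, 100), "fs")
  expect_error(calculation_resolution(100, 1), "n")
})

test_that("a bin-centered sinusoid recovers its peak-to-peak amplitude at its bin", {
  cfg <- spectral_config(fs = 250)
  sig <- tone_epoch(10, 10, n = 2048)   # 5 uV peak, snapped to grid
  sp <- amplitude_spectrum(sig, cfg)
  i <- which.max(sp$amplitude_pp_uv)
  expect_equal(sp$freq_hz[i], 10, tolerance = 0.13)
  expect_equal(sp$amplitude_pp_uv[i], 10, tolerance = 0.1)

  expect_true(all(amplitude_spectrum(numeric(2048), cfg)$amplitude_pp_uv == 0))
})

test_that("a pure DC offset concentrates at the 0 Hz bin", {
  cfg <- spectral_config(fs = 250)
  sp <- amplitude_spectrum(rep(3, 2048), cfg)
  expect_equal(sp$amplitude_uv[1], 3, tolerance = 1e-9)
  expect_lt(max(sp$amplitude_uv[sp$freq_hz >= 0.5]), 0.05)
})

test_that("spectrum invariants: grid spacing, power = squared magnitude, length check", {
  cfg <- spectral_config(fs = 250)
  sig <- tone_epoch(c(6, 10), c(4, 8), n = 2050)
  sp <- amplitude_spectrum(sig, cfg)
  expect_equal(unique(round(diff(sp$freq_hz), 12)),
               round(calculation_resolution(250, 2050), 12))
  expect_lt(max(abs(sp$power_uv2 - sp$amplitude_pp_uv^2)) /
              max(sp$power_uv2), 1e-9)
  cfg_n <- spectral_config(fs = 250, n = 2048)
  expect_error(amplitude_spectrum(sig, cfg_n), "2050")
})

test_that("the hann window recovers bin-centered amplitudes after gain correction", {
  cfg <- spectral_config(fs = 250, window = "hann")
  sig <- tone_epoch(10, 10, n = 2048)
  sp <- amplitude_spectrum(sig, cfg)
  i <- which.max(sp$amplitude_pp_uv)
  expect_equal(sp$amplitude_pp_uv[i], 10, tolerance = 0.1)
})

test_that("peak detection enforces the amplitude floor and minimum separation", {
  cfg <- spectral_config(fs = 250)
  n <- 2050
  # two tones 0.2 Hz apart: the larger survives
  sig <- tone_epoch(c(10, 10.2), c(10, 6), n = n)
  peaks <- detect_spectral_peaks(amplitude_spectrum(sig, cfg), cfg)
  in_alpha <- peaks[peaks$freq_hz > 8 & peaks$freq_hz < 12, ]
  expect_equal(nrow(in_alpha), 1)
  expect_equal(in_alpha$freq_hz, 10, tolerance = 0.13)

  # a tone below the 0.5 uV floor yields no peaks
  faint <- tone_epoch(10, 0.2, n = n)
  expect_equal(nrow(detect_spectral_peaks(amplitude_spectrum(faint, cfg), cfg)), 0)

  # three well-separated tones yield exactly three peaks
  sig3 <- tone_epoch(c(6, 10, 25), c(10, 10, 10), n = n)
  p3 <- detect_spectral_peaks(amplitude_spectrum(sig3, cfg), cfg)
  expect_equal(nrow(p3), 3)
  expect_equal(sort(p3$freq_hz), c(6, 10, 25), tolerance = 0.13)
})

test_that("two tones below the resolution limit merge; above it they split", {
  cfg <- spectral_config(fs = 250)
  n <- 2050
  r <- 250 / n
  # separation < r: one peak
  sig_close <- tone_epoch(c(10, 10 + 0.5 * r), c(8, 8), n = n, snap = FALSE)
  p_close <- detect_spectral_peaks(amplitude_spectrum(sig_close, cfg), cfg)
  expect_equal(nrow(p_close[p_close$freq_hz > 9 & p_close$freq_hz < 11, ]), 1)
  # separation >= 2r and >= 0.5 Hz: two peaks
  sig_far <- tone_epoch(c(10, 10.6), c(8, 8), n = n)
  p_far <- detect_spectral_peaks(amplitude_spectrum(sig_far, cfg), cfg)
  expect_equal(nrow(p_far[p_far$freq_hz > 9 & p_far$freq_hz < 11.5, ]), 2)
})

test_that("band amplitude extracts the dominant peak per band with half-open edges", {
  cfg <- spectral_config(fs = 250)
  sig <- tone_epoch(10, 10, n = 2050)
  sp <- amplitude_spectrum(sig, cfg)
  expect_equal(band_amplitude(sp, "Alpha", cfg), 10, tolerance = 0.1)
  for (b in c("Delta", "Theta", "SMR", "Beta1", "Beta2")) {
    expect_lt(band_amplitude(sp, b, cfg), 0.5)
  }
  # zero spectrum -> 0 for all bands
  sp0 <- amplitude_spectrum(numeric(2050), cfg)
  for (b in canonical_bands()$band) expect_equal(band_amplitude(sp0, b, cfg), 0)
  # 12 Hz (on-grid in a 10 s buffer) belongs to SMR, not Alpha
  sp12 <- amplitude_spectrum(tone_epoch(12, 10, n = 2500, snap = FALSE), cfg)
  expect_equal(band_amplitude(sp12, "SMR", cfg), 10, tolerance = 0.1)
  expect_lt(band_amplitude(sp12, "Alpha", cfg), 0.5)
  expect_error(band_amplitude(sp, "Gamma", cfg), "unknown band")
})

test_that("no frequency bin in [0.5, 35) is assigned to two bands", {
  bands <- qeegband:::canonical_band_list()
  f <- seq(0.5, 34.99, by = 250 / 2050)
  counts <- rowSums(vapply(bands, function(b) qeegband:::in_band(f, b),
                           logical(length(f))))
  expect_true(all(counts == 1))
})

test_that("integral-average mode averages bin amplitudes over the band", {
  cfg <- spectral_config(fs = 250, mode = "integral_average")
  sig <- tone_epoch(10, 10, n = 2050)
  sp <- amplitude_spectrum(sig, cfg)
  alpha_bins <- sum(sp$freq_hz >= 8 & sp$freq_hz < 12)
  expect_equal(band_amplitude(sp, "Alpha", cfg), 10 / alpha_bins,
               tolerance = 0.01)
})

test_that("subject band tables average per-epoch amplitudes over unrejected epochs", {
  # identical epochs: table equals a single epoch's amplitudes
  fs <- 250; len <- 2050
  one <- tone_epoch(10, 8, n = len)
  m <- matrix(rep(rep(one, 3), each = 2), nrow = 2)
  rec <- recording(m, fs = fs, labels = c("Cz", "Pz"))
  tbl <- subject_band_table(epoch_recording(rec, 8.2))
  alpha <- tbl$amplitude_uv[tbl$band == "Alpha" & tbl$lead == "Cz"]
  expect_equal(alpha, 8, tolerance = 0.1)
  expect_equal(unique(tbl$n_epochs), 3)

  # epochs alternating 4 and 6 uV Alpha -> 5 uV
  alt <- c(tone_epoch(10, 4, n = len), tone_epoch(10, 6, n = len))
  rec2 <- recording(matrix(rep(alt, each = 2), nrow = 2), fs = fs,
                    labels = c("Cz", "Pz"))
  tbl2 <- subject_band_table(epoch_recording(rec2, 8.2))
  expect_equal(tbl2$amplitude_uv[tbl2$band == "Alpha" & tbl2$lead == "Cz"],
               5, tolerance = 0.05)

  # zero surviving epochs propagates as a failure
  ep <- epoch_recording(rec, 8.2)
  ep$rejected[] <- TRUE
  expect_error(subject_band_table(ep), "no unrejected epochs")
})
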