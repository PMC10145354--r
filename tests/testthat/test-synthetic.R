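test_that("a single-band profile yields a sinusoid at the target peak-to-peak amplitude", {
  prof <- band_profile(c(Alpha = 10), center_freqs = c(Alpha = 10))
  rec <- generate_clean_recording(prof, fs = 250, duration_s = 10, seed = 1)
  cz <- rec$samples["Cz", ]
  expect_equal(diff(range(cz)), 10, tolerance = 0.01)     # peak-to-peak
  # dominant frequency is 10 Hz
  sp <- amplitude_spectrum(cz[1:2050], spectral_config(fs = 250))
  expect_equal(sp$freq_hz[which.max(sp$amplitude_pp_uv)], 10, tolerance = 0.13)
})

test_that("an all-zero profile yields a recording at (or below) the noise floor", {
  zero <- band_profile(c(Alpha = 0))
  rec <- generate_clean_recording(zero, duration_s = 10, seed = 1)
  expect_true(all(rec$samples == 0))
  noisy <- generate_clean_recording(zero, duration_s = 10, seed = 1,
                                    noise_floor_uv = 0.1)
  expect_lt(max(abs(noisy$samples)), 1)
})

test_that("generator rejects sub-Nyquist sampling rates and negative amplitudes", {
  prof <- band_profile(c(Beta2 = 5))
  expect_error(generate_clean_recording(prof, fs = 60, duration_s = 10),
               "Nyquist")
  expect_error(band_profile(c(Alpha = -1)), ">= 0")
  expect_error(band_profile(c(Gamma = 5)), "unknown band")
  expect_error(band_profile(c(Alpha = 5), center_freqs = c(Alpha = 13)),
               "outside")
})

test_that("amplitude fidelity holds per channel and band through the analysis pipeline", {
  ref <- reference_cohort_stats()
  amp <- matrix(0, 9, 6, dimnames = list(nine_leads(), canonical_bands()$band))
  for (i in seq_len(nrow(ref))) amp[ref$lead[i], ref$band[i]] <- ref$mean[i]
  prof <- band_profile(amp)
  rec <- generate_clean_recording(prof, fs = 250, duration_s = 16.4, seed = 5)
  tbl <- subject_band_table(epoch_recording(rec))
  merged <- dplyr::inner_join(tbl, ref, by = c("lead", "band"))
  expect_gt(nrow(merged), 50)
  expect_lt(max(abs(merged$amplitude_uv - merged$mean) / merged$mean), 0.01)
})

test_that("cohorts are reproducible, truncated at zero, and degenerate at SD 0", {
  spec <- cohort_spec(n_subjects = 3, duration_s = 8.2, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$recordings[[2]]$samples, b$recordings[[2]]$samples)
  expect_true(all(a$ground_truth$amplitude_uv >= 0))

  params0 <- reference_cohort_stats()
  params0$sd <- 0
  spec0 <- cohort_spec(n_subjects = 2, params = params0,
                       duration_s = 8.2, seed = 1)
  c0 <- generate_cohort(spec0)
  gt <- c0$ground_truth
  expect_identical(gt$amplitude_uv[gt$subject == "S01"],
                   gt$amplitude_uv[gt$subject == "S02"])
})

test_that("cohort ground-truth means track the generating means within 3 SE", {
  spec <- cohort_spec(n_subjects = 18, duration_s = 8.2, seed = 123)
  coh <- generate_cohort(spec)
  ref <- reference_cohort_stats()
  means <- coh$ground_truth |>
    dplyr::group_by(lead, band) |>
    dplyr::summarise(emp = mean(amplitude_uv), .groups = "drop") |>
    dplyr::inner_join(ref, by = c("lead", "band"))
  frac_ok <- mean(abs(means$emp - means$mean) <= 3 * means$sd / sqrt(18))
  expect_gt(frac_ok, 0.9)
})

test_that("cohort spec validation catches bad inputs", {
  expect_error(cohort_spec(n_subjects = 1), ">= 2")
  bad <- reference_cohort_stats(); bad$sd[1] <- -1
  expect_error(cohort_spec(params = bad), ">= 0")
  expect_error(cohort_spec(fs = 250, duration_s = 10.001), "integer sample")
})

test_that("cohort specs load from YAML config documents", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 4", "fs: 250", "duration_s: 8.2", "seed: 7"), path)
  spec <- read_cohort_spec(path)
  expect_equal(spec$n_subjects, 4L)
  expect_equal(spec$seed, 7L)
  expect_equal(nrow(spec$params), 54)
})

test_that("artifact injection is conservative and seed-deterministic", {
  prof <- band_profile(c(Alpha = 10, Theta = 8))
  rec <- generate_clean_recording(prof, duration_s = 20, seed = 2)
  specs <- list(artifact_spec("blink"), artifact_spec("ecg"),
                artifact_spec("emg"), artifact_spec("jaw"),
                artifact_spec("respiration"))
  inj <- inject_artifacts(rec, specs, seed = 3)
  # contaminated - artifacts == clean, sample-exact
  expect_equal(inj$recording$samples - inj$artifacts, rec$samples,
               tolerance = 1e-12)
  inj2 <- inject_artifacts(rec, specs, seed = 3)
  expect_identical(inj$recording$samples, inj2$recording$samples)
  expect_identical(sort(names(inj$by_class)),
                   sort(c("blink", "ecg", "emg", "jaw", "respiration")))
})

test_that("an empty artifact list returns the input unchanged", {
  prof <- band_profile(c(Alpha = 10))
  rec <- generate_clean_recording(prof, duration_s = 10, seed = 2)
  inj <- inject_artifacts(rec, list(), seed = 1)
  expect_identical(inj$recording$samples, rec$samples)
  expect_true(all(inj$artifacts == 0))
})

test_that("unknown artifact classes are rejected with the supported list", {
  expect_error(artifact_spec("yawn"), "blink, ecg, emg, jaw, respiration")
})

test_that("blinks load frontal channels and barely touch parietal ones", {
  prof <- band_profile(c(Alpha = 10))
  rec <- generate_clean_recording(prof, duration_s = 60, seed = 4)
  inj <- inject_artifacts(rec, artifact_spec("blink", 12, 100), seed = 5)
  rms_added <- apply(inj$artifacts, 1, function(x) sqrt(mean(x^2)))
  rms_clean <- apply(rec$samples, 1, function(x) sqrt(mean(x^2)))
  rms_cont <- apply(inj$recording$samples, 1, function(x) sqrt(mean(x^2)))
  expect_gt(rms_added[["Fz"]], rms_clean[["Fz"]])          # frontal dominated
  expect_lt(abs(rms_cont[["P3"]] / rms_clean[["P3"]] - 1), 0.05)  # parietal RMS ~unchanged
})

test_that("the ECG artifact has its spectral fundamental at the beat rate", {
  prof <- band_profile(c(Alpha = 10))
  rec <- generate_clean_recording(prof, fs = 250, duration_s = 16.4, seed = 4)
  inj <- inject_artifacts(rec, artifact_spec("ecg", rate_per_min = 60,
                                             amplitude_uv = 50), seed = 5)
  wave <- inj$by_class$ecg["Cz", ]
  cfg <- spectral_config(fs = 250)
  sp <- amplitude_spectrum(wave[1:4000], cfg)   # 16 s: 1 Hz lines on-grid
  pk <- detect_spectral_peaks(sp, cfg)
  comb <- pk[pk$freq_hz > 0.3 & pk$freq_hz < 12, ]
  # harmonic comb of the 1 Hz beat: lines at integer multiples, 1 Hz apart
  expect_gte(nrow(comb), 3)
  expect_equal(min(comb$freq_hz), 1, tolerance = 0.07)
  expect_lt(max(abs(comb$freq_hz - round(comb$freq_hz))), 0.07)
  expect_equal(median(diff(comb$freq_hz)), 1, tolerance = 0.1)
})

test_that("cohorts export to EDF plus a ground-truth TSV", {
  spec <- cohort_spec(n_subjects = 2, duration_s = 8.2, seed = 6)
  coh <- generate_cohort(spec)
  dir <- tempfile("cohort_")
  write_cohort_edf(coh, dir)
  expect_length(list.files(dir, pattern = "\\.edf$"), 2)
  gt <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  expect_equal(nrow(gt), nrow(coh$ground_truth))
  back <- read_edf_recording(file.path(dir, "S01.edf"))
  expect_identical(back$labels, nine_leads())
})
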