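# BSS scenarios use shared-phase mode (volume-conduction-style coherent
# rhythms) plus a 1 uV noise floor: the source regime ICA assumes.
make_contaminated <- function(seed, duration_s = 60,
                              specs = list(artifact_spec("blink"),
                                           artifact_spec("ecg"))) {
  coh <- generate_cohort(cohort_spec(n_subjects = 2, duration_s = duration_s,
                                     seed = seed),
                         phase_mode = "shared", noise_floor_uv = 1)
  clean <- coh$recordings[[1]]
  inj <- inject_artifacts(clean, specs, seed = seed + 500L)
  list(clean = clean, contaminated = inj$recording, artifacts = inj$artifacts)
}

channel_correlations <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) stats::cor(a[i, ], b[i, ]),
         numeric(1))
}

test_that("with rejection disabled the ICA round trip reproduces the input", {
  # full-rank (per-channel) data: the decomposition keeps all components
  clean <- generate_cohort(cohort_spec(n_subjects = 2, duration_s = 60,
                                       seed = 21))$recordings[[1]]
  ep <- epoch_recording(clean)
  res <- remove_artifacts_bss(ep, bss_config(thresholds = c(blink = Inf,
                                                            ecg = Inf,
                                                            emg = Inf)))
  err <- sqrt(mean((res$epochs$epochs - ep$epochs)^2))
  expect_lt(err, 1e-6)
  expect_length(res$report$rejected, 0)
  expect_equal(res$report$n_sources, 9)
})

test_that("blink cleaning restores frontal channels toward the clean signal", {
  cs <- make_contaminated(31)
  ep <- epoch_recording(cs$contaminated)
  res <- remove_artifacts_bss(ep)
  clean_mat <- qeegband:::epochs_to_matrix(epoch_recording(cs$clean))
  cont_mat <- qeegband:::epochs_to_matrix(ep)
  cleaned_mat <- qeegband:::epochs_to_matrix(res$epochs)
  frontal <- match(c("Fz", "F3", "F4"), cs$clean$labels)
  pre <- channel_correlations(clean_mat, cont_mat)[frontal]
  post <- channel_correlations(clean_mat, cleaned_mat)[frontal]
  expect_true(all(pre < 0.90))
  expect_true(all(post >= 0.90))
  expect_true(all(post > pre))
  expect_gt(length(res$report$rejected), 0)
})

test_that("pure ECG contamination yields a rejected source with a 1 Hz fundamental", {
  # pure contamination: cardiac spikes over the broadband floor alone
  clean <- generate_clean_recording(band_profile(c(Alpha = 0)),
                                    duration_s = 60, seed = 77,
                                    noise_floor_uv = 1)
  inj <- inject_artifacts(clean, artifact_spec("ecg", rate_per_min = 60,
                                               amplitude_uv = 40), seed = 78)
  ep <- epoch_recording(inj$recording)
  res <- remove_artifacts_bss(ep)
  expect_gt(length(res$report$rejected), 0)
  # reconstruct the rejected part and locate its spectral fundamental
  removed <- qeegband:::epochs_to_matrix(ep) -
    qeegband:::epochs_to_matrix(res$epochs)
  wave <- removed[which(clean$labels == "Cz"), ]
  # low floor: we are inspecting a reconstructed artifact, not brain rhythms
  cfg <- spectral_config(fs = 250, min_peak_uv = 0.25)
  sp <- amplitude_spectrum(wave[1:4000], cfg)   # 16 s: 1 Hz lines on-grid
  pk <- detect_spectral_peaks(sp, cfg)
  comb <- pk[pk$freq_hz > 0.3 & pk$freq_hz < 12, ]
  expect_gte(nrow(comb), 3)
  expect_equal(min(comb$freq_hz), 1, tolerance = 0.07)
  expect_lt(max(abs(comb$freq_hz - round(comb$freq_hz))), 0.07)
  expect_equal(median(diff(comb$freq_hz)), 1, tolerance = 0.1)
})

test_that("cleaning improves the median clean-signal correlation across seeded cohorts", {
  pre_med <- numeric(0)
  post_med <- numeric(0)
  for (seed in 1:5) {
    cs <- make_contaminated(seed * 101L, duration_s = 41)
    ep <- epoch_recording(cs$contaminated)
    res <- remove_artifacts_bss(ep)
    clean_mat <- qeegband:::epochs_to_matrix(epoch_recording(cs$clean))
    weighted <- match(c("Fz", "F3", "F4"), cs$clean$labels)
    pre_med <- c(pre_med, channel_correlations(
      clean_mat, qeegband:::epochs_to_matrix(ep))[weighted])
    post_med <- c(post_med, channel_correlations(
      clean_mat, qeegband:::epochs_to_matrix(res$epochs))[weighted])
  }
  expect_gt(median(post_med), median(pre_med))
})

test_that("degenerate rank fails naming the collinear channels", {
  n <- 9 * 9 * 20 * 3
  base <- sin(seq_len(n) / 5) + rnorm(n, 0, 0.1)
  m <- rbind(Fz = base, Cz = 2 * base, Pz = rnorm(n))
  rec <- recording(m, fs = 250, labels = c("Fz", "Cz", "Pz"))
  ep <- epoch_recording(rec, 2)
  expect_error(remove_artifacts_bss(ep), "Cz~Fz")
})

test_that("too little data for a stable decomposition is refused", {
  rec <- recording(matrix(rnorm(9 * 500), 9), fs = 250, labels = nine_leads())
  ep <- epoch_recording(rec, 2)
  expect_error(remove_artifacts_bss(ep), "20 x 9")
})
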