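#' @title Synthetic EEG generation
#' @description Generates multichannel eyes-closed EEG with known per-band
#'   peak-to-peak amplitude ground truth, cohorts of such recordings drawn
#'   from per-lead amplitude distributions, and parametric physiological
#'   artifacts (blinks, ECG, EMG, jaw, respiration) that can be injected
#'   and exactly subtracted again. Every downstream stage of the pipeline
#'   is testable against these generators.
#' @name synthetic_eeg
NULL

# Default per-band carrier frequencies (Hz). All lie on the k/8.2 Hz grid,
# so they are bin-centered for the default 8.2 s analysis epoch.
default_band_freqs <- function() {
  c(Delta = 18 / 8.2, Theta = 49 / 8.2, Alpha = 82 / 8.2,
    SMR = 111 / 8.2, Beta1 = 143 / 8.2, Beta2 = 225 / 8.2)
}

#' Per-channel band amplitude profile
#'
#' Target peak-to-peak amplitudes (microvolts, the unit in which QEEG
#' analyzers tabulate band activity) for each of the six canonical bands on
#' each lead, with optional per-band carrier frequencies.
#'
#' @param amplitudes Either a named numeric vector over the six bands
#'   (applied to every lead) or a leads x bands numeric matrix with
#'   dimnames. Values are peak-to-peak microvolts, all `>= 0`.
#' @param center_freqs Optional named numeric vector of per-band carrier
#'   frequencies (Hz); each must lie inside its band. Defaults to fixed
#'   mid-band carriers on the 1/8.2 Hz grid.
#' @param leads Channel labels (default the nine-lead montage).
#' @return A `band_profile` object.
#' @examples
#' band_profile(c(Delta = 16, Theta = 10, Alpha = 10, SMR = 5,
#'                Beta1 = 6, Beta2 = 7))
#' @export
band_profile <- function(amplitudes, center_freqs = NULL, leads = nine_leads()) {
  bands <- BAND_NAMES
  if (is.matrix(amplitudes)) {
    if (is.null(rownames(amplitudes)) || is.null(colnames(amplitudes))) {
      stop("amplitude matrix needs lead rownames and band colnames",
           call. = FALSE)
    }
    leads <- rownames(amplitudes)
    bad <- setdiff(colnames(amplitudes), bands)
    if (length(bad)) {
      stop("unknown band(s): ", paste(bad, collapse = ", "),
           "; bands are ", paste(bands, collapse = ", "), call. = FALSE)
    }
    amp <- matrix(0, length(leads), length(bands),
                  dimnames = list(leads, bands))
    amp[, colnames(amplitudes)] <- amplitudes
  } else {
    bad <- setdiff(names(amplitudes), bands)
    if (length(bad)) {
      stop("unknown band(s): ", paste(bad, collapse = ", "),
           "; bands are ", paste(bands, collapse = ", "), call. = FALSE)
    }
    amp <- matrix(0, length(leads), length(bands),
                  dimnames = list(leads, bands))
    amp[, names(amplitudes)] <- rep(amplitudes, each = length(leads))
  }
  if (any(amp < 0)) {
    stop("band amplitudes must be >= 0 microvolts", call. = FALSE)
  }
  freqs <- default_band_freqs()
  if (!is.null(center_freqs)) {
    bad <- setdiff(names(center_freqs), bands)
    if (length(bad)) stop("unknown band(s) in center_freqs: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    freqs[names(center_freqs)] <- center_freqs
  }
  cb <- canonical_bands()
  for (b in bands) {
    lo <- cb$low_hz[cb$band == b]; hi <- cb$high_hz[cb$band == b]
    if (freqs[b] < lo || freqs[b] >= hi) {
      stop("center frequency ", freqs[b], " Hz for ", b,
           " lies outside [", lo, ", ", hi, ") Hz", call. = FALSE)
    }
  }
  structure(list(amplitudes = amp, center_freqs = freqs, leads = leads),
            class = "band_profile")
}

#' Generate a clean (artifact-free) synthetic recording
#'
#' Each channel is a sum of one narrow-band component per band: by default
#' a fixed-frequency sinusoid of zero-to-peak amplitude equal to half the
#' profile's peak-to-peak target (random phase), optionally with a slow
#' random-walk frequency jitter, or band-passed Gaussian noise of matched
#' RMS. An optional broadband white-noise floor can be added.
#'
#' @param profile A [band_profile()].
#' @param fs Sampling rate in Hz; must be at least twice the highest band
#'   edge (70 Hz for Beta2 at 35 Hz).
#' @param duration_s Recording length in seconds; at least one 8.2 s
#'   analysis buffer.
#' @param seed Integer seed controlling phases/jitter/noise.
#' @param mode `"sinusoid"` (default, deterministic amplitude oracle) or
#'   `"narrowband_noise"`.
#' @param phase_mode `"per_channel"` (default): every channel draws its
#'   own phase per band, so channels are mutually independent;
#'   `"shared"`: each band's oscillator time course is shared by all
#'   channels (channel amplitudes still follow the profile exactly),
#'   emulating the inter-lead coherence that volume conduction produces
#'   in real scalp EEG. Shared mode keeps the number of latent sources
#'   below the channel count, the regime blind source separation
#'   assumes; pair it with a small `noise_floor_uv` to keep the data
#'   full-rank.
#' @param freq_jitter_hz Standard deviation (Hz) of the per-sample
#'   random-walk carrier jitter; 0 disables (default).
#' @param noise_floor_uv RMS of an added broadband Gaussian floor in
#'   microvolts (default 0).
#' @param subject,condition Identification tags for the output.
#' @return A `qeeg_recording`; `attr(, "profile")` carries the generating
#'   profile (the amplitude ground truth).
#' @export
generate_clean_recording <- function(profile, fs = 250, duration_s = 600,
                                     seed = 1L,
                                     mode = c("sinusoid", "narrowband_noise"),
                                     phase_mode = c("per_channel", "shared"),
                                     freq_jitter_hz = 0,
                                     noise_floor_uv = 0,
                                     subject = "sim", condition = "eyes-closed") {
  stopifnot(inherits(profile, "band_profile"))
  mode <- match.arg(mode)
  phase_mode <- match.arg(phase_mode)
  if (fs < 2 * 35) {
    stop("fs = ", fs, " Hz violates the Nyquist requirement for the 35 Hz ",
         "upper band edge (need fs >= 70 Hz)", call. = FALSE)
  }
  if (duration_s < 8.2) {
    stop("duration_s must cover at least one 8.2 s computing buffer",
         call. = FALSE)
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  leads <- profile$leads
  cb <- canonical_bands()

  samples <- with_seed(seed, {
    # unit-amplitude band waveform (zero-to-peak 1 for sinusoids, matched
    # RMS for narrow-band noise)
    unit_wave <- function(b) {
      f0 <- profile$center_freqs[[b]]
      if (mode == "sinusoid") {
        phase <- stats::runif(1, 0, 2 * pi)
        if (freq_jitter_hz > 0) {
          # integrate a random-walk instantaneous frequency around f0
          dev <- cumsum(stats::rnorm(n, 0, freq_jitter_hz / sqrt(fs)))
          inst <- f0 + dev - mean(dev)
          sin(2 * pi * cumsum(inst) / fs + phase)
        } else {
          sin(2 * pi * f0 * t + phase)
        }
      } else {
        lo <- cb$low_hz[cb$band == b]; hi <- cb$high_hz[cb$band == b]
        nb <- bandpass(stats::rnorm(n), lo, hi, fs)
        nb / rms(nb) / sqrt(2)
      }
    }
    shared <- if (phase_mode == "shared") {
      stats::setNames(lapply(BAND_NAMES, unit_wave), BAND_NAMES)
    }
    out <- matrix(0, length(leads), n, dimnames = list(leads, NULL))
    for (ch in seq_along(leads)) {
      sig <- numeric(n)
      for (b in BAND_NAMES) {
        a_pp <- profile$amplitudes[ch, b]
        if (a_pp <= 0) next
        wave <- if (phase_mode == "shared") shared[[b]] else unit_wave(b)
        sig <- sig + (a_pp / 2) * wave
      }
      if (noise_floor_uv > 0) {
        sig <- sig + stats::rnorm(n, 0, noise_floor_uv)
      }
      out[ch, ] <- sig
    }
    out
  })

  rec <- recording(samples, fs = fs, labels = leads,
                   subject = subject, condition = condition)
  rec$provenance <- paste0("simulated:", mode, ":", phase_mode, ":seed", seed)
  attr(rec, "profile") <- profile
  rec
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 2); default 18, the study-size
#'   cohort the default parameters describe.
#' @param params Tibble with columns `band`, `lead`, `mean`, `sd`
#'   (peak-to-peak microvolts): the per-lead per-band amplitude
#'   distributions. Defaults to [reference_cohort_stats()].
#' @param fs Sampling rate in Hz (default 250).
#' @param duration_s Per-subject recording length in seconds (default 600,
#'   a ten-minute eyes-closed session).
#' @param seed Integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 18L,
                        params = reference_cohort_stats(),
                        fs = 250, duration_s = 600, seed = 1L) {
  stopifnot(all(c("band", "lead", "mean", "sd") %in% names(params)))
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (any(params$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-6) {
    stop("duration_s x fs must be an integer sample count", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), params = params,
                 fs = fs, duration_s = duration_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read a cohort specification from a YAML/JSON config document
#'
#' Recognized keys: `n_subjects`, `fs`, `duration_s`, `seed`, and
#' optionally `params` (a record list with band/lead/mean/sd). Missing
#' keys take the [cohort_spec()] defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  params <- if (!is.null(doc$params)) {
    dplyr::bind_rows(lapply(doc$params, tibble::as_tibble))
  } else {
    reference_cohort_stats()
  }
  cohort_spec(
    n_subjects = doc$n_subjects %||% 18L,
    params = params,
    fs = doc$fs %||% 250,
    duration_s = doc$duration_s %||% 600,
    seed = doc$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort with ground truth
#'
#' Per-subject, per-lead, per-band amplitudes are drawn from normal
#' distributions with the spec's mean/SD, truncated at zero (negative
#' microvolt amplitudes are unphysical), and each subject's recording is
#' synthesized with [generate_clean_recording()].
#'
#' @param spec A [cohort_spec()].
#' @param ... Passed on to [generate_clean_recording()] (e.g. `mode`,
#'   `noise_floor_uv`).
#' @return A list with `recordings` (list of `qeeg_recording`) and
#'   `ground_truth` (tibble: `subject`, `lead`, `band`, `amplitude_uv`).
#' @export
generate_cohort <- function(spec, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- spec$params
  leads <- unique(params$lead)
  bands <- intersect(BAND_NAMES, unique(params$band))

  draws <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      amp <- matrix(0, length(leads), length(bands),
                    dimnames = list(leads, bands))
      for (i in seq_len(nrow(params))) {
        amp[params$lead[i], params$band[i]] <-
          rnorm_trunc0(1, params$mean[i], params$sd[i])
      }
      amp
    })
  })

  recordings <- vector("list", spec$n_subjects)
  gt <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    prof <- band_profile(draws[[s]])
    subject_id <- sprintf("S%02d", s)
    recordings[[s]] <- generate_clean_recording(
      prof, fs = spec$fs, duration_s = spec$duration_s,
      seed = spec$seed * 1000L + s, subject = subject_id, ...
    )
    gt[[s]] <- tibble::tibble(
      subject = subject_id,
      lead = rep(leads, times = length(bands)),
      band = rep(bands, each = length(leads)),
      amplitude_uv = as.vector(draws[[s]][, bands])
    )
  }
  list(recordings = recordings, ground_truth = dplyr::bind_rows(gt))
}

#' Write a generated cohort as EDF files plus a ground-truth table
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$recordings, function(rec) {
    p <- file.path(dir, paste0(rec$subject, ".edf"))
    write_edf_recording(rec, p)
    p
  }, character(1))
  gt_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(cohort$ground_truth, gt_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(paths, gt_path))
}
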