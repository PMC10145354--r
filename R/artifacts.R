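#' @title Parametric physiological artifacts
#' @description Templates for the artifact classes that contaminate scalp
#'   EEG — eye blinks, cardiac (ECG) spikes, muscle (EMG) bursts, jaw
#'   movement and respiration — with per-class spatial weightings over the
#'   nine-lead montage. Injection returns both the contaminated recording
#'   and the exact added waveforms, so removal methods can be scored
#'   against ground truth.
#' @name artifacts
NULL

ARTIFACT_CLASSES <- c("blink", "ecg", "emg", "jaw", "respiration")

# Default spatial gains per artifact class over the nine leads, reflecting
# the usual scalp topographies: ocular and jaw artifacts are frontal-
# dominant, EMG loads lateral-frontal, ECG and respiration are diffuse.
default_artifact_weights <- function(class) {
  leads <- nine_leads()
  w <- switch(class,
    blink       = c(Fz = 1.0, F3 = 0.9, F4 = 0.9, Cz = 0.30, C3 = 0.25,
                    C4 = 0.25, Pz = 0.08, P3 = 0.05, P4 = 0.05),
    ecg         = c(Fz = 0.3, F3 = 0.3, F4 = 0.3, Cz = 0.3, C3 = 0.3,
                    C4 = 0.3, Pz = 0.3, P3 = 0.3, P4 = 0.3),
    emg         = c(Fz = 0.4, F3 = 0.9, F4 = 0.9, Cz = 0.2, C3 = 0.35,
                    C4 = 0.35, Pz = 0.15, P3 = 0.2, P4 = 0.2),
    jaw         = c(Fz = 0.8, F3 = 0.9, F4 = 0.9, Cz = 0.5, C3 = 0.6,
                    C4 = 0.6, Pz = 0.2, P3 = 0.25, P4 = 0.25),
    respiration = c(Fz = 0.5, F3 = 0.5, F4 = 0.5, Cz = 0.5, C3 = 0.5,
                    C4 = 0.5, Pz = 0.5, P3 = 0.5, P4 = 0.5),
    stop("unknown artifact class '", class, "'; supported classes: ",
         paste(ARTIFACT_CLASSES, collapse = ", "), call. = FALSE)
  )
  w[leads]
}

#' Specify an artifact source
#'
#' @param class One of `"blink"`, `"ecg"`, `"emg"`, `"jaw"`,
#'   `"respiration"`.
#' @param rate_per_min Event rate (events/minute; for respiration, cycles
#'   per minute). Must be positive.
#' @param amplitude_uv Waveform amplitude in microvolts at a unit spatial
#'   weight (peak for transients, RMS for EMG bursts). Must be positive.
#' @param weights Named numeric vector of per-lead gains; defaults to the
#'   class's canonical scalp topography.
#' @return An `artifact_spec` object.
#' @examples
#' artifact_spec("blink", rate_per_min = 12, amplitude_uv = 100)
#' @export
artifact_spec <- function(class, rate_per_min = NULL, amplitude_uv = NULL,
                          weights = NULL) {
  if (!class %in% ARTIFACT_CLASSES) {
    stop("unknown artifact class '", class, "'; supported classes: ",
         paste(ARTIFACT_CLASSES, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    blink = c(12, 100), ecg = c(66, 20), emg = c(6, 30),
    jaw = c(4, 60), respiration = c(15, 10)
  )[[class]]
  rate_per_min <- rate_per_min %||% defaults[1]
  amplitude_uv <- amplitude_uv %||% defaults[2]
  if (!is.numeric(rate_per_min) || rate_per_min <= 0) {
    stop("rate_per_min must be > 0", call. = FALSE)
  }
  if (!is.numeric(amplitude_uv) || amplitude_uv <= 0) {
    stop("amplitude_uv must be > 0", call. = FALSE)
  }
  weights <- weights %||% default_artifact_weights(class)
  if (!all(is.finite(weights))) {
    stop("spatial weights must be finite", call. = FALSE)
  }
  structure(list(class = class, rate_per_min = rate_per_min,
                 amplitude_uv = amplitude_uv, weights = weights),
            class = "artifact_spec")
}

# Single-channel (unit-weight) artifact waveform of n samples at fs.
artifact_waveform <- function(spec, n, fs) {
  t <- (seq_len(n) - 1) / fs
  dur_s <- n / fs
  switch(spec$class,
    blink = {
      # smooth biphasic ~0.3 s transient at jittered event times
      width <- 0.3
      tpl_n <- round(width * fs)
      tt <- seq_len(tpl_n) / fs
      tpl <- sin(2 * pi * tt / width) * (0.5 - 0.5 * cos(2 * pi * tt / width))
      tpl <- tpl / max(abs(tpl)) * spec$amplitude_uv
      n_ev <- max(1L, round(spec$rate_per_min * dur_s / 60))
      grid <- (seq_len(n_ev) - 0.5) / n_ev * dur_s
      times <- grid + stats::runif(n_ev, -0.2, 0.2) * dur_s / n_ev
      place_events(n, fs, times, tpl)
    },
    ecg = {
      # strictly periodic QRS-like biphasic spike train: fundamental at
      # rate/60 Hz plus harmonics
      period <- round(fs * 60 / spec$rate_per_min)
      width <- 0.04
      tpl_n <- max(5L, round(2 * width * fs))
      tt <- (seq_len(tpl_n) - tpl_n / 2) / fs
      tpl <- -tt / width * exp(0.5 - (tt / width)^2 / 2)  # gaussian derivative
      tpl <- tpl / max(abs(tpl)) * spec$amplitude_uv
      starts <- seq(1, n, by = period)
      place_events(n, fs, (starts - 1) / fs, tpl)
    },
    emg = {
      # bursts of 20-45 Hz noise, ~0.8 s each
      burst_s <- 0.8
      n_ev <- max(1L, round(spec$rate_per_min * dur_s / 60))
      tpl_n <- round(burst_s * fs)
      out <- numeric(n)
      grid <- (seq_len(n_ev) - 0.5) / n_ev * dur_s
      times <- grid + stats::runif(n_ev, -0.2, 0.2) * dur_s / n_ev
      for (tm in times) {
        noise <- bandpass(stats::rnorm(tpl_n), 20, 45, fs)
        env <- 0.5 - 0.5 * cos(2 * pi * seq_len(tpl_n) / tpl_n)
        burst <- noise * env
        burst <- burst / rms(burst) * spec$amplitude_uv
        i0 <- round(tm * fs) + 1L
        idx <- i0:min(n, i0 + tpl_n - 1L)
        out[idx] <- out[idx] + burst[seq_along(idx)]
      }
      out
    },
    jaw = {
      # slower (~0.6 s) monophasic frontal-central bump
      width <- 0.6
      tpl_n <- round(width * fs)
      tpl <- (0.5 - 0.5 * cos(2 * pi * seq_len(tpl_n) / tpl_n)) *
        spec$amplitude_uv
      n_ev <- max(1L, round(spec$rate_per_min * dur_s / 60))
      grid <- (seq_len(n_ev) - 0.5) / n_ev * dur_s
      times <- grid + stats::runif(n_ev, -0.2, 0.2) * dur_s / n_ev
      place_events(n, fs, times, tpl)
    },
    respiration = {
      # continuous slow oscillation at rate/60 Hz
      f <- spec$rate_per_min / 60
      spec$amplitude_uv * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  )
}

# Add a template at each event time (seconds), clipping at the record end.
place_events <- function(n, fs, times_s, tpl) {
  out <- numeric(n)
  for (tm in times_s) {
    i0 <- max(1L, round(tm * fs) + 1L)
    if (i0 > n) next
    idx <- i0:min(n, i0 + length(tpl) - 1L)
    out[idx] <- out[idx] + tpl[seq_along(idx)]
  }
  out
}

#' Inject artifacts into a recording
#'
#' Adds each artifact spec's waveform, scaled by its per-lead spatial
#' weights, to the recording. The exact added component is returned, so
#' `contaminated$samples - artifacts == clean$samples` holds sample-wise.
#'
#' @param x A `qeeg_recording`.
#' @param specs A list of [artifact_spec()] objects (a single spec is
#'   accepted too). An empty list returns the input unchanged.
#' @param seed Integer seed for event-time jitter and EMG noise.
#' @return A list with `recording` (contaminated `qeeg_recording`),
#'   `artifacts` (channels x time matrix of everything added) and
#'   `by_class` (named list of per-class matrices).
#' @export
inject_artifacts <- function(x, specs, seed = 1L) {
  stopifnot(inherits(x, "qeeg_recording"))
  if (inherits(specs, "artifact_spec")) specs <- list(specs)
  if (!length(specs)) {
    return(list(recording = x,
                artifacts = matrix(0, nrow(x$samples), ncol(x$samples),
                                   dimnames = dimnames(x$samples)),
                by_class = list()))
  }
  for (s in specs) stopifnot(inherits(s, "artifact_spec"))
  n <- ncol(x$samples)

  by_class <- with_seed(seed, {
    lapply(specs, function(sp) {
      wave <- artifact_waveform(sp, n, x$fs)
      w <- sp$weights
      missing <- setdiff(x$labels, names(w))
      if (length(missing)) {
        stop("artifact spec '", sp$class, "' has no spatial weight for ",
             "lead(s): ", paste(missing, collapse = ", "), call. = FALSE)
      }
      m <- outer(unname(w[x$labels]), wave)
      dimnames(m) <- dimnames(x$samples)
      m
    })
  })
  names(by_class) <- vapply(specs, `[[`, "", "class")

  total <- Reduce(`+`, by_class)
  dimnames(total) <- dimnames(x$samples)
  out <- x
  out$samples <- x$samples + total
  out$provenance <- c(x$provenance,
                      paste0("artifacts:", paste(names(by_class), collapse = "+")))
  list(recording = out, artifacts = total, by_class = by_class)
}
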