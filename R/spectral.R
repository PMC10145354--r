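#' @title FFT amplitude quantification
#' @description The quantification core: one-sided FFT amplitude spectra
#'   scaled to peak-to-peak microvolts, constrained spectral peak
#'   detection (amplitude floor and minimum peak separation), and per-band
#'   amplitude extraction in dominant-peak or integral-average mode.
#' @name spectral
NULL

#' Spectral analysis configuration
#'
#' @param fs Sampling rate in Hz.
#' @param n Computing-buffer length in samples; `NULL` (default) takes
#'   each analyzed epoch's own length. When set, epoch lengths must match
#'   it exactly — the pipeline never pads or truncates silently.
#' @param min_peak_uv Minimum peak-to-peak amplitude for a spectral peak
#'   (microvolts, default 0.5).
#' @param min_separation_hz Minimum frequency distance between retained
#'   peaks (Hz, default 0.5). Must be at least the spectral resolution
#'   `fs/n`.
#' @param window `"rectangular"` (default; exact peak-to-peak recovery for
#'   bin-centered tones) or `"hann"` (amplitude-corrected by its coherent
#'   gain of 0.5).
#' @param mode Band-amplitude mode: `"dominant_peak"` (default) or
#'   `"integral_average"`. See [band_amplitude()].
#' @param peak_correction If `TRUE` (default), dominant-peak amplitudes
#'   are leakage-corrected by a local energy sum over +/-3 bins around the
#'   peak (exact for bin-centered tones, bounds the scalloping loss for
#'   off-grid tones); `FALSE` uses the raw peak-bin amplitude.
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(fs = 250, n = NULL, min_peak_uv = 0.5,
                            min_separation_hz = 0.5,
                            window = c("rectangular", "hann"),
                            mode = c("dominant_peak", "integral_average"),
                            peak_correction = TRUE) {
  window <- match.arg(window)
  mode <- match.arg(mode)
  if (!(fs > 0)) stop("fs must be > 0", call. = FALSE)
  if (!is.null(n)) {
    if (n < 2) stop("buffer length n must be >= 2 samples", call. = FALSE)
    if (min_separation_hz < fs / n) {
      stop("min_separation_hz (", min_separation_hz, ") is below the ",
           "spectral resolution fs/n = ", fs / n, " Hz", call. = FALSE)
    }
  }
  if (min_peak_uv < 0) stop("min_peak_uv must be >= 0", call. = FALSE)
  structure(list(fs = fs, n = n, min_peak_uv = min_peak_uv,
                 min_separation_hz = min_separation_hz, window = window,
                 mode = mode, peak_correction = peak_correction),
            class = "spectral_config")
}

#' Spectral calculation resolution
#'
#' The gap between adjacent frequency values of the FFT grid,
#' `r = fs / N`, for sampling rate `fs` and computing-buffer length `N`.
#' Equivalently `1 / T` for a buffer spanning `T` seconds: a 1 s epoch
#' gives 1 Hz resolution, a 4 s epoch 0.25 Hz, and the 8.2 s / 2048-point
#' buffer 0.12 Hz (to two decimals).
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param n Buffer length in samples (>= 2).
#' @return Resolution in Hz.
#' @examples
#' calculation_resolution(2048 / 8.2, 2048)  # ~0.122 Hz
#' @export
calculation_resolution <- function(fs, n) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2 samples", call. = FALSE)
  fs / n
}

#' One-sided FFT amplitude spectrum of one epoch channel
#'
#' Computes the complex spectrum `A(z) + j F(z)` on the grid `k * fs / N`
#' and scales it to amplitudes: zero-to-peak amplitude `2|X_k|/N` for
#' interior bins (DC and Nyquist unscaled by 2), peak-to-peak amplitude
#' twice that, and power the square of the peak-to-peak magnitude.
#'
#' @param signal Numeric vector of one channel's epoch samples
#'   (microvolts). Length must equal the configured buffer length when one
#'   is set.
#' @param config A [spectral_config()].
#' @param channel,epoch Optional provenance tags stored in the result.
#' @return A `amplitude_spectrum` object: tibble-like list with
#'   `freq_hz`, `complex`, `amplitude_uv` (zero-to-peak),
#'   `amplitude_pp_uv`, `power_uv2`, plus `fs`, `n`, `window`.
#' @export
amplitude_spectrum <- function(signal, config = spectral_config(),
                               channel = NA_character_, epoch = NA_integer_) {
  n <- length(signal)
  if (!is.null(config$n) && n != config$n) {
    stop("signal length ", n, " does not match the configured buffer ",
         "length ", config$n, call. = FALSE)
  }
  if (!all(is.finite(signal))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  gain <- 1
  if (config$window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
    signal <- signal * w
    gain <- mean(w)                      # coherent gain 0.5
  }
  x <- stats::fft(signal)
  half <- floor(n / 2) + 1L
  xh <- x[seq_len(half)]
  scale <- rep(2 / (n * gain), half)
  scale[1] <- 1 / (n * gain)             # DC
  if (n %% 2 == 0) scale[half] <- 1 / (n * gain)  # Nyquist
  amp <- Mod(xh) * scale
  structure(
    list(freq_hz = (seq_len(half) - 1) * config$fs / n,
         complex = xh,
         amplitude_uv = amp,
         amplitude_pp_uv = 2 * amp,
         power_uv2 = (2 * amp)^2,
         fs = config$fs, n = n, window = config$window,
         channel = channel, epoch = epoch),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum> %d bins, 0-%.1f Hz, resolution %.4g Hz\n",
              length(x$freq_hz), max(x$freq_hz), x$fs / x$n))
  top <- order(x$amplitude_pp_uv, decreasing = TRUE)[1:3]
  cat("  top bins:",
      paste(sprintf("%.2f Hz (%.2f uVpp)", x$freq_hz[top],
                    x$amplitude_pp_uv[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Export a spectrum as a tab-separated table
#' @param x An `amplitude_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  utils::write.table(
    data.frame(freq_hz = x$freq_hz, amplitude_pp_uv = x$amplitude_pp_uv,
               power_uv2 = x$power_uv2),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Detect constrained spectral peaks
#'
#' Local maxima of the peak-to-peak amplitude versus frequency curve, kept
#' only when their amplitude reaches the configured floor (default 0.5
#' microvolts) and thinned so that retained peaks are at least the
#' configured separation (default 0.5 Hz) apart: of two closer candidates
#' the larger survives, ties breaking toward the lower frequency.
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param config A [spectral_config()].
#' @return Tibble with `freq_hz` and `amplitude_pp_uv`, ordered by
#'   frequency; zero rows when nothing passes the floor.
#' @export
detect_spectral_peaks <- function(spectrum, config = spectral_config()) {
  a <- spectrum$amplitude_pp_uv
  f <- spectrum$freq_hz
  m <- length(a)
  if (m < 2) return(tibble::tibble(freq_hz = numeric(), amplitude_pp_uv = numeric()))
  left <- c(-Inf, a[-m])
  right <- c(a[-1], -Inf)
  is_max <- a >= left & a > right        # plateaus resolve to lowest bin
  cand <- which(is_max & a >= config$min_peak_uv)
  if (!length(cand)) {
    return(tibble::tibble(freq_hz = numeric(), amplitude_pp_uv = numeric()))
  }
  # greedy thinning: largest amplitude first, lower frequency on ties
  ord <- cand[order(-a[cand], f[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(f[i] - f[kept]) >= config$min_separation_hz)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  tibble::tibble(freq_hz = f[kept], amplitude_pp_uv = a[kept])
}

# Leakage-corrected peak-to-peak amplitude at bin `i`: local energy sum
# over +/- `halfwidth` bins (Parseval-based; exact for a bin-centered tone).
corrected_peak_pp <- function(spectrum, i, halfwidth = 3L) {
  idx <- max(2L, i - halfwidth):min(length(spectrum$amplitude_pp_uv), i + halfwidth)
  if (i == 1L) idx <- 1L                 # DC peak: no symmetric leakage sum
  sqrt(sum(spectrum$amplitude_pp_uv[idx]^2))
}

#' Band amplitude from a spectrum
#'
#' In dominant-peak mode (default), the amplitude of the largest detected
#' spectral peak whose frequency falls in the band's half-open interval
#' `[low, high)`, leakage-corrected unless the config disables it; 0 when
#' no peak in the band passes the amplitude floor. In integral-average
#' mode, the mean per-bin peak-to-peak amplitude over the band's bins.
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param band A `qeeg_band` or canonical band name.
#' @param config A [spectral_config()]; its `mode` field selects the
#'   estimator unless `mode` is given explicitly.
#' @param mode Optional override, `"dominant_peak"` or
#'   `"integral_average"`.
#' @return Peak-to-peak amplitude in microvolts.
#' @export
band_amplitude <- function(spectrum, band, config = spectral_config(),
                           mode = NULL) {
  band <- as_band(band)
  mode <- mode %||% config$mode
  peaks <- if (mode == "dominant_peak") detect_spectral_peaks(spectrum, config)
  band_amplitude_impl(spectrum, band, config, mode, peaks)
}

# Shared estimator; `peaks` may be precomputed to avoid re-detection when
# several bands are read off one spectrum.
band_amplitude_impl <- function(spectrum, band, config, mode, peaks) {
  sel <- in_band(spectrum$freq_hz, band)
  if (!any(sel)) return(0)
  if (mode == "integral_average") {
    return(mean(spectrum$amplitude_pp_uv[sel]))
  }
  peaks <- peaks[in_band(peaks$freq_hz, band), , drop = FALSE]
  if (!nrow(peaks)) return(0)
  top <- which.max(peaks$amplitude_pp_uv)
  if (!config$peak_correction) return(peaks$amplitude_pp_uv[top])
  i <- which.min(abs(spectrum$freq_hz - peaks$freq_hz[top]))
  corrected_peak_pp(spectrum, i)
}

#' Per-subject band amplitude table
#'
#' For each lead and band, the arithmetic mean of per-epoch band
#' amplitudes over unrejected epochs.
#'
#' @param x A `qeeg_epochs` with at least one unrejected epoch.
#' @param config A [spectral_config()]; its `n`, when set, must equal the
#'   epoch length in samples.
#' @param bands List of bands (default the six canonical bands).
#' @return A tibble (`subject`, `lead`, `band`, `amplitude_uv`,
#'   `n_epochs`, `mode`): the subject's band-amplitude table in
#'   peak-to-peak microvolts.
#' @export
subject_band_table <- function(x, config = spectral_config(fs = x$fs),
                               bands = canonical_band_list()) {
  stopifnot(inherits(x, "qeeg_epochs"))
  keep <- which(!x$rejected)
  if (!length(keep)) {
    stop("no unrejected epochs remain for subject ", x$subject, call. = FALSE)
  }
  if (abs(config$fs - x$fs) > 1e-9) {
    stop("config fs (", config$fs, ") does not match epoch fs (", x$fs, ")",
         call. = FALSE)
  }
  bands <- lapply(bands, as_band)
  band_names <- vapply(bands, `[[`, "", "name")
  n_lead <- dim(x$epochs)[2]
  acc <- matrix(0, n_lead, length(bands),
                dimnames = list(x$labels, band_names))
  for (e in keep) {
    for (ch in seq_len(n_lead)) {
      sp <- amplitude_spectrum(x$epochs[e, ch, ], config,
                               channel = x$labels[ch], epoch = e)
      peaks <- if (config$mode == "dominant_peak") {
        detect_spectral_peaks(sp, config)
      }
      for (b in seq_along(bands)) {
        acc[ch, b] <- acc[ch, b] +
          band_amplitude_impl(sp, bands[[b]], config, config$mode, peaks)
      }
    }
  }
  acc <- acc / length(keep)
  tibble::tibble(
    subject = x$subject,
    lead = rep(x$labels, times = length(bands)),
    band = rep(band_names, each = n_lead),
    amplitude_uv = as.vector(acc),
    n_epochs = length(keep),
    mode = config$mode
  )
}

#' Band amplitude tables for a list of epoched subjects
#'
#' @param epoch_list List of `qeeg_epochs`.
#' @param config,bands As in [subject_band_table()].
#' @return Row-bound tibble over subjects.
#' @export
cohort_band_table <- function(epoch_list, config = NULL,
                              bands = canonical_band_list()) {
  dplyr::bind_rows(lapply(epoch_list, function(ep) {
    cfg <- config %||% spectral_config(fs = ep$fs)
    subject_band_table(ep, cfg, bands)
  }))
}
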