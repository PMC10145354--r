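#' @title Blind source separation artifact removal
#' @description Estimates statistically independent sources from the
#'   epoched multichannel record (FastICA on the concatenated epochs),
#'   scores each source against documented artifact signatures — frontal
#'   low-frequency spiky transients for blinks, ~1 Hz periodic spiking for
#'   ECG, >20 Hz spectral dominance with a bursty envelope for EMG — zeroes
#'   sources whose score exceeds the configured threshold, and
#'   reconstructs the data from the remaining sources.
#' @name bss
NULL

#' BSS configuration
#'
#' @param thresholds Named numeric vector of rejection thresholds per
#'   artifact signature (`blink`, `ecg`, `emg`), each in `[0, 1]`; a
#'   source is zeroed when any class score exceeds its threshold. Set a
#'   threshold to `Inf` to disable that class.
#' @param seed Seed for the FastICA initialization (deterministic runs).
#' @param max_iter,tol FastICA iteration controls.
#' @param var_keep Fraction of total variance retained by the PCA step
#'   before ICA (default 0.999). Full-rank data is left unreduced, and
#'   reconstruction with nothing rejected is then exact; near-degenerate
#'   noise dimensions are dropped, which symmetric FastICA needs to
#'   converge.
#' @return A `bss_config` list.
#' @export
bss_config <- function(thresholds = c(blink = 0.2, ecg = 0.5, emg = 0.5),
                       seed = 1L, max_iter = 1000L, tol = 1e-6,
                       var_keep = 0.999) {
  stopifnot(all(c("blink", "ecg", "emg") %in% names(thresholds)))
  structure(list(thresholds = thresholds, seed = seed,
                 max_iter = max_iter, tol = tol, var_keep = var_keep),
            class = "bss_config")
}

# Power fraction of `x` below/above a cut frequency, via its periodogram.
power_fraction <- function(x, fs, cut_hz, below = TRUE) {
  n <- length(x)
  p <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]^2
  f <- (seq_along(p) - 1) * fs / n
  sel <- if (below) f < cut_hz else f >= cut_hz
  sum(p[sel]) / sum(p)
}

# Spikiness in [0, 1): 0 for Gaussian or sub-Gaussian, toward 1 for
# heavy-tailed transient trains.
spikiness <- function(x) {
  k <- mean((x - mean(x))^4) / stats::var(x)^2
  1 - exp(-max(0, k - 3) / 5)
}

# Periodicity of the signal's energy envelope: maximal normalized
# autocorrelation of x^2 over lags corresponding to 0.4-2 s (the
# physiological heart-beat range).
envelope_periodicity <- function(x, fs) {
  e <- x^2
  e <- e - mean(e)
  lags <- seq(max(2L, round(0.4 * fs)), min(length(x) - 2L, round(2 * fs)))
  ac <- stats::acf(e, lag.max = max(lags), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  max(ac[lags + 1L] / ac[1L])
}

# Score every source against the three artifact signatures. `mixing` is
# channels x sources in sensor space; labels index its rows.
score_sources <- function(sources, mixing, labels, fs) {
  frontal <- intersect(c("Fz", "F3", "F4"), labels)
  scores <- vapply(seq_len(nrow(sources)), function(j) {
    s <- sources[j, ]
    a <- abs(mixing[, j])
    frontal_frac <- if (length(frontal)) sum(a[match(frontal, labels)]) / sum(a) else 0
    spik <- spikiness(s)
    f_low <- power_fraction(s, fs, 5, below = TRUE)
    f_high <- power_fraction(s, fs, 20, below = FALSE)
    c(blink = f_low * spik * frontal_frac,
      ecg = envelope_periodicity(s, fs) * spik,
      emg = f_high * spik)
  }, c(blink = 0, ecg = 0, emg = 0))
  t(scores)                              # sources x classes
}

#' Remove artifacts by blind source separation
#'
#' @param x A `qeeg_epochs` object with at least 2 channels and enough
#'   samples (>= 20 x channels^2) for a stable decomposition.
#' @param config A [bss_config()].
#' @return A list with `epochs` (cleaned `qeeg_epochs`) and `report`, a
#'   `bss_report` carrying the number of estimated sources, the indices of
#'   rejected sources, the per-source artifact-likelihood scores and the
#'   fraction of each channel's variance removed.
#' @export
remove_artifacts_bss <- function(x, config = bss_config()) {
  stopifnot(inherits(x, "qeeg_epochs"))
  n_ch <- dim(x$epochs)[2]
  if (n_ch < 2) stop("BSS needs at least 2 channels", call. = FALSE)
  n_ep <- dim(x$epochs)[1]
  len <- dim(x$epochs)[3]
  if (n_ep * len < 20 * n_ch^2) {
    stop("too little data for BSS: ", n_ep * len, " samples < 20 x ",
         n_ch, "^2 = ", 20 * n_ch^2, call. = FALSE)
  }

  flat <- matrix(aperm(x$epochs, c(2, 3, 1)), nrow = n_ch)  # ch x (time*epoch)
  rownames(flat) <- x$labels
  dec <- fast_ica(flat, seed = config$seed,
                  max_iter = config$max_iter, tol = config$tol,
                  var_keep = config$var_keep)

  scores <- score_sources(dec$sources, dec$mixing, x$labels, x$fs)
  thr <- config$thresholds
  rejected <- which(
    scores[, "blink"] > thr[["blink"]] |
    scores[, "ecg"] > thr[["ecg"]] |
    scores[, "emg"] > thr[["emg"]]
  )

  src_kept <- dec$sources
  if (length(rejected)) src_kept[rejected, ] <- 0
  clean_flat <- dec$mixing %*% src_kept + dec$means

  var_before <- apply(flat, 1, stats::var)
  var_removed <- pmax(0, pmin(1, 1 - apply(clean_flat, 1, stats::var) /
                                   ifelse(var_before > 0, var_before, 1)))

  out <- x
  out$epochs <- aperm(array(clean_flat, dim = c(n_ch, len, n_ep)), c(3, 1, 2))
  dimnames(out$epochs) <- dimnames(x$epochs)

  report <- structure(
    list(n_sources = nrow(dec$sources), rejected = rejected,
         scores = scores, var_removed = stats::setNames(var_removed, x$labels),
         n_iter = dec$n_iter, thresholds = thr),
    class = "bss_report"
  )
  list(epochs = out, report = report)
}

#' @export
print.bss_report <- function(x, ...) {
  cat(sprintf("<bss_report> %d sources, %d rejected (%s)\n",
              x$n_sources, length(x$rejected),
              if (length(x$rejected)) paste(x$rejected, collapse = ", ")
              else "none"))
  cat("  max scores: ",
      paste(sprintf("%s=%.2f", colnames(x$scores),
                    apply(x$scores, 2, max)), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a BSS report to JSON
#' @param report A `bss_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bss_report <- function(report, path) {
  jsonlite::write_json(
    list(n_sources = report$n_sources,
         rejected = as.integer(report$rejected),
         scores = as.data.frame(report$scores),
         var_removed = as.list(report$var_removed),
         n_iter = report$n_iter),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
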