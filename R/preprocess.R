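#' @title Preprocessing: re-referencing, epoching, epoch rejection
#' @name preprocess
NULL

#' Re-reference to the Fz/Cz/Pz midline
#'
#' Subtracts the arithmetic mean of the three midline leads (Fz, Cz, Pz)
#' from every channel, sample-wise. This is the package's reading of a
#' midline-reference transform; single-electrode referencing is available
#' via `reference`.
#'
#' @param x A `qeeg_recording` containing Fz, Cz and Pz.
#' @param reference Character vector of reference leads (default
#'   `c("Fz", "Cz", "Pz")`); a single lead gives conventional
#'   single-electrode re-referencing.
#' @return The re-referenced `qeeg_recording`, with the operation recorded
#'   in its provenance.
#' @export
rereference_midline <- function(x, reference = c("Fz", "Cz", "Pz")) {
  stopifnot(inherits(x, "qeeg_recording"))
  assert_leads(x, reference)
  ref <- colMeans(x$samples[reference, , drop = FALSE])
  out <- x
  out$samples <- sweep(x$samples, 2, ref, "-")
  out$provenance <- c(x$provenance,
                      paste0("reref:", paste(reference, collapse = "+")))
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Produces the maximal set of whole epochs; trailing samples that do not
#' fill an epoch are discarded. The default 8.2 s epoch is the computing
#' buffer that gives the pipeline's 0.12 Hz spectral resolution at 250 Hz.
#'
#' @param x A `qeeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 8.2).
#' @param overlap Fractional overlap between consecutive epochs in
#'   `[0, 1)`; default 0.
#' @return A `qeeg_epochs` object: array `epochs` (epoch x channel x time),
#'   `fs`, `epoch_length_s`, `labels`, `subject`, and a logical `rejected`
#'   flag per epoch (all `FALSE` initially).
#' @export
epoch_recording <- function(x, epoch_length_s = 8.2, overlap = 0) {
  stopifnot(inherits(x, "qeeg_recording"))
  if (overlap < 0 || overlap >= 1) {
    stop("overlap must lie in [0, 1)", call. = FALSE)
  }
  len <- round(epoch_length_s * x$fs)
  if (len < 2) {
    stop("epoch_length_s x fs must be an integer >= 2 samples", call. = FALSE)
  }
  n <- ncol(x$samples)
  if (n < len) {
    stop("recording (", n / x$fs, " s) is shorter than one epoch; need at ",
         "least ", epoch_length_s, " s", call. = FALSE)
  }
  step <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, n - len + 1L, by = step)
  epochs <- array(0, dim = c(length(starts), nrow(x$samples), len),
                  dimnames = list(NULL, x$labels, NULL))
  for (i in seq_along(starts)) {
    epochs[i, , ] <- x$samples[, starts[i]:(starts[i] + len - 1L)]
  }
  structure(
    list(epochs = epochs, fs = x$fs, epoch_length_s = epoch_length_s,
         labels = x$labels, subject = x$subject,
         rejected = rep(FALSE, length(starts))),
    class = "qeeg_epochs"
  )
}

#' @export
print.qeeg_epochs <- function(x, ...) {
  cat(sprintf("<qeeg_epochs> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject, dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$fs))
  cat(sprintf("  epoch length %g s; %d rejected\n",
              x$epoch_length_s, sum(x$rejected)))
  invisible(x)
}

#' Flag epochs exceeding a peak-to-peak amplitude limit
#'
#' Guards against residual artifacts before spectral averaging: an epoch
#' whose range on any channel exceeds the limit is flagged and excluded
#' from downstream averaging. At least one epoch must survive.
#'
#' @param x A `qeeg_epochs`.
#' @param peak_to_peak_limit_uv Rejection threshold in microvolts
#'   (default 200).
#' @return `x` with its `rejected` flags updated.
#' @export
reject_bad_epochs <- function(x, peak_to_peak_limit_uv = 200) {
  stopifnot(inherits(x, "qeeg_epochs"))
  if (!(peak_to_peak_limit_uv > 0)) {
    stop("peak_to_peak_limit_uv must be > 0", call. = FALSE)
  }
  ranges <- apply(x$epochs, 1, function(ep) {
    max(apply(ep, 1, function(ch) diff(range(ch))))
  })
  flag <- ranges > peak_to_peak_limit_uv
  if (all(flag)) {
    stop("all ", length(flag), " epochs exceed the ", peak_to_peak_limit_uv,
         " microvolt peak-to-peak limit (observed ranges ",
         paste(sprintf("%.1f", sort(ranges)), collapse = ", "), ")",
         call. = FALSE)
  }
  x$rejected <- x$rejected | flag
  x
}

# Concatenate unrejected epochs back into a channels x time matrix.
epochs_to_matrix <- function(x, keep_rejected = TRUE) {
  keep <- if (keep_rejected) seq_len(dim(x$epochs)[1]) else which(!x$rejected)
  mats <- lapply(keep, function(i) x$epochs[i, , , drop = TRUE])
  do.call(cbind, mats)
}
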