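#' @title Multichannel EEG recording container
#' @description A `qeeg_recording` holds a channels x time matrix of
#'   microvolt samples together with the sampling rate, 10-20 channel
#'   labels, a subject identifier and the eyes condition of the session.
#'   All pipeline stages consume and return this container.
#' @name qeeg_recording
NULL

#' The nine-lead montage used by the pipeline
#'
#' Frontal Fz/F3/F4, central Cz/C3/C4 and parietal Pz/P3/P4, in canonical
#' order. Midline leads carry a `z` suffix; odd indices are left hemisphere,
#' even indices right.
#'
#' @return Character vector of the nine lead labels.
#' @export
nine_leads <- function() {
  c("Fz", "F3", "F4", "Cz", "C3", "C4", "Pz", "P3", "P4")
}

#' Construct an EEG recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels; normalized to canonical 10-20 form
#'   (see [normalize_labels()]).
#' @param subject Subject identifier string.
#' @param condition Eyes-condition tag, e.g. `"eyes-closed"`.
#' @return A `qeeg_recording` object.
#' @export
recording <- function(samples, fs, labels,
                      subject = "unknown", condition = "eyes-closed") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric channels x time matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  labels <- normalize_labels(labels)
  if (length(labels) != nrow(samples)) {
    stop("got ", length(labels), " labels for ", nrow(samples),
         " channels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels after normalization: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, labels = labels,
         subject = subject, condition = condition,
         provenance = character(0)),
    class = "qeeg_recording"
  )
}

#' @export
print.qeeg_recording <- function(x, ...) {
  cat(sprintf("<qeeg_recording> subject=%s (%s)\n", x$subject, x$condition))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param x A `qeeg_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "qeeg_recording"))
  ncol(x$samples) / x$fs
}

#' Normalize channel labels to canonical 10-20 names
#'
#' Strips `"EEG "` prefixes and reference suffixes such as `"-REF"` or
#' `"-A1"`, trims whitespace and fixes case so that e.g. `"EEG Fz-REF"`,
#' `"FZ"` and `"fz"` all map to `"Fz"`. Labels that are not 10-20 names are
#' returned trimmed but otherwise untouched. The mapping is idempotent.
#'
#' @param labels Character vector of raw channel labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_labels(c("EEG Fz-REF", "c3", "PZ"))
#' @export
normalize_labels <- function(labels) {
  stopifnot(is.character(labels))
  x <- trimws(labels)
  x <- sub("^EEG[ _]+", "", x, ignore.case = TRUE)
  x <- sub("-(REF|LE|A1|A2|AVG)$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  # canonical case: site letter(s) upper, z suffix lower
  fix_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)([0-9]+|z|Z)$", lab))[[1]]
    if (length(m) == 3L) {
      suffix <- ifelse(m[3] %in% c("z", "Z"), "z", m[3])
      paste0(toupper(m[2]), suffix)
    } else {
      lab
    }
  }
  vapply(x, fix_one, character(1), USE.NAMES = FALSE)
}

#' Subset a recording to a montage
#'
#' Selects the requested leads and returns them in the requested order
#' (default: the canonical nine-lead order).
#'
#' @param x A `qeeg_recording`.
#' @param leads Character vector of lead labels to keep.
#' @return A `qeeg_recording` restricted to `leads`.
#' @export
select_montage <- function(x, leads = nine_leads()) {
  stopifnot(inherits(x, "qeeg_recording"))
  leads <- normalize_labels(leads)
  missing <- setdiff(leads, x$labels)
  if (length(missing)) {
    stop("requested lead(s) absent from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- x
  out$samples <- x$samples[leads, , drop = FALSE]
  out$labels <- leads
  out$provenance <- c(x$provenance, paste0("montage:", length(leads), "ch"))
  out
}

# Require that the recording carries all of `leads`; error names the absentees.
assert_leads <- function(x, leads) {
  missing <- setdiff(leads, x$labels)
  if (length(missing)) {
    stop("recording is missing required lead(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
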