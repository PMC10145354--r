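#' Canonical EEG frequency bands
#'
#' The six bands used throughout the package: Delta 0.5-4, Theta 4-8,
#' Alpha 8-12, SMR 12-15, Beta1 15-20, Beta2 20-35 Hz. Band intervals are
#' half-open `[low, high)`, so a component at exactly 12 Hz belongs to SMR,
#' not Alpha; with that convention the shared printed edges (4, 8, 12, 15,
#' 20 Hz) are assigned to exactly one band each.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`, one row per
#'   band in canonical order.
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  tibble::tibble(
    band    = c("Delta", "Theta", "Alpha", "SMR", "Beta1", "Beta2"),
    low_hz  = c(0.5, 4, 8, 12, 15, 20),
    high_hz = c(4, 8, 12, 15, 20, 35)
  )
}

BAND_NAMES <- c("Delta", "Theta", "Alpha", "SMR", "Beta1", "Beta2")

#' Define a frequency band
#'
#' @param name Band label.
#' @param low_hz,high_hz Band edges in Hz; the interval is `[low_hz, high_hz)`.
#' @return A `qeeg_band` object (named list with `name`, `low_hz`, `high_hz`).
#' @examples
#' band("Alpha", 8, 12)
#' @export
band <- function(name, low_hz, high_hz) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      !(low_hz > 0) || !(high_hz > low_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz, got [",
         low_hz, ", ", high_hz, ")", call. = FALSE)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "qeeg_band")
}

#' @export
print.qeeg_band <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g) Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

# Resolve a band given as a qeeg_band, a canonical name, or a row index.
as_band <- function(x) {
  if (inherits(x, "qeeg_band")) return(x)
  if (is.character(x) && length(x) == 1L) {
    cb <- canonical_bands()
    i <- match(x, cb$band)
    if (is.na(i)) {
      stop("unknown band '", x, "'; canonical bands are ",
           paste(cb$band, collapse = ", "), call. = FALSE)
    }
    return(band(cb$band[i], cb$low_hz[i], cb$high_hz[i]))
  }
  stop("cannot interpret band of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

# List of the six canonical bands as qeeg_band objects.
canonical_band_list <- function() {
  cb <- canonical_bands()
  stats::setNames(
    lapply(seq_len(nrow(cb)), function(i) band(cb$band[i], cb$low_hz[i], cb$high_hz[i])),
    cb$band
  )
}

# TRUE for frequencies falling in [low, high).
in_band <- function(freq_hz, band) {
  freq_hz >= band$low_hz & freq_hz < band$high_hz
}
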