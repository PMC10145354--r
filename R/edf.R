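#' @title EDF input/output
#' @description Minimal, self-contained reader and writer for the European
#'   Data Format (EDF), the de-facto interchange standard for EEG. EDF
#'   stores an ASCII header followed by 16-bit little-endian samples with a
#'   per-channel linear mapping between digital and physical values, so a
#'   write/read round trip quantizes amplitudes to (physical range)/65534.
#' @name edf_io
NULL

EDF_HEADER_BYTES <- 256L
EDF_SIGNAL_HEADER_BYTES <- 256L

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

# scale factor from an EDF physical-dimension string to microvolts
dimension_to_uv <- function(dim) {
  d <- trimws(dim)
  scale <- c("uV" = 1, "µV" = 1, "UV" = 1, "mV" = 1e3, "MV" = 1e3, "V" = 1e6)
  i <- match(d, names(scale))
  if (is.na(i)) {
    stop("channel physical dimension '", d,
         "' cannot be converted to microvolts (supported: uV, mV, V)",
         call. = FALSE)
  }
  unname(scale[i])
}

#' Write a recording to an EDF file
#'
#' Samples are stored as 16-bit integers against a per-channel physical
#' range spanning the channel's observed amplitude, in microvolts. One data
#' record per second is used when the sampling rate is an integer and the
#' duration a whole number of seconds; otherwise the whole signal is written
#' as a single data record.
#'
#' @param x A `qeeg_recording` (amplitudes in microvolts).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(x, path) {
  stopifnot(inherits(x, "qeeg_recording"))
  ns <- nrow(x$samples)
  n_samp <- ncol(x$samples)

  if (x$fs == round(x$fs) && n_samp %% x$fs == 0) {
    record_dur <- 1
    spr <- as.integer(x$fs)
  } else {
    record_dur <- n_samp / x$fs
    spr <- n_samp
  }
  n_rec <- as.integer(n_samp / spr)

  dig_min <- -32767L; dig_max <- 32767L
  phys_max <- apply(abs(x$samples), 1, max)
  phys_max <- pmax(phys_max * 1.0001, 1)  # nonzero range even for flat channels
  phys_min <- -phys_max

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(x$subject, 80),
    pad_field(x$condition, 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(EDF_HEADER_BYTES + ns * EDF_SIGNAL_HEADER_BYTES, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format(record_dur, digits = 7), 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(values, width) {
    writeChar(paste(vapply(values, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(x$labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(formatC(phys_min, format = "g", digits = 7), 8)
  field(formatC(phys_max, format = "g", digits = 7), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  # re-read the formatted physical extrema so the stored mapping is exact
  pmin_stored <- as.numeric(formatC(phys_min, format = "g", digits = 7))
  pmax_stored <- as.numeric(formatC(phys_max, format = "g", digits = 7))
  gain <- (pmax_stored - pmin_stored) / (dig_max - dig_min)

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- vapply(seq_len(ns), function(ch) {
      d <- round((x$samples[ch, idx] - pmin_stored[ch]) / gain[ch]) + dig_min
      as.integer(pmin(pmax(d, dig_min), dig_max))
    }, integer(spr))
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF/EDF+ file
#'
#' Channel labels are normalized to canonical 10-20 names (case fixed,
#' `"EEG "` prefixes and reference suffixes stripped) and amplitudes are
#' converted to microvolts whatever physical dimension (uV, mV, V) the file
#' declares.
#'
#' @param path EDF file path.
#' @param channels Optional character vector: keep only these leads (after
#'   normalization), in the given order.
#' @param strict_montage If `TRUE`, fail unless all nine canonical leads
#'   are present, naming any missing lead.
#' @return A `qeeg_recording` in microvolts.
#' @export
read_edf_recording <- function(path, channels = NULL, strict_montage = FALSE) {
  if (!file.exists(path)) {
    stop("EDF file does not exist: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  rd <- function(width) readChar(con, width, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) {
    stop("not an EDF file (header version '", version, "'): ", path,
         call. = FALSE)
  }
  patient <- trimws(rd(80))
  rec_id <- trimws(rd(80))
  rd(8); rd(8)                              # start date/time, unused
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  record_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1L || is.na(header_bytes) ||
      header_bytes != EDF_HEADER_BYTES + ns * EDF_SIGNAL_HEADER_BYTES) {
    stop("malformed EDF header (signal count/header size) in ", path,
         call. = FALSE)
  }
  rdn <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  }
  labels <- rdn(16)
  rdn(80)
  dims <- rdn(8)
  phys_min <- as.numeric(rdn(8))
  phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8))
  dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) ||
      any(dig_max <= dig_min) || any(spr < 1L)) {
    stop("malformed EDF signal headers in ", path, call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF with per-channel sampling rates is not supported: ", path,
         call. = FALSE)
  }
  spr <- spr[1]
  fs <- spr / record_dur

  if (is.na(n_rec) || n_rec < 0L) {  # -1 means "unknown" per the format
    data_bytes <- file.size(path) - header_bytes
    n_rec <- as.integer(data_bytes / (2 * ns * spr))
  }
  raw <- readBin(con, "integer", n = n_rec * ns * spr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * ns * spr) {
    stop("EDF data section truncated in ", path, call. = FALSE)
  }
  arr <- array(as.numeric(raw), dim = c(spr, ns, n_rec))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  to_uv <- vapply(dims, dimension_to_uv, numeric(1))

  samples <- matrix(0, nrow = ns, ncol = spr * n_rec)
  for (ch in seq_len(ns)) {
    phys <- (as.vector(arr[, ch, ]) - dig_min[ch]) * gain[ch] + phys_min[ch]
    samples[ch, ] <- phys * to_uv[ch]
  }

  out <- recording(samples, fs = fs, labels = labels,
                   subject = if (nzchar(patient)) patient else "unknown",
                   condition = if (nzchar(rec_id)) rec_id else "unknown")
  out$provenance <- paste0("edf:", basename(path))
  if (strict_montage) assert_leads(out, nine_leads())
  if (!is.null(channels)) out <- select_montage(out, channels)
  out
}
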