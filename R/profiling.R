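#' @title Normative profiling and asymmetry
#' @description Compares band amplitudes against adult normative ceilings,
#'   flags exceedances per lead, and scores inter-hemispheric asymmetry
#'   between homologous lead pairs.
#' @name profiling
NULL

#' Adult normative amplitude ceilings
#'
#' The per-band peak-to-peak amplitude ceilings regarded as normal for
#' adults in eyes-closed resting QEEG: Delta up to 20, Theta up to 15,
#' Alpha up to 10, and SMR, Beta1, Beta2 up to 6 microvolts. Any ceiling
#' can be overridden.
#'
#' @param ... Named overrides in microvolts, e.g. `Alpha = 12`.
#' @return Named numeric vector over the six canonical bands.
#' @examples
#' normative_scale()
#' normative_scale(Beta2 = 8)
#' @export
normative_scale <- function(...) {
  scale <- c(Delta = 20, Theta = 15, Alpha = 10, SMR = 6, Beta1 = 6, Beta2 = 6)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(scale))
    if (length(bad)) {
      stop("unknown band(s) in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(over <= 0)) stop("ceilings must be > 0 microvolts", call. = FALSE)
    scale[names(over)] <- over
  }
  scale
}

#' Classify band amplitudes against the normative scale
#'
#' An amplitude strictly above its band's ceiling is flagged as an
#' exceedance ("normal below the ceiling"); the exceedance magnitude is
#' `max(0, amplitude - ceiling)`. The input table is never modified.
#'
#' @param table Tibble with columns `lead`, `band`, `amplitude_uv` (and
#'   optionally `subject`).
#' @param scale Named ceilings from [normative_scale()].
#' @return The table with added `ceiling_uv`, `exceeds` (logical) and
#'   `exceedance_uv` columns.
#' @export
classify_against_norms <- function(table, scale = normative_scale()) {
  stopifnot(all(c("lead", "band", "amplitude_uv") %in% names(table)))
  missing <- setdiff(unique(table$band), names(scale))
  if (length(missing)) {
    stop("band(s) missing from the normative scale: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- table
  out$ceiling_uv <- unname(scale[out$band])
  out$exceeds <- out$amplitude_uv > out$ceiling_uv
  out$exceedance_uv <- pmax(0, out$amplitude_uv - out$ceiling_uv)
  out
}

#' Inter-hemispheric asymmetry index
#'
#' Percent amplitude difference between homologous left/right leads. The
#' default convention divides the absolute difference by the pair mean
#' (symmetric and bounded at 200%); dividing by the smaller or the larger
#' amplitude is selectable. The index is symmetric under swapping the
#' leads and zero only when they are equal.
#'
#' @param left,right Band amplitudes in microvolts (both >= 0, not both
#'   zero).
#' @param convention `"mean"` (default), `"smaller"` or `"larger"`
#'   denominator.
#' @return Asymmetry in percent, with the convention attached as an
#'   attribute.
#' @examples
#' asymmetry_index(7.81, 10.13)  # ~25.9% — above a 20% criterion
#' @export
asymmetry_index <- function(left, right, convention = c("mean", "smaller", "larger")) {
  convention <- match.arg(convention)
  if (left < 0 || right < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (left == 0 && right == 0) {
    out <- NA_real_
    attr(out, "convention") <- convention
    return(out)
  }
  denom <- switch(convention,
                  mean = (left + right) / 2,
                  smaller = min(left, right),
                  larger = max(left, right))
  if (denom == 0) {                       # smaller-denominator with one zero
    out <- NA_real_
    attr(out, "convention") <- convention
    return(out)
  }
  out <- 100 * abs(right - left) / denom
  attr(out, "convention") <- convention
  out
}

HOMOLOGOUS_PAIRS <- list(c("F3", "F4"), c("C3", "C4"), c("P3", "P4"))

# Asymmetry table for one subject's (or group-mean) band table.
asymmetry_table <- function(table, convention = "mean", threshold_pct = 20) {
  rows <- list()
  for (pair in HOMOLOGOUS_PAIRS) {
    for (b in unique(table$band)) {
      l <- table$amplitude_uv[table$lead == pair[1] & table$band == b]
      r <- table$amplitude_uv[table$lead == pair[2] & table$band == b]
      if (!length(l) || !length(r)) next
      idx <- asymmetry_index(l, r, convention)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pair = paste(pair, collapse = "/"), band = b,
        left_uv = l, right_uv = r,
        asymmetry_pct = as.numeric(idx),
        convention = convention,
        asymmetric = !is.na(idx) & idx > threshold_pct
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Build normative profiles for subjects and the group
#'
#' Classifies every subject's band-amplitude table against the normative
#' scale and scores homologous-pair asymmetry; the group profile is
#' computed on the across-subject mean amplitude table (and, separately,
#' the per-lead count of subjects exceeding each ceiling).
#'
#' @param table Tibble with `subject`, `lead`, `band`, `amplitude_uv`.
#' @param scale Ceilings from [normative_scale()].
#' @param asymmetry_threshold_pct Asymmetry criterion in percent
#'   (default 20).
#' @param convention Asymmetry denominator convention (see
#'   [asymmetry_index()]).
#' @return A `qeeg_profile` list: `subjects` (classified per-subject
#'   rows), `subject_asymmetry`, `group` (classification of the mean
#'   table), `group_asymmetry`, `exceedance_counts` (per lead/band number
#'   of subjects above the ceiling), and the parameters used.
#' @export
build_profile <- function(table, scale = normative_scale(),
                          asymmetry_threshold_pct = 20,
                          convention = "mean") {
  stopifnot(all(c("lead", "band", "amplitude_uv") %in% names(table)))
  if (!"subject" %in% names(table)) table$subject <- "S01"
  if (!nrow(table)) stop("empty band-amplitude table", call. = FALSE)

  subjects <- classify_against_norms(table, scale)
  subject_asym <- dplyr::bind_rows(lapply(split(table, table$subject), function(tb) {
    out <- asymmetry_table(tb, convention, asymmetry_threshold_pct)
    if (nrow(out)) out$subject <- tb$subject[1]
    out
  }))

  group_tbl <- table |>
    dplyr::group_by(lead, band) |>
    dplyr::summarise(amplitude_uv = mean(amplitude_uv), .groups = "drop")
  group <- classify_against_norms(group_tbl, scale)
  group_asym <- asymmetry_table(group_tbl, convention, asymmetry_threshold_pct)

  counts <- subjects |>
    dplyr::group_by(lead, band) |>
    dplyr::summarise(n_exceeding = sum(exceeds), n = dplyr::n(),
                     .groups = "drop")

  structure(
    list(subjects = subjects, subject_asymmetry = subject_asym,
         group = group, group_asymmetry = group_asym,
         exceedance_counts = counts,
         scale = scale, asymmetry_threshold_pct = asymmetry_threshold_pct,
         convention = convention),
    class = "qeeg_profile"
  )
}

#' @export
print.qeeg_profile <- function(x, ...) {
  flagged <- x$group[x$group$exceeds, ]
  cat("<qeeg_profile>\n")
  cat(sprintf("  group exceedances (%d):\n", nrow(flagged)))
  if (nrow(flagged)) {
    for (i in seq_len(nrow(flagged))) {
      cat(sprintf("    %-5s %-5s %.2f uV > %g uV ceiling\n",
                  flagged$band[i], flagged$lead[i], flagged$amplitude_uv[i],
                  flagged$ceiling_uv[i]))
    }
  }
  asym <- x$group_asymmetry[x$group_asymmetry$asymmetric, ]
  cat(sprintf("  group asymmetries > %g%% (%d):\n",
              x$asymmetry_threshold_pct, nrow(asym)))
  if (nrow(asym)) {
    for (i in seq_len(nrow(asym))) {
      cat(sprintf("    %-5s %s: %.1f%%\n", asym$band[i], asym$pair[i],
                  asym$asymmetry_pct[i]))
    }
  }
  invisible(x)
}

#' Serialize a profile to JSON
#' @param x A `qeeg_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  jsonlite::write_json(
    list(group = x$group, group_asymmetry = x$group_asymmetry,
         exceedance_counts = x$exceedance_counts,
         scale = as.list(x$scale),
         asymmetry_threshold_pct = x$asymmetry_threshold_pct,
         convention = x$convention),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
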