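#' Reference cohort band-amplitude statistics
#'
#' Published group summary statistics (mean, min, max, quartiles, SD of
#' per-lead peak-to-peak band amplitudes, in microvolts) for an eyes-closed
#' resting QEEG cohort of 18 adult K-1 kickboxing athletes on the nine-lead
#' montage. These are the default distribution parameters of the synthetic
#' cohort generator ([cohort_spec()]) and the worked-example inputs for
#' normative classification and asymmetry scoring.
#'
#' The SMR rows for F3 and F4 violate the order-statistic chain
#' `min <= Q1 <= Q3 <= max` as printed (an apparent column shift in the
#' source tables); [validate_descriptive_table()] flags them. Only the
#' `mean` and `sd` columns are used for simulation.
#'
#' @return A tibble with columns `band`, `lead`, `mean`, `min`, `max`,
#'   `q1`, `q3`, `sd` (all microvolts) and `n` (subjects).
#' @examples
#' reference_cohort_stats()
#' @export
reference_cohort_stats <- function() {
  rows <- rbind(
    # band, lead, mean, min, max, q1, q3, sd
    c("Delta", "Fz", 19.54, 13.03, 33.78, 13.84, 22.19, 7.50),
    c("Delta", "F3", 14.01, 11.48, 22.84, 12.19, 14.21, 3.01),
    c("Delta", "F4", 15.10, 10.62, 26.35, 12.28, 16.00, 4.33),
    c("Delta", "Cz", 16.85,  9.13, 24.98, 13.03, 19.45, 4.47),
    c("Delta", "C3", 16.24, 12.19, 23.23, 13.98, 19.43, 3.54),
    c("Delta", "C4", 16.14, 10.62, 26.35, 13.28, 18.62, 3.87),
    c("Delta", "Pz", 16.88, 10.62, 26.35, 12.28, 22.28, 5.32),
    c("Delta", "P3", 17.34, 11.48, 34.21, 12.83, 21.99, 6.78),
    c("Delta", "P4", 15.96, 10.62, 26.35, 13.28, 19.45, 4.13),
    c("Theta", "Fz", 13.83,  9.19, 27.55, 11.77, 14.91, 4.20),
    c("Theta", "F3", 12.56,  9.88, 17.19, 11.78, 13.70, 1.86),
    c("Theta", "F4", 12.99,  9.90, 18.37, 11.91, 14.37, 2.14),
    c("Theta", "Cz",  9.08,  6.69, 11.67,  7.38, 10.10, 1.66),
    c("Theta", "C3",  8.58,  6.59, 11.10,  7.63, 10.59, 1.69),
    c("Theta", "C4",  8.91,  5.78, 11.78,  6.71, 11.78, 2.48),
    c("Theta", "Pz",  8.53,  5.14, 10.62,  6.85, 10.62, 2.11),
    c("Theta", "P3",  8.99,  6.01, 10.93,  7.54, 10.12, 1.68),
    c("Theta", "P4",  8.38,  5.08, 10.08,  7.25, 10.08, 1.85),
    c("Alpha", "Fz",  8.77,  6.31, 14.34,  6.87,  9.31, 2.77),
    c("Alpha", "F3",  7.81,  5.45, 11.56,  6.77,  7.58, 1.89),
    c("Alpha", "F4", 10.13,  5.58, 35.37,  6.11, 10.12, 7.33),
    c("Alpha", "Cz", 10.30,  5.58, 18.58,  7.53, 10.70, 4.17),
    c("Alpha", "C3", 11.02,  5.34, 19.79,  8.34, 16.71, 4.42),
    c("Alpha", "C4", 10.64,  7.01, 19.88,  7.14, 16.18, 4.40),
    c("Alpha", "Pz",  8.26,  4.69, 12.07,  6.18,  9.94, 2.32),
    c("Alpha", "P3",  9.22,  4.68, 13.09,  7.68, 11.69, 2.62),
    c("Alpha", "P4",  8.43,  4.60, 11.98,  7.08,  9.94, 2.33),
    c("SMR",   "Fz",  4.69,  3.74,  6.14,  4.00,  5.08, 0.81),
    c("SMR",   "F3",  4.86,  0.87,  3.67,  6.11,  3.83, 5.31),
    c("SMR",   "F4",  6.31,  4.37,  3.12, 15.64,  3.58, 5.25),
    c("SMR",   "Cz",  4.77,  3.02,  7.02,  3.68,  5.39, 1.11),
    c("SMR",   "C3",  4.63,  4.21,  7.58,  4.27,  4.59, 0.76),
    c("SMR",   "C4",  3.74,  3.21,  5.41,  3.45,  3.92, 0.49),
    c("SMR",   "Pz",  5.14,  3.47,  7.38,  4.18,  5.76, 1.28),
    c("SMR",   "P3",  5.25,  3.47,  8.80,  4.39,  5.80, 1.45),
    c("SMR",   "P4",  5.18,  3.18,  9.18,  3.58,  5.66, 1.76),
    c("Beta1", "Fz",  5.33,  4.50,  6.59,  5.03,  5.63, 0.67),
    c("Beta1", "F3",  6.48,  4.98,  9.77,  5.60,  6.77, 1.61),
    c("Beta1", "F4",  8.05,  4.09, 19.30,  5.58,  6.69, 5.25),
    c("Beta1", "Cz",  5.76,  4.81,  7.59,  5.20,  6.19, 0.94),
    c("Beta1", "C3",  6.04,  4.80,  7.83,  5.38,  6.93, 1.06),
    c("Beta1", "C4",  5.44,  4.21,  6.88,  4.82,  6.27, 0.92),
    c("Beta1", "Pz",  5.59,  4.21,  7.51,  4.44,  6.35, 1.06),
    c("Beta1", "P3",  6.49,  4.91,  7.96,  5.89,  7.44, 1.04),
    c("Beta1", "P4",  5.66,  4.43,  7.51,  4.44,  6.35, 1.11),
    c("Beta2", "Fz",  6.70,  5.66,  7.96,  6.16,  7.31, 0.77),
    c("Beta2", "F3",  8.39,  6.06, 14.67,  7.31,  9.41, 2.01),
    c("Beta2", "F4",  9.40,  5.21, 15.27,  7.08, 11.17, 2.70),
    c("Beta2", "Cz",  6.97,  5.18,  9.25,  6.25,  7.49, 0.86),
    c("Beta2", "C3",  7.40,  6.14,  9.82,  6.40,  7.64, 1.00),
    c("Beta2", "C4",  7.63,  6.38,  9.28,  6.69,  7.89, 0.86),
    c("Beta2", "Pz",  7.35,  6.18,  9.28,  6.69,  7.81, 0.83),
    c("Beta2", "P3",  8.21,  6.79,  9.29,  7.46,  8.79, 0.80),
    c("Beta2", "P4",  8.21,  5.85,  9.56,  7.15,  8.79, 0.94)
  )
  tibble::tibble(
    band = as.character(rows[, 1]),
    lead = as.character(rows[, 2]),
    mean = as.numeric(rows[, 3]),
    min  = as.numeric(rows[, 4]),
    max  = as.numeric(rows[, 5]),
    q1   = as.numeric(rows[, 6]),
    q3   = as.numeric(rows[, 7]),
    sd   = as.numeric(rows[, 8]),
    n    = 18L
  )
}

#' Validate a table of descriptive statistics
#'
#' Checks each row of an externally supplied descriptive table for internal
#' consistency: `min <= Q1 <= Q3 <= max` and `min <= mean <= max`, with a
#' small tolerance for quartile-method differences between software.
#'
#' @param tbl Tibble/data.frame with columns `mean`, `min`, `max`, `q1`,
#'   `q3` (and optionally `band`, `lead` used in messages).
#' @param tol Slack in microvolts allowed on each inequality (default 0.05,
#'   i.e. printed rounding).
#' @return `tbl` with a logical `consistent` column and a `problem`
#'   character column describing the first violated inequality (`NA` when
#'   consistent).
#' @export
validate_descriptive_table <- function(tbl, tol = 0.05) {
  stopifnot(all(c("mean", "min", "max", "q1", "q3") %in% names(tbl)))
  problem <- rep(NA_character_, nrow(tbl))
  chk <- function(lhs, rhs, msg) {
    bad <- tbl[[lhs]] > tbl[[rhs]] + tol
    problem[bad & is.na(problem)] <<- sprintf("%s > %s", lhs, msg)
    invisible(NULL)
  }
  chk("min", "q1", "Q1")
  chk("q1", "q3", "Q3")
  chk("q3", "max", "max")
  chk("min", "mean", "mean")
  chk("mean", "max", "max")
  tbl$consistent <- is.na(problem)
  tbl$problem <- problem
  tbl
}
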