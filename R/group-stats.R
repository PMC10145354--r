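#' @title Group statistics
#' @description Descriptive statistics per lead/band and region-wise
#'   one-way repeated-measures ANOVA (frontal, central, parietal lead
#'   triplets) with partial eta-squared and assumption checks
#'   (Shapiro-Wilk normality per lead, Levene homogeneity).
#' @name group_stats
NULL

#' Descriptive statistics of a sample of amplitudes
#'
#' Mean, min, max, quartiles (linear interpolation of order statistics,
#' quantile type 7) and sample SD (n-1 denominator).
#'
#' @param values Numeric vector, length >= 2.
#' @return A one-row tibble: `mean`, `min`, `max`, `q1`, `q3`, `sd`, `n`.
#' @examples
#' descriptive_stats(c(1, 2, 3, 4, 5))
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2) {
    stop("descriptive statistics need n >= 2 values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    mean = mean(values), min = min(values), max = max(values),
    q1 = q[1], q3 = q[2], sd = stats::sd(values), n = length(values)
  )
}

#' One-way repeated-measures ANOVA over three leads
#'
#' Within-subjects F test for a subjects x 3 amplitude matrix, by direct
#' sums-of-squares decomposition: `F = MS_condition / MS_error` on
#' `(2, 2(n-1))` degrees of freedom after removing between-subject
#' variance. The effect size is partial eta-squared,
#' `SS_condition / (SS_condition + SS_error)`. Assumption checks
#' (Shapiro-Wilk per lead; Levene on absolute deviations from lead
#' medians) are attached but never used to switch tests silently.
#'
#' @param m Numeric matrix, subjects (rows, >= 3) x leads (3 columns),
#'   complete cases only; column names identify the leads.
#' @return A one-row tibble: `f`, `p`, `eta_sq_partial`, `df1`, `df2`,
#'   `shapiro_p` (list-column, one p per lead), `levene_p`, `n`.
#' @export
rm_anova <- function(m) {
  if (!is.matrix(m) || ncol(m) != 3) {
    stop("rm_anova expects a subjects x 3 matrix", call. = FALSE)
  }
  if (nrow(m) < 3) stop("rm_anova needs >= 3 subjects", call. = FALSE)
  if (anyNA(m)) {
    stop("rm_anova requires complete cases; missing cells are not imputed",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else ifelse(ms_cond > 0, Inf, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  eta <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0

  shapiro_p <- apply(m, 2, function(col) {
    if (stats::sd(col) == 0) NA_real_ else stats::shapiro.test(col)$p.value
  })
  # Brown-Forsythe form of Levene's test: one-way ANOVA on absolute
  # deviations from the column medians
  dev <- abs(sweep(m, 2, apply(m, 2, stats::median)))
  lev <- stats::oneway.test(
    dev ~ grp,
    data = data.frame(dev = as.vector(dev),
                      grp = factor(rep(colnames(m) %||% seq_len(k),
                                       each = n))),
    var.equal = TRUE
  )
  tibble::tibble(
    f = f, p = p, eta_sq_partial = eta, df1 = df1, df2 = df2,
    shapiro_p = list(shapiro_p), levene_p = lev$p.value, n = n
  )
}

REGIONS <- list(frontal = c("Fz", "F3", "F4"),
                central = c("Cz", "C3", "C4"),
                parietal = c("Pz", "P3", "P4"))

#' Region-wise ANOVA battery
#'
#' For each band and each lead triplet (frontal Fz/F3/F4, central
#' Cz/C3/C4, parietal Pz/P3/P4), one repeated-measures ANOVA comparing
#' the three leads within subjects: 18 tests over the six canonical
#' bands. No multiple-testing correction is applied (per-test alpha).
#'
#' @param table Tibble with `subject`, `lead`, `band`, `amplitude_uv`
#'   covering all nine leads.
#' @return Tibble with one row per band x region: `band`, `region`,
#'   `leads`, plus the [rm_anova()] columns.
#' @export
region_battery <- function(table) {
  stopifnot(all(c("subject", "lead", "band", "amplitude_uv") %in% names(table)))
  missing <- setdiff(nine_leads(), unique(table$lead))
  if (length(missing)) {
    stop("band table is missing lead(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (b in unique(table$band)) {
    tb <- table[table$band == b, ]
    for (rg in names(REGIONS)) {
      leads <- REGIONS[[rg]]
      wide <- vapply(leads, function(ld) {
        sub <- tb[tb$lead == ld, ]
        sub$amplitude_uv[order(sub$subject)]
      }, numeric(length(unique(tb$subject))))
      res <- rm_anova(wide)
      res$band <- b
      res$region <- rg
      res$leads <- paste(leads, collapse = " ")
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c("band", "region", "leads", "f", "p", "eta_sq_partial",
          "df1", "df2", "shapiro_p", "levene_p", "n")]
}

#' Band-wise descriptive tables with test lines
#'
#' Produces, for each band, the nine-lead descriptive table (Mean, Min,
#' Max, Q1, Q3, SD) together with the region-wise ANOVA p and effect
#' size — the layout in which group QEEG results are conventionally
#' reported.
#'
#' @param table Tibble with `subject`, `lead`, `band`, `amplitude_uv`.
#' @return A list with `descriptives` (tibble: band, lead + descriptive
#'   columns) and `anova` (the [region_battery()] result; zero rows for
#'   cohorts below the three subjects a within-subject F test needs).
#' @export
group_summary <- function(table) {
  desc <- table |>
    dplyr::group_by(band, lead) |>
    dplyr::reframe(descriptive_stats(amplitude_uv)) |>
    dplyr::ungroup()
  # canonical ordering
  desc <- desc[order(match(desc$band, BAND_NAMES),
                     match(desc$lead, nine_leads())), ]
  anova <- if (length(unique(table$subject)) >= 3) {
    region_battery(table)
  } else {
    tibble::tibble(band = character(), region = character(),
                   leads = character(), f = numeric(), p = numeric(),
                   eta_sq_partial = numeric(), df1 = numeric(),
                   df2 = numeric(), shapiro_p = list(),
                   levene_p = numeric(), n = integer())
  }
  list(descriptives = desc, anova = anova)
}
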