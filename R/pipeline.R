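#' @title End-to-end pipeline
#' @description Orchestrates simulate/load -> re-reference -> epoch ->
#'   BSS artifact removal -> epoch rejection -> FFT band quantification ->
#'   normative profiling -> group statistics from one configuration
#'   object, writing per-subject tables, profiles, band-wise group tables
#'   and a run manifest with content hashes.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Exactly one input source must be given: a directory of EDF recordings
#' or a simulation spec.
#'
#' @param edf_dir Directory containing `.edf` recordings (one per
#'   subject), or `NULL`.
#' @param simulate A [cohort_spec()] to generate the cohort, or `NULL`.
#' @param reference `"midline"` (subtract the Fz/Cz/Pz mean, default for
#'   recorded data), a single lead name, or `"none"`.
#' @param epoch_length_s,overlap Epoching parameters (defaults 8.2 s, 0).
#' @param run_bss Logical; run ICA artifact removal (default `TRUE` for
#'   EDF input, `FALSE` for simulated clean cohorts).
#' @param bss A [bss_config()].
#' @param reject_limit_uv Epoch peak-to-peak rejection limit (default 200).
#' @param spectral A [spectral_config()] or `NULL` to derive one from the
#'   data's sampling rate.
#' @param scale Normative ceilings ([normative_scale()]).
#' @param asymmetry_threshold_pct Asymmetry criterion (default 20).
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in all outputs (also the BSS seed
#'   unless `bss` overrides it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(edf_dir = NULL, simulate = NULL,
                            reference = "midline",
                            epoch_length_s = 8.2, overlap = 0,
                            run_bss = is.null(simulate),
                            bss = NULL,
                            reject_limit_uv = 200,
                            spectral = NULL,
                            scale = normative_scale(),
                            asymmetry_threshold_pct = 20,
                            out_dir = tempfile("qeeg_run_"),
                            seed = 1L) {
  if (is.null(edf_dir) == is.null(simulate)) {
    stop("exactly one input source is required: edf_dir or simulate",
         call. = FALSE)
  }
  structure(
    list(edf_dir = edf_dir, simulate = simulate, reference = reference,
         epoch_length_s = epoch_length_s, overlap = overlap,
         run_bss = run_bss, bss = bss %||% bss_config(seed = seed),
         reject_limit_uv = reject_limit_uv, spectral = spectral,
         scale = scale, asymmetry_threshold_pct = asymmetry_threshold_pct,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulate` is
#' passed to [cohort_spec()], `scale` to [normative_scale()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  simulate <- if (!is.null(doc$simulate)) {
    do.call(cohort_spec, doc$simulate)
  }
  scale <- if (!is.null(doc$scale)) do.call(normative_scale, doc$scale)
           else normative_scale()
  pipeline_config(
    edf_dir = doc$edf_dir, simulate = simulate,
    reference = doc$reference %||% "midline",
    epoch_length_s = doc$epoch_length_s %||% 8.2,
    overlap = doc$overlap %||% 0,
    run_bss = doc$run_bss %||% is.null(simulate),
    reject_limit_uv = doc$reject_limit_uv %||% 200,
    scale = scale,
    asymmetry_threshold_pct = doc$asymmetry_threshold_pct %||% 20,
    out_dir = doc$out_dir %||% tempfile("qeeg_run_"),
    seed = doc$seed %||% 1L
  )
}

# Quantify one recording through the configured stages; returns the
# subject band table plus stage counts.
process_recording <- function(rec, config) {
  if (identical(config$reference, "midline")) {
    rec <- rereference_midline(rec)
  } else if (!identical(config$reference, "none")) {
    rec <- rereference_midline(rec, reference = config$reference)
  }
  ep <- epoch_recording(rec, config$epoch_length_s, config$overlap)
  bss_report <- NULL
  if (config$run_bss) {
    res <- remove_artifacts_bss(ep, config$bss)
    ep <- res$epochs
    bss_report <- res$report
  }
  ep <- reject_bad_epochs(ep, config$reject_limit_uv)
  cfg <- config$spectral %||% spectral_config(fs = ep$fs)
  tbl <- subject_band_table(ep, cfg)
  list(table = tbl, bss_report = bss_report,
       n_epochs = length(ep$rejected), n_rejected = sum(ep$rejected))
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `band_table` (all subjects), `profile`
#'   (a `qeeg_profile`), `summary` (descriptives + ANOVA battery),
#'   `manifest` and `out_dir`. Side effect: per-subject TSV tables,
#'   `profile.json`, band-wise group tables, `anova.tsv` and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    recordings <- cohort$recordings
  } else {
    files <- sort(list.files(config$edf_dir, pattern = "\\.edf$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      stop("no EDF files found in directory ", config$edf_dir, call. = FALSE)
    }
    recordings <- lapply(files, read_edf_recording, strict_montage = TRUE)
  }

  tables <- vector("list", length(recordings))
  counts <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    res <- tryCatch(
      process_recording(rec, config),
      error = function(e) {
        stop("pipeline failed for subject ", rec$subject, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    tables[[i]] <- res$table
    counts[[i]] <- tibble::tibble(
      subject = rec$subject, n_epochs = res$n_epochs,
      n_rejected = res$n_rejected,
      n_bss_removed = if (is.null(res$bss_report)) 0L
                      else length(res$bss_report$rejected)
    )
    p <- file.path(config$out_dir, paste0(rec$subject, "_bands.tsv"))
    utils::write.table(res$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  band_table <- dplyr::bind_rows(tables)

  profile <- build_profile(band_table, config$scale,
                           config$asymmetry_threshold_pct)
  write_profile(profile, file.path(config$out_dir, "profile.json"))

  summary <- group_summary(band_table)
  for (b in unique(summary$descriptives$band)) {
    writeLines(render_band_table(summary, b),
               file.path(config$out_dir, paste0("group_", b, ".tsv")))
  }
  anova_out <- summary$anova
  anova_out$shapiro_p <- vapply(anova_out$shapiro_p, paste, "",
                                collapse = ";")
  utils::write.table(anova_out, file.path(config$out_dir, "anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("qeegband")),
    seed = config$seed,
    n_subjects = length(recordings),
    input = if (is.null(config$edf_dir)) "simulated" else config$edf_dir,
    reference = config$reference,
    epoch_length_s = config$epoch_length_s,
    stage_counts = dplyr::bind_rows(counts),
    files = tibble::tibble(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(band_table = band_table, profile = profile,
                 summary = summary, manifest = manifest,
                 out_dir = config$out_dir))
}

# "p < 0.001" below a thousandth, otherwise two/three decimals — the
# conventional table formatting; exact values always live in the JSON/TSV.
format_p <- function(p) {
  if (p < 0.001) "p < 0.001" else sprintf("p = %.2f", p)
}

#' Render one band's group table
#'
#' Nine lead rows (Mean Min Max Q1 Q3 SD, two-decimal microvolts) grouped
#' by region, each region followed by its ANOVA p and effect-size line.
#'
#' @param summary Result of [group_summary()].
#' @param band Band name to render.
#' @return Character vector of lines (tab-separated).
#' @export
render_band_table <- function(summary, band) {
  desc <- summary$descriptives[summary$descriptives$band == band, ]
  anov <- summary$anova[summary$anova$band == band, ]
  if (!nrow(desc)) {
    warning("no results for band ", band)
    return(character(0))
  }
  lines <- paste(band, "Mean", "Min", "Max", "Q1", "Q3", "SD", sep = "\t")
  for (rg in names(REGIONS)) {
    for (ld in REGIONS[[rg]]) {
      row <- desc[desc$lead == ld, ]
      if (!nrow(row)) next
      lines <- c(lines, paste(
        ld, sprintf("%.2f", row$mean), sprintf("%.2f", row$min),
        sprintf("%.2f", row$max), sprintf("%.2f", row$q1),
        sprintf("%.2f", row$q3), sprintf("%.2f", row$sd), sep = "\t"
      ))
    }
    arow <- anov[anov$region == rg, ]
    if (nrow(arow)) {
      lines <- c(lines, sprintf("\t%s ES = %.2f", format_p(arow$p),
                                arow$eta_sq_partial))
    }
  }
  lines
}
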