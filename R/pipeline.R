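## Pipeline orchestration: configuration-driven profiling of one sample
## (align -> detect -> calibrate -> annotate -> normalise -> frequency) and
## replicate comparison. Deterministic given its inputs; every report
## carries a hash of the resolved configuration.

#' Build or read a profiling configuration
#'
#' A configuration is a plain list (or a JSON file holding one) with
#' fields: `trace` (analyte CSV path), `markers` (JSON path or list with
#' `name`, `reference_s`, `observed_s`), `ladder` (JSON path or list with
#' `gu`, `time_s`, on the aligned axis), `enzyme` (`"GH10"`/`"GH11"`),
#' `library` (TSV path or tibble; default the packaged library),
#' `tolerance_gu` (default 0.015), `min_snr` (default 5), `reference`
#' (default the enzyme's standard reference) and optional `out_dir`.
#'
#' @param config List or path to a JSON file.
#' @return Resolved configuration list.
#' @export
profile_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$trace)) abort("configuration error: no trace file given")
  if (is.character(config$trace) && !file.exists(config$trace)) {
    abort(sprintf("configuration error: trace file '%s' not found",
                  config$trace))
  }
  config$enzyme <- toupper(config$enzyme %||% "GH10")
  config$tolerance_gu <- config$tolerance_gu %||% 0.015
  config$min_snr <- config$min_snr %||% 5
  # the packaged library's lightest entries (GU 0.72, 0.80) migrate before
  # the first dextran rung, so calibration extrapolates by default
  config$extrapolate <- config$extrapolate %||% TRUE
  config$reference <- config$reference %||% default_reference(config$enzyme)
  config
}

.load_markers <- function(markers) {
  if (is.character(markers)) markers <- jsonlite::read_json(markers,
                                                            simplifyVector = TRUE)
  marker_set(markers$name, markers$reference_s, markers$observed_s)
}

.load_ladder <- function(ladder) {
  if (is.character(ladder)) ladder <- jsonlite::read_json(ladder,
                                                          simplifyVector = TRUE)
  dextran_ladder(ladder$time_s, ladder$gu)
}

.load_library <- function(library) {
  if (is.null(library)) return(gax_gu_library())
  if (is.character(library)) return(readr::read_tsv(library,
                                                    show_col_types = FALSE))
  library
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the profiling pipeline on one sample
#'
#' Executes align, detect, calibrate, annotate, normalise and frequency
#' stages; stage failures surface with the stage name. When the
#' configuration names `trace_high` (a higher-dilution replicate of the
#' same sample), both traces are processed and merged with
#' [merge_dilutions()].
#'
#' @param config See [profile_config()].
#' @return A `gax_profile`: list with `peaks` (annotated peak table),
#'   `normalized`, `frequency`, `enzyme`, `warnings` (unassigned /
#'   ambiguous area summary), `config_hash`.
#' @export
run_profile <- function(config) {
  config <- .stage("config", profile_config(config))
  markers <- .stage("align", .load_markers(config$markers))
  ladder <- .stage("calibrate", .load_ladder(config$ladder))
  library <- .stage("annotate", .load_library(config$library))

  process_one <- function(trace_path) {
    trace <- .stage("read", if (is.character(trace_path))
      read_trace_csv(trace_path) else trace_path)
    aligned <- .stage("align", align_trace(trace, markers))
    peaks <- .stage("detect", detect_peaks(aligned,
                                           min_snr = config$min_snr))
    peaks <- .stage("calibrate", gu_calibrate(peaks, ladder,
                                              extrapolate = config$extrapolate))
    .stage("annotate", annotate_peaks(peaks, library,
                                      tolerance_gu = config$tolerance_gu))
  }

  peaks <- process_one(config$trace)
  normalized <- .stage("normalize", suppressWarnings(
    normalize_areas(peaks, reference = config$reference,
                    enzyme = config$enzyme)))
  if (!is.null(config$trace_high)) {
    peaks_high <- process_one(config$trace_high)
    norm_high <- .stage("normalize", suppressWarnings(
      normalize_areas(peaks_high, reference = config$reference,
                      enzyme = config$enzyme)))
    normalized <- .stage("merge", merge_dilutions(
      list(high = norm_high, low = normalized),
      abundant = config$abundant %||% c("X", "XX")))
  }
  frequency <- .stage("quantify", substitution_frequency(normalized))

  excluded <- attr(normalized, "excluded")
  warnings <- tibble(
    n_peaks = nrow(peaks),
    n_assigned = sum(!is.na(peaks$assignment) & !peaks$ambiguous),
    n_ambiguous = sum(peaks$ambiguous),
    n_unassigned = sum(is.na(peaks$assignment)),
    unassigned_area = sum(excluded$area %||% 0)
  )
  report <- structure(list(
    peaks = peaks, normalized = normalized, frequency = frequency,
    enzyme = config$enzyme, warnings = warnings,
    config_hash = rlang::hash(config)
  ), class = "gax_profile")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(path) {
      readr::write_lines(sprintf("# config_hash: %s", report$config_hash),
                         path, append = TRUE)
      path
    }
    stamp(write_peak_tsv(peaks, file.path(config$out_dir, "peaks.tsv")))
    stamp(write_frequency_tsv(frequency,
                              file.path(config$out_dir, "frequency.tsv")))
  }
  report
}

#' @export
print.gax_profile <- function(x, ...) {
  cat(sprintf("<gax_profile> %s digest: %d peaks (%d assigned)\n",
              x$enzyme, x$warnings$n_peaks, x$warnings$n_assigned))
  print(x$frequency)
  invisible(x)
}

#' Compare substitution frequencies across replicate profiles
#'
#' @param reports List of [run_profile()] results (or `gax_freq` tables),
#'   optionally named by sample.
#' @return A `gax_comparison`: list with `matrix` (samples x classes
#'   tibble) and `summary` (per-class mean and sd across replicates).
#' @export
run_compare <- function(reports) {
  if (length(reports) < 1L) abort("need at least one report")
  freqs <- purrr::map(reports, function(r)
    if (inherits(r, "gax_profile")) r$frequency else r)
  classes <- purrr::map(freqs, function(f) sort(f$class))
  if (!all(vapply(classes, identical, logical(1), classes[[1]]))) {
    abort("reports do not share a common side-chain class set")
  }
  nm <- names(reports) %||% paste0("sample_", seq_along(reports))
  if (is.null(names(reports))) names(freqs) <- nm
  mat <- purrr::imap_dfr(freqs, function(f, id)
    dplyr::mutate(as_tibble(f)[c("class", "frequency_pct")], sample = id,
                  .before = 1))
  summary <- mat |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_pct = mean(.data$frequency_pct),
                     sd_pct = if (dplyr::n() > 1)
                       sd(.data$frequency_pct) else 0,
                     n = dplyr::n(), .groups = "drop")
  structure(list(matrix = mat, summary = summary),
            class = "gax_comparison")
}

#' @export
print.gax_comparison <- function(x, ...) {
  cat("<gax_comparison>\n")
  print(x$summary)
  invisible(x)
}
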