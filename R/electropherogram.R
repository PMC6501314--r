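## DASH electropherogram processing: mobility-marker alignment, peak
## detection and integration, dextran-ladder glucose-unit calibration, and
## annotation against the packaged GU library.

#' Electropherogram trace
#'
#' @param time_s Migration time (seconds), strictly increasing.
#' @param rfu Signal (relative fluorescence units).
#' @param channel Channel identifier.
#' @return Tibble of class `gax_trace` with columns `time_s`, `rfu`.
#' @export
gax_trace <- function(time_s, rfu, channel = "analyte") {
  if (length(time_s) != length(rfu)) abort("time and signal lengths differ")
  if (any(diff(time_s) <= 0)) abort("time must be strictly increasing")
  out <- tibble(time_s = as.numeric(time_s), rfu = as.numeric(rfu))
  attr(out, "channel") <- channel
  class(out) <- c("gax_trace", class(out))
  out
}

#' Read / write a trace CSV
#'
#' Two-column CSV with header `time_s, rfu` (one file per capillary).
#'
#' @param path File path.
#' @param trace A [gax_trace()].
#' @param channel Channel identifier to attach on read.
#' @export
read_trace_csv <- function(path, channel = "analyte") {
  x <- readr::read_csv(path, show_col_types = FALSE)
  gax_trace(x$time_s, x$rfu, channel = channel)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace[c("time_s", "rfu")], path)
  invisible(path)
}

# local maxima above a threshold, plateau-aware: a flat-topped peak (equal
# consecutive samples, common when an apex falls midway between samples)
# reports its plateau midpoint
local_maxima <- function(y, thr) {
  s <- sign(diff(y))
  idx <- which(s != 0)
  if (length(idx) < 2L) return(integer(0))
  a <- idx[-length(idx)]
  b <- idx[-1]
  pk <- which(s[a] > 0 & s[b] < 0)
  apex <- (a[pk] + 1L + b[pk]) %/% 2L
  apex[y[apex] > thr]
}

# piecewise-linear map through (x, y) nodes with linear extrapolation using
# the terminal segment slopes
piecewise_linear <- function(x, y) {
  force(x); force(y)
  n <- length(x)
  function(t) {
    out <- approx(x, y, xout = t, rule = 2)$y
    lo <- t < x[1]; hi <- t > x[n]
    if (any(lo)) {
      sl <- (y[2] - y[1]) / (x[2] - x[1])
      out[lo] <- y[1] + sl * (t[lo] - x[1])
    }
    if (any(hi)) {
      sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      out[hi] <- y[n] + sl * (t[hi] - x[n])
    }
    out
  }
}

#' Mobility marker set
#'
#' Internal electrophoretic mobility standards mixed into each sample; their
#' observed migration times are mapped onto fixed reference positions to
#' remove capillary-to-capillary variation.
#'
#' @param name Marker names.
#' @param reference_s Canonical positions (seconds), strictly increasing.
#' @param observed_s Observed times in the trace being aligned.
#' @return Tibble of class `gax_markers`.
#' @export
marker_set <- function(name, reference_s, observed_s) {
  if (length(reference_s) < 2L) abort("alignment needs at least 2 markers")
  if (any(diff(reference_s) <= 0)) {
    abort("marker reference positions must be strictly increasing")
  }
  if (any(diff(observed_s) <= 0)) {
    abort("observed marker times must be strictly increasing in reference order")
  }
  out <- tibble(name = name, reference_s = reference_s,
                observed_s = observed_s)
  class(out) <- c("gax_markers", class(out))
  out
}

#' Align a trace to the canonical time axis
#'
#' Piecewise-linear time warp carrying each observed marker time onto its
#' reference position, with linear extrapolation beyond the terminal
#' markers. Signal values are untouched.
#'
#' @param trace A [gax_trace()].
#' @param markers A [marker_set()].
#' @return The aligned trace.
#' @export
align_trace <- function(trace, markers) {
  if (!inherits(markers, "gax_markers")) {
    markers <- marker_set(markers$name, markers$reference_s,
                          markers$observed_s)
  }
  warp <- piecewise_linear(markers$observed_s, markers$reference_s)
  out <- gax_trace(warp(trace$time_s), trace$rfu,
                   channel = attr(trace, "channel"))
  attr(out, "aligned") <- TRUE
  out
}

#' Detect and integrate peaks
#'
#' Local maxima of the baseline-subtracted signal above `min_snr` times a
#' robust noise estimate. The baseline is a running median of width
#' `baseline_window_s`; noise is estimated as the scaled median absolute
#' deviation (1.4826 x MAD) of the detrended signal. Peak areas are
#' trapezoidal integrals of the detrended signal between the flanking local
#' minima; apex times are refined by parabolic interpolation through the
#' three samples around each maximum.
#'
#' @param trace An aligned [gax_trace()] with >= 100 samples.
#' @param min_snr Detection threshold in noise units (default 5).
#' @param baseline_window_s Running-median window (seconds; default 121).
#' @return Tibble of class `gax_peaks`: `apex_time_s`, `height`, `area`,
#'   `snr`.
#' @export
detect_peaks <- function(trace, min_snr = 5, baseline_window_s = 121) {
  n <- nrow(trace)
  if (n < 100L) abort("trace too short for processing (< 100 samples)")
  dt <- median(diff(trace$time_s))
  k <- max(3L, round(baseline_window_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  baseline <- as.numeric(runmed(trace$rfu, k, endrule = "median"))
  detr <- as.vector(trace$rfu - baseline)
  noise <- mad(detr)
  thr <- if (noise > 0) min_snr * noise else
    max(.Machine$double.eps, 1e-9 * max(abs(detr), 1))
  apex <- local_maxima(detr, thr)
  if (length(apex) == 0L) {
    out <- tibble(apex_time_s = double(), height = double(),
                  area = double(), snr = double())
    class(out) <- c("gax_peaks", class(out))
    return(out)
  }
  # flanking local minima of the detrended signal
  d <- diff(detr)
  minima <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
  minima <- sort(unique(c(1L, minima, n)))
  lb <- vapply(apex, function(i) max(minima[minima < i]), double(1))
  rb <- vapply(apex, function(i) min(minima[minima > i]), double(1))
  area <- mapply(function(a, b)
    pracma::trapz(trace$time_s[a:b], detr[a:b]), lb, rb)
  # parabolic apex refinement
  apex_t <- vapply(seq_along(apex), function(j) {
    i <- apex[j]
    if (i <= 1L || i >= n) return(trace$time_s[i])
    y0 <- detr[i - 1]; y1 <- detr[i]; y2 <- detr[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(trace$time_s[i])
    trace$time_s[i] + 0.5 * (y0 - y2) / den * dt
  }, double(1))
  out <- tibble(apex_time_s = apex_t, height = detr[apex], area = area,
                snr = detr[apex] / max(noise, .Machine$double.eps)) |>
    dplyr::arrange(.data$apex_time_s)
  class(out) <- c("gax_peaks", class(out))
  out
}

#' Dextran ladder
#'
#' Glucose-oligomer ladder peaks defining the glucose-unit (GU) axis:
#' ladder peak i migrates at `time_s[i]` and is assigned integer GU
#' `gu[i]`.
#'
#' @param time_s Ladder peak times (aligned axis), strictly increasing.
#' @param gu Integer GU values (default `1:length(time_s)`).
#' @return Tibble of class `gax_ladder`.
#' @export
dextran_ladder <- function(time_s, gu = seq_along(time_s)) {
  if (length(time_s) < 6L) abort("ladder needs at least 6 rungs")
  if (any(diff(time_s) <= 0)) abort("ladder times must increase with GU")
  out <- tibble(gu = as.numeric(gu), time_s = as.numeric(time_s))
  class(out) <- c("gax_ladder", class(out))
  out
}

#' Calibrate peak migration to glucose units
#'
#' Monotone piecewise-linear interpolation of the ladder (time -> GU);
#' ladder nodes map to their integer GU exactly. Peaks outside the ladder
#' span are flagged and left uncalibrated unless `extrapolate = TRUE`.
#'
#' @param peaks A [detect_peaks()] table.
#' @param ladder A [dextran_ladder()].
#' @param extrapolate Allow linear extrapolation beyond the terminal rungs.
#' @return `peaks` with columns `gu` and `out_of_range` added.
#' @export
gu_calibrate <- function(peaks, ladder, extrapolate = FALSE) {
  f <- piecewise_linear(ladder$time_s, ladder$gu)
  gu <- f(peaks$apex_time_s)
  oor <- peaks$apex_time_s < min(ladder$time_s) |
    peaks$apex_time_s > max(ladder$time_s)
  if (!extrapolate) gu[oor] <- NA_real_
  peaks$gu <- gu
  peaks$out_of_range <- oor
  peaks
}

#' Annotate calibrated peaks against a GU library
#'
#' Assigns each peak the nearest library entry within `tolerance_gu`. When
#' two or more entries fall inside the tolerance the peak is flagged
#' ambiguous and all candidate names are reported (`;`-separated), rather
#' than silently resolving the tie.
#'
#' @param peaks Calibrated peaks (with `gu`).
#' @param library A GU library tibble with `faure_name` and `gu` columns
#'   (default the packaged library, [gax_gu_library()]).
#' @param tolerance_gu Assignment tolerance in GU. The default 0.015 is half
#'   the tightest spacing in the packaged library (0.03 GU), so true
#'   co-migration ambiguity is reported instead of mis-assigned.
#' @return `peaks` with `assignment` (name or `NA`), `ambiguous` (logical)
#'   and `n_candidates` columns.
#' @export
annotate_peaks <- function(peaks, library = gax_gu_library(),
                           tolerance_gu = 0.015) {
  assignment <- rep(NA_character_, nrow(peaks))
  ambiguous <- rep(FALSE, nrow(peaks))
  ncand <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- peaks$gu[i]
    if (is.na(g)) next
    d <- abs(library$gu - g)
    hit <- which(d <= tolerance_gu)
    ncand[i] <- length(hit)
    if (length(hit) == 1L) {
      assignment[i] <- library$faure_name[hit]
    } else if (length(hit) > 1L) {
      assignment[i] <- paste(library$faure_name[hit[order(d[hit])]],
                             collapse = ";")
      ambiguous[i] <- TRUE
    }
  }
  peaks$assignment <- assignment
  peaks$ambiguous <- ambiguous
  peaks$n_candidates <- ncand
  peaks
}

#' Packaged GU mobility library
#'
#' The reference library of GAX oligosaccharide structures with their DASH
#' migration positions in glucose units, joined with the enzymatic
#' reference table ([enzyme_reference()]). The `B^2,3U^(4Me)2XX` /
#' `D^2,3U^(4Me)2XX` entry could not be distinguished structurally; it is
#' carried as one entry whose `faure_name` is the D-type candidate with the
#' B-type alternative in `alt_name`.
#'
#' @param full If `TRUE` (default) join the enzyme columns.
#' @return Tibble, one row per library entry, ordered by GU.
#' @export
gax_gu_library <- function(full = TRUE) {
  lib <- readr::read_tsv(system.file("extdata", "gu_library.tsv",
                                     package = "gaxr"),
                         show_col_types = FALSE)
  if (full) {
    lib <- dplyr::left_join(lib, enzyme_reference(), by = "faure_name")
  }
  dplyr::arrange(lib, .data$gu)
}

#' Write an annotated peak table
#'
#' @param peaks Annotated, calibrated peaks.
#' @param path Output TSV path.
#' @export
write_peak_tsv <- function(peaks, path) {
  readr::write_tsv(
    dplyr::select(peaks, dplyr::any_of(c("apex_time_s", "area", "gu",
                                         "assignment", "ambiguous"))), path)
  invisible(path)
}
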