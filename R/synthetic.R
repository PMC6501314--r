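## Synthetic-data generation: substituted xylan polymers with known ground
## truth, digest abundance tables, DASH-style electropherograms with marker
## and ladder channels, and CID fragment spectra.

#' Polymer generation model
#'
#' Independent per-residue substitution draws: each backbone Xylp carries at
#' most one side chain, drawn with the given per-class probabilities
#' (remaining mass = unsubstituted).
#'
#' @param length Backbone residues (>= 10).
#' @param p_araf,p_glca,p_meglca,p_d,p_b Per-residue probabilities of a
#'   single `A^3` Araf, unmethylated `U^2` GlcA, `U^(4Me)2` MeGlcA,
#'   `D^2,3` and `B^2,3` chain.
#' @param seed Integer seed making the draw reproducible.
#' @return A `polymer_model` object.
#' @export
polymer_model <- function(length, p_araf = 0, p_glca = 0, p_meglca = 0,
                          p_d = 0, p_b = 0, seed = 1L) {
  p <- c(p_araf, p_glca, p_meglca, p_d, p_b)
  if (any(p < 0) || sum(p) > 1) {
    abort("substitution probabilities must be >= 0 and sum to <= 1")
  }
  if (length < 10L) abort("polymer length must be >= 10")
  structure(list(length = as.integer(length), p_araf = p_araf,
                 p_glca = p_glca, p_meglca = p_meglca, p_d = p_d, p_b = p_b,
                 seed = as.integer(seed)),
            class = "polymer_model")
}

#' Tissue presets for polymer generation
#'
#' Named parameter bundles encoding the substitution frequencies reported
#' for vegetative grass tissues, used as round-trip fixtures (the generating
#' probabilities are the reported frequencies, so recovering them validates
#' the pipeline's bookkeeping, not the biology): miscanthus leaf and stem
#' (arabinosylation 10-12%, glucuronidation 3-6% mostly methylated, with the
#' disaccharide D^2,3 chain at 1.3% in leaf vs 0.2% in stem), rice stem
#' (largely unmethylated GlcA, leaf-like D^2,3 abundance) and a generic
#' grass midpoint. Each preset also names the digest enzyme it emulates
#' (GH10 throughout).
#'
#' @param name One of `"miscanthus-leaf"`, `"miscanthus-stem"`,
#'   `"rice-stem"`, `"generic-grass"`.
#' @param length Backbone residues.
#' @param seed Integer seed.
#' @return List: `model` (a [polymer_model()]) and `enzyme`.
#' @export
gax_preset <- function(name, length = 200000L, seed = 1L) {
  pars <- switch(name,
    "miscanthus-leaf" = list(p_araf = 0.10, p_glca = 0.005,
                             p_meglca = 0.030, p_d = 0.013),
    "miscanthus-stem" = list(p_araf = 0.12, p_glca = 0.005,
                             p_meglca = 0.055, p_d = 0.002),
    "rice-stem" = list(p_araf = 0.11, p_glca = 0.040, p_meglca = 0.005,
                       p_d = 0.010),
    "generic-grass" = list(p_araf = 0.11, p_glca = 0.010, p_meglca = 0.030,
                           p_d = 0.007),
    abort(sprintf("unknown preset '%s'", name))
  )
  list(model = polymer_model(length, p_araf = pars$p_araf,
                             p_glca = pars$p_glca, p_meglca = pars$p_meglca,
                             p_d = pars$p_d, seed = seed),
       enzyme = "GH10", name = name)
}

#' Simulate a substituted xylan polymer
#'
#' @param model A [polymer_model()].
#' @return A [xylan_polymer()] with a `model` attribute.
#' @export
simulate_polymer <- function(model) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(model$seed)
    expr
  }
  sub <- withr_seed(
    sample(c(0L, 1L, 3L, 5L, 7L, 8L), model$length, replace = TRUE,
           prob = c(1 - (model$p_araf + model$p_glca + model$p_meglca +
                           model$p_d + model$p_b),
                    model$p_araf, model$p_glca, model$p_meglca, model$p_d,
                    model$p_b))
  )
  out <- xylan_polymer(sub)
  attr(out, "model") <- model
  out
}

#' Simulate a complete digest abundance table
#'
#' Simulates a polymer, digests it to completion and returns the molar
#' abundance table with the realised (counted on the simulated polymer) and
#' generating class frequencies attached as the `truth` attribute.
#'
#' @param model A [polymer_model()] or preset name (see [gax_preset()]).
#' @param rule An [endo_rule()] (defaults to the preset's enzyme, else
#'   GH10).
#' @param length,seed Used only when `model` is a preset name.
#' @return A `gax_digest` tibble (`faure_name`, `dp`, `count`) with `truth`
#'   attribute: tibble `class`, `generating_pct`, `realized_pct`.
#' @export
simulate_digest_profile <- function(model, rule = NULL, length = 200000L,
                                    seed = 1L) {
  if (is.character(model)) {
    preset <- gax_preset(model, length = length, seed = seed)
    model <- preset$model
    rule <- rule %||% switch(preset$enzyme, GH10 = gh10_rule(),
                             GH11 = gh11_rule())
  }
  rule <- rule %||% gh10_rule()
  polymer <- simulate_polymer(model)
  digest <- digest_complete(polymer, rule)
  cl <- chain_lookup()
  s <- polymer$sub[polymer$sub > 0L]
  kinds <- cl$kind[s]
  n <- dp(polymer)
  realized <- c(sum(kinds == "Araf"), sum(kinds %in% c("GlcA", "MeGlcA")),
                sum(kinds %in% c("D", "B"))) / n
  generating <- c(model$p_araf, model$p_glca + model$p_meglca,
                  model$p_d + model$p_b)
  attr(digest, "truth") <- tibble(
    class = substitution_classes(),
    generating_pct = 100 * generating,
    realized_pct = 100 * realized
  )
  attr(digest, "model") <- model
  digest
}

#' Trace synthesis configuration
#'
#' The migration-time axis is a fixed monotone quadratic
#' `t(GU) = 2000 + 600 GU - 10 GU^2` seconds (monotone for GU < 30); the
#' ladder spans integer GU 1..12 and seven mobility markers sit evenly
#' spaced across the run. Analyte peaks are Gaussians of width
#' `peak_sd_s` whose areas are proportional to molar abundance
#' (`area_per_unit` RFU.s per molar count); Gaussian noise of sd `noise_sd`
#' is added and the signal is clipped at `saturation`.
#'
#' @param mapping Function GU -> seconds (strictly increasing over the
#'   simulated range).
#' @param peak_sd_s Gaussian peak sd (seconds).
#' @param noise_sd Additive noise sd (RFU).
#' @param dt_s Sampling interval (seconds).
#' @param area_per_unit Peak area per molar abundance unit (RFU.s).
#' @param saturation Detector ceiling (RFU).
#' @param ladder_gu Integer GU values of the dextran ladder rungs.
#' @param n_markers Number of mobility markers.
#' @param seed Integer seed for the noise and decoy draws.
#' @return A `trace_config` list.
#' @export
trace_config <- function(mapping = function(gu) 2000 + 600 * gu - 10 * gu^2,
                         peak_sd_s = 2, noise_sd = 0, dt_s = 0.5,
                         area_per_unit = 1, saturation = 64000,
                         ladder_gu = 1:12, n_markers = 7L, seed = 1L) {
  if (peak_sd_s <= 0) abort("peak width must be > 0")
  structure(list(mapping = mapping, peak_sd_s = peak_sd_s,
                 noise_sd = noise_sd, dt_s = dt_s,
                 area_per_unit = area_per_unit, saturation = saturation,
                 ladder_gu = ladder_gu, n_markers = as.integer(n_markers),
                 seed = as.integer(seed)),
            class = "trace_config")
}

# deterministic synthetic GU positions for digest products absent from the
# library: evenly spread over [6, 11.8] (inside the default ladder span so
# calibration never extrapolates), spacing capped at 0.12 GU and never below
# 0.04 GU so default annotation stays unambiguous; a name-keyed jitter keeps
# the assignment stable under insertions
synthetic_gu_positions <- function(names) {
  names <- sort(unique(names))
  n <- length(names)
  if (n == 0L) return(tibble(faure_name = character(), gu = double()))
  spacing <- max(0.04, min(0.12, 5.8 / n))
  jitter <- vapply(names, function(nm)
    (sum(utf8ToInt(nm) * seq_along(utf8ToInt(nm))) %% 97) / 97, double(1))
  tibble(faure_name = names,
         gu = 6 + spacing * (seq_len(n) - 1L) + 0.25 * spacing * jitter,
         synthetic = TRUE)
}

#' Synthesize a DASH experiment from a digest abundance table
#'
#' Emits three channels on a shared time axis: the analyte trace (one
#' Gaussian per product at the migration time of its library GU), the
#' dextran-ladder channel and the mobility-marker channel. Products absent
#' from `library` are placed at deterministic synthetic GU positions >= 6
#' (spaced widely enough to stay unambiguous) and reported in the returned
#' `extended_library` with `synthetic = TRUE`, so processing can either
#' annotate against the extended library (full recovery) or against the
#' packaged one (exercising the unassigned path).
#'
#' @param abundances Tibble `faure_name`, `count` (e.g. a
#'   [simulate_digest_profile()] result).
#' @param library GU library used for peak placement.
#' @param config A [trace_config()].
#' @return List of class `gax_synth_experiment`: `analyte`,
#'   `ladder_channel`, `marker_channel` ([gax_trace()]s), `markers`
#'   ([marker_set()]), `ladder` ([dextran_ladder()], true times),
#'   `extended_library`, `truth` (abundances with placement GU).
#' @export
synthesize_trace <- function(abundances, library = gax_gu_library(),
                             config = trace_config()) {
  placed <- dplyr::left_join(
    as_tibble(abundances)[c("faure_name", "count")],
    library[c("faure_name", "gu")], by = "faure_name")
  unknown <- synthetic_gu_positions(placed$faure_name[is.na(placed$gu)])
  if (nrow(unknown) > 0L) {
    placed$gu[is.na(placed$gu)] <-
      unknown$gu[match(placed$faure_name[is.na(placed$gu)],
                       unknown$faure_name)]
  }
  gmax <- max(c(config$ladder_gu, placed$gu, 0))
  tt <- config$mapping(seq(0, gmax + 0.5, by = 0.01))
  if (any(diff(tt) <= 0)) {
    abort("time mapping must be strictly increasing over the simulated GU range")
  }
  t0 <- config$mapping(0) - 120
  t1 <- config$mapping(gmax + 0.5) + 120
  grid <- seq(t0, t1, by = config$dt_s)
  sd <- config$peak_sd_s

  gaussians <- function(times, areas) {
    y <- numeric(length(grid))
    for (i in seq_along(times)) {
      lo <- max(1L, floor((times[i] - 6 * sd - t0) / config$dt_s) + 1L)
      hi <- min(length(grid), ceiling((times[i] + 6 * sd - t0) /
                                        config$dt_s) + 1L)
      w <- lo:hi
      y[w] <- y[w] + areas[i] / (sd * sqrt(2 * pi)) *
        exp(-0.5 * ((grid[w] - times[i]) / sd)^2)
    }
    y
  }

  analyte_t <- config$mapping(placed$gu)
  y_analyte <- gaussians(analyte_t, placed$count * config$area_per_unit)
  ladder_t <- config$mapping(config$ladder_gu)
  y_ladder <- gaussians(ladder_t, rep(1000, length(ladder_t)))
  marker_t <- seq(t0 + 150, t1 - 150, length.out = config$n_markers)
  y_marker <- gaussians(marker_t, rep(1000, config$n_markers))

  if (config$noise_sd > 0) {
    set.seed(config$seed)
    y_analyte <- y_analyte + rnorm(length(grid), 0, config$noise_sd)
    y_ladder <- y_ladder + rnorm(length(grid), 0, config$noise_sd)
    y_marker <- y_marker + rnorm(length(grid), 0, config$noise_sd)
  }
  clip <- function(y) pmin(y, config$saturation)

  ext <- dplyr::bind_rows(
    dplyr::mutate(library[c("faure_name", "gu")], synthetic = FALSE),
    unknown)
  structure(list(
    analyte = gax_trace(grid, clip(y_analyte), channel = "analyte"),
    ladder_channel = gax_trace(grid, clip(y_ladder), channel = "ladder"),
    marker_channel = gax_trace(grid, clip(y_marker), channel = "marker"),
    markers = marker_set(sprintf("M%d", seq_len(config$n_markers)),
                         marker_t, marker_t),
    ladder = dextran_ladder(ladder_t, config$ladder_gu),
    extended_library = ext,
    truth = dplyr::mutate(placed, time_s = analyte_t),
    config = config
  ), class = "gax_synth_experiment")
}

#' Synthesize a CID fragment spectrum
#'
#' Predicted fragment m/z values of a labelled structure with random
#' intensities, plus optional decoy noise peaks kept at least 2 Da away
#' from any true ion.
#'
#' @param struct `xylan_oligo` or Faure name (labelled for MS).
#' @param n_decoys Number of decoy peaks.
#' @param seed Integer seed.
#' @param masses A [mass_table()].
#' @return A [spectrum_peaks()] table with the precursor attribute set.
#' @export
synthesize_spectrum <- function(struct, n_decoys = 0L, seed = 1L,
                                masses = mass_table()) {
  if (is.character(struct)) struct <- parse_faure(struct, label = "2-AA")
  pred <- predict_fragments(struct, masses = masses)
  mzs <- sort(unique(round(pred$mz, 4)))
  set.seed(seed)
  ints <- runif(length(mzs), 50, 1000)
  if (n_decoys > 0L) {
    lo <- max(100, min(mzs) - 100); hi <- max(mzs) + 100
    dec <- numeric(0)
    while (length(dec) < n_decoys) {
      cand <- runif(2L * n_decoys, lo, hi)
      cand <- cand[vapply(cand, function(m) all(abs(m - c(mzs, dec)) > 2),
                          logical(1))]
      dec <- c(dec, cand)
    }
    dec <- dec[seq_len(n_decoys)]
    mzs <- c(mzs, dec)
    ints <- c(ints, runif(length(dec), 10, 100))
  }
  spectrum_peaks(mzs, ints, precursor_mz = precursor_mz(struct,
                                                        masses = masses))
}

#' Materialise a synthetic experiment directory
#'
#' Writes the CSV/JSON/TSV files a [run_profile()] configuration consumes:
#' per-channel trace CSVs, marker and ladder JSON definitions, the extended
#' GU library TSV and the ground-truth table.
#'
#' @param experiment A [synthesize_trace()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trace_csv(experiment$analyte, file.path(dir, "analyte.csv"))
  write_trace_csv(experiment$ladder_channel, file.path(dir, "ladder.csv"))
  write_trace_csv(experiment$marker_channel, file.path(dir, "marker.csv"))
  jsonlite::write_json(list(
    name = experiment$markers$name,
    reference_s = experiment$markers$reference_s,
    observed_s = experiment$markers$observed_s),
    file.path(dir, "markers.json"), digits = NA)
  jsonlite::write_json(list(gu = experiment$ladder$gu,
                            time_s = experiment$ladder$time_s),
                       file.path(dir, "ladder.json"), digits = NA)
  readr::write_tsv(experiment$extended_library,
                   file.path(dir, "library.tsv"))
  readr::write_tsv(experiment$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
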