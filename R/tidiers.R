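## broom-style accessors.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a spectrum annotation
#'
#' @param x A [annotate_spectrum()] result.
#' @param ... Unused.
#' @return The match table, one row per matched observed peak.
#' @exportS3Method generics::tidy
tidy.gax_annotation <- function(x, ...) x$matches

#' @rdname tidy.gax_annotation
#' @exportS3Method generics::glance
glance.gax_annotation <- function(x, ...) {
  tibble(candidate = to_faure(x$struct),
         n_matched = nrow(x$matches),
         n_observed = nrow(x$matches) + nrow(x$unmatched),
         observed_coverage = x$observed_coverage,
         coverage = x$coverage,
         n_predicted = x$n_predicted)
}

#' Tidy a profile report
#'
#' @param x A [run_profile()] result.
#' @param ... Unused.
#' @return `tidy()`: the frequency table; `glance()`: one-row summary.
#' @exportS3Method generics::tidy
tidy.gax_profile <- function(x, ...) as_tibble(x$frequency)

#' @rdname tidy.gax_profile
#' @exportS3Method generics::glance
glance.gax_profile <- function(x, ...) {
  dplyr::bind_cols(tibble(enzyme = x$enzyme), x$warnings,
                   tibble(config_hash = x$config_hash))
}

#' Tidy a replicate comparison
#'
#' @param x A [run_compare()] result.
#' @param ... Unused.
#' @return `tidy()`: the long samples x classes table; `glance()`: the
#'   per-class mean/sd summary.
#' @exportS3Method generics::tidy
tidy.gax_comparison <- function(x, ...) x$matrix

#' @rdname tidy.gax_comparison
#' @exportS3Method generics::glance
glance.gax_comparison <- function(x, ...) x$summary
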