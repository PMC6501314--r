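#' Packaged CID ion ledgers
#'
#' The published high-energy MALDI-CID ion assignments for the library
#' oligosaccharides (unknowns N1-N12 from the miscanthus GH10/GH11 digests,
#' M1/M2 from leaf material): observed m/z values with their reported ion
#' labels. Used as annotation fixtures; ion labels follow the source
#' spectra's subscript conventions, which for side-chain cleavages differ
#' from this package's backbone indexing.
#'
#' @return Tibble: `unknown_id`, `faure_name`, `ion`, `mz`.
#' @export
cid_ledgers <- function() {
  readr::read_tsv(system.file("extdata", "cid_ledgers.tsv",
                              package = "gaxr"),
                  show_col_types = FALSE)
}
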