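## Structure model and Faure-nomenclature parser/serializer for
## (glucurono)arabinoxylan oligosaccharides and polymers.
##
## A structure is a backbone of beta-1,4-linked Xylp residues, position 1 at
## the non-reducing end, each position carrying at most one typed side chain
## (integer code, see chain_codes()). Faure names read non-reducing ->
## reducing end, one token per backbone residue: X, A^p, U^p, U^(4Me)p with
## p in {2,3}, and the disaccharide chains D^2,3 / B^2,3.

#' Construct a xylan oligosaccharide
#'
#' Low-level constructor for the structure object used throughout gaxr.
#' `sub` holds one integer per backbone Xylp residue (position 1 =
#' non-reducing end): 0 for unsubstituted, otherwise a side-chain code from
#' [chain_codes()].
#'
#' @param sub Integer vector of side-chain codes, one per backbone residue.
#' @param label Reducing-end label: `"none"`, `"2-AA"` (mass spectrometry) or
#'   `"APTS"` (electrophoresis).
#' @param allow_disubstitution Unused by the default single-chain encoding;
#'   kept so stricter front ends (e.g. cereal-grain arabinoxylan with
#'   di-substituted residues) can relax validation in future encodings.
#' @return An object of class `xylan_oligo`.
#' @seealso [parse_faure()], [to_faure()], [oligo_composition()]
#' @export
xylan_oligo <- function(sub, label = "none", allow_disubstitution = FALSE) {
  sub <- as.integer(sub)
  if (length(sub) < 1L) abort("a xylan oligosaccharide needs DP >= 1")
  if (anyNA(sub) || any(sub < 0L) || any(sub > 8L)) {
    abort("side-chain codes must be integers in 0..8")
  }
  if (!label %in% c("none", "2-AA", "APTS")) {
    abort('label must be one of "none", "2-AA", "APTS"')
  }
  structure(list(sub = sub, label = label), class = "xylan_oligo")
}

#' Construct a xylan polymer
#'
#' Same encoding as [xylan_oligo()] but unlabelled and typically long; used
#' as the substrate for in-silico digestion.
#'
#' @inheritParams xylan_oligo
#' @return An object of class `c("xylan_polymer", "xylan_oligo")`.
#' @export
xylan_polymer <- function(sub) {
  x <- xylan_oligo(sub, label = "none")
  class(x) <- c("xylan_polymer", class(x))
  x
}

#' @export
print.xylan_oligo <- function(x, ...) {
  nm <- if (dp(x) <= 40) to_faure(x) else
    paste0(to_faure(xylan_oligo(x$sub[1:40])), "... (truncated)")
  cat(sprintf("<xylan_oligo> DP %d, label %s\n  %s\n", dp(x), x$label, nm))
  invisible(x)
}

#' Degree of polymerisation
#'
#' Number of backbone Xylp residues (side-chain residues not counted).
#'
#' @param struct A `xylan_oligo`.
#' @return Integer DP.
#' @export
dp <- function(struct) length(struct$sub)

#' Side chains of a structure
#'
#' @param struct A `xylan_oligo`.
#' @return Tibble with one row per side chain: backbone `position`, `code`,
#'   `kind`, attachment `o_pos` and residue counts.
#' @export
side_chains <- function(struct) {
  idx <- which(struct$sub > 0L)
  cc <- chain_codes()
  out <- cc[match(struct$sub[idx], cc$code), ]
  dplyr::bind_cols(tibble(position = idx), out)
}

faure_token_rx <- function() {
  # longest-first alternation so U^(4Me)2 wins over U^2 etc.
  "^(U\\^\\(4Me\\)[23]|[DB]\\^2,3|A\\^[23]|U\\^[23]|X)"
}

#' Parse a Faure nomenclature name
#'
#' Reads a heteroxylan one-letter name (e.g. `"XA^3XX"`, `"U^(4Me)2X"`,
#' `"D^2,3X"`) into a structure object. Tokens are read from the
#' non-reducing end; each token contributes one backbone Xylp, with the
#' superscript giving the attachment O-position of the side chain. The
#' disaccharide chains `D^2,3` (beta-Xylp-(1->2)-alpha-Araf-(1->3)) and
#' `B^2,3` (Araf-(1->2)-alpha-Araf-(1->3)) always attach at O-3.
#'
#' @param name A single Faure name.
#' @param label Reducing-end label to attach (`"none"`, `"2-AA"`, `"APTS"`).
#' @return A [xylan_oligo()].
#' @examples
#' parse_faure("XA^3XX")
#' to_faure(parse_faure("D^2,3X"))
#' @export
parse_faure <- function(name, label = "none") {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name)) {
    abort("parse error: name must be a non-empty string")
  }
  cc <- chain_codes()
  rest <- name
  pos <- 1L
  codes <- integer(0)
  rx <- faure_token_rx()
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr(rx, rest, perl = TRUE))
    if (length(m) == 0L) {
      bad <- substr(rest, 1L, 10L)
      abort(sprintf(
        "parse error: unrecognised token starting at '%s' (character %d of '%s')",
        bad, pos, name))
    }
    codes <- c(codes, if (m == "X") 0L else cc$code[match(m, cc$token)])
    pos <- pos + nchar(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  xylan_oligo(codes, label = label)
}

#' Serialize a structure to its Faure name
#'
#' Inverse of [parse_faure()]: `parse_faure(to_faure(s))` recovers `s`.
#'
#' @param struct A `xylan_oligo`.
#' @return A single string.
#' @export
to_faure <- function(struct) {
  stopifnot(inherits(struct, "xylan_oligo"))
  cl <- chain_lookup()
  tok <- ifelse(struct$sub == 0L, "X", cl$token[pmax(struct$sub, 1L)])
  paste(tok, collapse = "")
}

# vectorised faure naming for integer-coded fragments: `sub` codes and a
# grouping factor; returns one name per group, in group order.
faure_names_grouped <- function(sub, group) {
  cl <- chain_lookup()
  tok <- ifelse(sub == 0L, "X", cl$token[pmax(sub, 1L)])
  unname(vapply(split(tok, group), paste, collapse = "",
                FUN.VALUE = character(1)))
}

#' Residue composition of a structure
#'
#' Counts residues by class: pentoses (backbone Xylp, Araf, and the Xylp of
#' D-type chains), hexuronates (GlcA) and 4-O-methyl hexuronates (MeGlcA).
#' A Pent_n assignment from a sodiated precursor mass corresponds to
#' `pentose == n`.
#'
#' @param struct A `xylan_oligo`, or a character Faure name.
#' @return One-row tibble: `pentose`, `hexuronic`, `methyl_hexuronic`.
#' @examples
#' oligo_composition("A^3X")      # Pent_3
#' oligo_composition("U^(4Me)2X") # Pent_2 + 1 MeGlcA
#' @export
oligo_composition <- function(struct) {
  if (is.character(struct)) struct <- parse_faure(struct)
  cl <- chain_lookup()
  s <- struct$sub[struct$sub > 0L]
  tibble(
    pentose = length(struct$sub) + sum(cl$pentose[s]),
    hexuronic = sum(cl$hexuronic[s]),
    methyl_hexuronic = sum(cl$methyl_hexuronic[s])
  )
}

#' Side-chain class counts used in quantitation
#'
#' Counts backbone Xylp residues and side chains by quantitation class:
#' single `Araf` chains, `[Me]GlcA` (methylated and unmethylated uronates
#' together) and the disaccharide `D^2,3` class (D- and B-type chains). The
#' Xylp of a D chain counts toward the side chain, never the backbone.
#'
#' @param names Character vector of Faure names.
#' @return Tibble with one row per name: `faure_name`, `n_xyl`, `n_araf`,
#'   `n_uronic`, `n_d`.
#' @export
oligo_class_counts <- function(names) {
  cl <- chain_lookup()
  one <- function(nm) {
    s <- parse_faure(nm)$sub
    ch <- s[s > 0L]
    kinds <- cl$kind[ch]
    c(n_xyl = length(s),
      n_araf = sum(kinds == "Araf"),
      n_uronic = sum(kinds %in% c("GlcA", "MeGlcA")),
      n_d = sum(kinds %in% c("D", "B")))
  }
  uniq <- unique(names)
  m <- t(vapply(uniq, one, FUN.VALUE = c(n_xyl = 0, n_araf = 0,
                                         n_uronic = 0, n_d = 0)))
  out <- as_tibble(m[match(names, uniq), , drop = FALSE])
  dplyr::bind_cols(tibble(faure_name = names), out)
}

#' Read / write Faure name tables
#'
#' Bulk I/O for structure lists as TSV with columns `name` and an optional
#' free-text `description`.
#'
#' @param path File path.
#' @param x Tibble with at least a `name` column.
#' @return `read_faure_tsv()` returns a tibble with the file's columns plus
#'   parse-derived `dp` and composition counts.
#' @export
read_faure_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"name" %in% names(x)) abort("faure TSV needs a 'name' column")
  comp <- purrr::map_dfr(x$name, oligo_composition)
  dplyr::bind_cols(x, tibble(dp = vapply(x$name, function(n)
    dp(parse_faure(n)), integer(1), USE.NAMES = FALSE)), comp)
}

#' @rdname read_faure_tsv
#' @export
write_faure_tsv <- function(x, path) {
  readr::write_tsv(dplyr::select(x, dplyr::any_of(c("name", "description"))),
                   path)
  invisible(path)
}
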