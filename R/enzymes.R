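## Rule-based in-silico digestion of (glucurono)arabinoxylan.
##
## Endo-xylanase specificity is modelled through subsite constraints: for a
## scissile backbone bond, subsite -1 is the residue on its non-reducing
## side (which donates the product's new reducing end) and +1 the residue on
## its reducing side; a side chain sitting in a blocked subsite makes the
## bond non-cleavable. GH10 tolerates substituents closer to the cleavage
## site than GH11, which prefers unsubstituted stretches.

#' Endo-xylanase cleavage rule
#'
#' @param name Rule name, e.g. `"GH10"`.
#' @param blocked_subsites Named list: side-chain kind (`Araf`, `GlcA`,
#'   `MeGlcA`, `D`, `B`) -> integer subsites from `{-2, -1, 1, 2}` that the
#'   substituent blocks. Subsite `-1` must be blocked for every kind (an
#'   endo-xylanase cannot form a product whose new reducing end is
#'   substituted at the catalytic site).
#' @param min_product_dp Smallest product DP the enzyme releases (default 2;
#'   free xylose appears in digests only as a minor product).
#' @return An `endo_rule` object.
#' @export
endo_rule <- function(name, blocked_subsites, min_product_dp = 2L) {
  kinds <- c("Araf", "GlcA", "MeGlcA", "D", "B")
  if (!all(kinds %in% names(blocked_subsites))) {
    abort("blocked_subsites must cover Araf, GlcA, MeGlcA, D and B")
  }
  for (k in kinds) {
    ss <- blocked_subsites[[k]]
    if (!all(ss %in% c(-2L, -1L, 1L, 2L))) {
      abort("subsites must come from {-2, -1, 1, 2}")
    }
    if (!(-1L %in% ss)) abort(sprintf("subsite -1 must be blocked for %s", k))
  }
  if (min_product_dp < 1L) abort("min_product_dp must be >= 1")
  structure(list(name = name, blocked_subsites = blocked_subsites,
                 min_product_dp = as.integer(min_product_dp)),
            class = "endo_rule")
}

#' Default GH10 / GH11 endo-xylanase rules
#'
#' GH10: every substituent blocks subsite -1 only, so cleavage directly on
#' the reducing side of a substituted residue is allowed and products of the
#' `A^3X` / `U^(4Me)2X` type arise. GH11: Araf blocks \{-1, +1\}; the bulkier
#' [Me]GlcA and disaccharide chains block \{-2, -1, +1\}, yielding
#' `XA^3XX` / `XU^(4Me)2XX`-type products.
#'
#' @return An [endo_rule()].
#' @export
gh10_rule <- function() {
  endo_rule("GH10", list(Araf = -1L, GlcA = -1L, MeGlcA = -1L,
                         D = -1L, B = -1L))
}

#' @rdname gh10_rule
#' @export
gh11_rule <- function() {
  wide <- c(-2L, -1L, 1L)
  endo_rule("GH11", list(Araf = c(-1L, 1L), GlcA = wide, MeGlcA = wide,
                         D = wide, B = wide))
}

#' Bonds an endo-xylanase can cleave
#'
#' Backbone bond k links residues k and k+1 (positions counted from the
#' non-reducing end). A bond is cleavable when no substituted residue of the
#' substrate occupies one of the substituent's blocked subsites; subsites
#' falling outside the substrate are vacuously satisfied.
#'
#' @param substrate A `xylan_oligo`/`xylan_polymer` or Faure name.
#' @param rule An [endo_rule()].
#' @return Integer vector of cleavable bond indices (possibly empty).
#' @export
cleavable_bonds <- function(substrate, rule) {
  if (is.character(substrate)) substrate <- parse_faure(substrate)
  n <- dp(substrate)
  if (n < 2L) return(integer(0))
  allowed <- rep(TRUE, n - 1L)
  cl <- chain_lookup()
  subpos <- which(substrate$sub > 0L)
  for (p in subpos) {
    kind <- cl$kind[substrate$sub[p]]
    for (ss in rule$blocked_subsites[[kind]]) {
      b <- if (ss < 0L) p - ss - 1L else p - ss
      if (b >= 1L && b <= n - 1L) allowed[b] <- FALSE
    }
  }
  which(allowed)
}

# first-fit complete digestion on an integer substitution vector; returns the
# product boundary ends. Equivalent to the recursive "cleave the first
# cleavable bond leaving both fragments >= min_dp" definition: the left
# fragment of a first-fit cut never contains an earlier eligible bond.
digest_boundaries <- function(n, allowed_idx, min_dp) {
  ends <- integer(0)
  s <- 1L
  i <- 1L
  nb <- length(allowed_idx)
  while (TRUE) {
    lo <- s + min_dp - 1L
    hi <- n - min_dp
    while (i <= nb && allowed_idx[i] < lo) i <- i + 1L
    if (i <= nb && allowed_idx[i] <= hi) {
      ends <- c(ends, allowed_idx[i])
      s <- allowed_idx[i] + 1L
      i <- i + 1L
    } else {
      ends <- c(ends, n)
      break
    }
  }
  ends
}

#' Complete endo-xylanase digestion
#'
#' Deterministic complete hydrolysis: scanning from the non-reducing end,
#' the first cleavable bond leaving both fragments at least
#' `min_product_dp` long is cut, and both fragments are digested further
#' until no such bond remains. The cleavage pattern is deterministic, and
#' quantitation downstream depends only on the conserved residue counts,
#' not on the pattern.
#'
#' @param substrate A `xylan_oligo`/`xylan_polymer` or Faure name.
#' @param rule An [endo_rule()].
#' @return A `gax_digest`: tibble with `faure_name`, `dp`, `count` (molar),
#'   plus attributes `substrate_dp` and `enzyme`.
#' @examples
#' digest_complete(xylan_polymer(rep(0L, 6)), gh10_rule())  # X6 -> 3 x X2
#' @export
digest_complete <- function(substrate, rule) {
  if (is.character(substrate)) substrate <- parse_faure(substrate)
  n <- dp(substrate)
  if (n < 2L * rule$min_product_dp) {
    out <- tibble(faure_name = to_faure(substrate), dp = n, count = 1)
  } else {
    ends <- digest_boundaries(n, cleavable_bonds(substrate, rule),
                              rule$min_product_dp)
    starts <- c(1L, head(ends, -1L) + 1L)
    pid <- rep.int(seq_along(ends), ends - starts + 1L)
    nm <- faure_names_grouped(substrate$sub, pid)
    out <- tibble(faure_name = nm, dp = ends - starts + 1L) |>
      dplyr::count(.data$faure_name, .data$dp, name = "count") |>
      dplyr::arrange(.data$dp, .data$faure_name)
    out$count <- as.numeric(out$count)
  }
  attr(out, "substrate_dp") <- n
  attr(out, "enzyme") <- rule$name
  class(out) <- c("gax_digest", class(out))
  out
}

#' All structurally possible endo-digestion products
#'
#' Every contiguous fragment whose two boundaries are each either a
#' substrate end or a cleavable bond. This is the set of products that can
#' occur across partial or complete digests (Table-style product
#' assignment), a superset of the deterministic [digest_complete()] output.
#'
#' @inheritParams digest_complete
#' @param max_dp Cap on candidate length (keeps the enumeration quadratic
#'   only in the number of boundaries within the cap).
#' @return Tibble `faure_name`, `dp`, unique candidates.
#' @export
candidate_products <- function(substrate, rule, max_dp = 12L) {
  if (is.character(substrate)) substrate <- parse_faure(substrate)
  n <- dp(substrate)
  cuts <- c(0L, cleavable_bonds(substrate, rule), n)
  nm <- character(0); dps <- integer(0)
  for (a in seq_len(length(cuts) - 1L)) {
    for (b in (a + 1L):length(cuts)) {
      len <- cuts[b] - cuts[a]
      if (len > max_dp) break
      frag <- substrate$sub[(cuts[a] + 1L):cuts[b]]
      nm <- c(nm, to_faure(xylan_oligo(frag)))
      dps <- c(dps, len)
    }
  }
  dplyr::distinct(tibble(faure_name = nm, dp = dps)) |>
    dplyr::arrange(.data$dp, .data$faure_name)
}

## ---- exo-acting enzymes ----------------------------------------------------

# neighbour substitution helper: TRUE if backbone position p exists and is
# substituted
.subst_at <- function(struct, p) {
  p >= 1L && p <= dp(struct) && struct$sub[p] > 0L
}

#' Exo-enzyme trimming rules
#'
#' Structural predicates for the exo-acting enzymes used in sequential
#' digests, each removing one moiety when its condition is met:
#' * `GH51` arabinofuranosidase: removes any single Araf side chain.
#' * `GH62` arabinofuranosidase: removes a single Araf only when both
#'   backbone neighbours of the bearing residue are unsubstituted (steric
#'   exclusion around tandem substitution).
#' * `GH67` alpha-glucuronidase: removes a `[Me]GlcA` when the substrate
#'   backbone has DP >= 3 (empirical rule reproducing the observed
#'   sensitivity pattern; see the methods vignette for why the
#'   terminal-only mechanism is not used).
#' * `GH115` alpha-glucuronidase: removes a `[Me]GlcA` when the backbone
#'   neighbour on the non-reducing side of the bearing residue is
#'   unsubstituted or absent.
#' * `CgGH3` beta-xylosidase: removes the terminal Xylp of a `D^2,3` chain
#'   (leaving `A^3`) when both backbone neighbours of the bearing residue
#'   are unsubstituted.
#' * `TrGH3` beta-xylosidase: removes the non-reducing terminal backbone
#'   Xylp when it is unsubstituted.
#'
#' @param name One of `"GH51"`, `"GH62"`, `"GH67"`, `"GH115"`, `"CgGH3"`,
#'   `"TrGH3"`.
#' @return An `exo_rule` object.
#' @export
exo_rule <- function(name) {
  name <- match.arg(name, c("GH51", "GH62", "GH67", "GH115", "CgGH3",
                            "TrGH3"))
  structure(list(name = name), class = "exo_rule")
}

#' @rdname exo_rule
#' @export
default_exo_rules <- function() {
  lapply(c("CgGH3", "GH51", "GH62", "GH67", "GH115"), exo_rule)
}

#' Apply an exo-enzyme rule once
#'
#' @param oligo A `xylan_oligo` or Faure name.
#' @param rule An [exo_rule()].
#' @return List: `product` (`xylan_oligo`), `acted` (logical), `released`
#'   (character description of the removed moiety, or `NA`).
#' @examples
#' apply_exo("U^(4Me)2X", exo_rule("GH115"))$acted   # TRUE
#' apply_exo("A^3A^3X", exo_rule("GH62"))$acted      # FALSE
#' @export
apply_exo <- function(oligo, rule) {
  if (is.character(oligo)) oligo <- parse_faure(oligo)
  cl <- chain_lookup()
  s <- oligo$sub
  kinds <- ifelse(s > 0L, cl$kind[pmax(s, 1L)], "")
  not_acted <- list(product = oligo, acted = FALSE, released = NA_character_)
  free_neighbours <- function(p) {
    !.subst_at(oligo, p - 1L) && !.subst_at(oligo, p + 1L)
  }
  drop_chain <- function(p, released) {
    s[p] <- 0L
    list(product = xylan_oligo(s, label = oligo$label), acted = TRUE,
         released = released)
  }
  switch(rule$name,
    GH51 = {
      p <- which(kinds == "Araf")[1]
      if (is.na(p)) not_acted else drop_chain(p, "Araf")
    },
    GH62 = {
      ps <- which(kinds == "Araf")
      ps <- ps[vapply(ps, free_neighbours, logical(1))]
      if (length(ps) == 0L) not_acted else drop_chain(ps[1], "Araf")
    },
    GH67 = {
      p <- which(kinds %in% c("GlcA", "MeGlcA"))[1]
      if (is.na(p) || dp(oligo) < 3L) not_acted else
        drop_chain(p, kinds[p])
    },
    GH115 = {
      ps <- which(kinds %in% c("GlcA", "MeGlcA"))
      ps <- ps[!vapply(ps, function(p) .subst_at(oligo, p - 1L), logical(1))]
      if (length(ps) == 0L) not_acted else drop_chain(ps[1], kinds[ps[1]])
    },
    CgGH3 = {
      ps <- which(kinds == "D")
      ps <- ps[vapply(ps, free_neighbours, logical(1))]
      if (length(ps) == 0L) not_acted else {
        s[ps[1]] <- 1L  # D^2,3 -> A^3
        list(product = xylan_oligo(s, label = oligo$label), acted = TRUE,
             released = "Xylp")
      }
    },
    TrGH3 = {
      if (dp(oligo) >= 2L && s[1] == 0L) {
        list(product = xylan_oligo(s[-1], label = oligo$label), acted = TRUE,
             released = "Xylp")
      } else not_acted
    }
  )
}

#' Enzyme sensitivity matrix
#'
#' Classifies each oligosaccharide as `sensitive` (the exo rule acts) or
#' `resistant` for each enzyme.
#'
#' @param oligos Character vector of Faure names.
#' @param rules List of [exo_rule()] (default the five enzymes of the
#'   packaged reference table).
#' @return Tibble: `faure_name` plus one column per enzyme with values
#'   `"sensitive"`/`"resistant"`.
#' @export
sensitivity_matrix <- function(oligos, rules = default_exo_rules()) {
  cols <- purrr::map(rules, function(r) {
    vapply(oligos, function(o) {
      if (apply_exo(o, r)$acted) "sensitive" else "resistant"
    }, character(1), USE.NAMES = FALSE)
  })
  names(cols) <- vapply(rules, function(r) r$name, character(1))
  dplyr::bind_cols(tibble(faure_name = oligos), as_tibble(cols))
}

#' Packaged enzymatic reference table
#'
#' Transcription of the published enzymatic analysis of the library
#' oligosaccharides: which xylanase (GH10/GH11) produces each structure
#' (`none`/`minor`/`major`) and its sensitivity (`+`), resistance (`-`) or
#' `NT` (not tested) for the CgGH3, GH51, GH62, GH67 and GH115 enzymes.
#'
#' @return Tibble, one row per library oligosaccharide.
#' @export
enzyme_reference <- function() {
  readr::read_tsv(system.file("extdata", "enzyme_sensitivity.tsv",
                              package = "gaxr"),
                  show_col_types = FALSE)
}
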