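frag <- function(name, fam, idx) {
  fr <- predict_fragments(parse_faure(name, label = "2-AA"))
  fr$mz[fr$family == fam & !is.na(fr$index) & fr$index == idx][1]
}

test_that("sodiated precursors reproduce the printed values", {
  expect_lt(abs(precursor_mz("A^3X", label = "2-AA") - 558.1), 0.5)
  expect_lt(abs(precursor_mz("A^3XXX", label = "2-AA") - 822.0), 0.5)
  expect_lt(abs(precursor_mz("U^(4Me)2X", label = "2-AA") - 616.0), 0.5)
  expect_lt(abs(precursor_mz("XA^3A^3X", label = "2-AA") - 954.3), 0.5)
  # closed-form single residue, unlabelled
  expect_equal(precursor_mz("X"), 132.0423 + 18.0106 + 22.9898,
               tolerance = 1e-6)
  expect_error(precursor_mz("X", label = "APTS"), "APTS")
})

test_that("mass table internal consistency", {
  m <- mass_table()
  expect_lt(abs((m$methyl_hexuronic - m$hexuronic) - 14.0157), 1e-3)
  expect_true(all(unlist(m[c("pentose", "hexuronic", "methyl_hexuronic",
                             "water", "sodium")]) > 0))
})

test_that("diagnostic fragments reproduce the printed values", {
  expect_lt(abs(frag("A^3X", "Y", 1) - 294.1), 0.5)
  expect_lt(abs(frag("XA^3A^3X", "X15", 1) - 322.1), 0.5)
  expect_lt(abs(frag("XA^3X", "W", 2) - 424.1), 0.5)
  expect_lt(abs(frag("XA^3X", "X02", 1) - 336.1), 0.5)
  # consecutive Y ions of a linear region differ by one pentose
  fr <- predict_fragments(parse_faure("XXXXXX", label = "2-AA"))
  y <- sort(fr$mz[fr$family == "Y"])
  expect_equal(diff(y), rep(132.0423, 4), tolerance = 1e-4)
})

test_that("DP1 structures yield no glycosidic fragments", {
  expect_equal(nrow(predict_fragments(parse_faure("X", label = "2-AA"))), 0L)
})

test_that("unknown families are rejected; unlabelled prediction allowed", {
  expect_error(predict_fragments("A^3X", families = "Q"), "unknown ion family")
  fr <- predict_fragments(parse_faure("XX"))  # label none, mass 0
  expect_lt(abs(fr$mz[fr$family == "Y" & fr$index == 1] -
                  (132.0423 + 18.0106 + 22.9898)), 1e-4)
})

test_that("B/Y complementarity and Y monotonicity hold on random structures", {
  m <- mass_table()
  set.seed(7)
  for (i in 1:50) {
    x <- random_oligo(label = "2-AA")
    if (dp(x) < 2) next
    fr <- predict_fragments(x)
    p <- precursor_mz(x)
    yk <- fr[fr$family == "Y" & !is.na(fr$index), ]
    bk <- fr[fr$family == "B" & !is.na(fr$index), ]
    for (k in yk$index) {
      b <- bk$mz[bk$index == dp(x) - k]
      if (length(b)) expect_lt(abs(yk$mz[yk$index == k] + b -
                                     (p + m$sodium)), 1e-3)
    }
    expect_true(all(diff(yk$mz[order(yk$index)]) > 0))
  }
})

test_that("adding a side chain shifts the precursor by its residue mass", {
  base <- precursor_mz("XXX", label = "2-AA")
  expect_equal(precursor_mz("XA^3X", label = "2-AA") - base, 132.0423,
               tolerance = 1e-6)
  expect_equal(precursor_mz("XU^(4Me)2X", label = "2-AA") - base, 190.0477,
               tolerance = 1e-6)
  expect_equal(precursor_mz("XD^2,3X", label = "2-AA") - base, 264.0846,
               tolerance = 1e-6)
})

test_that("every printed ion ledger annotates fully at 1 Da", {
  led <- cid_ledgers()
  for (id in unique(led$unknown_id)) {
    sub <- led[led$unknown_id == id, ]
    st <- parse_faure(sub$faure_name[1], label = "2-AA")
    prec <- sub$mz[sub$ion == "precursor"]
    tol_prec <- if (prec > 1000) 1.0 else 0.5
    expect_lt(abs(precursor_mz(st) - prec), tol_prec)
    ions <- sub[sub$ion != "precursor", ]
    ann <- annotate_spectrum(spectrum_peaks(ions$mz), st, tolerance = 1.0)
    expect_equal(ann$observed_coverage, 1.0,
                 info = paste("ledger", id))
    # sequence-defining families hold to 0.5 Da below m/z 1000
    core <- ions[grepl("^(Y|W|1,5X|1,4X|0,2X)", ions$ion) & ions$mz < 1000, ]
    for (mz in core$mz) {
      row <- ann$matches[ann$matches$observed_mz == mz, ]
      expect_lt(abs(row$error_da[1]), 0.5)
    }
  }
})

test_that("annotation is greedy, one-to-one, and degrades for wrong candidates", {
  led <- cid_ledgers()
  n4 <- led[led$unknown_id == "N4" & led$ion != "precursor", ]
  peaks <- spectrum_peaks(c(n4$mz, 558.1))
  good <- annotate_spectrum(peaks, parse_faure("A^3X", label = "2-AA"),
                            tolerance = 1.0)
  expect_equal(nrow(good$matches), nrow(n4))  # all but the precursor peak
  expect_false(any(duplicated(good$matches$observed_mz)))
  wrong <- annotate_spectrum(peaks, parse_faure("XXX", label = "2-AA"),
                             tolerance = 1.0)
  expect_lt(nrow(wrong$matches), nrow(good$matches))
  # empty peak list
  empty <- annotate_spectrum(spectrum_peaks(numeric(0)),
                             parse_faure("A^3X", label = "2-AA"))
  expect_equal(nrow(empty$matches), 0L)
})

test_that("candidate ranking filters by precursor and prefers the truth", {
  lib <- gax_gu_library()
  # among GH10 products, exactly three Pent_5 isomers share the 822.0
  # precursor (the structural isomers resolved from one SEC fraction)
  gh10_names <- lib$faure_name[lib$gh10_product]
  pent5 <- gh10_names[vapply(gh10_names, function(nm)
    oligo_composition(nm)$pentose == 5 &&
      oligo_composition(nm)$hexuronic + oligo_composition(nm)$methyl_hexuronic == 0,
    logical(1))]
  expect_setequal(pent5, c("A^3A^3X", "A^3XXX", "D^2,3XX"))
  led <- cid_ledgers()
  n6 <- led[led$unknown_id == "N6" & led$ion != "precursor", ]
  peaks <- spectrum_peaks(c(n6$mz, 822.0), precursor_mz = 822.0)
  ranked <- rank_candidates(peaks, gh10_names)
  expect_setequal(ranked$faure_name, pent5)
  expect_lt(which(ranked$faure_name == "A^3A^3X"),
            which(ranked$faure_name == "A^3XXX"))
  # single compatible candidate comes back unchanged
  one <- rank_candidates(peaks, "A^3A^3X")
  expect_equal(one$faure_name, "A^3A^3X")
  # incompatible candidate set gives an empty, diagnosed result
  expect_warning(none <- rank_candidates(peaks, "XX"), "precursor")
  expect_equal(nrow(none), 0L)
})

test_that("MGF files round trip", {
  sp <- synthesize_spectrum("A^3X", n_decoys = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(N4 = sp), path)
  back <- read_mgf(path)
  expect_equal(names(back), "N4")
  expect_equal(back$N4$mz, sp$mz, tolerance = 1e-6)
  expect_equal(attr(back$N4, "precursor_mz"), attr(sp, "precursor_mz"),
               tolerance = 1e-6)
})
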