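test_that("subsite constraints pick out the cleavable bonds", {
  # unsubstituted X6: every bond open for GH10
  expect_equal(cleavable_bonds(xylan_oligo(rep(0L, 6)), gh10_rule()), 1:5)
  # DP5, Araf at position 2, GH11 (Araf blocks -1 and +1)
  expect_equal(cleavable_bonds(xylan_oligo(c(0L, 1L, 0L, 0L, 0L)),
                               gh11_rule()), 3:4)
  # DP4, Araf at position 2, GH10 (blocks -1 only)
  expect_equal(cleavable_bonds(xylan_oligo(c(0L, 1L, 0L, 0L)),
                               gh10_rule()), c(1L, 3L))
})

test_that("endo rules validate their subsite maps", {
  expect_error(endo_rule("bad", list(Araf = 1L, GlcA = -1L, MeGlcA = -1L,
                                     D = -1L, B = -1L)),
               "subsite -1")
  expect_error(endo_rule("bad", list(Araf = -3L, GlcA = -1L, MeGlcA = -1L,
                                     D = -1L, B = -1L)),
               "subsites")
})

test_that("complete digestion follows the leftmost-greedy rule", {
  expect_equal(digest_complete(xylan_polymer(rep(0L, 6)), gh10_rule())$count,
               3)  # {X2, X2, X2}
  d <- digest_complete(xylan_polymer(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)),
                       gh10_rule())
  expect_setequal(d$faure_name, c("XX", "XA^3X", "XXX"))
  expect_equal(d$count, rep(1, 3))
  # below the minimum substrate size nothing happens
  d2 <- digest_complete(parse_faure("XX"), gh10_rule())
  expect_equal(d2$faure_name, "XX")
})

test_that("digestion conserves backbone and side-chain counts", {
  set.seed(13)
  for (rule in list(gh10_rule(), gh11_rule())) {
    for (i in 1:20) {
      sub <- as.integer(ifelse(runif(80) < 0.25, sample(1:8, 80, TRUE), 0L))
      poly <- xylan_polymer(sub)
      d <- digest_complete(poly, rule)
      cc <- oligo_class_counts(d$faure_name)
      expect_equal(sum(cc$n_xyl * d$count), 80L)
      truth <- oligo_class_counts(to_faure(poly))
      expect_equal(sum(cc$n_araf * d$count), truth$n_araf)
      expect_equal(sum(cc$n_uronic * d$count), truth$n_uronic)
      expect_equal(sum(cc$n_d * d$count), truth$n_d)
    }
  }
})

test_that("complete-digest products are candidates, and redigestion is a fixed point", {
  set.seed(29)
  for (i in 1:15) {
    sub <- as.integer(ifelse(runif(40) < 0.2, sample(1:8, 40, TRUE), 0L))
    poly <- xylan_polymer(sub)
    for (rule in list(gh10_rule(), gh11_rule())) {
      d <- digest_complete(poly, rule)
      cand <- candidate_products(poly, rule, max_dp = 40)
      expect_true(all(d$faure_name %in% cand$faure_name))
      for (nm in d$faure_name) {
        re <- digest_complete(parse_faure(nm), rule)
        expect_equal(re$faure_name, nm)
      }
    }
  }
})

test_that("candidate products contain the characteristic enzyme products", {
  # GH10 around isolated / tandem Araf
  poly <- parse_faure("XXXA^3XXXA^3A^3XXX")
  cand <- candidate_products(poly, gh10_rule())$faure_name
  for (nm in c("A^3X", "XA^3X", "A^3XXX", "A^3A^3X")) {
    expect_true(nm %in% cand, info = nm)
  }
  # GH11 around isolated MeGlcA
  cand11 <- candidate_products(parse_faure("XXXU^(4Me)2XXXX"),
                               gh11_rule())$faure_name
  expect_true("XU^(4Me)2XX" %in% cand11)
  # unsubstituted substrate never yields substituted names
  expect_false(any(grepl("[AUDB]", candidate_products(parse_faure("XXX"),
                                                      gh10_rule())$faure_name)))
})

test_that("exo-enzyme predicates act as characterised", {
  r <- apply_exo("U^(4Me)2X", exo_rule("GH115"))
  expect_true(r$acted)
  expect_equal(r$released, "MeGlcA")
  expect_equal(to_faure(r$product), "XX")
  expect_false(apply_exo("U^(4Me)2X", exo_rule("GH67"))$acted)  # DP2
  expect_true(apply_exo("U^(4Me)2XX", exo_rule("GH67"))$acted)
  expect_false(apply_exo("A^3A^3X", exo_rule("GH62"))$acted)    # tandem Araf
  expect_true(apply_exo("A^3X", exo_rule("GH62"))$acted)
  expect_false(apply_exo("XX", exo_rule("GH51"))$acted)
  # CgGH3 shaves the D chain's terminal Xylp, leaving A^3
  r <- apply_exo("D^2,3XX", exo_rule("CgGH3"))
  expect_true(r$acted)
  expect_equal(to_faure(r$product), "A^3XX")
  # ...but is blocked by a substituted neighbour
  expect_false(apply_exo("D^2,3U^(4Me)2XX", exo_rule("CgGH3"))$acted)
  # TrGH3 trims the unsubstituted non-reducing terminal Xylp
  r <- apply_exo("XA^3X", exo_rule("TrGH3"))
  expect_true(r$acted)
  expect_equal(to_faure(r$product), "A^3X")
  expect_false(apply_exo("A^3X", exo_rule("TrGH3"))$acted)
})

test_that("exo action conserves backbone except for TrGH3", {
  set.seed(5)
  for (i in 1:40) {
    x <- random_oligo()
    for (r in default_exo_rules()) {
      out <- apply_exo(x, r)
      expect_equal(dp(out$product), dp(x))
      if (!out$acted) expect_same_structure(out$product, x)
    }
    tr <- apply_exo(x, exo_rule("TrGH3"))
    expect_equal(dp(tr$product), dp(x) - as.integer(tr$acted))
  }
})

test_that("the default rules reproduce every tested reference cell", {
  ref <- enzyme_reference()
  sm <- sensitivity_matrix(ref$faure_name)
  for (enz in c("CgGH3", "GH51", "GH62", "GH67", "GH115")) {
    tested <- ref[[enz]] != "NT"
    pred <- ifelse(sm[[enz]] == "sensitive", "+", "-")
    expect_equal(pred[tested], ref[[enz]][tested],
                 info = paste("enzyme", enz))
  }
})

test_that("the sensitivity matrix is order-invariant and handles edge input", {
  expect_equal(nrow(sensitivity_matrix(character(0))), 0L)
  nms <- enzyme_reference()$faure_name
  set.seed(3)
  perm <- sample(nms)
  a <- sensitivity_matrix(nms)
  b <- sensitivity_matrix(perm)
  expect_equal(dplyr::arrange(a, faure_name), dplyr::arrange(b, faure_name))
})
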