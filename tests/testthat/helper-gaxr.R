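# shared fixture builders

# random valid structure: DP in [1, max_dp], random side chains over the full
# code alphabet (at most one per residue by construction)
random_oligo <- function(max_dp = 12, p_sub = 0.3, label = "none") {
  n <- sample.int(max_dp, 1)
  sub <- ifelse(runif(n) < p_sub, sample(1:8, n, replace = TRUE), 0L)
  xylan_oligo(as.integer(sub), label = label)
}

# trace of Gaussian peaks on a flat baseline
gaussian_trace <- function(centers, areas, sd = 4, t0 = 0, t1 = NULL,
                           dt = 0.25, noise_sd = 0, baseline = 0,
                           seed = NULL) {
  t1 <- t1 %||% (max(centers) + 20 * sd)
  tt <- seq(t0, t1, by = dt)
  y <- rep(baseline, length(tt))
  for (i in seq_along(centers)) {
    y <- y + areas[i] / (sd * sqrt(2 * pi)) *
      exp(-0.5 * ((tt - centers[i]) / sd)^2)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(tt), 0, noise_sd)
  }
  gax_trace(tt, y)
}

expect_same_structure <- function(a, b) {
  expect_identical(a$sub, b$sub)
  expect_identical(a$label, b$label)
}
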