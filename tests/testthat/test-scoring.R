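test_that("matched SPI chi-score: identity, arithmetic, double-loop oracle", {
  cx <- toy50()
  qm <- qm40()
  oris <- random_orientations(3, subspace_bounds(22.5), "per_angle", seed = 81)
  ps <- simulate_pattern_set(cx, oris, qm)
  expect_equal(as.numeric(spi_score_matched(ps, ps)), 0)

  # model = 3, data = 1, sigma = 1 at every pixel: chi = 4
  mk <- function(val) {
    p <- ps
    p$patterns <- lapply(p$patterns, function(x) {
      x$intensity[qm$mask] <- val
      x$sigma <- pmax(sqrt(pmax(x$intensity, 0)), 1)
      x
    })
    p
  }
  expect_equal(as.numeric(spi_score_matched(mk(3), mk(1))), 4.0)

  # random sets vs an independent double loop
  set.seed(82)
  rnd <- function() {
    p <- ps
    p$patterns <- lapply(p$patterns, function(x) {
      x$intensity[qm$mask] <- runif(sum(qm$mask), 0, 50)
      x$sigma <- pmax(sqrt(pmax(x$intensity, 0)), 1)
      x
    })
    p
  }
  a <- rnd(); b <- rnd()
  got <- as.numeric(spi_score_matched(a, b))
  acc <- 0
  for (n in seq_along(a$patterns)) {
    s <- 0
    for (m in which(qm$mask))
      s <- s + ((a$patterns[[n]]$intensity[m] - b$patterns[[n]]$intensity[m]) /
                  b$patterns[[n]]$sigma[m])^2
    acc <- acc + s / sum(qm$mask)
  }
  expect_equal(got, acc / length(a$patterns), tolerance = 1e-12)

  expect_error(spi_score_matched(ps, simulate_pattern_set(cx, oris, qm48())),
               "pixel counts")
})

test_that("orientation-matching SPI score: identity, min property, oracle", {
  cx <- toy50()
  qm <- qm40()
  g <- make_grid(11.25, subspace_bounds(22.5))
  on_grid <- g$triples[c(3L, 40L, 77L, 100L), ]
  exps <- simulate_pattern_set(cx, on_grid, qm)

  # native model, on-grid noise-free data: exactly zero
  chi <- spi_score_matching(exps, cx, g)
  expect_equal(as.numeric(chi), 0)

  # Eq-4-style minimum never exceeds any fixed orientation assignment
  dec <- make_decoy_ladder(cx, 3, seed = 83)$decoys[[1]]
  bank <- build_bank(dec, g, qm, "raw", scale_factor = 1)
  chi_min <- spi_score_matching(exps, bank = bank)
  set.seed(84)
  for (k in 1:50) {
    assign_idx <- sample(nrow(g$triples), length(exps$patterns),
                         replace = TRUE)
    fixed <- mean(vapply(seq_along(exps$patterns), function(n) {
      e <- exps$patterns[[n]]
      mean(((bank$features[, assign_idx[n]] - e$intensity[qm$mask]) /
              e$sigma[qm$mask])^2)
    }, numeric(1)))
    expect_lte(as.numeric(chi_min), fixed + 1e-12)
  }

  # exhaustive per-pair loop oracle: 5 decoys x 20 patterns x 27 triples
  g27 <- make_grid(22.5, subspace_bounds(22.5))
  exps20 <- simulate_pattern_set(
    cx, random_orientations(20, subspace_bounds(22.5), "per_angle",
                            seed = 85), qm)
  ds <- make_decoy_ladder(cx, seq(1, 9, by = 2), seed = 86)
  for (dec in ds$decoys[c(1, 3, 5)]) {
    got <- as.numeric(spi_score_matching(exps20, dec, g27))
    sim <- pattern_simulator(dec, qm)
    bankI <- sapply(seq_len(nrow(g27$triples)), function(i)
      sim(g27$triples[i, ])$intensity[qm$mask])
    oracle <- mean(vapply(exps20$patterns, function(e) {
      min(colMeans(((bankI - e$intensity[qm$mask]) / e$sigma[qm$mask])^2))
    }, numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("SAXS chi-score: identity, arithmetic, orientation invariance", {
  cx <- toy50()
  qm <- qm40()
  ps <- simulate_pattern_set(
    cx, random_orientations(150, sampler = "so3", seed = 87), qm)
  ps <- scale_to_photons(ps)

  # feeding the data profile back as the model gives exactly zero
  bins <- radial_bins(qm, 20L)
  dp <- radial_profile(ps, bins = bins)
  expect_equal(as.numeric(saxs_score(ps, dp$intensity, bins = bins)), 0)

  # two bins with residual/sigma = (1, 3): chi = (1 + 9) / 2 = 5
  fake <- dp$intensity
  ok <- which(!is.na(fake))[1:2]
  fake[ok] <- fake[ok] + c(1, 3) * dp$sigma[ok]
  keep <- rep(NA_real_, length(fake)); keep[ok] <- fake[ok]
  expect_equal(as.numeric(saxs_score(ps, keep, bins = bins)), 5.0,
               tolerance = 1e-9)

  # the model side is orientation-free: the score of a decoy depends only
  # on its internal structure, and data drawn at re-randomized orientations
  # gives the same score up to sampling error
  dec <- make_decoy_ladder(cx, 6, seed = 88)$decoys[[1]]
  s1 <- as.numeric(saxs_score(ps, dec, bins = bins))
  ps2 <- scale_to_photons(simulate_pattern_set(
    cx, random_orientations(150, sampler = "so3", seed = 89), qm))
  s2 <- as.numeric(saxs_score(ps2, dec, bins = bins))
  expect_lt(abs(log(s1 / s2)), log(1.6))

  # and the native model scores far lower than a displaced decoy
  expect_lt(as.numeric(saxs_score(ps, cx, bins = bins)), s1 / 10)
})

test_that("model-side Debye profile matches the pattern-averaging route", {
  cx <- make_toy_complex(8L, 5L, seed = 5L)
  qm <- qm32()
  bins <- radial_bins(qm, 10L)
  ps <- simulate_pattern_set(
    cx, random_orientations(3000, sampler = "so3", seed = 90), qm)
  dp <- radial_profile(ps, bins = bins)
  mp <- saxs_model_profile(cx, qm, bins)
  ok <- !is.na(dp$intensity)
  # per-bin agreement within a few percent at 3000 orientations
  expect_lt(max(abs(dp$intensity[ok] / mp[ok] - 1)), 0.1)
})

test_that("s-score: identity, decorrelation, refinement, symmetry", {
  cx <- toy50()
  s0 <- s_score(cx, cx, rot_step = 30, bounds = subspace_bounds(30))
  expect_equal(as.numeric(s0), 0, tolerance = 1e-9)
  expect_equal(attr(s0, "cc"), 1, tolerance = 1e-9)

  # uncorrelated random maps decorrelate at 32^3 voxels
  set.seed(91)
  a <- array(runif(32^3), dim = c(32, 32, 32))
  b <- array(runif(32^3), dim = c(32, 32, 32))
  expect_lt(abs(density_correlation(a, b)), 0.1)

  # nested-grid refinement can only improve the maximum correlation
  dec <- generate_decoys(cx, 1, rot_max = 25, trans_max = 6, seed = 92)$decoys[[1]]
  coarse <- s_score(dec, cx, rot_step = 30, bounds = subspace_bounds(30))
  fine <- s_score(dec, cx, rot_step = 15, bounds = subspace_bounds(30))
  expect_lte(attr(coarse, "cc"), attr(fine, "cc") + 1e-12)
  expect_gte(as.numeric(coarse), as.numeric(fine) - 1e-12)

  # symmetry up to grid/interpolation tolerance
  sab <- s_score(dec, cx, rot_step = 15, bounds = subspace_bounds(45))
  sba <- s_score(cx, dec, rot_step = 15, bounds = subspace_bounds(45))
  expect_lt(abs(as.numeric(sab) - as.numeric(sba)), 0.05)

  # an all-constant (information-free) map is rejected
  expect_error(density_correlation(array(1, c(4, 4, 4)),
                                   array(runif(64), c(4, 4, 4))),
               "degenerate")
})

test_that("combine_zscores standardizes, orients and sums", {
  set.seed(93)
  a <- runif(30); b <- runif(30)
  # combining a score with itself preserves its ranking
  expect_equal(order(combine_zscores(a, a)), order(a))
  # perfect disagreement of standardized scores cancels to zero
  za <- as.numeric(scale(a))
  expect_equal(combine_zscores(za, -za), rep(0, 30), tolerance = 1e-12)
  # arithmetic oracle
  manual <- (a - mean(a)) / sd(a) + (b - mean(b)) / sd(b)
  expect_equal(combine_zscores(a, b), manual, tolerance = 1e-12)
  # higher-is-better columns are flipped
  expect_equal(combine_zscores(a, -b, lower_better_b = FALSE), manual,
               tolerance = 1e-12)
  expect_error(combine_zscores(a, rep(1, 30)), "zero-variance")
})

test_that("decoy-set SPI scoring equals the per-decoy matched path", {
  cx <- toy50()
  qm <- qm32()
  ds <- make_decoy_ladder(cx, c(1, 4, 9), seed = 96, mode = "rigid")
  oris <- random_orientations(5, sampler = "so3", seed = 97)
  data_ps <- scale_to_photons(simulate_pattern_set(cx, oris, qm))
  sf <- data_ps$scale_factor
  fast <- spi_score_decoy_set(ds, data_ps)
  slow <- vapply(ds$decoys, function(dec) {
    mps <- simulate_pattern_set(dec, oris, qm)
    mps$patterns <- lapply(mps$patterns, function(p) {
      p$intensity <- p$intensity * sf; p
    })
    as.numeric(spi_score_matched(mps, data_ps))
  }, numeric(1))
  expect_equal(as.numeric(fast), slow, tolerance = 1e-10)
})

test_that("SPI score batches converge with pattern count", {
  cx <- toy50()
  qm <- qm32()
  oris <- random_orientations(600, subspace_bounds(22.5), "per_angle",
                              seed = 94)
  data_ps <- scale_to_photons(simulate_pattern_set(cx, oris, qm))
  dec <- make_decoy_ladder(cx, 5, seed = 95)$decoys[[1]]
  mps <- simulate_pattern_set(dec, oris, qm)
  mps$patterns <- lapply(mps$patterns, function(p) {
    p$intensity <- p$intensity * data_ps$scale_factor; p
  })
  per <- attr(spi_score_matched(mps, data_ps), "per_pattern")
  batch_sd <- function(b) {
    groups <- split(per, (seq_along(per) - 1) %/% b)
    sd(vapply(groups, mean, numeric(1)))
  }
  sds <- c(batch_sd(10L), batch_sd(100L), batch_sd(300L))
  expect_true(all(diff(sds) < 0))
})
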