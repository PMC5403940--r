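test_that("detector geometry validates and the q map satisfies q = 4pi sin(theta)/lambda", {
  det <- det48()
  qm <- qm48()

  # the pixel at an integer beam center carries q = 0
  di <- beam_detector(n_fast = 9L, n_slow = 9L, pixel_size = 8,
                      distance = 30, beam_center = c(4, 4), d_min = 4)
  qi <- build_qmap(di)
  ic <- which(qi$px == 4L & qi$py == 4L)
  expect_length(ic, 1L)
  expect_equal(qi$qmag[ic], 0)
  expect_equal(qi$qvecs[ic, ], c(0, 0, 0))

  # |q| recomputed from the scattering angle at every pixel
  r <- sqrt(((qm$px - det$beam_center[1]) * det$pixel_size)^2 +
            ((qm$py - det$beam_center[2]) * det$pixel_size)^2)
  theta <- atan2(r, det$distance) / 2
  expect_equal(qm$qmag, 4 * pi * sin(theta) / det$wavelength,
               tolerance = 1e-12)
  expect_equal(qm$qmag, sqrt(rowSums(qm$qvecs^2)), tolerance = 1e-12)

  # a pixel engineered at 2theta = 60 deg, lambda = 1: |q| = 2 pi
  d60 <- beam_detector(wavelength = 1, distance = 50,
                       pixel_size = 50 * tan(pi / 3) / 2,
                       n_fast = 3L, n_slow = 3L, beam_center = c(0, 0),
                       d_min = 1)
  q60 <- build_qmap(d60)
  i60 <- which(q60$px == 2L & q60$py == 0L)
  expect_equal(q60$qmag[i60], 2 * pi, tolerance = 1e-9)

  # masked fraction: every usable pixel sits inside the 4 A shell
  expect_true(all(qm$qmag[qm$mask] <= 2 * pi / 4 + 1e-12))
  expect_true(any(!qm$mask))

  # geometry that cannot reach d_min is rejected
  expect_error(beam_detector(distance = 500, n_fast = 32L, n_slow = 32L,
                             pixel_size = 0.2),
               "detector edge")
})

test_that("structure_factor: point-atom limits, symmetry, linearity, oracle", {
  set.seed(21)
  qv <- matrix(rnorm(15, sd = 0.6), 5, 3)
  qmag <- sqrt(rowSums(qv^2))

  # single atom at the origin: F = f(|q|), zero phase
  one <- atomic_model("N", matrix(0, 1, 3))
  F1 <- structure_factor(one, qv)
  expect_equal(Im(F1), rep(0, 5), tolerance = 1e-12)
  expect_equal(Re(F1), form_factor("N", qmag), tolerance = 1e-12)

  # centrosymmetric pair at +-r/2: F = 2 f cos(q.r/2), purely real
  rvec <- c(1.2, -0.4, 2.0)
  pair <- atomic_model(c("O", "O"), rbind(rvec / 2, -rvec / 2))
  Fp <- structure_factor(pair, qv)
  expect_equal(Im(Fp), rep(0, 5), tolerance = 1e-10)
  expect_equal(Re(Fp),
               2 * form_factor("O", qmag) * cos(as.numeric(qv %*% rvec) / 2),
               tolerance = 1e-12)

  # 7-atom model vs an independently coded double loop
  set.seed(22)
  m7 <- atomic_model(c("C", "C", "N", "O", "S", "C", "O"),
                     matrix(rnorm(21, sd = 4), 7, 3))
  Fm <- structure_factor(m7, qv)
  brute <- vapply(1:5, function(k) {
    s <- 0 + 0i
    for (j in 1:7)
      s <- s + form_factor(m7$elements[j], sqrt(sum(qv[k, ]^2))) *
        exp(1i * sum(qv[k, ] * m7$coords[j, ]))
    s
  }, complex(1))
  expect_lt(max(Mod(Fm - brute) / Mod(brute)), 1e-10)

  # linearity in the model
  a <- atomic_model(m7$elements[1:3], m7$coords[1:3, ])
  b <- atomic_model(m7$elements[4:7], m7$coords[4:7, ])
  expect_equal(structure_factor(a, qv) + structure_factor(b, qv), Fm,
               tolerance = 1e-12)

  expect_error(structure_factor(atomic_model("C", matrix(0, 1, 3)),
                                matrix(NA_real_, 1, 3)), "finite")
})

test_that("simulating a rotated model equals sampling rotated q vectors", {
  cx <- toy50()
  qm <- qm40()
  ori <- c(35, 70, -15)
  p <- simulate_pattern(cx, ori, qm)
  R <- euler_matrix(ori[1], ori[2], ori[3])
  Fq <- structure_factor(cx, qm$qvecs[qm$mask, ] %*% R)  # rows q -> R^T q
  expect_equal(p$intensity[qm$mask], Mod(Fq)^2,
               tolerance = 1e-8)
  expect_true(all(p$intensity[qm$mask] >= 0))
  expect_true(all(is.finite(p$intensity[qm$mask])))
  # the fast simulator path is numerically identical
  p2 <- pattern_simulator(cx, qm)(ori)
  expect_equal(p$intensity, p2$intensity, tolerance = 1e-9)
})

test_that("Friedel symmetry: exact in Fourier space, approximate on the detector", {
  cx <- toy50()
  # exact statement for real scattering factors: |F(q)| = |F(-q)|
  set.seed(41)
  qv <- matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(Mod(structure_factor(cx, qv)),
               Mod(structure_factor(cx, -qv)), tolerance = 1e-12)

  # on the detector the mirror pixel keeps the same Ewald q_z, so the
  # symmetry is only asymptotic in the small-angle (flat-sphere) limit;
  # check it on a long-distance low-resolution geometry
  det <- beam_detector(wavelength = 1, distance = 1000, pixel_size = 1,
                       n_fast = 33L, n_slow = 33L, d_min = 46)
  qm <- build_qmap(det)
  p <- simulate_pattern(cx, c(12, 40, 5), qm)
  cxy <- det$beam_center  # (16, 16): integer, so mirrors are pixels
  low <- which(qm$mask &
               (qm$px - cxy[1])^2 + (qm$py - cxy[2])^2 <= 25 &
               !(qm$px == cxy[1] & qm$py == cxy[2]))
  expect_gt(length(low), 20L)
  rel <- vapply(low, function(i) {
    j <- which(qm$px == 2 * cxy[1] - qm$px[i] &
               qm$py == 2 * cxy[2] - qm$py[i])
    abs(p$intensity[i] - p$intensity[j]) /
      max(p$intensity[i], p$intensity[j])
  }, numeric(1))
  expect_lt(max(rel), 1e-2)
})

test_that("scale_to_photons pins the target-shell mean at one photon", {
  cx <- toy50()
  qm <- qm48()
  ps <- simulate_pattern_set(cx, random_orientations(8, seed = 31), qm)
  scaled <- scale_to_photons(ps, d_target = 4)
  qt <- 2 * pi / 4
  shell <- qm$mask & abs(qm$qmag - qt) <= 0.03 * qt
  shell_mean <- mean(vapply(scaled$patterns,
                            function(p) mean(p$intensity[shell]), numeric(1)))
  expect_equal(shell_mean, 1.0, tolerance = 1e-9)
  expect_true(all(vapply(scaled$patterns,
                         function(p) all(p$sigma[qm$mask] >= 1), logical(1))))

  # scaling an already-calibrated set is the identity
  again <- scale_to_photons(scaled, d_target = 4)
  expect_equal(again$scale_factor, 1, tolerance = 1e-9)

  # homogeneity: doubling the input halves the factor, output invariant
  doubled <- ps
  doubled$patterns <- lapply(ps$patterns, function(p) {
    p$intensity <- p$intensity * 2; p
  })
  s2 <- scale_to_photons(doubled, d_target = 4)
  expect_equal(s2$scale_factor, scaled$scale_factor / 2, tolerance = 1e-12)
  expect_equal(s2$patterns[[1]]$intensity, scaled$patterns[[1]]$intensity,
               tolerance = 1e-9)

  expect_error(scale_to_photons(ps, d_target = 100), "shell")
})

test_that("add_noise: identity, Poisson statistics, SNR calibration, determinism", {
  qm <- qm48()
  n_ok <- sum(qm$mask)

  # identity when everything is off
  p <- radial_test_pattern(qm)
  same <- add_noise(p, poisson = FALSE, snr = NULL, seed = 1)
  expect_equal(same$intensity, p$intensity)

  # Poisson mean: >= 1e4 pixels at I = 100
  det_big <- beam_detector(n_fast = 104L, n_slow = 104L, pixel_size = 0.26,
                           distance = 50)
  qb <- build_qmap(det_big)
  npix <- length(qb$qmag)
  expect_gt(npix, 1e4)
  pb <- spidock:::new_pattern(rep(100, npix), c(0, 0, 0))
  noisy <- add_noise(pb, poisson = TRUE, snr = NULL, seed = 2)
  expect_lt(abs(mean(noisy$intensity) - 100), 3 * sqrt(100 / npix))

  # SNR sweep: measured background variance within 10% of Var(signal)/snr.
  # A bright baseline keeps zero-clipping negligible so the variance of the
  # added background is measured cleanly.
  set.seed(33)
  bright <- spidock:::new_pattern(runif(npix, 1000, 1400), c(0, 0, 0))
  vsig <- var(bright$intensity)
  for (snr in c(100, 10, 1, 0.1)) {
    ns <- add_noise(bright, poisson = FALSE, snr = snr, seed = 7)
    added <- ns$intensity - bright$intensity
    expect_lt(abs(var(added) / (vsig / snr) - 1), 0.10)
  }

  # clipped at zero, deterministic under seed
  ns1 <- add_noise(bright, poisson = TRUE, snr = 1, seed = 5)
  ns2 <- add_noise(bright, poisson = TRUE, snr = 1, seed = 5)
  expect_identical(ns1$intensity, ns2$intensity)
  expect_true(all(ns1$intensity >= 0))
  expect_error(add_noise(bright, snr = -2), "snr")
})
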