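#' Euler-angle rotation matrix
#'
#' Euler angles `(alpha, beta, gamma)` in degrees, active extrinsic z-y-z
#' convention: the model is rotated by `alpha` about the lab z axis, then by
#' `beta` about the lab y axis, then by `gamma` about the lab z axis, i.e.
#' `R = Rz(gamma) Ry(beta) Rz(alpha)`.  With the beam along +z, the last
#' angle `gamma` is an in-plane rotation of the diffraction pattern, and
#' `beta` is the tilt (polar) angle; the angular auto-correlation and radial
#' reductions are therefore independent of `gamma`.
#'
#' @param alpha,beta,gamma Euler angles, degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
euler_matrix <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  d <- pi / 180
  rz(gamma * d) %*% ry(beta * d) %*% rz(alpha * d)
}

#' Structure factor by direct summation
#'
#' Computes `F(q) = sum_j f_j(|q|) exp(i q . r_j)` over all atoms of the
#' model, with `f_j` the tabulated atomic scattering factor.  This is the
#' exact coherent sum of scattered wavefunctions from the atomic point
#' model; no polarization, solid-angle or absorption corrections are
#' applied.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param qvecs n x 3 matrix of momentum-transfer vectors, 1/Angstrom.
#' @return Complex vector of structure factors, one per q vector.
#' @export
structure_factor <- function(model, qvecs) {
  if (inherits(model, "complex_model")) model <- merge_subunits(model)
  stopifnot(inherits(model, "atomic_model"))
  qvecs <- as.matrix(qvecs)
  if (ncol(qvecs) != 3L) stop("'qvecs' must be n x 3")
  if (!all(is.finite(qvecs))) stop("q vectors must be finite")
  qmag <- sqrt(rowSums(qvecs^2))
  Fre <- numeric(nrow(qvecs))
  Fim <- numeric(nrow(qvecs))
  for (el in unique(model$elements)) {
    sel <- model$elements == el
    ph <- qvecs %*% t(model$coords[sel, , drop = FALSE])
    f <- form_factor(el, qmag)
    Fre <- Fre + f * rowSums(cos(ph))
    Fim <- Fim + f * rowSums(sin(ph))
  }
  complex(real = Fre, imaginary = Fim)
}

#' Precompute a fast per-orientation pattern simulator
#'
#' Factors the orientation-independent parts of the direct summation — the
#' per-pixel atomic scattering factors of each element and the usable-pixel
#' q vectors — out of the per-pattern work, so that banks and large pattern
#' sets can be simulated cheaply.  `simulate_pattern()` and the returned
#' closure produce identical intensities.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param qmap A `qmap`.
#' @param sigma_floor Per-pixel sigma floor, photons.
#' @return A function `(orientation) -> pattern`.
#' @export
pattern_simulator <- function(model, qmap, sigma_floor = 1) {
  amp <- amplitude_simulator(model, qmap)
  mask <- qmap$mask
  npix <- length(qmap$qmag)
  function(orientation) {
    Fm <- amp(orientation)
    intens <- rep(NA_real_, npix)
    intens[mask] <- Re(Fm)^2 + Im(Fm)^2
    new_pattern(intens, orientation, sigma_floor = sigma_floor)
  }
}

#' Precompute a per-orientation structure-factor (amplitude) simulator
#'
#' Like [pattern_simulator()] but returning complex structure factors on the
#' usable pixels.  Amplitudes of rigid parts are additive, so the fixed
#' subunit of a decoy series can be simulated once and combined with each
#' decoy's mobile-subunit amplitudes (see [spi_score_decoy_set()]).
#'
#' @inheritParams pattern_simulator
#' @return A function `(orientation) -> complex vector` over `qmap$mask`
#'   pixels.
#' @export
amplitude_simulator <- function(model, qmap) {
  if (inherits(model, "complex_model")) model <- merge_subunits(model)
  stopifnot(inherits(model, "atomic_model"), inherits(qmap, "qmap"))
  Qm <- qmap$qvecs[qmap$mask, , drop = FALSE]
  qmag <- qmap$qmag[qmap$mask]
  els <- unique(model$elements)
  G <- vapply(els, function(e) as.numeric(model$elements == e),
              numeric(n_atoms(model)))                # atoms x elements
  FM <- vapply(els, function(e) form_factor(e, qmag),
               numeric(length(qmag)))                 # pixels x elements
  coords <- model$coords
  function(orientation) {
    R <- euler_matrix(orientation[1], orientation[2], orientation[3])
    ph <- Qm %*% t(coords %*% t(R))
    complex(real = rowSums((cos(ph) %*% G) * FM),
            imaginary = rowSums((sin(ph) %*% G) * FM))
  }
}

#' Simulate one noise-free scattering pattern
#'
#' Rotates the model actively by the Euler triple (see [euler_matrix()]) and
#' evaluates the scattering intensity `I(q) = |F(q)|^2` on the Ewald-sphere
#' q map.  Masked pixels are set to `NA`.  The returned pattern carries a
#' provisional `sigma = sqrt(I)` floored at `sigma_floor`; the photon-budget
#' scaling step recomputes it on the photon scale.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param orientation Length-3 Euler triple `(alpha, beta, gamma)`, degrees.
#' @param qmap A `qmap` from [build_qmap()].
#' @param sigma_floor Lower bound for per-pixel standard deviations
#'   (photons); 1 photon by default, the Poisson sigma of the smallest
#'   countable signal.
#' @return A `pattern`: list with `intensity`, `sigma` (per pixel, masked
#'   pixels NA), `orientation`, `noise_meta`.
#' @export
simulate_pattern <- function(model, orientation, qmap, sigma_floor = 1) {
  stopifnot(inherits(qmap, "qmap"), length(orientation) == 3L)
  if (inherits(model, "complex_model")) model <- merge_subunits(model)
  R <- euler_matrix(orientation[1], orientation[2], orientation[3])
  rotated <- atomic_model(model$elements, model$coords %*% t(R), model$label)
  intens <- rep(NA_real_, length(qmap$qmag))
  Fm <- structure_factor(rotated, qmap$qvecs[qmap$mask, , drop = FALSE])
  intens[qmap$mask] <- Re(Fm)^2 + Im(Fm)^2
  new_pattern(intens, orientation, sigma_floor = sigma_floor)
}

new_pattern <- function(intensity, orientation,
                        noise_meta = list(poisson = FALSE, snr = NULL,
                                          seed = NULL),
                        sigma_floor = 1) {
  structure(list(intensity = intensity,
                 sigma = pmax(sqrt(pmax(intensity, 0)), sigma_floor),
                 orientation = as.numeric(orientation),
                 noise_meta = noise_meta),
            class = "pattern")
}

#' Collect patterns sharing one q map into a set
#'
#' @param patterns List of `pattern` objects of identical length.
#' @param qmap The shared `qmap`.
#' @param source_label Free-text provenance label.
#' @return A `pattern_set`.
#' @export
pattern_set <- function(patterns, qmap, source_label = "") {
  stopifnot(length(patterns) >= 1L, inherits(qmap, "qmap"))
  len <- lengths(lapply(patterns, `[[`, "intensity"))
  if (length(unique(len)) != 1L || len[1] != length(qmap$qmag))
    stop("all patterns must match the qmap pixel count")
  structure(list(patterns = patterns, qmap = qmap,
                 source_label = source_label,
                 scale_factor = NA_real_),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set '%s': %d patterns x %d pixels\n", x$source_label,
              length(x$patterns), length(x$qmap$qmag)))
  invisible(x)
}

#' Orientation matrix of a pattern set
#' @param ps A `pattern_set`.
#' @return N x 3 matrix of Euler triples, degrees.
#' @export
orientations <- function(ps) {
  do.call(rbind, lapply(ps$patterns, `[[`, "orientation"))
}

#' Simulate a set of patterns at given orientations
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param oris N x 3 matrix of Euler triples, degrees.
#' @param qmap A `qmap`.
#' @param source_label Provenance label.
#' @inheritParams simulate_pattern
#' @return A `pattern_set` of noise-free patterns.
#' @export
simulate_pattern_set <- function(model, oris, qmap, source_label = "",
                                 sigma_floor = 1) {
  oris <- as.matrix(oris)
  sim <- pattern_simulator(model, qmap, sigma_floor = sigma_floor)
  pats <- lapply(seq_len(nrow(oris)), function(i) sim(oris[i, ]))
  pattern_set(pats, qmap, source_label)
}

#' Draw random particle orientations
#'
#' Two samplers: `"so3"` draws uniformly on the rotation group (alpha and
#' gamma uniform on the circle, cos(beta) uniform), which is the physical
#' model of randomly tumbling particles; `"per_angle"` draws each Euler
#' angle independently and uniformly within its bounds, which matches
#' confined-subspace experiments but is *not* uniform on SO(3).
#'
#' @param n Number of orientations.
#' @param bounds List with `alpha`, `beta`, `gamma` 2-vectors (degrees), or
#'   NULL for the full ranges.
#' @param sampler `"so3"` or `"per_angle"`.
#' @param seed Integer RNG seed, or NULL to use the current RNG stream.
#' @return n x 3 matrix of Euler triples, degrees.
#' @export
random_orientations <- function(n, bounds = NULL,
                                sampler = c("so3", "per_angle"),
                                seed = NULL) {
  sampler <- match.arg(sampler)
  if (is.null(bounds))
    bounds <- list(alpha = c(0, 360), beta = c(0, 180), gamma = c(0, 360))
  draw <- function() {
    if (sampler == "so3") {
      cb <- stats::runif(n, cos(bounds$beta[2] * pi / 180),
                         cos(bounds$beta[1] * pi / 180))
      beta <- acos(cb) * 180 / pi
    } else {
      beta <- stats::runif(n, bounds$beta[1], bounds$beta[2])
    }
    cbind(alpha = stats::runif(n, bounds$alpha[1], bounds$alpha[2]),
          beta = beta,
          gamma = stats::runif(n, bounds$gamma[1], bounds$gamma[2]))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Scale a pattern set to the reference photon budget
#'
#' Applies one global multiplicative factor (the role of the incident
#' intensity I0) chosen so that the mean intensity over all pixels of all
#' patterns in the resolution shell at `d_target` equals exactly 1 photon.
#' Per-pixel sigmas are reset to `sqrt(I)` floored at `sigma_floor`.
#'
#' @param ps A `pattern_set`.
#' @param d_target Target resolution shell, Angstrom (default 4).
#' @param shell_frac Relative half-width of the shell in `|q|` (default 3%).
#' @param photons Target shell mean (default 1).
#' @inheritParams simulate_pattern
#' @return The rescaled `pattern_set`; the factor applied is stored in
#'   `$scale_factor`.
#' @export
scale_to_photons <- function(ps, d_target = 4, shell_frac = 0.03,
                             photons = 1, sigma_floor = 1) {
  stopifnot(inherits(ps, "pattern_set"), d_target > 0, photons > 0)
  qt <- 2 * pi / d_target
  shell <- ps$qmap$mask & abs(ps$qmap$qmag - qt) <= shell_frac * qt
  if (!any(shell))
    stop("no unmasked pixels in the ", d_target, " A shell")
  shell_mean <- mean(vapply(ps$patterns,
                            function(p) mean(p$intensity[shell]),
                            numeric(1)))
  if (!is.finite(shell_mean) || shell_mean <= 0)
    stop("shell mean is not positive; cannot scale")
  fac <- photons / shell_mean
  ps$patterns <- lapply(ps$patterns, function(p) {
    p$intensity <- p$intensity * fac
    p$sigma <- pmax(sqrt(pmax(p$intensity, 0)), sigma_floor)
    p
  })
  ps$scale_factor <- fac
  ps
}

#' Add detection noise to a pattern
#'
#' Photon-counting (Poisson) noise is applied first when enabled; an
#' additive Gaussian background with variance `Var(signal)/snr` is then
#' added when `snr` is given, where `Var(signal)` is the variance of the
#' noise-free intensities of this pattern over usable pixels (SNR = signal
#' variance / noise variance).  Negative results are clipped to zero and
#' sigmas recomputed as `sqrt(I)` floored.
#'
#' @param p A `pattern`.
#' @param poisson Apply Poisson noise?
#' @param snr Signal-to-noise ratio for the Gaussian background, or NULL for
#'   none.
#' @param seed Integer RNG seed, or NULL to use the current RNG stream.
#' @inheritParams simulate_pattern
#' @return The noisy `pattern`.
#' @export
add_noise <- function(p, poisson = TRUE, snr = NULL, seed = NULL,
                      sigma_floor = 1) {
  stopifnot(inherits(p, "pattern"))
  if (!is.null(snr) && snr <= 0) stop("'snr' must be positive")
  ok <- !is.na(p$intensity)
  apply_noise <- function() {
    x <- p$intensity
    if (poisson) x[ok] <- stats::rpois(sum(ok), x[ok])
    if (!is.null(snr)) {
      vsig <- stats::var(p$intensity[ok])
      x[ok] <- x[ok] + stats::rnorm(sum(ok), 0, sqrt(vsig / snr))
    }
    x[ok] <- pmax(x[ok], 0)
    x
  }
  x <- if (is.null(seed)) apply_noise() else with_seed(seed, apply_noise())
  new_pattern(x, p$orientation,
              noise_meta = list(poisson = poisson, snr = snr, seed = seed),
              sigma_floor = sigma_floor)
}

#' Add noise to every pattern of a set
#'
#' Per-pattern seeds are derived deterministically from `seed` so the result
#' is reproducible and independent of evaluation order.
#'
#' @param ps A `pattern_set`.
#' @inheritParams add_noise
#' @return The noisy `pattern_set`.
#' @export
add_noise_set <- function(ps, poisson = TRUE, snr = NULL, seed = 1L,
                          sigma_floor = 1) {
  stopifnot(inherits(ps, "pattern_set"))
  ps$patterns <- lapply(seq_along(ps$patterns), function(i)
    add_noise(ps$patterns[[i]], poisson = poisson, snr = snr,
              seed = (seed + 104729L * i) %% .Machine$integer.max,
              sigma_floor = sigma_floor))
  ps
}

#' Save / load a pattern set
#'
#' Pattern sets are persisted as single RDS files carrying the full object
#' (q map, intensities, sigmas, orientations, noise metadata, scale factor).
#'
#' @param ps A `pattern_set`.
#' @param path File path.
#' @return `write_pattern_set` invisibly returns `path`;
#'   `read_pattern_set` returns the `pattern_set`.
#' @export
write_pattern_set <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_set"))
  saveRDS(ps, path)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  ps <- readRDS(path)
  if (!inherits(ps, "pattern_set")) stop("not a pattern_set file: ", path)
  ps
}
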