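## Reduced representations of patterns: (q, phi) polar resampling, radial
## (SAXS-like) profiles, and per-ring angular auto-correlation.

#' Equal-|q| radial binning of a q map
#'
#' Bins span (0, q_mask] in K equal steps; bin centers at midpoints.
#'
#' @param qmap A `qmap`.
#' @param n_bins Number of radial bins.
#' @return List with `breaks`, `q_centers`, and per-pixel `bin` index
#'   (NA for masked or out-of-range pixels).
#' @export
radial_bins <- function(qmap, n_bins = 30L) {
  stopifnot(inherits(qmap, "qmap"), n_bins >= 2L)
  qmax <- 2 * pi / qmap$det$d_min
  breaks <- seq(0, qmax, length.out = n_bins + 1L)
  bin <- findInterval(qmap$qmag, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  bin[!qmap$mask | bin < 1L | bin > n_bins] <- NA_integer_
  bin[qmap$qmag == 0] <- 1L
  list(breaks = breaks,
       q_centers = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       bin = bin)
}

#' Radial (SAXS-like) intensity profile
#'
#' Discretized angular average at fixed `|q|`: usable pixels are grouped
#' into equal-width `|q|` bins and averaged.  For a `pattern_set`, pixels of
#' all N patterns are pooled per bin, which realizes the aggregate
#' SAXS profile of the data.  Sigmas are propagated from photon statistics,
#' `sqrt(mean I / effective count)`, floored at
#' `sigma_floor / sqrt(effective count)`; empty bins are returned as NA.
#'
#' @param x A `pattern` or `pattern_set`.
#' @param qmap The shared `qmap` (taken from the set when `x` is one).
#' @param n_bins Number of radial bins.
#' @param bins Optional precomputed [radial_bins()] result.
#' @param sigma_floor Photon-count sigma floor.
#' @return A `radial_profile`: list with `q_centers`, `intensity`, `sigma`,
#'   `n_eff` (per-bin pixel counts).
#' @export
radial_profile <- function(x, qmap = NULL, n_bins = 30L, bins = NULL,
                           sigma_floor = 1) {
  if (inherits(x, "pattern_set")) {
    qmap <- x$qmap
    pats <- x$patterns
  } else if (inherits(x, "pattern")) {
    if (is.null(qmap)) stop("'qmap' required for a single pattern")
    pats <- list(x)
  } else stop("'x' must be a pattern or pattern_set")
  if (is.null(bins)) bins <- radial_bins(qmap, n_bins)
  nb <- length(bins$q_centers)
  ok <- !is.na(bins$bin)
  idx <- bins$bin[ok]
  sums <- numeric(nb); count <- numeric(nb)
  for (p in pats) {
    v <- p$intensity[ok]
    s <- rowsum(v, idx)
    sums[as.integer(rownames(s))] <- sums[as.integer(rownames(s))] + s[, 1L]
    count <- count + tabulate(idx, nbins = nb)
  }
  mean_i <- ifelse(count > 0, sums / count, NA_real_)
  sig <- ifelse(count > 0,
                pmax(sqrt(pmax(mean_i, 0) / count),
                     sigma_floor / sqrt(count)),
                NA_real_)
  structure(list(q_centers = bins$q_centers, intensity = mean_i,
                 sigma = sig, n_eff = count),
            class = "radial_profile")
}

#' Build a polar resampler for a detector
#'
#' Precomputes bilinear-interpolation weights mapping a Cartesian pattern
#' onto K rings of constant `|q|` times B azimuth samples.  Ring radii are
#' the [radial_bins()] centers mapped to detector radius through the Ewald
#' geometry; azimuth samples start at phi = 0 along the fast axis and run
#' counter-clockwise.  Rings with any sample falling outside the usable
#' detector area are flagged unusable.
#'
#' @param qmap A `qmap`.
#' @param n_qbins Number of rings K.
#' @param n_phibins Number of azimuth samples B per ring.
#' @return A `polar_sampler` with sparse weights `W` ((K*B) x n_pixels),
#'   `q_centers`, `phi` (radians), logical `ring_ok`.
#' @export
polar_sampler <- function(qmap, n_qbins = 20L, n_phibins = 64L) {
  stopifnot(inherits(qmap, "qmap"), n_qbins >= 2L, n_phibins >= 2L)
  det <- qmap$det
  rb <- radial_bins(qmap, n_qbins)
  theta <- asin(pmin(1, rb$q_centers * det$wavelength / (4 * pi)))
  r_mm <- det$distance * tan(2 * theta)
  r_px <- r_mm / det$pixel_size
  phi <- (seq_len(n_phibins) - 1L) * 2 * pi / n_phibins
  sx <- as.numeric(outer(cos(phi), r_px)) + det$beam_center[1]  # B x K
  sy <- as.numeric(outer(sin(phi), r_px)) + det$beam_center[2]
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  inside <- i0 >= 0 & j0 >= 0 & i0 + 1 <= det$n_fast - 1 &
    j0 + 1 <= det$n_slow - 1
  pix <- function(i, j) i + j * det$n_fast + 1L  # fast-axis-major, 1-based
  ns <- length(sx)
  rows <- rep(seq_len(ns), 4L)
  cols <- rep(1L, 4L * ns); w <- numeric(4L * ns)
  ii <- which(inside)
  corner <- function(di, dj, wt, k) {
    cols[(k - 1L) * ns + ii] <<- pix(i0[ii] + di, j0[ii] + dj)
    w[(k - 1L) * ns + ii] <<- wt[ii]
  }
  corner(0L, 0L, (1 - fx) * (1 - fy), 1L)
  corner(1L, 0L, fx * (1 - fy), 2L)
  corner(0L, 1L, (1 - fx) * fy, 3L)
  corner(1L, 1L, fx * fy, 4L)
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = w,
                            dims = c(ns, length(qmap$qmag)))
  # a sample is valid if inside the detector and all its stencil pixels are
  # unmasked; a ring is usable only if all its samples are valid
  stencil_ok <- inside
  for (k in 1:4) {
    cid <- cols[(k - 1L) * ns + seq_len(ns)]
    stencil_ok <- stencil_ok & qmap$mask[cid]
  }
  ring_ok <- vapply(seq_len(n_qbins), function(k)
    all(stencil_ok[(k - 1L) * n_phibins + seq_len(n_phibins)]), logical(1))
  structure(list(W = W, q_centers = rb$q_centers, phi = phi,
                 n_qbins = n_qbins, n_phibins = n_phibins,
                 ring_ok = ring_ok),
            class = "polar_sampler")
}

#' Resample a pattern onto the polar (q, phi) grid
#'
#' @param p A `pattern` (or bare intensity vector).
#' @param sampler A [polar_sampler()].
#' @return Matrix K x B of interpolated intensities; unusable rings are NA.
#' @export
to_polar <- function(p, sampler) {
  stopifnot(inherits(sampler, "polar_sampler"))
  v <- if (inherits(p, "pattern")) p$intensity else as.numeric(p)
  v[is.na(v)] <- 0
  s <- as.numeric(sampler$W %*% v)
  m <- matrix(s, nrow = sampler$n_qbins, ncol = sampler$n_phibins,
              byrow = TRUE)
  m[!sampler$ring_ok, ] <- NA_real_
  m
}

#' Angular auto-correlation of a pattern
#'
#' Per ring of constant `|q|`, the circular autocorrelation over azimuth,
#' `AC(q, dphi) = sum_phi I(q, phi) I(q, phi + dphi) * (2 pi / B)`,
#' a discretization of the continuous angular auto-correlation integral.
#' The AC is invariant under in-plane rotation of the pattern, which is what
#' makes it useful for orientation matching without sampling the in-plane
#' angle.  Computed by FFT; agrees with the direct double loop to machine
#' precision.
#'
#' @param p A `pattern` or a K x B polar matrix from [to_polar()].
#' @param sampler A [polar_sampler()] (required when `p` is a pattern).
#' @return An `ac_pattern`: list with `q_centers`, `dphi` (radians), and
#'   `ac` (K x B matrix; unusable rings NA).
#' @export
auto_correlation <- function(p, sampler = NULL) {
  if (inherits(p, "pattern")) {
    if (is.null(sampler)) stop("'sampler' required for a pattern")
    m <- to_polar(p, sampler)
    qc <- sampler$q_centers
  } else {
    m <- as.matrix(p)
    qc <- if (!is.null(sampler)) sampler$q_centers else
      seq_len(nrow(m))
  }
  B <- ncol(m)
  dphi_bin <- 2 * pi / B
  ac <- t(apply(m, 1L, function(x) {
    if (anyNA(x)) return(rep(NA_real_, B))
    Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE)) / B * dphi_bin
  }))
  structure(list(q_centers = qc, dphi = (seq_len(B) - 1L) * dphi_bin,
                 ac = ac),
            class = "ac_pattern")
}
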