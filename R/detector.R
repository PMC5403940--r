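#' Beam and detector geometry
#'
#' Describes a flat 2D photon-counting detector downstream of the sample,
#' with the incident beam along +z.  The default geometry (128 x 128 pixels
#' of 0.2 mm at 49 mm with a 1.0 Angstrom beam) places the detector edge just
#' beyond 4 Angstrom resolution, the highest measurable shell used
#' throughout this package (resolution convention d = 2 pi / q).
#'
#' @param wavelength X-ray wavelength, Angstrom.
#' @param distance Sample-detector distance, mm.
#' @param pixel_size Pixel edge, mm.
#' @param n_fast,n_slow Pixel counts along the fast and slow axes.
#' @param beam_center Length-2 beam center in (possibly fractional) pixel
#'   units, 0-based; defaults to the detector center.
#' @param d_min Requested highest resolution, Angstrom; pixels beyond
#'   `q = 2 pi / d_min` are masked out.  The geometry must reach `d_min` at
#'   the detector edge or construction fails.
#' @return A `beam_detector` object.
#' @export
beam_detector <- function(wavelength = 1.0, distance = 49, pixel_size = 0.2,
                          n_fast = 128L, n_slow = 128L,
                          beam_center = NULL, d_min = 4.0) {
  stopifnot(wavelength > 0, distance > 0, pixel_size > 0, d_min > 0,
            n_fast >= 2L, n_slow >= 2L)
  if (is.null(beam_center))
    beam_center <- c((n_fast - 1) / 2, (n_slow - 1) / 2)
  stopifnot(length(beam_center) == 2L)
  det <- structure(list(wavelength = wavelength, distance = distance,
                        pixel_size = pixel_size,
                        n_fast = as.integer(n_fast),
                        n_slow = as.integer(n_slow),
                        beam_center = as.numeric(beam_center),
                        d_min = d_min),
                   class = "beam_detector")
  # farthest pixel center from the beam center, mm
  dx <- (c(0, det$n_fast - 1) - beam_center[1]) * pixel_size
  dy <- (c(0, det$n_slow - 1) - beam_center[2]) * pixel_size
  r_edge <- sqrt(max(dx^2) + max(dy^2))
  q_edge <- 4 * pi * sin(atan2(r_edge, distance) / 2) / wavelength
  if (q_edge < 2 * pi / d_min)
    stop(sprintf(paste0("detector edge reaches only d = %.2f A; requested ",
                        "d_min = %.2f A"), 2 * pi / q_edge, d_min))
  det
}

#' @export
print.beam_detector <- function(x, ...) {
  cat(sprintf(paste0("beam_detector: %dx%d px (%.3g mm) at %.3g mm, ",
                     "lambda %.3g A, d_min %.3g A\n"),
              x$n_fast, x$n_slow, x$pixel_size, x$distance, x$wavelength,
              x$d_min))
  invisible(x)
}

#' Map detector pixels onto the Ewald sphere
#'
#' For each pixel center, the unit scattered direction `k0` from sample to
#' pixel is computed and the momentum transfer taken as
#' `q = (2 pi / lambda) (k0 - ki)` with `ki` the unit incident direction
#' along +z (full Ewald curvature, not a flat-detector approximation).  Its
#' magnitude satisfies `|q| = 4 pi sin(theta) / lambda` with `2 theta` the
#' scattering angle.  Pixels with `|q| > 2 pi / d_min` are masked.
#'
#' @param det A `beam_detector`.
#' @return A `qmap`: list with `qvecs` (n_pixels x 3, 1/Angstrom, pixel order
#'   fast-axis-major), `qmag`, logical `mask` (TRUE = usable), the pixel
#'   coordinates `px`, `py` (0-based), and the generating `det`.
#' @export
build_qmap <- function(det) {
  stopifnot(inherits(det, "beam_detector"))
  px <- rep(seq_len(det$n_fast) - 1L, times = det$n_slow)
  py <- rep(seq_len(det$n_slow) - 1L, each = det$n_fast)
  x <- (px - det$beam_center[1]) * det$pixel_size
  y <- (py - det$beam_center[2]) * det$pixel_size
  z <- det$distance
  nrm <- sqrt(x^2 + y^2 + z^2)
  k0 <- cbind(x / nrm, y / nrm, z / nrm)
  qvecs <- (2 * pi / det$wavelength) * sweep(k0, 2L, c(0, 0, 1))
  qmag <- sqrt(rowSums(qvecs^2))
  mask <- qmag <= 2 * pi / det$d_min
  structure(list(qvecs = qvecs, qmag = qmag, mask = mask,
                 px = px, py = py, det = det),
            class = "qmap")
}

#' @export
print.qmap <- function(x, ...) {
  cat(sprintf("qmap: %d pixels, %d usable (q <= %.4g 1/A)\n",
              length(x$qmag), sum(x$mask), 2 * pi / x$det$d_min))
  invisible(x)
}
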