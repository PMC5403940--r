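#' Construct an atomic model
#'
#' An `atomic_model` is an element-typed point set: one row of Cartesian
#' coordinates (Angstrom) per atom, plus an element symbol per atom.  It is
#' the minimal structural representation needed for scattering simulation and
#' density rasterization; occupancies, B-factors and hydrogens are not
#' carried.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix, n_atoms x 3, Angstrom.
#' @param label Free-text identifier.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("'coords' must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("model must contain at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  elements <- .norm_element(as.character(elements))
  if (length(elements) != nrow(coords))
    stop("one element symbol required per atom")
  atomic_number(elements)  # validates every symbol is parameterized
  dimnames(coords) <- NULL
  structure(list(elements = elements, coords = coords,
                 label = as.character(label)[1L]),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model '%s': %d atoms (%s)\n", x$label, n_atoms(x),
              paste(sprintf("%s:%d", names(table(x$elements)),
                            as.integer(table(x$elements))), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a model
#' @param model An `atomic_model` or `complex_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) {
  if (inherits(model, "complex_model"))
    return(n_atoms(model$fixed) + n_atoms(model$mobile))
  nrow(model$coords)
}

#' Center of mass of a model
#'
#' Electron-count-weighted centroid, consistent with the electron-density
#' view of the structure taken throughout the package.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @return Length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(model) {
  if (inherits(model, "complex_model")) model <- merge_subunits(model)
  w <- atomic_number(model$elements)
  colSums(model$coords * w) / sum(w)
}

#' Two-subunit complex model
#'
#' Represents a binary complex in the docking convention: the first subunit
#' is held fixed (it defines the laboratory frame) and the second is the
#' mobile partner that rigid-body decoy generation perturbs.
#'
#' @param fixed,mobile `atomic_model` subunits.
#' @param label Free-text identifier.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(fixed, mobile, label = "") {
  stopifnot(inherits(fixed, "atomic_model"), inherits(mobile, "atomic_model"))
  structure(list(fixed = fixed, mobile = mobile,
                 label = as.character(label)[1L]),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("complex_model '%s': fixed %d + mobile %d atoms\n",
              x$label, n_atoms(x$fixed), n_atoms(x$mobile)))
  invisible(x)
}

#' Flatten a complex into a single atomic model
#'
#' Fixed-subunit atoms come first, mobile-subunit atoms second; this ordering
#' is relied upon by the RMSD convention.
#'
#' @param cx A `complex_model`.
#' @return An `atomic_model`.
#' @export
merge_subunits <- function(cx) {
  stopifnot(inherits(cx, "complex_model"))
  atomic_model(c(cx$fixed$elements, cx$mobile$elements),
               rbind(cx$fixed$coords, cx$mobile$coords),
               label = cx$label)
}

#' Rigid-body transform
#'
#' @param rotation 3 x 3 rotation matrix (determinant +1).
#' @param translation Length-3 numeric vector, Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a model
#'
#' Coordinates map as `x -> R x + t` (active convention).  An optional pivot
#' rotates about a point other than the origin.
#'
#' @param model An `atomic_model`.
#' @param tf A `rigid_transform`.
#' @param pivot Optional length-3 rotation center, Angstrom.
#' @return The transformed `atomic_model`.
#' @export
apply_transform <- function(model, tf, pivot = NULL) {
  stopifnot(inherits(model, "atomic_model"), inherits(tf, "rigid_transform"))
  xyz <- model$coords
  if (!is.null(pivot)) xyz <- sweep(xyz, 2L, pivot)
  xyz <- xyz %*% t(tf$rotation)
  if (!is.null(pivot)) xyz <- sweep(xyz, 2L, pivot, "+")
  xyz <- sweep(xyz, 2L, tf$translation, "+")
  atomic_model(model$elements, xyz, model$label)
}

## run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## uniform random unit 3-vectors (draws from the current RNG stream)
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## rotation matrix from axis (unit 3-vector) and angle (radians), Rodrigues
axis_angle_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a toy two-subunit complex
#'
#' Builds a compact pseudo-random "protein-like" complex for simulation
#' studies: two tangent spheres of uniformly placed points with a C/N/O
#' composition typical of protein heavy atoms (63/16/21 percent) and a mean
#' heavy-atom density of 0.05 atoms per cubic Angstrom.  Each subunit is
#' recentered so its center of mass sits exactly at its nominal sphere
#' center; the mobile subunit's center of mass therefore lies at exactly
#' `r_fixed + r_mobile` Angstrom from the fixed subunit's along +x (returned
#' in attribute `"separation"`).
#'
#' @param n_fixed,n_mobile Atom counts of the two subunits.
#' @param seed Integer RNG seed; the output is a pure function of the inputs.
#' @return A `complex_model` with attribute `"separation"`.
#' @export
make_toy_complex <- function(n_fixed = 50L, n_mobile = 30L, seed = 1L) {
  stopifnot(n_fixed >= 1L, n_mobile >= 1L)
  density <- 0.05                     # heavy atoms / A^3
  radius <- function(n) (3 * n / (4 * pi * density))^(1 / 3)
  sphere_points <- function(n, r) {
    u <- stats::runif(n)^(1 / 3) * r  # uniform in the ball
    runif_sphere(n) * u
  }
  draw_elements <- function(n)
    sample(c("C", "N", "O"), n, replace = TRUE, prob = c(0.63, 0.16, 0.21))
  with_seed(seed, {
    r1 <- radius(n_fixed); r2 <- radius(n_mobile)
    e1 <- draw_elements(n_fixed); e2 <- draw_elements(n_mobile)
    x1 <- sphere_points(n_fixed, r1)
    x2 <- sphere_points(n_mobile, r2)
    m1 <- atomic_model(e1, x1, "fixed")
    m1$coords <- sweep(m1$coords, 2L, center_of_mass(m1))
    m2 <- atomic_model(e2, x2, "mobile")
    sep <- r1 + r2
    m2$coords <- sweep(sweep(m2$coords, 2L, center_of_mass(m2)),
                       2L, c(sep, 0, 0), "+")
    out <- complex_model(m1, m2, sprintf("toy_%d_%d_s%d", n_fixed, n_mobile,
                                         seed))
    attr(out, "separation") <- sep
    out
  })
}
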