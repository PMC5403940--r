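#' Discretized Euler-angle grid
#'
#' Cartesian product of per-angle linspaces with one common step.  A full
#' 360-degree interval is sampled half-open (both endpoints would be the
#' same rotation); any narrower interval — in particular the confined
#' proof-of-principle subspace `-22.5 <= alpha, beta, gamma <= 22.5` — is
#' sampled inclusive of both endpoints.  The step must divide each interval.
#'
#' @param step Grid step, degrees.
#' @param bounds List with `alpha`, `beta`, `gamma` 2-vectors (degrees).
#'   Defaults to full SO(3): alpha, gamma in `[0, 360)`, beta in `[0, 180]`.
#' @return An `orientation_grid`: list with `triples` (n x 3 matrix, columns
#'   alpha/beta/gamma), `step`, `bounds`.
#' @export
make_grid <- function(step, bounds = NULL) {
  stopifnot(step > 0)
  if (is.null(bounds))
    bounds <- list(alpha = c(0, 360), beta = c(0, 180), gamma = c(0, 360))
  axis_vals <- function(b) {
    width <- b[2] - b[1]
    if (width < 0) stop("invalid bounds")
    if (width == 0) return(b[1])
    k <- width / step
    if (abs(k - round(k)) > 1e-9)
      stop(sprintf("step %.6g does not divide the interval [%.6g, %.6g]",
                   step, b[1], b[2]))
    if (abs(width - 360) < 1e-9) seq(b[1], b[2] - step, by = step)
    else seq(b[1], b[2], by = step)
  }
  av <- axis_vals(bounds$alpha)
  bv <- axis_vals(bounds$beta)
  gv <- axis_vals(bounds$gamma)
  g <- expand.grid(alpha = av, beta = bv, gamma = gv,
                   KEEP.OUT.ATTRS = FALSE)
  structure(list(triples = as.matrix(g), step = step, bounds = bounds),
            class = "orientation_grid")
}

#' Symmetric confined-subspace bounds
#'
#' @param half Half-width in degrees (default 22.5, the proof-of-principle
#'   subspace).
#' @return A bounds list for [make_grid()].
#' @export
subspace_bounds <- function(half = 22.5) {
  list(alpha = c(-half, half), beta = c(-half, half), gamma = c(-half, half))
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("orientation_grid: %d triples, step %.3g deg\n",
              nrow(x$triples), x$step))
  invisible(x)
}

#' Build a reference bank of model patterns
#'
#' Simulates noise-free patterns of the model at every grid orientation and
#' stores them in the requested representation.  Raw banks keep the usable
#' pixels of each pattern (one entry per grid triple).  For the reduced
#' representations (`"ac"`, `"radial"`) the in-plane angle gamma does not
#' affect the representation, so only the unique `(alpha, beta)` pairs are
#' simulated (at gamma = 0) and the bank size drops from n^3 to n^2.
#' Bank intensities are multiplied by `scale_factor` so they live on the
#' same photon scale as the experimental set they will be matched against.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param grid An `orientation_grid`.
#' @param qmap A `qmap`.
#' @param representation `"raw"`, `"ac"` or `"radial"`.
#' @param scale_factor Global photon scale factor of the experimental set.
#' @param sampler A [polar_sampler()] for the `"ac"` representation
#'   (required); also used by `"radial"` when `bins` is NULL.
#' @param n_bins Radial bin count for the `"radial"` representation.
#' @param sigma_floor Photon-count sigma floor.
#' @return A `reference_bank`: list with `grid` (possibly gamma-collapsed),
#'   `representation`, `features` (n_features x n_entries matrix), plus the
#'   reduction settings.
#' @export
build_bank <- function(model, grid, qmap,
                       representation = c("raw", "ac", "radial"),
                       scale_factor = 1, sampler = NULL, n_bins = 30L,
                       sigma_floor = 1) {
  representation <- match.arg(representation)
  stopifnot(inherits(grid, "orientation_grid"), inherits(qmap, "qmap"))
  triples <- grid$triples
  if (representation != "raw") {
    ab <- unique(triples[, c("alpha", "beta"), drop = FALSE])
    triples <- cbind(ab, gamma = NA_real_)
  }
  if (representation == "ac" && is.null(sampler))
    stop("'sampler' is required for the ac representation")
  bins <- if (representation == "radial") radial_bins(qmap, n_bins) else NULL
  sim <- pattern_simulator(model, qmap, sigma_floor = sigma_floor)
  feat_of <- function(ori) {
    o <- ori; if (is.na(o[3])) o[3] <- 0
    p <- sim(o)
    p$intensity <- p$intensity * scale_factor
    switch(representation,
           raw = p$intensity[qmap$mask],
           radial = radial_profile(p, qmap, bins = bins,
                                   sigma_floor = sigma_floor)$intensity,
           ac = {
             a <- auto_correlation(to_polar(p, sampler), sampler)
             as.numeric(t(a$ac[!is.na(a$ac[, 1L]), , drop = FALSE]))
           })
  }
  f1 <- feat_of(triples[1L, ])
  features <- matrix(NA_real_, nrow = length(f1), ncol = nrow(triples))
  features[, 1L] <- f1
  if (nrow(triples) > 1L)
    for (i in 2:nrow(triples)) features[, i] <- feat_of(triples[i, ])
  keep <- !is.na(features[, 1L])
  structure(list(grid = grid, triples = triples,
                 representation = representation,
                 features = features[keep, , drop = FALSE],
                 feature_keep = keep,
                 scale_factor = scale_factor, sampler = sampler,
                 bins = bins, sigma_floor = sigma_floor,
                 qmap = qmap),
            class = "reference_bank")
}

#' @export
print.reference_bank <- function(x, ...) {
  cat(sprintf("reference_bank (%s): %d entries x %d features\n",
              x$representation, ncol(x$features), nrow(x$features)))
  invisible(x)
}

## experimental pattern -> (features, sigmas) in the bank's representation.
## The chi denominator always derives from the *experimental* side, mapped
## through the same reduction; photon-statistics form, floored.
.reduce_exp <- function(p, bank) {
  switch(bank$representation,
         raw = {
           list(e = p$intensity[bank$qmap$mask],
                s = p$sigma[bank$qmap$mask])
         },
         radial = {
           pr <- radial_profile(p, bank$qmap, bins = bank$bins,
                                sigma_floor = bank$sigma_floor)
           list(e = pr$intensity[bank$feature_keep],
                s = pr$sigma[bank$feature_keep])
         },
         ac = {
           a <- auto_correlation(to_polar(p, bank$sampler), bank$sampler)
           ok <- !is.na(a$ac[, 1L])
           e <- as.numeric(t(a$ac[ok, , drop = FALSE]))
           list(e = e, s = pmax(sqrt(abs(e)), bank$sigma_floor))
         })
}

#' Match one experimental pattern against a reference bank
#'
#' Evaluates the chi-score of the experimental pattern against every bank
#' entry — mean over features of `((I_bank - I_exp) / sigma_exp)^2` — and
#' returns the minimizing grid orientation.  Ties are broken by the lowest
#' flat grid index.
#'
#' @param exp_pattern A `pattern`.
#' @param bank A `reference_bank`.
#' @return A one-row data frame: alpha, beta, gamma, chi, chi_runner_up,
#'   comparisons.
#' @export
match_pattern <- function(exp_pattern, bank) {
  stopifnot(inherits(exp_pattern, "pattern"),
            inherits(bank, "reference_bank"))
  if (ncol(bank$features) == 0L) stop("empty reference bank")
  r <- .reduce_exp(exp_pattern, bank)
  chi <- colMeans(((bank$features - r$e) / r$s)^2)
  best <- which.min(chi)
  runner <- if (length(chi) > 1L) min(chi[-best]) else NA_real_
  data.frame(alpha = unname(bank$triples[best, "alpha"]),
             beta = unname(bank$triples[best, "beta"]),
             gamma = unname(bank$triples[best, "gamma"]),
             chi = unname(chi[best]), chi_runner_up = runner,
             comparisons = length(chi))
}

#' Geodesic distance between two orientations
#'
#' The rotation angle of `R(a)^T R(b)`, in degrees — the natural metric on
#' the rotation group.  Euler triples are only a chart on SO(3): at the
#' `beta = 0` pole the z-y-z parameterization is degenerate (only
#' `alpha + gamma` is identifiable), so per-angle differences overstate the
#' true orientation error there, while this metric does not.
#'
#' @param a,b Euler triples (degrees) or 3 x 3 rotation matrices.
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_distance <- function(a, b) {
  Ra <- if (is.matrix(a) && all(dim(a) == 3L)) a
        else euler_matrix(a[1], a[2], a[3])
  Rb <- if (is.matrix(b) && all(dim(b) == 3L)) b
        else euler_matrix(b[1], b[2], b[3])
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Geodesic radius of the one-grid-step neighborhood of an orientation
#'
#' The largest [rotation_distance()] between `triple` and any of the 26
#' triples obtained by shifting each Euler angle by at most one grid step.
#' "Recovered within one grid step per angle" is then the chart-independent
#' statement `rotation_distance(true, recovered) <= one_step_radius(true,
#' step)`.
#'
#' @param triple Euler triple, degrees.
#' @param step Grid step, degrees.
#' @return Distance in degrees.
#' @export
one_step_radius <- function(triple, step) {
  offs <- expand.grid(da = c(-step, 0, step), db = c(-step, 0, step),
                      dg = c(-step, 0, step))
  max(apply(offs, 1L, function(d)
    rotation_distance(triple, triple + as.numeric(d))))
}

#' Match every pattern of a set against a bank
#'
#' @param exps A `pattern_set`.
#' @param bank A `reference_bank`.
#' @return A `match_result` data frame (one row per pattern, plus
#'   `pattern_id`), with attribute `"total_comparisons"` — the number of
#'   pattern-to-entry chi evaluations, which scales as `n^3 * M` for raw
#'   banks and `n^2 * M` for the reduced representations.
#' @export
match_set <- function(exps, bank) {
  stopifnot(inherits(exps, "pattern_set"))
  rows <- lapply(exps$patterns, match_pattern, bank = bank)
  out <- do.call(rbind, rows)
  out <- cbind(pattern_id = seq_len(nrow(out)), out)
  attr(out, "total_comparisons") <- sum(out$comparisons)
  class(out) <- c("match_result", class(out))
  out
}

#' Write a match result as TSV
#' @param mr A `match_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_match_result <- function(mr, path) {
  utils::write.table(as.data.frame(mr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
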