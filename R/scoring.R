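#' SPI chi-score at matched orientations
#'
#' The single-particle chi-score between a model pattern set and the
#' "experimental" data set when the n-th model pattern shares the n-th data
#' pattern's orientation: the mean over patterns of the mean over usable
#' pixels of `((I_model - I_data) / sigma_data)^2`, with the data sigma
#' taken from photon statistics (`sqrt(I)`, floored).
#'
#' @param model_ps,data_ps `pattern_set`s of equal shape whose n-th
#'   patterns share an orientation.
#' @return Numeric chi-square value with attribute `"per_pattern"` (the N
#'   per-pattern chi values).
#' @export
spi_score_matched <- function(model_ps, data_ps) {
  stopifnot(inherits(model_ps, "pattern_set"),
            inherits(data_ps, "pattern_set"))
  if (length(model_ps$patterns) != length(data_ps$patterns))
    stop("pattern counts differ")
  if (length(model_ps$qmap$qmag) != length(data_ps$qmap$qmag))
    stop("pixel counts differ")
  mask <- data_ps$qmap$mask
  per <- vapply(seq_along(data_ps$patterns), function(n) {
    if (max(abs(model_ps$patterns[[n]]$orientation -
                data_ps$patterns[[n]]$orientation)) > 1e-9)
      warning("pattern ", n, ": orientations differ; matched-orientation ",
              "scoring assumes identical orientations")
    im <- model_ps$patterns[[n]]$intensity[mask]
    id <- data_ps$patterns[[n]]$intensity[mask]
    sd_ <- data_ps$patterns[[n]]$sigma[mask]
    mean(((im - id) / sd_)^2)
  }, numeric(1))
  structure(mean(per), per_pattern = per)
}

#' Matched-orientation SPI scores for a whole decoy set
#'
#' Computes the matched-orientation SPI chi-score of every decoy against the
#' experimental set.  Because all decoys of a docking series share the fixed
#' subunit, its complex structure factors are simulated once per orientation
#' and only the mobile subunit is recomputed per decoy; the result is
#' numerically identical to scoring each decoy with [spi_score_matched()].
#'
#' @param ds A `decoy_set` whose decoys share the native's fixed subunit.
#' @param data_ps The experimental `pattern_set` (photon-scaled).
#' @return Numeric vector of chi-scores, one per decoy, with attribute
#'   `"per_pattern"` (N x n_decoys matrix).
#' @export
spi_score_decoy_set <- function(ds, data_ps) {
  stopifnot(inherits(ds, "decoy_set"), inherits(data_ps, "pattern_set"))
  shared <- all(vapply(ds$decoys, function(d)
    isTRUE(all.equal(d$fixed$coords, ds$native$fixed$coords,
                     tolerance = 1e-12)), logical(1)))
  qm <- data_ps$qmap
  mask <- qm$mask
  sf <- data_ps$scale_factor
  if (is.na(sf)) sf <- 1
  oris <- orientations(data_ps)
  N <- nrow(oris)
  if (!shared) {
    # decoys do not share the fixed subunit: plain per-decoy path
    per <- vapply(ds$decoys, function(dec) {
      mps <- simulate_pattern_set(dec, oris, qm)
      mps$patterns <- lapply(mps$patterns, function(p) {
        p$intensity <- p$intensity * sf
        p
      })
      attr(spi_score_matched(mps, data_ps), "per_pattern")
    }, numeric(N))
  } else {
    amp_fix <- amplitude_simulator(ds$native$fixed, qm)
    Ffix <- vapply(seq_len(N), function(n) amp_fix(oris[n, ]),
                   complex(sum(mask)))
    Id <- vapply(data_ps$patterns, function(p) p$intensity[mask],
                 numeric(sum(mask)))
    Sd <- vapply(data_ps$patterns, function(p) p$sigma[mask],
                 numeric(sum(mask)))
    per <- vapply(ds$decoys, function(dec) {
      amp_mob <- amplitude_simulator(dec$mobile, qm)
      vapply(seq_len(N), function(n) {
        Fm <- Ffix[, n] + amp_mob(oris[n, ])
        im <- (Re(Fm)^2 + Im(Fm)^2) * sf
        mean(((im - Id[, n]) / Sd[, n])^2)
      }, numeric(1))
    }, numeric(N))
  }
  structure(colMeans(per), per_pattern = per)
}

#' SPI chi-score with orientation matching
#'
#' The realistic form of the SPI chi-score: for each experimental pattern,
#' the minimum chi over all bank orientations of the candidate model is
#' taken, and the per-pattern minima are averaged.  When the true
#' orientations lie on the grid and the model is the native structure, this
#' equals the matched-orientation score (zero for noise-free data); it can
#' never exceed the chi obtained under any fixed orientation assignment.
#'
#' @param data_ps The experimental `pattern_set` (already photon-scaled).
#' @param model Candidate `complex_model` or `atomic_model`.
#' @param grid An `orientation_grid`.
#' @param representation `"raw"`, `"ac"` or `"radial"` (see [build_bank()]).
#' @param bank Optional prebuilt `reference_bank` (overrides model/grid).
#' @param ... Passed to [build_bank()] (e.g. `sampler`, `n_bins`).
#' @return Numeric chi-square with attributes `"per_pattern"`, `"matches"`
#'   (the [match_set()] table) and `"comparisons"`.
#' @export
spi_score_matching <- function(data_ps, model = NULL, grid = NULL,
                               representation = "raw", bank = NULL, ...) {
  if (is.null(bank)) {
    sf <- data_ps$scale_factor
    if (is.na(sf)) sf <- 1
    bank <- build_bank(model, grid, data_ps$qmap,
                       representation = representation,
                       scale_factor = sf, ...)
  }
  mr <- match_set(data_ps, bank)
  structure(mean(mr$chi), per_pattern = mr$chi, matches = mr,
            comparisons = attr(mr, "total_comparisons"))
}

#' Rotationally averaged scattering profile by the Debye formula
#'
#' Exact orientational average of the scattering intensity of a rigid
#' model: `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij) / (q r_ij)`.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param q Numeric vector of momentum-transfer magnitudes, 1/Angstrom.
#' @return Numeric intensity at each `q`.
#' @export
debye_profile <- function(model, q) {
  if (inherits(model, "complex_model")) model <- merge_subunits(model)
  stopifnot(inherits(model, "atomic_model"))
  els <- unique(model$elements)
  xyz <- model$coords
  out <- numeric(length(q))
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  for (a in seq_along(els)) for (b in seq_len(a)) {
    ia <- which(model$elements == els[a])
    ib <- which(model$elements == els[b])
    d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
                rowSums(xyz[ib, , drop = FALSE]^2), "+") -
      2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
    d <- sqrt(pmax(as.numeric(d2), 0))
    w <- if (a == b) 1 else 2   # off-diagonal element pairs counted twice
    fa <- form_factor(els[a], q)
    fb <- form_factor(els[b], q)
    # chunk over q to bound the outer() allocation
    step <- max(1L, floor(2e6 / length(d)))
    for (s in seq(1L, length(q), by = step)) {
      ii <- s:min(s + step - 1L, length(q))
      out[ii] <- out[ii] +
        w * fa[ii] * fb[ii] * rowSums(sinc(outer(q[ii], d)))
    }
  }
  out
}

#' Model-side SAXS profile on the detector's radial bins
#'
#' Evaluates the Debye intensity at every usable pixel's `|q|` and averages
#' it in the same radial bins used for the data profile, so model and data
#' are reduced identically.
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param qmap A `qmap`.
#' @param bins A [radial_bins()] result.
#' @param scale_factor Photon scale factor of the data set.
#' @return Numeric per-bin model intensity (NA for empty bins).
#' @export
saxs_model_profile <- function(model, qmap, bins, scale_factor = 1) {
  ok <- !is.na(bins$bin)
  qv <- qmap$qmag[ok]
  # Debye depends on |q| only: evaluate on the unique pixel radii
  uq <- sort(unique(qv))
  iv <- debye_profile(model, uq)[match(qv, uq)] * scale_factor
  nb <- length(bins$q_centers)
  s <- rowsum(iv, bins$bin[ok])
  cnt <- tabulate(bins$bin[ok], nbins = nb)
  out <- rep(NA_real_, nb)
  out[as.integer(rownames(s))] <- s[, 1L] /
    cnt[as.integer(rownames(s))]
  out
}

#' SAXS chi-score between data patterns and a candidate model
#'
#' The data side aggregates all patterns into a radial profile (the
#' angular/pattern average); the model side is the exact rotational average
#' by the Debye formula, reduced through the same radial binning and placed
#' on the same photon scale.  The score is the mean over bins of
#' `((I_model - I_data) / sigma_data)^2`.
#'
#' @param data_ps The experimental `pattern_set`.
#' @param model Candidate model, or a precomputed per-bin model profile.
#' @param n_bins Number of radial bins.
#' @param bins Optional precomputed [radial_bins()].
#' @param sigma_floor Photon-count sigma floor.
#' @return Numeric chi-square with attributes `"data_profile"` and
#'   `"model_profile"`.
#' @export
saxs_score <- function(data_ps, model, n_bins = 30L, bins = NULL,
                       sigma_floor = 1) {
  stopifnot(inherits(data_ps, "pattern_set"))
  if (is.null(bins)) bins <- radial_bins(data_ps$qmap, n_bins)
  dp <- radial_profile(data_ps, bins = bins, sigma_floor = sigma_floor)
  sf <- data_ps$scale_factor
  if (is.na(sf)) sf <- 1
  mp <- if (is.numeric(model)) {
    if (length(model) != length(dp$intensity))
      stop("model profile binning does not match the data profile")
    model
  } else saxs_model_profile(model, data_ps$qmap, bins, scale_factor = sf)
  ok <- !is.na(dp$intensity) & !is.na(mp)
  chi <- mean(((mp[ok] - dp$intensity[ok]) / dp$sigma[ok])^2)
  structure(chi, data_profile = dp, model_profile = mp)
}

#' Density-overlap difference score (s-score)
#'
#' Both models are shifted so their (electron-weighted) centers of mass sit
#' at the origin, rasterized on one common grid, and the Pearson correlation
#' of the two density maps is maximized over a grid of relative rotations of
#' the second model.  The score is `s = 1 - max cc`, a distance-like
#' measure: 0 for identical shapes, approaching 1 for uncorrelated ones.
#' No translational search is performed (the centering fixes it).
#'
#' @param model_a,model_b `atomic_model` or `complex_model` objects.
#' @param rot_step Rotation-grid step, degrees.
#' @param bounds Optional Euler bounds (see [make_grid()]); defaults to the
#'   full rotation group.
#' @param voxel_size,padding Rasterization parameters, Angstrom.
#' @return Numeric s-score with attributes `"cc"` (max correlation) and
#'   `"best_rotation"` (Euler triple).
#' @export
s_score <- function(model_a, model_b, rot_step = 10, bounds = NULL,
                    voxel_size = 2, padding = 6) {
  am <- if (inherits(model_a, "complex_model")) merge_subunits(model_a)
        else model_a
  bm <- if (inherits(model_b, "complex_model")) merge_subunits(model_b)
        else model_b
  am$coords <- sweep(am$coords, 2L, center_of_mass(am))
  bm$coords <- sweep(bm$coords, 2L, center_of_mass(bm))
  half <- max(abs(am$coords), abs(bm$coords)) + padding
  m <- ceiling(half / voxel_size)
  dims <- rep(2L * m + 1L, 3L)
  grid <- density_grid(rep(-m * voxel_size, 3L), dims, voxel_size)
  va <- as.numeric(rasterize_on_grid(am, grid))
  if (stats::sd(va) == 0) stop("degenerate (constant) density map")
  rot_grid <- make_grid(rot_step, bounds)
  best_cc <- -Inf
  best_tri <- rot_grid$triples[1L, ]
  for (i in seq_len(nrow(rot_grid$triples))) {
    tri <- rot_grid$triples[i, ]
    rb <- bm
    rb$coords <- bm$coords %*% t(euler_matrix(tri[1], tri[2], tri[3]))
    vb <- as.numeric(rasterize_on_grid(rb, grid))
    cc <- stats::cor(va, vb)
    if (is.finite(cc) && cc > best_cc) {
      best_cc <- cc
      best_tri <- tri
    }
  }
  structure(1 - best_cc, cc = best_cc, best_rotation = best_tri)
}

#' Combine two scores by standardized (Z-score) summation
#'
#' Each score column is standardized to zero mean and unit variance across
#' decoys; columns whose better direction is "higher" are sign-flipped so
#' that lower always means better, and the two Z-scores are summed.
#'
#' @param scores_a,scores_b Numeric vectors of equal length.
#' @param lower_better_a,lower_better_b Is lower better for each input?
#' @return Numeric combined score (lower = better).
#' @export
combine_zscores <- function(scores_a, scores_b,
                            lower_better_a = TRUE, lower_better_b = TRUE) {
  stopifnot(length(scores_a) == length(scores_b),
            all(is.finite(scores_a)), all(is.finite(scores_b)))
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0)
    stop("cannot standardize a zero-variance score column")
  za <- as.numeric(scale(scores_a)) * if (lower_better_a) 1 else -1
  zb <- as.numeric(scale(scores_b)) * if (lower_better_b) 1 else -1
  za + zb
}
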