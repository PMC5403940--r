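## End-to-end orchestration: the cmd_* functions are the R surface behind
## the command-line script (inst/cli/spidock.R) and are directly usable from
## an interactive session.  Every command is deterministic given (config,
## seed) and embeds the configuration and seed in its output.

detector_from_config <- function(cfg) {
  beam_detector(wavelength = cfg$wavelength, distance = cfg$distance,
                pixel_size = cfg$pixel_size, n_fast = cfg$n_fast,
                n_slow = cfg$n_slow, d_min = cfg$d_min)
}

#' Simulate an "experimental" pattern set from a native structure
#'
#' Draws `n_patterns` random orientations (within the configured subspace,
#' per-angle uniform by default; SO(3)-uniform optional), simulates
#' noise-free patterns, scales them to the photon budget (shell mean of one
#' photon at `d_target`), and applies the configured noise.
#'
#' @param native A `complex_model`/`atomic_model`, or a PDB path.
#' @param config Configuration list from [load_config()].
#' @param out Optional path: the pattern set is saved there as RDS.
#' @return The `pattern_set` (invisibly if `out` is given); the config is
#'   attached as attribute `"config"`.
#' @export
cmd_simulate <- function(native, config = default_config(), out = NULL) {
  if (is.character(native)) native <- read_complex_pdb(native)
  det <- detector_from_config(config)
  qm <- build_qmap(det)
  oris <- random_orientations(config$n_patterns,
                              bounds = config_bounds(config$orient_half_deg),
                              sampler = config$sampler,
                              seed = config$seed)
  ps <- simulate_pattern_set(native, oris, qm,
                             source_label = "experimental",
                             sigma_floor = config$sigma_floor)
  ps <- scale_to_photons(ps, d_target = config$d_target,
                         shell_frac = config$shell_frac,
                         sigma_floor = config$sigma_floor)
  if (isTRUE(config$poisson) || !is.na(config$snr))
    ps <- add_noise_set(ps, poisson = isTRUE(config$poisson),
                        snr = if (is.na(config$snr)) NULL else config$snr,
                        seed = config$seed,
                        sigma_floor = config$sigma_floor)
  attr(ps, "config") <- config
  if (!is.null(out)) {
    write_pattern_set(ps, out)
    return(invisible(ps))
  }
  ps
}

#' Generate and persist a decoy set
#'
#' @param native A `complex_model` or PDB path.
#' @param config Configuration list.
#' @param out_dir Optional output directory for PDBs + manifest.
#' @return The `decoy_set` (invisibly if `out_dir` is given).
#' @export
cmd_decoys <- function(native, config = default_config(), out_dir = NULL) {
  if (is.character(native)) native <- read_complex_pdb(native)
  ds <- generate_decoys(native, n = config$n_decoys,
                        rot_max = config$rot_max,
                        trans_max = config$trans_max, seed = config$seed)
  if (!is.null(out_dir)) {
    write_decoy_set(ds, out_dir)
    return(invisible(ds))
  }
  ds
}

#' Score a decoy set against an experimental pattern set
#'
#' Computes, per decoy: the SPI chi-score (matched orientations, or
#' orientation matching over the configured grid), the SAXS chi-score, the
#' RMSD to the native, and optionally the density-overlap s-score.
#'
#' @param patterns A `pattern_set` or RDS path from [cmd_simulate()].
#' @param decoys A `decoy_set` or directory from [cmd_decoys()].
#' @param config Configuration list.
#' @param out Optional TSV path for the score table.
#' @param verbose Print per-decoy progress to stderr.
#' @return A score-table data frame (decoy_id, spi_score, saxs_score, rmsd,
#'   and s_score when enabled), with attribute `"comparisons"` in matching
#'   mode.
#' @export
cmd_score <- function(patterns, decoys, config = default_config(),
                      out = NULL, verbose = FALSE) {
  if (is.character(patterns)) patterns <- read_pattern_set(patterns)
  if (is.character(decoys)) decoys <- read_decoy_set(decoys)
  pcfg <- attr(patterns, "config")
  if (!is.null(pcfg)) {
    geo <- c("wavelength", "distance", "pixel_size", "n_fast", "n_slow",
             "d_min")
    bad <- geo[!vapply(geo, function(k)
      isTRUE(all.equal(pcfg[[k]], config[[k]])), logical(1))]
    if (length(bad))
      stop("pattern-set geometry differs from config for: ",
           paste(sprintf("%s (%s vs %s)", bad, sapply(pcfg[bad], format),
                         sapply(config[bad], format)), collapse = ", "))
  }
  qm <- patterns$qmap
  bins <- radial_bins(qm, config$saxs_bins)
  grid <- NULL; sampler <- NULL
  if (config$spi_mode == "matching") {
    grid <- make_grid(config$grid_step,
                      config_bounds(config$grid_half_deg))
    if (config$representation == "ac")
      sampler <- polar_sampler(qm, config$n_qbins, config$n_phibins)
  }
  oris <- orientations(patterns)
  sf <- patterns$scale_factor
  if (is.na(sf)) sf <- 1
  total_comparisons <- 0
  rows <- lapply(seq_along(decoys$decoys), function(i) {
    dec <- decoys$decoys[[i]]
    if (config$spi_mode == "matched") {
      mps <- simulate_pattern_set(dec, oris, qm,
                                  sigma_floor = config$sigma_floor)
      mps$patterns <- lapply(mps$patterns, function(p) {
        p$intensity <- p$intensity * sf
        p
      })
      spi <- spi_score_matched(mps, patterns)
    } else {
      spi <- spi_score_matching(patterns, dec, grid,
                                representation = config$representation,
                                sampler = sampler,
                                n_bins = config$saxs_bins,
                                sigma_floor = config$sigma_floor)
      total_comparisons <<- total_comparisons + attr(spi, "comparisons")
    }
    sx <- saxs_score(patterns, dec, bins = bins,
                     sigma_floor = config$sigma_floor)
    row <- data.frame(decoy_id = decoys$manifest$decoy_id[i],
                      spi_score = as.numeric(spi),
                      saxs_score = as.numeric(sx),
                      rmsd = decoys$rmsd[i])
    if (isTRUE(config$with_s_score))
      row$s_score <- as.numeric(
        s_score(dec, decoys$native, rot_step = config$s_rot_step,
                bounds = config_bounds(config$s_half_deg)))
    if (verbose)
      message(sprintf("scored %s: spi %.4g saxs %.4g", row$decoy_id,
                      row$spi_score, row$saxs_score))
    row
  })
  tab <- do.call(rbind, rows)
  attr(tab, "comparisons") <- total_comparisons
  if (!is.null(out)) {
    meta <- list(spi_mode = config$spi_mode,
                 representation = config$representation,
                 seed = config$seed,
                 n_patterns = length(patterns$patterns),
                 comparisons = total_comparisons)
    write_score_table(tab, out, meta = meta)
    return(invisible(tab))
  }
  tab
}

#' Rank a score table: curves, AUCs and correlations per score column
#'
#' @param table A score-table data frame or TSV path.
#' @param config Configuration list.
#' @param difference_column `"rmsd"` (default) or `"s_score"`.
#' @param out Optional TSV path for the AUC summary.
#' @return List with `auc` (one row per score x selection size), `curves`
#'   (per score), `correlations` (Pearson r per score).
#' @export
cmd_rank <- function(table, config = default_config(),
                     difference_column = "rmsd", out = NULL) {
  if (is.character(table)) table <- read_score_table(table)
  n_sel <- parse_n_select(config$n_select)
  score_cols <- intersect(c("spi_score", "saxs_score", "s_score",
                            "external_score"), names(table))
  score_cols <- setdiff(score_cols, difference_column)
  curves <- lapply(score_cols, function(sc)
    ranking_curves(table, sc, difference_column, n_select = n_sel,
                   bins = config$rank_bins))
  names(curves) <- score_cols
  auc <- do.call(rbind, lapply(curves, `[[`, "auc"))
  rownames(auc) <- NULL
  cors <- vapply(score_cols, function(sc)
    score_difference_correlation(table, sc, difference_column), numeric(1))
  res <- list(auc = auc, curves = curves, correlations = cors)
  if (!is.null(out)) {
    write_score_table(auc, out,
                      meta = list(difference = difference_column,
                                  seed = config$seed))
    return(invisible(res))
  }
  res
}
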