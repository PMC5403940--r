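#' Default run configuration
#'
#' One flat list of every tunable of the simulate / decoys / score / rank
#' pipeline, each with a working default.  Geometry defaults place the
#' detector edge just past 4 Angstrom resolution; the simulation default of
#' 1000 patterns is the budget at which the SPI score is converged for
#' systems of this size.  `NA` for `snr` or `grid_half_deg` means
#' "disabled" / "full range".
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    # geometry
    wavelength = 1.0, distance = 49, pixel_size = 0.2,
    n_fast = 128L, n_slow = 128L, d_min = 4.0,
    # simulation
    n_patterns = 1000L, d_target = 4.0, shell_frac = 0.03,
    poisson = TRUE, snr = NA_real_, seed = 1L,
    sampler = "per_angle", orient_half_deg = 22.5,
    # orientation grid / matching
    grid_step = 3.0, grid_half_deg = 22.5, representation = "raw",
    n_qbins = 20L, n_phibins = 64L,
    # decoys
    n_decoys = 100L, rot_max = 30, trans_max = 10,
    # scoring / ranking
    spi_mode = "matched", saxs_bins = 30L, with_s_score = FALSE,
    s_rot_step = 15, s_half_deg = 45,
    n_select = "25,100,all", rank_bins = 25L,
    sigma_floor = 1.0
  )
}

#' Load a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are rejected; values are coerced to the type of the
#' default.  `overrides` (e.g. parsed command-line flags) take precedence
#' over the file, which takes precedence over the defaults.
#'
#' @param path Path to a config file, or NULL for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  set_key <- function(cfg, key, val) {
    if (!key %in% names(cfg)) stop("unknown configuration key: ", key)
    ref <- cfg[[key]]
    cfg[[key]] <- if (is.character(ref)) as.character(val)
    else if (is.logical(ref)) as.logical(val)
    else if (is.integer(ref)) as.integer(val)
    else as.numeric(val)
    if (is.na(cfg[[key]]) && !is.na(ref) && !identical(val, "NA"))
      stop("cannot parse value for key '", key, "': ", val)
    cfg
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("malformed config line: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      cfg <- set_key(cfg, key, val)
    }
  }
  for (key in names(overrides))
    cfg <- set_key(cfg, key, overrides[[key]])
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$wavelength > 0, cfg$distance > 0, cfg$pixel_size > 0,
            cfg$d_min > 0, cfg$n_patterns >= 1L, cfg$n_decoys >= 1L,
            cfg$grid_step > 0, cfg$sigma_floor >= 0)
  if (!cfg$sampler %in% c("so3", "per_angle"))
    stop("sampler must be 'so3' or 'per_angle'")
  if (!cfg$representation %in% c("raw", "ac", "radial"))
    stop("representation must be raw, ac or radial")
  if (!cfg$spi_mode %in% c("matched", "matching"))
    stop("spi_mode must be 'matched' or 'matching'")
  if (!is.na(cfg$snr) && cfg$snr <= 0) stop("snr must be positive")
  cfg
}

## orientation bounds implied by a config (NA half-width = full ranges)
config_bounds <- function(half_deg) {
  if (is.na(half_deg)) NULL else subspace_bounds(half_deg)
}

## selection sizes: "25,100,all" -> c(25, 100, NA)
parse_n_select <- function(spec) {
  parts <- trimws(strsplit(spec, ",")[[1]])
  vapply(parts, function(p)
    if (tolower(p) == "all") NA_real_ else as.numeric(p), numeric(1),
    USE.NAMES = FALSE)
}
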