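## Run configuration: a flat, human-editable YAML file with four sections
## (instrument, plume, probe, analysis) plus a seed.  Every key has a
## documented default; unknown keys are rejected by name so a typo cannot
## silently fall back to a default.

.default_config <- function() {
  list(
    instrument = list(
      voltage_kV = c(3.5, 4.5, 5.5),
      gap_mm = 12.7,
      drift_m = 1.0,
      bin_ns = 2.0),
    plume = list(
      species = c("(CHCA)H+", "(CHCA)2H+"),
      tE_mean_ns = c(46, 64),
      tE_sd_ns = c(11, 12),
      tE_shape = "gaussian_truncated_at_zero",
      v0_mean_ms = 500,
      v0_sd_ms = 150,
      ions_per_shot = 5000,
      shots_per_spectrum = 20),
    probe = list(
      slab_low_mm = c(0.6, 1.6, 2.6, 3.6),
      slab_thickness_mm = 1.0,
      delays_ns = seq(0, 500, by = 50),
      dissociation_prob = 1.0),
    analysis = list(
      min_depth = 0.15,
      min_width_bins = 3,
      center_tolerance = 0.5,
      v0_assumed_ms = 500,
      hist_bin_ns = 10),
    seed = 1)
}

.check_keys <- function(user, defaults, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", full, " must be a section")
      .check_keys(user[[k]], defaults[[k]], full)
    }
  }
}

.validate_config <- function(cfg) {
  with(cfg$instrument, {
    if (any(voltage_kV <= 0)) stop("config instrument.voltage_kV must be positive")
    if (gap_mm <= 0) stop("config instrument.gap_mm must be positive")
    if (bin_ns <= 0) stop("config instrument.bin_ns must be positive")
  })
  with(cfg$plume, {
    if (length(tE_mean_ns) != length(species) ||
        length(tE_sd_ns) != length(species))
      stop("config plume: tE_mean_ns/tE_sd_ns must match species length")
    if (any(tE_mean_ns < 0) || any(tE_sd_ns < 0))
      stop("config plume.tE_mean_ns/tE_sd_ns must be non-negative")
    if (ions_per_shot < 1) stop("config plume.ions_per_shot must be >= 1")
  })
  with(cfg$probe, {
    if (slab_thickness_mm <= 0)
      stop("config probe.slab_thickness_mm must be positive")
    if (dissociation_prob < 0 || dissociation_prob > 1)
      stop("config probe.dissociation_prob must lie in [0, 1]")
    if (is.unsorted(delays_ns)) stop("config probe.delays_ns must be ascending")
  })
  with(cfg$analysis, {
    if (min_depth <= 0 || min_depth > 1)
      stop("config analysis.min_depth must lie in (0, 1]")
  })
  invisible(cfg)
}

#' Load (or default) a run configuration
#'
#' Reads a YAML file, fills every missing key with its documented default,
#' rejects unknown keys by name, and validates ranges.  Interface units
#' are bench units: kV, mm, ns, m/s.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @return A validated `run_config` list with sections `instrument`,
#'   `plume`, `probe`, `analysis`, and `seed`, plus attribute
#'   `config_hash` (md5 of the effective config).
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    .check_keys(user, cfg)
    for (sec in names(user)) {
      if (is.list(cfg[[sec]]) && !is.null(names(cfg[[sec]]))) {
        for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  .validate_config(cfg)
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of an effective configuration
#'
#' md5 of the canonical JSON rendering; embedded in output provenance so
#' any result can be traced to the exact configuration that produced it.
#'
#' @param cfg A `run_config` (or plain list).
#' @return Character md5 digest.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  attributes(cfg)[c("config_hash", "class")] <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Build the simulation objects a configuration describes
#'
#' Expands a `run_config` into the [scenario_grid], per-species
#' [plume_model] list and [instrument_config] template used by
#' [generate_scenario()].
#'
#' @param cfg A `run_config` from [load_config()].
#' @return List with `grid`, `models`, `instrument`, and `analysis`
#'   (the analysis section unchanged).
#' @export
config_objects <- function(cfg) {
  sp_all <- chca_species()
  unknown <- setdiff(cfg$plume$species, names(sp_all))
  if (length(unknown))
    stop("config plume.species not in species table: ",
         paste(unknown, collapse = ", "))
  models <- lapply(seq_along(cfg$plume$species), function(i)
    plume_model(sp_all[[cfg$plume$species[i]]],
                cfg$plume$tE_mean_ns[i] * 1e-9,
                cfg$plume$tE_sd_ns[i] * 1e-9,
                tE_shape = cfg$plume$tE_shape,
                v0_mean = cfg$plume$v0_mean_ms,
                v0_sd = cfg$plume$v0_sd_ms,
                ions_per_shot = cfg$plume$ions_per_shot))
  names(models) <- cfg$plume$species
  grid <- scenario_grid(
    slabs = lapply(cfg$probe$slab_low_mm, function(lo)
      c(lo, lo + cfg$probe$slab_thickness_mm) * 1e-3),
    delays = cfg$probe$delays_ns * 1e-9,
    voltages = cfg$instrument$voltage_kV * 1e3,
    shots_per_spectrum = cfg$plume$shots_per_spectrum,
    seed = cfg$seed)
  instrument <- instrument_config(cfg$instrument$voltage_kV[1] * 1e3,
                                  gap = cfg$instrument$gap_mm * 1e-3,
                                  drift_length = cfg$instrument$drift_m,
                                  bin_width = cfg$instrument$bin_ns * 1e-9)
  list(grid = grid, models = models, instrument = instrument,
       analysis = cfg$analysis)
}

#' Run the configured pipeline end to end
#'
#' Convenience wrapper: simulate the configured scenario, scan it to
#' observation points, and estimate per-species ejection times.  The
#' building blocks ([generate_scenario()], [scan_to_observations()],
#' [estimate_tE()]) remain the primary interface.
#'
#' @param cfg A `run_config`; `NULL` for defaults.
#' @param seed Optional seed overriding the config's.
#' @return List with `archive`, `observations`, and `estimates` (named
#'   per species).
#' @export
run_pipeline <- function(cfg = NULL, seed = NULL) {
  if (is.null(cfg)) cfg <- load_config()
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ob <- config_objects(cfg)
  archive <- generate_scenario(ob$grid, ob$models, ob$instrument,
                               dissociation_prob = cfg$probe$dissociation_prob)
  obs <- scan_to_observations(archive,
                              min_depth = ob$analysis$min_depth,
                              min_width_bins = ob$analysis$min_width_bins,
                              tolerance = ob$analysis$center_tolerance)
  estimates <- lapply(ob$models, function(m) {
    pts <- obs[obs$label == m$species$label, , drop = FALSE]
    if (!nrow(pts)) return(NULL)
    estimate_tE(pts, m$species, v0_assumed = ob$analysis$v0_assumed_ms,
                hist_bin_width = ob$analysis$hist_bin_ns * 1e-9)
  })
  list(archive = archive, observations = obs, estimates = estimates)
}
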