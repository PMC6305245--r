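## File dialects.  Spectra travel as plain two-column CSV (tof_ns,
## intensity; one row per bin centre, 6 significant digits) with a JSON
## sidecar carrying instrument, scenario and seed provenance; observation
## tables and results as structured JSON (or CSV with the same columns).
## Interface units are the bench units: ns, mm, kV.

.provenance <- function(extra = list()) {
  c(list(package = "plumetrace",
         version = as.character(utils::packageVersion("plumetrace"))),
    extra)
}

#' Write a spectrum as CSV plus JSON sidecar
#'
#' @param spectrum A `maldi_spectrum`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(tof_ns = signif(.bin_centers(spectrum) * 1e9, 6),
                   intensity = signif(spectrum$counts, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- .provenance(c(spectrum$metadata,
                        list(bin_width_ns = diff(spectrum$bin_edges[1:2]) * 1e9,
                             tof_start_ns = spectrum$bin_edges[1] * 1e9)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_csv()]
#'
#' @param path CSV path; the `<path>.json` sidecar must be present.
#' @return A `maldi_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("tof_ns", "intensity") %in% names(df)))
    stop("spectrum CSV must have columns tof_ns,intensity: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  bw <- side$bin_width_ns * 1e-9
  start <- side$tof_start_ns * 1e-9
  edges <- seq(start, by = bw, length.out = nrow(df) + 1L)
  md <- side[setdiff(names(side), c("package", "version", "bin_width_ns",
                                    "tof_start_ns"))]
  if (!is.null(md$probe))
    md$probe <- probe_event(md$probe$delta_t, md$probe$slab_low,
                            md$probe$slab_high, md$probe$dissociation_prob)
  structure(list(bin_edges = edges, counts = df$intensity, metadata = md),
            class = "maldi_spectrum")
}

#' Write a scenario archive to a directory tree
#'
#' One sub-directory per voltage holding `baseline.csv` and
#' `probe_z{low}-{high}mm_dt{ns}ns.csv` files, each with its JSON sidecar,
#' plus a top-level `scenario.json` describing the grid, species, and
#' seed.
#'
#' @param archive A `scenario_archive`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_archive <- function(archive, dir) {
  stopifnot(inherits(archive, "scenario_archive"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (vname in names(archive$voltages)) {
    v <- archive$voltages[[vname]]
    vdir <- file.path(dir, vname)
    dir.create(vdir, showWarnings = FALSE)
    write_spectrum_csv(v$baseline, file.path(vdir, "baseline.csv"))
    for (key in names(v$probed)) {
      pr <- v$probed[[key]]$metadata$probe
      fn <- sprintf("probe_z%.1f-%.1fmm_dt%.0fns.csv",
                    pr$slab_low * 1e3, pr$slab_high * 1e3, pr$delta_t * 1e9)
      write_spectrum_csv(v$probed[[key]], file.path(vdir, fn))
    }
  }
  manifest <- .provenance(list(
    seed = archive$grid$seed,
    voltages = archive$grid$voltages,
    delays_ns = archive$grid$delays * 1e9,
    slabs_mm = lapply(archive$grid$slabs, function(s) s * 1e3),
    shots_per_spectrum = archive$grid$shots_per_spectrum,
    gap_mm = archive$voltages[[1]]$instrument$gap * 1e3,
    drift_m = archive$voltages[[1]]$instrument$drift_length,
    bin_ns = archive$voltages[[1]]$instrument$bin_width * 1e9,
    dissociation_prob = archive$dissociation_prob,
    fragments_on = archive$fragments_on,
    shot_noise = archive$shot_noise,
    species = lapply(unname(archive$species), function(sp)
      list(label = sp$label, mass_u = sp$mass, charge = sp$charge,
           nominal_mz = sp$nominal_mz, formula = sp$formula))))
  jsonlite::write_json(manifest, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scenario archive directory
#'
#' @param dir Directory written by [write_scenario_archive()].
#' @return A `scenario_archive` (without the generating `plume_model`s,
#'   which are not needed for analysis).
#' @export
read_scenario_archive <- function(dir) {
  man_path <- file.path(dir, "scenario.json")
  if (!file.exists(man_path)) stop("not a scenario archive: ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  species <- lapply(seq_len(nrow(man$species)), function(i)
    ion_species(man$species$label[i], man$species$mass_u[i],
                man$species$charge[i], man$species$nominal_mz[i],
                man$species$formula[i]))
  names(species) <- man$species$label
  slabs <- if (is.matrix(man$slabs_mm)) {
    lapply(seq_len(nrow(man$slabs_mm)), function(i) man$slabs_mm[i, ] * 1e-3)
  } else {
    lapply(man$slabs_mm, function(s) unlist(s) * 1e-3)
  }
  grid <- scenario_grid(slabs = slabs,
                        delays = man$delays_ns * 1e-9,
                        voltages = man$voltages,
                        shots_per_spectrum = man$shots_per_spectrum,
                        seed = man$seed)
  per_voltage <- lapply(man$voltages, function(V) {
    vdir <- file.path(dir, sprintf("%.0fV", V))
    base_path <- file.path(vdir, "baseline.csv")
    if (!file.exists(base_path)) stop("missing baseline for ", V, " V")
    inst <- instrument_config(V, gap = man$gap_mm * 1e-3,
                              drift_length = man$drift_m,
                              bin_width = man$bin_ns * 1e-9)
    probed_files <- list.files(vdir, pattern = "^probe_.*\\.csv$")
    probed <- lapply(probed_files, function(f)
      read_spectrum_csv(file.path(vdir, f)))
    names(probed) <- sub("\\.csv$", "", probed_files)
    list(instrument = inst, baseline = read_spectrum_csv(base_path),
         probed = probed)
  })
  names(per_voltage) <- sprintf("%.0fV", man$voltages)
  structure(list(voltages = per_voltage, grid = grid, models = NULL,
                 species = species,
                 dissociation_prob = man$dissociation_prob,
                 fragments_on = man$fragments_on,
                 shot_noise = man$shot_noise),
            class = "scenario_archive")
}

#' Write / read observation tables
#'
#' Observation points travel as JSON (array of objects) or CSV with the
#' columns `label, voltage_V, delta_t_ns, z_corrected_mm, fwd_fraction,
#' slab_low_mm, slab_high_mm, field_Vm`.
#'
#' @param points Observation data frame from [scan_to_observations()].
#' @param path Output path; `.json` or `.csv` decides the dialect.
#' @return `path`, invisibly.
#' @export
write_observations <- function(points, path) {
  out <- data.frame(label = points$label, voltage_V = points$voltage_V,
                    field_Vm = points$field_Vm,
                    delta_t_ns = points$delta_t * 1e9,
                    z_corrected_mm = points$z_corrected * 1e3,
                    fwd_fraction = points$fwd_fraction,
                    slab_low_mm = points$slab_low * 1e3,
                    slab_high_mm = points$slab_high * 1e3)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(provenance = .provenance(), points = out),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)$points
  } else {
    utils::read.csv(path)
  }
  if (!NROW(out))
    return(data.frame(label = character(), voltage_V = numeric(),
                      field_Vm = numeric(), delta_t = numeric(),
                      z_corrected = numeric(), fwd_fraction = numeric(),
                      slab_low = numeric(), slab_high = numeric()))
  data.frame(label = out$label, voltage_V = out$voltage_V,
             field_Vm = out$field_Vm, delta_t = out$delta_t_ns * 1e-9,
             z_corrected = out$z_corrected_mm * 1e-3,
             fwd_fraction = out$fwd_fraction,
             slab_low = out$slab_low_mm * 1e-3,
             slab_high = out$slab_high_mm * 1e-3)
}

#' Write an ejection-time result file
#'
#' @param estimate An `ejection_estimate`.
#' @param path Output JSON path.
#' @param global_fit Optional result of [fit_global_tE()] to embed.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(estimate, path, global_fit = NULL) {
  pv <- estimate$per_voltage
  per_voltage <- lapply(seq_len(nrow(pv)), function(i)
    list(mean_ns = pv$mean[i] * 1e9,
         sd_ns = if (is.na(pv$sd[i])) NULL else pv$sd[i] * 1e9,
         n = pv$n[i]))
  names(per_voltage) <- as.character(pv$voltage_V)
  body <- list(
    provenance = .provenance(list(v0_assumed = estimate$v0_assumed)),
    species = estimate$species$label,
    per_point = lapply(seq_len(nrow(estimate$points)), function(i)
      list(delta_t_ns = estimate$points$delta_t[i] * 1e9,
           z_mm = estimate$points$z_corrected[i] * 1e3,
           voltage_V = estimate$points$voltage_V[i],
           tE_ns = estimate$points$t_E[i] * 1e9,
           valid = estimate$points$valid[i])),
    per_voltage = per_voltage,
    overall = list(mean_ns = estimate$overall$mean * 1e9,
                   sd_ns = if (is.na(estimate$overall$sd)) NULL
                           else estimate$overall$sd * 1e9,
                   n = estimate$overall$n))
  if (!is.null(global_fit)) body$global_fit_tE_ns <- global_fit$t_E * 1e9
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
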