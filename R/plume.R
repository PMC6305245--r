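## Monte-Carlo generator of MALDI ion-packet ensembles: per-species
## ejection-time and initial-velocity distributions, probe-slab depletion,
## shot-averaged TOF spectra.  This is the synthetic-data side of the
## closed loop; its defaults are the study conditions the analysis is
## validated under.

#' Statistical model of one species' ion packet
#'
#' Each ion is drawn independently: an ejection time `t_E` from a
#' truncated-at-zero gaussian (or a moment-matched lognormal) and an
#' initial velocity `v0` from a truncated gaussian.  Defaults for the
#' velocity reflect the ~500 m/s axial velocities reported for MALDI
#' plumes; ejection-time defaults are set per species (see
#' [default_plume_models()]).
#'
#' @param species An [ion_species].
#' @param tE_mean,tE_sd Mean and sd of the ejection-time distribution, in
#'   seconds.
#' @param tE_shape `"gaussian_truncated_at_zero"` or `"lognormal"`
#'   (moment-matched to `tE_mean`, `tE_sd`).
#' @param v0_mean,v0_sd Mean and sd of the initial-velocity distribution,
#'   in m/s (gaussian truncated at zero).
#' @param ions_per_shot Ions of this species produced per MALDI shot.
#' @return An object of class `plume_model`.
#' @export
plume_model <- function(species, tE_mean, tE_sd,
                        tE_shape = c("gaussian_truncated_at_zero", "lognormal"),
                        v0_mean = 500, v0_sd = 150, ions_per_shot = 5000L) {
  tE_shape <- match.arg(tE_shape)
  stopifnot(inherits(species, "ion_species"),
            tE_mean >= 0, tE_sd >= 0, v0_mean >= 0, v0_sd >= 0,
            ions_per_shot >= 1)
  structure(list(species = species, tE_mean = tE_mean, tE_sd = tE_sd,
                 tE_shape = tE_shape, v0_mean = v0_mean, v0_sd = v0_sd,
                 ions_per_shot = as.integer(ions_per_shot)),
            class = "plume_model")
}

#' Default packet models for the CHCA monomer and dimer
#'
#' Ejection-time distributions: monomer mean 46 ns, sd 11 ns; dimer mean
#' 64 ns, sd 12 ns; both gaussians truncated at zero.  Velocities:
#' mean 500 m/s, sd 150 m/s.
#'
#' @param ions_per_shot Ions per species per shot.
#' @return Named list of [plume_model] objects (`monomer`, `dimer`).
#' @export
default_plume_models <- function(ions_per_shot = 5000L) {
  sp <- chca_species()
  list(
    monomer = plume_model(sp[["(CHCA)H+"]], 46e-9, 11e-9,
                          ions_per_shot = ions_per_shot),
    dimer   = plume_model(sp[["(CHCA)2H+"]], 64e-9, 12e-9,
                          ions_per_shot = ions_per_shot))
}

#' Sheet-probe depletion event
#'
#' A 1-mm-thick slab of intense UV light crossing the plume at delay
#' `delta_t`; ions inside `[slab_low, slab_high)` at that instant are
#' photodissociated with probability `dissociation_prob`.
#'
#' @param delta_t Probe delay from the MALDI pulse centre, seconds.
#' @param slab_low,slab_high Slab boundaries in metres from the surface.
#' @param dissociation_prob Removal probability for an ion inside the
#'   slab.  Default 1: at the probe fluences modelled here depletion is
#'   saturated.
#' @return An object of class `probe_event`.
#' @export
probe_event <- function(delta_t, slab_low, slab_high, dissociation_prob = 1) {
  stopifnot(delta_t >= 0, slab_high > slab_low,
            dissociation_prob >= 0, dissociation_prob <= 1)
  structure(list(delta_t = delta_t, slab_low = slab_low,
                 slab_high = slab_high,
                 dissociation_prob = dissociation_prob),
            class = "probe_event")
}

#' Measurement grid of probe positions, delays and voltages
#'
#' @param slabs List of `c(z_low, z_high)` pairs in metres.  Default: four
#'   1-mm slabs from 0.6--1.6 mm to 3.6--4.6 mm.
#' @param delays Probe delays in seconds, ascending.  Default 0--500 ns in
#'   50-ns steps.
#' @param voltages Accelerating voltages in volts.  Default 3.5/4.5/5.5 kV.
#' @param shots_per_spectrum MALDI shots averaged per spectrum (default 20).
#' @param seed Integer seed from which every ensemble draw is derived.
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(slabs = lapply(0:3, function(k) c(0.6e-3, 1.6e-3) + k * 1e-3),
                          delays = seq(0, 500e-9, by = 50e-9),
                          voltages = c(3500, 4500, 5500),
                          shots_per_spectrum = 20L, seed = 1L) {
  stopifnot(length(slabs) >= 1, length(delays) >= 1, length(voltages) >= 1,
            !is.unsorted(delays), shots_per_spectrum >= 1)
  structure(list(slabs = slabs, delays = delays, voltages = voltages,
                 shots_per_spectrum = as.integer(shots_per_spectrum),
                 seed = as.integer(seed)),
            class = "scenario_grid")
}

## truncated-at-zero draws: redraw negatives rather than clip, so the
## shape near zero is a renormalized gaussian, not a point mass
.rtruncnorm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

.rlnorm_matched <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw an ion ensemble from a plume model
#'
#' @param model A [plume_model].
#' @param n_shots Number of MALDI shots to draw.
#' @param seed Optional integer seed; draws are bitwise reproducible given
#'   the same seed.
#' @return A data frame (`ion_ensemble`) with one row per ion: `shot`,
#'   `t_E` (s), `v0` (m/s), and the species `label`.
#' @export
sample_ions <- function(model, n_shots, seed = NULL) {
  stopifnot(inherits(model, "plume_model"), n_shots >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- model$ions_per_shot * n_shots
  t_E <- switch(model$tE_shape,
    gaussian_truncated_at_zero = .rtruncnorm(n, model$tE_mean, model$tE_sd),
    lognormal = .rlnorm_matched(n, model$tE_mean, model$tE_sd))
  v0 <- .rtruncnorm(n, model$v0_mean, model$v0_sd)
  structure(
    data.frame(shot = rep(seq_len(n_shots), each = model$ions_per_shot),
               t_E = t_E, v0 = v0, label = model$species$label),
    class = c("ion_ensemble", "data.frame"))
}

#' Positions of an ensemble at an observation time
#'
#' Vectorized [propagate_distance()]; ions not yet ejected report 0.
#'
#' @param ensemble An `ion_ensemble` from [sample_ions()].
#' @param species The [ion_species] of the ensemble.
#' @param field Extraction field in V/m.
#' @param delta_t Observation time in seconds.
#' @return Numeric vector of positions in metres, one per ion.
#' @export
positions_at <- function(ensemble, species, field, delta_t) {
  propagate_distance(ensemble$t_E, ensemble$v0, species, field, delta_t)
}

#' Apply a sheet-probe depletion event to an ensemble
#'
#' Partitions the ensemble exhaustively and disjointly into survivors and
#' dissociated ions.  Dissociated ions carry their kinematic state
#' (position, velocity) at the probe instant so fragments can be rendered.
#'
#' @param ensemble An `ion_ensemble`.
#' @param species Its [ion_species].
#' @param field Extraction field in V/m.
#' @param probe A [probe_event].
#' @param seed Optional seed for the Bernoulli removal draws (only used
#'   when `dissociation_prob < 1`).
#' @return List with elements `survivors` (ion_ensemble) and `dissociated`
#'   (ion_ensemble with extra columns `position`, `velocity` at the probe
#'   instant).
#' @export
apply_probe <- function(ensemble, species, field, probe, seed = NULL) {
  stopifnot(inherits(probe, "probe_event"))
  if (!is.null(seed)) set.seed(seed)
  z <- positions_at(ensemble, species, field, probe$delta_t)
  inside <- z >= probe$slab_low & z < probe$slab_high
  if (probe$dissociation_prob < 1) {
    hit <- inside & stats::runif(length(inside)) < probe$dissociation_prob
  } else {
    hit <- inside
  }
  a <- .accel(species, field)
  diss <- ensemble[hit, , drop = FALSE]
  diss$position <- z[hit]
  diss$velocity <- diss$v0 + a * (probe$delta_t - diss$t_E)
  diss$time <- rep(probe$delta_t, nrow(diss))
  list(survivors = ensemble[!hit, , drop = FALSE], dissociated = diss)
}

#' Default fragment mass list
#'
#' Generic CnHm+ fragment masses (u) used purely to render the low-mass
#' signals that accompany probe depletion; they take no part in any
#' ejection-time inference.
#' @return Named list of [ion_species].
#' @export
default_fragment_species <- function() {
  m <- c(27, 39, 51, 63, 77)
  out <- lapply(m, function(x) ion_species(sprintf("CnHm+ %d", x), x))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

## rbind without the row-name bookkeeping of rbind.data.frame (the
## ensembles here run to 10^5 rows per cell)
.fast_rbind <- function(dfs) {
  dfs <- dfs[vapply(dfs, NROW, 0L) > 0]
  if (!length(dfs)) return(NULL)
  cols <- lapply(names(dfs[[1]]), function(nm)
    unlist(lapply(dfs, `[[`, nm), use.names = FALSE))
  names(cols) <- names(dfs[[1]])
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}

## detector arrival times for a (possibly multi-species) ion table
.arrival_times <- function(tab, species_by_label, instrument) {
  if (is.null(tab) || !nrow(tab)) return(numeric(0))
  out <- numeric(nrow(tab))
  for (lab in unique(tab$label)) {
    i <- tab$label == lab
    out[i] <- time_of_flight(tab$t_E[i], tab$v0[i], species_by_label[[lab]],
                             instrument)
  }
  out
}

#' Render a shot-averaged TOF spectrum
#'
#' Histograms detector arrival times of the surviving ions (all species
#' merged), optionally adds the fragment arrivals of dissociated ions
#' (each dissociated parent yields one fragment with a mass drawn from
#' `fragment_species`), applies per-bin Poisson shot noise to each shot's
#' integer counts, and averages over shots.
#'
#' @param survivors Ion table(s) with columns `shot`, `t_E`, `v0`, `label`
#'   (rbind of per-species survivors).
#' @param dissociated Ion table with additional `position`, `velocity`,
#'   `time` columns (may have zero rows).
#' @param species_by_label Named list of [ion_species], keyed by `label`,
#'   covering every parent label present.
#' @param instrument An [instrument_config].
#' @param bin_edges Uniform histogram bin edges in seconds.
#' @param fragments_on Render dissociated ions as low-mass fragments?
#' @param fragment_species Fragment list (see [default_fragment_species()]).
#' @param shot_noise Apply per-bin Poisson noise per shot?
#' @param n_shots Number of shots averaged (defaults to max shot index).
#' @param seed Optional seed for fragment assignment and shot noise.
#' @return A `maldi_spectrum`: list with `bin_edges`, `counts` (mean ions
#'   per shot per bin) and `metadata`.
#' @export
render_spectrum <- function(survivors, dissociated = NULL, species_by_label,
                            instrument, bin_edges,
                            fragments_on = TRUE,
                            fragment_species = default_fragment_species(),
                            shot_noise = TRUE, n_shots = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(bin_edges) >= 2)
  if (is.null(n_shots))
    n_shots <- max(1L, survivors$shot,
                   if (NROW(dissociated)) dissociated$shot else 1L)
  arr <- .arrival_times(survivors, species_by_label, instrument)
  shots <- if (NROW(survivors)) survivors$shot else integer(0)
  if (fragments_on && NROW(dissociated)) {
    frag_idx <- sample.int(length(fragment_species), NROW(dissociated),
                           replace = TRUE)
    farr <- numeric(NROW(dissociated))
    for (k in seq_along(fragment_species)) {
      i <- frag_idx == k
      if (!any(i)) next
      st <- kinematic_state(dissociated$position[i], dissociated$velocity[i],
                            dissociated$time[i])
      ## parent: heaviest species present is a safe upper bound for the
      ## mass check; fragments are far lighter than any parent here
      par <- species_by_label[[dissociated$label[which(i)[1]]]]
      farr[i] <- fragment_arrival(st, par, fragment_species[[k]], instrument)
    }
    arr <- c(arr, farr)
    shots <- c(shots, dissociated$shot)
  }
  out_of_range <- arr < bin_edges[1] | arr >= bin_edges[length(bin_edges)]
  if (any(out_of_range))
    stop("arrival times outside the bin range, e.g. (s): ",
         paste(signif(utils::head(arr[out_of_range], 5), 6), collapse = ", "))
  nb <- length(bin_edges) - 1L
  idx <- findInterval(arr, bin_edges, rightmost.closed = FALSE)
  if (shot_noise) {
    ## per-shot integer histograms in one tabulate, then Poisson per bin
    cs <- tabulate(idx + (shots - 1L) * nb, nbins = nb * n_shots)
    nz <- which(cs > 0)
    cs[nz] <- stats::rpois(length(nz), cs[nz])
    counts <- .rowSums(cs, nb, n_shots) / n_shots
  } else {
    counts <- tabulate(idx, nbins = nb) / n_shots
  }
  structure(list(bin_edges = bin_edges, counts = counts,
                 metadata = list(voltage = instrument$voltage,
                                 gap = instrument$gap,
                                 drift_length = instrument$drift_length,
                                 n_shots = n_shots,
                                 n_ions = length(arr),
                                 shot_noise = shot_noise,
                                 fragments_on = fragments_on)),
            class = "maldi_spectrum")
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf("<maldi_spectrum> %d bins (%.2f-%.2f us), %.1f ions/shot, %d shots\n",
              length(x$counts), x$bin_edges[1] * 1e6,
              x$bin_edges[length(x$bin_edges)] * 1e6,
              sum(x$counts), x$metadata$n_shots))
  invisible(x)
}

#' @export
plot.maldi_spectrum <- function(x, xlim = NULL, ...) {
  ctr <- .bin_centers(x) * 1e6
  plot(ctr, x$counts, type = "l", xlab = "TOF (us)",
       ylab = "mean ions / shot / bin", xlim = xlim, ...)
  invisible(x)
}

.bin_centers <- function(spectrum) {
  e <- spectrum$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

## deterministic per-cell seed stream, kept under 2^31
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

## shared bin edges for one voltage: from 0 to just past the slowest
## conceivable parent arrival (late ejection, zero initial velocity)
.scenario_bin_edges <- function(instrument, species_list, tE_max = 1e-6) {
  tmax <- max(vapply(species_list, function(sp)
    time_of_flight(tE_max, 0, sp, instrument), 0))
  nb <- ceiling(1.05 * tmax / instrument$bin_width)
  seq(0, nb * instrument$bin_width, by = instrument$bin_width)
}

#' Generate a full probe-scan scenario archive
#'
#' For each voltage, draws a fresh ensemble per spectrum and renders one
#' baseline (no probe) plus one probed spectrum per (slab, delay) cell.
#' Fully reproducible from the grid seed.
#'
#' @param grid A [scenario_grid].
#' @param models List of [plume_model] objects, one per species.
#' @param instrument_template An [instrument_config] whose gap, drift and
#'   binning are reused at every voltage (its own voltage is ignored).
#' @param dissociation_prob Probability that a probe-slab ion is removed.
#' @param fragments_on,shot_noise Passed to [render_spectrum()].
#' @return A `scenario_archive`: per-voltage baseline and probed spectra
#'   with full provenance (grid, model parameters, seed).
#' @export
generate_scenario <- function(grid, models = default_plume_models(),
                              instrument_template = instrument_config(4500),
                              dissociation_prob = 1,
                              fragments_on = TRUE, shot_noise = TRUE) {
  stopifnot(inherits(grid, "scenario_grid"))
  species_by_label <- lapply(models, `[[`, "species")
  names(species_by_label) <- vapply(species_by_label, `[[`, "", "label")
  cell <- 0L
  per_voltage <- lapply(grid$voltages, function(V) {
    inst <- instrument_config(V, gap = instrument_template$gap,
                              drift_length = instrument_template$drift_length,
                              bin_width = instrument_template$bin_width)
    edges <- .scenario_bin_edges(inst, species_by_label)
    draw_cell <- function(probe) {
      cell <<- cell + 1L
      s <- .derive_seed(grid$seed, cell)
      set.seed(s)
      ens_list <- lapply(models, sample_ions, n_shots = grid$shots_per_spectrum)
      if (is.null(probe)) {
        surv <- .fast_rbind(ens_list)
        diss <- NULL
      } else {
        parts <- lapply(ens_list, function(e)
          apply_probe(e, species_by_label[[e$label[1]]], inst$field, probe))
        surv <- .fast_rbind(lapply(parts, `[[`, "survivors"))
        diss <- .fast_rbind(lapply(parts, `[[`, "dissociated"))
      }
      render_spectrum(surv, diss, species_by_label, inst, edges,
                      fragments_on = fragments_on, shot_noise = shot_noise,
                      n_shots = grid$shots_per_spectrum)
    }
    baseline <- draw_cell(NULL)
    probed <- list()
    for (si in seq_along(grid$slabs)) {
      for (dt in grid$delays) {
        pr <- probe_event(dt, grid$slabs[[si]][1], grid$slabs[[si]][2],
                          dissociation_prob)
        key <- sprintf("slab%d_dt%.0fns", si, dt * 1e9)
        sp <- draw_cell(pr)
        sp$metadata$probe <- pr
        sp$metadata$slab_index <- si
        probed[[key]] <- sp
      }
    }
    list(instrument = inst, baseline = baseline, probed = probed)
  })
  names(per_voltage) <- sprintf("%.0fV", grid$voltages)
  structure(list(voltages = per_voltage, grid = grid, models = models,
                 species = species_by_label,
                 dissociation_prob = dissociation_prob,
                 fragments_on = fragments_on, shot_noise = shot_noise),
            class = "scenario_archive")
}

#' @export
print.scenario_archive <- function(x, ...) {
  n_probed <- sum(vapply(x$voltages, function(v) length(v$probed), 0L))
  cat(sprintf("<scenario_archive> %d voltages, %d baselines + %d probed spectra, seed %d\n",
              length(x$voltages), length(x$voltages), n_probed, x$grid$seed))
  invisible(x)
}
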