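## Spectrum differencing: locate the missing segment the probe carved out
## of a species' TOF peak, decide whether the packet centre was hit, and
## correct the probe position using the forward/backward remnant ratio.
##
## Sign convention: in a linear TOF, ions spatially ahead of the slab
## arrive EARLIER; "forward" remnant area therefore lies at earlier TOF
## than the missing segment.

#' Per-bin fractional depletion of a probed spectrum
#'
#' `d_i = max(0, (b_i - p_i) / b_i)` on bins whose baseline counts exceed
#' a floor (a fraction of the in-window maximum); bins below the floor are
#' reported as 0 so that peak tails cannot produce 0/0 artefacts.
#'
#' @param baseline,probed `maldi_spectrum` objects on identical bins.
#' @param peak_window `c(lo, hi)` TOF window (seconds) containing one
#'   species' peak.
#' @param floor_frac Baseline floor as a fraction of the window maximum.
#' @return A `depletion_profile`: data frame with `tof` (bin centres,
#'   window bins only), `baseline`, `probed`, `depletion`, plus the bin
#'   width as attribute `bin_width`.
#' @export
depletion_profile <- function(baseline, probed, peak_window,
                              floor_frac = 0.01) {
  if (length(baseline$bin_edges) != length(probed$bin_edges) ||
      any(abs(baseline$bin_edges - probed$bin_edges) > 1e-15))
    stop("baseline and probed spectra are binned differently")
  ctr <- .bin_centers(baseline)
  in_win <- ctr >= peak_window[1] & ctr <= peak_window[2]
  if (!any(in_win)) stop("peak_window contains no bins")
  b <- baseline$counts[in_win]
  p <- probed$counts[in_win]
  if (max(b) <= 0) stop("baseline has no counts in peak_window")
  ok <- b >= floor_frac * max(b)
  d <- numeric(length(b))
  d[ok] <- pmax(0, (b[ok] - p[ok]) / b[ok])
  structure(data.frame(tof = ctr[in_win], baseline = b, probed = p,
                       depletion = d),
            bin_width = diff(baseline$bin_edges[1:2]),
            class = c("depletion_profile", "data.frame"))
}

#' Find the missing segment in a depletion profile
#'
#' Scans for contiguous runs of bins with depletion at or above
#' `min_depth`, discards runs shorter than `min_width_bins`, and returns
#' the run with the largest integrated depletion (ties broken by earliest
#' TOF).
#'
#' The segment centroid is weighted by the absolute missing counts
#' `baseline - probed` per bin, i.e. it is the mean TOF of the ions the
#' probe removed.  (Weighting by the fractional depletion would collapse
#' to the run's geometric midpoint whenever depletion saturates, as it
#' does at the probe fluences modelled here.)
#'
#' @param profile A `depletion_profile`.
#' @param min_depth Minimum fractional depletion for a bin to count.
#' @param min_width_bins Minimum run length in bins.
#' @return A `depletion_segment` (list with `tof_window`, `depth` = max
#'   fractional depletion, `centroid` = missing-count-weighted TOF,
#'   `area` = integrated fractional depletion, `bins` = in-profile
#'   indices), or `NULL` if no run qualifies.
#' @export
find_missing_segment <- function(profile, min_depth = 0.15,
                                 min_width_bins = 3L) {
  above <- profile$depletion >= min_depth
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_width_bins)
  if (!length(runs)) return(NULL)
  areas <- vapply(runs, function(k)
    sum(profile$depletion[starts[k]:ends[k]]), 0)
  best <- runs[order(-areas, starts[runs])[1]]
  idx <- starts[best]:ends[best]
  d <- profile$depletion[idx]
  miss <- pmax(profile$baseline[idx] - profile$probed[idx], 0)
  if (sum(miss) <= 0) miss <- d   # degenerate: fall back to fractional weights
  hw <- attr(profile, "bin_width") / 2
  structure(list(
    tof_window = c(profile$tof[idx[1]] - hw, profile$tof[idx[length(idx)]] + hw),
    depth = max(d),
    centroid = sum(profile$tof[idx] * miss) / sum(miss),
    area = sum(d),
    bins = idx), class = "depletion_segment")
}

## centroid and FWHM of the baseline peak within the profile window;
## FWHM by linear interpolation of the half-maximum crossings
.peak_shape <- function(profile) {
  b <- profile$baseline
  tof <- profile$tof
  centroid <- sum(tof * b) / sum(b)
  imax <- which.max(b)
  half <- b[imax] / 2
  left <- imax
  while (left > 1 && b[left] > half) left <- left - 1
  t_left <- if (b[left] <= half && left < imax)
    tof[left] + (half - b[left]) / (b[left + 1] - b[left]) * (tof[left + 1] - tof[left])
  else tof[1]
  right <- imax
  n <- length(b)
  while (right < n && b[right] > half) right <- right + 1
  t_right <- if (b[right] <= half && right > imax)
    tof[right - 1] + (b[right - 1] - half) / (b[right - 1] - b[right]) * (tof[right] - tof[right - 1])
  else tof[n]
  list(centroid = centroid, fwhm = t_right - t_left, mode = tof[imax])
}

#' Was the packet centre inside the probe slab?
#'
#' True when the depletion segment's centroid falls within
#' `tolerance * FWHM` of the baseline peak centroid.
#'
#' @param profile The `depletion_profile` the segment came from (supplies
#'   the baseline peak shape).
#' @param segment A `depletion_segment`.
#' @param tolerance Fraction of the baseline FWHM (default 0.5).  With
#'   probe delays sampled on a 50-ns grid, the best-aligned delay for a
#'   slab can still leave the removed-ion centroid up to about half the
#'   peak FWHM from the peak centre; the remnant-area position correction
#'   absorbs exactly this misalignment, so such cells are accepted.
#' @return Logical flag.
#' @export
is_center_hit <- function(profile, segment, tolerance = 0.5) {
  if (is.null(segment)) return(FALSE)
  shape <- .peak_shape(profile)
  abs(segment$centroid - shape$centroid) <= tolerance * shape$fwhm
}

#' Correct the probe position using the remnant forward/backward ratio
#'
#' After the probe removes the slab's worth of ions, the remnant peak
#' splits into a forward part (earlier TOF; ions that were spatially ahead
#' of the slab) and a backward part.  Their area ratio locates the packet
#' centre inside the slab: `z = z_low + w * A_f / (A_f + A_b)` with `w`
#' the slab thickness.  Equal areas put the centre at the slab midpoint.
#'
#' @param slab `c(z_low, z_high)` in metres.
#' @param profile The `depletion_profile` (its `probed` column supplies
#'   the remnant areas).
#' @param segment The `depletion_segment` splitting forward from backward.
#' @return List with `z_corrected` (m) and `fwd_fraction` = `A_f / (A_f + A_b)`.
#' @export
correct_z <- function(slab, profile, segment) {
  stopifnot(!is.null(segment))
  fwd <- profile$tof < segment$tof_window[1]
  bwd <- profile$tof > segment$tof_window[2]
  a_f <- sum(profile$probed[fwd])
  a_b <- sum(profile$probed[bwd])
  if (a_f + a_b <= 0) stop("no remnant signal on either side of the segment")
  frac <- a_f / (a_f + a_b)
  list(z_corrected = slab[1] + (slab[2] - slab[1]) * frac,
       fwd_fraction = frac)
}

#' Expected TOF window of a species' peak
#'
#' A deliberately generous window derived only from the species identity
#' and the instrument (never from the generating distributions): arrival
#' times spanned by ejection times in `tE_range` and velocities in
#' `v0_range`, padded by `pad` seconds.
#'
#' @param species An [ion_species].
#' @param instrument An [instrument_config].
#' @param tE_range,v0_range Ranges (s, m/s) the window must cover.
#' @param pad Extra margin on each side, seconds.
#' @return `c(lo, hi)` in seconds.
#' @export
species_tof_window <- function(species, instrument,
                               tE_range = c(0, 300e-9),
                               v0_range = c(0, 2000), pad = 20e-9) {
  corners <- c(
    time_of_flight(tE_range[1], v0_range[2], species, instrument),
    time_of_flight(tE_range[2], v0_range[1], species, instrument))
  c(min(corners) - pad, max(corners) + pad)
}

#' Scan a scenario archive into observation points
#'
#' For every (voltage, slab, delay, species) cell: difference the probed
#' spectrum against that voltage's baseline inside the species' TOF
#' window, find the missing segment, keep the cell only if the packet
#' centre was hit, and correct the probe position by the remnant-area
#' ratio.  If several delays qualify for one slab, each becomes a point.
#'
#' @param archive A `scenario_archive` from [generate_scenario()], or a
#'   directory written by [write_scenario_archive()].
#' @param min_depth,min_width_bins Passed to [find_missing_segment()].
#' @param tolerance Passed to [is_center_hit()].
#' @param tE_window_max Upper ejection-time bound (s) used to size the
#'   species TOF windows.
#' @return Data frame of observation points: `label`, `voltage_V`,
#'   `field_Vm`, `delta_t` (s), `z_corrected` (m), `fwd_fraction`,
#'   `slab_low`, `slab_high` (m).
#' @export
scan_to_observations <- function(archive, min_depth = 0.15,
                                 min_width_bins = 3L, tolerance = 0.5,
                                 tE_window_max = 300e-9) {
  if (is.character(archive)) archive <- read_scenario_archive(archive)
  stopifnot(inherits(archive, "scenario_archive"))
  rows <- list()
  for (vname in names(archive$voltages)) {
    v <- archive$voltages[[vname]]
    if (is.null(v$baseline)) stop("missing baseline for voltage ", vname)
    for (sp in archive$species) {
      win <- species_tof_window(sp, v$instrument,
                                tE_range = c(0, tE_window_max))
      for (key in names(v$probed)) {
        probed <- v$probed[[key]]
        prof <- depletion_profile(v$baseline, probed, win)
        seg <- find_missing_segment(prof, min_depth, min_width_bins)
        if (is.null(seg) || !is_center_hit(prof, seg, tolerance)) next
        pr <- probed$metadata$probe
        ## a probe that swallowed the whole packet leaves no remnant to
        ## weigh; the slab midpoint is then the best available position
        cz <- tryCatch(correct_z(c(pr$slab_low, pr$slab_high), prof, seg),
                       error = function(e)
                         list(z_corrected = (pr$slab_low + pr$slab_high) / 2,
                              fwd_fraction = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          label = sp$label, voltage_V = v$instrument$voltage,
          field_Vm = v$instrument$field, delta_t = pr$delta_t,
          z_corrected = cz$z_corrected, fwd_fraction = cz$fwd_fraction,
          slab_low = pr$slab_low, slab_high = pr$slab_high)
      }
    }
  }
  if (!length(rows))
    return(data.frame(label = character(), voltage_V = numeric(),
                      field_Vm = numeric(), delta_t = numeric(),
                      z_corrected = numeric(), fwd_fraction = numeric(),
                      slab_low = numeric(), slab_high = numeric()))
  do.call(rbind, rows)
}
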