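# synthetic spectra on 1-ns bins for exercising the differencing stage
mk_spec <- function(counts, bin = 1e-9, t0 = 0) {
  structure(list(bin_edges = seq(t0, by = bin, length.out = length(counts) + 1),
                 counts = counts, metadata = list()),
            class = "maldi_spectrum")
}

gauss_counts <- function(n = 200, mu = 100, s = 15, height = 1000) {
  height * exp(-((seq_len(n) - mu) / s)^2 / 2)
}

test_that("depletion profiles are zero without depletion and one when emptied", {
  b <- mk_spec(gauss_counts())
  win <- c(0, 200e-9)
  expect_true(all(depletion_profile(b, b, win)$depletion == 0))

  p <- mk_spec(rep(0, 200))
  prof <- depletion_profile(b, p, win)
  above_floor <- prof$baseline >= 0.01 * max(prof$baseline)
  expect_true(all(prof$depletion[above_floor] == 1))
  expect_true(all(prof$depletion[!above_floor] == 0))

  bad <- mk_spec(gauss_counts(), bin = 2e-9)
  expect_error(depletion_profile(b, bad, win), "binned differently")
  expect_error(depletion_profile(b, b, c(300e-9, 400e-9)), "no bins")
})

test_that("segment search picks the largest-area qualifying run", {
  base <- rep(1000, 120)
  probed <- rep(1000, 120)
  probed[20:24] <- 200    # area 0.8 * 5 = 4.0
  probed[60:69] <- 500    # area 0.5 * 10 = 5.0
  prof <- depletion_profile(mk_spec(base), mk_spec(probed), c(0, 120e-9))

  seg <- find_missing_segment(prof)
  expect_equal(seg$bins, 60:69)
  expect_equal(seg$depth, 0.5)
  # saturated-run centroid: missing-count-weighted mean of the run
  expect_equal(seg$centroid, mean(prof$tof[60:69]))

  # flat profile: no segment
  expect_null(find_missing_segment(
    depletion_profile(mk_spec(base), mk_spec(base), c(0, 120e-9))))

  # runs below the width threshold are ignored
  probed2 <- rep(1000, 120); probed2[50:51] <- 0
  prof2 <- depletion_profile(mk_spec(base), mk_spec(probed2), c(0, 120e-9))
  expect_null(find_missing_segment(prof2, min_width_bins = 3))
  expect_equal(find_missing_segment(prof2, min_width_bins = 2)$bins, 50:51)

  # exact area tie: earliest run wins
  probed3 <- rep(1000, 120); probed3[10:14] <- 0; probed3[80:84] <- 0
  prof3 <- depletion_profile(mk_spec(base), mk_spec(probed3), c(0, 120e-9))
  expect_equal(find_missing_segment(prof3)$bins, 10:14)
})

test_that("segment detection is translation-covariant", {
  base <- c(gauss_counts(), rep(0, 40))
  probed <- base; probed[90:110] <- probed[90:110] * 0.1
  k <- 25
  prof <- depletion_profile(mk_spec(base), mk_spec(probed), c(0, 240e-9))
  prof_shift <- depletion_profile(mk_spec(c(rep(0, k), base[1:(240 - k)])),
                                  mk_spec(c(rep(0, k), probed[1:(240 - k)])),
                                  c(0, 240e-9))
  s1 <- find_missing_segment(prof)
  s2 <- find_missing_segment(prof_shift)
  expect_equal(s2$bins, s1$bins + k)
  expect_equal(s2$centroid - s1$centroid, k * 1e-9, tolerance = 1e-12)
})

test_that("centre hits are judged against the baseline peak", {
  base <- gauss_counts(n = 200, mu = 100, s = 15)
  # segment centred on the peak
  probed <- base; probed[95:105] <- 0
  prof <- depletion_profile(mk_spec(base), mk_spec(probed), c(0, 200e-9))
  seg <- find_missing_segment(prof)
  expect_true(is_center_hit(prof, seg))

  # segment a full FWHM away from the centroid fails at any tolerance < 1
  fw <- round(2 * sqrt(2 * log(2)) * 15)   # ~35 bins
  probed2 <- base; probed2[(95:105) - fw] <- 0
  prof2 <- depletion_profile(mk_spec(base), mk_spec(probed2), c(0, 200e-9))
  seg2 <- find_missing_segment(prof2)
  expect_false(is_center_hit(prof2, seg2))
  expect_false(is_center_hit(prof2, NULL))
})

test_that("the remnant-area rule locates the packet centre inside the slab", {
  slab <- c(0.6e-3, 1.6e-3)
  # remnants untouched by the probe on both sides of an emptied centre
  base <- rep(1000, 100)
  probed <- base; probed[31:70] <- 0
  prof <- depletion_profile(mk_spec(base), mk_spec(probed), c(0, 100e-9))
  seg <- find_missing_segment(prof)
  expect_equal(seg$bins, 31:70)
  cz <- correct_z(slab, prof, seg)
  expect_equal(cz$fwd_fraction, 0.5)
  expect_equal(cz$z_corrected, mean(slab))

  # forward area three times the backward area: 3/4 of the way up the slab
  base2 <- c(rep(900, 30), rep(1000, 40), rep(300, 30))
  probed2 <- base2; probed2[31:70] <- 0
  prof2 <- depletion_profile(mk_spec(base2), mk_spec(probed2), c(0, 100e-9))
  cz2 <- correct_z(slab, prof2, find_missing_segment(prof2))
  expect_equal(cz2$fwd_fraction, 0.75)
  expect_equal(cz2$z_corrected, slab[1] + 0.75 * diff(slab))
  expect_true(cz2$z_corrected >= slab[1] && cz2$z_corrected <= slab[2])

  # no remnant at all: nothing to weigh
  empty <- mk_spec(rep(0, 100))
  prof3 <- depletion_profile(mk_spec(base), empty, c(0, 100e-9))
  expect_error(correct_z(slab, prof3, find_missing_segment(prof3)),
               "remnant")
})

test_that("on noise-free spectra the segment is the TOF image of the slab", {
  m <- default_plume_models()$monomer
  m$ions_per_shot <- 20000L
  inst <- instrument_config(4500)
  sp_by <- list("(CHCA)H+" = m$species)
  edges <- seq(14.8e-6, 15.8e-6, by = inst$bin_width)
  ens <- sample_ions(m, 1, seed = 17)
  pr <- probe_event(150e-9, 0.6e-3, 1.6e-3)
  parts <- apply_probe(ens, m$species, inst$field, pr)
  base <- render_spectrum(ens, NULL, sp_by, inst, edges,
                          fragments_on = FALSE, shot_noise = FALSE, n_shots = 1)
  probed <- render_spectrum(parts$survivors, NULL, sp_by, inst, edges,
                            fragments_on = FALSE, shot_noise = FALSE,
                            n_shots = 1)
  prof <- depletion_profile(base, probed, species_tof_window(m$species, inst))
  seg <- find_missing_segment(prof)

  # ions on the slab boundaries at the probe instant map to the segment edges
  tE_hi <- invert_ejection_time(pr$slab_low, pr$delta_t, m$v0_mean,
                                m$species, inst$field)$t_E
  tE_lo <- invert_ejection_time(pr$slab_high, pr$delta_t, m$v0_mean,
                                m$species, inst$field)$t_E
  tof_lo <- time_of_flight(tE_lo, m$v0_mean, m$species, inst)
  tof_hi <- time_of_flight(tE_hi, m$v0_mean, m$species, inst)
  # the baseline floor clips the visible segment inside the slab image;
  # both edges must agree to a few bins where the peak has support
  expect_gt(seg$tof_window[1], tof_lo - 3 * inst$bin_width)
  expect_lt(seg$tof_window[2], tof_hi + 3 * inst$bin_width)
  expect_gt(seg$tof_window[2] - seg$tof_window[1], 10 * inst$bin_width)
})

test_that("scanning an archive yields centre-hit observation points", {
  g <- tiny_grid(delays = c(100, 150, 200) * 1e-9, seed = 42,
                 shots = 10)
  arc <- generate_scenario(g, tiny_models(3000))
  obs <- scan_to_observations(arc)
  mono <- obs[obs$label == "(CHCA)H+", ]
  # the monomer transit of the 0.6-1.6 mm slab at 4.5 kV peaks at 150 ns
  expect_true(any(abs(mono$delta_t - 150e-9) < 1e-15))
  expect_false(any(abs(mono$delta_t - 100e-9) < 1e-15))
  expect_true(all(obs$z_corrected >= obs$slab_low &
                  obs$z_corrected <= obs$slab_high))
  expect_true(all(obs$fwd_fraction >= 0 & obs$fwd_fraction <= 1))

  # no-probe grid gives an empty table with the documented columns
  g0 <- tiny_grid(delays = 0, seed = 42)
  obs0 <- scan_to_observations(generate_scenario(g0, tiny_models(200)))
  expect_equal(nrow(obs0), 0L)
  expect_true(all(c("label", "voltage_V", "delta_t", "z_corrected",
                    "fwd_fraction") %in% names(obs0)))

  # a missing baseline is an error naming the voltage
  arc_broken <- arc
  arc_broken$voltages[[1]]$baseline <- NULL
  expect_error(scan_to_observations(arc_broken), "baseline")
})
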