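test_that("ensemble draws are reproducible and respect the distributions", {
  m <- default_plume_models()$monomer
  m$ions_per_shot <- 500L
  a <- sample_ions(m, n_shots = 4, seed = 99)
  b <- sample_ions(m, n_shots = 4, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 2000L)
  expect_equal(unique(a$shot), 1:4)
  expect_true(all(a$t_E >= 0) && all(a$v0 >= 0))

  # degenerate spread: every ion identical
  m0 <- m; m0$tE_sd <- 0
  d <- sample_ions(m0, 1, seed = 1)
  expect_true(all(d$t_E == m$tE_mean))

  # law of large numbers; truncation at zero is by redraw, and with a
  # mean four sds above zero it barely shifts the mean
  mbig <- m; mbig$ions_per_shot <- 100000L
  big <- sample_ions(mbig, 1, seed = 3)
  se <- m$tE_sd / sqrt(1e5)
  expect_lt(abs(mean(big$t_E) - m$tE_mean), 3.2 * se)

  # lognormal option is moment-matched
  ml <- m; ml$tE_shape <- "lognormal"; ml$ions_per_shot <- 100000L
  lg <- sample_ions(ml, 1, seed = 4)
  expect_equal(mean(lg$t_E), m$tE_mean, tolerance = 2e-3)
  expect_equal(sd(lg$t_E), m$tE_sd, tolerance = 2e-2)
})

test_that("ensemble positions follow the closed-form trajectory", {
  m <- default_plume_models()$monomer
  inst <- instrument_config(4500)
  ens <- sample_ions(m, n_shots = 3, seed = 5)  # 15000 ions

  expect_true(all(positions_at(ens, m$species, inst$field, 0) == 0))

  # dispersionless ensemble reproduces the closed form exactly
  m0 <- m; m0$tE_sd <- 0; m0$v0_sd <- 0; m0$ions_per_shot <- 10L
  e0 <- sample_ions(m0, 1, seed = 1)
  expect_equal(positions_at(e0, m$species, inst$field, 150e-9),
               rep(propagate_distance(m$tE_mean, m$v0_mean, m$species,
                                      inst$field, 150e-9), 10))

  # ensemble centroid tracks the closed form at the distribution means
  z <- positions_at(ens, m$species, inst$field, 150e-9)
  z_ctr <- propagate_distance(m$tE_mean, m$v0_mean, m$species, inst$field,
                              150e-9)
  expect_equal(mean(z), z_ctr, tolerance = 0.01)

  # monomer packet centred inside the first slab near delta_t = 150 ns
  expect_gt(z_ctr, 0.6e-3)
  expect_lt(z_ctr, 1.6e-3)
})

test_that("the probe partitions an ensemble exhaustively and disjointly", {
  m <- default_plume_models()$monomer
  m$ions_per_shot <- 2000L
  inst <- instrument_config(4500)
  ens <- sample_ions(m, 2, seed = 8)

  pr <- probe_event(150e-9, 0.6e-3, 1.6e-3)
  parts <- apply_probe(ens, m$species, inst$field, pr)
  expect_equal(nrow(parts$survivors) + nrow(parts$dissociated), nrow(ens))
  z <- positions_at(parts$dissociated, m$species, inst$field, pr$delta_t)
  expect_true(all(z >= pr$slab_low & z < pr$slab_high))
  zs <- positions_at(parts$survivors, m$species, inst$field, pr$delta_t)
  expect_true(all(zs < pr$slab_low | zs >= pr$slab_high))

  # inert probe: nothing removed
  pr0 <- probe_event(150e-9, 0.6e-3, 1.6e-3, dissociation_prob = 0)
  expect_equal(nrow(apply_probe(ens, m$species, inst$field, pr0)$dissociated), 0L)

  # slab beyond the plume: nothing removed
  far <- probe_event(150e-9, 10e-3, 11e-3)
  expect_equal(nrow(apply_probe(ens, m$species, inst$field, far)$dissociated), 0L)

  # dissociated ions carry the kinematic state at the probe instant
  a <- oracle_accel(m$species, inst$field)
  d <- parts$dissociated
  expect_equal(d$velocity, d$v0 + a * (pr$delta_t - d$t_E), tolerance = 1e-12)
})

test_that("rendered spectra conserve ions and show the probe's missing segment", {
  m <- default_plume_models()$monomer
  m$ions_per_shot <- 3000L
  inst <- instrument_config(4500)
  sp_by <- list("(CHCA)H+" = m$species)
  edges <- seq(14e-6, 17e-6, by = inst$bin_width)
  ens <- sample_ions(m, 4, seed = 12)

  base <- render_spectrum(ens, NULL, sp_by, inst, edges,
                          fragments_on = FALSE, shot_noise = FALSE,
                          n_shots = 4)
  expect_equal(sum(base$counts) * 4, nrow(ens))

  pr <- probe_event(150e-9, 0.6e-3, 1.6e-3)
  parts <- apply_probe(ens, m$species, inst$field, pr)
  probed <- render_spectrum(parts$survivors, parts$dissociated, sp_by, inst,
                            edges, fragments_on = FALSE, shot_noise = FALSE,
                            n_shots = 4)
  # same ensemble, no noise: depletion can only remove counts
  expect_true(all(probed$counts <= base$counts + 1e-12))

  # centre hit leaves a bimodal remnant: mass on both sides of a gap
  gap_bins <- which(base$counts > max(base$counts) * 0.3 & probed$counts == 0)
  expect_gt(length(gap_bins), 0)
  expect_gt(sum(probed$counts[seq_len(min(gap_bins) - 1)]), 0)
  expect_gt(sum(probed$counts[seq(max(gap_bins) + 1, length(probed$counts))]), 0)

  # with fragments rendered into a full-range spectrum, counts conserve
  full_edges <- seq(0, 17e-6, by = 4e-9)
  probed_full <- render_spectrum(parts$survivors, parts$dissociated, sp_by,
                                 inst, full_edges, fragments_on = TRUE,
                                 shot_noise = FALSE, n_shots = 4)
  expect_equal(sum(probed_full$counts) * 4, nrow(ens))

  # arrivals outside the bin range are a named error
  expect_error(render_spectrum(ens, NULL, sp_by, inst,
                               seq(0, 1e-6, by = 1e-8),
                               fragments_on = FALSE, shot_noise = FALSE,
                               n_shots = 4),
               "outside the bin range")
})

test_that("scenario archives have the promised shape and are seed-reproducible", {
  g1 <- tiny_grid(delays = 150e-9, seed = 21, shots = 2)
  arc1 <- generate_scenario(g1, tiny_models(200))
  expect_length(arc1$voltages, 1)
  expect_length(arc1$voltages[[1]]$probed, 1)  # 1 baseline + 1 probed

  g <- scenario_grid(slabs = list(c(0.6e-3, 1.6e-3), c(1.6e-3, 2.6e-3)),
                     delays = c(100, 150, 200) * 1e-9,
                     voltages = c(3500, 4500), shots_per_spectrum = 2,
                     seed = 33)
  arc <- generate_scenario(g, tiny_models(200))
  expect_length(arc$voltages, 2)                       # one baseline each
  expect_length(arc$voltages[[1]]$probed, 2 * 3)       # slabs x delays

  arc_again <- generate_scenario(g, tiny_models(200))
  expect_identical(arc$voltages[["4500V"]]$baseline$counts,
                   arc_again$voltages[["4500V"]]$baseline$counts)
  key <- names(arc$voltages[[1]]$probed)[3]
  expect_identical(arc$voltages[[1]]$probed[[key]]$counts,
                   arc_again$voltages[[1]]$probed[[key]]$counts)

  g2 <- g; g2$seed <- 34L
  arc_other <- generate_scenario(g2, tiny_models(200))
  expect_false(identical(arc$voltages[[1]]$baseline$counts,
                         arc_other$voltages[[1]]$baseline$counts))
})
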