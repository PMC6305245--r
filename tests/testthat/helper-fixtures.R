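# Small, fast simulation fixtures shared across test files.

monomer <- chca_species()[["(CHCA)H+"]]
dimer <- chca_species()[["(CHCA)2H+"]]

# reduced-size models: same distributions as the defaults, fewer ions
tiny_models <- function(ions_per_shot = 1000L) {
  lapply(default_plume_models(), function(m) {
    m$ions_per_shot <- as.integer(ions_per_shot)
    m
  })
}

# single-voltage grid around the monomer transit of the first slab
tiny_grid <- function(delays = c(100, 150, 200) * 1e-9, seed = 42L,
                      slabs = list(c(0.6e-3, 1.6e-3)), voltages = 4500,
                      shots = 5L) {
  scenario_grid(slabs = slabs, delays = delays, voltages = voltages,
                shots_per_spectrum = shots, seed = seed)
}
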