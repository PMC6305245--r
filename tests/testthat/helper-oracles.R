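# Independent numeric oracles, kept free of the package's closed forms.

# acceleration q e E / m for a species (duplicated from first principles on
# purpose: the oracle must not call package internals)
oracle_accel <- function(species, field) {
  e_charge <- 1.602176634e-19
  species$charge * e_charge * field / species$mass_kg
}

# velocity-Verlet integration of x'' = a from (x=0, v=v0) over tau seconds;
# vectorized over cases.  Returns final positions.
verlet_position <- function(t_E, v0, a, delta_t, dt = 1e-11) {
  n <- max(length(t_E), length(v0), length(a), length(delta_t))
  t_E <- rep_len(t_E, n); v0 <- rep_len(v0, n)
  a <- rep_len(a, n); delta_t <- rep_len(delta_t, n)
  tau <- pmax(delta_t - t_E, 0)
  nstep <- floor(tau / dt)
  x <- numeric(n); v <- v0
  for (k in seq_len(max(nstep))) {
    act <- nstep >= k
    x[act] <- x[act] + v[act] * dt + 0.5 * a[act] * dt^2
    v[act] <- v[act] + a[act] * dt
  }
  rem <- tau - nstep * dt
  x + v * rem + 0.5 * a * rem^2
}

# velocity-Verlet flight time: accelerate from (x0, v0) until crossing the
# gap (linear interpolation inside the crossing step), then drift.
verlet_tof <- function(t_E, v0, a, gap, drift, dt = 1e-11, x0 = 0) {
  n <- max(length(t_E), length(v0), length(a), length(x0))
  t_E <- rep_len(t_E, n); v0 <- rep_len(v0, n)
  a <- rep_len(a, n); x0 <- rep_len(x0, n)
  x <- x0; v <- v0
  t_cross <- rep(NA_real_, n); v_cross <- rep(NA_real_, n)
  t <- 0
  while (anyNA(t_cross)) {
    act <- is.na(t_cross)
    x_new <- x[act] + v[act] * dt + 0.5 * a[act] * dt^2
    v_new <- v[act] + a[act] * dt
    crossed <- x_new >= gap
    if (any(crossed)) {
      i <- which(act)[crossed]
      frac <- (gap - x[i]) / (x_new[crossed] - x[i])
      t_cross[i] <- t + frac * dt
      v_cross[i] <- v[i] + a[i] * frac * dt
    }
    x[act] <- x_new; v[act] <- v_new
    t <- t + dt
  }
  t_E + t_cross + drift / v_cross
}

# brute-force inversion: scan t_E on a fine grid, pick the best fit to z
scan_invert_tE <- function(z, delta_t, v0, species, field, step = 1e-11) {
  grid <- seq(0, delta_t, by = step)
  a <- oracle_accel(species, field)
  tau <- delta_t - grid
  zz <- v0 * tau + 0.5 * a * tau^2
  grid[which.min(abs(zz - z))]
}
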