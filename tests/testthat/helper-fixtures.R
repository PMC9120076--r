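# Shared small-scale fixtures for fast unit tests.

small_grid <- function() list(n = c(128L, 128L), pixel_mm = 0.1)

small_geom <- function(n_elements = 128L) {
  ring_geometry(n_elements = n_elements, radius_mm = 10, fs_mhz = 20,
                n_samples = 320L)
}

# Point-source initial pressure at pixel (row, col) on the small grid
point_p0 <- function(row, col, value = 1, grid = small_grid()) {
  m <- matrix(0, grid$n[1], grid$n[2])
  m[row, col] <- value
  m
}

# mm coordinates of a pixel centre on a grid (origin at grid centre)
pixel_mm_coords <- function(row, col, grid) {
  c(x = (col - (grid$n[2] + 1) / 2) * grid$pixel_mm,
    y = (row - (grid$n[1] + 1) / 2) * grid$pixel_mm)
}

# Brute-force fine-step Euler integration of the switching kinetics,
# independent of the event-based solver in the package.
euler_trajectory <- function(schedule, kin, f0 = 0, dt = 1e-4) {
  np <- pulses_per_cycle(schedule)
  pulse_rel <- (seq_len(np) - 1) / schedule$pulse_rate
  f <- f0
  out <- numeric(0)
  for (cyc in seq_len(schedule$n_cycles)) {
    for (i in seq_len(round(schedule$t_on_phase / dt))) {
      f <- f + dt * kin$k_on * (1 - f)
    }
    t <- 0
    k_next <- 1
    n_steps <- round(schedule$t_imaging_phase / dt)
    for (i in seq_len(n_steps)) {
      if (k_next <= np && t >= pulse_rel[k_next] - dt / 2) {
        out <- c(out, f)
        f <- f * (1 - kin$delta_off_pulse)
        k_next <- k_next + 1
      }
      if (t >= schedule$t_790_delay) f <- f - dt * kin$k_off_cw * f
      t <- t + dt
    }
  }
  out
}

expect_images_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
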