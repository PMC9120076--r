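#' Ring transducer-array geometry
#'
#' Full-ring detection geometry with uniformly spaced point-like elements.
#' Defaults are a desk-scale analogue of a whole-body small-animal ring
#' scanner: 512 elements on a 20 mm radius, homogeneous speed of sound
#' 1.5 mm/us, 20 MHz sampling. 512 elements keep the angular sampling above
#' the Nyquist requirement of the transducer pass-band over the field of
#' view; fewer elements leave visible streak artifacts.
#'
#' @param n_elements Number of elements on the ring.
#' @param radius_mm Ring radius, mm; must exceed the phantom half-extent.
#' @param center_mm Ring centre (x, y), mm.
#' @param c_mm_us Speed of sound, mm/us.
#' @param fs_mhz Sampling rate, MHz.
#' @param n_samples Samples per acquisition.
#' @return A `ring_geometry` object with element positions precomputed.
#' @export
ring_geometry <- function(n_elements = 512L, radius_mm = 20,
                          center_mm = c(0, 0), c_mm_us = 1.5,
                          fs_mhz = 20, n_samples = 640L) {
  stopifnot(n_elements >= 3, radius_mm > 0, c_mm_us > 0, fs_mhz > 0,
            n_samples > 2)
  ang <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
  structure(list(n_elements = as.integer(n_elements), radius_mm = radius_mm,
                 center_mm = center_mm, c_mm_us = c_mm_us, fs_mhz = fs_mhz,
                 n_samples = as.integer(n_samples),
                 elem_x = center_mm[1] + radius_mm * cos(ang),
                 elem_y = center_mm[2] + radius_mm * sin(ang)),
            class = "ring_geometry")
}

#' Transducer frequency response
#' @param center_freq_mhz Centre frequency, MHz.
#' @param fractional_bandwidth One-way fractional bandwidth (e.g. 0.8).
#' @export
transducer_response <- function(center_freq_mhz = 4, fractional_bandwidth = 0.8) {
  stopifnot(center_freq_mhz > 0, fractional_bandwidth > 0)
  structure(list(center_freq_mhz = center_freq_mhz,
                 fractional_bandwidth = fractional_bandwidth),
            class = "transducer_response")
}

#' Acquisition physics configuration
#'
#' Grueneisen efficiency, surface fluence and its depth model, and additive
#' sensor noise. With `fluence_mode = "attenuated"` the local fluence decays
#' as exp(-mu_eff * depth) with depth measured radially inward from a
#' circular skin surface of radius `body_radius_mm`.
#'
#' @param grueneisen Grueneisen parameter (dimensionless).
#' @param fluence_mj_cm2 Surface fluence, mJ/cm^2.
#' @param fluence_mode "uniform" or "attenuated".
#' @param mu_eff_mm Effective optical attenuation, mm^-1 (attenuated mode).
#' @param body_radius_mm Radius of the skin surface for the depth model, mm.
#' @param noise_std Std of additive Gaussian sensor noise (sinogram units).
#' @param seed Optional integer seed for the noise stream.
#' @export
acoustics_config <- function(grueneisen = 0.2, fluence_mj_cm2 = 5,
                             fluence_mode = c("uniform", "attenuated"),
                             mu_eff_mm = 0.1, body_radius_mm = 11,
                             noise_std = 0, seed = NULL) {
  fluence_mode <- match.arg(fluence_mode)
  stopifnot(grueneisen > 0, fluence_mj_cm2 > 0, noise_std >= 0, mu_eff_mm >= 0)
  structure(list(grueneisen = grueneisen, fluence_mj_cm2 = fluence_mj_cm2,
                 fluence_mode = fluence_mode, mu_eff_mm = mu_eff_mm,
                 body_radius_mm = body_radius_mm, noise_std = noise_std,
                 seed = seed),
            class = "acoustics_config")
}

#' Initial photoacoustic pressure
#'
#' p0 = Grueneisen * F(x, y) * mu_a(x, y). In uniform mode F is constant; in
#' attenuated mode F decays exponentially with depth below the circular skin
#' surface.
#'
#' @param mu_a Absorption coefficient map, mm^-1.
#' @param cfg An `acoustics_config`.
#' @param pixel_mm Pixel size (needed for the depth model), mm.
#' @return Initial-pressure map (arbitrary units), same size as `mu_a`.
#' @export
initial_pressure <- function(mu_a, cfg, pixel_mm = 0.1) {
  stopifnot(inherits(cfg, "acoustics_config"), all(mu_a >= 0))
  Fmap <- cfg$fluence_mj_cm2
  if (cfg$fluence_mode == "attenuated") {
    grid <- list(n = dim(mu_a), pixel_mm = pixel_mm)
    co <- .phantom_coords(grid)
    depth <- pmax(0, cfg$body_radius_mm - sqrt(co$x^2 + co$y^2))
    Fmap <- cfg$fluence_mj_cm2 * exp(-cfg$mu_eff_mm * depth)
  }
  cfg$grueneisen * Fmap * mu_a
}

.new_sinogram <- function(data, geom, wavelength = NA_real_, pulse = NA_integer_,
                          cycle = NA_integer_, f = NA_real_) {
  structure(list(data = data, geom = geom, wavelength = wavelength,
                 pulse = pulse, cycle = cycle, f = f),
            class = "sinogram")
}

#' Forward project an initial-pressure map onto a ring array
#'
#' Far-field circular-mean model of 2D photoacoustic wave propagation: the
#' detected signal of each element at time t is the mean of p0 over the
#' circle of radius c*t about the element (zero outside the grid), followed
#' by the time-derivative operator. The circular means are accumulated by
#' depositing each pixel's p0, weighted by pixel area, into the two time
#' bins bracketing its travel time, then normalising by the annulus measure.
#'
#' @param p0 Initial-pressure map.
#' @param geom A `ring_geometry`.
#' @param pixel_mm Pixel size, mm.
#' @return A noise-free wideband `sinogram` (n_elements x n_samples).
#' @export
forward_project <- function(p0, geom, pixel_mm = 0.1) {
  stopifnot(inherits(geom, "ring_geometry"), all(is.finite(p0)))
  grid <- list(n = dim(p0), pixel_mm = pixel_mm)
  co <- .phantom_coords(grid)
  half <- max(abs(range(co$x)), abs(range(co$y)))
  if (geom$radius_mm <= half * sqrt(2)) {
    # ring must enclose the grid corners
    if (any(p0[sqrt(co$x^2 + co$y^2) >= geom$radius_mm] != 0)) {
      stop("geometry does not enclose the support of p0", call. = FALSE)
    }
  }
  dt <- 1 / geom$fs_mhz                  # us
  dr <- geom$c_mm_us * dt                # mm per sample
  dmax <- geom$radius_mm + sqrt(max(co$x^2 + co$y^2))
  if (dmax / dr + 2 > geom$n_samples) {
    stop(sprintf("n_samples too short: need >= %d to cover the farthest pixel",
                 ceiling(dmax / dr) + 2L), call. = FALSE)
  }
  px <- as.vector(co$x); py <- as.vector(co$y); v <- as.vector(p0)
  nz <- which(v != 0)
  out <- matrix(0, geom$n_elements, geom$n_samples)
  pix_area <- pixel_mm^2
  t_idx <- seq_len(geom$n_samples)
  r_k <- pmax(t_idx - 1, 0.5) * dr       # annulus radius per bin (avoid r=0)
  ann <- 2 * pi * r_k * dr               # annulus measure
  if (length(nz) > 0) {
    vx <- v[nz] * pix_area
    for (e in seq_len(geom$n_elements)) {
      d <- sqrt((px[nz] - geom$elem_x[e])^2 + (py[nz] - geom$elem_y[e])^2)
      s <- d / dr + 1                    # fractional sample index (1-based)
      i0 <- floor(s); fr <- s - i0
      idx <- c(i0, i0 + 1)
      w <- c(vx * (1 - fr), vx * fr)
      acc <- rowsum(w, idx)
      out[e, as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  M <- sweep(out, 2, ann, "/")           # circular means
  # central-difference time derivative
  d1 <- (cbind(M[, -1, drop = FALSE], 0) -
           cbind(0, M[, -geom$n_samples, drop = FALSE])) / (2 * dt)
  .new_sinogram(d1, geom)
}

#' Apply the transducer band-pass response
#'
#' Zero-phase frequency-domain band-pass centred on the transducer centre
#' frequency, with a Gaussian magnitude whose full width at half maximum
#' equals the fractional bandwidth times the centre frequency. The response
#' is built as H(f) = g(|f| - fc) - g(|f| + fc), which is exactly zero at DC.
#'
#' @param sino A `sinogram`.
#' @param resp A `transducer_response`.
#' @return The filtered `sinogram`.
#' @export
apply_transducer <- function(sino, resp) {
  stopifnot(inherits(sino, "sinogram"), inherits(resp, "transducer_response"))
  geom <- sino$geom
  fmax_needed <- 2 * resp$center_freq_mhz * (1 + resp$fractional_bandwidth / 2)
  if (geom$fs_mhz <= fmax_needed) {
    stop(sprintf("sampling rate %g MHz violates the band-pass condition (> %g MHz)",
                 geom$fs_mhz, fmax_needed), call. = FALSE)
  }
  ns <- ncol(sino$data)
  f <- geom$fs_mhz * c(0:(ns %/% 2), -((ns - ns %/% 2 - 1):1)) / ns
  sigma <- resp$fractional_bandwidth * resp$center_freq_mhz / (2 * sqrt(2 * log(2)))
  g <- function(x) exp(-x^2 / (2 * sigma^2))
  H <- g(abs(f) - resp$center_freq_mhz) - g(abs(f) + resp$center_freq_mhz)
  Y <- t(stats::mvfft(t(sino$data)))
  sino$data <- Re(t(stats::mvfft(t(Y * rep(H, each = nrow(Y))), inverse = TRUE))) / ns
  sino
}

#' Add sensor noise to a sinogram
#'
#' I.i.d. zero-mean Gaussian noise of standard deviation `noise_std`. With a
#' `seed` the draw is reproducible and the caller's RNG state is untouched;
#' with `seed = NULL` the current RNG stream is consumed.
#'
#' @param sino A `sinogram`.
#' @param noise_std Noise standard deviation (sinogram units).
#' @param seed Optional integer seed.
#' @export
add_noise <- function(sino, noise_std, seed = NULL) {
  stopifnot(inherits(sino, "sinogram"), noise_std >= 0)
  if (noise_std == 0) return(sino)
  draw <- function() matrix(stats::rnorm(length(sino$data), sd = noise_std),
                            nrow(sino$data), ncol(sino$data))
  noise <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  sino$data <- sino$data + noise
  sino
}

#' Simulate a photoswitching acquisition
#'
#' Runs the photoswitching kinetics over the schedule and forward-models one
#' sinogram per imaging pulse at the imaging wavelength, with the total
#' probe concentration split between Pfr and Pr according to the trajectory,
#' then applies the transducer response and additive noise.
#'
#' @param phantom A `phantom`.
#' @param lib A `spectral_library`.
#' @param schedule An `illumination_schedule`.
#' @param kin A `kinetics_params`.
#' @param geom A `ring_geometry`.
#' @param resp A `transducer_response`.
#' @param cfg An `acoustics_config`.
#' @param pulses "all" to record every pulse, or "endpoints" to record only
#'   the first `m` and last `m` pulses of each cycle (the ON- and OFF-state
#'   frames used by the differential pipeline).
#' @param m Frames per state when `pulses = "endpoints"`.
#' @param f0 Initial Pfr fraction.
#' @return List of `sinogram` objects with `cycle`, `pulse` and `f` fields.
#' @export
simulate_acquisition <- function(phantom, lib, schedule, kin, geom, resp, cfg,
                                 pulses = c("all", "endpoints"), m = 1, f0 = 0) {
  pulses <- match.arg(pulses)
  traj <- pfr_trajectory(schedule, kin, f0 = f0)
  np <- pulses_per_cycle(schedule)
  if (pulses == "endpoints") {
    if (2 * m > np) stop("m too large for pulses per cycle", call. = FALSE)
    keep <- traj$pulse <= m | traj$pulse > np - m
    traj <- traj[keep, , drop = FALSE]
  }
  lapply(seq_len(nrow(traj)), function(i) {
    mu <- absorption_map(phantom, lib, schedule$imaging_wavelength_nm,
                         f = traj$f[i])
    p0 <- initial_pressure(mu, cfg, pixel_mm = phantom$grid$pixel_mm)
    s <- forward_project(p0, geom, pixel_mm = phantom$grid$pixel_mm)
    s <- apply_transducer(s, resp)
    s <- add_noise(s, cfg$noise_std)
    s$wavelength <- schedule$imaging_wavelength_nm
    s$pulse <- traj$pulse[i]; s$cycle <- traj$cycle[i]; s$f <- traj$f[i]
    s
  })
}
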