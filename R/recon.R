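#' @keywords internal
.backproject <- function(sino, grid, term) {
  geom <- sino$geom
  co <- .phantom_coords(grid)
  dt <- 1 / geom$fs_mhz
  dr <- geom$c_mm_us * dt
  ns <- geom$n_samples
  px <- as.vector(co$x); py <- as.vector(co$y)
  inside <- sqrt(px^2 + py^2) < geom$radius_mm
  img <- numeric(length(px))
  n_bad <- 0L
  for (e in seq_len(geom$n_elements)) {
    d <- sqrt((px - geom$elem_x[e])^2 + (py - geom$elem_y[e])^2)
    s <- d / dr + 1
    i0 <- floor(s); fr <- s - i0
    bad <- i0 + 1 > ns
    if (any(bad & inside)) n_bad <- max(n_bad, sum(bad & inside))
    i0[bad] <- ns - 1L; fr[bad] <- 0
    img <- img + term[e, i0] * (1 - fr) + term[e, i0 + 1] * fr
  }
  if (n_bad > 0) {
    stop(sprintf("travel time beyond recorded samples for %d pixel(s)", n_bad),
         call. = FALSE)
  }
  img <- img / geom$n_elements
  img[!inside] <- 0
  matrix(img, grid$n[1], grid$n[2])
}

.recon_grid <- function(sino, grid) {
  if (is.null(grid)) grid <- list(n = c(256L, 256L), pixel_mm = 0.1)
  grid
}

#' Universal back-projection reconstruction
#'
#' Reconstructs the initial-pressure distribution from a ring-array sinogram
#' by back-projecting the filtered term b(t) = 2*p(t) - 2*t*dp/dt along
#' circular isochrones, a 2D full-ring adaptation of the universal
#' back-projection formula with uniform angular weights. The time derivative
#' uses central differences; arc values are linearly interpolated in time.
#' Pixels outside the ring are not reconstructed (set to zero).
#'
#' @param sino A `sinogram`.
#' @param grid Reconstruction grid: list with `n` (rows, cols) and
#'   `pixel_mm`. Defaults to a 256 x 256 grid at 0.1 mm matching the default
#'   phantom grid.
#' @return A `recon_image`: list with `pixels` (matrix), `grid`, and the
#'   provenance fields of the sinogram.
#' @export
ubp_reconstruct <- function(sino, grid = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  grid <- .recon_grid(sino, grid)
  geom <- sino$geom
  dt <- 1 / geom$fs_mhz
  tvec <- (seq_len(geom$n_samples) - 1) * dt
  p <- sino$data
  ns <- geom$n_samples
  dp <- (cbind(p[, -1, drop = FALSE], 0) -
           cbind(0, p[, -ns, drop = FALSE])) / (2 * dt)
  b <- 2 * p - 2 * sweep(dp, 2, tvec, "*")
  structure(list(pixels = .backproject(sino, grid, b), grid = grid,
                 wavelength = sino$wavelength, pulse = sino$pulse,
                 cycle = sino$cycle, f = sino$f, method = "ubp"),
            class = "recon_image")
}

#' Delay-and-sum reconstruction
#'
#' Plain delay-and-sum beamforming of the raw sinogram (no filter term);
#' an independent cross-check for the universal back-projection path.
#'
#' @inheritParams ubp_reconstruct
#' @return A `recon_image`.
#' @export
das_reconstruct <- function(sino, grid = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  grid <- .recon_grid(sino, grid)
  structure(list(pixels = .backproject(sino, grid, sino$data), grid = grid,
                 wavelength = sino$wavelength, pulse = sino$pulse,
                 cycle = sino$cycle, f = sino$f, method = "das"),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image:%s> %dx%d @ %g mm/px, range [%.3g, %.3g]\n",
              x$method, x$grid$n[1], x$grid$n[2], x$grid$pixel_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
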