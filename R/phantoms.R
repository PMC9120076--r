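#' @keywords internal
.new_phantom <- function(n = c(256L, 256L), pixel_mm = 0.1, seed = NA_integer_,
                         kind = "empty") {
  zero <- matrix(0, n[1], n[2])
  structure(list(
    grid = list(n = as.integer(n), pixel_mm = pixel_mm),
    maps = list(HbO2 = zero, HbR = zero, BphP1 = zero),
    masks = list(),
    seed = seed, kind = kind),
    class = "phantom")
}

# Pixel-centre coordinates in mm; origin at grid centre, x along columns,
# y along rows increasing downward.
.phantom_coords <- function(grid) {
  ny <- grid$n[1]; nx <- grid$n[2]; h <- grid$pixel_mm
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  list(x = matrix(x, ny, nx, byrow = TRUE),
       y = matrix(y, ny, nx, byrow = FALSE))
}

.disk_mask <- function(grid, cx, cy, r) {
  co <- .phantom_coords(grid)
  (co$x - cx)^2 + (co$y - cy)^2 <= r^2
}

.ellipse_mask <- function(grid, cx, cy, a, b) {
  co <- .phantom_coords(grid)
  ((co$x - cx) / a)^2 + ((co$y - cy) / b)^2 <= 1
}

# Anti-aliased rasterization: fractional pixel coverage of the region
# defined by `inside(x, y)`, evaluated on a `sub` x `sub` subpixel lattice.
# `cov` carries the area-accurate fraction used for concentration maps;
# `mask` is the fully covered interior, on which maps are exactly constant.
.coverage <- function(grid, inside, sub = 4L) {
  ny <- grid$n[1]; nx <- grid$n[2]; h <- grid$pixel_mm
  off <- ((seq_len(sub) - 0.5) / sub - 0.5) * h
  cov <- matrix(0, ny, nx)
  x0 <- (seq_len(nx) - (nx + 1) / 2) * h
  y0 <- (seq_len(ny) - (ny + 1) / 2) * h
  for (oy in off) for (ox in off) {
    cov <- cov + inside(matrix(x0 + ox, ny, nx, byrow = TRUE),
                        matrix(y0 + oy, ny, nx, byrow = FALSE))
  }
  cov <- cov / sub^2
  list(cov = cov, mask = cov >= 1 - 1e-12)
}

.disk_coverage <- function(grid, cx, cy, r) {
  .coverage(grid, function(x, y) (x - cx)^2 + (y - cy)^2 <= r^2)
}

.ellipse_coverage <- function(grid, cx, cy, a, b) {
  .coverage(grid, function(x, y) ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1)
}

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so generators are pure in (config, seed).
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Calibration-tube phantom
#'
#' Disk-shaped "Eppendorf tube" regions holding purified photoswitchable
#' probe at known concentrations, imaged side by side with no hemoglobin,
#' emulating the concentration-calibration experiment (10 nM to 10 uM).
#' Tubes are placed at equal angles on a circle about the grid centre.
#'
#' @param concentrations Numeric vector of BphP1 concentrations in M, all in
#'   (0, 1e-4]. May be empty.
#' @param tube_radius_mm Radius of each tube disk, mm.
#' @param placement_radius_mm Radius of the circle on which tube centres sit, mm.
#' @param n Grid size (rows, cols).
#' @param pixel_mm Pixel size, mm.
#' @param seed Integer seed (placement is deterministic; the seed is recorded
#'   for provenance).
#' @return A `phantom` with masks `tube_1`, `tube_2`, ... in input order and
#'   a `background` mask.
#' @export
make_tube_phantom <- function(concentrations, tube_radius_mm = 1.2,
                              placement_radius_mm = 6, n = c(256L, 256L),
                              pixel_mm = 0.1, seed = 1L) {
  k <- length(concentrations)
  if (k > 0 && (any(concentrations <= 0) || any(concentrations > 1e-4))) {
    stop("tube concentrations must be in (0, 1e-4] M", call. = FALSE)
  }
  ph <- .new_phantom(n, pixel_mm, seed, kind = "tubes")
  if (k == 0) {
    ph$masks$background <- matrix(TRUE, n[1], n[2])
    return(ph)
  }
  half <- min(n) * pixel_mm / 2
  if (placement_radius_mm + tube_radius_mm >= half) {
    stop("tubes do not fit within the grid", call. = FALSE)
  }
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cx <- if (k == 1) 0 else placement_radius_mm * cos(ang)
  cy <- if (k == 1) 0 else placement_radius_mm * sin(ang)
  if (k > 1) {
    sep <- 2 * placement_radius_mm * sin(pi / k)
    if (sep <= 2 * tube_radius_mm) {
      stop("requested tube count/size overlap at this placement radius",
           call. = FALSE)
    }
  }
  for (i in seq_len(k)) {
    cc <- .disk_coverage(ph$grid, cx[i], cy[i], tube_radius_mm)
    ph$maps$BphP1 <- ph$maps$BphP1 + concentrations[i] * cc$cov
    ph$masks[[paste0("tube_", i)]] <- cc$mask
  }
  # background for noise estimation: outside the imaged sample region
  # (the tube cluster plus a margin for near-field ringing)
  ph$masks$background <- !.disk_mask(ph$grid, 0, 0,
                                     placement_radius_mm + tube_radius_mm + 2)
  ph
}

#' Mouse-abdomen cross-section phantom
#'
#' An elliptical body outline containing organ regions (liver, spleen,
#' stomach, intestine) carrying the photoswitchable probe at configured
#' intracellular concentrations, plus randomly placed blood-vessel segments
#' carrying oxy/deoxy-hemoglobin at physiological blood values and no probe.
#'
#' @param organ_levels Named numeric vector/list of BphP1 concentrations in M;
#'   names drawn from liver, spleen, stomach, intestine. Missing organs get 0.
#' @param n_vessels Number of random vessel segments (>= 0).
#' @param total_hb_M Total hemoglobin in vessel pixels, M (heme-equivalent).
#' @param so2 Blood oxygen saturation in [0, 1]; HbO2 = so2 * total, HbR = rest.
#' @param vessel_width_mm Range of vessel widths, mm.
#' @param n Grid size (rows, cols).
#' @param pixel_mm Pixel size, mm.
#' @param seed Integer RNG seed; same config + seed gives identical phantoms.
#' @return A `phantom` with organ, `vessel`, `body` and `background` masks.
#' @export
make_crosssection_phantom <- function(organ_levels = c(liver = 1e-7),
                                      n_vessels = 12, total_hb_M = 2.3e-3,
                                      so2 = 0.8, vessel_width_mm = c(0.2, 0.6),
                                      n = c(256L, 256L), pixel_mm = 0.1,
                                      seed = 1L) {
  organ_levels <- unlist(organ_levels)
  allowed <- c("liver", "spleen", "stomach", "intestine")
  if (length(organ_levels) > 0) {
    bad <- setdiff(names(organ_levels), allowed)
    if (length(bad) > 0) stop("unknown organ(s): ", paste(bad, collapse = ", "),
                              call. = FALSE)
    if (any(organ_levels < 0)) stop("organ levels must be >= 0", call. = FALSE)
  }
  stopifnot(n_vessels >= 0, so2 >= 0, so2 <= 1, total_hb_M >= 0)
  ph <- .new_phantom(n, pixel_mm, seed, kind = "crosssection")
  half_x <- n[2] * pixel_mm / 2; half_y <- n[1] * pixel_mm / 2
  a_body <- 0.86 * half_x; b_body <- 0.78 * half_y
  body <- .ellipse_mask(ph$grid, 0, 0, a_body, b_body)

  # fixed anatomy-like layout within the body ellipse, scaled to the grid
  u <- min(half_x, half_y)
  organ_geom <- list(
    liver     = c(cx = -0.30, cy =  0.00, a = 0.28, b = 0.20),
    spleen    = c(cx =  0.45, cy =  0.00, a = 0.10, b = 0.18),
    stomach   = c(cx =  0.12, cy = -0.32, a = 0.18, b = 0.13),
    intestine = c(cx =  0.10, cy =  0.38, a = 0.20, b = 0.13))
  organ_cov <- lapply(organ_geom, function(g) {
    .ellipse_coverage(ph$grid, g["cx"] * u, g["cy"] * u, g["a"] * u, g["b"] * u)
  })
  for (org in names(organ_levels)) {
    ph$maps$BphP1 <- ph$maps$BphP1 + organ_levels[[org]] * organ_cov[[org]]$cov
  }
  for (org in allowed) ph$masks[[org]] <- organ_cov[[org]]$mask

  vessel <- matrix(FALSE, n[1], n[2])
  if (n_vessels > 0) {
    segs <- .with_seed(seed, {
      lapply(seq_len(n_vessels), function(i) {
        th <- stats::runif(1, 0, 2 * pi)
        r0 <- stats::runif(1, 0, 0.75)
        cx <- r0 * a_body * cos(th); cy <- r0 * b_body * sin(th)
        len <- stats::runif(1, 2, 6)
        dir <- stats::runif(1, 0, 2 * pi)
        w <- stats::runif(1, vessel_width_mm[1], vessel_width_mm[2])
        c(x1 = cx - len / 2 * cos(dir), y1 = cy - len / 2 * sin(dir),
          x2 = cx + len / 2 * cos(dir), y2 = cy + len / 2 * sin(dir), w = w)
      })
    })
    inside_union <- function(x, y) {
      out <- matrix(FALSE, nrow(x), ncol(x))
      for (s in segs) {
        vx <- s[["x2"]] - s[["x1"]]; vy <- s[["y2"]] - s[["y1"]]
        L2 <- max(vx^2 + vy^2, 1e-12)
        tt <- pmin(1, pmax(0, ((x - s[["x1"]]) * vx + (y - s[["y1"]]) * vy) / L2))
        dx <- x - (s[["x1"]] + tt * vx); dy <- y - (s[["y1"]] + tt * vy)
        out <- out | (dx^2 + dy^2 <= (s[["w"]] / 2)^2)
      }
      out & ((x / a_body)^2 + (y / b_body)^2 <= 1)
    }
    cc <- .coverage(ph$grid, inside_union)
    ph$maps$HbO2 <- so2 * total_hb_M * cc$cov
    ph$maps$HbR <- (1 - so2) * total_hb_M * cc$cov
    vessel <- cc$mask
  }
  ph$masks$vessel <- vessel
  ph$masks$body <- body
  ph$masks$background <- !body
  ph
}

#' Multi-embryo abdomen phantom
#'
#' Disk-shaped embryos carrying the photoswitchable probe at sampled sizes
#' and depths below the body outline, over a maternal background of
#' hemoglobin-carrying vessels with no probe. Depth is measured vertically
#' from the upper body-outline boundary toward the interior.
#'
#' @param n_embryos Number of embryos.
#' @param depth_range_mm Depth range (min, max) of embryo centres, mm.
#' @param embryo_conc_M BphP1 concentration inside each embryo, M.
#' @param embryo_radius_mm Range of embryo radii, mm.
#' @param n_vessels Number of maternal vessel segments.
#' @param n Grid size (rows, cols).
#' @param pixel_mm Pixel size, mm.
#' @param seed Integer RNG seed.
#' @param max_tries Placement retries before a geometry error.
#' @return A `phantom` with masks `embryo_1..n`, `vessel`, `body`, `background`.
#' @export
make_embryo_phantom <- function(n_embryos = 7, depth_range_mm = c(1, 7),
                                embryo_conc_M = 5e-7,
                                embryo_radius_mm = c(1.0, 2.2),
                                n_vessels = 10, n = c(256L, 256L),
                                pixel_mm = 0.1, seed = 1L, max_tries = 2000) {
  stopifnot(n_embryos >= 0, depth_range_mm[1] <= depth_range_mm[2],
            embryo_conc_M >= 0)
  base <- make_crosssection_phantom(organ_levels = numeric(0),
                                    n_vessels = n_vessels, n = n,
                                    pixel_mm = pixel_mm, seed = seed)
  ph <- base
  ph$kind <- "embryo"
  ph$seed <- seed
  for (org in c("liver", "spleen", "stomach", "intestine")) ph$masks[[org]] <- NULL
  if (n_embryos == 0) return(ph)

  half_x <- n[2] * pixel_mm / 2; half_y <- n[1] * pixel_mm / 2
  a_body <- 0.86 * half_x; b_body <- 0.78 * half_y
  placed <- ph$masks$body & FALSE
  centres <- matrix(NA_real_, 0, 3)  # cx, cy, r
  .with_seed(seed + 1L, {
    tries <- 0
    while (nrow(centres) < n_embryos) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("could not place ", n_embryos, " non-overlapping embryos",
             call. = FALSE)
      }
      r <- stats::runif(1, embryo_radius_mm[1], embryo_radius_mm[2])
      d <- stats::runif(1, depth_range_mm[1], depth_range_mm[2])
      cx <- stats::runif(1, -0.8, 0.8) * a_body
      # upper boundary of the body ellipse at this x
      if (abs(cx) >= a_body) next
      y_top <- -b_body * sqrt(1 - (cx / a_body)^2)
      cy <- y_top + d
      # must sit inside the body with its full radius
      if (((cx / (a_body - r))^2 + (cy / (b_body - r))^2) > 1) next
      ok <- TRUE
      if (nrow(centres) > 0) {
        dd <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
        if (any(dd < centres[, 3] + r + 0.3)) ok <- FALSE
      }
      if (!ok) next
      centres <- rbind(centres, c(cx, cy, r))
    }
  })
  for (i in seq_len(n_embryos)) {
    cc <- .disk_coverage(ph$grid, centres[i, 1], centres[i, 2], centres[i, 3])
    # embryos displace maternal blood in this 2D model
    ph$maps$HbO2 <- ph$maps$HbO2 * (1 - cc$cov)
    ph$maps$HbR <- ph$maps$HbR * (1 - cc$cov)
    ph$maps$BphP1 <- ph$maps$BphP1 + embryo_conc_M * cc$cov
    ph$masks$vessel <- ph$masks$vessel & !(cc$cov > 0)
    ph$masks[[paste0("embryo_", i)]] <- cc$mask
  }
  ph
}

#' Rigid sinusoidal breathing-like displacement
#'
#' Translates all concentration maps and masks by
#' `amplitude * sin(2*pi*t/period)` along the vertical (y) axis, emulating
#' periodic breathing motion. Displacement is applied by bilinear
#' interpolation for maps; masks are shifted the same way and re-binarised.
#'
#' @param phantom A `phantom`.
#' @param amplitude_mm Motion amplitude, mm (>= 0).
#' @param period_s Motion period, s.
#' @param t_s Time, s.
#' @return The displaced `phantom`.
#' @export
apply_motion <- function(phantom, amplitude_mm, period_s, t_s) {
  stopifnot(inherits(phantom, "phantom"), amplitude_mm >= 0, period_s > 0)
  dy <- amplitude_mm * sin(2 * pi * t_s / period_s)
  if (dy == 0) return(phantom)
  shift_px <- dy / phantom$grid$pixel_mm
  shift_mat <- function(m) {
    ny <- nrow(m)
    i0 <- floor(shift_px); fr <- shift_px - i0
    src1 <- seq_len(ny) - i0       # contributes weight (1 - fr)
    src2 <- src1 - 1               # contributes weight fr
    g <- function(idx) {
      out <- matrix(0, ny, ncol(m))
      keep <- idx >= 1 & idx <= ny
      out[keep, ] <- m[idx[keep], ]
      out
    }
    (1 - fr) * g(src1) + fr * g(src2)
  }
  phantom$maps <- lapply(phantom$maps, shift_mat)
  phantom$masks <- lapply(phantom$masks, function(m) shift_mat(m * 1) >= 0.5)
  phantom
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom:%s> %dx%d @ %g mm/px, masks: %s\n", x$kind,
              x$grid$n[1], x$grid$n[2], x$grid$pixel_mm,
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}
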