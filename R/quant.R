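#' Fit a concentration calibration curve
#'
#' Ordinary least squares of differential signal on known probe
#' concentration from the calibration-tube phantom (e.g. tubes from 10 nM
#' to 10 uM imaged side by side). The intercept is fitted (not forced
#' through the origin) to absorb the non-negative floor of envelope images.
#'
#' @param concentrations Known concentrations, M (strictly increasing, > 0).
#' @param signals Region-mean differential signals, image units.
#' @return A `calibration_curve` with `slope`, `intercept`, `r_squared`.
#' @export
fit_calibration <- function(concentrations, signals) {
  if (length(concentrations) < 2 || length(signals) != length(concentrations)) {
    stop("need >= 2 calibration tubes with matching signals", call. = FALSE)
  }
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0)) {
    stop("concentrations must be positive and strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(signals ~ concentrations)
  cf <- stats::coef(fit)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  curve <- structure(list(concentrations = concentrations, signals = signals,
                          slope = unname(cf[2]), intercept = unname(cf[1]),
                          r_squared = r2,
                          nonpositive_slope = unname(cf[2]) <= 0),
                     class = "calibration_curve")
  if (curve$nonpositive_slope) {
    warning("calibration slope is not positive", call. = FALSE)
  }
  curve
}

#' Estimate concentration from a calibration curve
#'
#' Inverts the linear calibration: (signal - intercept) / slope. Negative
#' estimates are clipped to zero with `clipped = TRUE` in the attribute.
#'
#' @param signal Region-mean differential signal(s).
#' @param curve A `calibration_curve` with positive slope.
#' @return Estimated concentration(s), M, with attribute `clipped`.
#' @export
estimate_concentration <- function(signal, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration curve has non-positive slope",
                             call. = FALSE)
  est <- (signal - curve$intercept) / curve$slope
  clipped <- est < 0
  est[clipped] <- 0
  attr(est, "clipped") <- clipped
  est
}

#' Contrast-to-noise ratio
#'
#' (mean over the signal mask - mean over the background mask) divided by
#' the standard deviation over the background mask.
#'
#' @param map Image matrix.
#' @param signal_mask,background_mask Non-empty, disjoint logical masks.
#' @export
cnr <- function(map, signal_mask, background_mask) {
  if (!any(signal_mask) || !any(background_mask)) {
    stop("signal and background masks must be non-empty", call. = FALSE)
  }
  if (any(signal_mask & background_mask)) {
    stop("signal and background masks must be disjoint", call. = FALSE)
  }
  s <- stats::sd(map[background_mask])
  if (s == 0) stop("background standard deviation is zero; CNR undefined",
                   call. = FALSE)
  (mean(map[signal_mask]) - mean(map[background_mask])) / s
}

#' Noise-equivalent detection sensitivity
#'
#' The probe concentration divided by the image contrast-to-noise ratio:
#' the concentration that would give CNR = 1.
#'
#' @param concentration Probe concentration, M.
#' @param cnr_value Contrast-to-noise ratio (> 0).
#' @return Sensitivity, M.
#' @export
detection_sensitivity <- function(concentration, cnr_value) {
  if (cnr_value <= 0) stop("CNR must be positive", call. = FALSE)
  concentration / cnr_value
}

#' Organ levels relative to a reference organ
#'
#' Per-organ mean differential signal divided by the mean of the reference
#' organ (e.g. normalised to the liver).
#'
#' @param diff Differential image matrix.
#' @param organ_masks Named list of logical masks.
#' @param reference Name of the reference organ.
#' @return Named numeric vector; the reference maps to exactly 1.
#' @export
organ_relative <- function(diff, organ_masks, reference = "liver") {
  if (!reference %in% names(organ_masks)) {
    stop("reference organ '", reference, "' not among the masks", call. = FALSE)
  }
  means <- vapply(organ_masks, function(m) mean(diff[m]), numeric(1))
  ref <- means[[reference]]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference organ mean must be positive", call. = FALSE)
  }
  means / ref
}

#' Light-to-dark activation fold ratio
#'
#' Fold activation of a light-induced expression system after subtracting
#' the reporter-only background:
#' (full_light - reporter_light) / (full_dark - reporter_dark).
#'
#' @param full_light,full_dark Signals of the full system, illuminated / dark.
#' @param reporter_light,reporter_dark Signals of the reporter-only control.
#' @export
light_to_dark_ratio <- function(full_light, full_dark,
                                reporter_light, reporter_dark) {
  denom <- full_dark - reporter_dark
  if (denom <= 0) {
    stop("background-subtracted dark signal must be positive; ratio undefined",
         call. = FALSE)
  }
  (full_light - reporter_light) / denom
}

#' Linear spectral unmixing baseline
#'
#' Pixelwise least-squares solve of image(lambda) = E %*% c for species
#' concentrations from images at two or more wavelengths; the conventional
#' multi-wavelength alternative to differential detection.
#'
#' @param images List of matrices (one per wavelength) on a common grid.
#' @param wavelengths Wavelengths, nm (length >= number of species).
#' @param lib A `spectral_library`.
#' @param species Character vector of species to unmix.
#' @return Named list of concentration-scale maps (units of the images
#'   divided by extinction; proportional to M under a linear pipeline).
#' @export
linear_unmix <- function(images, wavelengths, lib, species) {
  stopifnot(length(images) == length(wavelengths))
  if (length(wavelengths) < length(species)) {
    stop("need at least as many wavelengths as species", call. = FALSE)
  }
  E <- sapply(species, function(sp) extinction(lib, sp, wavelengths))
  E <- matrix(E, nrow = length(wavelengths))
  if (qr(E)$rank < length(species)) {
    stop("extinction matrix is rank-deficient for these wavelengths/species",
         call. = FALSE)
  }
  Y <- t(sapply(images, as.vector))          # wavelengths x pixels
  if (length(wavelengths) == 1) Y <- matrix(Y, nrow = 1)
  C <- qr.solve(E, Y)                        # species x pixels
  if (length(species) == 1) C <- matrix(C, nrow = 1)
  d <- dim(images[[1]])
  out <- lapply(seq_along(species), function(i) matrix(C[i, ], d[1], d[2]))
  names(out) <- species
  out
}
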