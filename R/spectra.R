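#' Chromophore species recognised by the spectral library
#'
#' HbO2 and HbR are oxy- and deoxy-hemoglobin; BphP1_Pfr and BphP1_Pr are
#' the far-red-absorbing ground ("ON") and red-absorbing activated ("OFF")
#' states of the bacterial phytochrome probe.
#' @keywords internal
.rspat_species <- c("HbO2", "HbR", "BphP1_Pfr", "BphP1_Pr")

#' Load a molar extinction spectra table
#'
#' Reads a CSV table with a `wavelength_nm` column and one column per
#' chromophore species (`HbO2`, `HbR`, `BphP1_Pfr`, `BphP1_Pr`), each giving
#' the molar extinction coefficient in M^-1 cm^-1. Wavelengths must be
#' strictly increasing and all coefficients non-negative. Lookups between
#' tabulated wavelengths are linearly interpolated.
#'
#' @param path Path to the CSV file. Defaults to the packaged fixture
#'   covering 600-900 nm at 5 nm steps.
#' @return A `spectral_library` object with fields `wavelengths` (nm) and
#'   `epsilon` (matrix, wavelengths x species).
#' @examples
#' lib <- load_spectra()
#' extinction(lib, "BphP1_Pfr", 750)
#' @export
load_spectra <- function(path = system.file("extdata", "bphp1_hb_extinction.csv",
                                            package = "rspat")) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(tab)) {
    stop("spectra file must have a 'wavelength_nm' column", call. = FALSE)
  }
  missing <- setdiff(.rspat_species, names(tab))
  if (length(missing) > 0) {
    stop("spectra file is missing species column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wl <- tab$wavelength_nm
  if (any(!is.finite(wl)) || any(diff(wl) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  eps <- as.matrix(tab[, .rspat_species])
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("extinction coefficients must be finite and non-negative", call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wl), epsilon = eps),
            class = "spectral_library")
}

#' Look up molar extinction coefficients
#'
#' Linear interpolation between tabulated wavelengths; querying outside the
#' tabulated range is an error.
#'
#' @param lib A `spectral_library`.
#' @param species Species name (one of the library columns).
#' @param wavelength Wavelength(s) in nm.
#' @return Extinction coefficient(s) in M^-1 cm^-1.
#' @export
extinction <- function(lib, species, wavelength) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!species %in% colnames(lib$epsilon)) {
    stop("unknown species: ", species, call. = FALSE)
  }
  rng <- range(lib$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2])) {
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]), call. = FALSE)
  }
  if (length(lib$wavelengths) == 1L) {
    return(rep(unname(lib$epsilon[1, species]), length(wavelength)))
  }
  stats::approx(lib$wavelengths, lib$epsilon[, species], xout = wavelength)$y
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d wavelengths, %g-%g nm, species: %s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              paste(colnames(x$epsilon), collapse = ", ")))
  invisible(x)
}

#' Optical absorption map of a phantom
#'
#' Builds the absorption coefficient map mu_a (mm^-1) at one wavelength from
#' the phantom's molar concentration maps:
#' mu_a = ln(10)/10 * sum_i eps_i(lambda) * c_i,
#' where the factor ln(10) converts decadic extinction to a Napierian
#' absorption coefficient and /10 converts cm^-1 to mm^-1. The total BphP1
#' concentration is split between the Pfr and Pr states by the Pfr fraction
#' `f`: f*c into BphP1_Pfr and (1-f)*c into BphP1_Pr.
#'
#' @param phantom A `phantom` object (see [make_tube_phantom()]).
#' @param lib A `spectral_library`.
#' @param wavelength Wavelength in nm.
#' @param f Pfr state fraction in [0, 1].
#' @return Matrix of mu_a values in mm^-1, same grid as the phantom.
#' @export
absorption_map <- function(phantom, lib, wavelength, f = 1) {
  stopifnot(inherits(phantom, "phantom"), length(f) == 1L, f >= 0, f <= 1)
  mu <- matrix(0, nrow(phantom$maps$BphP1), ncol(phantom$maps$BphP1))
  scale <- log(10) / 10   # decadic cm^-1 -> Napierian mm^-1
  mu <- mu + extinction(lib, "HbO2", wavelength) * phantom$maps$HbO2
  mu <- mu + extinction(lib, "HbR", wavelength) * phantom$maps$HbR
  eps_b <- f * extinction(lib, "BphP1_Pfr", wavelength) +
    (1 - f) * extinction(lib, "BphP1_Pr", wavelength)
  mu <- mu + eps_b * phantom$maps$BphP1
  mu * scale
}
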