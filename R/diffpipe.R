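#' Hilbert-envelope of a reconstructed image
#'
#' Magnitude of the analytic signal computed along one image axis,
#' rectifying the oscillatory (bipolar) reconstructed photoacoustic
#' amplitudes into a non-negative envelope.
#'
#' @param image A `recon_image` or a plain matrix.
#' @param axis "rows" (along each row, the default) or "cols".
#' @return Same type as the input, with non-negative pixel values.
#' @export
envelope <- function(image, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- if (inherits(image, "recon_image")) image$pixels else image
  stopifnot(all(is.finite(m)))
  work <- if (axis == "rows") t(m) else m
  n <- nrow(work)
  # analytic-signal multiplier: double positive frequencies, kill negative
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(work) * h
  env <- Mod(stats::mvfft(A, inverse = TRUE)) / n
  env <- if (axis == "rows") t(env) else env
  if (inherits(image, "recon_image")) { image$pixels <- env; image } else env
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood; image borders
#' are handled by reflection. Implemented as a vectorised compare-exchange
#' network over the nine shifted copies of the image.
#'
#' @param image A `recon_image` or matrix, at least 3x3.
#' @return Same type as the input.
#' @export
median3x3 <- function(image) {
  m <- if (inherits(image, "recon_image")) image$pixels else image
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop("image must be at least 3x3", call. = FALSE)
  }
  ny <- nrow(m); nx <- ncol(m)
  pad <- rbind(m[2, , drop = FALSE], m, m[ny - 1, , drop = FALSE])
  pad <- cbind(pad[, 2, drop = FALSE], pad, pad[, nx - 1, drop = FALSE])
  v <- vector("list", 9)
  k <- 0
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1
    v[[k]] <- as.vector(pad[dy + seq_len(ny), dx + seq_len(nx)])
  }
  # median-of-9 compare-exchange network (Smith); pairs are 1-based
  cex <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  cex(2, 3); cex(5, 6); cex(8, 9)
  cex(1, 2); cex(4, 5); cex(7, 8)
  cex(2, 3); cex(5, 6); cex(8, 9)
  cex(1, 4); cex(6, 9); cex(5, 8)
  cex(4, 7); cex(2, 5); cex(3, 6)
  cex(5, 8); cex(5, 3); cex(7, 5)
  cex(5, 3)
  med <- matrix(v[[5]], ny, nx)
  if (inherits(image, "recon_image")) { image$pixels <- med; image } else med
}

#' @keywords internal
.pixels_of <- function(x) if (inherits(x, "recon_image")) x$pixels else x

#' Standard per-frame processing: envelope then 3x3 median
#' @param image A `recon_image` or matrix.
#' @param axis Envelope axis, see [envelope()].
#' @export
process_frame <- function(image, axis = "rows") {
  median3x3(envelope(image, axis = axis))
}

#' Build the ON- and OFF-state images of one cycle
#'
#' The ON image is the mean of the first `m` processed frames of the cycle's
#' reconstruction stack (acquired at the beginning of the imaging phase,
#' probe fully ON) and the OFF image the mean of the last `m` (probe
#' switched OFF). Processing is Hilbert envelope followed by 3x3 median.
#'
#' @param stack List of `recon_image`s (or matrices) for one cycle, in pulse
#'   order.
#' @param m Frames per state.
#' @param axis Envelope axis.
#' @return List with matrices `on` and `off`.
#' @export
make_state_images <- function(stack, m = 1, axis = "rows") {
  n <- length(stack)
  if (2 * m > n) stop("m frames per state exceed half the stack", call. = FALSE)
  proc <- function(idx) {
    mats <- lapply(stack[idx], function(im) .pixels_of(process_frame(im, axis)))
    Reduce(`+`, mats) / length(mats)
  }
  list(on = proc(seq_len(m)), off = proc(n - m + seq_len(m)))
}

#' Differential (ON minus OFF) image
#' @param on_image,off_image Matrices on the same grid.
#' @return Matrix `on_image - off_image`.
#' @export
differential_image <- function(on_image, off_image) {
  on_image <- .pixels_of(on_image); off_image <- .pixels_of(off_image)
  if (!identical(dim(on_image), dim(off_image))) {
    stop("ON and OFF images must share the same grid", call. = FALSE)
  }
  on_image - off_image
}

#' Average per-cycle differential images
#' @param diffs Non-empty list of matrices.
#' @export
average_cycles <- function(diffs) {
  if (length(diffs) == 0) stop("no cycles to average", call. = FALSE)
  Reduce(`+`, diffs) / length(diffs)
}

#' Background noise level of a differential image
#'
#' Sample standard deviation of the differential image over a background
#' mask outside the imaged object.
#'
#' @param diff Matrix.
#' @param background_mask Logical matrix, non-empty.
#' @export
noise_std_background <- function(diff, background_mask) {
  if (!any(background_mask)) stop("empty background mask", call. = FALSE)
  stats::sd(diff[background_mask])
}

#' Threshold a differential image at three times the noise level
#'
#' One-sided threshold: pixels with differential signal >= 3 * sigma are
#' kept; all others are zeroed in the masked map. The raw differential image
#' should be retained for quantification.
#'
#' @param diff Matrix.
#' @param sigma Background noise standard deviation (>= 0).
#' @param k Threshold multiple (default 3).
#' @return List with logical `mask` and matrix `masked`.
#' @export
threshold_mask <- function(diff, sigma, k = 3) {
  stopifnot(sigma >= 0)
  mask <- diff >= k * sigma & diff > 0
  masked <- diff
  masked[!mask] <- 0
  list(mask = mask, masked = masked)
}

#' Region-of-interest time course across pulses
#'
#' Mean of each processed frame over an ROI mask, ordered by pulse time,
#' showing the photoswitching decay within each imaging phase.
#'
#' @param stack List of `recon_image`s (with `cycle`/`pulse` fields) or
#'   matrices.
#' @param roi_mask Non-empty logical matrix.
#' @param axis Envelope axis.
#' @param processed Set TRUE if the stack is already envelope/median
#'   processed.
#' @return A `time_course` data frame with columns `cycle`, `pulse`,
#'   `roi_mean`.
#' @export
extract_timecourse <- function(stack, roi_mask, axis = "rows",
                               processed = FALSE) {
  if (!any(roi_mask)) stop("empty ROI mask", call. = FALSE)
  rows <- lapply(stack, function(im) {
    px <- if (processed) .pixels_of(im) else .pixels_of(process_frame(im, axis))
    data.frame(
      cycle = if (inherits(im, "recon_image") && !is.na(im$cycle)) im$cycle else NA,
      pulse = if (inherits(im, "recon_image") && !is.na(im$pulse)) im$pulse else NA,
      roi_mean = mean(px[roi_mask]))
  })
  tc <- do.call(rbind, rows)
  if (all(is.na(tc$pulse))) tc$pulse <- seq_len(nrow(tc))
  if (all(is.na(tc$cycle))) tc$cycle <- 1L
  tc <- tc[order(tc$cycle, tc$pulse), , drop = FALSE]
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' Fit the photoswitching decay rate of a time course
#'
#' Least-squares fit of A * exp(-k * n) + b over pulse index n within one
#' imaging phase. A flat (degenerate) signal returns k = 0 with
#' `degenerate = TRUE`.
#'
#' @param tc A `time_course` (one imaging phase) or numeric vector of ROI
#'   means in pulse order.
#' @return List with `k` (per pulse), `amplitude`, `offset`, `degenerate`.
#' @export
fit_switch_rate <- function(tc) {
  y <- if (is.data.frame(tc)) tc$roi_mean else as.numeric(tc)
  if (any(!is.finite(y))) stop("non-finite values in time course", call. = FALSE)
  if (length(y) < 4) stop("need at least 4 points", call. = FALSE)
  n <- seq_along(y) - 1
  rng <- diff(range(y))
  if (rng <= 1e-12 * max(abs(y), 1)) {
    return(list(k = 0, amplitude = 0, offset = mean(y), degenerate = TRUE))
  }
  a0 <- y[1] - y[length(y)]
  b0 <- min(y)
  k0 <- {
    # crude log-linear start on the positive part of the decay
    z <- y - b0 + 1e-3 * abs(rng)
    max(1e-3, -stats::coef(stats::lm(log(z) ~ n))[2])
  }
  fit <- minpack.lm::nlsLM(y ~ A * exp(-k * n) + b,
                           start = list(A = a0, k = k0, b = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(k = unname(cf["k"]), amplitude = unname(cf["A"]),
       offset = unname(cf["b"]), degenerate = FALSE)
}
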