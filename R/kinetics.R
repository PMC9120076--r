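#' Two-state photoswitching rate parameters
#'
#' Effective phase-level rates of the Pfr <-> Pr photoswitching of a
#' bacterial phytochrome probe under the cyclic illumination schedule.
#' During the switch-ON phase (red continuous-wave light) the Pfr fraction
#' f obeys df/dt = k_on * (1 - f). During the imaging phase each far-red
#' imaging pulse converts a fixed fraction `delta_off_pulse` of the Pfr
#' population to Pr, and after the 790 nm continuous-wave light turns on,
#' f additionally decays at rate `k_off_cw`.
#'
#' Defaults are chosen so that under the 8 s + 8 s cycle the probe is
#' essentially fully ON at the first imaging pulse (f > 0.999) and almost
#' fully OFF at the last (f < 0.1).
#'
#' @param k_on Switch-ON rate under CW red light, s^-1.
#' @param k_off_cw Switch-OFF rate under 790 nm CW light, s^-1.
#' @param delta_off_pulse Fractional Pfr -> Pr conversion per imaging pulse.
#' @return A `kinetics_params` object.
#' @export
kinetics_params <- function(k_on = 1.0, k_off_cw = 0.5, delta_off_pulse = 0.15) {
  stopifnot(k_on >= 0, k_off_cw >= 0,
            delta_off_pulse >= 0, delta_off_pulse <= 1)
  structure(list(k_on = k_on, k_off_cw = k_off_cw,
                 delta_off_pulse = delta_off_pulse),
            class = "kinetics_params")
}

#' Cyclic photoswitching / imaging illumination schedule
#'
#' One cycle consists of `t_on_phase` seconds of continuous-wave switch-ON
#' light followed by `t_imaging_phase` seconds of pulsed far-red imaging
#' light; the switch-OFF continuous-wave light turns on `t_790_delay`
#' seconds into the imaging phase. The defaults reproduce a 16 s cycle:
#' 8 s ON light, 8 s imaging at 10 Hz, 790 nm light from 6 s into imaging.
#'
#' @param t_on_phase Duration of the switch-ON phase, s.
#' @param t_imaging_phase Duration of the pulsed imaging phase, s.
#' @param t_790_delay Delay of the 790 nm CW light within the imaging phase, s.
#' @param pulse_rate Imaging pulse repetition rate, Hz.
#' @param n_cycles Number of switching/imaging cycles.
#' @param on_wavelength_nm Switch-ON laser wavelength (config value; red CW).
#' @param imaging_wavelength_nm Pulsed imaging wavelength, nm.
#' @return An `illumination_schedule` object.
#' @export
illumination_schedule <- function(t_on_phase = 8, t_imaging_phase = 8,
                                  t_790_delay = 6, pulse_rate = 10,
                                  n_cycles = 1, on_wavelength_nm = 635,
                                  imaging_wavelength_nm = 750) {
  if (t_on_phase < 0 || t_imaging_phase < 0 || t_790_delay < 0) {
    stop("schedule durations must be non-negative", call. = FALSE)
  }
  stopifnot(pulse_rate > 0, n_cycles >= 1)
  structure(list(t_on_phase = t_on_phase, t_imaging_phase = t_imaging_phase,
                 t_790_delay = t_790_delay, pulse_rate = pulse_rate,
                 n_cycles = as.integer(n_cycles),
                 on_wavelength_nm = on_wavelength_nm,
                 imaging_wavelength_nm = imaging_wavelength_nm),
            class = "illumination_schedule")
}

#' Number of imaging pulses per cycle
#' @param schedule An `illumination_schedule`.
#' @export
pulses_per_cycle <- function(schedule) {
  as.integer(floor(schedule$t_imaging_phase * schedule$pulse_rate))
}

#' Pfr state fraction at every imaging pulse
#'
#' Event-based piecewise-analytic solution of the two-state kinetics over
#' the cyclic schedule. Within the ON phase the mono-exponential solution
#' f(t) = 1 - (1 - f0) exp(-k_on t) is applied in closed form; within the
#' imaging phase the Pfr fraction is sampled at each pulse time (before
#' that pulse's own OFF kick), multiplied by (1 - delta_off_pulse) at the
#' pulse, and decays at `k_off_cw` over the part of each inter-pulse
#' interval that falls after the 790 nm light turns on.
#'
#' @param schedule An `illumination_schedule`.
#' @param kin A `kinetics_params`.
#' @param f0 Initial Pfr fraction in [0, 1].
#' @return A `switch_trajectory`: data frame with columns `cycle`, `pulse`,
#'   `time_s` (absolute time of each imaging pulse) and `f`.
#' @export
pfr_trajectory <- function(schedule, kin, f0 = 0) {
  stopifnot(inherits(schedule, "illumination_schedule"),
            inherits(kin, "kinetics_params"), f0 >= 0, f0 <= 1)
  np <- pulses_per_cycle(schedule)
  t_cycle <- schedule$t_on_phase + schedule$t_imaging_phase
  dt <- 1 / schedule$pulse_rate
  out <- vector("list", schedule$n_cycles)
  f <- f0
  for (cyc in seq_len(schedule$n_cycles)) {
    t0 <- (cyc - 1) * t_cycle
    f <- 1 - (1 - f) * exp(-kin$k_on * schedule$t_on_phase)
    fk <- numeric(np)
    tk <- t0 + schedule$t_on_phase + (seq_len(np) - 1) * dt
    for (k in seq_len(np)) {
      fk[k] <- f
      f <- f * (1 - kin$delta_off_pulse)
      # CW off-switching over the slice of [t_k, t_k + dt] (or to phase end
      # for the final pulse) that lies after the 790 nm delay
      t_rel <- (k - 1) * dt
      t_next <- if (k < np) t_rel + dt else schedule$t_imaging_phase
      overlap <- max(0, t_next - max(t_rel, schedule$t_790_delay))
      f <- f * exp(-kin$k_off_cw * overlap)
    }
    out[[cyc]] <- data.frame(cycle = cyc, pulse = seq_len(np),
                             time_s = tk, f = fk)
  }
  traj <- do.call(rbind, out)
  class(traj) <- c("switch_trajectory", "data.frame")
  traj
}
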