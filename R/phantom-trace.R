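# Synthetic isometric force traces with staircase motor-unit recruitment,
# tetanic fusion and fatigue decay — the substrate for validating the
# force-trace analytics.

#' Specification for a synthetic force-trace phantom
#'
#' The muscle is a pool of motor units, each with a twitch force and a
#' recruitment threshold (stimulus intensity above which it fires). A
#' stimulus pulse at intensity `I` elicits one twitch from every unit with
#' threshold `<= I`; twitches follow an alpha-function kernel. Pulses at
#' tetanic rates (>= 20 Hz) additionally fuse: their amplitude is scaled by
#' `tetanic_fusion_gain` on top of linear twitch summation. During repeated
#' stimulation the per-twitch amplitude decays as `exp(-t / fatigue_tau_s)`
#' from the first stimulus (`Inf` = no fatigue). Additive Gaussian noise
#' models the transducer.
#'
#' @param n_motor_units number of units.
#' @param unit_twitch_forces_g positive per-unit twitch forces, grams.
#' @param recruitment_thresholds strictly increasing stimulus intensities.
#' @param tetanic_fusion_gain multiplier (>= 1) applied to pulses in
#'   tetanic-rate events.
#' @param twitch_time_to_peak_s alpha-kernel time constant (kernel peaks at
#'   1 at this latency).
#' @param fatigue_tau_s fatigue decay constant, s (`Inf` = none).
#' @param sampling_hz trace sampling rate.
#' @param noise_sd_g transducer noise SD, grams.
#' @param seed integer seed.
#' @return An object of class `trace_phantom_spec`.
#' @export
trace_phantom_spec <- function(n_motor_units = 6,
                               unit_twitch_forces_g = NULL,
                               recruitment_thresholds = NULL,
                               tetanic_fusion_gain = 1.5,
                               twitch_time_to_peak_s = 0.02,
                               fatigue_tau_s = Inf,
                               sampling_hz = 1000,
                               noise_sd_g = 0.005,
                               seed = 1L) {
  n <- as.integer(n_motor_units)
  if (n < 1L) stopf("need at least one motor unit")
  if (is.null(unit_twitch_forces_g))
    unit_twitch_forces_g <- 0.08 * 1.25^(seq_len(n) - 1)
  if (is.null(recruitment_thresholds))
    recruitment_thresholds <- seq(0.15, 0.9, length.out = n)
  check_positive(unit_twitch_forces_g, "unit_twitch_forces_g")
  if (length(unit_twitch_forces_g) != n || length(recruitment_thresholds) != n)
    stopf("unit forces and thresholds must have length n_motor_units")
  if (any(diff(recruitment_thresholds) <= 0))
    stopf("recruitment_thresholds must be strictly increasing")
  if (tetanic_fusion_gain < 1) stopf("tetanic_fusion_gain must be >= 1")
  check_positive(twitch_time_to_peak_s, "twitch_time_to_peak_s")
  check_positive(sampling_hz, "sampling_hz")
  if (noise_sd_g < 0) stopf("noise_sd_g must be >= 0")
  structure(list(n_motor_units = n,
                 unit_twitch_forces_g = unit_twitch_forces_g,
                 recruitment_thresholds = recruitment_thresholds,
                 tetanic_fusion_gain = tetanic_fusion_gain,
                 twitch_time_to_peak_s = twitch_time_to_peak_s,
                 fatigue_tau_s = fatigue_tau_s,
                 sampling_hz = sampling_hz, noise_sd_g = noise_sd_g,
                 seed = as.integer(seed)),
            class = "trace_phantom_spec")
}

#' Stimulus programs
#'
#' Stimulus events are rows of a data frame with columns `t_start_s`,
#' `t_end_s`, `kind` (`"ONS"` optical or `"ENS"` electrical),
#' `frequency_hz` (`NA` for a single pulse) and `intensity` (normalized
#' drive). Three canonical programs are provided:
#'
#' * `stim_twitch_ramp()`: single pulses at monotonically increasing
#'   intensity — the incremental-recruitment protocol underlying motor unit
#'   number estimation;
#' * `stim_tetanus()`: one sustained high-frequency burst;
#' * `stim_fatigue()`: brief tetanic bursts repeated for minutes (defaults:
#'   250 ms of 20 Hz every 1 s for 180 s).
#'
#' @param intensities increasing stimulus intensities, one pulse each.
#' @param start_s first pulse time.
#' @param interval_s spacing between pulses.
#' @param kind `"ONS"` or `"ENS"`.
#' @return data frame of stimulus events.
#' @export
stim_twitch_ramp <- function(intensities, start_s = 0.5, interval_s = 0.5,
                             kind = "ONS") {
  t0 <- start_s + (seq_along(intensities) - 1) * interval_s
  data.frame(t_start_s = t0, t_end_s = t0, kind = kind,
             frequency_hz = NA_real_, intensity = intensities,
             stringsAsFactors = FALSE)
}

#' @rdname stim_twitch_ramp
#' @param t_start_s burst onset.
#' @param duration_s burst duration.
#' @param frequency_hz pulse rate within the burst.
#' @param intensity stimulus drive.
#' @export
stim_tetanus <- function(t_start_s = 0.5, duration_s = 1,
                         frequency_hz = 20, intensity = 1, kind = "ONS") {
  data.frame(t_start_s = t_start_s, t_end_s = t_start_s + duration_s,
             kind = kind, frequency_hz = frequency_hz,
             intensity = intensity, stringsAsFactors = FALSE)
}

#' @rdname stim_twitch_ramp
#' @param burst_s burst length, s.
#' @param period_s burst repetition period, s.
#' @param total_s protocol duration, s.
#' @export
stim_fatigue <- function(t_start_s = 0.5, burst_s = 0.25, period_s = 1,
                         total_s = 180, frequency_hz = 20, intensity = 1,
                         kind = "ONS") {
  t0 <- seq(t_start_s, t_start_s + total_s - period_s, by = period_s)
  data.frame(t_start_s = t0, t_end_s = t0 + burst_s, kind = kind,
             frequency_hz = frequency_hz, intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Annotated isometric force trace
#'
#' @param time_s strictly increasing, uniformly sampled time grid.
#' @param force_g force series, grams.
#' @param sampling_hz sampling rate.
#' @param stim_events stimulus-event data frame (see [stim_twitch_ramp()]).
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time_s, force_g, sampling_hz, stim_events) {
  if (length(time_s) != length(force_g))
    stopf("time and force must have equal length")
  dt <- diff(time_s)
  if (any(dt <= 0)) stopf("time_s must be strictly increasing")
  if (max(abs(dt - 1 / sampling_hz)) > 1e-9 * max(1, 1 / sampling_hz))
    stopf("sampling must be uniform at sampling_hz")
  if (nrow(stim_events) &&
      (min(stim_events$t_start_s) < time_s[1] ||
       max(stim_events$t_end_s) > time_s[length(time_s)]))
    stopf("stimulus events must lie within the trace time range")
  structure(list(time_s = time_s, force_g = force_g,
                 sampling_hz = sampling_hz, stim_events = stim_events),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %.1f s @ %g Hz, %d stimulus event(s), force range [%.3g, %.3g] g\n",
              max(x$time_s), x$sampling_hz, nrow(x$stim_events),
              min(x$force_g), max(x$force_g)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$force_g, type = "l", xlab = "time (s)",
                 ylab = "force (g)", ...)
  if (nrow(x$stim_events))
    graphics::rug(x$stim_events$t_start_s, col = "red")
  invisible(x)
}

#' Generate a synthetic force trace for a stimulus program
#'
#' Superposes one alpha-function twitch per (pulse, recruited unit) pair:
#' `k(t) = (t/tau) exp(1 - t/tau)` (unit peak at `t = tau`). Pulse
#' amplitudes carry the fatigue envelope and, within tetanic-rate events
#' (>= 20 Hz), the fusion gain. Implemented as a single convolution of a
#' per-pulse amplitude impulse train with the kernel.
#'
#' @param spec a [trace_phantom_spec()].
#' @param stim_program stimulus-event data frame.
#' @param duration_s trace length; default covers the program plus 0.5 s.
#' @return a [force_trace()]; the noiseless trace is attached as attribute
#'   `"clean"` for oracle testing.
#' @export
generate_force_trace <- function(spec, stim_program, duration_s = NULL) {
  stopifnot(inherits(spec, "trace_phantom_spec"))
  if (!nrow(stim_program)) stopf("stimulus program is empty")
  duration_s <- duration_s %||% (max(stim_program$t_end_s) + 0.5)
  if (max(stim_program$t_end_s) > duration_s)
    stopf("stimulus program extends beyond the trace duration")
  with_seed(spec$seed, {
    fs <- spec$sampling_hz
    nsamp <- floor(duration_s * fs) + 1L
    tt <- (seq_len(nsamp) - 1) / fs
    pulses_t <- numeric(0); pulses_a <- numeric(0)
    t_first <- min(stim_program$t_start_s)
    for (k in seq_len(nrow(stim_program))) {
      ev <- stim_program[k, ]
      pt <- if (is.na(ev$frequency_hz) || ev$t_end_s <= ev$t_start_s)
        ev$t_start_s
      else seq(ev$t_start_s, ev$t_end_s, by = 1 / ev$frequency_hz)
      recruited <- spec$recruitment_thresholds <= ev$intensity
      base_amp <- sum(spec$unit_twitch_forces_g[recruited])
      if (base_amp == 0) next
      gain <- if (!is.na(ev$frequency_hz) && ev$frequency_hz >= 20)
        spec$tetanic_fusion_gain else 1
      env <- if (is.finite(spec$fatigue_tau_s))
        exp(-(pt - t_first) / spec$fatigue_tau_s) else rep(1, length(pt))
      pulses_t <- c(pulses_t, pt)
      pulses_a <- c(pulses_a, base_amp * gain * env)
    }
    tau <- spec$twitch_time_to_peak_s
    klen <- ceiling(8 * tau * fs)
    kt <- (seq_len(klen) - 1) / fs
    kernel <- (kt / tau) * exp(1 - kt / tau)
    impulse <- numeric(nsamp)
    if (length(pulses_t)) {
      idx <- round(pulses_t * fs) + 1L
      keep <- idx >= 1L & idx <= nsamp
      for (i in which(keep))
        impulse[idx[i]] <- impulse[idx[i]] + pulses_a[i]
    }
    clean <- stats::convolve(c(impulse, numeric(klen)), rev(kernel),
                             type = "open")[seq_len(nsamp)]
    force <- clean
    if (spec$noise_sd_g > 0)
      force <- force + stats::rnorm(nsamp, 0, spec$noise_sd_g)
    tr <- force_trace(tt, force, fs, stim_program)
    attr(tr, "clean") <- clean
    tr
  })
}
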