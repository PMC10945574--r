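# Isometric force-trace analytics: maximal tetanic/twitch force, fold
# change, optical-vs-electrical efficiency, incremental motor unit number
# estimation, and the repeated-burst fatigue index.

FUSION_THRESHOLD_HZ <- 20    # event rates at/above this are tetanic
PEAK_TAIL_S <- 0.05          # twitch-kernel decay allowance after a window
BASELINE_S <- 0.2            # pre-stimulus window for baseline estimation

force_in <- function(trace, t0, t1) {
  trace$force_g[trace$time_s >= t0 & trace$time_s <= t1]
}

event_baseline <- function(trace, t_start) {
  pre <- force_in(trace, t_start - BASELINE_S, t_start - 1e-9)
  if (!length(pre)) pre <- trace$force_g[1]
  stats::median(pre)
}

is_tetanic <- function(events) {
  !is.na(events$frequency_hz) & events$frequency_hz >= FUSION_THRESHOLD_HZ
}

#' Maximal tetanic force
#'
#' Maximum baseline-subtracted force within tetanic stimulus windows
#' (event frequency >= 20 Hz, the tetanic stimulation rate); the baseline is
#' the median force over the 200 ms preceding each event, which makes the
#' measure invariant to constant trace offsets.
#'
#' @param trace a [force_trace()].
#' @return force in grams.
#' @export
max_tetanic_force <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- trace$stim_events[is_tetanic(trace$stim_events), , drop = FALSE]
  if (!nrow(ev)) stopf("trace has no tetanic (>= %g Hz) stimulus events",
                       FUSION_THRESHOLD_HZ)
  peaks <- vapply(seq_len(nrow(ev)), function(k) {
    w <- force_in(trace, ev$t_start_s[k], ev$t_end_s[k] + PEAK_TAIL_S)
    max(w) - event_baseline(trace, ev$t_start_s[k])
  }, numeric(1))
  max(peaks)
}

#' Maximal twitch force
#'
#' As [max_tetanic_force()] but over single-pulse (sub-fusion) events.
#'
#' @param trace a [force_trace()].
#' @return force in grams.
#' @export
max_twitch_force <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- trace$stim_events[!is_tetanic(trace$stim_events), , drop = FALSE]
  if (!nrow(ev)) stopf("trace has no twitch (single-pulse) stimulus events")
  peaks <- vapply(seq_len(nrow(ev)), function(k) {
    w <- force_in(trace, ev$t_start_s[k], ev$t_end_s[k] + 2 * PEAK_TAIL_S)
    max(w) - event_baseline(trace, ev$t_start_s[k])
  }, numeric(1))
  max(peaks)
}

#' Force fold change
#'
#' Ratio of a test force to a reference force. Full precision is returned;
#' reports conventionally display one decimal (e.g. 7.5 g vs 0.8 g is a
#' 9.4-fold increase).
#'
#' @param test_g,reference_g forces in grams; `reference_g > 0`.
#' @return the ratio.
#' @examples
#' fold_change(7.5, 0.8)          # 9.375
#' round(fold_change(7.5, 0.8), 1)  # displayed as 9.4
#' @export
fold_change <- function(test_g, reference_g) {
  if (!is.finite(reference_g) || reference_g <= 0)
    stopf("reference force must be > 0")
  if (test_g < 0) stopf("test force must be >= 0")
  test_g / reference_g
}

#' Optically elicited force as a percentage of the electrical maximum
#'
#' `100 * ons_max_g / ens_max_g`: the fraction of total residual muscle
#' force (supra-maximal electrical nerve stimulation, which recruits every
#' axon) reached by optical stimulation of the engrafted units alone.
#'
#' @param ons_max_g maximal force under optical stimulation, g.
#' @param ens_max_g maximal force under supra-maximal electrical
#'   stimulation, g; must be > 0.
#' @return percentage.
#' @examples
#' percent_of_ens(22.7, 100)  # 22.7
#' @export
percent_of_ens <- function(ons_max_g, ens_max_g) {
  if (!is.finite(ens_max_g) || ens_max_g <= 0)
    stopf("ens_max_g must be > 0")
  if (ons_max_g < 0) stopf("ons_max_g must be >= 0")
  100 * ons_max_g / ens_max_g
}

#' Motor unit number estimation by increment counting
#'
#' Twitch amplitudes are measured for single-pulse stimuli sorted by
#' increasing intensity; an increment is declared whenever the amplitude
#' rises more than `k` noise SDs above the running plateau (mean amplitude
#' since the previous increment), and the estimate is the number of
#' increments. Twitch amplitudes are read as the mean force over a short
#' window centred on the twitch peak (latency taken from the strongest
#' response), which averages the transducer noise down by an order of
#' magnitude while keeping >98% of the peak of a ~20 ms twitch; the
#' detection threshold stays scaled to the raw pre-stimulus baseline SD, so
#' spurious units are never declared from peak-picking noise while any step
#' exceeding `k` baseline SDs is still resolved. With noise comparable to
#' the unit steps the estimate is conservative (it can only miss steps, not
#' invent them), so it decreases monotonically with noise on average.
#'
#' @param trace a [force_trace()] whose program contains >= 5 single-pulse
#'   events at monotonically increasing intensities.
#' @param k detection threshold in noise SDs.
#' @param peak_window_s width of the peak-centred averaging window, seconds.
#' @return integer estimate of the motor unit count.
#' @export
mune_estimate <- function(trace, k = 3, peak_window_s = 0.02) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- trace$stim_events[!is_tetanic(trace$stim_events), , drop = FALSE]
  if (nrow(ev) < 5L)
    stopf("need >= 5 single-pulse stimuli for an increment-count estimate")
  ev <- ev[order(ev$intensity), , drop = FALSE]
  pre <- force_in(trace, ev$t_start_s[1] - BASELINE_S, ev$t_start_s[1] - 1e-9)
  noise_sd <- if (length(pre) > 2) stats::sd(pre) else 0
  # twitch-peak latency from the strongest (last) response, on a lightly
  # smoothed copy so the latency itself is noise-robust
  fs <- trace$sampling_hz
  w_len <- max(1L, round(0.005 * fs))
  smf <- if (w_len > 1L) {
    kern <- rep(1 / w_len, w_len)
    f <- stats::filter(c(rep(trace$force_g[1], w_len), trace$force_g,
                         rep(trace$force_g[length(trace$force_g)], w_len)),
                       kern, sides = 2)
    as.numeric(f[(w_len + 1):(w_len + length(trace$force_g))])
  } else trace$force_g
  i_ev <- nrow(ev)
  sel <- which(trace$time_s >= ev$t_start_s[i_ev] &
                 trace$time_s <= ev$t_start_s[i_ev] + 2 * PEAK_TAIL_S)
  t_peak <- trace$time_s[sel[which.max(smf[sel])]] - ev$t_start_s[i_ev]
  half <- peak_window_s / 2
  amps <- vapply(seq_len(nrow(ev)), function(i) {
    w <- force_in(trace, ev$t_start_s[i] + t_peak - half,
                  ev$t_start_s[i] + t_peak + half)
    mean(w) - event_baseline(trace, ev$t_start_s[i])
  }, numeric(1))
  mune <- 0L
  plateau <- 0
  plateau_n <- 1L  # the zero-response level counts as the first plateau
  for (a in amps) {
    if (a > plateau + k * noise_sd) {
      mune <- mune + 1L
      plateau <- a
      plateau_n <- 1L
    } else {
      plateau <- (plateau * plateau_n + a) / (plateau_n + 1L)
      plateau_n <- plateau_n + 1L
    }
  }
  mune
}

#' Fatigue index over a repeated-burst protocol
#'
#' `1 - mean(peak of final n bursts) / mean(peak of first n bursts)`,
#' clipped to `[0, 1]`: 0 = no decline, 1 = complete force loss. Burst peaks
#' are baseline-subtracted using the pre-protocol baseline. The protocol
#' must contain at least 20 bursts and span at least 170 s (the canonical
#' protocol is a 250 ms, 20 Hz burst every 1 s for 180 s).
#'
#' @param trace a [force_trace()] carrying the burst events.
#' @param n_ref number of bursts averaged at each end.
#' @return index in `[0, 1]`.
#' @export
fatigue_index <- function(trace, n_ref = 10) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- trace$stim_events[is_tetanic(trace$stim_events), , drop = FALSE]
  if (nrow(ev) < 20L) stopf("need >= 20 bursts for a fatigue index")
  span <- max(ev$t_end_s) - min(ev$t_start_s)
  if (span < 170) stopf("burst protocol spans only %.1f s (need >= 170 s)", span)
  ev <- ev[order(ev$t_start_s), , drop = FALSE]
  base <- event_baseline(trace, ev$t_start_s[1])
  peaks <- vapply(seq_len(nrow(ev)), function(i)
    max(force_in(trace, ev$t_start_s[i], ev$t_end_s[i] + PEAK_TAIL_S)) - base,
    numeric(1))
  first <- mean(peaks[seq_len(n_ref)])
  last <- mean(peaks[seq.int(nrow(ev) - n_ref + 1L, nrow(ev))])
  if (first <= 0) stopf("non-positive initial burst force")
  min(max(1 - last / first, 0), 1)
}

#' Assemble a physiology summary for one trace
#'
#' Computes every contractile metric the trace's stimulus program supports:
#' maximal tetanic and twitch force, fold change versus a reference force,
#' percent of the electrical maximum, MUNE (when an intensity ramp of >= 5
#' single pulses is present) and fatigue index (when a repeated-burst
#' protocol is present).
#'
#' @param trace a [force_trace()].
#' @param reference_g optional reference maximal force for `fold_change`.
#' @param ens_max_g optional electrical-stimulation maximum for
#'   `percent_of_ens`.
#' @return list of class `physiology_summary`.
#' @export
physiology_summary <- function(trace, reference_g = NULL, ens_max_g = NULL) {
  ev <- trace$stim_events
  tet <- is_tetanic(ev)
  out <- list(max_tetanic_force_g = NA_real_, max_twitch_force_g = NA_real_,
              fold_change = NA_real_, percent_of_ens = NA_real_,
              mune = NA_integer_, fatigue_index = NA_real_)
  if (any(tet)) out$max_tetanic_force_g <- max_tetanic_force(trace)
  if (any(!tet)) out$max_twitch_force_g <- max_twitch_force(trace)
  if (!is.null(reference_g) && any(tet))
    out$fold_change <- fold_change(out$max_tetanic_force_g, reference_g)
  if (!is.null(ens_max_g) && any(tet))
    out$percent_of_ens <- percent_of_ens(out$max_tetanic_force_g, ens_max_g)
  single <- ev[!tet, , drop = FALSE]
  if (nrow(single) >= 5L && all(diff(single$intensity) > 0))
    out$mune <- mune_estimate(trace)
  if (sum(tet) >= 20L &&
      (max(ev$t_end_s[tet]) - min(ev$t_start_s[tet])) >= 170)
    out$fatigue_index <- fatigue_index(trace)
  structure(out, class = "physiology_summary")
}

#' @export
print.physiology_summary <- function(x, ...) {
  cat("<physiology_summary>\n")
  if (!is.na(x$max_tetanic_force_g))
    cat(sprintf("  max tetanic force: %.2f g\n", x$max_tetanic_force_g))
  if (!is.na(x$max_twitch_force_g))
    cat(sprintf("  max twitch force:  %.3f g\n", x$max_twitch_force_g))
  if (!is.na(x$fold_change))
    cat(sprintf("  fold change:       %.1f\n", x$fold_change))
  if (!is.na(x$percent_of_ens))
    cat(sprintf("  %% of ENS maximum:  %.1f%%\n", x$percent_of_ens))
  if (!is.na(x$mune))
    cat(sprintf("  MUNE:              %d units\n", x$mune))
  if (!is.na(x$fatigue_index))
    cat(sprintf("  fatigue index:     %.3f\n", x$fatigue_index))
  invisible(x)
}
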