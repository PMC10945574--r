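# Force-trace analytics: tetanic/twitch force, fold change, ONS/ENS
# efficiency, MUNE, and fatigue index.

# Hand-built trace: flat baseline with one rectangular tetanic plateau.
plateau_trace <- function(baseline = 1, plateau = 7.5, fs = 1000) {
  tt <- seq(0, 3, by = 1 / fs)
  f <- rep(baseline, length(tt))
  f[tt >= 1 & tt <= 2] <- baseline + plateau
  force_trace(tt, f, fs, stim_tetanus(t_start_s = 1, duration_s = 1,
                                      frequency_hz = 40))
}

test_that("maximal tetanic force is baseline-subtracted and offset-invariant", {
  tr <- plateau_trace(baseline = 1, plateau = 7.5)
  expect_equal(max_tetanic_force(tr), 7.5, tolerance = 1e-9)
  shifted <- tr
  shifted$force_g <- tr$force_g + 11.3
  expect_equal(max_tetanic_force(shifted), max_tetanic_force(tr),
               tolerance = 1e-9)
})

test_that("traces without tetanic events are rejected", {
  tt <- seq(0, 2, by = 1e-3)
  tr <- force_trace(tt, rep(0, length(tt)), 1000,
                    stim_twitch_ramp(c(0.2, 0.4, 0.6), start_s = 0.5,
                                     interval_s = 0.3))
  expect_error(max_tetanic_force(tr), "tetanic")
  expect_error(fatigue_index(tr), "bursts")
})

test_that("phantom tetanic force is recovered near the known fused force", {
  sp <- trace_phantom_spec(n_motor_units = 6, noise_sd_g = 0.005, seed = 4)
  tr <- generate_force_trace(sp, stim_tetanus(0.5, 1, 40, intensity = 1))
  clean_peak <- max(attr(tr, "clean"))
  expect_lt(abs(max_tetanic_force(tr) - clean_peak), 5 * sp$noise_sd_g)
})

test_that("fold change follows the display convention", {
  expect_equal(fold_change(7.5, 0.8), 9.375)
  expect_equal(round(fold_change(7.5, 0.8), 1), 9.4)
  expect_equal(fold_change(3.2, 3.2), 1)
  expect_equal(fold_change(0, 5), 0)
  expect_error(fold_change(1, 0), "> 0")
  expect_error(fold_change(1, -2), "> 0")
})

test_that("ONS efficiency is a percentage of the electrical maximum", {
  expect_equal(percent_of_ens(22.7, 100), 22.7)
  expect_equal(percent_of_ens(0, 10), 0)
  expect_error(percent_of_ens(1, 0), "> 0")
  # trained vs untrained efficiency: 22.7% vs 1.46% is a > 13-fold gain
  expect_gte(22.7 / 1.46, 13)
})

test_that("MUNE recovers the unit count on a clean staircase", {
  sp <- trace_phantom_spec(n_motor_units = 6, noise_sd_g = 0.002, seed = 9)
  tr <- generate_force_trace(sp, stim_twitch_ramp(seq(0.05, 1, by = 0.05)))
  expect_identical(mune_estimate(tr), 6L)
})

test_that("a flat zero response gives MUNE 0, few stimuli are an error", {
  tt <- seq(0, 6, by = 1e-3)
  ramp <- stim_twitch_ramp(seq(0.1, 1, length.out = 10))
  tr <- force_trace(tt, rnorm(length(tt), 0, 1e-4), 1000, ramp)
  expect_identical(mune_estimate(tr), 0L)
  short <- force_trace(tt, rep(0, length(tt)), 1000,
                       stim_twitch_ramp(c(0.2, 0.5, 0.8), start_s = 0.5))
  expect_error(mune_estimate(short), ">= 5")
})

test_that("MUNE degrades monotonically (on average) with noise", {
  ramp <- stim_twitch_ramp(seq(0.05, 1, by = 0.05))
  med_mune <- vapply(c(0.002, 0.05, 0.3), function(ns) {
    ests <- vapply(1:7, function(s) {
      sp <- trace_phantom_spec(n_motor_units = 6, noise_sd_g = ns, seed = s)
      mune_estimate(generate_force_trace(sp, ramp))
    }, integer(1))
    median(ests)
  }, numeric(1))
  expect_true(all(diff(med_mune) <= 0))
})

test_that("fatigue index is 0 for constant bursts and ~0.75 for 25% decay", {
  prog <- stim_fatigue(total_s = 180)
  const <- generate_force_trace(trace_phantom_spec(fatigue_tau_s = Inf,
                                                   noise_sd_g = 0.005,
                                                   seed = 3), prog)
  expect_lte(fatigue_index(const), 0.02)
  # tau chosen so the late-window / early-window envelope ratio is 25%
  tau <- 170 / log(4)
  dec <- generate_force_trace(trace_phantom_spec(fatigue_tau_s = tau,
                                                 noise_sd_g = 0.005,
                                                 seed = 3), prog)
  expect_equal(fatigue_index(dec), 0.75, tolerance = 0.02)
})

test_that("fatigue index rises with the fatigue rate", {
  prog <- stim_fatigue(total_s = 180)
  idx <- vapply(c(Inf, 400, 150, 60), function(tau)
    fatigue_index(generate_force_trace(
      trace_phantom_spec(fatigue_tau_s = tau, noise_sd_g = 0.002, seed = 5),
      prog)), numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("short burst protocols are rejected", {
  prog <- stim_fatigue(total_s = 30)
  tr <- generate_force_trace(trace_phantom_spec(seed = 1), prog)
  expect_error(fatigue_index(tr), "170")
})

test_that("the summary assembles every metric the program supports", {
  sp <- trace_phantom_spec(n_motor_units = 6, noise_sd_g = 0.002, seed = 8)
  prog <- rbind(stim_twitch_ramp(seq(0.05, 1, by = 0.05), start_s = 0.5),
                stim_tetanus(t_start_s = 12, duration_s = 1, frequency_hz = 40))
  tr <- generate_force_trace(sp, prog)
  s <- physiology_summary(tr, reference_g = 0.8, ens_max_g = 20)
  expect_identical(s$mune, 6L)
  expect_false(is.na(s$max_tetanic_force_g))
  expect_false(is.na(s$max_twitch_force_g))
  expect_equal(s$fold_change, s$max_tetanic_force_g / 0.8)
  expect_equal(s$percent_of_ens, 100 * s$max_tetanic_force_g / 20)
  expect_true(is.na(s$fatigue_index))  # no repeated-burst protocol present
})
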