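# Phantom generators: determinism, geometric truth, and statistical
# structure of the simulated populations.

test_that("muscle phantom is a deterministic function of spec + seed", {
  sp <- clean_muscle_spec(n_fibers = 2, seed = 3)
  a <- generate_muscle_phantom(sp)
  b <- generate_muscle_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  c2 <- generate_muscle_phantom(clean_muscle_spec(n_fibers = 2, seed = 4))
  expect_false(identical(a$truth$fibers$csa_um2, c2$truth$fibers$csa_um2))
})

test_that("truth records and label volume agree (truth conservation)", {
  ph <- generate_muscle_phantom(clean_muscle_spec(n_fibers = 5, seed = 9))
  ids <- sort(setdiff(unique(as.vector(ph$labels)), 0L))
  expect_identical(ids, ph$truth$fibers$fiber_id)
  expect_true(all(ph$truth$fibers$csa_um2 > 0))
})

test_that("a zero-eccentricity fibre is a circular cylinder with CSA pi r^2", {
  ph <- cylinder_phantom(csa = 350)
  f <- ph$truth$fibers
  expect_equal(f$semi_major_um, f$semi_minor_um, tolerance = 1e-9)
  expect_equal(f$csa_um2, pi * f$semi_major_um^2, tolerance = 1e-12)
  expect_equal(c(f$axis_x, f$axis_y, f$axis_z), c(1, 0, 0), tolerance = 1e-12)
})

test_that("voxel-count CSA of truth labels matches the analytic ellipse area", {
  # straight fibres, no tilt: every x-slice of the label volume is the same
  # rasterized ellipse, so per-slice voxel count x voxel area ~ pi a b
  sp <- clean_muscle_spec(n_fibers = 3, seed = 5, axis_tilt_deg = 0)
  ph <- generate_muscle_phantom(sp)
  vs <- sp$voxel_size_um
  nx <- dim(ph$labels)[3]
  for (k in seq_len(nrow(ph$truth$fibers))) {
    f <- ph$truth$fibers[k, ]
    vox_area <- sum(ph$labels == f$fiber_id) / nx * vs[2] * vs[3]
    band <- ellipse_perimeter(f$semi_major_um, f$semi_minor_um) * max(vs)
    expect_lt(abs(vox_area - f$csa_um2), band)
  }
})

test_that("class composition follows the multinomial law of the spec", {
  # generating fractions = the observed fibre-class composition
  # (62 graft / 13 endogenous / 28 denervated / 117 unconfirmed of 220)
  expected <- c(graft = 62, endogenous = 13, denervated = 28,
                unconfirmed = 117)
  frac <- expected / 220
  sp <- muscle_phantom_spec(n_fibers = 220, class_fractions = frac,
                            fov_um = c(80, 20000), seed = 21)
  ph <- generate_muscle_phantom(sp, raster = FALSE)
  obs <- table(factor(ph$truth$fibers$class, levels = names(frac)))
  band <- 1.96 * sqrt(220 * frac * (1 - frac))
  expect_true(all(abs(as.numeric(obs) - expected) <= band))
})

test_that("per-class mean CSA converges to the spec mean (3 SE at n=500)", {
  sp <- muscle_phantom_spec(n_fibers = 2000, fov_um = c(80, 2e5), seed = 31)
  counts <- c(graft = 500L, endogenous = 500L, denervated = 500L,
              unconfirmed = 500L)
  ph <- generate_muscle_phantom(sp, raster = FALSE, class_counts = counts)
  f <- ph$truth$fibers
  for (cl in names(counts)) {
    v <- f$csa_um2[f$class == cl]
    expect_length(v, 500L)
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - sp$csa_mean_um2[[cl]]), 3 * se)
  }
})

test_that("muscle phantom encodes innervation classes in the truth", {
  sp <- clean_muscle_spec(n_fibers = 6, seed = 13)
  ph <- generate_muscle_phantom(sp, raster = FALSE)
  f <- ph$truth$fibers; ep <- ph$truth$endplates
  expect_identical(sort(ep$fiber_id),
                   sort(f$fiber_id[f$class != "unconfirmed"]))
  for (k in seq_len(nrow(ep))) {
    cl <- f$class[match(ep$fiber_id[k], f$fiber_id)]
    expect_true(switch(cl,
      graft = ep$category[k] %in% c("graft_full", "graft_partial"),
      endogenous = ep$category[k] == "endogenous",
      denervated = ep$category[k] == "denervated"))
  }
})

test_that("impossible packing fails with the achievable count", {
  sp <- muscle_phantom_spec(n_fibers = 50, fov_um = c(40, 80), seed = 1)
  expect_error(generate_muscle_phantom(sp, raster = FALSE),
               "achievable count")
})

## ---- nerve phantoms ----

test_that("an empty nerve spec yields a blank image and empty table", {
  np <- generate_nerve_phantom(nerve_phantom_spec(
    n_axons = 0, image_size_px = c(64, 64), psf_sigma_um = 0,
    noise = no_noise, seed = 1))
  expect_identical(nrow(np$truth), 0L)
  expect_equal(max(np$image$data), 0)
})

test_that("sampled axon calibres match the analytic lognormal moments", {
  mu <- log(6); sg <- 0.5
  sp <- nerve_phantom_spec(n_axons = 1000,
                           calibre_mixture = list(meanlog = mu, sdlog = sg,
                                                  weight = 1),
                           image_size_px = c(2000, 2000), pixel_size_um = 0.25,
                           seed = 17)
  np <- generate_nerve_phantom(sp, raster = FALSE)
  m_true <- exp(mu + sg^2 / 2)
  sd_true <- m_true * sqrt(exp(sg^2) - 1)
  expect_lt(abs(mean(np$truth$csa_um2) - m_true),
            3 * sd_true / sqrt(1000))
  expect_equal(np$truth$csa_um2, pi * np$truth$radius_um^2, tolerance = 1e-12)
})

test_that("motor_fraction = 1 gives identical channel supports", {
  np <- generate_nerve_phantom(nerve_phantom_spec(
    n_axons = 25, motor_fraction = 1, image_size_px = c(220, 220),
    psf_sigma_um = 0, noise = no_noise, seed = 2))
  expect_identical(np$image$data[1, , ] > 0, np$image$data[2, , ] > 0)
  expect_true(all(np$truth$is_motor))
})

test_that("packed axon discs never overlap", {
  np <- generate_nerve_phantom(nerve_phantom_spec(
    n_axons = 80, image_size_px = c(300, 300), seed = 4), raster = FALSE)
  t <- np$truth
  dmat <- as.matrix(dist(cbind(t$x_um, t$y_um)))
  rsum <- outer(t$radius_um, t$radius_um, "+")
  diag(dmat) <- Inf
  expect_true(all(dmat >= rsum))
})

## ---- force-trace phantoms ----

test_that("a single supra-threshold pulse peaks at the unit twitch force", {
  sp <- trace_phantom_spec(n_motor_units = 1, unit_twitch_forces_g = 0.5,
                           recruitment_thresholds = 0.3, noise_sd_g = 0,
                           seed = 1)
  tr <- generate_force_trace(sp, stim_twitch_ramp(0.8, start_s = 0.5))
  expect_equal(max(tr$force_g), 0.5, tolerance = 1e-6)
  sub <- generate_force_trace(sp, stim_twitch_ramp(0.1, start_s = 0.5))
  expect_equal(max(sub$force_g), 0, tolerance = 1e-9)
})

test_that("a ramp over 6 units builds a staircase with exactly 6 increments", {
  sp <- trace_phantom_spec(n_motor_units = 6, noise_sd_g = 0, seed = 1)
  ramp <- stim_twitch_ramp(seq(0.05, 1, by = 0.05))
  tr <- generate_force_trace(sp, ramp)
  amps <- vapply(seq_len(nrow(ramp)), function(i) {
    w <- tr$force_g[tr$time_s >= ramp$t_start_s[i] &
                      tr$time_s <= ramp$t_start_s[i] + 0.1]
    max(w)
  }, numeric(1))
  expect_identical(sum(diff(amps) > 1e-9), 6L)
})

test_that("without fatigue, burst peaks stay constant over the protocol", {
  sp <- trace_phantom_spec(fatigue_tau_s = Inf, noise_sd_g = 0, seed = 1)
  prog <- stim_fatigue(total_s = 180)
  tr <- generate_force_trace(sp, prog)
  peaks <- vapply(seq_len(nrow(prog)), function(i)
    max(tr$force_g[tr$time_s >= prog$t_start_s[i] &
                     tr$time_s <= prog$t_end_s[i] + 0.05]), numeric(1))
  expect_lt(diff(range(peaks)) / max(peaks), 1e-6)
})
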