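#' Specification for a synthetic longitudinal muscle-section volume
#'
#' Describes a ground-truthed phantom emulating a confocal z-stack through a
#' thick (default 30 um) longitudinal muscle section: quasi-parallel
#' elliptical-cylinder fibres running along x with class-dependent CSA
#' distributions, alpha-BTx endplate blobs on fibre surfaces, and GFP / ChAT
#' axon-terminal signal that encodes each fibre's innervation class:
#'
#' * `graft` fibres carry an endplate overlapped by a GFP+ terminal,
#' * `endogenous` fibres an endplate overlapped by a ChAT-only terminal,
#' * `denervated` fibres a bare endplate,
#' * `unconfirmed` fibres have no endplate inside the imaged volume.
#'
#' Default class fractions follow the observed fibre-class composition
#' (unconfirmed 0.50, graft 0.31, denervated 0.13, endogenous 0.06) and the
#' default class mean CSAs are the reported group means (922.3, 1018.3,
#' 525.4, 668.8 um^2).
#'
#' @param n_fibers number of fibres to pack.
#' @param class_fractions named fractions over
#'   `graft, endogenous, denervated, unconfirmed`; must sum to 1.
#' @param csa_mean_um2 named per-class mean CSA (um^2) of the lognormal
#'   fibre-size law.
#' @param csa_cv coefficient of variation of fibre CSA (scalar or per class).
#' @param fiber_eccentricity_range `[0,1)` pair; fibre cross-sections are
#'   ellipses with eccentricity drawn uniformly from this range.
#' @param axis_tilt_deg maximal angular jitter of fibre axes away from the
#'   section long axis (x), degrees.
#' @param voxel_size_um `(x, y, z)` voxel calibration, um.
#' @param section_thickness_um physical section thickness (z extent), um.
#'   Fibres whose cross-section does not fit are still generated but flagged
#'   `clipped`.
#' @param fov_um `(x, y)` field of view, um.
#' @param endplate_radius_um endplate blob radius, um.
#' @param axon_radius_um preterminal axon tube radius, um.
#' @param psf_sigma_um isotropic-in-um Gaussian PSF sigma (0 = none).
#' @param noise list `poisson_scale` (photons at intensity 1; 0 = off) and
#'   `gaussian_sd` (additive read noise, normalized units).
#' @param min_separation_um minimum clearance between fibre surfaces.
#' @param coverage_range range of the graft terminal's fractional coverage of
#'   its endplate; coverage >= 0.5 is a fully innervated junction.
#' @param seed integer seed; the whole phantom is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `muscle_phantom_spec`.
#' @export
muscle_phantom_spec <- function(n_fibers = 10,
                                class_fractions = c(graft = 0.31,
                                                    endogenous = 0.06,
                                                    denervated = 0.13,
                                                    unconfirmed = 0.50),
                                csa_mean_um2 = c(graft = 922.3,
                                                 endogenous = 1018.3,
                                                 denervated = 525.4,
                                                 unconfirmed = 668.8),
                                csa_cv = 0.25,
                                fiber_eccentricity_range = c(0.3, 0.8),
                                axis_tilt_deg = 8,
                                voxel_size_um = c(0.4, 0.4, 1.0),
                                section_thickness_um = 30,
                                fov_um = c(80, 400),
                                endplate_radius_um = 5,
                                axon_radius_um = 1.2,
                                psf_sigma_um = 0.4,
                                noise = list(poisson_scale = 100,
                                             gaussian_sd = 0.01),
                                min_separation_um = 2,
                                coverage_range = c(0.15, 0.95),
                                seed = 1L) {
  cls <- c("graft", "endogenous", "denervated", "unconfirmed")
  if (!setequal(names(class_fractions), cls))
    stopf("class_fractions must be named over: %s", paste(cls, collapse = ", "))
  class_fractions <- class_fractions[cls]
  check_fraction(class_fractions, "class_fractions")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stopf("class_fractions must sum to 1 (got %.12f)", sum(class_fractions))
  if (!setequal(names(csa_mean_um2), cls))
    stopf("csa_mean_um2 must be named over: %s", paste(cls, collapse = ", "))
  csa_mean_um2 <- csa_mean_um2[cls]
  check_positive(csa_mean_um2, "csa_mean_um2")
  if (length(csa_cv) == 1L) csa_cv <- stats::setNames(rep(csa_cv, 4), cls)
  csa_cv <- csa_cv[cls]
  check_positive(csa_cv, "csa_cv")
  ecc <- as.numeric(fiber_eccentricity_range)
  if (length(ecc) != 2L || any(ecc < 0) || any(ecc >= 1) || ecc[1] > ecc[2])
    stopf("fiber_eccentricity_range must be an ordered pair in [0, 1)")
  check_positive(voxel_size_um, "voxel_size_um")
  check_positive(section_thickness_um, "section_thickness_um")
  check_positive(fov_um, "fov_um")
  check_positive(endplate_radius_um, "endplate_radius_um")
  if (axis_tilt_deg < 0 || axis_tilt_deg >= 45)
    stopf("axis_tilt_deg must lie in [0, 45)")
  structure(list(n_fibers = as.integer(n_fibers),
                 class_fractions = class_fractions,
                 csa_mean_um2 = csa_mean_um2, csa_cv = csa_cv,
                 fiber_eccentricity_range = ecc,
                 axis_tilt_deg = axis_tilt_deg,
                 voxel_size_um = as.numeric(voxel_size_um),
                 section_thickness_um = section_thickness_um,
                 fov_um = as.numeric(fov_um),
                 endplate_radius_um = endplate_radius_um,
                 axon_radius_um = axon_radius_um,
                 psf_sigma_um = psf_sigma_um,
                 noise = noise,
                 min_separation_um = min_separation_um,
                 coverage_range = as.numeric(coverage_range),
                 seed = as.integer(seed)),
            class = "muscle_phantom_spec")
}

# lognormal parametrized by arithmetic mean m and CV
rlnorm_mean_cv <- function(n, m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# voxel-centre coordinate vectors of the raster grid
grid_coords <- function(extent_um, voxel_size_um) {
  lapply(seq_along(extent_um), function(i)
    seq(0, extent_um[i], by = voxel_size_um[i]))
}

# Broadcast the three coordinate vectors (z, y, x order) to full arrays.
coord_arrays <- function(zs, ys, xs) {
  d <- c(length(zs), length(ys), length(xs))
  list(z = array(rep(zs, times = d[2] * d[3]), d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       x = array(rep(xs, each = d[1] * d[2]), d))
}

# Paint value into ch (3-D [z,y,x]) where the ball |p - centre| <= r; keeps
# the maximum of existing and new signal.
render_sphere <- function(ch, centre, r, value, vs, zs, ys, xs) {
  iz <- which(zs >= centre[3] - r & zs <= centre[3] + r)
  iy <- which(ys >= centre[2] - r & ys <= centre[2] + r)
  ix <- which(xs >= centre[1] - r & xs <= centre[1] + r)
  if (!length(iz) || !length(iy) || !length(ix)) return(ch)
  co <- coord_arrays(zs[iz], ys[iy], xs[ix])
  inside <- (co$x - centre[1])^2 + (co$y - centre[2])^2 +
    (co$z - centre[3])^2 <= r^2
  sub <- ch[iz, iy, ix, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  ch[iz, iy, ix] <- sub
  ch
}

# Paint a capsule (cylinder with spherical caps) from p0 to p1, radius r.
render_capsule <- function(ch, p0, p1, r, value, vs, zs, ys, xs) {
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  iz <- which(zs >= lo[3] & zs <= hi[3])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  ix <- which(xs >= lo[1] & xs <= hi[1])
  if (!length(iz) || !length(iy) || !length(ix)) return(ch)
  co <- coord_arrays(zs[iz], ys[iy], xs[ix])
  u <- p1 - p0; L <- sqrt(sum(u^2))
  if (L < 1e-9) return(render_sphere(ch, p0, r, value, vs, zs, ys, xs))
  u <- u / L
  wx <- co$x - p0[1]; wy <- co$y - p0[2]; wz <- co$z - p0[3]
  t <- pmin(pmax(wx * u[1] + wy * u[2] + wz * u[3], 0), L)
  d2 <- (wx - t * u[1])^2 + (wy - t * u[2])^2 + (wz - t * u[3])^2
  inside <- d2 <= r^2
  sub <- ch[iz, iy, ix, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  ch[iz, iy, ix] <- sub
  ch
}

#' Generate a ground-truthed muscle-section phantom
#'
#' Packs elliptical-cylinder fibres into the section, rasterizes a label
#' volume and four intensity channels (`fiber`, `btx`, `gfp`, `chat`),
#' applies the PSF and a Poisson + Gaussian confocal noise model, and
#' returns the volume together with analytic per-fibre / per-endplate ground
#' truth. True CSA is the analytic ellipse area `pi * a * b`, recorded
#' before rasterization.
#'
#' @param spec a [muscle_phantom_spec()].
#' @param raster generate the voxel data? With `FALSE` only the geometric
#'   ground truth is generated (fast; used for large-n statistical studies
#'   of the fibre-population model).
#' @param class_counts optional named integer vector fixing the exact
#'   per-class fibre composition instead of multinomial sampling.
#' @return A list of class `muscle_phantom` with elements `volume` (a
#'   [volume_image()] or `NULL`), `labels` (integer `(z, y, x)` truth label
#'   volume or `NULL`), and `truth` (list of data frames `fibers`,
#'   `endplates`).
#' @examples
#' sp <- muscle_phantom_spec(n_fibers = 2, fov_um = c(40, 120),
#'                           psf_sigma_um = 0,
#'                           noise = list(poisson_scale = 0, gaussian_sd = 0))
#' ph <- generate_muscle_phantom(sp)
#' ph$truth$fibers$csa_um2
#' @export
generate_muscle_phantom <- function(spec, raster = TRUE, class_counts = NULL) {
  stopifnot(inherits(spec, "muscle_phantom_spec"))
  with_seed(spec$seed, {
    cls <- names(spec$class_fractions)
    n <- spec$n_fibers
    if (is.null(class_counts)) {
      classes <- sample(cls, n, replace = TRUE, prob = spec$class_fractions)
    } else {
      if (!setequal(names(class_counts), cls) || sum(class_counts) != n)
        stopf("class_counts must be named over all classes and sum to n_fibers")
      classes <- rep(names(class_counts), times = class_counts[cls][cls])
      classes <- sample(classes)  # random placement order
    }
    thick <- spec$section_thickness_um
    fov <- spec$fov_um
    tilt_max <- spec$axis_tilt_deg * pi / 180

    # Geometry (size, shape, orientation) is drawn ONCE per fibre; packing
    # rejection resamples only the position. Redrawing geometry on rejection
    # would select against large fibres and bias the CSA law downward.
    fibers <- vector("list", n)
    placed_y <- numeric(0); placed_z <- numeric(0); placed_R <- numeric(0)
    attempts <- 0L; max_attempts <- 10L * n
    for (i in seq_len(n)) {
      ci <- classes[i]
      csa <- rlnorm_mean_cv(1, spec$csa_mean_um2[[ci]], spec$csa_cv[[ci]])
      e <- stats::runif(1, spec$fiber_eccentricity_range[1],
                        spec$fiber_eccentricity_range[2])
      q <- sqrt(1 - e^2)
      a <- sqrt(csa / (pi * q)); b <- a * q
      theta <- stats::runif(1, 0, tilt_max)
      phi <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
      basis <- orthobasis(d)
      psi <- stats::runif(1, 0, 2 * pi)
      e1 <- cos(psi) * basis$u + sin(psi) * basis$v
      e2 <- -sin(psi) * basis$u + cos(psi) * basis$v
      drift <- abs(tan(theta)) * fov[1] / 2
      R <- a + drift
      ext_z <- sqrt((a * e1[3])^2 + (b * e2[3])^2)
      placed <- FALSE
      while (attempts < max_attempts) {
        attempts <- attempts + 1L
        cy <- stats::runif(1, min(R + 1, fov[2] / 2),
                           max(fov[2] - R - 1, fov[2] / 2))
        cz <- if (thick - 2 * (ext_z + drift) > 0.5)
          stats::runif(1, ext_z + drift + 0.25, thick - ext_z - drift - 0.25)
        else thick / 2
        if (length(placed_y)) {
          dd <- sqrt((placed_y - cy)^2 + (placed_z - cz)^2)
          if (any(dd < placed_R + R + spec$min_separation_um)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stopf(paste("could not pack %d fibres in %d attempts;",
                    "achievable count with this spec: %d"),
              n, max_attempts, i - 1L)
      cx <- fov[1] / 2
      zlo <- cz - drift - ext_z; zhi <- cz + drift + ext_z
      clipped <- zlo < 0 || zhi > thick
      placed_y <- c(placed_y, cy); placed_z <- c(placed_z, cz)
      placed_R <- c(placed_R, R)
      fibers[[i]] <- data.frame(
        fiber_id = i, class = ci, csa_um2 = pi * a * b,
        semi_major_um = a, semi_minor_um = b,
        centre_x_um = cx, centre_y_um = cy, centre_z_um = cz,
        axis_x = d[1], axis_y = d[2], axis_z = d[3],
        e1_x = e1[1], e1_y = e1[2], e1_z = e1[3],
        e2_x = e2[1], e2_y = e2[2], e2_z = e2[3],
        clipped = clipped, stringsAsFactors = FALSE)
    }
    fib <- do.call(rbind, fibers)

    # endplates + terminals (geometry truth)
    r_e <- spec$endplate_radius_um
    eps <- list(); ep_id <- 0L
    for (k in seq_len(n)) {
      if (fib$class[k] == "unconfirmed") next
      d <- c(fib$axis_x[k], fib$axis_y[k], fib$axis_z[k])
      e1 <- c(fib$e1_x[k], fib$e1_y[k], fib$e1_z[k])
      e2 <- c(fib$e2_x[k], fib$e2_y[k], fib$e2_z[k])
      ctr <- c(fib$centre_x_um[k], fib$centre_y_um[k], fib$centre_z_um[k])
      a <- fib$semi_major_um[k]; b <- fib$semi_minor_um[k]
      p <- NULL
      for (try in 1:30) {
        xe <- stats::runif(1, 0.15, 0.85) * fov[1]
        tt <- (xe - ctr[1]) / d[1]
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- ctr + tt * d + a * cos(ang) * e1 + b * sin(ang) * e2
        if (cand[2] > r_e / 2 && cand[2] < fov[2] - r_e / 2 &&
            cand[3] > r_e / 2 && cand[3] < thick - r_e / 2) { p <- cand; break }
        p <- cand
      }
      ep_id <- ep_id + 1L
      coverage <- switch(fib$class[k],
        graft = stats::runif(1, spec$coverage_range[1], spec$coverage_range[2]),
        endogenous = stats::runif(1, 0.5, 0.95),
        denervated = 0)
      category <- switch(fib$class[k],
        graft = if (coverage >= 0.5) "graft_full" else "graft_partial",
        endogenous = "endogenous",
        denervated = "denervated")
      eps[[ep_id]] <- data.frame(
        endplate_id = ep_id, fiber_id = fib$fiber_id[k],
        x_um = p[1], y_um = p[2], z_um = p[3],
        radius_um = r_e, coverage = coverage, category = category,
        stringsAsFactors = FALSE)
    }
    ep <- if (length(eps)) do.call(rbind, eps) else
      data.frame(endplate_id = integer(), fiber_id = integer(),
                 x_um = numeric(), y_um = numeric(), z_um = numeric(),
                 radius_um = numeric(), coverage = numeric(),
                 category = character(), stringsAsFactors = FALSE)

    fiber_intensity <- stats::runif(n, 0.5, 0.9)

    out <- list(volume = NULL, labels = NULL,
                truth = list(fibers = fib, endplates = ep),
                spec = spec)
    class(out) <- "muscle_phantom"
    if (!raster) return(out)

    vs <- spec$voxel_size_um
    xs <- grid_coords(c(fov[1]), vs[1])[[1]]
    ys <- grid_coords(c(fov[2]), vs[2])[[1]]
    zs <- grid_coords(c(thick), vs[3])[[1]]
    dims <- c(length(zs), length(ys), length(xs))
    labels <- array(0L, dims)
    for (k in seq_len(n)) {
      d <- c(fib$axis_x[k], fib$axis_y[k], fib$axis_z[k])
      e1 <- c(fib$e1_x[k], fib$e1_y[k], fib$e1_z[k])
      e2 <- c(fib$e2_x[k], fib$e2_y[k], fib$e2_z[k])
      ctr <- c(fib$centre_x_um[k], fib$centre_y_um[k], fib$centre_z_um[k])
      a <- fib$semi_major_um[k]; b <- fib$semi_minor_um[k]
      R <- a + abs(tan(acos(min(d[1], 1)))) * fov[1] / 2 + max(vs)
      iy <- which(ys >= ctr[2] - R & ys <= ctr[2] + R)
      iz <- which(zs >= ctr[3] - R & zs <= ctr[3] + R)
      if (!length(iy) || !length(iz)) next
      co <- coord_arrays(zs[iz], ys[iy], xs)
      wx <- co$x - ctr[1]; wy <- co$y - ctr[2]; wz <- co$z - ctr[3]
      t <- wx * d[1] + wy * d[2] + wz * d[3]
      rx <- wx - t * d[1]; ry <- wy - t * d[2]; rz <- wz - t * d[3]
      cu <- rx * e1[1] + ry * e1[2] + rz * e1[3]
      cv <- rx * e2[1] + ry * e2[2] + rz * e2[3]
      inside <- (cu / a)^2 + (cv / b)^2 <= 1
      sub <- labels[iz, iy, , drop = FALSE]
      sub[inside & sub == 0L] <- k
      labels[iz, iy, ] <- sub
    }

    lut <- c(0, fiber_intensity)
    fiber_ch <- array(lut[labels + 1L], dims)
    btx <- array(0, dims); gfp <- array(0, dims); chat <- array(0, dims)
    if (nrow(ep)) {
      for (k in seq_len(nrow(ep))) {
        p <- c(ep$x_um[k], ep$y_um[k], ep$z_um[k])
        btx <- render_sphere(btx, p, r_e, 0.9, vs, zs, ys, xs)
        if (ep$category[k] %in% c("graft_full", "graft_partial", "endogenous")) {
          rt <- r_e * ep$coverage[k]^(1 / 3)
          dt <- normalize3(c(-1, stats::runif(1, -0.3, 0.3),
                             stats::runif(1, -0.3, 0.3)))
          target <- if (ep$category[k] == "endogenous") "chat" else "gfp"
          chn <- if (target == "gfp") gfp else chat
          chn <- render_sphere(chn, p, rt, 0.85, vs, zs, ys, xs)
          chn <- render_capsule(chn, p, p + 15 * dt, spec$axon_radius_um,
                                0.8, vs, zs, ys, xs)
          if (target == "gfp") gfp <- chn else chat <- chn
        }
      }
    }

    sig_vox <- spec$psf_sigma_um / c(vs[3], vs[2], vs[1])
    chans <- list(fiber_ch, btx, gfp, chat)
    for (j in seq_along(chans)) {
      x <- chans[[j]]
      if (spec$psf_sigma_um > 0) x <- gauss_smooth(x, sig_vox)
      if (spec$noise$poisson_scale > 0)
        x <- array(stats::rpois(length(x), spec$noise$poisson_scale * x) /
                     spec$noise$poisson_scale, dims)
      if (spec$noise$gaussian_sd > 0)
        x <- x + stats::rnorm(length(x), 0, spec$noise$gaussian_sd)
      chans[[j]] <- quantize_uint16(pmin(pmax(x, 0), 1))
    }
    arr <- array(0, c(4, dims))
    for (j in 1:4) arr[j, , , ] <- chans[[j]]
    out$volume <- volume_image(arr, vs,
                               c(fiber = 1L, btx = 2L, gfp = 3L, chat = 4L))
    out$labels <- labels
    out
  })
}

#' @export
print.muscle_phantom <- function(x, ...) {
  cat(sprintf("<muscle_phantom> %d fibres (%s)%s\n",
              nrow(x$truth$fibers),
              paste(names(table(x$truth$fibers$class)),
                    table(x$truth$fibers$class), sep = ":", collapse = " "),
              if (is.null(x$volume)) " [truth only]" else ""))
  invisible(x)
}
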