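#' Specification for a synthetic nerve cross-section image
#'
#' Emulates a transverse nerve section labelled for total axons
#' (beta-III-tubulin) and motor axons (ChAT): non-overlapping discs with
#' calibres (CSA, um^2) drawn from a lognormal mixture — by default bimodal,
#' a small-calibre and a large-calibre component, as observed in mixed
#' peripheral nerve — and a motor subset rendered in both channels.
#'
#' @param n_axons number of axons to pack.
#' @param motor_fraction probability that an axon is a motor axon.
#' @param calibre_mixture list with numeric vectors `meanlog`, `sdlog`,
#'   `weight` (weights sum to 1) defining the lognormal mixture on CSA um^2.
#' @param image_size_px `(rows, cols)` of the rendered image.
#' @param pixel_size_um pixel pitch, um.
#' @param min_separation_um minimum clearance between axon boundaries.
#' @param psf_sigma_um Gaussian blur sigma, um (0 = none).
#' @param noise list `poisson_scale`, `gaussian_sd` as in
#'   [muscle_phantom_spec()].
#' @param seed integer seed.
#' @return An object of class `nerve_phantom_spec`.
#' @export
nerve_phantom_spec <- function(n_axons = 300, motor_fraction = 0.25,
                               calibre_mixture = list(
                                 meanlog = c(log(4), log(25)),
                                 sdlog = c(0.6, 0.35),
                                 weight = c(0.65, 0.35)),
                               image_size_px = c(512, 512),
                               pixel_size_um = 0.25,
                               min_separation_um = 0.5,
                               psf_sigma_um = 0.3,
                               noise = list(poisson_scale = 100,
                                            gaussian_sd = 0.01),
                               seed = 1L) {
  if (n_axons < 0) stopf("n_axons must be >= 0")
  check_fraction(motor_fraction, "motor_fraction")
  w <- calibre_mixture$weight
  if (abs(sum(w) - 1) > 1e-9) stopf("mixture weights must sum to 1")
  if (length(unique(lengths(calibre_mixture))) != 1L)
    stopf("mixture meanlog, sdlog, weight must have equal length")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(calibre_mixture$sdlog, "sdlog")
  structure(list(n_axons = as.integer(n_axons),
                 motor_fraction = motor_fraction,
                 calibre_mixture = calibre_mixture,
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um,
                 min_separation_um = min_separation_um,
                 psf_sigma_um = psf_sigma_um, noise = noise,
                 seed = as.integer(seed)),
            class = "nerve_phantom_spec")
}

#' Generate a ground-truthed nerve cross-section phantom
#'
#' Draws per-axon CSAs from the calibre mixture, packs non-overlapping discs
#' by random sequential placement, renders a two-channel image (`bIII` =
#' all axons, `chat` = motor subset), and returns the analytic truth table.
#' With `motor_fraction = 1` the two channels have identical support.
#'
#' @param spec a [nerve_phantom_spec()].
#' @param raster render the image? With `FALSE` only the truth table is
#'   generated (fast path for distribution-level studies).
#' @return list of class `nerve_phantom`: `image` (a [plane_image()] or
#'   `NULL`) and `truth` (data frame `axon_id`, `csa_um2`, `radius_um`,
#'   `x_um`, `y_um`, `is_motor`, `component`).
#' @export
generate_nerve_phantom <- function(spec, raster = TRUE) {
  stopifnot(inherits(spec, "nerve_phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$n_axons
    mix <- spec$calibre_mixture
    empty_truth <- data.frame(axon_id = integer(), csa_um2 = numeric(),
                              radius_um = numeric(), x_um = numeric(),
                              y_um = numeric(), is_motor = logical(),
                              component = integer())
    fov <- (spec$image_size_px - 1) * spec$pixel_size_um  # rows, cols extent
    if (n == 0L) {
      truth <- empty_truth
    } else {
      comp <- sample.int(length(mix$weight), n, replace = TRUE,
                         prob = mix$weight)
      csa <- stats::rlnorm(n, mix$meanlog[comp], mix$sdlog[comp])
      r <- sqrt(csa / pi)
      is_motor <- stats::runif(n) < spec$motor_fraction
      ord <- order(r, decreasing = TRUE)  # place large discs first
      xs <- numeric(0); ys <- numeric(0); rs <- numeric(0); keep <- integer(0)
      attempts <- 0L; max_attempts <- 10L * n
      for (i in ord) {
        placed <- FALSE
        while (attempts < max_attempts) {
          attempts <- attempts + 1L
          x <- stats::runif(1, r[i], fov[2] - r[i])
          y <- stats::runif(1, r[i], fov[1] - r[i])
          if (!length(xs) ||
              all((xs - x)^2 + (ys - y)^2 >=
                    (rs + r[i] + spec$min_separation_um)^2)) {
            xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r[i])
            keep <- c(keep, i); placed <- TRUE; break
          }
        }
        if (!placed)
          stopf(paste("could not pack %d axons in %d attempts;",
                      "achievable count with this spec: %d"),
                n, max_attempts, length(keep))
      }
      o <- order(keep)
      truth <- data.frame(axon_id = seq_len(n), csa_um2 = csa[keep][o],
                          radius_um = r[keep][o], x_um = xs[o], y_um = ys[o],
                          is_motor = is_motor[keep][o],
                          component = comp[keep][o])
    }
    out <- list(image = NULL, truth = truth, spec = spec)
    class(out) <- "nerve_phantom"
    if (!raster) return(out)

    nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
    ps <- spec$pixel_size_um
    biii <- matrix(0, nr, nc); chat <- matrix(0, nr, nc)
    if (nrow(truth)) {
      px <- (seq_len(nc) - 1) * ps
      py <- (seq_len(nr) - 1) * ps
      for (k in seq_len(nrow(truth))) {
        rr <- truth$radius_um[k]
        ic <- which(px >= truth$x_um[k] - rr & px <= truth$x_um[k] + rr)
        ir <- which(py >= truth$y_um[k] - rr & py <= truth$y_um[k] + rr)
        if (!length(ic) || !length(ir)) next
        dx2 <- outer(rep(1, length(ir)), (px[ic] - truth$x_um[k])^2)
        dy2 <- outer((py[ir] - truth$y_um[k])^2, rep(1, length(ic)))
        inside <- dx2 + dy2 <= rr^2
        sub <- biii[ir, ic, drop = FALSE]; sub[inside] <- 0.85
        biii[ir, ic] <- sub
        if (truth$is_motor[k]) {
          sub <- chat[ir, ic, drop = FALSE]; sub[inside] <- 0.85
          chat[ir, ic] <- sub
        }
      }
    }
    chans <- list(biii, chat)
    for (j in seq_along(chans)) {
      x <- chans[[j]]
      if (spec$psf_sigma_um > 0)
        x <- gauss_smooth(x, rep(spec$psf_sigma_um / ps, 2))
      if (spec$noise$poisson_scale > 0)
        x <- matrix(stats::rpois(length(x), spec$noise$poisson_scale * x) /
                      spec$noise$poisson_scale, nr, nc)
      if (spec$noise$gaussian_sd > 0)
        x <- x + stats::rnorm(length(x), 0, spec$noise$gaussian_sd)
      chans[[j]] <- quantize_uint16(pmin(pmax(x, 0), 1))
    }
    arr <- array(0, c(2, nr, nc))
    arr[1, , ] <- chans[[1]]; arr[2, , ] <- chans[[2]]
    out$image <- plane_image(arr, ps, c(bIII = 1L, chat = 2L))
    out
  })
}

#' @export
print.nerve_phantom <- function(x, ...) {
  cat(sprintf("<nerve_phantom> %d axons (%d motor)%s\n",
              nrow(x$truth), sum(x$truth$is_motor),
              if (is.null(x$image)) " [truth only]" else ""))
  invisible(x)
}
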