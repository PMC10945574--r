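# Shared fixtures, built once per test run. All phantoms here are small and
# deterministic; heavier study-scale runs live in test-acceptance.R.

no_noise <- list(poisson_scale = 0, gaussian_sd = 0)

# Zero-noise muscle spec whose fibres comfortably fit a 30-um section.
clean_muscle_spec <- function(n_fibers = 4, seed = 7, psf_sigma_um = 0,
                              noise = no_noise, ...) {
  muscle_phantom_spec(
    n_fibers = n_fibers,
    csa_mean_um2 = c(graft = 400, endogenous = 420, denervated = 300,
                     unconfirmed = 350),
    csa_cv = 0.2,
    fiber_eccentricity_range = c(0.2, 0.6),
    fov_um = c(60, 60 * n_fibers),
    psf_sigma_um = psf_sigma_um, noise = noise,
    seed = seed, ...)
}

# One straight circular-cylinder fibre along x (no tilt, no eccentricity).
cylinder_phantom <- function(csa = 350, seed = 11) {
  generate_muscle_phantom(muscle_phantom_spec(
    n_fibers = 1,
    class_fractions = c(graft = 0, endogenous = 0, denervated = 0,
                        unconfirmed = 1),
    csa_mean_um2 = c(graft = csa, endogenous = csa, denervated = csa,
                     unconfirmed = csa),
    csa_cv = 1e-6, fiber_eccentricity_range = c(0, 0),
    axis_tilt_deg = 0, fov_um = c(60, 80),
    psf_sigma_um = 0, noise = no_noise, seed = seed))
}

# Binary slice image with well-separated discs; returns the image and truth.
disc_slice <- function(centres_px, radii_px, size = c(120, 120),
                       pixel_size_um = 0.5) {
  img <- matrix(0, size[1], size[2])
  rr <- row(img); cc <- col(img)
  for (k in seq_len(nrow(centres_px))) {
    img[(rr - centres_px[k, 1])^2 + (cc - centres_px[k, 2])^2 <=
          radii_px[k]^2] <- 0.8
  }
  plane_image(array(img, c(1, size[1], size[2])), pixel_size_um,
              c(fiber = 1L))
}

# Ramanujan approximation of an ellipse perimeter.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Measured disc area on a slice by half-maximum thresholding (oracle-side
# area counter, independent of the segmentation pipeline).
threshold_area <- function(slice, channel = "fiber") {
  m <- get_plane_channel(slice, channel)
  m[is.na(m)] <- 0
  sum(m > max(m) / 2) * slice$pixel_size_um^2
}
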