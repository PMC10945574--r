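# Digital transverse reslicing: all geometry is done in physical micrometre
# coordinates so anisotropic voxels need no prior resampling (which would
# interpolate twice).

# Right-handed orthonormal in-plane basis for a unit normal.
orthobasis <- function(n) {
  n <- normalize3(n)
  ref <- diag(3)[, which.min(abs(n))]
  u <- normalize3(cross3(n, ref))
  v <- cross3(n, u)
  list(u = u, v = v)
}

#' Oriented sampling plane for digital reslicing
#'
#' A plane is defined by its origin (plane centre), unit normal (the local
#' fibre axis for transverse reslicing), an orthonormal in-plane basis
#' `(u, v)`, a physical extent and a sampling pixel size. If `basis_u` /
#' `basis_v` are omitted a deterministic basis is constructed from the
#' normal.
#'
#' @param origin_um plane centre, `(x, y, z)` um.
#' @param normal_um plane normal (need not be unit length).
#' @param extent_um `(width, height)` of the sampled window, um.
#' @param pixel_size_um sampling pitch, um (square pixels).
#' @param basis_u,basis_v optional in-plane unit vectors; must form an
#'   orthonormal triplet with the normal.
#' @return An object of class `reslice_plane`.
#' @export
reslice_plane <- function(origin_um, normal_um, extent_um, pixel_size_um,
                          basis_u = NULL, basis_v = NULL) {
  n <- normalize3(as.numeric(normal_um))
  if (is.null(basis_u) || is.null(basis_v)) {
    b <- orthobasis(n)
    basis_u <- b$u; basis_v <- b$v
  }
  m <- rbind(n, basis_u, basis_v)
  if (max(abs(m %*% t(m) - diag(3))) > 1e-9)
    stopf("normal, basis_u, basis_v must be orthonormal to 1e-9")
  extent_um <- as.numeric(extent_um)
  if (length(extent_um) == 1L) extent_um <- rep(extent_um, 2)
  check_positive(extent_um, "extent_um")
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(origin_um = as.numeric(origin_um), normal_um = n,
                 basis_u = basis_u, basis_v = basis_v,
                 extent_um = extent_um, pixel_size_um = pixel_size_um),
            class = "reslice_plane")
}

# Trilinear interpolation of a (z, y, x) array at world points (N x 3,
# columns x/y/z um). Points outside the voxel-centre hull return NA.
trilinear_sample <- function(arr, pts, voxel_size_um) {
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  fx <- pts[, 1] / voxel_size_um[1]
  fy <- pts[, 2] / voxel_size_um[2]
  fz <- pts[, 3] / voxel_size_um[3]
  tol <- 1e-9
  ok <- fx >= -tol & fx <= nx - 1 + tol &
        fy >= -tol & fy <= ny - 1 + tol &
        fz >= -tol & fz <= nz - 1 + tol
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  fx <- pmin(pmax(fx[ok], 0), nx - 1)
  fy <- pmin(pmax(fy[ok], 0), ny - 1)
  fz <- pmin(pmax(fz[ok], 0), nz - 1)
  x0 <- pmin(floor(fx), max(nx - 2, 0)); wx <- fx - x0
  y0 <- pmin(floor(fy), max(ny - 2, 0)); wy <- fy - y0
  z0 <- pmin(floor(fz), max(nz - 2, 0)); wz <- fz - z0
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1); z1 <- pmin(z0 + 1, nz - 1)
  g <- function(zi, yi, xi) arr[cbind(zi + 1, yi + 1, xi + 1)]
  val <-
    g(z0, y0, x0) * (1 - wz) * (1 - wy) * (1 - wx) +
    g(z0, y0, x1) * (1 - wz) * (1 - wy) * wx +
    g(z0, y1, x0) * (1 - wz) * wy * (1 - wx) +
    g(z0, y1, x1) * (1 - wz) * wy * wx +
    g(z1, y0, x0) * wz * (1 - wy) * (1 - wx) +
    g(z1, y0, x1) * wz * (1 - wy) * wx +
    g(z1, y1, x0) * wz * wy * (1 - wx) +
    g(z1, y1, x1) * wz * wy * wx
  out[ok] <- val
  out
}

#' Estimate the local fibre axis by structure-tensor eigenanalysis
#'
#' The dominant orientation of the fibre-channel intensity inside a
#' rectangular ROI: intensity gradients are computed by central differences
#' in physical micrometre space (anisotropy-corrected), their outer products
#' averaged over the ROI, and the axis is the eigenvector of the smallest
#' eigenvalue of that structure tensor (the direction along which intensity
#' varies least). The sign is fixed to a positive x component (ties: positive
#' y, then z).
#'
#' @param vol a [volume_image()] with a `fiber` channel (or use `channel`).
#' @param roi list with integer elements `x`, `y`, `z`, each a 1-based
#'   inclusive voxel index range `c(lo, hi)`; `NULL` = whole volume.
#' @param channel channel role or index to analyse.
#' @param sigma_um Gaussian pre-smoothing in um.
#' @return unit 3-vector `(x, y, z)`.
#' @export
estimate_fiber_axis <- function(vol, roi = NULL, channel = "fiber",
                                sigma_um = 1) {
  stopifnot(inherits(vol, "volume_image"))
  a <- get_channel(vol, channel)
  d <- dim(a)
  if (!is.null(roi)) {
    rz <- roi$z %||% c(1L, d[1]); ry <- roi$y %||% c(1L, d[2])
    rx <- roi$x %||% c(1L, d[3])
    if (rx[1] > rx[2] || ry[1] > ry[2] || rz[1] > rz[2])
      stopf("ROI is empty")
    a <- a[max(1, rz[1]):min(d[1], rz[2]),
           max(1, ry[1]):min(d[2], ry[2]),
           max(1, rx[1]):min(d[3], rx[2]), drop = FALSE]
  }
  if (any(dim(a) < 3L))
    stopf("ROI too small for gradient estimation (need >= 3 voxels per axis)")
  vs <- vol$voxel_size_um
  if (sigma_um > 0)
    a <- gauss_smooth(a, sigma_um / c(vs[3], vs[2], vs[1]))
  dd <- dim(a)
  iz <- 2:(dd[1] - 1); iy <- 2:(dd[2] - 1); ix <- 2:(dd[3] - 1)
  gx <- (a[iz, iy, ix + 1, drop = FALSE] - a[iz, iy, ix - 1, drop = FALSE]) / (2 * vs[1])
  gy <- (a[iz, iy + 1, ix, drop = FALSE] - a[iz, iy - 1, ix, drop = FALSE]) / (2 * vs[2])
  gz <- (a[iz + 1, iy, ix, drop = FALSE] - a[iz - 1, iy, ix, drop = FALSE]) / (2 * vs[3])
  J <- matrix(c(mean(gx * gx), mean(gx * gy), mean(gx * gz),
                mean(gx * gy), mean(gy * gy), mean(gy * gz),
                mean(gx * gz), mean(gy * gz), mean(gz * gz)), 3, 3)
  scale <- (max(a) - min(a))^2 / max(vs)^2
  if (sum(diag(J)) <= 1e-12 * max(scale, 1e-300))
    stopf("degenerate structure tensor: ROI intensity is uniform; use a larger ROI")
  ev <- eigen(J, symmetric = TRUE)
  lam <- ev$values  # decreasing
  if ((lam[2] - lam[3]) <= 1e-6 * lam[1])
    stopf("degenerate structure tensor: no dominant orientation in ROI; use a larger ROI")
  v <- ev$vectors[, 3]
  s <- if (abs(v[1]) > 1e-9) sign(v[1]) else if (abs(v[2]) > 1e-9) sign(v[2]) else sign(v[3])
  v * s
}

# ROI (voxel index ranges) around a world point.
roi_around <- function(vol, centre_um, half_um) {
  d <- dim(vol$data)
  vs <- vol$voxel_size_um
  if (length(half_um) == 1L) half_um <- rep(half_um, 3)
  ix <- round(centre_um[1] / vs[1]) + 1L
  iy <- round(centre_um[2] / vs[2]) + 1L
  iz <- round(centre_um[3] / vs[3]) + 1L
  hx <- ceiling(half_um[1] / vs[1]); hy <- ceiling(half_um[2] / vs[2])
  hz <- ceiling(half_um[3] / vs[3])
  list(x = c(max(1L, ix - hx), min(d[4], ix + hx)),
       y = c(max(1L, iy - hy), min(d[3], iy + hy)),
       z = c(max(1L, iz - hz), min(d[2], iz + hz)))
}

#' Extract a virtual transverse slice by trilinear interpolation
#'
#' Samples all channels of the volume on the plane's pixel grid in physical
#' micrometre space. Samples falling outside the volume are `NA` (missing,
#' never zero) and stay excluded from downstream area measurements.
#'
#' @param vol a [volume_image()].
#' @param plane a [reslice_plane()].
#' @return a [plane_image()] carrying the plane and pixel size.
#' @export
reslice_volume <- function(vol, plane) {
  stopifnot(inherits(vol, "volume_image"), inherits(plane, "reslice_plane"))
  ps <- plane$pixel_size_um
  nu <- max(2L, round(plane$extent_um[1] / ps) + 1L)
  nv <- max(2L, round(plane$extent_um[2] / ps) + 1L)
  su <- (seq_len(nu) - 1 - (nu - 1) / 2) * ps
  sv <- (seq_len(nv) - 1 - (nv - 1) / 2) * ps
  U <- matrix(rep(su, each = nv), nv, nu)
  V <- matrix(rep(sv, times = nu), nv, nu)
  pts <- cbind(
    plane$origin_um[1] + U * plane$basis_u[1] + V * plane$basis_v[1],
    plane$origin_um[2] + U * plane$basis_u[2] + V * plane$basis_v[2],
    plane$origin_um[3] + U * plane$basis_u[3] + V * plane$basis_v[3])
  dim(pts) <- c(nv * nu, 3)
  nc <- dim(vol$data)[1]
  out <- array(NA_real_, c(nc, nv, nu))
  any_inside <- FALSE
  for (ch in seq_len(nc)) {
    v <- trilinear_sample(get_channel(vol, ch), pts, vol$voxel_size_um)
    if (!any_inside && any(!is.na(v))) any_inside <- TRUE
    out[ch, , ] <- matrix(v, nv, nu)
  }
  if (!any_inside) stopf("reslice plane lies entirely outside the volume")
  plane_image(out, ps, vol$channel_roles, plane = plane)
}
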