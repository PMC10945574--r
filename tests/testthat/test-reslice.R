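# Axis estimation and digital transverse reslicing: exactness guarantees
# and the oblique-geometry behaviour that underpins CSA fidelity.

make_affine_volume <- function(coef = c(2, 0.3, 0.7, -0.2),
                               dims = c(8, 24, 24), vs = c(0.5, 0.5, 1.0)) {
  # intensity = c0 + c1 x + c2 y + c3 z at voxel centres (um)
  arr <- array(0, c(1, dims))
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    xs <- (seq_len(dims[3]) - 1) * vs[1]
    arr[1, z, y, ] <- coef[1] + coef[2] * xs +
      coef[3] * (y - 1) * vs[2] + coef[4] * (z - 1) * vs[3]
  }
  volume_image(arr, vs, c(fiber = 1L))
}

test_that("a native z-slice reslices exactly", {
  set.seed(42)
  dims <- c(6, 12, 12)
  arr <- array(round(runif(prod(dims)) * 65535) / 65535, c(1, dims))
  v <- volume_image(arr, c(0.5, 0.5, 1.0), c(fiber = 1L))
  k <- 3L  # 0-based z index of the sampled plane
  pl <- reslice_plane(
    origin_um = c((dims[3] - 1) / 2 * 0.5, (dims[2] - 1) / 2 * 0.5, k * 1.0),
    normal_um = c(0, 0, 1),
    extent_um = c((dims[3] - 1) * 0.5, (dims[2] - 1) * 0.5),
    pixel_size_um = 0.5,
    basis_u = c(1, 0, 0), basis_v = c(0, 1, 0))
  sl <- reslice_volume(v, pl)
  expect_identical(dim(sl$data), as.integer(c(1, dims[2], dims[3])))
  expect_equal(matrix(sl$data[1, , ], dims[2], dims[3]),
               matrix(arr[1, k + 1L, , ], dims[2], dims[3]),
               tolerance = 0)
})

test_that("trilinear reslicing is exact on affine intensity fields", {
  coef <- c(2, 0.3, 0.7, -0.2)
  v <- make_affine_volume(coef)
  pl <- reslice_plane(c(4.1, 4.3, 3.2), c(1, 0.5, 0.25), c(3, 3), 0.22)
  sl <- reslice_volume(v, pl)
  nu <- dim(sl$data)[3]; nv <- dim(sl$data)[2]
  su <- (seq_len(nu) - 1 - (nu - 1) / 2) * pl$pixel_size_um
  sv <- (seq_len(nv) - 1 - (nv - 1) / 2) * pl$pixel_size_um
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    pt <- pl$origin_um + su[i] * pl$basis_u + sv[j] * pl$basis_v
    expected <- coef[1] + sum(coef[2:4] * pt)
    expect_equal(sl$data[1, j, i], expected, tolerance = 1e-6)
  }
})

test_that("a 90-degree plane equals the permuted native yz-slice", {
  set.seed(7)
  dims <- c(10, 10, 10)
  arr <- array(runif(prod(dims)), c(1, dims))
  v <- volume_image(arr, c(0.5, 0.5, 0.5), c(fiber = 1L))
  k <- 4L  # 0-based x index
  pl <- reslice_plane(
    origin_um = c(k * 0.5, (dims[2] - 1) / 2 * 0.5, (dims[1] - 1) / 2 * 0.5),
    normal_um = c(1, 0, 0),
    extent_um = c((dims[2] - 1) * 0.5, (dims[1] - 1) * 0.5),
    pixel_size_um = 0.5,
    basis_u = c(0, 1, 0), basis_v = c(0, 0, 1))
  sl <- reslice_volume(v, pl)
  native <- t(matrix(arr[1, , , k + 1L], dims[1], dims[2]))  # (y, z) -> rows z
  expect_equal(matrix(sl$data[1, , ], dim(sl$data)[2], dim(sl$data)[3]),
               t(native), tolerance = 0)
})

test_that("a plane outside the volume is an error", {
  v <- make_affine_volume()
  pl <- reslice_plane(c(500, 500, 500), c(0, 0, 1), c(3, 3), 0.5)
  expect_error(reslice_volume(v, pl), "outside")
})

test_that("plane constructor enforces orthonormality", {
  expect_error(reslice_plane(c(0, 0, 0), c(0, 0, 1), c(3, 3), 0.5,
                             basis_u = c(1, 0, 0), basis_v = c(1, 1, 0) / sqrt(2)),
               "orthonormal")
  pl <- reslice_plane(c(0, 0, 0), c(1, 2, 3), c(3, 3), 0.5)
  m <- rbind(pl$normal_um, pl$basis_u, pl$basis_v)
  expect_equal(m %*% t(m), diag(3), tolerance = 1e-9)
})

test_that("fibre axes are recovered by the structure tensor", {
  # untilted fibres: axis = (1, 0, 0) within 1 degree
  ph0 <- generate_muscle_phantom(clean_muscle_spec(n_fibers = 1, seed = 2,
                                                   axis_tilt_deg = 0))
  f0 <- ph0$truth$fibers
  ax0 <- estimate_fiber_axis(ph0$volume,
    dcalms:::roi_around(ph0$volume,
      c(f0$centre_x_um, f0$centre_y_um, f0$centre_z_um), 15))
  expect_lt(acos(min(1, abs(ax0[1]))) * 180 / pi, 1)

  # tilted fibres: recovered within 2 degrees of the generator truth
  ph <- generate_muscle_phantom(clean_muscle_spec(n_fibers = 3, seed = 8,
                                                  axis_tilt_deg = 10))
  for (k in seq_len(3)) {
    f <- ph$truth$fibers[k, ]
    ax <- estimate_fiber_axis(ph$volume,
      dcalms:::roi_around(ph$volume,
        c(f$centre_x_um, f$centre_y_um, f$centre_z_um), 15))
    truth <- c(f$axis_x, f$axis_y, f$axis_z)
    ang <- acos(min(1, abs(sum(ax * truth)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("uniform ROIs give a degenerate-tensor error", {
  v <- volume_image(array(0.5, c(1, 8, 16, 16)), c(0.5, 0.5, 1),
                    c(fiber = 1L))
  expect_error(estimate_fiber_axis(v), "uniform")
})

test_that("perpendicular and oblique cylinder sections have analytic areas", {
  ph <- cylinder_phantom(csa = 350)
  f <- ph$truth$fibers
  r <- f$semi_major_um
  ctr <- c(f$centre_x_um, f$centre_y_um, f$centre_z_um)
  for (theta_deg in c(0, 15, 30)) {
    th <- theta_deg * pi / 180
    normal <- c(cos(th), sin(th), 0)  # tilted away from the fibre axis in xy
    pl <- reslice_plane(ctr, normal, c(50, 50), 0.4)
    sl <- reslice_volume(ph$volume, pl)
    area <- threshold_area(sl)
    expected <- pi * r^2 / cos(th)
    band <- ellipse_perimeter(r / cos(th), r) * pl$pixel_size_um
    expect_lt(abs(area - expected), band)
  }
})
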