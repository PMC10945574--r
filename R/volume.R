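#' Calibrated multichannel 3-D volume
#'
#' `volume_image()` is the canonical in-memory container for confocal
#' z-stacks throughout the package. Data are stored in a fixed axis order
#' `(channel, z, y, x)`; voxel sizes are physical micrometres per voxel along
#' `(x, y, z)`. World coordinates are voxel-centre positions in micrometres,
#' with voxel `(0, 0, 0)` at the origin (0-based voxel indexing).
#'
#' @param data numeric 4-D array ordered `(channel, z, y, x)` with
#'   non-negative intensities.
#' @param voxel_size_um positive numeric length-3 vector, micrometres per
#'   voxel along `(x, y, z)`.
#' @param channel_roles named integer vector mapping channel roles (e.g.
#'   `fiber`, `btx`, `gfp`, `chat`, `bIII`) to 1-based channel indices.
#'
#' @return An object of class `volume_image`: a list with elements `data`,
#'   `voxel_size_um` and `channel_roles`.
#' @examples
#' a <- array(0, c(1, 4, 8, 8))
#' v <- volume_image(a, c(0.3, 0.3, 1), c(fiber = 1))
#' dim(get_channel(v, "fiber"))
#' @export
volume_image <- function(data, voxel_size_um, channel_roles = integer()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("'data' must be a 4-D array ordered (channel, z, y, x)")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L) stopf("'voxel_size_um' must have length 3 (x, y, z)")
  check_positive(voxel_size_um, "voxel_size_um")
  nc <- dim(data)[1]
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (length(roles)) {
    if (is.null(names(roles)) || any(!nzchar(names(roles))))
      stopf("'channel_roles' must be a named vector")
    if (any(roles < 1L) || any(roles > nc))
      stopf("channel role indices must lie in 1..%d (volume has %d channel(s))", nc, nc)
    if (anyDuplicated(roles)) stopf("channel role indices must be distinct")
  }
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 channel_roles = roles),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d channel(s), z=%d y=%d x=%d voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (x,y,z): %s um\n",
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  if (length(x$channel_roles))
    cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                  x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a volume as a 3-D array
#'
#' @param vol a [volume_image()].
#' @param role role name present in `vol$channel_roles`, or an integer
#'   channel index.
#' @return 3-D numeric array ordered `(z, y, x)`.
#' @export
get_channel <- function(vol, role) {
  stopifnot(inherits(vol, "volume_image"))
  i <- if (is.character(role)) {
    if (!role %in% names(vol$channel_roles))
      stopf("volume has no channel with role '%s'", role)
    vol$channel_roles[[role]]
  } else as.integer(role)
  d <- dim(vol$data)
  array(vol$data[i, , , ], d[2:4])
}

# World extent of the volume: voxel centres span [0, (n-1)*voxel_size].
volume_extent_um <- function(vol) {
  d <- dim(vol$data)
  c(x = (d[4] - 1) * vol$voxel_size_um[1],
    y = (d[3] - 1) * vol$voxel_size_um[2],
    z = (d[2] - 1) * vol$voxel_size_um[3])
}

#' Calibrated multichannel 2-D image
#'
#' Container for planar images: virtual transverse slices produced by
#' [reslice_volume()] and nerve cross-sections. Pixels sampled outside the
#' source volume are `NA` ("missing", never zero-filled) and are excluded
#' from all downstream area measurements.
#'
#' @param data numeric 3-D array ordered `(channel, row, column)`.
#' @param pixel_size_um positive scalar, micrometres per pixel (square
#'   pixels).
#' @param channel_roles named integer vector as in [volume_image()].
#' @param plane optional [reslice_plane()] of origin.
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(data, pixel_size_um, channel_roles = integer(),
                        plane = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array ordered (channel, row, column)")
  check_positive(pixel_size_um, "pixel_size_um")
  nc <- dim(data)[1]
  roles <- as.integer(channel_roles)
  names(roles) <- names(channel_roles)
  if (length(roles) && (any(roles < 1L) || any(roles > nc)))
    stopf("channel role indices out of range")
  structure(list(data = data, pixel_size_um = as.numeric(pixel_size_um),
                 channel_roles = roles, plane = plane),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<plane_image> %d channel(s), %d x %d px @ %.4g um/px (%d missing px)\n",
              d[1], d[2], d[3], x$pixel_size_um,
              sum(is.na(x$data[1, , ]))))
  invisible(x)
}

#' @rdname get_channel
#' @export
get_plane_channel <- function(vol, role) {
  stopifnot(inherits(vol, "plane_image"))
  i <- if (is.character(role)) {
    if (!role %in% names(vol$channel_roles))
      stopf("image has no channel with role '%s'", role)
    vol$channel_roles[[role]]
  } else as.integer(role)
  d <- dim(vol$data)
  matrix(vol$data[i, , ], d[2], d[3])
}
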