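#' Write a calibrated volume to TIFF
#'
#' Pages are written z-major with channels interleaved fastest (page
#' `(z-1)*nc + c`), as 16-bit TIFF (the native confocal bit depth).
#' Calibration, axis order and channel roles are recorded in a JSON metadata
#' sidecar at `<path>.meta.json`; [read_volume()] restores them. Intensities
#' must lie in `[0, 1]` (the normalized detector range); values produced by
#' the phantom generators are already quantized to the 16-bit grid so the
#' round trip is bit-identical.
#'
#' @param vol a [volume_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$data)
  if (anyNA(vol$data) || min(vol$data) < 0 || max(vol$data) > 1)
    stopf("volume intensities must lie in [0, 1] for float TIFF storage")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (z in seq_len(d[2])) {
    for (ch in seq_len(d[1])) {
      pages[[k]] <- matrix(vol$data[ch, z, , ], d[3], d[4])
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(
    axes = "CZYX", n_channels = d[1], n_z = d[2], n_y = d[3], n_x = d[4],
    page_order = "z-major, channel fastest",
    voxel_size_um = list(x = vol$voxel_size_um[1], y = vol$voxel_size_um[2],
                         z = vol$voxel_size_um[3]),
    channel_roles = as.list(vol$channel_roles))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibrated volume from TIFF
#'
#' Calibration is taken from the `<path>.meta.json` sidecar written by
#' [write_volume()] when present, otherwise from the explicit
#' `voxel_size_um` override. A file with neither is an error: voxel size is
#' never silently assumed.
#'
#' @param path TIFF path.
#' @param role_map named integer vector mapping roles to channel indices;
#'   defaults to the roles stored in the sidecar.
#' @param voxel_size_um explicit `(x, y, z)` calibration override in
#'   micrometres, required when no sidecar exists.
#' @param n_channels number of interleaved channels when no sidecar exists
#'   (default 1).
#' @return a [volume_image()].
#' @export
read_volume <- function(path, role_map = NULL, voxel_size_um = NULL,
                        n_channels = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (!is.null(meta)) {
    nc <- meta$n_channels
    vs <- c(meta$voxel_size_um$x, meta$voxel_size_um$y, meta$voxel_size_um$z)
    if (!is.null(voxel_size_um)) vs <- as.numeric(voxel_size_um)
    roles <- unlist(meta$channel_roles)
  } else {
    if (is.null(voxel_size_um))
      stopf(paste("no calibration metadata found for '%s';",
                  "pass voxel_size_um explicitly"), path)
    nc <- n_channels %||% 1L
    vs <- as.numeric(voxel_size_um)
    roles <- integer()
  }
  if (np %% nc != 0L)
    stopf("%d TIFF pages are not divisible by %d channels", np, nc)
  nz <- np %/% nc
  pd <- dim(pages[[1]])
  # pages may carry an alpha/extra sample dimension; keep greyscale plane 1
  getp <- function(p) if (length(dim(p)) == 3L) p[, , 1] else p
  arr <- array(0, c(nc, nz, pd[1], pd[2]))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      arr[ch, z, , ] <- getp(pages[[k]])
      k <- k + 1L
    }
  }
  if (!is.null(role_map)) roles <- role_map
  if (length(roles) && (any(roles < 1L) || any(roles > nc)))
    stopf("role map requests channel(s) %s but file has %d channel(s)",
          paste(roles[roles < 1L | roles > nc], collapse = ", "), nc)
  volume_image(arr, vs, roles)
}

#' Write a record table to CSV
#'
#' Plain UTF-8 CSV with a header row, `.` decimal separator and a stable
#' column order. Non-finite values in measurement columns (any column whose
#' name ends in `_um2`, `_um3`, `_um` or `_g`) are rejected rather than
#' written.
#'
#' @param records data frame of records (may have zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stopf("'records' must be a data frame")
  meas <- grep("(_um2|_um3|_um|_g)$", names(records), value = TRUE)
  for (col in meas) {
    v <- records[[col]]
    if (is.numeric(v) && any(!is.finite(v)))
      stopf("non-finite values in measurement column '%s'", col)
  }
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
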