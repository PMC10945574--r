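# Fibre segmentation and CSA measurement on virtual transverse slices.
# CSA is always pixel count x pixel_size^2; regions touching missing-data
# pixels or the image border are flagged `clipped` (their area is only a
# lower bound) and excluded from group statistics by default.

#' Segment muscle fibres on a transverse slice
#'
#' Two modes mirroring a semi-automated workflow:
#'
#' * **seeded** (`seeds` given): marker-controlled region growing
#'   ([EBImage::propagate()]) on the inverted smoothed fibre channel within
#'   the Otsu foreground mask, one region per seed;
#' * **automated** (`seeds = NULL`): Otsu foreground, then watershed of the
#'   distance transform ([EBImage::watershed()]), which splits touching
#'   fibres at distance-map ridges.
#'
#' Both modes are deterministic. Regions smaller than `min_size_px` are
#' suppressed as noise specks. Missing-data (`NA`) pixels never contribute
#' foreground; labels touching them or the image border are reported as
#' clipped.
#'
#' @param slice a [plane_image()] (or plain matrix) holding the fibre
#'   channel.
#' @param seeds optional integer matrix with columns `row`, `col` (pixel
#'   coordinates) of one seed per fibre.
#' @param channel channel role or index of the fibre signal.
#' @param sigma_px Gaussian pre-smoothing in pixels.
#' @param min_size_px minimum region size kept.
#' @param tolerance,ext watershed parameters passed to
#'   [EBImage::watershed()].
#' @return An object of class `fiber_labels`: list with `labels` (integer
#'   matrix), `pixel_size_um`, `clipped_ids`, and `status` (`"ok"` or
#'   `"empty"`).
#' @export
segment_fibers <- function(slice, seeds = NULL, channel = "fiber",
                           sigma_px = 1, min_size_px = 20,
                           tolerance = 1, ext = 1) {
  if (is.matrix(slice)) {
    img <- slice
    ps <- attr(slice, "pixel_size_um") %||% 1
  } else {
    stopifnot(inherits(slice, "plane_image"))
    img <- if (length(slice$channel_roles)) get_plane_channel(slice, channel)
           else matrix(slice$data[1, , ], dim(slice$data)[2], dim(slice$data)[3])
    ps <- slice$pixel_size_um
  }
  na_mask <- is.na(img)
  img[na_mask] <- 0
  sm <- if (sigma_px > 0) gauss_smooth(img, c(sigma_px, sigma_px)) else img
  rng <- range(sm)
  empty <- structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          pixel_size_um = ps, clipped_ids = integer(),
                          status = "empty"), class = "fiber_labels")
  if (diff(rng) <= 0) {
    warnf("no foreground signal on slice; returning empty labelling")
    return(empty)
  }
  th <- otsu_threshold(sm)
  fg <- sm > th & !na_mask
  if (!any(fg)) {
    warnf("no foreground after thresholding; returning empty labelling")
    return(empty)
  }
  if (is.null(seeds)) {
    dm <- EBImage::distmap(EBImage::Image(fg * 1))
    lab <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
    labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  } else {
    seeds <- as.matrix(seeds)
    seed_img <- matrix(0L, nrow(img), ncol(img))
    for (k in seq_len(nrow(seeds)))
      seed_img[seeds[k, 1], seeds[k, 2]] <- k
    inv <- max(sm) - sm
    lab <- EBImage::propagate(EBImage::Image(inv), EBImage::Image(seed_img),
                              mask = EBImage::Image(fg * 1))
    labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  }
  cnt <- tabulate(labels[labels > 0L])
  small <- which(cnt > 0L & cnt < min_size_px)
  if (length(small)) labels[labels %in% small] <- 0L
  clipped <- clipped_labels(labels, na_mask)
  structure(list(labels = labels, pixel_size_um = ps,
                 clipped_ids = clipped, status = "ok"),
            class = "fiber_labels")
}

# Labels touching the image border or a missing-data pixel (4-neighbourhood).
clipped_labels <- function(labels, na_mask) {
  nr <- nrow(labels); nc <- ncol(labels)
  ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  if (any(na_mask)) {
    shift <- function(m, dr, dc) {
      out <- matrix(FALSE, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    near_na <- na_mask | shift(na_mask, 1, 0) | shift(na_mask, -1, 0) |
      shift(na_mask, 0, 1) | shift(na_mask, 0, -1)
    ids <- unique(c(ids, labels[near_na]))
  }
  sort(setdiff(ids, 0L))
}

#' Compute per-fibre cross-sectional areas from a labelled slice
#'
#' `csa_um2 = pixel count * pixel_size_um^2`. Clipped regions are retained
#' in the table with `clipped = TRUE`; [summarize_csa_by_class()] excludes
#' them from statistics by default.
#'
#' @param labels a `fiber_labels` object from [segment_fibers()], or an
#'   integer label matrix (then `pixel_size_um` is required).
#' @param pixel_size_um calibration override, um/px.
#' @return data frame with columns `fiber_id`, `csa_um2`, `centroid_u_um`,
#'   `centroid_v_um`, `n_px`, `clipped`.
#' @examples
#' m <- matrix(0L, 20, 20); m[5:14, 5:14] <- 1L
#' compute_csa(m, pixel_size_um = 0.5)  # 100 px -> 25 um^2
#' @export
compute_csa <- function(labels, pixel_size_um = NULL) {
  if (inherits(labels, "fiber_labels")) {
    ps <- pixel_size_um %||% labels$pixel_size_um
    clipped_ids <- labels$clipped_ids
    labels <- labels$labels
  } else {
    ps <- pixel_size_um
    clipped_ids <- integer()
  }
  if (is.null(ps)) stopf("pixel_size_um calibration is required")
  check_positive(ps, "pixel_size_um")
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(ids))
    return(data.frame(fiber_id = integer(), csa_um2 = numeric(),
                      centroid_u_um = numeric(), centroid_v_um = numeric(),
                      n_px = integer(), clipped = logical()))
  rows <- row(labels); cols <- col(labels)
  out <- lapply(ids, function(id) {
    sel <- labels == id
    n <- sum(sel)
    data.frame(fiber_id = id, csa_um2 = n * ps^2,
               centroid_u_um = (mean(cols[sel]) - 1) * ps,
               centroid_v_um = (mean(rows[sel]) - 1) * ps,
               n_px = n, clipped = id %in% clipped_ids)
  })
  do.call(rbind, out)
}

#' Summarize fibre CSA by innervation class
#'
#' Mean, SEM (sample SD / sqrt(n)) and n per class. Classes with `n < 2`
#' report `NA` SEM. Clipped fibres are excluded by default because their
#' measured area is only a lower bound.
#'
#' @param records data frame with at least `csa_um2` and
#'   `innervation_class` (and optionally `clipped`).
#' @param exclude_clipped drop clipped fibres before summarizing.
#' @return data frame with columns `innervation_class`, `mean_csa_um2`,
#'   `sem_csa_um2`, `n`.
#' @export
summarize_csa_by_class <- function(records, exclude_clipped = TRUE) {
  if (!nrow(records))
    return(data.frame(innervation_class = character(),
                      mean_csa_um2 = numeric(), sem_csa_um2 = numeric(),
                      n = integer()))
  if (!"innervation_class" %in% names(records))
    stopf("records must carry an 'innervation_class' column")
  if (exclude_clipped && "clipped" %in% names(records))
    records <- records[!records$clipped, , drop = FALSE]
  sp <- split(records$csa_um2, records$innervation_class)
  out <- lapply(names(sp), function(cl) {
    ms <- mean_sem(sp[[cl]])
    data.frame(innervation_class = cl, mean_csa_um2 = ms$mean,
               sem_csa_um2 = ms$sem, n = ms$n)
  })
  do.call(rbind, out)
}

#' Measure one fibre's CSA by local axis estimation and transverse reslicing
#'
#' The per-fibre measurement at the heart of the digital-reslicing workflow:
#' estimate the local fibre axis around a seed point (structure tensor),
#' extract the plane perpendicular to that axis through the point, segment
#' the slice, take the region containing the plane centre, and convert its
#' pixel count to um^2. With `mode = "cos-correction"` the slice is instead
#' taken in the fixed section plane (normal x) and the area multiplied by
#' the cosine of the local tilt.
#'
#' @param vol a [volume_image()] with a `fiber` channel.
#' @param point_um seed point on the fibre, `(x, y, z)` um.
#' @param axis `"auto"` (structure tensor) or an explicit 3-vector.
#' @param mode `"axis-perpendicular"` (canonical) or `"cos-correction"`.
#' @param roi_half_um half-size of the axis-estimation ROI, um.
#' @param extent_um reslice window edge length, um.
#' @param pixel_size_um reslice sampling pitch; defaults to the xy voxel
#'   size.
#' @param ... passed to [segment_fibers()].
#' @return one-row data frame: `csa_um2`, `n_px`, `clipped`, `axis_x/y/z`,
#'   `tilt_deg`, `status`.
#' @export
measure_fiber_csa <- function(vol, point_um, axis = "auto",
                              mode = c("axis-perpendicular", "cos-correction"),
                              roi_half_um = 15, extent_um = 60,
                              pixel_size_um = NULL, ...) {
  mode <- match.arg(mode)
  ps <- pixel_size_um %||% min(vol$voxel_size_um[1:2])
  ax <- if (identical(axis, "auto"))
    estimate_fiber_axis(vol, roi = roi_around(vol, point_um, roi_half_um))
  else normalize3(as.numeric(axis))
  tilt <- acos(min(1, abs(ax[1]))) * 180 / pi
  normal <- if (mode == "axis-perpendicular") ax else c(1, 0, 0)
  pl <- reslice_plane(point_um, normal, extent_um, ps)
  sl <- reslice_volume(vol, pl)
  seg <- segment_fibers(sl, ...)
  fail <- data.frame(csa_um2 = NA_real_, n_px = 0L, clipped = NA,
                     axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
                     tilt_deg = tilt, status = "no-fiber-at-point")
  if (seg$status == "empty") return(fail)
  ctr <- c(round((nrow(seg$labels) + 1) / 2), round((ncol(seg$labels) + 1) / 2))
  id <- seg$labels[ctr[1], ctr[2]]
  if (id == 0L) {  # search a small neighbourhood around the seed
    r <- max(1L, ceiling(2 / ps))
    win <- seg$labels[max(1, ctr[1] - r):min(nrow(seg$labels), ctr[1] + r),
                      max(1, ctr[2] - r):min(ncol(seg$labels), ctr[2] + r)]
    cand <- setdiff(unique(as.vector(win)), 0L)
    if (!length(cand)) return(fail)
    id <- cand[which.max(tabulate(match(win, cand)))]
  }
  n <- sum(seg$labels == id)
  csa <- n * ps^2
  if (mode == "cos-correction") csa <- csa * cos(tilt * pi / 180)
  data.frame(csa_um2 = csa, n_px = n, clipped = id %in% seg$clipped_ids,
             axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
             tilt_deg = tilt, status = "ok")
}

#' Run the digital-reslicing CSA workflow over a set of seed points
#'
#' Applies [measure_fiber_csa()] at each seed point (one per fibre, e.g.
#' user-placed clicks in the semi-automated workflow) and assembles a fibre
#' record table.
#'
#' @param vol a [volume_image()].
#' @param points_um numeric matrix, one row `(x, y, z)` per fibre.
#' @param ... passed to [measure_fiber_csa()].
#' @return data frame with one row per seed point (`point_id`, measurement
#'   columns as in [measure_fiber_csa()]).
#' @export
dcalms_run <- function(vol, points_um, ...) {
  points_um <- as.matrix(points_um)
  out <- lapply(seq_len(nrow(points_um)), function(i) {
    rec <- measure_fiber_csa(vol, points_um[i, ], ...)
    cbind(point_id = i, rec)
  })
  do.call(rbind, out)
}
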