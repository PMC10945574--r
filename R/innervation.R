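# Endplate detection, GFP/ChAT colocalization scoring, and fibre-class
# assignment. An endplate is "innervated by the graft" when a sufficient
# fraction of its voxels carry GFP signal; ChAT-only overlap marks
# endogenous innervation; neither marks a denervated endplate.

#' Default colocalization thresholds for endplate classification
#'
#' `t_full` is the minimum GFP overlap fraction of a fully innervated
#' junction; `t_min` is the minimum overlap counted as innervation at all.
#' The category taxonomy shows full/partial graft innervation, endogenous
#' (GFP-negative, ChAT-positive) innervation and denervated endplates; the
#' cut-offs themselves are tunable analysis parameters.
#'
#' @param t_full full-innervation GFP overlap threshold (default 0.5).
#' @param t_min minimal overlap counted as innervation (default 0.05).
#' @return list with elements `t_full`, `t_min`.
#' @export
innervation_thresholds <- function(t_full = 0.5, t_min = 0.05) {
  check_fraction(t_full, "t_full"); check_fraction(t_min, "t_min")
  if (t_min >= t_full) stopf("t_min (%.3g) must be < t_full (%.3g)", t_min, t_full)
  list(t_full = t_full, t_min = t_min)
}

#' Detect alpha-BTx endplates in a volume
#'
#' Gaussian-smoothed BTx channel, global Otsu threshold, 3-D connected
#' components (26-connectivity), volume filter. For each component the GFP
#' and ChAT overlap fractions are computed: a voxel is channel-positive when
#' its intensity exceeds a per-endplate local Otsu threshold over the
#' endplate's padded bounding box (robust to shading); an endplate whose
#' neighbourhood carries no appreciable signal in a channel scores 0.
#' Two endplates closer than the blur scale merge into one component; this
#' is inherent to intensity-based detection and documented behaviour.
#'
#' @param vol a [volume_image()] with `btx` (and optionally `gfp`, `chat`)
#'   channels.
#' @param sigma_um smoothing sigma, um.
#' @param min_volume_um3,max_volume_um3 size filter on component volume.
#' @param thresholds an [innervation_thresholds()] list.
#' @param min_signal minimum dynamic range (neighbourhood maximum minus
#'   median, on the denoised channel) below which a channel is considered
#'   absent around an endplate; guards the local Otsu from splitting pure
#'   noise into spurious "positive" voxels.
#' @return data frame (`endplate_record`s): `endplate_id`, centroid
#'   `x/y/z_um`, `volume_um3`, `gfp_overlap`, `chat_overlap`, `category`.
#' @export
detect_endplates <- function(vol, sigma_um = 0.5,
                             min_volume_um3 = 20, max_volume_um3 = 5000,
                             thresholds = innervation_thresholds(),
                             min_signal = 0.2) {
  stopifnot(inherits(vol, "volume_image"))
  btx <- get_channel(vol, "btx")
  vs <- vol$voxel_size_um
  empty <- data.frame(endplate_id = integer(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      volume_um3 = numeric(), gfp_overlap = numeric(),
                      chat_overlap = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  if (max(btx) <= 0) return(empty)
  sm <- if (sigma_um > 0) gauss_smooth(btx, sigma_um / c(vs[3], vs[2], vs[1])) else btx
  th <- otsu_threshold(sm)
  mask <- sm > th
  if (!any(mask)) return(empty)
  lab <- label_components_3d(mask)
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  voxvol <- prod(vs)
  has_gfp <- "gfp" %in% names(vol$channel_roles)
  has_chat <- "chat" %in% names(vol$channel_roles)
  # colocalization is scored on denoised channels: thresholding raw noise
  # would manufacture spurious overlap at low SNR
  smooth_ch <- function(role) {
    x <- get_channel(vol, role)
    if (sigma_um > 0) gauss_smooth(x, sigma_um / c(vs[3], vs[2], vs[1])) else x
  }
  gfp <- if (has_gfp) smooth_ch("gfp") else NULL
  chat <- if (has_chat) smooth_ch("chat") else NULL
  d <- dim(btx)
  rows <- list(); kept <- 0L
  for (id in ids) {
    sel <- which(lab == id)
    nvox <- length(sel)
    v_um3 <- nvox * voxvol
    if (v_um3 < min_volume_um3 || v_um3 > max_volume_um3) next
    co <- arrayInd(sel, d)  # z, y, x
    kept <- kept + 1L
    pad <- 3L
    rz <- c(max(1L, min(co[, 1]) - pad), min(d[1], max(co[, 1]) + pad))
    ry <- c(max(1L, min(co[, 2]) - pad), min(d[2], max(co[, 2]) + pad))
    rx <- c(max(1L, min(co[, 3]) - pad), min(d[3], max(co[, 3]) + pad))
    overlap <- function(chn) {
      if (is.null(chn)) return(0)
      neigh <- chn[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2]]
      if (max(neigh) - stats::median(neigh) < min_signal) return(0)
      thc <- otsu_threshold(neigh)
      mean(chn[sel] > thc)
    }
    rows[[kept]] <- data.frame(
      endplate_id = kept,
      x_um = (mean(co[, 3]) - 1) * vs[1],
      y_um = (mean(co[, 2]) - 1) * vs[2],
      z_um = (mean(co[, 1]) - 1) * vs[3],
      volume_um3 = v_um3,
      gfp_overlap = overlap(gfp),
      chat_overlap = overlap(chat),
      stringsAsFactors = FALSE)
  }
  if (!kept) return(empty)
  out <- do.call(rbind, rows)
  out$category <- classify_endplate(out$gfp_overlap, out$chat_overlap,
                                    thresholds)
  out
}

#' Classify an endplate from its colocalization overlaps
#'
#' Category rules (vectorized):
#' * `graft_full` if `gfp_overlap >= t_full`;
#' * `graft_partial` if `t_min <= gfp_overlap < t_full`;
#' * `endogenous` if `gfp_overlap < t_min` and `chat_overlap >= t_min`;
#' * `denervated` otherwise.
#'
#' @param gfp_overlap,chat_overlap overlap fractions in `[0, 1]`.
#' @param thresholds an [innervation_thresholds()] list.
#' @return character vector of categories.
#' @examples
#' classify_endplate(c(0.9, 0, 0), c(0, 0.7, 0))
#' @export
classify_endplate <- function(gfp_overlap, chat_overlap,
                              thresholds = innervation_thresholds()) {
  check_fraction(gfp_overlap, "gfp_overlap")
  check_fraction(chat_overlap, "chat_overlap")
  ifelse(gfp_overlap >= thresholds$t_full, "graft_full",
    ifelse(gfp_overlap >= thresholds$t_min, "graft_partial",
      ifelse(chat_overlap >= thresholds$t_min, "endogenous", "denervated")))
}

#' Innervated-endplate percentage
#'
#' `100 * n_innervated / n_total`, reported to one decimal place; the
#' convention for "innervated" in graft-reinnervation counts is
#' `graft_full + graft_partial` (endplates showing any YFP/GFP
#' colocalization).
#'
#' @param n_innervated,n_total non-negative counts, `n_total > 0`.
#' @return percentage rounded to 1 decimal.
#' @examples
#' innervation_fraction(364, 3482)  # 10.5
#' @export
innervation_fraction <- function(n_innervated, n_total) {
  if (n_total <= 0) stopf("n_total must be > 0")
  if (n_innervated < 0 || n_innervated > n_total)
    stopf("need 0 <= n_innervated <= n_total")
  round(100 * n_innervated / n_total, 1)
}

#' Assign innervation classes to fibres from their endplates
#'
#' Each endplate is attached to the fibre whose label region contains its
#' centroid (searching up to `max_dist_um` around the centroid when it falls
#' between labels, e.g. on the fibre surface). A fibre's class is derived
#' from its endplates with precedence `graft > endogenous > denervated`
#' when several disagree (a fibre carrying both a graft-innervated and a
#' denervated endplate is a graft-innervated fibre); fibres with no endplate
#' in the volume are `unconfirmed`.
#'
#' @param labels integer `(z, y, x)` fibre label volume.
#' @param endplates data frame from [detect_endplates()] (needs centroid
#'   columns and `category`).
#' @param voxel_size_um `(x, y, z)` calibration of `labels`, um.
#' @param max_dist_um centroid-to-fibre search radius.
#' @return list with `fibers` (data frame `fiber_id`,
#'   `innervation_class`, `n_endplates`) and `endplates` (input with a
#'   `fiber_id` column added).
#' @export
assign_fibers <- function(labels, endplates, voxel_size_um,
                          max_dist_um = 6) {
  d <- dim(labels)
  vs <- as.numeric(voxel_size_um)
  ep <- endplates
  ep$fiber_id <- rep(NA_integer_, nrow(ep))
  for (k in seq_len(nrow(ep))) {
    ctr <- c(ep$x_um[k], ep$y_um[k], ep$z_um[k])
    iv <- pmin(pmax(round(ctr / vs) + 1L, 1L), c(d[3], d[2], d[1]))
    id <- labels[iv[3], iv[2], iv[1]]
    if (id == 0L) {
      h <- ceiling(max_dist_um / vs)
      rx <- max(1L, iv[1] - h[1]):min(d[3], iv[1] + h[1])
      ry <- max(1L, iv[2] - h[2]):min(d[2], iv[2] + h[2])
      rz <- max(1L, iv[3] - h[3]):min(d[1], iv[3] + h[3])
      sub <- labels[rz, ry, rx, drop = FALSE]
      nz <- which(sub > 0L)
      if (length(nz)) {
        co <- arrayInd(nz, dim(sub))
        dx <- (rx[co[, 3]] - 1) * vs[1] - ctr[1]
        dy <- (ry[co[, 2]] - 1) * vs[2] - ctr[2]
        dz <- (rz[co[, 1]] - 1) * vs[3] - ctr[3]
        d2 <- dx^2 + dy^2 + dz^2
        if (min(d2) <= max_dist_um^2) id <- sub[nz[which.min(d2)]]
      }
    }
    if (id > 0L) ep$fiber_id[k] <- id
  }
  cls_of <- function(cats) {
    if (any(cats %in% c("graft_full", "graft_partial"))) return("graft")
    if (any(cats == "endogenous")) return("endogenous")
    if (any(cats == "denervated")) return("denervated")
    "unconfirmed"
  }
  all_ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  fib <- data.frame(fiber_id = all_ids,
                    innervation_class = "unconfirmed",
                    n_endplates = 0L, stringsAsFactors = FALSE)
  if (nrow(ep)) {
    sp <- split(ep$category, ep$fiber_id)
    for (fid in names(sp)) {
      i <- match(as.integer(fid), fib$fiber_id)
      if (is.na(i)) next
      fib$innervation_class[i] <- cls_of(sp[[fid]])
      fib$n_endplates[i] <- length(sp[[fid]])
    }
  }
  list(fibers = fib, endplates = ep)
}
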