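# Nerve cross-section analysis: axon segmentation, per-axon CSA, binned
# size distributions, and the two-factor group comparison used to contrast
# genotype/treatment groups across the calibre spectrum.

#' Segment axons on a calibrated nerve cross-section
#'
#' Smoothed-Otsu foreground, watershed of the distance transform to split
#' touching axons, and a size filter in um^2. CSA is pixel count times
#' pixel area, consistent with the fibre-CSA definition used elsewhere in
#' the package.
#'
#' @param image a [plane_image()] or a plain matrix (then `pixel_size_um`
#'   must be supplied via attribute or argument).
#' @param channel channel role (`"bIII"` or `"chat"`) or index.
#' @param sigma_px Gaussian pre-smoothing, px.
#' @param min_area_um2,max_area_um2 size filter on axon area.
#' @param pixel_size_um calibration override, um/px.
#' @param tolerance,ext watershed parameters.
#' @return An object of class `fiber_labels` (label matrix + calibration),
#'   reusable with [compute_csa()].
#' @export
segment_axons <- function(image, channel = "bIII", sigma_px = 1,
                          min_area_um2 = 0.5, max_area_um2 = Inf,
                          pixel_size_um = NULL, tolerance = 1, ext = 1) {
  if (is.matrix(image)) {
    img <- image
    ps <- pixel_size_um %||% attr(image, "pixel_size_um") %||%
      stopf("pixel_size_um calibration is required")
  } else {
    stopifnot(inherits(image, "plane_image"))
    img <- get_plane_channel(image, channel)
    ps <- pixel_size_um %||% image$pixel_size_um
  }
  min_px <- max(1L, floor(min_area_um2 / ps^2))
  seg <- segment_fibers(img |> `attr<-`("pixel_size_um", ps), seeds = NULL,
                        sigma_px = sigma_px, min_size_px = min_px,
                        tolerance = tolerance, ext = ext)
  if (is.finite(max_area_um2) && seg$status == "ok") {
    cnt <- tabulate(seg$labels[seg$labels > 0L])
    big <- which(cnt > max_area_um2 / ps^2)
    if (length(big)) seg$labels[seg$labels %in% big] <- 0L
  }
  seg
}

#' Build an axon table from a two-channel nerve image
#'
#' Segments the total-axon (`bIII`) channel and marks an axon as motor when
#' at least `motor_overlap` of its pixels are ChAT-positive (Otsu threshold
#' on the ChAT channel). Guarantees the motor subset is contained in the
#' total set.
#'
#' @param image a two-channel [plane_image()] with roles `bIII` and `chat`.
#' @param motor_overlap minimum ChAT-positive pixel fraction.
#' @param ... passed to [segment_axons()].
#' @return data frame: `axon_id`, `csa_um2`, `centroid_u_um`,
#'   `centroid_v_um`, `is_motor`.
#' @export
measure_axons <- function(image, motor_overlap = 0.5, ...) {
  stopifnot(inherits(image, "plane_image"))
  seg <- segment_axons(image, channel = "bIII", ...)
  tab <- compute_csa(seg)
  names(tab)[names(tab) == "fiber_id"] <- "axon_id"
  tab$clipped <- NULL
  if (!nrow(tab)) {
    tab$is_motor <- logical(0)
    return(tab)
  }
  chat <- get_plane_channel(image, "chat")
  chat[is.na(chat)] <- 0
  pos <- if (max(chat) > 0) chat > otsu_threshold(chat) else
    matrix(FALSE, nrow(chat), ncol(chat))
  tab$is_motor <- vapply(tab$axon_id, function(id)
    mean(pos[seg$labels == id]) >= motor_overlap, logical(1))
  tab
}

#' Bin axon calibres into a size distribution
#'
#' Right-open bins `[e_i, e_{i+1})`; values outside the edges are counted in
#' reported overflow bins, so counts always conserve the table size. When
#' `section` is given, per-section counts are retained for group statistics.
#'
#' @param table axon table with `csa_um2` (and `is_motor` for
#'   `subset = "motor"`).
#' @param bin_edges strictly increasing numeric vector; default 20
#'   equal-width bins over the 1st-99th percentile of the subset.
#' @param subset `"total"` or `"motor"`.
#' @param group group label carried into comparisons (genotype x treatment).
#' @param section optional per-row section identifier (column name or
#'   vector).
#' @return An object of class `size_distribution`: list with `bin_edges_um2`,
#'   `counts`, `underflow`, `overflow`, `group`, `n_sections`,
#'   `counts_by_section` (sections x bins matrix or `NULL`).
#' @export
build_size_distribution <- function(table, bin_edges = NULL,
                                    subset = c("total", "motor"),
                                    group = "group", section = NULL) {
  subset <- match.arg(subset)
  x <- table
  if (subset == "motor") {
    if (!"is_motor" %in% names(x)) stopf("table has no 'is_motor' column")
    x <- x[x$is_motor, , drop = FALSE]
  }
  sec <- NULL
  if (!is.null(section)) {
    sec <- if (is.character(section) && length(section) == 1L &&
               section %in% names(x)) x[[section]] else section
    if (length(sec) != nrow(x)) stopf("'section' must match the table rows")
  }
  v <- x$csa_um2
  if (is.null(bin_edges)) {
    if (!length(v)) stopf("cannot derive bin edges from an empty table")
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
    if (q[1] >= q[2]) q <- range(v) + c(-0.5, 0.5)
    bin_edges <- seq(q[1], q[2], length.out = 21L)
  }
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stopf("bin_edges must be strictly increasing")
  nb <- length(bin_edges) - 1L
  bin_of <- function(vv) findInterval(vv, bin_edges, left.open = FALSE)
  count_one <- function(vv) {
    idx <- bin_of(vv)
    in_range <- idx >= 1L & idx <= nb & vv < bin_edges[nb + 1L]
    list(counts = tabulate(idx[in_range], nbins = nb),
         under = sum(idx == 0L), over = sum(!in_range & idx != 0L))
  }
  tot <- count_one(v)
  cbs <- NULL; n_sections <- 1L
  if (!is.null(sec)) {
    sp <- split(v, sec)
    n_sections <- length(sp)
    cbs <- t(vapply(sp, function(vv) count_one(vv)$counts, numeric(nb)))
    rownames(cbs) <- names(sp)
  }
  structure(list(bin_edges_um2 = bin_edges, counts = tot$counts,
                 underflow = tot$under, overflow = tot$over,
                 group = group, n_sections = n_sections,
                 counts_by_section = cbs),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> group '%s': %d bins over [%.3g, %.3g] um^2, n = %d (+%d under, +%d over), %d section(s)\n",
              x$group, length(x$counts), min(x$bin_edges_um2),
              max(x$bin_edges_um2), sum(x$counts), x$underflow, x$overflow,
              x$n_sections))
  invisible(x)
}

#' Compare axon size distributions across groups
#'
#' Two-factor ANOVA (factors: group, size bin) on per-section bin counts,
#' with per-bin group comparisons corrected across bins (Sidak) and flagged
#' at the significance cut-points used in the package's star convention.
#' All distributions must share bin edges and carry per-section counts;
#' a single section per group leaves no residual degrees of freedom and is
#' an error.
#'
#' @param groups list of [build_size_distribution()] objects with
#'   per-section counts.
#' @return list of class `distribution_comparison`: `anova` (a
#'   [two_way_anova()] result), `per_bin` (data frame with per-bin p,
#'   Sidak-adjusted p, stars).
#' @export
compare_distributions <- function(groups) {
  if (length(groups) < 2L) stopf("need >= 2 groups")
  if (!all(vapply(groups, inherits, logical(1), "size_distribution")))
    stopf("all groups must be size_distribution objects")
  edges <- groups[[1]]$bin_edges_um2
  for (g in groups[-1])
    if (!isTRUE(all.equal(g$bin_edges_um2, edges)))
      stopf("all groups must share common bin edges")
  if (any(vapply(groups, function(g) is.null(g$counts_by_section), logical(1))))
    stopf("per-section counts are required (build with 'section =')")
  if (any(vapply(groups, function(g) nrow(g$counts_by_section), integer(1)) < 2L))
    stopf("each group needs >= 2 sections for a residual error term")
  nb <- length(edges) - 1L
  long <- do.call(rbind, lapply(groups, function(g) {
    m <- g$counts_by_section
    data.frame(count = as.vector(t(m)),
               group = g$group,
               bin = factor(rep(seq_len(nb), times = nrow(m)),
                            levels = seq_len(nb)),
               section = rep(rownames(m) %||% seq_len(nrow(m)), each = nb),
               stringsAsFactors = FALSE)
  }))
  an <- two_way_anova(long$count, long$group, long$bin,
                      factor_names = c("group", "size_bin"))
  per_bin <- do.call(rbind, lapply(seq_len(nb), function(b) {
    d <- long[long$bin == b, ]
    p <- tryCatch({
      if (length(unique(d$group)) == 2L) {
        stats::t.test(count ~ group, data = d, var.equal = TRUE)$p.value
      } else {
        stats::anova(stats::lm(count ~ group, data = d))[["Pr(>F)"]][1]
      }
    }, error = function(e) NA_real_)
    if (!is.na(p) && !is.finite(p)) p <- NA_real_
    data.frame(bin = b, bin_lo_um2 = edges[b], bin_hi_um2 = edges[b + 1L],
               p = p)
  }))
  per_bin$p_adj <- 1 - (1 - per_bin$p)^nb  # Sidak across bins
  per_bin$stars <- p_stars(per_bin$p_adj)
  per_bin$significant <- !is.na(per_bin$p_adj) & per_bin$p_adj <= 0.05
  structure(list(anova = an, per_bin = per_bin),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  print(x$anova)
  sig <- x$per_bin[x$per_bin$significant, , drop = FALSE]
  cat(sprintf("per-bin comparisons (Sidak over %d bins): %d significant\n",
              nrow(x$per_bin), nrow(sig)))
  invisible(x)
}
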