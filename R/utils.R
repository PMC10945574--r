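# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be finite and > 0", name)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Quantize normalized intensities to the 16-bit storage grid (the native
# confocal bit depth). Written volumes are stored as 16-bit TIFF; quantizing
# generator output up front makes write/read round trips bit-identical.
quantize_uint16 <- function(x) {
  round(x * 65535) / 65535
}

## ---- vector geometry (world coordinates are (x, y, z) in micrometres) ----

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stopf("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- separable Gaussian smoothing for 2-D/3-D arrays ----

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve along one axis of an n-d array with replicate padding.
smooth_axis <- function(arr, axis, kernel) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  dm <- dim(a)
  m <- matrix(a, nrow = dm[1])
  r <- (length(kernel) - 1L) / 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(dm[1], r), , drop = FALSE])
  f <- stats::filter(mp, kernel, sides = 2)
  f <- f[(r + 1L):(r + dm[1]), , drop = FALSE]
  out <- array(as.numeric(f), dm)
  aperm(out, order(perm))
}

# sigma_vox: one sigma per array axis (same order as dim(arr)).
gauss_smooth <- function(arr, sigma_vox) {
  for (ax in seq_along(dim(arr))) {
    if (sigma_vox[ax] > 0)
      arr <- smooth_axis(arr, ax, gauss_kernel(sigma_vox[ax]))
  }
  arr
}

## ---- thresholding ----

# Global Otsu threshold on arbitrary-dimensional data, returned on the
# original intensity scale. EBImage::otsu() thresholds per 2-D frame, so the
# data are flattened to a single frame first.
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  v01 <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(matrix(v01, ncol = 1L), range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

## ---- 3-D connected components (26-connectivity) ----

# Label a logical mask [z, y, x]. Foreground voxels become graph nodes, edges
# connect 26-neighbours, and igraph components give the labelling.
label_components_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stopf("mask must be a 3-D array")
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, d)  # columns: z, y, x
  node <- integer(prod(d))
  node[idx] <- seq_along(idx)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dz != 0 | offs$dy != 0 | offs$dx != 0, ]
  # keep the 13 lexicographically-positive half of the 26 neighbours
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                 (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]
  ef <- integer(0); et <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, 1] + offs$dz[k]; y2 <- co[, 2] + offs$dy[k]; x2 <- co[, 3] + offs$dx[k]
    ok <- z2 >= 1L & z2 <= d[1] & y2 >= 1L & y2 <= d[2] & x2 >= 1L & x2 <= d[3]
    if (!any(ok)) next
    lin2 <- (x2[ok] - 1L) * d[1] * d[2] + (y2[ok] - 1L) * d[1] + z2[ok]
    nb <- node[lin2]
    hit <- nb > 0L
    if (!any(hit)) next
    ef <- c(ef, which(ok)[hit])
    et <- c(et, nb[hit])
  }
  g <- igraph::make_graph(rbind(ef, et), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# mean/SEM star helper lives in stats-report.R
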