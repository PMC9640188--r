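#' Calibrated multi-channel image stack
#'
#' The substrate of every intensity operation in the package: a named list of
#' 3D voxel arrays (dimensions row = y, column = x, slice = z-plane) sharing
#' one spatial calibration. Voxel centers sit at world coordinates
#' \code{x = (col - 0.5) * pixel_size}, \code{y = (row - 0.5) * pixel_size},
#' and true depth \code{z = (plane - 0.5) * z_step * axial_scale} relative to
#' the stack origin, so a point at true depth z lands on continuous plane
#' index \code{z / (axial_scale * z_step) + 0.5}. Downstream multiplication of
#' plane differences by \code{z_step * axial_scale} therefore recovers true
#' axial distances.
#'
#' @param channels named list of numeric 3D arrays with identical dimensions.
#' @param pixel_size_xy in-plane pixel size, um.
#' @param z_step stage z step, um.
#' @param axial_scale true-z per stage-z factor (0.81 for oil objectives on
#'   aqueous samples).
#' @param origin world coordinate (um, length 3: x, y, true z) of the corner of
#'   voxel (row 1, col 1, plane 1); defaults to c(0, 0, 0).
#' @return An object of class \code{"image_stack"}.
#' @export
image_stack <- function(channels, pixel_size_xy, z_step, axial_scale = 0.81,
                        origin = c(0, 0, 0)) {
  if (is.array(channels)) channels <- list(channel1 = channels)
  stopifnot(is.list(channels), length(channels) >= 1)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array [y, x, z]")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share dimensions")
  stopifnot(pixel_size_xy > 0, z_step > 0, axial_scale > 0, axial_scale <= 1)
  structure(list(
    channels = channels,
    pixel_size_xy = pixel_size_xy,
    z_step = z_step,
    axial_scale = axial_scale,
    origin = as.numeric(origin)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d px, %d planes, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel %.3f um, z step %.2f um, axial scale %.2f\n",
              x$pixel_size_xy, x$z_step, x$axial_scale))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

get_channel <- function(stack, channel) {
  if (is.numeric(channel)) return(stack$channels[[channel]])
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[channel]]
}

#' Convert between world (um) and voxel-index coordinates
#'
#' World coordinates are (x, y, true z) in um; indices are (row, col, plane),
#' fractional, with voxel centers at integer indices.
#'
#' @param stack an \code{image_stack}.
#' @param pts numeric matrix (n x 3) of world points (x, y, z_true in um), or a
#'   length-3 vector.
#' @return n x 3 matrix of (row, col, plane) indices (fractional).
#' @export
world_to_index <- function(stack, pts) {
  pts <- rbind_pts(pts)
  px <- stack$pixel_size_xy
  zd <- stack$z_step * stack$axial_scale
  cbind(row   = (pts[, 2] - stack$origin[2]) / px + 0.5,
        col   = (pts[, 1] - stack$origin[1]) / px + 0.5,
        plane = (pts[, 3] - stack$origin[3]) / zd + 0.5)
}

#' @rdname world_to_index
#' @param idx numeric matrix (n x 3) of (row, col, plane) indices.
#' @export
index_to_world <- function(stack, idx) {
  idx <- rbind_pts(idx)
  px <- stack$pixel_size_xy
  zd <- stack$z_step * stack$axial_scale
  cbind(x = (idx[, 2] - 0.5) * px + stack$origin[1],
        y = (idx[, 1] - 0.5) * px + stack$origin[2],
        z = (idx[, 3] - 0.5) * zd + stack$origin[3])
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  storage.mode(pts) <- "double"
  pts
}

## ---- separable Gaussian convolution --------------------------------------

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# banded convolution matrix with renormalized (reflected mass) edges so that
# total intensity is conserved
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- (j - r):(j + r)
    keep <- i >= 1 & i <= n
    col <- numeric(n)
    col[i[keep]] <- kernel[keep]
    m[, j] <- col / sum(kernel[keep])
  }
  m
}

# convolve a 3D array with an anisotropic separable Gaussian;
# sigmas are in voxel units c(row, col, plane)
blur3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || d[ax] == 1) next
    k <- gauss_kernel(s)
    cm <- conv_matrix(d[ax], k)
    vol <- apply_along(vol, ax, cm)
  }
  vol
}

# multiply each fiber of `vol` along axis `ax` by conv matrix `cm`
apply_along <- function(vol, ax, cm) {
  d <- dim(vol)
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- matrix(v, nrow = dv[1])
  v <- cm %*% v
  v <- array(v, dv)
  aperm(v, order(perm))
}

blur2d <- function(img, sigma_px) {
  d <- dim(img)
  k <- gauss_kernel(sigma_px)
  if (length(k) > 1) {
    img <- conv_matrix(d[1], k) %*% img
    img <- img %*% t(conv_matrix(d[2], k))
  }
  img
}

## ---- bilinear sampling and profiles --------------------------------------

# bilinear interpolation of a 2D image at fractional (row, col) positions
bilinear2d <- function(img, rows, cols) {
  d <- dim(img)
  r0 <- pmin(pmax(floor(rows), 1L), d[1] - 1L)
  c0 <- pmin(pmax(floor(cols), 1L), d[2] - 1L)
  fr <- pmin(pmax(rows - r0, 0), 1)
  fc <- pmin(pmax(cols - c0, 0), 1)
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1L, c0)]
  v01 <- img[cbind(r0, c0 + 1L)]
  v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

#' Mean-intensity profile along a polyline
#'
#' Samples a 2D image along a polyline, averaging transversely over a band of
#' the given width, as with an ImageJ segmented-line selection. Sampling step
#' defaults to one pixel.
#'
#' @param img 2D numeric matrix.
#' @param polyline n x 2 matrix of (x, y) vertices in um.
#' @param pixel_size um per pixel.
#' @param width_px transverse averaging width in pixels.
#' @param step_um sampling step along the line, um (default one pixel).
#' @return data.frame with columns \code{arclength} (um) and \code{intensity}.
#' @export
profile_along_line <- function(img, polyline, pixel_size, width_px = 1,
                               step_um = pixel_size) {
  polyline <- rbind_pts(polyline)
  if (nrow(polyline) < 2) stop("polyline needs at least 2 vertices")
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  s <- seq(0, total, by = step_um)
  cum <- c(0, cumsum(seg_len))
  # position and tangent at each arclength
  pos <- matrix(NA_real_, length(s), 2)
  tan_ <- matrix(NA_real_, length(s), 2)
  for (i in seq_along(s)) {
    j <- max(which(cum <= s[i] + 1e-12))
    j <- min(j, nrow(seg))
    t_ <- (s[i] - cum[j]) / seg_len[j]
    pos[i, ] <- polyline[j, ] + t_ * seg[j, ]
    tan_[i, ] <- seg[j, ] / seg_len[j]
  }
  nrm <- cbind(-tan_[, 2], tan_[, 1])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pixel_size
  vals <- matrix(NA_real_, length(s), length(offs))
  for (k in seq_along(offs)) {
    p <- pos + offs[k] * nrm
    rows <- p[, 2] / pixel_size + 0.5
    cols <- p[, 1] / pixel_size + 0.5
    vals[, k] <- bilinear2d(img, rows, cols)
  }
  data.frame(arclength = s, intensity = rowMeans(vals))
}
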