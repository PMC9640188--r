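#' Re-slice a side-view z-stack into an end-on view
#'
#' Transforms a z-stack of a horizontally lying spindle (long axis pre-aligned
#' with the in-plane x axis) into an end-on view by the axis permutation
#' I'(i px, j px, k zd) = I(k zd, i px, j px): each output plane is a y-z
#' cross-section at one x position. The axial coordinate is rescaled by
#' \code{axial_scale} (0.81) to true depth and resampled to the in-plane pixel
#' pitch with nearest or linear interpolation. With \code{axial_scale = 1} and
#' isotropic voxels the transform is a pure axis permutation and conserves
#' total intensity exactly under nearest interpolation.
#'
#' @param stack an \code{image_stack}, or a 3D array plus calibration.
#' @param channel channel to transform (ignored for a bare array).
#' @param axial_scale true-z per stage-z factor; defaults to the stack's.
#' @param interpolation "linear" (default) or "nearest".
#' @param pixel_size,z_step calibration when \code{stack} is a bare array.
#' @return An object of class \code{"end_on_volume"}: isotropized array
#'   (rows = y, cols = resampled z, planes = x), the pixel pitch, and
#'   provenance (axial scale and interpolation used).
#' @export
rotate_to_end_on <- function(stack, channel = 1, axial_scale = NULL,
                             interpolation = c("linear", "nearest"),
                             pixel_size = NULL, z_step = NULL) {
  interpolation <- match.arg(interpolation)
  if (inherits(stack, "image_stack")) {
    vol <- get_channel(stack, channel)
    pixel_size <- stack$pixel_size_xy
    z_step <- stack$z_step
    if (is.null(axial_scale)) axial_scale <- stack$axial_scale
  } else {
    vol <- stack
    if (is.null(pixel_size) || is.null(z_step))
      stop("missing calibration metadata for the transform")
    if (is.null(axial_scale)) axial_scale <- 0.81
  }
  d <- dim(vol)
  zd <- z_step * axial_scale
  nz_out <- max(1L, round(d[3] * zd / pixel_size))
  # true z at output column centers, at exactly the in-plane pixel pitch
  zt <- (seq_len(nz_out) - 0.5) * pixel_size
  k <- zt / zd + 0.5  # source plane index, fractional
  out <- array(0, c(d[1], nz_out, d[2]))
  if (interpolation == "nearest") {
    ks <- pmin(pmax(round(k), 1L), d[3])
    for (j in seq_len(nz_out)) out[, j, ] <- vol[, , ks[j]]
  } else {
    k0 <- pmin(pmax(floor(k), 1L), d[3] - 1L)
    f <- pmin(pmax(k - k0, 0), 1)
    for (j in seq_len(nz_out))
      out[, j, ] <- (1 - f[j]) * vol[, , k0[j]] + f[j] * vol[, , k0[j] + 1L]
  }
  structure(list(volume = out, pixel_size = pixel_size,
                 axial_scale = axial_scale, interpolation = interpolation,
                 source_z_step = z_step, source_dim = d),
            class = "end_on_volume")
}

#' @describeIn rotate_to_end_on Inverse transform back to the side view (for
#'   round-trip validation); returns a 3D array with the source dimensions.
#' @param end_on an \code{end_on_volume}.
#' @export
end_on_inverse <- function(end_on, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  v <- end_on$volume
  d_src <- end_on$source_dim
  zd <- end_on$source_z_step * end_on$axial_scale
  nz_out <- dim(v)[2]
  out <- array(0, d_src)
  zt <- (seq_len(d_src[3]) - 0.5) * zd
  j <- zt / end_on$pixel_size + 0.5
  if (interpolation == "nearest") {
    js <- pmin(pmax(round(j), 1L), nz_out)
    for (k in seq_len(d_src[3])) out[, , k] <- v[, js[k], ]
  } else {
    j0 <- pmin(pmax(floor(j), 1L), nz_out - 1L)
    f <- pmin(pmax(j - j0, 0), 1)
    for (k in seq_len(d_src[3]))
      out[, , k] <- (1 - f[k]) * v[, j0[k], ] + f[k] * v[, j0[k] + 1L, ]
  }
  out
}

#' Sum-intensity projection over a plane range
#'
#' Voxelwise sum over the stated slices. The published defaults are 10 central
#' end-on slices (covering 0.83 um along the spindle axis) for bundle counting
#' and PRC1 profiles, and 5 central side-view slices for side-view intensities.
#'
#' @param volume 3D array or \code{end_on_volume}.
#' @param plane_range indices of the planes (third dimension) to sum; default:
#'   the 10 central planes.
#' @return 2D matrix.
#' @export
sum_projection <- function(volume, plane_range = NULL) {
  v <- if (inherits(volume, "end_on_volume")) volume$volume else volume
  n <- dim(v)[3]
  if (is.null(plane_range)) plane_range <- central_planes(n, 10)
  if (length(plane_range) == 0) stop("empty plane range")
  if (min(plane_range) < 1 || max(plane_range) > n)
    stop("plane range outside the volume")
  if (length(plane_range) == 1) return(v[, , plane_range])
  apply(v[, , plane_range, drop = FALSE], c(1, 2), sum)
}

central_planes <- function(n, k) {
  k <- min(k, n)
  start <- floor((n - k) / 2) + 1L
  start:(start + k - 1L)
}

#' Count distinct bundles in an end-on projection
#'
#' Automated operationalization of manual bundle counting: the projection is
#' lightly smoothed, local maxima are detected, maxima closer together than
#' \code{min_separation} are merged (brightest wins), and maxima whose height
#' above background falls below \code{prominence_fraction} of the global range
#' are discarded.
#'
#' @param projection 2D matrix (end-on sum projection; rows = y, cols =
#'   resampled z).
#' @param pixel_size um per pixel of the projection.
#' @param min_separation minimum center-to-center bundle distance, um.
#' @param prominence_fraction fraction of (global max - background) a maximum
#'   must reach above background.
#' @param smooth_sigma_um Gaussian smoothing sigma, um; a scalar or a
#'   length-2 vector (rows, cols). The default smooths more along the column
#'   (axial) direction, matching the axially elongated PSF footprint of
#'   end-on projections so that one bundle yields one maximum.
#' @param background background level; default: image median.
#' @return list with \code{count}, \code{coords_px} (row, col) and
#'   \code{coords_um} (x = col, y = row, um).
#' @export
count_bundles <- function(projection, pixel_size,
                          min_separation = 0.3,
                          prominence_fraction = 0.10,
                          smooth_sigma_um = c(0.10, 0.25),
                          background = NULL) {
  if (length(smooth_sigma_um) == 1)
    smooth_sigma_um <- rep(smooth_sigma_um, 2)
  img <- projection
  if (smooth_sigma_um[1] > 0)
    img <- conv_matrix(nrow(img),
                       gauss_kernel(smooth_sigma_um[1] / pixel_size)) %*% img
  if (smooth_sigma_um[2] > 0)
    img <- img %*% t(conv_matrix(ncol(img),
                                 gauss_kernel(smooth_sigma_um[2] / pixel_size)))
  if (is.null(background)) background <- stats::median(img)
  thr <- background + prominence_fraction * (max(img) - background)
  d <- dim(img)
  if (max(img) <= background || all(img < thr))
    return(list(count = 0L, coords_px = matrix(0, 0, 2),
                coords_um = matrix(0, 0, 2)))
  # strict 8-neighborhood local maxima (interior pixels)
  ctr <- img[2:(d[1] - 1), 2:(d[2] - 1)]
  is_max <- ctr >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- img[2:(d[1] - 1) + dr, 2:(d[2] - 1) + dc]
    is_max <- is_max & (ctr > nb | (ctr == nb & (dr < 0 | (dr == 0 & dc < 0))))
  }
  w <- which(is_max, arr.ind = TRUE)
  if (nrow(w) == 0)
    return(list(count = 0L, coords_px = matrix(0, 0, 2),
                coords_um = matrix(0, 0, 2)))
  peaks <- cbind(row = w[, 1] + 1L, col = w[, 2] + 1L)
  vals <- img[peaks]
  ord <- order(vals, decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  min_sep_px <- min_separation / pixel_size
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      j <- (i + 1):nrow(peaks)
      dd <- sqrt((peaks[j, 1] - peaks[i, 1])^2 +
                 (peaks[j, 2] - peaks[i, 2])^2)
      keep[j[dd < min_sep_px]] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  list(count = nrow(peaks),
       coords_px = peaks,
       coords_um = cbind(x = (peaks[, 2] - 0.5) * pixel_size,
                         y = (peaks[, 1] - 0.5) * pixel_size))
}

#' Intensity profile across the spindle diameter
#'
#' Mean transverse intensity along a through-center line of an end-on
#' projection, averaged over a wide band (default 50 px, as with a 50-pixel
#' wide straight-line selection).
#'
#' @param projection 2D matrix.
#' @param p1,p2 line endpoints (x, y) in um.
#' @param pixel_size um per pixel.
#' @param line_width_px transverse averaging width, pixels.
#' @return data.frame (arclength, intensity).
#' @export
diameter_profile <- function(projection, p1, p2, pixel_size,
                             line_width_px = 50) {
  d <- dim(projection)
  for (p in list(p1, p2)) {
    if (p[1] < 0 || p[1] > d[2] * pixel_size ||
        p[2] < 0 || p[2] > d[1] * pixel_size)
      stop("profile line exits the image")
  }
  profile_along_line(projection, rbind(p1, p2), pixel_size,
                     width_px = line_width_px)
}
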