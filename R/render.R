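#' Render a spindle model into a calibrated image stack
#'
#' Forward model for all intensity measurements. Each fiber centerline is
#' rasterized with line-integrated intensity \code{mt_count * unit_brightness}
#' per um, convolved with the anisotropic Gaussian PSF, and placed so that a
#' point at true depth z lands on plane index \code{z / (axial_scale * z_step)}
#' -- downstream multiplication of plane differences by
#' \code{z_step * axial_scale} then recovers true axial distances. Kinetochores
#' are rendered as diffraction-limited puncta in their own channel and PRC1
#' overlap segments in a third channel. Background is added and, when noise is
#' enabled, Poisson shot noise at \code{poisson_gain} photons per a.u. plus
#' Gaussian read noise.
#'
#' @param model a \code{spindle_model}.
#' @param optics an \code{\link{optics_params}} object.
#' @param shape optional voxel dimensions c(rows, cols, planes); when omitted
#'   the volume is sized to enclose the model plus a PSF margin. When given, it
#'   must enclose the model's bounding box after axial scaling.
#' @param seed integer seed for the noise draws.
#' @param channels subset of c("tubulin", "kinetochore", "prc1") to render.
#' @param noise logical; disable for exact photometric tests.
#' @param kc_brightness integrated intensity of one kinetochore punctum, a.u.
#' @param margin_um extra space around the model bounding box, um.
#' @return An \code{\link{image_stack}} whose origin is expressed in model
#'   coordinates, so \code{\link{world_to_index}} maps model points to voxels.
#' @examples
#' m <- make_spindle_model(n_pairs = 2, spindle_length = 4, spindle_width = 2,
#'                         n_astral = 0, seed = 1)
#' st <- render(m, optics_params("confocal"), seed = 1, noise = FALSE)
#' dim(st)
#' @export
render <- function(model, optics, shape = NULL, seed = 1,
                   channels = c("tubulin", "kinetochore", "prc1"),
                   noise = TRUE, kc_brightness = 5000, margin_um = 0.8) {
  stopifnot(inherits(model, "spindle_model"), inherits(optics, "optics_params"))
  channels <- match.arg(channels, several.ok = TRUE)
  px <- optics$pixel_size_xy
  zd <- plane_pitch_um(optics)

  pts <- model_points(model)
  if (nrow(pts) == 0) pts <- matrix(0, 1, 3)
  lo <- apply(pts, 2, min) - margin_um
  hi <- apply(pts, 2, max) + margin_um
  if (is.null(shape)) {
    shape <- c(ceiling((hi[2] - lo[2]) / px),
               ceiling((hi[1] - lo[1]) / px),
               max(3L, ceiling((hi[3] - lo[3]) / zd)))
    origin <- c(lo[1], lo[2], lo[3])
  } else {
    stopifnot(length(shape) == 3)
    ext <- c(shape[2] * px, shape[1] * px, shape[3] * zd)
    need <- hi - lo
    if (any(need > ext + 1e-9))
      stop("model bounding box exceeds the requested volume shape")
    origin <- (lo + hi) / 2 - ext / 2
  }
  shape <- as.integer(shape)

  stack <- image_stack(
    channels = stats::setNames(
      rep(list(array(0, shape)), length(channels)), channels),
    pixel_size_xy = px, z_step = optics$z_step,
    axial_scale = optics$axial_scale, origin = origin)

  sigma_vox <- c(optics$psf_sigma_xy / px, optics$psf_sigma_xy / px,
                 optics$psf_sigma_z / optics$z_step)

  if ("tubulin" %in% channels) {
    vol <- array(0, shape)
    for (f in model$fibers) {
      sm <- sample_centerline(f$centerline, ds = px / 2)
      w <- f$mt_count * optics$unit_brightness * sm$ds
      vol <- deposit_trilinear(vol, world_to_index(stack, sm$pts), w)
    }
    stack$channels$tubulin <- blur3d(vol, sigma_vox)
  }
  if ("kinetochore" %in% channels) {
    vol <- array(0, shape)
    kc <- rbind(model$sisters1, model$sisters2)
    if (nrow(kc) > 0) {
      vol <- deposit_trilinear(vol, world_to_index(stack, kc),
                               rep(kc_brightness, nrow(kc)))
    }
    stack$channels$kinetochore <- blur3d(vol, sigma_vox)
  }
  if ("prc1" %in% channels) {
    vol <- array(0, shape)
    for (s in model$prc1_segments) {
      sm <- sample_centerline(s$centerline, ds = px / 2)
      vol <- deposit_trilinear(vol, world_to_index(stack, sm$pts),
                               rep(s$brightness_per_um * sm$ds[1], nrow(sm$pts)))
    }
    stack$channels$prc1 <- blur3d(vol, sigma_vox)
  }

  for (ch in channels)
    stack$channels[[ch]] <- stack$channels[[ch]] + optics$background_level
  if (noise) {
    withr::with_seed(as.integer(seed), {
      for (ch in channels)
        stack$channels[[ch]] <- add_noise(stack$channels[[ch]], optics)
    })
  }
  stack
}

model_points <- function(model) {
  pts <- do.call(rbind, c(
    lapply(model$fibers, `[[`, "centerline"),
    list(model$sisters1, model$sisters2, model$poles)))
  pts[stats::complete.cases(pts), , drop = FALSE]
}

# resample a polyline at (approximately) equal arclength steps
sample_centerline <- function(centerline, ds) {
  centerline <- rbind_pts(centerline)
  seg <- diff(centerline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  n <- max(2L, ceiling(total / ds) + 1L)
  s <- seq(0, total, length.out = n)
  cum <- c(0, cumsum(seg_len))
  j <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  t_ <- (s - cum[j]) / seg_len[j]
  pts <- centerline[j, , drop = FALSE] + seg[j, , drop = FALSE] * t_
  list(pts = pts, ds = rep(total / (n - 1), n))
}

# trilinear scatter-add of weights at fractional (row, col, plane) indices
deposit_trilinear <- function(vol, idx, w) {
  d <- dim(vol)
  r0 <- floor(idx[, 1]); c0 <- floor(idx[, 2]); p0 <- floor(idx[, 3])
  fr <- idx[, 1] - r0; fc <- idx[, 2] - c0; fp <- idx[, 3] - p0
  acc_i <- integer(0); acc_w <- numeric(0)
  for (dr in 0:1) for (dc in 0:1) for (dp in 0:1) {
    rr <- r0 + dr; cc <- c0 + dc; pp <- p0 + dp
    ww <- w * (if (dr) fr else 1 - fr) *
              (if (dc) fc else 1 - fc) *
              (if (dp) fp else 1 - fp)
    ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2] & pp >= 1 & pp <= d[3] &
      ww > 0
    if (any(ok)) {
      lin <- (pp[ok] - 1) * d[1] * d[2] + (cc[ok] - 1) * d[1] + rr[ok]
      acc_i <- c(acc_i, lin); acc_w <- c(acc_w, ww[ok])
    }
  }
  if (length(acc_i)) {
    tab <- rowsum(acc_w, acc_i)
    vol[as.integer(rownames(tab))] <- vol[as.integer(rownames(tab))] + tab[, 1]
  }
  vol
}

add_noise <- function(vol, optics) {
  g <- optics$poisson_gain
  shot <- stats::rpois(length(vol), pmax(vol, 0) * g) / g
  shot <- array(shot, dim(vol))
  if (optics$read_noise_sigma > 0)
    shot <- shot + array(stats::rnorm(length(vol), 0, optics$read_noise_sigma),
                         dim(vol))
  shot
}
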