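#' Distance between photoactivation mark and the nearer pole
#'
#' Both channels of one frame are Gaussian-blurred (default sigma 2 px, as
#' with an ImageJ Gaussian Blur of sigma 2), intensity profiles are taken along
#' a 10-px wide pole-to-pole line, and the distance between the
#' photoactivation-peak and the nearer tubulin pole peak is returned. Peak
#' positions use parabolic sub-pixel refinement around the discrete argmax.
#'
#' @param tubulin,photo 2D matrices (one frame each).
#' @param profile_line pole-to-pole polyline (n x 2, um).
#' @param pixel_size um per pixel.
#' @param blur_sigma_px Gaussian blur sigma, pixels.
#' @param line_width_px profile width, pixels.
#' @param min_prominence minimum (peak - median) / median contrast of the mark
#'   profile; below this the mark is reported lost (NA).
#' @return list with \code{distance_um} (NA when the mark is lost),
#'   \code{mark_s}, \code{pole_s} (arclength positions, um).
#' @export
mark_pole_distance <- function(tubulin, photo, profile_line, pixel_size,
                               blur_sigma_px = 2, line_width_px = 10,
                               min_prominence = 0.5) {
  tub_b <- blur2d(tubulin, blur_sigma_px)
  pho_b <- blur2d(photo, blur_sigma_px)
  ptub <- profile_along_line(tub_b, profile_line, pixel_size,
                             width_px = line_width_px)
  ppho <- profile_along_line(pho_b, profile_line, pixel_size,
                             width_px = line_width_px)

  med <- stats::median(ppho$intensity)
  prom <- (max(ppho$intensity) - med) / max(med, .Machine$double.eps)
  if (!is.finite(prom) || prom < min_prominence) {
    warning("photoactivation mark lost: no sufficiently prominent peak")
    return(list(distance_um = NA_real_, mark_s = NA_real_, pole_s = NA_real_))
  }
  mark_s <- peak_position(ppho)
  # pole peaks: the profile runs pole to pole, so look near the two ends
  n <- nrow(ptub)
  third <- max(2L, floor(n / 3))
  s_first <- peak_position(ptub[seq_len(third), ])
  s_last <- peak_position(ptub[(n - third + 1):n, ])
  pole_s <- if (abs(mark_s - s_first) <= abs(mark_s - s_last)) s_first
            else s_last
  list(distance_um = abs(mark_s - pole_s), mark_s = mark_s, pole_s = pole_s)
}

# argmax with parabolic sub-sample refinement
peak_position <- function(profile) {
  v <- profile$intensity
  s <- profile$arclength
  i <- which.max(v)
  if (i > 1 && i < length(v)) {
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (abs(denom) > .Machine$double.eps) {
      delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
      delta <- max(-0.5, min(0.5, delta))
      return(s[i] + delta * mean(diff(s)))
    }
  }
  s[i]
}

#' Linear rate from a distance time series
#'
#' Ordinary least-squares slope of distance over time, converted to um/min.
#' Sign convention: mark-pole and kinetochore-pole series report positive
#' approach speeds (poleward flux, anaphase A); pole-pole series report
#' positive separation speed (anaphase B).
#'
#' @param times seconds, strictly increasing (>= 2 frames).
#' @param distances um.
#' @param object_pair one of "mark_pole", "kc_pole", "pole_pole".
#' @return An object of class \code{"rate_estimate"}: \code{slope} (um/min,
#'   sign per convention), \code{intercept} (um), \code{r_squared},
#'   \code{n_frames}.
#' @examples
#' linear_rate(seq(0, 40, 10), c(5, 4.9, 4.8, 4.7, 4.6))$slope  # 0.6
#' @export
linear_rate <- function(times, distances,
                        object_pair = c("mark_pole", "kc_pole", "pole_pole")) {
  object_pair <- match.arg(object_pair)
  ok <- is.finite(times) & is.finite(distances)
  times <- times[ok]; distances <- distances[ok]
  if (length(times) < 2) stop("linear rate needs at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  fit <- stats::lm(distances ~ times)
  slope_um_min <- unname(stats::coef(fit)[2]) * 60
  if (object_pair != "pole_pole") slope_um_min <- -slope_um_min
  ss_tot <- sum((distances - mean(distances))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = slope_um_min,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_frames = length(times),
                 object_pair = object_pair),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate_estimate [%s]: %.3f um/min (R^2 %.3f, n %d)\n",
              x$object_pair, x$slope, x$r_squared, x$n_frames))
  invisible(x)
}

#' Detect anaphase onset from an interkinetochore distance series
#'
#' Onset is the last frame before the interkinetochore distance starts a
#' sustained increase: the first run of \code{n_sustained} consecutive
#' frame-to-frame increases with cumulative rise at least \code{min_rise}.
#' Frames are indexed from 0. Invariant to adding a constant to the series.
#'
#' @param distances um, one value per frame (frames 0, 1, ...).
#' @param n_sustained length of the required run of increases.
#' @param min_rise required cumulative rise over the run, um.
#' @return 0-based onset frame index, or NA (with a warning) when no
#'   qualifying run exists.
#' @examples
#' detect_onset(c(1.0, 1.0, 1.0, 1.1, 1.3, 1.6))  # 2
#' @export
detect_onset <- function(distances, n_sustained = 3, min_rise = 0.1) {
  n <- length(distances)
  if (n < n_sustained + 1) stop("series too short for onset detection")
  d <- diff(distances)
  for (i in seq_len(n - n_sustained)) {
    run <- d[i:(i + n_sustained - 1)]
    if (all(run > 0) && sum(run) >= min_rise)
      return(i - 1L)  # last frame before the first rise, 0-based
  }
  warning("no anaphase onset found in series")
  NA_integer_
}
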