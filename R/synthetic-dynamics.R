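#' Simulate anaphase kinetochore and pole trajectories
#'
#' Generates a time-indexed trajectory set for every kinetochore pair of a
#' spindle model together with the pole positions, planting segregation-error
#' phenotypes on chosen pairs. Normal pairs split at anaphase onset, each
#' sister approaching its pole at the anaphase A speed while the poles separate
#' at the anaphase B speed. Planted phenotypes:
#' \describe{
#'   \item{misaligned}{both sisters sit outside the metaphase plate (displaced
#'     toward one pole) from before onset; if missegregating, both end up
#'     nearer that same pole.}
#'   \item{lagging}{one sister stays near the equator during anaphase with its
#'     punctum elongation raised above the stretch threshold (stretched
#'     CENP-A); if missegregating it then crosses to the pole opposite its
#'     pre-onset side.}
#'   \item{other}{the pair never separates and remains near the plate with
#'     normal elongation.}
#' }
#' The interkinetochore distance of separated pairs is non-decreasing after
#' onset by construction.
#'
#' @param model a \code{spindle_model}.
#' @param error_spec data.frame with columns \code{pair_id},
#'   \code{class} (one of "normal", "misaligned", "lagging", "other") and
#'   \code{missegregates} (logical); pairs not listed are normal.
#' @param kinetics list with \code{anaphase_A_speed} and
#'   \code{anaphase_B_speed} (um/min, >= 0) and \code{onset_frame} (0-based).
#' @param n_frames number of frames.
#' @param dt frame interval, seconds (default 30 s, the anaphase live-imaging
#'   interval).
#' @param position_noise_sd localization noise added to every coordinate, um.
#' @param elongation_threshold stretch threshold separating lagging puncta.
#' @param seed integer seed.
#' @return list with \code{trajectories} (class \code{trajectory_set}: one row
#'   per object and frame, columns frame, time_s, object, pair_id, sister,
#'   x, y, z, elongation) and \code{truth} (per-pair planted classes).
#' @export
make_anaphase_timelapse <- function(model,
                                    error_spec = NULL,
                                    kinetics = list(anaphase_A_speed = 1.0,
                                                    anaphase_B_speed = 1.0,
                                                    onset_frame = 3),
                                    n_frames = 16,
                                    dt = 30,
                                    position_noise_sd = 0,
                                    elongation_threshold = 1.5,
                                    seed = 1) {
  stopifnot(inherits(model, "spindle_model"))
  if (dt <= 0) stop("dt must be > 0")
  vA <- kinetics$anaphase_A_speed / 60  # um/s
  vB <- kinetics$anaphase_B_speed / 60
  onset <- kinetics$onset_frame
  if (vA < 0 || vB < 0) stop("speeds must be >= 0")
  if (onset >= n_frames) stop("onset_frame must be < n_frames")

  n_pairs <- nrow(model$truth_pairs)
  classes <- rep("normal", n_pairs)
  misseg <- rep(FALSE, n_pairs)
  if (!is.null(error_spec) && nrow(error_spec) > 0) {
    classes[error_spec$pair_id] <- as.character(error_spec$class)
    if (!is.null(error_spec$missegregates))
      misseg[error_spec$pair_id] <- error_spec$missegregates
  }

  L0 <- model$poles[2, 1] - model$poles[1, 1]
  frames <- seq_len(n_frames) - 1L
  times <- frames * dt

  withr::with_seed(as.integer(seed), {
    rows <- list()
    push <- function(frame, object, pair_id, sister, p, elong = 1) {
      rows[[length(rows) + 1L]] <<- data.frame(
        frame = frame, time_s = frame * dt, object = object,
        pair_id = pair_id, sister = sister,
        x = p[1], y = p[2], z = p[3], elongation = elong,
        stringsAsFactors = FALSE)
    }
    pole_x <- function(t_s, side) {
      dtp <- pmax(0, t_s - onset * dt)
      side * (L0 / 2 + vB / 2 * dtp)
    }
    for (f in frames) {
      t_s <- f * dt
      push(f, "pole", NA_integer_, NA_integer_, c(pole_x(t_s, -1), 0, 0))
      push(f, "pole", NA_integer_, NA_integer_, c(pole_x(t_s, +1), 0, 0))
    }

    # position a sister so its distance to the (moving) target pole is
    # exactly d0 - v * dtp along the fixed pole-to-sister unit vector:
    # the kinetochore-pole approach speed is then the planted speed
    poleward <- function(s0, pole0, pole_t, v, dtp, floor_um = 0.4) {
      u <- s0 - pole0
      d0 <- sqrt(sum(u^2))
      u <- u / d0
      pole_t + u * max(d0 - v * dtp, floor_um)
    }
    for (i in seq_len(n_pairs)) {
      s1 <- model$sisters1[i, ]; s2 <- model$sisters2[i, ]
      # side: sister 1 segregates to the -x pole, sister 2 to +x
      if (s1[1] > s2[1]) { tmp <- s1; s1 <- s2; s2 <- tmp }
      cls <- classes[i]
      if (cls == "misaligned") {
        # both sisters displaced toward the -x pole, outside the plate
        off <- c(-0.35 * L0, 0, 0)
        s1 <- s1 + off; s2 <- s2 + off
      }
      pA0 <- c(-L0 / 2, 0, 0); pB0 <- c(L0 / 2, 0, 0)
      for (f in frames) {
        t_s <- f * dt
        dtp <- max(0, t_s - onset * dt)
        pA <- c(pole_x(t_s, -1), 0, 0); pB <- c(pole_x(t_s, +1), 0, 0)
        e1 <- 1; e2 <- 1
        if (cls == "normal" || cls == "misaligned") {
          if (cls == "misaligned" && misseg[i]) {
            # both approach the -x pole
            p1t <- poleward(s1, pA0, pA, vA, dtp)
            p2t <- poleward(s2, pA0, pA, 0.8 * vA, dtp)
          } else {
            p1t <- poleward(s1, pA0, pA, vA, dtp)
            p2t <- poleward(s2, pB0, pB, vA, dtp)
          }
        } else if (cls == "lagging") {
          p1t <- poleward(s1, pA0, pA, vA, dtp)
          if (misseg[i]) {
            # the stretched +x-side sister ends up crossing to the -x pole
            p2t <- poleward(s2, pA0, pA, 0.35 * vA, dtp)
          } else {
            p2t <- poleward(s2, pB0, pB, 0.35 * vA, dtp)
          }
          if (dtp > 0) e2 <- elongation_threshold + 1.0
        } else { # other: never separates
          p1t <- s1; p2t <- s2
        }
        nse <- function(p) p + stats::rnorm(3, 0, position_noise_sd)
        push(f, "kinetochore", i, 1L, nse(p1t), e1 + stats::rnorm(1, 0, 0.03))
        push(f, "kinetochore", i, 2L, nse(p2t), e2 + stats::rnorm(1, 0, 0.03))
      }
    }
    traj <- do.call(rbind, rows)
  })
  attr(traj, "dt") <- dt
  attr(traj, "onset_frame") <- onset
  class(traj) <- c("trajectory_set", "data.frame")

  truth <- model$truth_pairs
  truth$error_class <- ifelse(classes == "normal", "none", classes)
  truth$missegregates <- misseg
  list(trajectories = traj, truth = truth)
}

# move p toward target by distance d (stopping 0.4 um short of the target)
approach <- function(p, target, d) {
  v <- target - p
  len <- sqrt(sum(v^2))
  d <- min(d, max(0, len - 0.4))
  p + v / len * d
}

#' Simulate a photoactivation time series for poleward flux measurement
#'
#' Renders a 2D time-lapse of a horizontal spindle with a transverse
#' Gaussian-profile photoactivation mark whose center translates toward the
#' nearer pole at the planted flux speed, over a static spindle-background
#' tubulin field with bright poles. The frame interval defaults to 10 s,
#' matching the photoactivation acquisition protocol.
#'
#' @param spindle_length pole-to-pole distance, um.
#' @param flux_speed planted poleward flux, um/min (>= 0).
#' @param mark_width transverse mark thickness (Gaussian sigma along x), um.
#' @param mark_offset_um initial distance of the mark from the spindle
#'   midplane, toward the +x pole, um.
#' @param n_frames number of frames (>= 5 for a valid flux fit).
#' @param dt frame interval, seconds.
#' @param optics an \code{optics_params} (confocal preset applies).
#' @param noise logical; Poisson + read noise per frame.
#' @param seed integer seed.
#' @return list with \code{tubulin} and \code{photo} arrays (rows x cols x
#'   frames), \code{pixel_size}, \code{dt}, pole positions, and \code{truth}
#'   (per-frame true mark center and mark-pole distance).
#' @export
make_photoactivation_series <- function(spindle_length = 12,
                                        flux_speed = 1.0,
                                        mark_width = 0.5,
                                        mark_offset_um = 2,
                                        n_frames = 8,
                                        dt = 10,
                                        optics = optics_params("confocal"),
                                        noise = TRUE,
                                        seed = 1) {
  if (flux_speed < 0) stop("flux_speed must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  px <- optics$pixel_size_xy
  width_um <- 4
  len_um <- spindle_length + 3
  nx <- ceiling(len_um / px); ny <- ceiling(width_um / px)
  x_um <- ((seq_len(nx)) - 0.5) * px
  y_um <- ((seq_len(ny)) - 0.5) * px
  x0 <- len_um / 2  # spindle midplane
  pole_x <- c(x0 - spindle_length / 2, x0 + spindle_length / 2)
  half_w <- 1.2     # spindle half-thickness in y

  mark_x0 <- x0 + mark_offset_um
  if (mark_x0 + mark_width > pole_x[2] || mark_x0 - mark_width < pole_x[1])
    stop("photoactivation mark does not fit within the spindle")

  # static tubulin field: plateau between poles with bright pole puncta
  spindle_body <- outer(exp(-0.5 * ((y_um - width_um / 2) / (half_w / 2))^2),
                        as.numeric(x_um > pole_x[1] & x_um < pole_x[2])) * 120
  pole_img <- matrix(0, ny, nx)
  for (p in pole_x) {
    pole_img <- pole_img + 600 *
      outer(exp(-0.5 * ((y_um - width_um / 2) / 0.25)^2),
            exp(-0.5 * ((x_um - p) / 0.25)^2))
  }
  tub0 <- spindle_body + pole_img + optics$background_level

  tub <- array(0, c(ny, nx, n_frames))
  pho <- array(0, c(ny, nx, n_frames))
  truth <- data.frame(frame = seq_len(n_frames) - 1L,
                      mark_x_um = NA_real_, mark_pole_um = NA_real_)
  # mark moves toward the nearer pole
  nearer <- which.min(abs(pole_x - mark_x0))
  dir_ <- sign(pole_x[nearer] - mark_x0)
  withr::with_seed(as.integer(seed), {
    for (f in seq_len(n_frames)) {
      t_s <- (f - 1) * dt
      mx <- mark_x0 + dir_ * flux_speed / 60 * t_s
      band <- outer(exp(-0.5 * ((y_um - width_um / 2) / (half_w / 2))^2),
                    exp(-0.5 * ((x_um - mx) / mark_width)^2)) * 400
      tub_f <- tub0
      pho_f <- band + optics$background_level
      if (noise) {
        tub_f <- add_noise(tub_f, optics)
        pho_f <- add_noise(pho_f, optics)
      }
      tub[, , f] <- tub_f
      pho[, , f] <- pho_f
      truth$mark_x_um[f] <- mx
      truth$mark_pole_um[f] <- abs(mx - pole_x[nearer])
    }
  })
  list(tubulin = tub, photo = pho, pixel_size = px, dt = dt,
       pole_x_um = pole_x, y_center_um = width_um / 2,
       nearer_pole = nearer, truth = truth)
}
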