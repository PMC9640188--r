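#' STED calibration scene: k-fibers, bridging fiber and astral microtubules
#'
#' A deterministic planar spindle phantom for ratiometric calibration studies:
#' two poles on the x axis, one on-axis kinetochore pair with sister k-fibers
#' (and optionally a bridging fiber), and a fan of astral microtubules of one
#' microtubule each radiating outward from each pole at fixed angles, so that
#' an empty between-astral background area exists by construction. All
#' structures lie in the central z plane, matching the single-z-plane square
#' ROI protocol.
#'
#' @param spindle_length pole-to-pole distance, um.
#' @param separation sister separation, um.
#' @param astral_angles_deg angles of the astral fan relative to the outward
#'   spindle axis, degrees.
#' @param astral_length_um astral fiber length, um.
#' @param mt_counts named vector of microtubules per class.
#' @param bridging logical: include the bridging fiber.
#' @param seed stored in the model (the scene itself is deterministic).
#' @return a \code{spindle_model}.
#' @export
make_calibration_scene <- function(spindle_length = 3,
                                   separation = 0.98,
                                   astral_angles_deg = c(-13, 13),
                                   astral_length_um = 3,
                                   mt_counts = c(k_fiber = 12.6,
                                                 bridging = 3.8, astral = 1.0),
                                   bridging = FALSE,
                                   seed = 1) {
  mt_counts <- fill_mt_counts(mt_counts)
  poles <- rbind(c(-spindle_length / 2, 0, 0), c(spindle_length / 2, 0, 0))
  s1 <- c(-separation / 2, 0, 0)
  s2 <- c( separation / 2, 0, 0)
  fibers <- list()
  fid <- 0L
  add <- function(class, mt, cl, pair = NA_integer_) {
    fid <<- fid + 1L
    fibers[[fid]] <<- list(fiber_id = fid, fiber_class = class, mt_count = mt,
                           centerline = cl, pair_id = pair)
  }
  # mild sag: measurement ROIs assume fibers locally parallel to the axis,
  # as on the rotated images of the published protocol
  add("k_fiber", mt_counts[["k_fiber"]], kfiber_arc(poles[1, ], s1, sag = 0.05), 1L)
  add("k_fiber", mt_counts[["k_fiber"]], kfiber_arc(poles[2, ], s2, sag = 0.05), 1L)
  if (bridging)
    add("bridging", mt_counts[["bridging"]], bridge_arc(s1, s2, sag = 0.1), 1L)
  for (p in 1:2) {
    outward <- c(-1, 1)[p]
    for (a in astral_angles_deg) {
      v <- c(outward * cos(a * pi / 180), sin(a * pi / 180), 0)
      add("astral", mt_counts[["astral"]],
          rbind(poles[p, ], poles[p, ] + astral_length_um * v))
    }
  }
  structure(list(
    poles = poles,
    sisters1 = matrix(s1, 1), sisters2 = matrix(s2, 1),
    fibers = fibers, prc1_segments = list(),
    depletion_factors = c(k_fiber = 1, bridging = 1, astral = 1,
                          interpolar_no_kc = 1),
    truth_pairs = data.frame(pair_id = 1L, sep_um = separation, tilt_deg = 0,
                             axis_dist_um = 0, bridging = bridging,
                             error_class = "none", missegregates = FALSE),
    truth_fibers = data.frame(
      fiber_id = vapply(fibers, `[[`, 0L, "fiber_id"),
      fiber_class = vapply(fibers, `[[`, "", "fiber_class"),
      mt_count = vapply(fibers, `[[`, 0, "mt_count"),
      pair_id = vapply(fibers, `[[`, 0L, "pair_id")),
    seed = as.integer(seed)
  ), class = "spindle_model")
}

#' Square-ROI fiber measurement of a rendered spindle model
#'
#' Applies the square-ROI measurement protocol to a rendered stack using the
#' model's ground-truth geometry for ROI placement (the in-silico counterpart
#' of manual ROI placement): the bridging ROI at the pair midpoint, k-fiber
#' ROIs on each sister k-fiber a fixed arc distance from the kinetochore,
#' astral ROIs at astral fiber midpoints with their background between two
#' astral fibers of the same pole, and the spindle background from empty areas
#' at least \code{clearance_um} from every rendered structure. Returns
#' background-corrected intensities and ratiometric microtubule counts.
#'
#' @param stack the rendered \code{image_stack} (tubulin channel).
#' @param model the \code{spindle_model} that was rendered.
#' @param optics the \code{optics_params} used for rendering.
#' @param roi_size_px ROI side (default per modality: 25 STED, 5 confocal).
#' @param n_background number of empty-area background ROIs (default per
#'   modality: 10 STED, 2 confocal).
#' @param k_offset_um arc distance of the k-fiber ROI from the kinetochore.
#' @param clearance_um minimum distance of empty areas from any structure.
#' @param n_k_ref calibration constant (microtubules per control k-fiber).
#' @param seed seed for the random empty-area placement.
#' @return list with data.frames \code{pairs} (per-pair I_b, I_k, n_b,
#'   bridging_detected) and \code{astral} (per-fiber I_a, n_a), plus
#'   \code{I_bcg}.
#' @export
measure_spindle_fibers <- function(stack, model, optics,
                                   roi_size_px = NULL,
                                   n_background = NULL,
                                   k_offset_um = 0.35,
                                   clearance_um = 0.4,
                                   n_k_ref = 12.6,
                                   seed = 1) {
  if (is.null(roi_size_px))
    roi_size_px <- if (optics$modality == "sted") 25L else 5L
  if (is.null(n_background))
    n_background <- if (optics$modality == "sted") 10L else 2L
  ch <- "tubulin"

  to_idx <- function(p) round(world_to_index(stack, p))
  # arc point at a given arclength from the end of a centerline
  arc_point_from_end <- function(cl, dist_um) {
    cl <- cl[rev(seq_len(nrow(cl))), , drop = FALSE]
    sm <- sample_centerline(cl, ds = 0.02)
    s <- cumsum(c(0, sqrt(rowSums(diff(sm$pts)^2))))
    sm$pts[which.min(abs(s - dist_um)), ]
  }

  # spindle background: empty areas within the spindle bounding region;
  # centerlines are densified so the clearance test sees whole fibers
  all_pts <- rbind(
    do.call(rbind, lapply(model$fibers, function(f)
      sample_centerline(f$centerline, ds = 0.05)$pts)),
    model$sisters1, model$sisters2, model$poles)
  withr::with_seed(as.integer(seed), {
    bg_pts <- matrix(NA_real_, 0, 3)
    guard <- 0L
    z0 <- if (nrow(model$sisters1) > 0) model$sisters1[1, 3] else
      mean(all_pts[, 3])
    while (nrow(bg_pts) < n_background && guard < 20000L) {
      guard <- guard + 1L
      cand <- c(stats::runif(1, min(all_pts[, 1]), max(all_pts[, 1])),
                stats::runif(1, min(all_pts[, 2]) - 0.5,
                             max(all_pts[, 2]) + 0.5), z0)
      dmin <- min(sqrt(rowSums(sweep(all_pts, 2, cand)^2)))
      idx <- to_idx(cand)
      d <- dim(stack)
      h <- (roi_size_px + 1) %/% 2
      if (dmin >= clearance_um &&
          idx[1] > h && idx[1] <= d[1] - h &&
          idx[2] > h && idx[2] <= d[2] - h)
        bg_pts <- rbind(bg_pts, cand)
    }
  })
  if (nrow(bg_pts) < n_background)
    stop("could not place enough empty background areas")
  I_bcg <- background_square(stack, ch,
                             t(apply(bg_pts, 1, function(p) to_idx(p))),
                             roi_size_px)

  tf <- model$truth_fibers
  # per-pair bridging and k-fiber measurements
  pair_rows <- list()
  for (i in seq_len(nrow(model$truth_pairs))) {
    pid <- model$truth_pairs$pair_id[i]
    mid <- (model$sisters1[i, ] + model$sisters2[i, ]) / 2
    I_b_raw <- measure_square_roi(stack, ch, to_idx(mid), roi_size_px)
    kf <- which(tf$fiber_class == "k_fiber" & tf$pair_id == pid)
    k_raw <- vapply(kf, function(j) {
      p <- arc_point_from_end(model$fibers[[j]]$centerline, k_offset_um)
      measure_square_roi(stack, ch, to_idx(p), roi_size_px)
    }, 0)
    ci <- corrected_fiber_intensity(bridging_raw = I_b_raw, k_raw = k_raw,
                                    background = I_bcg)
    pair_rows[[i]] <- data.frame(
      pair_id = pid, I_b = ci$I_b, I_k = ci$I_k,
      n_b = if (ci$I_k > 0) estimate_mt_number(ci$I_b, ci$I_k, n_k_ref)
            else NA_real_,
      bridging_detected = detect_bridging(ci$I_b))
  }
  pairs <- do.call(rbind, pair_rows)

  # mean corrected k-fiber intensity as the calibration denominator
  I_k_cal <- mean(pairs$I_k)

  # astral fibers: ROI at each midpoint, background between fibers per pole
  ast <- which(tf$fiber_class == "astral")
  astral <- NULL
  if (length(ast) > 0) {
    # measure away from the pole (65% along the fiber) where neighboring
    # astral fibers have fanned apart
    mids <- t(vapply(ast, function(j) {
      cl <- model$fibers[[j]]$centerline
      cl[1, ] + 0.65 * (cl[nrow(cl), ] - cl[1, ])
    }, numeric(3)))
    # group astral fibers by nearest pole
    pole_of <- apply(mids, 1, function(p)
      which.min(c(sum((p - model$poles[1, ])^2),
                  sum((p - model$poles[2, ])^2))))
    rows <- list()
    for (j in seq_along(ast)) {
      # between-astral background: midpoint between this fiber's midpoint and
      # the nearest other astral midpoint at the same pole
      same <- setdiff(which(pole_of == pole_of[j]), j)
      if (length(same) > 0) {
        dd <- sqrt(rowSums(sweep(mids[same, , drop = FALSE], 2, mids[j, ])^2))
        bg_pt <- (mids[j, ] + mids[same[which.min(dd)], ]) / 2
      } else bg_pt <- bg_pts[1, ]
      I_a_bcg <- measure_square_roi(stack, ch, to_idx(bg_pt), roi_size_px)
      I_a_raw <- measure_square_roi(stack, ch, to_idx(mids[j, ]), roi_size_px)
      I_a <- I_a_raw - I_a_bcg
      rows[[j]] <- data.frame(
        fiber_id = tf$fiber_id[ast[j]], I_a = I_a,
        n_a = if (I_k_cal > 0) estimate_mt_number(I_a, I_k_cal, n_k_ref)
              else NA_real_)
    }
    astral <- do.call(rbind, rows)
  }
  list(pairs = pairs, astral = astral, I_bcg = I_bcg, I_k_cal = I_k_cal)
}
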