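#' Ground-truth spindle models
#'
#' \code{make_spindle_model} builds a geometric/photometric description of a
#' bipolar metaphase spindle: two poles on the long (x) axis, kinetochore pairs
#' distributed in a prolate shell around the metaphase plate, k-fiber arcs from
#' each pole to each sister kinetochore, bridging-fiber arcs joining the sister
#' k-fibers for a stated fraction of pairs, and astral fibers radiating from
#' the poles. Microtubule counts per fiber class default to the electron
#' tomography calibration for RPE1 cells: 12.6 microtubules per k-fiber,
#' 3.8 per bridging fiber, and 1 per astral microtubule.
#'
#' Geometry notes: k-fibers are modeled as circular arcs sagging away from the
#' spindle axis (default 0.3 um at midpoint); bridging fibers as arcs joining
#' the sister kinetochores, sagging 0.1 um poleward/axisward of the
#' sister-sister segment. Pair sister axes make the planted tilt angle with the
#' pole-to-pole axis, at uniform random azimuth (or in-plane when
#' \code{planar = TRUE}, emulating the single-z-plane measurement geometry).
#'
#' @param n_pairs number of kinetochore pairs (>= 1).
#' @param spindle_length pole-to-pole distance, um.
#' @param spindle_width spindle diameter, um.
#' @param mean_separation mean sister separation, um.
#' @param sep_sd standard deviation of sister separation, um.
#' @param mean_tilt_deg mean planted tilt of sister axes to the pole axis, deg.
#' @param tilt_spread_deg standard deviation of planted tilt, deg.
#' @param bridging_fraction fraction of pairs carrying a bridging fiber.
#' @param mt_counts named vector of microtubules per fiber class
#'   (\code{k_fiber}, \code{bridging}, \code{astral}).
#' @param n_astral astral fibers per pole.
#' @param astral_length_um length of astral fibers, um.
#' @param plate_sd_um axial (x) spread of pair midpoints about the plate, um.
#' @param planar if TRUE, confine pair midpoints, sister axes and astral fibers
#'   to the central z plane.
#' @param seed integer seed; identical seed gives an identical model.
#' @return An object of class \code{"spindle_model"}: poles, pair table, fiber
#'   list, PRC1 segments and the embedded ground-truth tables
#'   (see \code{\link{ground_truth}}).
#' @examples
#' m <- make_spindle_model(n_pairs = 4, seed = 1)
#' ground_truth(m)$pairs
#' @export
make_spindle_model <- function(n_pairs,
                               spindle_length = 12,
                               spindle_width = 9,
                               mean_separation = 0.98,
                               sep_sd = 0,
                               mean_tilt_deg = 0,
                               tilt_spread_deg = 0,
                               bridging_fraction = 1,
                               mt_counts = c(k_fiber = 12.6, bridging = 3.8,
                                             astral = 1.0),
                               n_astral = 2,
                               astral_length_um = 1.5,
                               plate_sd_um = 0.15,
                               planar = FALSE,
                               seed = 1) {
  stopifnot(n_pairs >= 1)
  if (spindle_length <= 0 || spindle_width <= 0 || mean_separation <= 0)
    stop("spindle dimensions and separation must be positive")
  if (bridging_fraction < 0 || bridging_fraction > 1)
    stop("bridging_fraction must lie in [0, 1]")
  if (spindle_length <= mean_separation)
    stop("spindle_length must exceed mean_separation")
  mt_counts <- fill_mt_counts(mt_counts)

  withr::with_seed(as.integer(seed), {
    poles <- rbind(c(-spindle_length / 2, 0, 0),
                   c( spindle_length / 2, 0, 0))
    sep <- pmax(0.1, stats::rnorm(n_pairs, mean_separation, sep_sd))
    tilt <- fold_angle(mean_tilt_deg + stats::rnorm(n_pairs, 0, tilt_spread_deg))
    # pair midpoints: prolate shell around the plate
    r <- sqrt(stats::runif(n_pairs)) * 0.4 * spindle_width
    phi_pos <- if (planar) sample(c(0, pi), n_pairs, replace = TRUE)
               else stats::runif(n_pairs, 0, 2 * pi)
    mid <- cbind(stats::rnorm(n_pairs, 0, plate_sd_um),
                 r * cos(phi_pos), r * sin(phi_pos))
    if (planar) mid[, 3] <- 0
    # sister axis: tilt from x at random azimuth
    psi <- if (planar) sample(c(0, pi), n_pairs, replace = TRUE)
           else stats::runif(n_pairs, 0, 2 * pi)
    th <- tilt * pi / 180
    dir <- cbind(cos(th), sin(th) * cos(psi), sin(th) * sin(psi))
    if (planar) dir[, 3] <- 0
    s1 <- mid - dir * sep / 2
    s2 <- mid + dir * sep / 2

    has_bridge <- rep(FALSE, n_pairs)
    if (bridging_fraction > 0) {
      nb <- round(bridging_fraction * n_pairs)
      has_bridge[sample.int(n_pairs, nb)] <- TRUE
    }

    fibers <- list()
    prc1 <- list()
    fid <- 0L
    add_fiber <- function(class, mt, centerline, pair_id = NA_integer_) {
      fid <<- fid + 1L
      fibers[[fid]] <<- list(fiber_id = fid, fiber_class = class,
                             mt_count = mt, centerline = centerline,
                             pair_id = pair_id)
    }
    for (i in seq_len(n_pairs)) {
      # sister 1 attaches to the nearer pole, sister 2 to the other
      p_near <- if (s1[i, 1] <= s2[i, 1]) 1L else 2L
      add_fiber("k_fiber", mt_counts[["k_fiber"]],
                kfiber_arc(poles[p_near, ], s1[i, ], sag = 0.3), i)
      add_fiber("k_fiber", mt_counts[["k_fiber"]],
                kfiber_arc(poles[3L - p_near, ], s2[i, ], sag = 0.3), i)
      if (has_bridge[i]) {
        bc <- bridge_arc(s1[i, ], s2[i, ], sag = 0.1)
        add_fiber("bridging", mt_counts[["bridging"]], bc, i)
        prc1[[length(prc1) + 1L]] <-
          list(centerline = bc, brightness_per_um = 1000, pair_id = i)
      }
    }
    for (p in 1:2) {
      for (a in seq_len(n_astral)) {
        ang <- stats::runif(1, -pi / 3, pi / 3)
        outward <- sign(poles[p, 1] + 1e-9)
        d3 <- if (planar) 0 else stats::runif(1, -0.3, 0.3)
        v <- c(outward * cos(ang), sin(ang), d3)
        v <- v / sqrt(sum(v^2))
        line <- rbind(poles[p, ], poles[p, ] + astral_length_um * v)
        add_fiber("astral", mt_counts[["astral"]], line)
      }
    }

    truth_pairs <- data.frame(
      pair_id = seq_len(n_pairs),
      sep_um = sep,
      tilt_deg = tilt,
      axis_dist_um = sqrt(mid[, 2]^2 + mid[, 3]^2),
      bridging = has_bridge,
      error_class = "none",
      missegregates = FALSE,
      stringsAsFactors = FALSE)
    truth_fibers <- data.frame(
      fiber_id = vapply(fibers, `[[`, 0L, "fiber_id"),
      fiber_class = vapply(fibers, `[[`, "", "fiber_class"),
      mt_count = vapply(fibers, `[[`, 0, "mt_count"),
      pair_id = vapply(fibers, `[[`, 0L, "pair_id"),
      stringsAsFactors = FALSE)

    structure(list(
      poles = poles,
      sisters1 = s1, sisters2 = s2,
      fibers = fibers,
      prc1_segments = prc1,
      depletion_factors = c(k_fiber = 1, bridging = 1, astral = 1,
                            interpolar_no_kc = 1),
      truth_pairs = truth_pairs,
      truth_fibers = truth_fibers,
      seed = as.integer(seed)
    ), class = "spindle_model")
  })
}

fill_mt_counts <- function(mt_counts) {
  full <- c(k_fiber = 12.6, bridging = 3.8, astral = 1.0,
            interpolar_no_kc = 3.8)
  full[names(mt_counts)] <- mt_counts
  full
}

fold_angle <- function(deg) {
  deg <- abs(deg) %% 180
  ifelse(deg > 90, 180 - deg, deg)
}

#' @export
print.spindle_model <- function(x, ...) {
  cat(sprintf("spindle_model: %d pairs, %d fibers, pole-pole %.1f um, seed %d\n",
              nrow(x$truth_pairs), length(x$fibers),
              sqrt(sum((x$poles[1, ] - x$poles[2, ])^2)), x$seed))
  invisible(x)
}

#' Ground truth tables of a simulated spindle
#'
#' Returns the per-pair and per-fiber ground truth planted by the generator:
#' true separation, tilt, distance to the pole axis, bridging presence, planted
#' error class, and per-fiber microtubule counts. Regenerating the model with
#' the same seed reproduces these tables bit-identically.
#'
#' @param model a \code{spindle_model}.
#' @return list with data.frames \code{pairs} and \code{fibers}.
#' @export
ground_truth <- function(model) {
  stopifnot(inherits(model, "spindle_model"))
  list(pairs = model$truth_pairs, fibers = model$truth_fibers)
}

## ---- arcs -----------------------------------------------------------------

# circular arc from p1 to p2 bulging `sag` um along unit normal nhat
arc_points <- function(p1, p2, sag, nhat, n = 25) {
  chord <- p2 - p1
  d <- sqrt(sum(chord^2))
  if (d == 0) stop("degenerate arc: coincident endpoints")
  if (abs(sag) < 1e-9) {
    t <- seq(0, 1, length.out = n)
    return(outer(1 - t, p1) + outer(t, p2))
  }
  u <- chord / d
  mid <- (p1 + p2) / 2
  # 2D circle through (-d/2,0), (d/2,0), (0,sag)
  w0 <- (sag^2 - (d / 2)^2) / (2 * sag)
  R <- abs(sag - w0)
  a1 <- atan2(0 - w0, -d / 2)
  a2 <- atan2(0 - w0, d / 2)
  amid <- atan2(sag - w0, 0)
  # go from a1 to a2 passing through amid
  if (!angle_between(a1, amid, a2)) {
    if (a2 > a1) a2 <- a2 - 2 * pi else a2 <- a2 + 2 * pi
  }
  ang <- seq(a1, a2, length.out = n)
  t2 <- R * cos(ang)
  w2 <- w0 + R * sin(ang)
  sweep(outer(t2, u) + outer(w2, nhat), 2, mid, `+`)
}

angle_between <- function(a1, am, a2) {
  lo <- min(a1, a2); hi <- max(a1, a2)
  am >= lo && am <= hi
}

# unit vector from the spindle axis (x axis) toward point, perpendicular to chord
radial_normal <- function(p1, p2) {
  mid <- (p1 + p2) / 2
  rad <- c(0, mid[2], mid[3])
  chord <- p2 - p1
  chord <- chord / sqrt(sum(chord^2))
  perp <- rad - sum(rad * chord) * chord
  nl <- sqrt(sum(perp^2))
  if (nl < 1e-9) {
    # midpoint on the axis: any perpendicular
    perp <- c(-chord[2], chord[1], 0)
    nl <- sqrt(sum(perp^2))
    if (nl < 1e-9) { perp <- c(0, 1, 0); nl <- 1 }
  }
  perp / nl
}

kfiber_arc <- function(pole, kc, sag = 0.3, n = 25) {
  arc_points(pole, kc, sag, radial_normal(pole, kc), n)
}

bridge_arc <- function(s1, s2, sag = 0.1, n = 15) {
  # sags toward the spindle axis (poleward of the sister-sister segment)
  arc_points(s1, s2, sag, -radial_normal(s1, s2), n)
}

## ---- depletion ------------------------------------------------------------

#' Apply an augmin-depletion phenotype to a spindle model
#'
#' Scales per-class microtubule counts by the retained fraction and removes the
#' bridging fiber entirely from a randomly chosen fraction of pairs. The
#' default preset reproduces the augmin-depletion bookkeeping: bridging fibers
#' 3.8 -> 1.2 microtubules, k-fibers 12.6 -> 9.6, and 41\% of pairs left with
#' no bridging fiber at all.
#'
#' @param model a \code{spindle_model}.
#' @param retained named vector of retained-intensity fractions per fiber class.
#' @param bridging_removal_fraction fraction of bridged pairs whose bridging
#'   fiber is deleted outright (exactly \code{round(fraction * n)} pairs).
#' @param seed integer seed for the random choice of removed bridges.
#' @return The depleted \code{spindle_model} with updated ground truth.
#' @export
apply_depletion <- function(model,
                            retained = c(k_fiber = 9.6 / 12.6,
                                         bridging = 1.2 / 3.8,
                                         astral = 1,
                                         interpolar_no_kc = 1),
                            bridging_removal_fraction = 0.41,
                            seed = 1) {
  stopifnot(inherits(model, "spindle_model"))
  if (any(retained < 0 | retained > 1))
    stop("retained fractions must lie in [0, 1]")
  if (bridging_removal_fraction < 0 || bridging_removal_fraction > 1)
    stop("bridging_removal_fraction must lie in [0, 1]")
  retained_full <- model$depletion_factors
  retained_full[names(retained)] <- retained

  withr::with_seed(as.integer(seed), {
    for (i in seq_along(model$fibers)) {
      cls <- model$fibers[[i]]$fiber_class
      model$fibers[[i]]$mt_count <-
        model$fibers[[i]]$mt_count * retained_full[[cls]]
    }
    bridged <- which(model$truth_pairs$bridging)
    n_remove <- round(bridging_removal_fraction * length(bridged))
    if (n_remove > 0) {
      removed_pairs <- sort(sample(bridged, n_remove))
      keep <- vapply(model$fibers, function(f) {
        !(f$fiber_class == "bridging" && f$pair_id %in% removed_pairs)
      }, TRUE)
      model$fibers <- model$fibers[keep]
      model$prc1_segments <- Filter(function(s) !(s$pair_id %in% removed_pairs),
                                    model$prc1_segments)
      model$truth_pairs$bridging[removed_pairs] <- FALSE
    }
  })
  model$depletion_factors <- retained_full
  model$truth_fibers <- data.frame(
    fiber_id = vapply(model$fibers, `[[`, 0L, "fiber_id"),
    fiber_class = vapply(model$fibers, `[[`, "", "fiber_class"),
    mt_count = vapply(model$fibers, `[[`, 0, "mt_count"),
    pair_id = vapply(model$fibers, `[[`, 0L, "pair_id"),
    stringsAsFactors = FALSE)
  model
}

## ---- end-on phantom -------------------------------------------------------

#' Cross-section bundle phantom for end-on view analysis
#'
#' Builds a spindle model consisting of straight interpolar bundles running
#' parallel to the spindle (x) axis at given cross-section positions, each
#' carrying a PRC1-labeled overlap segment. Used to validate end-on re-slicing
#' and automated bundle counting against a planted bundle count.
#'
#' @param positions_yz n x 2 matrix of bundle (y, z) positions, um, relative to
#'   the spindle axis.
#' @param bundle_length bundle length along x, um.
#' @param mt_count microtubules per bundle.
#' @param prc1_brightness_per_um PRC1 line brightness, a.u./um.
#' @param jitter_sd_um positional jitter applied to the planted positions, um.
#' @param seed integer seed (used for jitter).
#' @return A \code{spindle_model} whose fibers are \code{interpolar_no_kc}
#'   bundles; planted positions are stored in \code{$truth_bundles}.
#' @export
make_end_on_phantom <- function(positions_yz, bundle_length = 4,
                                mt_count = 3.8,
                                prc1_brightness_per_um = 1000,
                                jitter_sd_um = 0.02, seed = 1) {
  positions_yz <- rbind_pts(positions_yz)
  withr::with_seed(as.integer(seed), {
    pos <- positions_yz +
      matrix(stats::rnorm(length(positions_yz), 0, jitter_sd_um),
             ncol = 2)
    fibers <- vector("list", nrow(pos))
    prc1 <- vector("list", nrow(pos))
    for (i in seq_len(nrow(pos))) {
      cl <- rbind(c(-bundle_length / 2, pos[i, 1], pos[i, 2]),
                  c( bundle_length / 2, pos[i, 1], pos[i, 2]))
      fibers[[i]] <- list(fiber_id = i, fiber_class = "interpolar_no_kc",
                          mt_count = mt_count, centerline = cl,
                          pair_id = NA_integer_)
      prc1[[i]] <- list(centerline = cl,
                        brightness_per_um = prc1_brightness_per_um,
                        pair_id = NA_integer_)
    }
    structure(list(
      poles = rbind(c(-bundle_length / 2 - 1, 0, 0),
                    c( bundle_length / 2 + 1, 0, 0)),
      sisters1 = matrix(numeric(0), 0, 3),
      sisters2 = matrix(numeric(0), 0, 3),
      fibers = fibers,
      prc1_segments = prc1,
      depletion_factors = c(k_fiber = 1, bridging = 1, astral = 1,
                            interpolar_no_kc = 1),
      truth_pairs = data.frame(),
      truth_fibers = data.frame(
        fiber_id = seq_len(nrow(pos)), fiber_class = "interpolar_no_kc",
        mt_count = mt_count, pair_id = NA_integer_),
      truth_bundles = data.frame(bundle_id = seq_len(nrow(pos)),
                                 y_um = pos[, 1], z_um = pos[, 2]),
      seed = as.integer(seed)
    ), class = "spindle_model")
  })
}

#' Evenly spaced positions on a ring
#'
#' Convenience layout for cross-section bundle phantoms.
#'
#' @param n number of positions.
#' @param radius ring radius, um.
#' @param phase angular offset, radians.
#' @return n x 2 matrix of (y, z) positions.
#' @export
ring_positions <- function(n, radius, phase = 0) {
  a <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(a), radius * sin(a))
}
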