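#' Classify a kinetochore pair's segregation behavior
#'
#' Applies the three-way segregation-error taxonomy to a pair's trajectories:
#' \describe{
#'   \item{misaligned}{both sisters lie outside the metaphase-plate slab 30 s
#'     before anaphase onset;}
#'   \item{lagging}{during anaphase one punctum's elongation (major/minor axis
#'     ratio, the operationalization of visibly stretched CENP-A) exceeds the
#'     stretch threshold while that sister sits in the central part of the
#'     spindle (middle third of the pole-to-pole span), outside the moving
#'     kinetochore masses;}
#'   \item{other}{remaining anomalies: pairs that never separate, or central
#'     non-stretched stragglers;}
#'   \item{none}{normal segregation.}
#' }
#' Precedence is misaligned > lagging > other. The 30 s look-back uses the
#' nearest acquired frame.
#'
#' @param pair_traj data.frame for one pair: columns frame, sister (1/2), x,
#'   y, z (um), elongation.
#' @param pole_traj data.frame for the poles: columns frame, sister (1/2 for
#'   the two poles) or pole id in \code{sister}, x, y, z.
#' @param onset 0-based anaphase onset frame.
#' @param dt frame interval, seconds.
#' @param plate_center,plate_half_thickness metaphase-plate slab (x-axis
#'   position and half thickness, um) at onset - 30 s; see
#'   \code{\link{estimate_plate}}.
#' @param stretch_threshold elongation above which a punctum counts as
#'   stretched.
#' @param lookback_s look-back time before onset for the misalignment test, s.
#' @param min_final_separation pairs whose sisters never exceed this distance
#'   (um) by the final frame count as unseparated ("other").
#' @return list of class \code{"error_record"}: \code{class},
#'   \code{missegregated}, \code{interkc_at_onset}, \code{tilt_at_onset}.
#' @export
classify_pair <- function(pair_traj, pole_traj, onset, dt,
                          plate_center, plate_half_thickness,
                          stretch_threshold = 1.5,
                          lookback_s = 30,
                          min_final_separation = 1.6) {
  if (is.null(pole_traj) || nrow(pole_traj) == 0)
    stop("incomplete input: missing pole track")
  frames <- sort(unique(pair_traj$frame))
  f_lb <- frames[which.min(abs(frames - (onset - lookback_s / dt)))]
  f_final <- max(frames)

  sis <- function(f, s) {
    r <- pair_traj[pair_traj$frame == f & pair_traj$sister == s, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  elong <- function(f, s)
    pair_traj$elongation[pair_traj$frame == f & pair_traj$sister == s][1]
  poles_at <- function(f) {
    r <- pole_traj[pole_traj$frame == f, ]
    r <- r[order(r$x), ]
    rbind(c(r$x[1], r$y[1], r$z[1]), c(r$x[2], r$y[2], r$z[2]))
  }

  # misaligned: both sisters outside the plate slab at onset - 30 s
  out_of_plate <- function(p) abs(p[1] - plate_center) > plate_half_thickness
  misaligned <- out_of_plate(sis(f_lb, 1)) && out_of_plate(sis(f_lb, 2))

  # lagging: stretched punctum in the central third during anaphase
  ana_frames <- frames[frames > onset]
  lagging <- FALSE
  for (f in ana_frames) {
    pl <- poles_at(f)
    span <- pl[2, 1] - pl[1, 1]
    ctr <- mean(pl[, 1])
    for (s in 1:2) {
      p <- sis(f, s)
      central <- abs(p[1] - ctr) < span / 6
      if (central && isTRUE(elong(f, s) > stretch_threshold)) lagging <- TRUE
    }
  }

  # other: never separates, or central non-stretched straggler at the end
  sep_final <- sqrt(sum((sis(f_final, 1) - sis(f_final, 2))^2))
  unseparated <- sep_final < min_final_separation
  pl_f <- poles_at(f_final)
  ctr_f <- mean(pl_f[, 1]); span_f <- pl_f[2, 1] - pl_f[1, 1]
  straggler <- any(vapply(1:2, function(s)
    abs(sis(f_final, s)[1] - ctr_f) < span_f / 6, TRUE))
  other <- unseparated || straggler

  cls <- if (misaligned) "misaligned" else if (lagging) "lagging"
         else if (other) "other" else "none"

  po <- poles_at(min(frames[frames >= onset]))
  s1o <- sis(onset, 1); s2o <- sis(onset, 2)
  interkc <- sqrt(sum((s2o - s1o)^2))
  u <- s2o - s1o; v <- po[2, ] - po[1, ]
  tilt <- if (sqrt(sum(u^2)) < 1e-12) NA_real_ else
    acos(pmin(1, abs(sum(u * v)) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))) * 180 / pi

  structure(list(class = cls,
                 missegregated = NA,
                 interkc_at_onset = interkc,
                 tilt_at_onset = tilt,
                 frame_lookback = f_lb),
            class = "error_record")
}

#' Estimate the metaphase-plate slab from kinetochore positions
#'
#' Plate center is the median axial (x) position of all kinetochores at the
#' look-back frame; the half thickness is a robust spread estimate
#' (2.5 median absolute deviations, floored at \code{min_half}).
#'
#' @param x_positions kinetochore x positions at onset - 30 s, um.
#' @param min_half minimum half thickness, um.
#' @return list(center, half_thickness).
#' @export
estimate_plate <- function(x_positions, min_half = 0.8) {
  ctr <- stats::median(x_positions)
  half <- max(min_half, 2.5 * stats::mad(x_positions))
  list(center = ctr, half_thickness = half)
}

#' Missegregation outcome of an erroneous pair
#'
#' For misaligned pairs: missegregated when both sisters end nearer the same
#' pole. For lagging pairs: missegregated when the stretched sister ends nearer
#' the pole opposite its pre-onset side. Equidistant endpoints are unresolved
#' (NA).
#'
#' @param final1,final2 final sister positions (um, length 3).
#' @param poles_final 2 x 3 matrix of final pole positions (ordered by x).
#' @param class "misaligned" or "lagging".
#' @param stretched_sister for lagging pairs, 1 or 2.
#' @param pre_onset_side for lagging pairs, which pole (1 or 2, row of
#'   \code{poles_final}) the stretched sister was on before onset.
#' @return logical flag (NA when unresolved).
#' @export
missegregation_outcome <- function(final1, final2, poles_final,
                                   class = c("misaligned", "lagging"),
                                   stretched_sister = NULL,
                                   pre_onset_side = NULL) {
  class <- match.arg(class)
  poles_final <- rbind_pts(poles_final)
  nearer <- function(p) {
    d1 <- sqrt(sum((p - poles_final[1, ])^2))
    d2 <- sqrt(sum((p - poles_final[2, ])^2))
    if (isTRUE(all.equal(d1, d2))) return(NA_integer_)
    if (d1 < d2) 1L else 2L
  }
  if (class == "misaligned") {
    n1 <- nearer(final1); n2 <- nearer(final2)
    if (is.na(n1) || is.na(n2)) return(NA)
    return(n1 == n2)
  }
  if (is.null(stretched_sister) || is.null(pre_onset_side))
    stop("lagging outcome needs stretched_sister and pre_onset_side")
  p <- if (stretched_sister == 1) final1 else final2
  np <- nearer(p)
  if (is.na(np)) return(NA)
  np != pre_onset_side
}

#' Census of segregation errors across cells
#'
#' Aggregates per-pair error records: mean and SEM of errors per cell, error
#' counts by class, missegregation fractions by class, and inner/outer
#' fractions among errors.
#'
#' @param records data.frame with columns \code{cell_id}, \code{class}
#'   ("misaligned"/"lagging"/"other"/"none"), optional \code{missegregated}
#'   (logical) and \code{region} ("inner"/"outer").
#' @return list with \code{errors_per_cell} (mean, sem, per-cell counts),
#'   \code{by_class} counts, \code{fraction_missegregating} by class, and
#'   \code{region_fractions} by class.
#' @export
error_census <- function(records) {
  stopifnot(nrow(records) >= 1)
  is_err <- records$class != "none"
  cells <- unique(records$cell_id)
  per_cell <- vapply(cells, function(cl)
    sum(is_err & records$cell_id == cl), 0)
  m <- mean(per_cell)
  sem <- if (length(per_cell) > 1) stats::sd(per_cell) / sqrt(length(per_cell))
         else 0
  by_class <- table(factor(records$class[is_err],
                           levels = c("misaligned", "lagging", "other")))
  frac_misseg <- NULL
  if (!is.null(records$missegregated)) {
    frac_misseg <- vapply(c("misaligned", "lagging"), function(cl) {
      sel <- records$class == cl & !is.na(records$missegregated)
      if (!any(sel)) return(NA_real_)
      mean(records$missegregated[sel])
    }, 0)
  }
  region_frac <- NULL
  if (!is.null(records$region)) {
    region_frac <- vapply(c("misaligned", "lagging", "other"), function(cl) {
      sel <- is_err & records$class == cl & !is.na(records$region)
      if (!any(sel)) return(NA_real_)
      mean(records$region[sel] == "inner")
    }, 0)
  }
  list(errors_per_cell = list(mean = m, sem = sem, per_cell = per_cell),
       by_class = by_class,
       fraction_missegregating = frac_misseg,
       region_fractions_inner = region_frac)
}
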