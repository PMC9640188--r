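# shared scene builders for the test suite

# empty planar model shell (no fibers/kinetochores) to hang structures on
bare_model <- function(seed = 1, spindle_length = 6) {
  m <- make_spindle_model(n_pairs = 1, spindle_length = spindle_length,
                          spindle_width = 2, n_astral = 0, seed = seed)
  m$fibers <- list()
  m$prc1_segments <- list()
  m$sisters1 <- matrix(numeric(0), 0, 3)
  m$sisters2 <- matrix(numeric(0), 0, 3)
  m
}

straight_fiber <- function(mt, y, x_half = 3, z = 0, class = "k_fiber") {
  list(fiber_id = 1L, fiber_class = class, mt_count = mt,
       centerline = rbind(c(-x_half, y, z), c(x_half, y, z)),
       pair_id = NA_integer_)
}

# render a single sister pair (kinetochore channel only) at given half-offset
render_pair <- function(dvec, optics, seed = 1, noise = TRUE) {
  m <- bare_model(seed)
  m$sisters1 <- matrix(-dvec, 1, 3)
  m$sisters2 <- matrix(dvec, 1, 3)
  list(model = m,
       stack = render(m, optics, seed = seed, noise = noise,
                      channels = "kinetochore"))
}

# measure a rendered pair: joint PSF fit, then 3D distance with correction
measured_pair_separation <- function(dvec, optics, seed, noise = TRUE) {
  rp <- render_pair(dvec, optics, seed = seed, noise = noise)
  st <- rp$stack
  idx <- world_to_index(st, rbind(-dvec, dvec))
  lp <- localize_pair(st, "kinetochore", idx[1, ], idx[2, ], optics)
  corrected_displacement(c(lp$p1[2], lp$p1[1], lp$p1[3]),
                         c(lp$p2[2], lp$p2[1], lp$p2[3]),
                         st$pixel_size_xy, st$z_step, st$axial_scale)
}

measured_pair_tilt <- function(dvec, optics, seed, noise = TRUE) {
  rp <- render_pair(dvec, optics, seed = seed, noise = noise)
  st <- rp$stack
  idx <- world_to_index(st, rbind(-dvec, dvec))
  lp <- localize_pair(st, "kinetochore", idx[1, ], idx[2, ], optics)
  pidx <- world_to_index(st, rp$model$poles)
  kinetochore_tilt(c(lp$p1[2], lp$p1[1], lp$p1[3]),
                   c(lp$p2[2], lp$p2[1], lp$p2[3]),
                   cbind(pidx[, 2], pidx[, 1], pidx[, 3]),
                   st$pixel_size_xy, st$z_step, st$axial_scale)
}

# unit vector at polar angle theta (from x axis) and azimuth phi
dir_vec <- function(theta_deg, phi) {
  th <- theta_deg * pi / 180
  c(cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
}

# planted anaphase cell used by classification tests
planted_anaphase <- function(n_pairs = 40, seed = 7,
                             error_spec = NULL, n_frames = 16) {
  m <- make_spindle_model(n_pairs = n_pairs, spindle_length = 10,
                          spindle_width = 6, n_astral = 0,
                          plate_sd_um = 0.2, seed = seed)
  make_anaphase_timelapse(m, error_spec = error_spec,
                          kinetics = list(anaphase_A_speed = 1.2,
                                          anaphase_B_speed = 0.8,
                                          onset_frame = 3),
                          n_frames = n_frames, dt = 30, seed = seed)
}

# run the full classifier over a trajectory set, returns classes per pair
classify_all <- function(tl) {
  traj <- tl$trajectories
  onset <- attr(traj, "onset_frame")
  dt <- attr(traj, "dt")
  poles <- traj[traj$object == "pole", ]
  kcs <- traj[traj$object == "kinetochore", ]
  f_lb_target <- onset - 30 / dt
  frames <- sort(unique(traj$frame))
  f_lb <- frames[which.min(abs(frames - f_lb_target))]
  plate <- estimate_plate(kcs$x[kcs$frame == f_lb])
  vapply(sort(unique(kcs$pair_id)), function(pid) {
    classify_pair(kcs[kcs$pair_id == pid, ], poles, onset, dt,
                  plate$center, plate$half_thickness)$class
  }, "")
}
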