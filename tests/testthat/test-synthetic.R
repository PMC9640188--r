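test_that("spindle models are deterministic in the seed and respect geometry", {
  m1 <- make_spindle_model(n_pairs = 8, seed = 11)
  m2 <- make_spindle_model(n_pairs = 8, seed = 11)
  expect_identical(m1$sisters1, m2$sisters1)
  expect_identical(m1$poles, m2$poles)
  expect_identical(ground_truth(m1), ground_truth(m2))
  m3 <- make_spindle_model(n_pairs = 8, seed = 12)
  expect_false(isTRUE(all.equal(m1$sisters1, m3$sisters1)))

  # zero tilt spread: sister axes parallel to the pole axis
  mz <- make_spindle_model(n_pairs = 1, tilt_spread_deg = 0, seed = 3)
  expect_equal(ground_truth(mz)$pairs$tilt_deg, 0)
  d <- mz$sisters2[1, ] - mz$sisters1[1, ]
  expect_equal(abs(d[1]) / sqrt(sum(d^2)), 1, tolerance = 1e-12)

  # mt counts recorded exactly as planted
  gt <- ground_truth(m1)$fibers
  expect_setequal(unique(gt$mt_count[gt$fiber_class == "k_fiber"]), 12.6)
  expect_setequal(unique(gt$mt_count[gt$fiber_class == "bridging"]), 3.8)
  expect_setequal(unique(gt$mt_count[gt$fiber_class == "astral"]), 1.0)

  expect_error(make_spindle_model(n_pairs = 2, spindle_length = -1),
               "positive")
  expect_error(make_spindle_model(n_pairs = 2, spindle_length = 0.5,
                                  mean_separation = 0.98), "exceed")
})

test_that("depletion scales counts and removes the stated fraction of bridges", {
  m <- make_spindle_model(n_pairs = 100, bridging_fraction = 1, seed = 5)
  # identity depletion leaves the model unchanged
  same <- apply_depletion(m, retained = c(k_fiber = 1, bridging = 1,
                                          astral = 1, interpolar_no_kc = 1),
                          bridging_removal_fraction = 0, seed = 1)
  expect_equal(ground_truth(same)$fibers, ground_truth(m)$fibers)

  dep <- apply_depletion(m, bridging_removal_fraction = 0.41, seed = 2)
  gt <- ground_truth(dep)$fibers
  expect_equal(unique(gt$mt_count[gt$fiber_class == "bridging"]), 1.2,
               tolerance = 1e-12)
  expect_equal(unique(gt$mt_count[gt$fiber_class == "k_fiber"]), 9.6,
               tolerance = 1e-12)
  # exactly 41 of 100 pairs lose their bridging fiber
  expect_equal(sum(!ground_truth(dep)$pairs$bridging), 41)
  expect_equal(sum(gt$fiber_class == "bridging"), 59)
})

test_that("rendering is photometrically linear in microtubule count", {
  op <- optics_params("confocal")
  m <- bare_model()
  m$fibers <- list(straight_fiber(12.6, 0), straight_fiber(3.8, 2))
  m$fibers[[2]]$fiber_id <- 2L
  st <- render(m, op, seed = 1, noise = FALSE, channels = "tubulin")
  i1 <- measure_square_roi(st, "tubulin",
                           round(world_to_index(st, c(0, 0, 0))), 5)
  i2 <- measure_square_roi(st, "tubulin",
                           round(world_to_index(st, c(0, 2, 0))), 5)
  bg <- op$background_level
  expect_equal((i2 - bg) / (i1 - bg), 3.8 / 12.6, tolerance = 0.02)
})

test_that("empty noiseless render is uniform background", {
  op <- optics_params("confocal")
  m <- bare_model()
  st <- render(m, op, shape = c(120, 120, 6), seed = 1, noise = FALSE,
               channels = "tubulin")
  expect_true(all(st$channels$tubulin == op$background_level))
})

test_that("axial placement encodes true z so the 0.81 correction round-trips", {
  op <- optics_params("confocal")  # z step 0.5, axial scale 0.81
  m <- bare_model()
  m$sisters1 <- matrix(c(0, 0, 0), 1)
  m$sisters2 <- matrix(c(0, 0, 1), 1)   # 1 um apart in true z only
  st <- render(m, op, seed = 1, noise = FALSE, channels = "kinetochore")
  idx <- world_to_index(st, rbind(c(0, 0, 0), c(0, 0, 1)))
  lp <- localize_pair(st, "kinetochore", idx[1, ], idx[2, ], op)
  dplanes <- unname(lp$p2[3] - lp$p1[3])
  expect_equal(dplanes, 1 / (0.81 * 0.5), tolerance = 0.02)  # 2.469 planes
  # axial round-trip: plane difference x z_step x axial_scale = true dz
  expect_lt(abs(dplanes * 0.5 * 0.81 - 1.0), 0.5 * 0.5 * 0.81)
})

test_that("renders are reproducible for a fixed seed", {
  op <- optics_params("confocal")
  m <- make_spindle_model(n_pairs = 2, spindle_length = 5, spindle_width = 2,
                          seed = 4)
  s1 <- render(m, op, seed = 9, channels = "tubulin")
  s2 <- render(m, op, seed = 9, channels = "tubulin")
  expect_identical(s1$channels$tubulin, s2$channels$tubulin)
  s3 <- render(m, op, seed = 10, channels = "tubulin")
  expect_false(identical(s1$channels$tubulin, s3$channels$tubulin))
})

test_that("render rejects volumes that cannot hold the model", {
  op <- optics_params("confocal")
  m <- make_spindle_model(n_pairs = 2, seed = 1)
  expect_error(render(m, op, shape = c(10, 10, 2)), "bounding box")
})

test_that("anaphase time-lapse plants labels and kinetics as stated", {
  spec <- data.frame(pair_id = c(2, 5, 9, 13, 30),
                     class = c("lagging", "lagging", "lagging",
                               "misaligned", "misaligned"),
                     missegregates = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  tl <- planted_anaphase(n_pairs = 40, error_spec = spec, seed = 21)
  expect_equal(sum(tl$truth$error_class == "lagging"), 3)
  expect_equal(sum(tl$truth$error_class == "misaligned"), 2)
  expect_equal(which(tl$truth$error_class != "none"), c(2, 5, 9, 13, 30))

  traj <- tl$trajectories
  onset <- attr(traj, "onset_frame")
  dt <- attr(traj, "dt")
  # noiseless anaphase A: kinetochore-pole approach slope equals planted speed
  kc <- traj[traj$object == "kinetochore" & traj$pair_id == 1 &
               traj$sister == 1, ]
  po <- traj[traj$object == "pole", ]
  d <- vapply(kc$frame, function(f) {
    p <- po[po$frame == f, ]
    p <- p[order(p$x), ]
    sqrt(sum((c(kc$x[kc$frame == f], kc$y[kc$frame == f],
                kc$z[kc$frame == f]) - c(p$x[1], p$y[1], p$z[1]))^2))
  }, 0)
  post <- kc$frame > onset & kc$frame <= onset + 4
  rate <- linear_rate(kc$time_s[post], d[post], "kc_pole")
  expect_equal(rate$slope, 1.2, tolerance = 1e-6)

  # interkinetochore distance non-decreasing after onset for separated pairs
  s1 <- traj[traj$object == "kinetochore" & traj$pair_id == 1 &
               traj$sister == 1, ]
  s2 <- traj[traj$object == "kinetochore" & traj$pair_id == 1 &
               traj$sister == 2, ]
  dk <- sqrt((s1$x - s2$x)^2 + (s1$y - s2$y)^2 + (s1$z - s2$z)^2)
  expect_true(all(diff(dk[s1$frame >= onset]) >= -1e-9))

  expect_error(make_anaphase_timelapse(
    make_spindle_model(2, seed = 1), dt = -1), "dt")
})

test_that("photoactivation series moves the mark at the planted flux speed", {
  op <- optics_params("confocal")
  ser <- make_photoactivation_series(flux_speed = 1.0, dt = 10, n_frames = 6,
                                     noise = FALSE, optics = op, seed = 1)
  # 1 um/min at 10 s spacing: 1/6 um per frame
  expect_equal(diff(ser$truth$mark_x_um), rep(1 / 6, 5), tolerance = 1e-9)

  ser0 <- make_photoactivation_series(flux_speed = 0, dt = 10, n_frames = 6,
                                      noise = FALSE, optics = op, seed = 1)
  expect_equal(diff(ser0$truth$mark_pole_um), rep(0, 5))

  sa <- make_photoactivation_series(seed = 3, optics = op)
  sb <- make_photoactivation_series(seed = 3, optics = op)
  expect_identical(sa$photo, sb$photo)
})
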