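make_flat_stack <- function(value, d = c(40, 40, 3)) {
  image_stack(array(value, d), pixel_size_xy = 0.1, z_step = 0.5)
}

test_that("square ROI means match hand counts and a pixel-loop oracle", {
  st <- make_flat_stack(7)
  expect_equal(measure_square_roi(st, 1, c(20, 20, 2), 5), 7)
  expect_equal(measure_square_roi(st, 1, c(20, 20, 2), 25), 7)

  # checkerboard with 13 ones in a 5x5 block
  img <- array(0, c(9, 9, 1))
  img[, , 1] <- outer(1:9, 1:9, function(i, j) (i + j) %% 2 == 0) * 1
  st2 <- image_stack(img, 0.1, 0.5)
  expect_equal(sum(img[3:7, 3:7, 1]), 13)
  expect_equal(measure_square_roi(st2, 1, c(5, 5, 1), 5), 13 / 25)

  # pixel-loop oracle on a rendered noiseless fiber
  op <- optics_params("confocal")
  m <- bare_model()
  m$fibers <- list(straight_fiber(12.6, 0))
  str <- render(m, op, seed = 1, noise = FALSE, channels = "tubulin")
  ctr <- round(world_to_index(str, c(0, 0, 0)))
  loop_mean <- {
    acc <- 0
    for (r in (ctr[1] - 2):(ctr[1] + 2))
      for (cc in (ctr[2] - 2):(ctr[2] + 2))
        acc <- acc + str$channels$tubulin[r, cc, ctr[3]]
    acc / 25
  }
  expect_equal(measure_square_roi(str, "tubulin", ctr, 5), loop_mean,
               tolerance = 1e-12)

  expect_error(measure_square_roi(st, 1, c(1, 1, 1), 5), "border")
})

test_that("background averaging and strict modality counts behave as specified", {
  st <- make_flat_stack(4)
  pts <- cbind(sample(10:30, 10), sample(10:30, 10), 2)
  expect_equal(background_square(st, 1, pts, 5), 4)

  # two ROIs with means 10 and 14 average to 12
  img <- array(10, c(20, 40, 1)); img[, 21:40, 1] <- 14
  st2 <- image_stack(img, 0.1, 0.5)
  expect_equal(background_square(st2, 1, rbind(c(10, 10, 1), c(10, 30, 1)), 5),
               12)

  expect_error(background_square(st, 1, matrix(numeric(0), 0, 3), 5),
               "at least one")
  expect_error(background_square(st, 1, pts[1:3, ], 5,
                                 strict_modality = "sted"), "10")
  expect_silent(background_square(st, 1, pts, 5, strict_modality = "sted"))
})

test_that("corrected intensities follow the subtraction rules", {
  expect_equal(corrected_fiber_intensity(bridging_raw = 50,
                                         background = 20)$I_b, 30)
  out <- corrected_fiber_intensity(k_raw = c(90, 110), background = 20)
  expect_equal(out$I_k, 80)
  expect_equal(corrected_fiber_intensity(bridging_raw = 20,
                                         background = 20)$I_b, 0)
  expect_equal(corrected_fiber_intensity(astral_raw = 7,
                                         background = 5)$I_a, 2)
  expect_error(corrected_fiber_intensity(k_raw = 90, background = 20),
               "two sister")
})

test_that("line-profile scheme recovers constructed and quadrature values", {
  # plateau 100 with central dip to 40, zero background
  s <- seq(0, 6, by = 0.01)
  v <- ifelse(abs(s - 3) < 0.4, 40, 100)
  pm <- line_profile_method(profile = data.frame(arclength = s, intensity = v),
                            midzone_profile = data.frame(arclength = s,
                                                         intensity = 0))
  expect_equal(pm$I_b, 40)
  expect_equal(pm$I_bk, 100)
  expect_equal(pm$I_k, 60)
  expect_equal(pm$bridge_center, 3, tolerance = 0.05)

  # flat profile: degenerate center warning and I_k = 0
  expect_warning(
    pf <- line_profile_method(
      profile = data.frame(arclength = s, intensity = rep(5, length(s))),
      midzone_profile = data.frame(arclength = s, intensity = 0)),
    "degenerate")
  expect_equal(pf$I_k, 0)

  # windows against a quadrature oracle on an analytic profile
  f <- function(x) 100 - 55 * exp(-0.5 * ((x - 3) / 0.6)^2)
  pm2 <- line_profile_method(
    profile = data.frame(arclength = s, intensity = f(s)),
    midzone_profile = data.frame(arclength = s, intensity = 0))
  I_b_oracle <- stats::integrate(f, 2.75, 3.25)$value / 0.5
  I_bk_oracle <- (stats::integrate(f, 1.25, 1.75)$value +
                  stats::integrate(f, 4.25, 4.75)$value) / 1
  expect_equal(pm2$I_b, I_b_oracle, tolerance = 0.01)
  expect_equal(pm2$I_bk, I_bk_oracle, tolerance = 0.01)

  expect_error(line_profile_method(
    profile = data.frame(arclength = s[s < 2], intensity = v[s < 2]),
    midzone_profile = NULL), "invalid geometry")
})

test_that("microtubule-number estimator is the calibrated intensity ratio", {
  expect_equal(estimate_mt_number(30, 100), 3.78)
  expect_equal(estimate_mt_number(100, 100), 12.6)
  expect_equal(estimate_mt_number(0, 50), 0)
  expect_error(estimate_mt_number(10, 0), "calibration")
  expect_error(estimate_mt_number(10, -3), "calibration")
})

test_that("microtubule-count estimates are invariant to intensity rescaling", {
  set.seed(1)
  I_b <- runif(20, 5, 50); I_k <- runif(20, 60, 120)
  for (gam in c(0.01, 1, 37.5)) {
    expect_equal(estimate_mt_number(gam * I_b, gam * I_k),
                 estimate_mt_number(I_b, I_k), tolerance = 1e-12)
  }
  # the full ROI pipeline is scale invariant too: scaling the stack scales
  # raw and background alike
  op <- optics_params("sted")
  m <- make_calibration_scene(seed = 2, bridging = TRUE)
  st <- render(m, op, seed = 2, noise = FALSE, channels = "tubulin")
  st2 <- st
  st2$channels$tubulin <- 3.7 * st2$channels$tubulin
  m1 <- measure_spindle_fibers(st, m, op, seed = 1)
  m2 <- measure_spindle_fibers(st2, m, op, seed = 1)
  expect_equal(m2$pairs$n_b, m1$pairs$n_b, tolerance = 1e-9)
  expect_equal(m2$astral$n_a, m1$astral$n_a, tolerance = 1e-9)
})

test_that("bridging detection is strict and matches planted absence rates", {
  expect_false(detect_bridging(-3))
  expect_false(detect_bridging(0))
  expect_true(detect_bridging(0.001))
  expect_true(detect_bridging(1, sigma_bcg = 0.4, k_sigma = 2))
  expect_false(detect_bridging(0.7, sigma_bcg = 0.4, k_sigma = 2))
})

test_that("noiseless recovery of planted counts is within 5 percent per class", {
  op <- optics_params("sted")
  m <- make_calibration_scene(seed = 3, bridging = TRUE)
  st <- render(m, op, seed = 3, noise = FALSE, channels = "tubulin")
  meas <- measure_spindle_fibers(st, m, op, seed = 3)
  expect_equal(meas$pairs$n_b, 3.8, tolerance = 0.05)
  expect_equal(mean(meas$astral$n_a), 1.0, tolerance = 0.05)
})

test_that("square-ROI and line-profile bridging intensities agree on phantoms", {
  # straight-fiber phantom: two k-fibers flanking a dimmer bridge, noiseless
  op <- optics_params("confocal")
  m <- bare_model()
  m$fibers <- list(
    straight_fiber(3.8, 0, x_half = 0.49),
    list(fiber_id = 2L, fiber_class = "k_fiber", mt_count = 12.6 + 3.8,
         centerline = rbind(c(-2.5, 0, 0), c(-0.49, 0, 0)), pair_id = 1L),
    list(fiber_id = 3L, fiber_class = "k_fiber", mt_count = 12.6 + 3.8,
         centerline = rbind(c(0.49, 0, 0), c(2.5, 0, 0)), pair_id = 1L))
  st <- render(m, op, seed = 1, noise = FALSE, channels = "tubulin")
  ctr <- round(world_to_index(st, c(0, 0, 0)))
  I_b_roi <- measure_square_roi(st, "tubulin", ctr, 5) - op$background_level

  z <- ctr[3]
  contour <- rbind(c(-2.3 - st$origin[1], -st$origin[2]),
                   c(2.3 - st$origin[1], -st$origin[2]))
  midzone <- rbind(c(-st$origin[1], 0.8 - st$origin[2]),
                   c(-st$origin[1] + 0.01, 1.6 - st$origin[2]))
  pm <- line_profile_method(st, "tubulin", contour, z, midzone)
  expect_equal(pm$I_b, I_b_roi, tolerance = 0.1)
})

test_that("depletion bookkeeping reproduces the published reductions", {
  # forward: counts 3.8 -> 1.2 and 12.6 -> 9.6 give 68% and 24%
  ctrl <- data.frame(fiber_class = c("bridging", "k_fiber"),
                     n_mt = c(3.8, 12.6))
  depl <- data.frame(fiber_class = c("bridging", "k_fiber"),
                     n_mt = c(1.2, 9.6))
  s <- depletion_summary(ctrl, depl)
  expect_equal(round(s$percent_reduction[s$fiber_class == "bridging"]), 68)
  expect_equal(round(s$percent_reduction[s$fiber_class == "k_fiber"]), 24)
  expect_equal(s$n_augmin[s$fiber_class == "bridging"], 2.6)
  expect_equal(s$n_augmin[s$fiber_class == "k_fiber"], 3.0)

  # identical lists: zero reduction
  s0 <- depletion_summary(ctrl, ctrl)
  expect_equal(s0$percent_reduction, c(0, 0))

  # reverse: from the printed percent reductions back to remaining counts
  bb <- depletion_bookkeeping(3.8, percent_reduction = 68)
  expect_equal(round(bb$n_remaining, 1), 1.2)
  expect_equal(round(bb$n_augmin, 1), 2.6)
  bk <- depletion_bookkeeping(12.6, percent_reduction = 24)
  expect_equal(round(bk$n_remaining, 1), 9.6)
  expect_equal(round(bk$n_augmin, 1), 3.0)
  expect_error(depletion_bookkeeping(0, percent_reduction = 50), "control")
})
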