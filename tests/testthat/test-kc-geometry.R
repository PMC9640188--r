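test_that("corrected displacement follows the scaled Pythagorean rule", {
  # 3-4-5 in plane
  expect_equal(corrected_displacement(c(0, 0, 0), c(6, 8, 0), 0.1, 0.5, 0.81),
               1.0)
  # axial only: 4 planes x 0.5 x 0.81
  expect_equal(corrected_displacement(c(0, 0, 0), c(0, 0, 4), 0.1, 0.5, 0.81),
               1.62)
  # axial_scale 1 reduces to Euclidean distance
  p1 <- c(3, 7, 2); p2 <- c(9, 1, 5)
  expect_equal(corrected_displacement(p1, p2, 0.2, 0.2, 1),
               sqrt(sum(((p2 - p1) * 0.2)^2)))
})

test_that("corrected displacement is a metric", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(3, 0, 20); b <- runif(3, 0, 20); cc <- runif(3, 0, 20)
    d <- function(x, y) corrected_displacement(x, y, 0.1, 0.4, 0.81)
    expect_equal(d(a, b), d(b, a))
    expect_gte(d(a, b) + d(b, cc) - d(a, cc), -1e-12)
    expect_equal(d(a, a), 0)
  }
})

test_that("interkinetochore distance handles modes, frames and degeneracy", {
  expect_equal(interkinetochore_distance(c(0, 0, 2), c(6, 8, 2), 0.1, 0.5),
               1.0)
  # 2D mode equals 3D mode for a same-plane pair
  expect_equal(interkinetochore_distance(c(0, 0, 2), c(6, 8, 2), 0.1, 0.5,
                                         mode = "2d"),
               interkinetochore_distance(c(0, 0, 2), c(6, 8, 2), 0.1, 0.5))
  expect_warning(interkinetochore_distance(c(1, 1, 1), c(1, 1, 1), 0.1, 0.5),
                 "degenerate")
  expect_error(interkinetochore_distance(c(0, 0, 0), c(1, 1, 0), 0.1, 0.5,
                                         frame1 = 1, frame2 = 2), "pairing")
})

test_that("axis distance decomposes into in-plane and axial components", {
  poles <- rbind(c(0, 0, 5), c(100, 0, 5))
  # a = 3 (30 px at 0.1), b = 4 (plane offset 9.876… not needed: construct)
  ad <- axis_distance(c(50, 30, 5 + 4 / (0.5 * 0.81)), poles, 0.1, 0.5, 0.81)
  expect_equal(ad$a, 3)
  expect_equal(ad$b, 4)
  expect_equal(ad$c, 5)
  # on-axis midpoint in the central plane
  ad0 <- axis_distance(c(50, 0, 5), poles, 0.1, 0.5, 0.81)
  expect_equal(ad0$c, 0)
  expect_error(axis_distance(c(1, 1, 1), rbind(c(2, 2, 2), c(2, 2, 2)),
                             0.1, 0.5), "degenerate")

  # randomized horizontal-spindle configurations vs a 3D point-line oracle
  set.seed(13)
  for (i in 1:25) {
    poles <- rbind(c(runif(2, 0, 50), 7), c(runif(2, 50, 100), 7))
    mid <- c(runif(2, 0, 100), runif(1, 1, 13))
    ad <- axis_distance(mid, poles, 0.1, 0.5, 0.81)
    # oracle: full 3D distance from the scaled point to the scaled axis line
    sc <- function(p) c(p[1] * 0.1, p[2] * 0.1, p[3] * 0.5 * 0.81)
    x0 <- sc(mid); a3 <- sc(poles[1, ]); b3 <- sc(poles[2, ])
    v <- b3 - a3
    dist3 <- sqrt(sum((x0 - a3 - sum((x0 - a3) * v) / sum(v^2) * v)^2))
    expect_equal(ad$c, dist3, tolerance = 1e-9)
  }
})

test_that("metaphase region split uses the cell mean with outer ties", {
  expect_equal(classify_region_metaphase(c(1, 3)), c("inner", "outer"))
  expect_equal(classify_region_metaphase(rep(2, 5)), rep("outer", 5))
  expect_error(classify_region_metaphase(1.5), "refused")

  set.seed(4)
  cv <- runif(100, 0, 5)
  got <- classify_region_metaphase(cv)
  expect_equal(got, ifelse(cv < mean(cv), "inner", "outer"))

  # invariance under global translation of coordinates: distances unchanged
  poles <- rbind(c(0, 0, 5), c(80, 0, 5))
  mids <- cbind(runif(10, 10, 70), runif(10, -20, 20), runif(10, 2, 8))
  cs <- apply(mids, 1, function(m)
    axis_distance(m, poles, 0.1, 0.5, 0.81)$c)
  shift <- c(11, -7, 0)
  cs2 <- apply(sweep(mids, 2, -shift), 1, function(m)
    axis_distance(m, sweep(poles, 2, -shift), 0.1, 0.5, 0.81)$c)
  expect_equal(classify_region_metaphase(cs2), classify_region_metaphase(cs))
})

test_that("anaphase region split uses the normalized 0.5 threshold", {
  expect_equal(classify_region_anaphase(1, 4), "inner")
  expect_equal(classify_region_anaphase(2, 4), "outer")  # boundary is outer
  expect_equal(classify_region_anaphase(5, 4), "outer")
  expect_error(classify_region_anaphase(1, 0), "half-width")
})

test_that("tilt matches closed forms and is invariant to relabeling/rotation", {
  poles <- rbind(c(0, 0, 0), c(10, 0, 0))
  px <- 1; zs <- 1; ax <- 1
  expect_equal(kinetochore_tilt(c(0, 0, 0), c(2, 0, 0), poles, px, zs, ax), 0)
  expect_equal(kinetochore_tilt(c(0, 0, 0), c(0, 2, 0), poles, px, zs, ax), 90)
  expect_equal(kinetochore_tilt(c(0, 0, 0), c(1, 1, 0), poles, px, zs, ax), 45)
  # sister relabeling
  expect_equal(kinetochore_tilt(c(1, 1, 0), c(0, 0, 0), poles, px, zs, ax), 45)
  # joint rigid rotation (in-plane, isotropic calibration)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(p) c(R %*% p[1:2], p[3])
  expect_equal(
    kinetochore_tilt(rot(c(0, 0, 0)), rot(c(1, 1, 0)),
                     t(apply(poles, 1, rot)), px, zs, ax), 45)
  expect_error(kinetochore_tilt(c(1, 1, 1), c(1, 1, 1), poles, px, zs, ax),
               "degenerate")
})

test_that("spindle dimensions come straight from the annotations", {
  sd_ <- spindle_dimensions(rbind(c(-6, 0), c(6, 0)),
                            bounding_offsets = c(-4, 4),
                            plate_points = rbind(c(0, -3.5), c(0, 3.5)))
  expect_equal(sd_$length, 12)
  expect_equal(sd_$width, 8)
  expect_equal(sd_$plate_diameter, 7)
  expect_error(spindle_dimensions(matrix(c(0, 0), 1, 2)), "incomplete")
})

test_that("separation and tilt recover planted truth on rendered pairs", {
  op <- optics_params("confocal")
  seps <- c(); tilts <- c()
  set.seed(31)
  for (i in 1:12) {
    phi <- runif(1, 0, 2 * pi)
    theta <- runif(1, 0, 90)
    dv <- 0.98 / 2 * dir_vec(theta, phi)
    seps <- c(seps, measured_pair_separation(dv, op, seed = i))
    dv2 <- 0.98 / 2 * dir_vec(19.7, phi)
    tilts <- c(tilts, measured_pair_tilt(dv2, op, seed = i + 100))
  }
  expect_lt(mean(abs(seps - 0.98)), 0.03)
  expect_lt(abs(mean(tilts) - 19.7), 2)
})
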