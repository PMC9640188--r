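test_that("end-on transform is the quoted axis permutation for a point", {
  vol <- array(0, c(6, 8, 5))
  vol[3, 5, 2] <- 1  # (row i, col j, plane k)
  st <- image_stack(vol, pixel_size_xy = 0.1, z_step = 0.1, axial_scale = 1)
  eo <- rotate_to_end_on(st, 1, interpolation = "nearest")
  # isotropic voxels + axial_scale 1: pure permutation, I'(i, k, j) = I(i, j, k)
  expect_equal(dim(eo$volume), c(6, 5, 8))
  expect_equal(eo$volume[3, 2, 5], 1)
  expect_equal(sum(eo$volume), 1)  # intensity conserved exactly
})

test_that("permutation case conserves intensity exactly with nearest", {
  set.seed(2)
  vol <- array(runif(6 * 8 * 5), c(6, 8, 5))
  st <- image_stack(vol, 0.1, 0.1, axial_scale = 1)
  eo <- rotate_to_end_on(st, 1, interpolation = "nearest")
  expect_equal(sum(eo$volume), sum(vol), tolerance = 1e-12)
  for (k in 1:5) expect_equal(eo$volume[, k, ], vol[, , k])
})

test_that("transform round-trip reproduces a smooth phantom within 1% RMS", {
  # band-limited phantom: sum of broad 3D Gaussians, anisotropic sampling
  px <- 0.1; zs <- 0.3; ax <- 0.81
  ny <- 40; nx <- 40; nz <- 30
  y <- (1:ny - 0.5) * px; x <- (1:nx - 0.5) * px; z <- (1:nz - 0.5) * zs * ax
  vol <- array(0, c(ny, nx, nz))
  for (ctr in list(c(2, 2, 3.2), c(1.4, 2.6, 4.5))) {
    g <- outer(exp(-0.5 * ((y - ctr[1]) / 0.6)^2),
               exp(-0.5 * ((x - ctr[2]) / 0.6)^2))
    for (k in 1:nz)
      vol[, , k] <- vol[, , k] + g * exp(-0.5 * ((z[k] - ctr[3]) / 0.9)^2)
  }
  st <- image_stack(vol, px, zs, axial_scale = ax)
  eo <- rotate_to_end_on(st, 1, interpolation = "linear")
  back <- end_on_inverse(eo, interpolation = "linear")
  rms <- sqrt(mean((back - vol)^2)) / sqrt(mean(vol^2))
  expect_lt(rms, 0.01)
})

test_that("sum projection equals a loop-accumulation oracle", {
  set.seed(5)
  vol <- array(runif(10 * 12 * 7), c(10, 12, 7))
  # two identical slices of value 3 sum to 6
  v3 <- array(3, c(4, 4, 2))
  expect_equal(sum_projection(v3, 1:2), matrix(6, 4, 4))
  # single-slice range is the identity
  expect_equal(sum_projection(vol, 4), vol[, , 4])
  # arbitrary range vs explicit loop
  oracle <- matrix(0, 10, 12)
  for (k in 2:6) oracle <- oracle + vol[, , k]
  expect_identical(sum_projection(vol, 2:6), oracle)
  expect_error(sum_projection(vol, integer(0)), "empty")
  expect_error(sum_projection(vol, 5:9), "outside")
})

test_that("bundle counting finds planted spots and ignores empty images", {
  px <- 0.05
  img <- matrix(0, 80, 80)
  xs <- (1:80 - 0.5) * px; ys <- xs
  centers <- rbind(c(1, 1), c(3, 1), c(1, 3), c(3, 3), c(2, 2))
  for (i in seq_len(nrow(centers)))
    img <- img + outer(exp(-0.5 * ((ys - centers[i, 2]) / 0.08)^2),
                       exp(-0.5 * ((xs - centers[i, 1]) / 0.08)^2))
  got <- count_bundles(img, px, smooth_sigma_um = 0.05)
  expect_equal(got$count, 5)
  # detected positions match the planted centers
  ord <- order(got$coords_um[, "x"], got$coords_um[, "y"])
  ordc <- order(centers[, 1], centers[, 2])
  expect_equal(got$coords_um[ord, "x"], centers[ordc, 1], tolerance = 0.06,
               ignore_attr = TRUE)

  expect_equal(count_bundles(matrix(0, 40, 40), px)$count, 0)
})

test_that("end-on pipeline recovers the planted control bundle count", {
  op <- optics_params("confocal")
  counts <- c()
  for (s in 1:4) {
    pos <- rbind(ring_positions(16, 2.8), ring_positions(12, 1.8, pi / 12))
    m <- make_end_on_phantom(pos, bundle_length = 4, seed = s)
    st <- render(m, op, seed = s, channels = "prc1")
    eo <- rotate_to_end_on(st, "prc1")
    counts <- c(counts, count_bundles(sum_projection(eo), eo$pixel_size)$count)
  }
  expect_lt(abs(mean(counts) - 28), 2.5)
})

test_that("depleted spindles show the peripheral (barrel) bundle arrangement", {
  op <- optics_params("confocal")
  radial_mean <- function(pos, seed) {
    m <- make_end_on_phantom(pos, bundle_length = 4, seed = seed)
    st <- render(m, op, seed = seed, channels = "prc1")
    eo <- rotate_to_end_on(st, "prc1")
    cb <- count_bundles(sum_projection(eo), eo$pixel_size)
    ctr <- colMeans(cb$coords_um)
    mean(sqrt((cb$coords_um[, 1] - ctr[1])^2 +
              (cb$coords_um[, 2] - ctr[2])^2))
  }
  # control: bundles throughout; depleted: central bundles removed, peripheral
  # curved bundles remain
  control <- rbind(ring_positions(12, 2.6), ring_positions(8, 1.4, pi / 8),
                   ring_positions(4, 0.7, pi / 4))
  depleted <- rbind(ring_positions(12, 2.9), ring_positions(4, 2.0, pi / 4))
  expect_gt(radial_mean(depleted, 3), radial_mean(control, 3))
})

test_that("diameter profiles are symmetric for disks and bimodal for rings", {
  px <- 0.05
  n <- 120
  xs <- (1:n - 0.5) * px
  rr <- sqrt(outer((xs - 3)^2, (xs - 3)^2, `+`))
  disk <- (rr < 1.5) * 10
  prof <- diameter_profile(disk, c(0.5, 3), c(5.5, 3), px, line_width_px = 5)
  v <- prof$intensity
  expect_lt(max(abs(v - rev(v))) / max(v), 0.01)

  ring <- (rr > 1.2 & rr < 1.6) * 10
  pr <- diameter_profile(ring, c(0.5, 3), c(5.5, 3), px, line_width_px = 5)
  # the two ring crossings: brightest sample on each side of the center
  ctr_s <- max(pr$arclength) / 2
  left <- pr[pr$arclength < ctr_s, ]
  right <- pr[pr$arclength >= ctr_s, ]
  pk <- c(left$arclength[which.max(left$intensity)],
          right$arclength[which.max(right$intensity)])
  expect_equal(abs(diff(pk)), 2 * 1.4, tolerance = 0.3)

  # equals a transverse-mean oracle: image whose value equals the column
  # index, so the profile along x must read the fractional column index
  img <- matrix(rep(seq_len(n), each = n), n, n)
  p2 <- diameter_profile(img, c(0.5, 3), c(5.5, 3), px, line_width_px = 7)
  oracle <- 0.5 / px + 0.5 + (0:(nrow(p2) - 1))
  expect_equal(p2$intensity[2:(nrow(p2) - 1)],
               oracle[2:(length(oracle) - 1)], tolerance = 1e-6)
  expect_error(diameter_profile(disk, c(-4, 3), c(9, 3), px), "exits")
})
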