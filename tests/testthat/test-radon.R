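test_that("forward projection reproduces the analytic disc chord length", {
  # homogeneous unit-density disc: the line integral at offset s is the
  # chord 2*sqrt(R^2 - s^2); anti-aliased rasterisation, pixel units
  n <- 128
  spec <- phantom_spec(fov_mm = n, n_px = n, primitives = list(
    list(shape = "disc", center_mm = c(0, 0), radius_mm = 40,
         material = "water", density = 1)))
  ph <- make_phantom(spec)
  sino <- radon_transform(ph$density, n_angles = 90)
  nb <- ncol(sino$values)
  s <- (seq_len(nb) - 1) - (nb - 1) / 2
  R <- 40
  inner <- abs(s) < 0.9 * R
  chord <- 2 * sqrt(pmax(R^2 - s[inner]^2, 0))
  rel <- sweep(sino$values[, inner], 2, chord) / chord[1]
  expect_lt(sqrt(mean(rel^2)), 0.005)
})

test_that("filtered back projection recovers a disc to a few HU", {
  n <- 128
  spec <- phantom_spec(fov_mm = n, n_px = n, primitives = list(
    list(shape = "disc", center_mm = c(0, 0), radius_mm = 40,
         material = "water", density = 1)))
  ph <- make_phantom(spec)
  img <- ph$density * 1000
  rec <- fbp_reconstruct(radon_transform(img, n_angles = 180), n)
  coord <- seq_len(n) - (n + 1) / 2
  r2 <- outer(coord^2, coord^2, "+")
  inner <- r2 <= 34^2
  expect_lt(sqrt(mean((rec[inner] - 1000)^2)), 10)
  far <- r2 >= 55^2 & r2 <= 60^2
  expect_lt(max(abs(rec[far])), 15)
})

test_that("the Hann window smooths without breaking quantitation", {
  n <- 128
  set.seed(9)
  img <- matrix(0, n, n)
  img[40:90, 40:90] <- 500
  sino <- radon_transform(img, n_angles = 180)
  ramp <- fbp_reconstruct(sino, n, window = "ramp")
  hann <- fbp_reconstruct(sino, n, window = "hann")
  expect_lt(abs(mean(hann[55:75, 55:75]) - 500), 10)
  expect_lt(tv_cost(hann), tv_cost(ramp))   # apodization reduces ripple
})

test_that("sinogram shape and angle grid follow the request", {
  sino <- radon_transform(matrix(0, 32, 32), n_angles = 45)
  expect_equal(nrow(sino$values), 45)
  expect_equal(sino$angles_deg[1], 0)
  expect_lt(max(sino$angles_deg), 180)
  expect_error(radon_transform(matrix(0, 16, 8)), "nrow")
})
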