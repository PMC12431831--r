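test_that("rasterized disc areas match analytic geometry within 2%", {
  ph <- make_phantom(default_phantom_spec(n_px = 256))
  px_mm2 <- prod(ph$spacing_mm)
  # water disc: 100 mm radius minus two 5 mm rods
  water_area <- sum(ph$per_material$water > 0.5) * px_mm2
  expect_lt(abs(water_area - (pi * 100^2 - 2 * pi * 5^2)) / (pi * 100^2), 0.02)
  ti_area <- sum(ph$per_material$titanium) / 4.506 * px_mm2
  expect_lt(abs(ti_area - 2 * pi * 5^2) / (2 * pi * 5^2), 0.02)
})

test_that("an empty spec rasterizes to all air", {
  ph <- make_phantom(phantom_spec(fov_mm = 64, n_px = 32))
  expect_true(all(ph$labels == "air"))
  expect_equal(max(ph$density), 0)
  expect_equal(sum(ph$metal), 0)
})

test_that("later primitives overwrite earlier ones (painter's order)", {
  spec <- phantom_spec(fov_mm = 100, n_px = 64, primitives = list(
    list(shape = "disc", center_mm = c(0, 0), radius_mm = 30,
         material = "water", density = 1),
    list(shape = "disc", center_mm = c(0, 0), radius_mm = 10,
         material = "bone", density = 1.9)))
  ph <- make_phantom(spec)
  expect_equal(ph$labels[32, 32], "bone")
  expect_equal(ph$density[32, 32], 1.9, tolerance = 1e-9)
  expect_equal(ph$mbi_true$bone[32, 32], 1.9, tolerance = 1e-9)
})

test_that("primitives outside the field of view are rejected", {
  expect_error(phantom_spec(fov_mm = 100, n_px = 32, primitives = list(
    list(shape = "disc", center_mm = c(45, 0), radius_mm = 10,
         material = "water", density = 1))), "outside")
})

test_that("ground truth replaces metal with the displaced material", {
  ph <- make_phantom(default_phantom_spec(n_px = 128))
  # true water basis is solid water everywhere inside the disc, rods included
  expect_true(all(abs(ph$mbi_true$water[ph$metal > 0] - 1.015) < 1e-6))
  expect_equal(max(abs(ph$mbi_true$bone)), 0)
})

test_that("the spectrum model is a valid two-layer split", {
  sp <- spectrum_model()
  expect_equal(sum(sp$w_low), 1, tolerance = 1e-12)
  expect_equal(sum(sp$w_high), 1, tolerance = 1e-12)
  expect_true(all(sp$w_low >= 0) && all(sp$w_high >= 0))
  expect_lt(sp$mean_low, sp$mean_high)
  expect_equal(range(sp$energy_kev), c(20, 140))
})

test_that("evaluation ROIs track the rod geometry", {
  spec <- default_phantom_spec()
  rois <- phantom_rois(spec)
  expect_length(rois, 3)
  # midpoint ROI at the centre, flankers on the perpendicular bisector
  expect_equal(rois[[1]]$center_mm, c(0, 0))
  expect_equal(abs(rois[[2]]$center_mm[2]), 16)
  rot <- random_rod_phantom_spec(3)
  rois2 <- phantom_rois(rot)
  rods <- Filter(function(p) p$material == "titanium", rot$primitives)
  mid <- (rods[[1]]$center_mm + rods[[2]]$center_mm) / 2
  expect_equal(rois2[[1]]$center_mm, mid, tolerance = 1e-9)
  # flanking ROIs are orthogonal to the rod axis
  axis <- rods[[2]]$center_mm - rods[[1]]$center_mm
  off <- rois2[[2]]$center_mm - mid
  expect_lt(abs(sum(axis * off)) / sqrt(sum(axis^2)) / sqrt(sum(off^2)), 1e-9)
})

test_that("random phantom specs are deterministic in their seed", {
  expect_identical(random_rod_phantom_spec(7), random_rod_phantom_spec(7))
  s1 <- random_rod_phantom_spec(1); s2 <- random_rod_phantom_spec(2)
  expect_false(identical(s1$primitives[[2]]$center_mm,
                         s2$primitives[[2]]$center_mm))
})

test_that("bundled fixtures load with the promised structure", {
  fx <- default_fixtures(64)
  expect_named(fx, c("paper_phantom", "no_metal", "two_implant"))
  expect_gt(sum(fx$paper_phantom$phantom$metal), 0)
  expect_equal(sum(fx$no_metal$phantom$metal), 0)
  expect_length(fx$two_implant$rois, 3)
  expect_equal(fx$paper_phantom$ref_hu, 15)  # solid water at 1.015 g/cm^3
})
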