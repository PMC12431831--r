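test_that("ground-truth series is the exact synthesis of the true basis", {
  fx <- default_fixtures(64)
  sim <- simulate_series(fx$paper_phantom$phantom, energies_kev = c(70, 140),
                         mode = "fast", seed = 1)
  direct <- synthesize_series(fx$paper_phantom$phantom$mbi_true, c(70, 140))
  for (i in 1:2)
    expect_equal(sim$truth$images[[i]]$pixels, direct$images[[i]]$pixels)
})

test_that("physics mode without metal reproduces the ground truth", {
  sim <- small_no_metal_sim()
  fx <- default_fixtures(160)
  interior <- interior_mask(fx$no_metal$phantom)
  for (i in seq_along(sim$series$images)) {
    d <- sim$series$images[[i]]$pixels - sim$truth$images[[i]]$pixels
    expect_lt(sqrt(mean(d[interior]^2)), 5)
  }
})

test_that("titanium rods create artifacts that fade with energy", {
  sim <- small_sim()
  met <- sim$metal
  cost_at <- function(e) {
    a <- series_at(sim$series, e)$pixels - series_at(sim$truth, e)$pixels
    a[met > 0] <- 0
    tv_cost(a, exclude = met)
  }
  expect_gt(cost_at(70), cost_at(140))
  expect_gt(cost_at(70), cost_at(100))
})

test_that("simulation is deterministic given its seed", {
  ph <- make_phantom(default_phantom_spec(n_px = 64))
  a <- simulate_series(ph, energies_kev = c(70, 140), seed = 5, n_angles = 90)
  b <- simulate_series(ph, energies_kev = c(70, 140), seed = 5, n_angles = 90)
  expect_identical(a$series$images[[1]]$pixels, b$series$images[[1]]$pixels)
  c2 <- simulate_series(ph, energies_kev = c(70, 140), seed = 6, n_angles = 90)
  expect_false(identical(a$series$images[[1]]$pixels,
                         c2$series$images[[1]]$pixels))
})

test_that("fast mode scales streaks by the titanium attenuation ratio", {
  ph <- make_phantom(default_phantom_spec(n_px = 64))
  sim <- simulate_series(ph, energies_kev = c(70, 140), mode = "fast",
                         seed = 2)
  met <- sim$metal
  art <- function(e) {
    a <- series_at(sim$series, e)$pixels - series_at(sim$truth, e)$pixels
    a[met > 0] <- 0
    a
  }
  tab <- atten_table()
  ratio <- (mass_atten(tab, "titanium", 70) / mass_atten(tab, "titanium", 140))^1.5
  a70 <- art(70); a140 <- art(140)
  expect_equal(max(abs(a70)) / max(abs(a140)), ratio, tolerance = 1e-6)
})

test_that("photon starvation is floored, logged, and bounded", {
  ph <- make_phantom(default_phantom_spec(n_px = 64))
  sim <- simulate_series(ph, energies_kev = c(70, 140), seed = 3,
                         photons = 1e3, n_angles = 90)
  expect_gt(sim$meta$n_starved, 0)
  expect_true(all(is.finite(sim$series$images[[1]]$pixels)))
})

test_that("simulated VMIs honour the storage cap", {
  sim <- small_sim()
  for (im in sim$series$images) expect_lte(max(im$pixels), 3071)
})
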