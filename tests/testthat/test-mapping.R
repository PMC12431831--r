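make_masks_all_free <- function(n) {
  mask_set(matrix(0L, n, n), matrix(1L, n, n), matrix(0L, n, n),
           matrix(1L, n, n))
}

test_that("an exact quadratic is recovered to 1e-6 relative", {
  set.seed(8)
  n <- 64
  hu <- matrix(runif(n * n, -200, 300), n, n)
  truth <- c(0.9, 1e-3, 1e-7)
  basis <- truth[1] + truth[2] * hu + truth[3] * hu^2
  fit <- fit_mapping(ct_image(hu), basis, make_masks_all_free(n))
  expect_lt(max(abs(fit$coefficients - truth) / abs(truth)), 1e-6)
  expect_lt(fit$residual_rms, 1e-10)
  expect_equal(fit$n_fit, sum(hu <= 150))
})

test_that("exactly linear data yields a vanishing quadratic term", {
  set.seed(9)
  n <- 32
  hu <- matrix(runif(n * n, -100, 100), n, n)
  basis <- 1.0 + 2e-3 * hu
  fit <- fit_mapping(ct_image(hu), basis, make_masks_all_free(n))
  expect_lt(abs(fit$coefficients[3]), 1e-9 * 2e-3)
})

test_that("noisy coefficients converge at n = 1e4, sigma = 0.01 g/cm3", {
  set.seed(10)
  n <- 100                       # 1e4 pixels
  hu <- matrix(runif(n * n, -200, 300), n, n)
  truth <- c(0.95, 8e-4, 1e-6)
  basis <- truth[1] + truth[2] * hu + truth[3] * hu^2 +
    matrix(rnorm(n * n, 0, 0.01), n, n)
  fit <- fit_mapping(ct_image(hu), basis, make_masks_all_free(n))
  expect_lt(max(abs(fit$coefficients - truth) / abs(truth)), 0.05)
})

test_that("degenerate fits are refused", {
  n <- 32
  # constant CT number: rank-deficient
  expect_error(fit_mapping(ct_image(matrix(0, n, n)), matrix(1, n, n),
                           make_masks_all_free(n)), "constant")
  # too few artifact-free pixels
  few <- mask_set(matrix(1L, n, n) * (matrix(seq_len(n * n), n, n) > 50),
                  matrix(1L, n, n) * (matrix(seq_len(n * n), n, n) <= 50),
                  matrix(0L, n, n), matrix(1L, n, n))
  expect_error(fit_mapping(ct_image(matrix(runif(n * n), n, n)),
                           matrix(1, n, n), few), ">= 100")
})

test_that("bone-excluded pixels are dropped from the fit", {
  set.seed(12)
  n <- 40
  hu <- matrix(runif(n * n, -100, 100), n, n)
  hu[1:5, ] <- 800               # bone-range CT numbers
  basis <- 1 + 1e-3 * hu
  basis[1:5, ] <- 99             # wildly off the soft-tissue relation
  fit <- fit_mapping(ct_image(hu), basis, make_masks_all_free(n),
                     bone_exclude_hu = 150)
  expect_lt(max(abs(fit$coefficients - c(1, 1e-3, 0))), 1e-6)
  expect_lte(fit$hu_domain[2], 150)
})

test_that("apply_mapping matches a scalar polynomial oracle and clamps", {
  model <- structure(list(coefficients = c(a0 = 0.5, a1 = 2e-3, a2 = -1e-6),
                          target = "water", hu_domain = c(-100, 200),
                          n_fit = 1000L, residual_rms = 0.01),
                     class = "mapping_model")
  hu <- c(-250, -100, 0, 137.5, 200, 900)
  got <- apply_mapping(model, hu)
  clamped <- pmin(pmax(hu, -100), 200)
  expect_equal(got, 0.5 + 2e-3 * clamped - 1e-6 * clamped^2, tolerance = 1e-12)
  expect_equal(got[1], got[2])                # below-domain clamps to min
  expect_equal(got[5], got[6])                # above-domain clamps to max
  const <- model; const$coefficients <- c(a0 = 1, a1 = 0, a2 = 0)
  expect_equal(apply_mapping(const, rnorm(10, 0, 500)), rep(1, 10))
})

test_that("mapping models serialize to JSON and back", {
  model <- structure(list(coefficients = c(a0 = 0.9, a1 = 1e-3, a2 = 2e-7),
                          target = "bone", hu_domain = c(-400, 120),
                          n_fit = 5000L, residual_rms = 0.021),
                     class = "mapping_model")
  f <- tempfile(fileext = ".json")
  write_mapping_model(model, f)
  r <- read_mapping_model(f)
  expect_equal(r$coefficients, model$coefficients)
  expect_equal(r$hu_domain, model$hu_domain)
  expect_equal(r$target, "bone")
})

test_that("correct_mbis changes pixels only inside the artifact mask", {
  set.seed(14)
  n <- 32
  mbi <- random_mbi(n, seed = 14)
  vmi0 <- ct_image(matrix(runif(n * n, -50, 100), n, n), energy_kev = 140)
  art <- matrix(0L, n, n); art[10:15, 10:15] <- 1L
  metal <- matrix(0L, n, n); metal[16, 16] <- 1L
  support <- matrix(1L, n, n)
  free <- matrix(1L, n, n); free[art > 0] <- 0L; free[metal > 0] <- 0L
  masks <- mask_set(art, free, metal, support)
  mw <- fit_mapping(vmi0, mbi$water, masks, target = "water")
  mb <- fit_mapping(vmi0, mbi$bone, masks, target = "bone")
  out <- correct_mbis(mbi, masks, mw, mb, vmi0)
  sel <- masks$artifact > 0
  expect_identical(out$water[!sel], mbi$water[!sel])   # untouched outside
  expect_identical(out$bone[!sel], mbi$bone[!sel])
  expect_equal(out$water[sel], apply_mapping(mw, vmi0$pixels[sel]))
  expect_identical(out$water[metal > 0], mbi$water[metal > 0])
  # empty artifact mask: exact identity
  empty <- mask_set(matrix(0L, n, n), free + art, metal, support)
  out2 <- correct_mbis(mbi, empty, mw, mb, vmi0)
  expect_identical(out2$water, mbi$water)
  expect_identical(out2$bone, mbi$bone)
})
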