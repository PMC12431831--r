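test_that("tv_cost matches its definition on hand-evaluated cases", {
  expect_equal(tv_cost(matrix(5, 7, 7)), 0)
  # 2x2 [[0,1],[0,1]] (rows y, cols x): only the top-left pixel has both
  # forward neighbours; gradient = sqrt(1^2 + 0^2) = 1
  expect_equal(tv_cost(matrix(c(0, 0, 1, 1), 2, 2)), 1)
  m <- matrix(rnorm(49), 7, 7)
  expect_equal(tv_cost(m), tv_cost(t(m)), tolerance = 1e-12)
})

test_that("tv_cost equals a scalar double-loop oracle on random images", {
  oracle <- function(m, excl = NULL) {
    acc <- 0
    for (x in seq_len(nrow(m) - 1)) for (y in seq_len(ncol(m) - 1)) {
      if (!is.null(excl) &&
          (excl[x, y] > 0 || excl[x + 1, y] > 0 || excl[x, y + 1] > 0)) next
      acc <- acc + sqrt((m[x + 1, y] - m[x, y])^2 + (m[x, y + 1] - m[x, y])^2)
    }
    acc
  }
  set.seed(21)
  for (i in 1:50) {
    nr <- sample(2:32, 1); nc <- sample(2:32, 1)
    m <- matrix(rnorm(nr * nc, 0, 100), nr, nc)
    excl <- if (i %% 3 == 0) matrix(rbinom(nr * nc, 1, 0.2), nr, nc) else NULL
    expect_equal(tv_cost(m, exclude = excl), oracle(m, excl),
                 tolerance = 1e-9)
  }
})

test_that("cost curve normalizes to a maximum of exactly one", {
  imgs <- lapply(1:4, function(i)
    ct_image(matrix(rnorm(64, 0, i * 10), 8, 8), energy_kev = 60 + 10 * i))
  cc <- cost_curve(imgs, c(70, 80, 90, 100))
  expect_equal(max(cc$cost_norm), 1)
  expect_true(all(cc$cost_norm > 0 & cc$cost_norm <= 1))
  same <- cost_curve(list(imgs[[1]], imgs[[1]]), c(70, 80))
  expect_equal(same$cost_norm, c(1, 1))
  expect_error(cost_curve(imgs[1], 70), "two")
})

test_that("uniform rescaling of all artifact images leaves C_norm unchanged", {
  set.seed(5)
  imgs <- lapply(1:5, function(i)
    ct_image(matrix(rnorm(100, 0, 20 * i), 10, 10), energy_kev = 60 + 10 * i))
  scaled <- lapply(imgs, function(im) { im$pixels <- 3.7 * im$pixels; im })
  e <- seq(70, 110, by = 10)
  expect_equal(cost_curve(imgs, e)$cost_norm, cost_curve(scaled, e)$cost_norm,
               tolerance = 1e-12)
})

test_that("optimal/worst selection follows the curve with stated tie rules", {
  mk <- function(costs, energies) {
    df <- data.frame(index = seq_along(costs), energy_kev = energies,
                     cost = costs, cost_norm = costs / max(costs))
    class(df) <- c("cost_curve", "data.frame")
    df
  }
  cc <- mk(c(1.0, 0.6, 0.3, 0.4, 0.5), c(70, 80, 100, 120, 140))
  expect_equal(select_optimal(cc), 100)
  expect_equal(select_worst(cc), 70)
  flat <- mk(rep(2, 4), c(70, 80, 100, 140))
  expect_equal(select_optimal(flat), 140)   # tie: higher energy wins
  expect_equal(select_worst(flat), 70)      # tie: lower energy wins
  one <- mk(1, 70)
  expect_error(select_optimal(one), "fewer than 2")
  expect_error(select_worst(one), "fewer than 2")
})

test_that("STS row flags equal a brute-force sort/median oracle", {
  brute_row <- function(v, delta) {
    sv <- sort(v)
    n <- length(sv)
    med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    v < med - delta | v > med + delta
  }
  set.seed(33)
  for (i in 1:100) {
    nc <- sample(5:40, 1)
    v <- rnorm(nc, 0, sample(c(3, 10, 40), 1))
    support <- matrix(1L, 1, nc)
    # single-row image, no morphology: must agree exactly
    got <- sts_mask(matrix(v, 1, nc), support, delta_hu = 10,
                    morphology = FALSE)
    expect_identical(as.logical(got), brute_row(v, 10))
  }
})

test_that("STS flags the stated worked example and handles edge cases", {
  row <- c(0, 0, 0, 50, 0, -40, 0, 0, 0)
  got <- sts_mask(matrix(row, 1, 9), matrix(1L, 1, 9), delta_hu = 10,
                  morphology = FALSE)
  expect_equal(which(got == 1), c(4, 6))     # the 50 and -40 outliers
  # all-zero artifact image flags nothing
  expect_equal(sum(sts_mask(matrix(0, 8, 8), matrix(1L, 8, 8),
                            erosion_px = 1)), 0)
  # an enormous band swallows everything
  expect_equal(sum(sts_mask(matrix(rnorm(64, 0, 5), 8, 8), matrix(1L, 8, 8),
                            delta_hu = 1e9, erosion_px = 1)), 0)
  # rows with fewer than 3 support pixels are skipped
  supp <- matrix(0L, 4, 8); supp[2, 1:2] <- 1L
  expect_equal(sum(sts_mask(matrix(1000, 4, 8), supp, morphology = FALSE)), 0)
  expect_error(sts_mask(matrix(0, 4, 4), matrix(0L, 4, 4)), "empty support")
})

test_that("metal segmentation thresholds, prunes specks and validates input", {
  px <- matrix(0, 32, 32)
  px[10:15, 10:15] <- 8000      # 36-px implant
  px[25, 25] <- 9000            # isolated 1-px speck
  img <- ct_image(px)
  m <- segment_metal(img, 2500)
  expect_equal(sum(m), 36)      # speck removed, implant kept
  expect_equal(sum(segment_metal(ct_image(matrix(0, 8, 8)), 2500)), 0)
  expect_error(segment_metal(img, 500), "1000")
})

test_that("artifact_image subtracts, zeroes metal and preserves algebra", {
  set.seed(2)
  ct <- ct_image(matrix(rnorm(64, 0, 50), 8, 8))
  corr <- ct_image(ct$pixels + matrix(rnorm(64, 0, 20), 8, 8))
  metal <- matrix(0L, 8, 8); metal[4, 4] <- 1L
  art <- artifact_image(ct, corr, metal)
  expect_equal(art$pixels[metal == 0] + corr$pixels[metal == 0],
               ct$pixels[metal == 0], tolerance = 1e-12)
  expect_equal(art$pixels[4, 4], 0)
  same <- artifact_image(ct, ct, metal)
  expect_equal(max(abs(same$pixels)), 0)
})

test_that("preliminary MAR validates its inputs", {
  img <- ct_image(matrix(0, 16, 16))
  expect_error(preliminary_mar(img, matrix(0L, 16, 16)), "empty metal")
  m <- matrix(0L, 16, 16); m[8, 8] <- 1L
  expect_error(preliminary_mar(ct_image(matrix(0, 16, 8)),
                               matrix(1L, 16, 8)), "square")
})

test_that("support mask fills interior holes", {
  px <- matrix(-1000, 32, 32)
  px[8:24, 8:24] <- 50
  px[15:17, 15:17] <- -900      # air pocket inside the body
  s <- support_mask(ct_image(px))
  expect_equal(s[16, 16], 1L)   # hole filled
  expect_equal(s[2, 2], 0L)
})

test_that("mask_set enforces the partition invariants", {
  a <- matrix(0L, 4, 4); f <- matrix(0L, 4, 4)
  mt <- matrix(0L, 4, 4); s <- matrix(1L, 4, 4)
  a[1:2, ] <- 1L; f[3:4, ] <- 1L
  ms <- mask_set(a, f, mt, s)
  expect_s3_class(ms, "mask_set")
  # artifact and metal overlapping is rejected
  mt2 <- mt; mt2[1, 1] <- 1L
  expect_error(mask_set(a, f, mt2, s), "disjoint")
  # a hole in the partition is rejected
  f2 <- f; f2[3, 3] <- 0L
  expect_error(mask_set(a, f2, mt, s), "partition")
})
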