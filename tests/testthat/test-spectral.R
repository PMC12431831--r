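tab <- atten_table()

test_that("pure water maps to 0 HU and vacuum to -1000 HU at every energy", {
  m <- mbi_pair(matrix(1, 4, 4), matrix(0, 4, 4))
  air <- mbi_pair(matrix(0, 4, 4), matrix(0, 4, 4))
  for (e in c(40, 70, 100, 140, 200)) {
    expect_equal(max(abs(synthesize_vmi(m, e, tab)$pixels)), 0,
                 tolerance = 1e-10)
    expect_equal(synthesize_vmi(air, e, tab)$pixels[1, 1], -1000,
                 tolerance = 1e-10)
  }
})

test_that("synthesize_vmi matches a scalar per-pixel evaluation", {
  mbi <- random_mbi(8, seed = 7)
  for (e in c(55, 120)) {
    img <- synthesize_vmi(mbi, e, tab)
    # independent scalar oracle, pixel by pixel
    mw <- mass_atten(tab, "water", e)
    mb <- mass_atten(tab, "bone", e)
    for (i in seq_len(8)) for (j in seq_len(8)) {
      expected <- (1000 / tab$rho_w) *
        ((mw / mw) * mbi$water[i, j] + (mb / mw) * mbi$bone[i, j]) - 1000
      expect_equal(img$pixels[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("decompose_mbi inverts synthesis to numerical precision", {
  for (seed in 1:10) {
    mbi <- random_mbi(16, seed = seed)
    lo <- synthesize_vmi(mbi, 70, tab)
    hi <- synthesize_vmi(mbi, 140, tab)
    rec <- decompose_mbi(lo, hi, tab)
    scale <- max(abs(mbi$water), abs(mbi$bone))
    expect_lt(max(abs(rec$water - mbi$water)) / scale, 1e-6)
    expect_lt(max(abs(rec$bone - mbi$bone)) / scale, 1e-6)
  }
})

test_that("zero-HU VMIs decompose to pure water", {
  z70 <- ct_image(matrix(0, 6, 6), energy_kev = 70)
  z140 <- ct_image(matrix(0, 6, 6), energy_kev = 140)
  rec <- decompose_mbi(z70, z140, tab)
  expect_equal(max(abs(rec$water - tab$rho_w)), 0, tolerance = 1e-9)
  expect_equal(max(abs(rec$bone)), 0, tolerance = 1e-9)
})

test_that("identical energies give a singular system", {
  a <- ct_image(matrix(0, 4, 4), energy_kev = 70)
  expect_error(decompose_mbi(a, a, tab), "near-singular")
})

test_that("synthesis is affine-linear in the basis images", {
  a <- random_mbi(8, seed = 1); b <- random_mbi(8, seed = 2)
  al <- 0.3; be <- 1.2
  comb <- mbi_pair(al * a$water + be * b$water, al * a$bone + be * b$bone)
  lhs <- synthesize_vmi(comb, 90, tab)$pixels
  rhs <- al * synthesize_vmi(a, 90, tab)$pixels +
    be * synthesize_vmi(b, 90, tab)$pixels +
    (al + be - 1) * 1000     # the -1000 offset is affine, not linear
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("a local VMI perturbation stays local through decomposition", {
  mbi <- random_mbi(16, seed = 3)
  lo <- synthesize_vmi(mbi, 70, tab)
  hi <- synthesize_vmi(mbi, 140, tab)
  lo2 <- lo
  lo2$pixels[3:5, 3:5] <- lo2$pixels[3:5, 3:5] + 200
  d <- decompose_mbi(lo2, hi, tab)
  ref <- decompose_mbi(lo, hi, tab)
  changed <- abs(d$water - ref$water) + abs(d$bone - ref$bone) > 1e-9
  expected <- matrix(FALSE, 16, 16)
  expected[3:5, 3:5] <- TRUE
  expect_identical(changed, expected)
})

test_that("synthesize_series maps synthesis across energies", {
  mbi <- random_mbi(8, seed = 5)
  s <- synthesize_series(mbi, c(70, 100, 140), tab)
  expect_length(s, 3)
  expect_equal(s$images[[2]]$pixels, synthesize_vmi(mbi, 100, tab)$pixels)
  s1 <- synthesize_series(mbi, 80, tab)
  expect_length(s1, 1)
})
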