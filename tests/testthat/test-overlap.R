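test_that("identical ellipses overlap 100% and far-apart ellipses 0%", {
  f <- ellipse_fit(c(0, 0), diag(2), 20)
  ov <- ellipse_overlap(f, f)
  expect_equal(ov$prop_of_B, 100, tolerance = 0.1)
  expect_equal(ov$area_B, f$SEAc, tolerance = 1e-10)  # default coverage

  g <- ellipse_fit(c(100, 0), diag(2), 20)
  expect_equal(ellipse_overlap(f, g)$prop_of_B, 0)
  expect_equal(ellipse_overlap(f, g)$area_intersection, 0)
})

test_that("a concentric 4x-covariance pair gives 25% occupancy of the larger", {
  A <- ellipse_fit(c(-20, 4), matrix(c(1.2, 0.4, 0.4, 2.0), 2), 15)
  B <- ellipse_fit(c(-20, 4), 4 * matrix(c(1.2, 0.4, 0.4, 2.0), 2), 15)
  ov <- ellipse_overlap(A, B)
  # A nests inside B, so intersection = area_A = area_B / 4
  expect_equal(ov$prop_of_B, 25, tolerance = 0.025)
  expect_equal(ov$area_intersection, ov$area_A, tolerance = 1e-3)
})

test_that("intersection area is symmetric; proportions differ by denominator only", {
  A <- ellipse_fit(c(0, 0), matrix(c(1.5, 0.3, 0.3, 0.8), 2), 12)
  B <- ellipse_fit(c(1.1, 0.6), matrix(c(0.9, -0.2, -0.2, 1.3), 2), 25)
  ab <- ellipse_overlap(A, B)
  ba <- ellipse_overlap(B, A)
  expect_equal(ab$area_intersection, ba$area_intersection, tolerance = 5e-3)
  # swapping arguments swaps the roles of the two areas
  expect_equal(ab$area_A, ba$area_B, tolerance = 1e-12)
  expect_equal(ab$area_B, ba$area_A, tolerance = 1e-12)
  expect_equal(ab$prop_of_B, 100 * ab$area_intersection / ab$area_B,
               tolerance = 1e-12)
  expect_equal(ba$prop_of_B, 100 * ba$area_intersection / ba$area_B,
               tolerance = 1e-12)
})

test_that("intersection matches an independent 2-D grid oracle", {
  A <- ellipse_fit(c(-20.5, 3.6), diag(c(1.4^2, 1.7^2)), 38)
  B <- ellipse_fit(c(-19.7, 4.4), matrix(c(2.9, 0.8, 0.8, 5.3), 2), 11)
  ov <- ellipse_overlap(A, B)
  cA <- (38 - 1) / (38 - 2)
  cB <- (11 - 1) / (11 - 2)
  oracle <- grid_overlap_area(A$centroid, A$covariance, cA,
                              B$centroid, B$covariance, cB)
  expect_equal(ov$area_intersection, oracle, tolerance = 2e-3)
  expect_lte(ov$area_intersection, min(ov$area_A, ov$area_B) + 1e-9)
})

test_that("coverage scales the contour as a chi-square quantile", {
  f <- ellipse_fit(c(0, 0), diag(2), 30)
  ov95 <- ellipse_overlap(f, f, coverage = 0.95)
  expect_equal(ov95$area_B, f$SEAc * stats::qchisq(0.95, 2), tolerance = 1e-9)
  expect_equal(ov95$prop_of_B, 100, tolerance = 0.1)
})
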