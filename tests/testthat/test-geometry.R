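test_that("pixel-to-q mapping satisfies the Ewald geometry", {
  g <- experiment_geometry(0.7749, 200, 0.172, c(0, 0), c(2000, 2000))
  # forward beam: q = 0 at the beam center
  expect_equal(as.numeric(pixel_to_q(g, matrix(c(0, 0), 1))),
               c(0, 0, 0))
  # closed-form trigonometric oracle for an off-axis pixel
  q <- pixel_to_q(g, matrix(c(100, 0), 1))
  two_theta <- atan2(100 * 0.172, 200)
  expect_equal(sqrt(sum(q^2)), 2 * sin(two_theta / 2) / 0.7749,
               tolerance = 1e-12)
  # pixel on the 2theta = 45 degree cone (offset = z_d): |q| = 2 sin(22.5)/lambda
  px45 <- 200 / 0.172
  g2 <- experiment_geometry(0.7749, 200, 0.172, c(0, 0), c(4000, 4000))
  q45 <- pixel_to_q(g2, matrix(c(px45, 0), 1))
  expect_equal(sqrt(sum(q45^2)), 2 * sin(pi / 8) / 0.7749,
               tolerance = 1e-12)
  # |q| increases monotonically along a radius
  qs <- pixel_to_q(g, cbind(seq(0, 500, by = 50), 0))
  expect_true(all(diff(sqrt(rowSums(qs^2))) > 0))
  expect_error(pixel_to_q(g, matrix(c(5000, 0), 1)), "bounds")
})

test_that("hkl mapping inverts q mapping and handles the identity case", {
  set.seed(7)
  A <- matrix(rnorm(9), 3, 3)
  hkl <- matrix(rnorm(60), 20, 3)
  for (phi in c(0, 33.5, 180)) {
    q <- hkl_to_q(A, phi, hkl)
    expect_equal(q_to_hkl(A, phi, q), hkl, tolerance = 1e-10)
  }
  # identity A at zero angle: hkl = q componentwise
  q <- matrix(rnorm(15), 5, 3)
  expect_equal(q_to_hkl(diag(3), 0, q), q, tolerance = 1e-12)
  # q = 0 maps to the origin; first column of R A maps to (1,0,0)
  expect_equal(as.numeric(q_to_hkl(A, 12, matrix(0, 1, 3))), c(0, 0, 0))
  RA <- rotation_matrix(c(0, 1, 0), 12) %*% A
  expect_equal(as.numeric(q_to_hkl(A, 12, matrix(RA[, 1], 1))),
               c(1, 0, 0), tolerance = 1e-10)
  expect_error(q_to_hkl(matrix(0, 3, 3), 0, q), "singular")
})

test_that("correction factors take their closed forms and normalize at the beam center", {
  g <- experiment_geometry(1, 100, 0.1, c(0, 0), c(4000, 4000),
                           polarization_fraction = 0.5)
  cf0 <- correction_factors(g, matrix(c(0, 0), 1))
  expect_equal(cf0$polarization, 1)
  expect_equal(cf0$solid_angle, 1)
  expect_equal(cf0$absorption, 1)
  # unpolarized limit: (1 + cos^2 2theta)/2 regardless of azimuth
  px <- rbind(c(300, 0), c(0, 300), c(212.13, 212.13))
  cf <- correction_factors(g, px)
  tt <- atan2(sqrt(rowSums((px * 0.1)^2)), 100)
  expect_equal(cf$polarization, (1 + cos(tt)^2) / 2, tolerance = 1e-4)
  # solid angle: cos^3 of the incidence angle
  expect_equal(cf$solid_angle, cos(tt)^3, tolerance = 1e-12)
  # derived example: cos(theta) = 0.9 gives 0.729
  r <- 100 * tan(acos(0.9)) / 0.1
  cf9 <- correction_factors(g, matrix(c(r, 0), 1))
  expect_equal(cf9$solid_angle, 0.729, tolerance = 1e-9)
})

test_that("correction factors are azimuthally invariant at f = 0.5 and parallax vanishes with a thin sensor", {
  g <- experiment_geometry(1, 100, 0.1, c(0, 0), c(4000, 4000),
                           polarization_fraction = 0.5)
  th <- seq(0, 2 * pi, length.out = 13)
  px <- cbind(250 * cos(th), 250 * sin(th))
  cf <- correction_factors(g, px)
  expect_lt(diff(range(cf$polarization)), 1e-10)
  expect_lt(diff(range(cf$solid_angle)), 1e-10)
  expect_lt(diff(range(cf$absorption)), 1e-10)
  # absorption factor >= 1 off-normal, increasing with incidence angle
  cfr <- correction_factors(g, cbind(seq(0, 1000, 100), 0))
  expect_true(all(diff(cfr$absorption) > 0))
  # parallax shift vanishes as sensor thickness -> 0
  g0 <- experiment_geometry(1, 100, 0.1, c(0, 0), c(4000, 4000),
                            sensor_thickness_mm = 0)
  cf0 <- correction_factors(g0, px)
  expect_equal(cf0$shifted_pixels, px, tolerance = 1e-12)
  # thick sensor shifts pixels radially inward (toward the beam center)
  cf1 <- correction_factors(g, matrix(c(500, 0), 1))
  expect_lt(cf1$shifted_pixels[1, 1], 500)
  expect_equal(cf1$shifted_pixels[1, 2], 0)
})

test_that("reciprocal basis gives |q| = 1/d for axial reflections", {
  cell <- c(25, 30, 20, 90, 105, 90)
  B <- reciprocal_basis(cell)
  # b* for a monoclinic (unique b) cell: |b*| = 1/b
  expect_equal(sqrt(sum(B[, 2]^2)), 1 / 30, tolerance = 1e-12)
  # a* and c* carry the beta obliquity: |a*| = 1/(a sin beta)
  expect_equal(sqrt(sum(B[, 1]^2)), 1 / (25 * sin(105 * pi / 180)),
               tolerance = 1e-12)
  # metric round trip: orthogonalization is the inverse transpose
  M <- orthogonalization_matrix(cell)
  expect_equal(t(B) %*% M, diag(3), tolerance = 1e-12)
})
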