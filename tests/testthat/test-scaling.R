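qmag_grid <- function(n) {
  g <- synthetic_geometry(n)
  matrix(sqrt(rowSums(pixel_to_q(g, diffusemap:::pixel_grid(g))^2)), n, n)
}

test_that("radial profile averages usable pixels per |q| bin", {
  qm <- qmag_grid(64)
  br <- radial_breaks(1.4, 40)
  const <- detector_frame(matrix(3.5, 64, 64), 0.3)
  p <- radial_profile(const, qm, br)
  expect_true(all(p$mean[p$count > 0] == 3.5))
  # I = |q|^2 gives monotone bin means
  fr <- detector_frame(qm^2, 0.3)
  p2 <- radial_profile(fr, qm, br)
  expect_true(all(diff(p2$mean[p2$count > 0]) > 0))
  # construction oracle: per-bin shell values are recovered exactly
  bin <- findInterval(qm, br, rightmost.closed = TRUE)
  shellvals <- sin(seq_len(40))
  fr3 <- detector_frame(matrix(shellvals[pmax(bin, 1)], 64, 64), 0.3)
  fr3$mask <- bin >= 1 & bin <= 40
  p3 <- radial_profile(fr3, qm, br)
  expect_equal(p3$mean[p3$count > 0], shellvals[which(p3$count > 0)])
})

test_that("scale factors take their closed forms", {
  qm <- qmag_grid(64)
  set.seed(5)
  base <- matrix(rpois(64^2, 100), 64, 64)
  ref <- detector_frame(base, 0.3)
  dbl <- detector_frame(2 * base, 0.3)
  # the 64 px toy detector only reaches |q| ~ 0.1, so the water-ring
  # window is moved inside its coverage
  wr <- c(30, 15)
  for (m in c("radial_profile", "water_ring", "overall")) {
    expect_equal(scale_factor(dbl, ref, qm, m, d_min = 2,
                              water_ring_d = wr), 0.5, tolerance = 1e-10)
    expect_equal(scale_factor(ref, ref, qm, m, d_min = 2,
                              water_ring_d = wr), 1, tolerance = 1e-10)
  }
  # scale equivariance: scaling a frame by c divides s by c
  s1 <- scale_factor(dbl, ref, qm, "radial_profile", d_min = 2)
  tripled <- detector_frame(3 * base, 0.3)
  expect_equal(scale_factor(tripled, ref, qm, "radial_profile", d_min = 2),
               2 * s1 / 3, tolerance = 1e-10)
  # least-squares closed form: build frames with known shell profiles
  br <- radial_breaks(2, 40)
  bin <- findInterval(qm, br, rightmost.closed = TRUE)
  inb <- matrix(bin >= 1 & bin <= 40, 64, 64)
  present <- which(tabulate(bin[inb], 40) > 0)
  prv <- 10 + runif(40)
  delta <- rnorm(40)
  delta[-present] <- 0
  delta <- delta - sum(delta[present] * prv[present]) /
    sum(prv[present]^2) * prv * (seq_len(40) %in% present)
  pfv <- prv + 0.3 * delta
  mkfr <- function(v) {
    fr <- detector_frame(matrix(v[pmax(bin, 1)], 64, 64), 0.3)
    fr$mask <- inb
    fr
  }
  s <- scale_factor(mkfr(pfv), mkfr(prv), qm, "radial_profile",
                    d_min = 2, n_bins = 40)
  pf <- pfv[present]; pr2 <- prv[present]
  expect_equal(s, sum(pf * pr2) / sum(pf^2), tolerance = 1e-10)
})

test_that("imported Bragg scale factors are looked up by frame index", {
  tf <- tempfile()
  write.table(data.frame(i = 1:3, f = c(1, 1.1, 1.3)), tf,
              row.names = FALSE, col.names = FALSE)
  tab <- read_bragg_scale_factors(tf)
  fr <- detector_frame(matrix(1, 4, 4), 0.3, frame_index = 2)
  expect_equal(scale_factor(fr, fr, NULL, "bragg", bragg_factors = tab),
               1.1)
  fr9 <- detector_frame(matrix(1, 4, 4), 0.3, frame_index = 9)
  expect_error(scale_factor(fr9, fr9, NULL, "bragg", bragg_factors = tab),
               "frame 9")
  unlink(tf)
})

test_that("radial variance removal strips exactly the leading components", {
  set.seed(11)
  nb <- 50
  common <- 100 * exp(-seq(0, 2, length.out = nb))
  shape <- sin(seq(0, 3 * pi, length.out = nb))
  amp <- rnorm(12)
  M <- outer(rep(1, 12), common) + outer(amp, shape)
  # rank-1 frame-specific variation is removed by one component
  corr <- radial_variance_correction(M, 1)
  resid <- M - corr
  expect_lt(max(apply(resid, 2, sd)), 1e-10)
  # the frame-average profile is retained (only deviations removed)
  expect_equal(colMeans(resid), colMeans(M), tolerance = 1e-10)
  # identical profiles: nothing to remove
  M0 <- outer(rep(1, 8), common)
  expect_lt(max(abs(radial_variance_correction(M0, 3))), 1e-10)
  # zero components is the identity
  expect_equal(radial_variance_correction(M, 0), M * 0)
  expect_error(radial_variance_correction(M[1:3, ], 3), "components")
})

test_that("removed subspace is variance-maximal (eigen property)", {
  set.seed(13)
  M <- matrix(rnorm(6 * 10), 6, 10)
  corr <- radial_variance_correction(M, 1)
  explained <- sum(corr^2)
  X <- sweep(M, 2, colMeans(M))
  # brute-force search over random unit directions cannot beat it
  for (i in 1:200) {
    v <- rnorm(10); v <- v / sqrt(sum(v^2))
    expect_lte(sum((X %*% v)^2), explained + 1e-8)
  }
})

test_that("per-pixel radial correction interpolates between bin centers", {
  qm <- qmag_grid(32)
  fr <- detector_frame(matrix(5, 32, 32), 0.3)
  centers <- seq(0.05, 0.7, length.out = 10)
  corr <- centers * 2
  out <- apply_radial_correction(fr, qm, centers, corr)
  expected <- 5 - approx(centers, corr, xout = qm, rule = 2)$y
  expect_equal(out$counts, matrix(expected, 32, 32), tolerance = 1e-12)
})
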