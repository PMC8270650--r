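test_that("merging averages pixel contributions per voxel and rejects the Bragg box", {
  # two synthetic 'frames' funneled through a direct hkl function
  mkframe <- function(vals) {
    fr <- detector_frame(matrix(vals, 1), 1)
    fr
  }
  hkls <- list(rbind(c(2.4, 0, 0), c(1, 1, 1.4), c(0.1, 0.1, 0.1)),
               rbind(c(2.45, 0.05, -0.05), c(1, 1, 1.6), c(5.4, 5.4, 5.4)))
  frames <- list(mkframe(c(7, 4, 99)), mkframe(c(9, 6, 50)))
  hkl_fun <- function(fr) hkls[[fr$frame_index]]
  frames[[1]]$frame_index <- 1L; frames[[2]]$frame_index <- 2L
  vol <- merge_frames(frames, hkl_fun, 3, c(10, 10, 10, 90, 90, 90))
  idx <- function(h, k, l) c(h + 4, k + 4, l + 4)
  # (2.4,0,0) and (2.45,..) offsets > 0.25 -> voxel (2,0,0) mean of 7, 9
  expect_equal(vol$values[4 + 2, 4, 4], 8)
  expect_equal(vol$count[4 + 2, 4, 4], 2)
  # (1,1,1.4) kept (offset 0.4), (1,1,1.6) kept -> rounds to (1,1,1)/(1,1,2)
  expect_equal(vol$values[5, 5, 5], 4)
  expect_equal(vol$values[5, 5, 6], 6)
  # (0.1,0.1,0.1) inside the Bragg box -> rejected; (5.4,...) outside grid
  expect_equal(vol$count[4, 4, 4], 0)
  expect_equal(attr(vol, "n_outside"), 1L)
  expect_equal(sum(vol$count), 4)
})

test_that("merging is permutation-invariant and honors the boundary rule", {
  set.seed(21)
  hkls <- lapply(1:4, function(i) matrix(runif(300, -3.4, 3.4), 100, 3))
  frames <- lapply(1:4, function(i) {
    fr <- detector_frame(matrix(rpois(100, 30), 1), 1, frame_index = i)
    fr
  })
  hkl_fun <- function(fr) hkls[[fr$frame_index]]
  v1 <- merge_frames(frames, hkl_fun, 4, c(10, 10, 10, 90, 90, 90))
  perm <- c(3, 1, 4, 2)
  v2 <- merge_frames(frames[perm], hkl_fun, 4, c(10, 10, 10, 90, 90, 90))
  expect_equal(v1$values, v2$values)
  expect_equal(v1$count, v2$count)
  # offset exactly 0.25 is rejected
  fr <- detector_frame(matrix(5, 1), 1, frame_index = 1L)
  v3 <- merge_frames(list(fr), function(f) rbind(c(1.25, 2.25, 0.75)), 4,
                     c(10, 10, 10, 90, 90, 90))
  expect_equal(sum(v3$count), 0)
})

test_that("symmetrization is a count-weighted orbit average and idempotent", {
  cell <- c(10, 12, 14, 90, 100, 90)
  n <- 9; hm <- 4
  vals <- array(NA_real_, c(n, n, n)); cnt <- array(0, c(n, n, n))
  at <- function(h, k, l) cbind(h + hm + 1, k + hm + 1, l + hm + 1)
  vals[at(1, 2, 3)] <- 10; cnt[at(1, 2, 3)] <- 1
  vals[at(-1, -2, -3)] <- 20; cnt[at(-1, -2, -3)] <- 1
  vals[at(2, 0, 1)] <- 5; cnt[at(2, 0, 1)] <- 3   # lone orbit member
  vol <- diffuse_volume(vals, cnt, cell, "2/m")
  fs <- symmetrize(vol, "friedel")
  expect_equal(fs$values[at(1, 2, 3)], 15)
  expect_equal(fs$values[at(-1, -2, -3)], 15)
  expect_equal(fs$count[at(1, 2, 3)], 2)
  expect_equal(fs$values[at(2, 0, 1)], 5)
  expect_equal(fs$values[at(-2, 0, -1)], 5)
  # count weighting: pooled mean, not mean of means
  vals2 <- vals; cnt2 <- cnt
  vals2[at(-1, -2, -3)] <- 20; cnt2[at(-1, -2, -3)] <- 3
  v2 <- symmetrize(diffuse_volume(vals2, cnt2, cell, "2/m"), "friedel")
  expect_equal(v2$values[at(1, 2, 3)], (10 * 1 + 20 * 3) / 4)
  # idempotence on values; exact group invariance
  ls1 <- symmetrize(vol, "laue")
  ls2 <- symmetrize(ls1, "laue")
  expect_equal(ls1$values, ls2$values)
  flip <- function(a) a[n:1, , n:1]
  expect_equal(ls1$values, flip(ls1$values))
  expect_equal(ls1$values, ls1$values[n:1, n:1, n:1])
  # friedel orbit is a subgroup of 2/m: laue(friedel(V)) = laue(V) on the
  # voxel values (counts double, being orbit sums of orbit sums)
  lsf <- symmetrize(symmetrize(vol, "friedel"), "laue")
  expect_equal(lsf$values, ls1$values)
  expect_equal(lsf$count, 2 * ls1$count)
  expect_error(symmetrize(diffuse_volume(vals, cnt, cell, "4/m")),
               "unsupported")
})

test_that("isotropic subtraction zeroes shell means and preserves anisotropy", {
  vol <- random_volume(8, seed = 31, frac_observed = 0.8)
  q <- volume_qmag(vol)
  # purely radial volume maps to ~0
  vol$values[vol$count > 0] <- (2 + 3 * q^2)[vol$count > 0]
  out <- subtract_isotropic(vol)
  # residual bounded by the within-shell spread of the radial input
  expect_lt(max(abs(out$values), na.rm = TRUE), 0.03)
  # constant volume maps to exactly 0
  volc <- vol; volc$values[volc$count > 0] <- 4
  expect_equal(max(abs(subtract_isotropic(volc)$values), na.rm = TRUE), 0)
  # radial + zero-shell-mean anisotropic part: anisotropy recovered
  set.seed(8)
  vola <- random_volume(8, seed = 32)
  aniso <- array(rnorm(17^3), c(17, 17, 17))
  # remove the radial component of the anisotropic part on fine shells
  va <- diffuse_volume(aniso, vola$count, vola$cell, "2/m")
  aniso0 <- subtract_isotropic(va, n_shells = 60)$values
  vola$values <- 10 * exp(-q) + aniso0
  rec <- subtract_isotropic(vola, n_shells = 60)
  cc <- pearson_cc(rec$values, aniso0)
  expect_gt(cc, 0.99)
  # observation-weighted shell means are zero to machine precision
  br <- seq(0, max(q[vola$count > 0]) * (1 + 1e-9), length.out = 61)
  bin <- findInterval(q, br, rightmost.closed = TRUE)
  w <- rec$count
  for (b in unique(bin[w > 0])) {
    sel <- bin == b & w > 0
    expect_lt(abs(sum(rec$values[sel] * w[sel]) / sum(w[sel])), 1e-8)
  }
})

test_that("completeness counts unique observed orbits per shell", {
  cell <- c(10, 12, 14, 90, 100, 90)
  vol <- random_volume(6, seed = 41, cell = cell)
  sh <- shell_scheme(d_min = max(cell[1:3]) / 5, n_shells = 4, d_max = Inf)
  comp <- completeness(vol, sh)
  expect_true(all(comp$completeness == 1))
  # drop whole orbits (even-k layers map onto themselves under 2/m)
  vol2 <- vol
  vol2$count[, seq(1, 13, 2), ] <- 0
  vol2$values[vol2$count == 0] <- NA
  comp2 <- completeness(vol2, sh)
  expect_true(all(comp2$completeness < 1))
  expect_true(all(comp2$completeness > 0))
})

test_that("HKL table and MRC round trips preserve the volume", {
  vol <- random_volume(5, seed = 51, frac_observed = 0.7)
  tf <- tempfile(fileext = ".hkl")
  write_hkl_table(vol, tf)
  back <- read_hkl_table(tf, vol$cell, vol$laue, hmax = 5)
  expect_equal(back$values, vol$values, tolerance = 1e-12)
  expect_equal(back$count, vol$count)
  unlink(tf)
  tm <- tempfile(fileext = ".mrc")
  write_mrc(vol, tm)
  con <- file(tm, "rb")
  hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
  expect_equal(hdr, c(11, 11, 11))
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_equal(mode, 2)
  seek(con, 1024)
  dat <- readBin(con, "numeric", 11^3, size = 4, endian = "little")
  close(con)
  v0 <- vol$values; v0[is.na(v0)] <- 0
  expect_equal(array(dat, c(11, 11, 11)), v0, tolerance = 1e-6)
  unlink(tm)
})
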