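test_that("reference intensity reduces to single-atom and pair closed forms", {
  cell <- c(12, 14, 10, 90, 90, 90)
  one <- atomic_model(data.frame(element = "C", x = 0, y = 0, z = 0,
                                 occupancy = 1, altloc = "", b = 0),
                      cell, "P1")
  ref <- reference_intensity(one, 4, "zero", laue = "-1")
  q <- volume_qmag(ref)
  expect_equal(ref$values, form_factor("C", q)^2, tolerance = 1e-10)
  # centrosymmetric pair: I = 4 f^2 cos^2(2 pi h.x)
  x <- c(0.13, 0.27, 0.41)
  pair <- atomic_model(data.frame(element = "O", x = c(x[1], -x[1]),
                                  y = c(x[2], -x[2]), z = c(x[3], -x[3]),
                                  occupancy = 1, altloc = "", b = 0),
                       cell, "P1")
  refp <- reference_intensity(pair, 3, "zero", laue = "-1")
  hkl <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  ph <- as.vector(2 * pi * hkl %*% x)
  fo <- as.vector(form_factor("O", volume_qmag(refp)))
  expect_equal(as.vector(refp$values), 4 * fo^2 * cos(ph)^2,
               tolerance = 1e-10)
})

test_that("isotropic ADPs equal anisotropic ADPs with a spherical U", {
  cell <- c(12, 14, 10, 90, 100, 90)
  b <- 15
  u <- b / (8 * pi^2)
  m <- atomic_model(data.frame(element = "N", x = 0.2, y = 0.3, z = 0.1,
                               occupancy = 1, altloc = "", b = b,
                               u11 = u, u22 = u, u33 = u,
                               u12 = 0, u13 = 0, u23 = 0), cell, "P1")
  r_iso <- reference_intensity(m, 4, "isotropic", laue = "-1")
  r_ani <- reference_intensity(m, 4, "anisotropic", laue = "-1")
  expect_equal(r_iso$values, r_ani$values, tolerance = 1e-10)
})

test_that("LLM kernel takes its closed form and integrates correctly", {
  cell <- c(24, 24, 24, 90, 90, 90)
  k <- llm_kernel(3, 6, cell, normalize = FALSE)
  # q = 0 value is the full integral of exp(-r/gamma): 8 pi gamma^3
  expect_equal(k[7, 7, 7], 8 * pi * 27)
  # at q_rad = 1/gamma the kernel is 1/4 of its peak
  g <- 4
  qr <- 1 / (2 * pi * g)   # |q| with q_rad = 1/gamma
  kv <- 8 * pi * g^3 / (1 + g^2 * (2 * pi * qr)^2)^2
  expect_equal(kv, 8 * pi * g^3 / 4)
  # grid sum over a sphere + exact analytic tail = total integral, to 1%
  gamma <- 3
  cellf <- c(96, 96, 96, 90, 90, 90)   # fine sampling, negligible aliasing
  hm <- 100
  kk <- llm_kernel(gamma, hm, cellf, normalize = FALSE)
  q <- volume_qmag(diffuse_volume(kk, array(1, dim(kk)), cellf, "-1"))
  Q <- 2 * pi * hm / 96
  voxvol <- (2 * pi)^3 / det(orthogonalization_matrix(cellf))
  ssum <- sum(kk[q <= Q / (2 * pi)]) * voxvol / (2 * pi)^3
  U <- gamma * Q
  inside <- (2 / pi) * (atan(U) - U / (1 + U^2))
  expect_lt(abs(ssum - inside) / 1, 0.01)
  expect_error(llm_kernel(-1, 4, cell), "positive")
})

test_that("LLM kernel matches the numeric 3D FFT of the exponential correlation", {
  gamma <- 2
  cell <- c(40, 40, 40, 90, 90, 90)
  N <- 41
  # direct-space grid conjugate to the hkl grid, minimum-image distances
  idx <- seq(0, N - 1)
  frac <- ifelse(idx > N / 2, idx - N, idx) / N
  r2 <- outer(outer((frac * 40)^2, (frac * 40)^2, "+"), (frac * 40)^2, "+")
  f <- exp(-sqrt(r2) / gamma)
  Fk <- Re(fft(f)) * (40^3 / N^3)
  # reorder to centered layout and compare with the closed form
  shift <- function(a) {
    i <- c((N %/% 2 + 2):N, 1:(N %/% 2 + 1))
    a[i, i, i]
  }
  Fc <- shift(Fk)
  kc <- llm_kernel(gamma, 20, cell, normalize = FALSE)
  # agreement within grid truncation/aliasing tolerance
  expect_lt(max(abs(Fc - kc)) / max(kc), 0.05)
  expect_gt(pearson_cc(Fc, kc), 0.999)
})

test_that("FFT convolution equals the brute-force double sum on a 5^3 grid", {
  set.seed(15)
  x <- array(rnorm(125), c(5, 5, 5))
  k <- array(runif(125), c(5, 5, 5))
  k <- k / sum(k)
  fftc <- diffusemap:::convolve3d(x, k)
  direct <- direct_convolve3d(x, k)
  expect_lt(max(abs(fftc - direct)) / max(abs(direct)), 1e-10)
})

test_that("LLM intensity obeys its limiting forms", {
  ref <- toy_reference()
  qrad2 <- (2 * pi * volume_qmag(ref))^2
  # sigma = 0 gives the zero map
  expect_equal(max(abs(llm_intensity(ref, 0, 5)$values)), 0)
  # delta-like kernel limit (gamma large vs grid): pointwise prefactor form
  big <- llm_intensity(ref, 0.4, 500)
  expected <- 0.16 * qrad2 * exp(-0.16 * qrad2) * ref$values
  expect_gt(pearson_cc(big$values, expected), 0.999)
})

test_that("RBT intensity matches saturation and small-displacement limits", {
  ref <- toy_reference()
  qrad2 <- (2 * pi * volume_qmag(ref))^2
  expect_equal(max(abs(rbt_intensity(ref, 0)$values)), 0)
  small <- rbt_intensity(ref, 0.01)
  expect_equal(small$values, 1e-4 * qrad2 * ref$values, tolerance = 1e-3)
  sat <- rbt_intensity(ref, 50)
  off <- volume_qmag(ref) > 0.1
  expect_equal(sat$values[off], ref$values[off], tolerance = 1e-8)
})

test_that("self-fit recovers generating parameters with CC = 1", {
  ref <- toy_reference()
  data_map <- process_like_data(llm_intensity(ref, 0.4, 7))
  fit <- fit_diffuse_model(data_map, reference = ref, kind = "llm",
                           adp_mode = "zero", d_min = 25 / 10, d_max = 20,
                           n_refine = 1)
  expect_gt(fit$cc, 0.9999)
  expect_lt(abs(fit$sigma - 0.4), 0.02)
  expect_lt(abs(fit$gamma - 7) / 7, 0.05)
  # CC objective is scale-invariant: rescaling the data changes nothing
  data2 <- data_map
  data2$values <- data_map$values * 17.3
  fit2 <- fit_diffuse_model(data2, reference = ref, kind = "llm",
                            adp_mode = "zero", d_min = 25 / 10, d_max = 20,
                            n_refine = 1)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  expect_equal(fit2$cc, fit$cc, tolerance = 1e-8)
})

test_that("model ordering: LLM beats RBT on LLM data and vice versa", {
  ref <- toy_reference()
  sh_dmin <- 25 / 10
  llm_data <- process_like_data(llm_intensity(ref, 0.4, 7))
  set.seed(77)
  llm_data$values <- llm_data$values +
    rnorm(length(llm_data$values), sd = 0.1 * sd(llm_data$values, na.rm = TRUE))
  f_llm <- fit_diffuse_model(llm_data, reference = ref, kind = "llm",
                             d_min = sh_dmin, d_max = 20, n_refine = 1)
  f_rbt <- fit_diffuse_model(llm_data, reference = ref, kind = "rbt",
                             d_min = sh_dmin, d_max = 20)
  expect_gt(f_llm$cc, f_rbt$cc)
  rbt_data <- process_like_data(rbt_intensity(ref, 0.4))
  set.seed(78)
  rbt_data$values <- rbt_data$values +
    rnorm(length(rbt_data$values), sd = 0.1 * sd(rbt_data$values, na.rm = TRUE))
  g_llm <- fit_diffuse_model(rbt_data, reference = ref, kind = "llm",
                             d_min = sh_dmin, d_max = 20, n_refine = 1)
  g_rbt <- fit_diffuse_model(rbt_data, reference = ref, kind = "rbt",
                             d_min = sh_dmin, d_max = 20)
  expect_gt(g_rbt$cc, g_llm$cc)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  ref <- toy_reference()
  data_map <- process_like_data(llm_intensity(ref, 0.4, 7))
  fit <- fit_diffuse_model(data_map, reference = ref, kind = "llm",
                           d_min = 25 / 10, d_max = 20, n_refine = 1)
  expect_named(coef(fit), c("sigma", "gamma"))
  pred <- predict(fit)
  expect_s3_class(pred, "diffuse_volume")
  expect_gt(pearson_cc(pred$values, data_map$values), 0.999)
  res <- residuals(fit)
  expect_lt(sd(res$values, na.rm = TRUE),
            0.05 * sd(data_map$values, na.rm = TRUE))
  expect_output(print(fit), "LLM fit")
  expect_output(print(summary(fit)), "objective evaluations")
})
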