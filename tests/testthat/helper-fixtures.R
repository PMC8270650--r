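# Shared fixtures, built once per test run and cached. Sizes are kept at
# desk scale: a small monoclinic toy cell for unit tests and a
# protein-sized cell for the end-to-end checks.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

toy_cell <- c(25, 30, 20, 90, 105, 90)

toy_model <- function() fixture("toy_model", function()
  make_toy_model(n_atoms = 20, cell = toy_cell, seed = 3))

# small synthetic scene shared by the generator and pipeline tests; the
# 256 px detector covers to about 2.55 Angstrom at its edge
synth_scene <- function() fixture("synth_scene", function() {
  cell <- c(50, 60, 40, 90, 105, 90)
  model <- make_toy_model(n_atoms = 40, cell = cell, seed = 3)
  list(cell = cell, model = model,
       truth = make_truth_volume(model, 0.4, 2.5, hmax = 26),
       geom = synthetic_geometry(256))
})

small_series <- function() fixture("small_series", function() {
  sc <- synth_scene()
  spec <- synthetic_spec(n_frames = 30, step_deg = 6, seed = 17)
  render_frames(sc$truth, spec, sc$geom)
})

toy_reference <- function() fixture("toy_reference", function()
  reference_intensity(select_conformer(toy_model()), 10, "zero"))

# random observed diffuse volume on a small grid
random_volume <- function(hmax = 8, seed = 1, cell = toy_cell,
                          frac_observed = 1) {
  set.seed(seed)
  n <- 2 * hmax + 1
  cnt <- array(1, c(n, n, n))
  if (frac_observed < 1)
    cnt[runif(n^3) > frac_observed] <- 0
  diffuse_volume(array(rnorm(n^3), c(n, n, n)), cnt, cell, "2/m")
}

# direct circular convolution oracle (brute-force sextuple sum);
# kernel_centered has its origin at the central element
direct_convolve3d <- function(x, kernel_centered) {
  n <- dim(x)[1]
  hm <- (n - 1) / 2
  wrap <- function(d) ((d + hm) %% n) - hm
  out <- array(0, dim(x))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    acc <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      acc <- acc + x[a, b, cc] *
        kernel_centered[wrap(i - a) + hm + 1,
                        wrap(j - b) + hm + 1,
                        wrap(k - cc) + hm + 1]
    }
    out[i, j, k] <- acc
  }
  out
}
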