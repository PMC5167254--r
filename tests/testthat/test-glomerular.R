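test_that("the lattice filter partitions a 357 x 197 map into 1805 unit values", {
  g <- bulb_geometry()
  img <- matrix(runif(357 * 197), nrow = 197, ncol = 357)
  p <- lattice_filter(img, g)
  expect_s3_class(p, "glomerular_pattern")
  expect_length(p, 1805)
  expect_true(all(is.finite(p)))
})

test_that("a constant image maps to a constant pattern", {
  g <- small_geom()
  p <- lattice_filter(matrix(2.5, 13, 21), g)
  expect_equal(as.numeric(p), rep(2.5, g$n_units))
})

test_that("cell means match a brute-force partition on a toy image", {
  g <- small_geom()  # 10 x 6 on a 20 x 12 toy image -> no remainder
  set.seed(11)
  img <- matrix(rnorm(20 * 12), nrow = 12, ncol = 20)
  p <- lattice_filter(img, g)
  for (u in seq_len(g$n_units)) {
    rows <- g$beta[u] * 2 + 1:2
    cols <- g$alpha[u] * 2 + 1:2
    expect_equal(p[u], mean(img[rows, cols]))
  }
  # global mean conserved when the dimensions divide evenly
  expect_equal(mean(p), mean(img))
})

test_that("remainder pixels are assigned from the low-index edge", {
  g <- bulb_geometry(3, 2)
  # 7 columns over 3 cells -> widths 3, 2, 2; 5 rows over 2 cells -> 3, 2
  img <- matrix(seq_len(35), nrow = 5, ncol = 7)
  p <- lattice_filter(img, g)
  expect_equal(p[1], mean(img[1:3, 1:3]))
  expect_equal(p[2], mean(img[1:3, 4:5]))
  expect_equal(p[6], mean(img[4:5, 6:7]))
})

test_that("a single bright region activates exactly the covering units", {
  g <- small_geom()
  img <- matrix(0, 12, 20)
  img[3:4, 5:6] <- 1  # exactly cell (alpha = 2, beta = 1), unit 13
  p <- lattice_filter(img, g)
  expect_equal(which(as.numeric(p) != 0), 13L)
  expect_equal(p[13], 1)
})

test_that("lattice filter rejects bad images", {
  g <- small_geom()
  expect_error(lattice_filter(matrix(1, 4, 20), g), "smaller than the lattice")
  bad <- matrix(1, 12, 20); bad[3, 3] <- NA
  expect_error(lattice_filter(bad, g), "non-finite")
})

test_that("binarization uses an inclusive threshold", {
  g <- bulb_geometry(2, 2)
  p <- glomerular_pattern(c(0.60, 0.59, 0.61, 0), g)
  b <- binarize_pattern(p, theta = 0.60)
  expect_equal(as.numeric(b), c(1, 0, 1, 0))
  expect_equal(as.numeric(binarize_pattern(glomerular_pattern(rep(0, 4), g))),
               rep(0, 4))
})

test_that("mixing odorants averages binary component maps", {
  g <- bulb_geometry(3, 2)
  b1 <- glomerular_pattern(c(1, 1, 0, 0, 0, 0), g, "A")
  b2 <- glomerular_pattern(c(0, 1, 1, 0, 0, 0), g, "B")
  b3 <- glomerular_pattern(c(0, 1, 0, 1, 0, 0), g, "C")
  m <- mix_odorants(list(b1, b2, b3))
  expect_equal(as.numeric(m), c(1, 3, 1, 1, 0, 0) / 3)
  expect_equal(attr(m, "component_ids"), c("A", "B", "C"))

  # k = 1 is the identity; disjoint singles give 1/k spikes
  expect_equal(as.numeric(mix_odorants(list(b1))), as.numeric(b1))
  d <- mix_odorants(list(
    glomerular_pattern(c(1, 0, 0, 0, 0, 0), g),
    glomerular_pattern(c(0, 1, 0, 0, 0, 0), g),
    glomerular_pattern(c(0, 0, 1, 0, 0, 0), g)))
  expect_equal(as.numeric(d), c(1, 1, 1, 0, 0, 0) / 3)

  # order invariance and the 1/k value lattice
  m2 <- mix_odorants(list(b3, b1, b2))
  expect_equal(as.numeric(m2), as.numeric(m))
  expect_true(all(as.numeric(m) %in% ((0:3) / 3)))

  expect_error(mix_odorants(list()), "non-empty")
  expect_error(mix_odorants(list(b1, glomerular_pattern(rep(0, 4), bulb_geometry(2, 2)))),
               "length")
})

test_that("the breath function ramps to the peak and decays exponentially", {
  g <- bulb_geometry(2, 2)
  mix <- mix_odorants(list(glomerular_pattern(c(1, 1, 0, 0), g)))
  resp <- respiration_params()
  tr <- sniff_waveform(mix, resp, n_cycles = 1, dt = 1)

  # peak equals P at t_inhale
  expect_equal(tr$drive[1, tr$times == 220], 1.0)
  # one decay constant past the inhalation peak
  expect_equal(tr$drive[1, tr$times == 253], exp(-1), tolerance = 1e-12)
  # undriven units stay at zero
  expect_equal(tr$drive[3, ], rep(0, length(tr$times)))
  # first cycle starts from zero drive
  expect_equal(tr$drive[1, 1], 0)
})

test_that("drive is continuous across cycles and peaks once per cycle", {
  g <- bulb_geometry(2, 2)
  mix <- mix_odorants(list(glomerular_pattern(c(1, 0, 0, 0), g)))
  resp <- respiration_params()
  tr <- sniff_waveform(mix, resp, n_cycles = 3, dt = 0.5)
  v <- tr$drive[1, ]
  # no jump anywhere (piecewise-smooth, bounded slope ~ 1/t_inhale scale)
  expect_lt(max(abs(diff(v))), 0.02)
  for (cyc in 1:3) {
    win <- tr$times > (cyc - 1) * 400 & tr$times <= cyc * 400
    expect_equal(tr$times[win][which.max(v[win])], (cyc - 1) * 400 + 220)
    expect_equal(max(v[win]), 1.0)
    # monotone ramp up then strictly decreasing decay
    ramp <- v[win][tr$times[win] <= (cyc - 1) * 400 + 220]
    expect_true(all(diff(ramp) >= 0))
    decay <- v[win][tr$times[win] > (cyc - 1) * 400 + 220]
    expect_true(all(diff(decay) < 0))
  }
  # cycles 2 and 3 are identical; cycle 1 differs only by its start
  w2 <- tr$drive[1, tr$times > 400 & tr$times <= 800]
  w3 <- tr$drive[1, tr$times > 800 & tr$times <= 1200]
  expect_equal(w2, w3)
})

test_that("respiration parameter validation", {
  expect_error(respiration_params(t_inhale = 500, t_exhale = 400), "t_inhale")
  expect_error(respiration_params(tau_exhale = -1), "tau_exhale")
  expect_error(sniff_waveform(
    mix_odorants(list(glomerular_pattern(rep(0, 4), bulb_geometry(2, 2)))),
    respiration_params(), n_cycles = 0), "n_cycles")
})

test_that("patterns round-trip through delimited text and min-max normalization", {
  g <- small_geom()
  set.seed(2)
  p <- glomerular_pattern(rnorm(g$n_units), g, "test")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern(p, path)
  back <- read_pattern(path)
  expect_equal(as.numeric(back), as.numeric(p))

  np <- normalize_pattern(p)
  expect_equal(range(np), c(0, 1))
  expect_equal(order(np), order(p))
  expect_equal(as.numeric(normalize_pattern(glomerular_pattern(rep(3, 60), g))),
               rep(0, 60))
})

test_that("grayscale PNG images are ingested as pixel matrices", {
  img <- matrix(runif(12 * 20), 12, 20)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  back <- read_activity_image(path)
  expect_equal(dim(back), c(12, 20))
  expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization
  p <- lattice_filter(back, small_geom())
  expect_length(p, 60)
})
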