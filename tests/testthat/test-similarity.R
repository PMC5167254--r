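# minimal trace builder for response tests
make_trace <- function(x_trace, dt = 1, resp = respiration_params()) {
  structure(list(times = seq(0, by = dt, length.out = ncol(x_trace)),
                 x_trace = x_trace, y_trace = NULL,
                 x = x_trace[, ncol(x_trace)], y = NULL,
                 syn = NULL, params = NULL, resp = resp),
            class = "sim_trace")
}

test_that("the spatial response integrates the normalized trace over one cycle", {
  # constant positive trace: x / max = 1 integrated over 400 ms
  tr <- make_trace(matrix(3, 2, 401))
  s <- mitral_response(tr)
  expect_equal(as.numeric(s), c(400, 400))

  # all-zero trace: the positivity guard zeroes the unit
  expect_equal(as.numeric(mitral_response(make_trace(matrix(0, 2, 401)))),
               c(0, 0))

  # positive rescaling leaves the response unchanged
  set.seed(5)
  xs <- matrix(abs(rnorm(3 * 401)) + 0.1, 3, 401)
  s1 <- mitral_response(make_trace(xs))
  s2 <- mitral_response(make_trace(xs * 17.3))
  expect_equal(as.numeric(s1), as.numeric(s2))

  expect_error(mitral_response(make_trace(matrix(1, 2, 100))),
               "less than one full")
})

test_that("only the last full cycle is scored", {
  xs <- cbind(matrix(5, 1, 400), matrix(2, 1, 401))
  s <- mitral_response(make_trace(xs))
  expect_equal(as.numeric(s), 400)  # constant over the final cycle
})

test_that("the response is insensitive to the recording stride", {
  g <- small_geom()
  syn <- quiet_synapses(g, 2, 3, seed = 6)
  mix <- mix_odorants(list(binarize_pattern(
    glomerular_pattern(as.numeric(seq_len(g$n_units) %% 3 == 0), g), 0.5)))
  sn <- sniff_waveform(mix, n_cycles = 1, dt = 1)
  s5 <- as.numeric(mitral_response(integrate_bulb(syn, sn, record_stride = 5L)))
  s10 <- as.numeric(mitral_response(integrate_bulb(syn, sn, record_stride = 10L)))
  s20 <- as.numeric(mitral_response(integrate_bulb(syn, sn, record_stride = 20L)))
  # sup error relative to the response scale (per-unit relative error is
  # meaningless for units whose own maximum sits near the guard); the
  # dominant stride effect is the per-unit grid maximum, which converges
  # at second order in the recording step
  expect_lt(max(abs(s10 - s5)) / max(abs(s5)), 5e-3)
  expect_lt(max(abs(s20 - s5)) / max(abs(s5)), 5e-2)
})

test_that("dissimilarity is one minus the Pearson correlation", {
  expect_equal(dissimilarity(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dissimilarity(c(1, 2, 3), c(3, 2, 1)), 2)
  # hand-computed from the definitional sums: r = 0.5
  expect_equal(dissimilarity(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(dissimilarity(c(1, 1, 1), c(1, 2, 3)), "zero variance.*first")
  expect_error(dissimilarity(c(1, 2), c(1, 2, 3)), "length")
})

test_that("dissimilarity matches the definitional-sum oracle on random vectors", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(dissimilarity(a, b), 1 - num / den, tolerance = 1e-12)
    # symmetry and range
    expect_equal(dissimilarity(a, b), dissimilarity(b, a))
    expect_gte(dissimilarity(a, b), 0)
    expect_lte(dissimilarity(a, b), 2)
    expect_equal(dissimilarity(a, a), 0)
    # invariant to positive affine rescaling
    expect_equal(dissimilarity(2.5 * a + 1, b), dissimilarity(a, b),
                 tolerance = 1e-12)
  }
})

test_that("behavior correlation reports r and the exact t-based p-value", {
  # construct vectors with correlation exactly 0.88 at n = 6
  x <- scale(1:6)[, 1]
  z <- scale(resid(lm(c(2, -1, 3, -2, 1, -3) ~ x)))[, 1]
  y <- 0.88 * x + sqrt(1 - 0.88^2) * z
  bc <- behavior_correlation(x, y)
  expect_equal(bc$r, 0.88, tolerance = 1e-12)
  expect_equal(bc$p, 0.020736, tolerance = 1e-4)
  expect_equal(bc$n, 6)

  # affine rates recover r = 1 with vanishing p
  e <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1)
  bc1 <- behavior_correlation(e, 50 + 30 * e)
  expect_equal(bc1$r, 1)
  expect_lt(bc1$p, 1e-10)
  bc2 <- behavior_correlation(e, 50 - 30 * e)
  expect_equal(bc2$r, -1)

  # permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  bc3 <- behavior_correlation(e[perm], (50 + 30 * e)[perm])
  expect_equal(bc3$r, bc1$r)
  expect_equal(bc3$p, bc1$p)

  expect_error(behavior_correlation(rep(1, 6), 1:6), "constant")
  expect_error(behavior_correlation(1:2, 1:2), "at least 3")
})

test_that("pairwise comparisons use Welch tests with Bonferroni correction", {
  set.seed(31)
  samples <- lapply(1:6, function(k) rnorm(20, mean = 0.1 * k, sd = 0.05))
  names(samples) <- paste0("o", 1:6)
  tab <- pairwise_bonferroni(samples)
  expect_equal(nrow(tab), 15)  # C(6, 2)
  expect_true(all(tab$adj_p >= tab$raw_p))
  expect_true(all(tab$adj_p <= 1))
  expect_equal(tab$adj_p, pmin(tab$raw_p * 15, 1))

  # raw p matches an independent Welch computation for one pair
  a <- samples[[1]]; b <- samples[[4]]
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 20 + var(b) / 20)
  df <- (var(a) / 20 + var(b) / 20)^2 /
    ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  p_ref <- 2 * pt(-abs(tstat), df)
  expect_equal(tab$raw_p[tab$odor_a == "o1" & tab$odor_b == "o4"], p_ref,
               tolerance = 1e-12)

  # identical samples are never significant
  same <- list(a = rep(0.4, 5), b = rep(0.4, 5))
  tab2 <- pairwise_bonferroni(same)
  expect_equal(tab2$adj_p, 1)
  expect_false(tab2$significant)

  # well-separated samples are significant at 0.01
  set.seed(7)
  far <- list(lo = rnorm(20, 0.1, 0.05), hi = rnorm(20, 1.0, 0.05))
  expect_true(pairwise_bonferroni(far)$significant)

  expect_error(pairwise_bonferroni(list(a = 1, b = 1:3)), "2 replicates")
  expect_error(pairwise_bonferroni(list(a = 1:3)), "2 odors")
})
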