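test_that("binning normalizes counts to mean 1", {
  # uniform positions: all bins near 1
  pos <- wgametrics:::local_seed(11, runif(2e5, 0, 1e5))
  d <- bin_and_normalize(pos, genome_length = 1e5)
  expect_identical(length(d$values), 400L)
  expect_lt(abs(mean(d$values) - 1), 1e-9)
  expect_true(all(abs(d$values - 1) < 0.5))

  # all reads in one bin of B bins -> that bin = B, others 0
  d1 <- bin_and_normalize(rep(10, 50), genome_length = 25000)
  expect_equal(d1$values[1], 100)
  expect_true(all(d1$values[-1] == 0))

  # one read total: defined, single bin value B
  d2 <- bin_and_normalize(0, genome_length = 2500)
  expect_equal(d2$values, c(10, rep(0, 9)))

  expect_error(bin_and_normalize(numeric(0), 1e4),
               class = "wga_insufficient_data")
  expect_error(bin_and_normalize(c(1, 1e5), genome_length = 1e5),
               class = "wga_malformed_input")
})

test_that("down-sampling draws floor(F * depth * L / (2 * 250)) pairs", {
  L <- 4686137                       # E. coli DH10B reference length
  expect_identical(pairs_for_depth(1, 20, L), 187445L)
  expect_identical(pairs_for_depth(0.5, 20, L), 93722L)
  expect_identical(pairs_for_depth(0, 20, L), 0L)

  pool <- seq_len(2e5)
  sub <- downsample_pairs(pool, 1, 20, L, seed = 1)
  expect_identical(length(sub), 187445L)
  expect_false(anyDuplicated(sub) > 0)
  expect_error(downsample_pairs(seq_len(1000), 1, 20, L),
               class = "wga_insufficient_data")
})

test_that("fractional coverage matches the Poisson zero class", {
  expect_equal(fractional_coverage(rep(0, 10)), 0)
  expect_equal(fractional_coverage(rep(2, 10)), 1)

  G <- 2e5
  depth <- 3
  starts <- wgametrics:::local_seed(21, {
    floor(runif(pairs_for_depth(1, depth, G), 0, G))
  })
  cov <- coverage_from_pair_starts(starts, G, span = 500)
  expect_identical(length(cov), as.integer(G))
  expect_equal(sum(cov), length(starts) * 500)   # mass conservation
  frac <- fractional_coverage(cov)
  expected <- 1 - exp(-depth)
  # binomial error on the covered fraction; bases are correlated over
  # a read span, widening the effective error by ~sqrt(span)
  tol <- 5 * sqrt(expected * (1 - expected) / (G / 500))
  expect_lt(abs(frac - expected), tol)
})

test_that("rarefaction is monotone and tracks 1 - exp(-d)", {
  G <- 1e5
  starts <- wgametrics:::local_seed(22, {
    floor(runif(pairs_for_depth(1, 12, G), 0, G))
  })
  grid <- c(0, 0.5, 1, 2, 4, 8)
  curve <- rarefaction_curve(starts, G, grid, seed = 3)
  expect_equal(curve$coverage[1], 0)
  expect_true(all(diff(curve$coverage) >= 0))
  expected <- 1 - exp(-grid[-1])
  tol <- 5 * sqrt(expected * (1 - expected) / (G / 500))
  expect_true(all(abs(curve$coverage[-1] - expected) < tol))

  adj <- rarefaction_curve(starts, G, grid, fraction_mapped = 0.5,
                           seed = 3)
  expect_equal(adj$raw_depth, grid / 0.5)

  expect_error(rarefaction_curve(starts, G, c(1, 100)),
               class = "wga_insufficient_data")
})

test_that("Gini matches hand values and is scale invariant", {
  expect_equal(gini_index(rep(5, 1000)), 0)
  expect_equal(gini_index(c(0, 0, 0, 9)), 0.75)
  x <- c(3, 0, 7, 2, 2, 9)
  expect_equal(gini_index(x * 7), gini_index(x))
  expect_error(gini_index(rep(0, 10)),
               class = "wga_insufficient_data")
  expect_error(gini_index(c(1, -1)), class = "wga_malformed_input")
})

test_that("Gini agrees with the Lorenz-area oracle and Pigou-Dalton", {
  for (s in 1:50) {
    x <- wgametrics:::local_seed(3000 + s,
                                 rpois(sample(5:200, 1),
                                       lambda = runif(1, 0.5, 20)))
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini_index(x), lorenz_gini_oracle(x),
                 tolerance = 1e-12)
    # transfer from a richer to a poorer site never increases Gini
    rich <- which.max(x)
    poor <- which.min(x)
    if (x[rich] > x[poor]) {
      y <- x
      amount <- (x[rich] - x[poor]) / 2
      y[rich] <- y[rich] - amount
      y[poor] <- y[poor] + amount
      expect_lte(gini_index(y), gini_index(x) + 1e-12)
    }
  }
})

test_that("the spectral fit recovers an AR(1) corner frequency", {
  # An AR(1) field with parameter phi has correlation length
  # tau = -1/log(phi) bins and a Lorentzian low-frequency spectrum
  # with corner 1 / (2 * pi * tau * bin_size).
  phi <- 0.9
  bin_size <- 250
  tau <- -1 / log(phi)
  theory <- 1 / (2 * pi * tau * bin_size)
  fcs <- vapply(1:5, function(s) {
    x <- wgametrics:::local_seed(400 + s, {
      as.numeric(arima.sim(list(ar = phi), 8192))
    })
    d <- mapping_density(exp(x / 10), bin_size = bin_size,
                         normalize = TRUE)
    fit <- spectral_rolloff(d)
    # the AR(1) spectrum exceeds a pure Lorentzian near Nyquist, so
    # allow a modest model-mismatch margin beyond the fit SE
    expect_true(abs(fit$fc - theory) < 2 * fit$fc_se ||
                  abs(fit$fc - theory) / theory < 0.35)
    fit$fc
  }, numeric(1))
  expect_lt(abs(median(fcs) - theory) / theory, 0.25)
})

test_that("white noise is reported as floor-dominated or ultra-fast", {
  x <- wgametrics:::local_seed(77, rnorm(4096, mean = 10, sd = 1))
  d <- mapping_density(x, bin_size = 250, normalize = TRUE)
  fit <- spectral_rolloff(d)
  expect_true(fit$floor_dominated || fit$fc > fit$nyquist / 2)
})

test_that("halving the base resolution doubles frequency units", {
  v <- wgametrics:::local_seed(88, {
    exp(as.numeric(arima.sim(list(ar = 0.8), 2048)) / 5)
  })
  d1 <- mapping_density(v, bin_size = 250, normalize = TRUE)
  d2 <- mapping_density(v, bin_size = 500, normalize = TRUE)
  f1 <- spectral_rolloff(d1, smoothing_window = 0)
  f2 <- spectral_rolloff(d2, smoothing_window = 0)
  expect_equal(f2$fc, f1$fc / 2, tolerance = 1e-8)
})

test_that("densities survive a BED-like round trip", {
  d <- simulate_bias_field(
    simulation_config(genome_length = 2e4, gain = 100, seed = 5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_density(d, path)
  back <- read_density(path)
  expect_equal(back$values, d$values, tolerance = 1e-12)
  expect_equal(back$bin_size, d$bin_size)
})
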