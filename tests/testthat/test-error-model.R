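test_that("discrepancy ratio applies both site filters", {
  sc <- data.frame(pos = 1:2, M = c(10, 8), C = c(0, 2))
  D <- discrepancy_ratio(sc, min_site_depth = 10,
                         max_contradiction_fraction = 0.5)
  expect_equal(as.numeric(D), 0.1)
  expect_identical(attr(D, "n_sites"), 2L)

  expect_equal(as.numeric(discrepancy_ratio(
    data.frame(M = c(20, 30), C = c(0, 0)))), 0)

  # a site contradicted in every base looks like a faulty reference
  faulty <- data.frame(M = 0, C = 10)
  expect_error(discrepancy_ratio(faulty, min_site_depth = 5,
                                 max_contradiction_fraction = 0.5),
               class = "wga_insufficient_data")

  # shallow sites are dropped
  mixed <- data.frame(M = c(3, 50), C = c(3, 1))
  D2 <- discrepancy_ratio(mixed, min_site_depth = 10)
  expect_equal(as.numeric(D2), 1 / 51)
})

test_that("D is invariant under uniform depth rescaling", {
  sc <- data.frame(M = c(100, 80, 120), C = c(1, 2, 0))
  sc10 <- data.frame(M = sc$M * 10, C = sc$C * 10)
  expect_equal(as.numeric(discrepancy_ratio(sc)),
               as.numeric(discrepancy_ratio(sc10)))
})

test_that("effective cycles is log2 of the gain", {
  expect_equal(effective_cycles(1), 0)
  expect_equal(effective_cycles(2), 1)
  expect_equal(effective_cycles(3000), 11.5507, tolerance = 1e-4)
  expect_error(effective_cycles(0.5), class = "wga_invalid_config")
})

test_that("a noiseless line is recovered exactly", {
  s <- data.frame(gain = 2^c(0, 10, 20),
                  D = 1e-3 + 2e-6 * c(0, 10, 20))
  fit <- fit_error_model(s)
  expect_equal(fit$D0, 1e-3, tolerance = 1e-12)
  expect_equal(fit$epsilon, 2e-6, tolerance = 1e-12)
  expect_false(fit$negative_slope)
})

test_that("samples beyond the gain cap are excluded from the fit", {
  s <- data.frame(gain = c(2^c(0, 10, 20), 1e9),
                  D = c(1e-3 + 2e-6 * c(0, 10, 20), 0.5))
  fit <- fit_error_model(s)
  expect_identical(fit$n_used, 3L)
  expect_lte(fit$gain_range[2], 5e7)
  expect_equal(fit$epsilon, 2e-6, tolerance = 1e-12)

  expect_error(fit_error_model(s[1:2, ]),
               class = "wga_insufficient_data")
})

test_that("epsilon recovery from simulated gain sweeps is unbiased", {
  run_sweep <- function(eps_true, seed) {
    gains <- 10^(1:7)
    D <- vapply(seq_along(gains), function(i) {
      cfg <- simulation_config(genome_length = 1e4, gain = gains[i],
                               epsilon = eps_true, d0 = 1e-3)
      sc <- simulate_site_counts(cfg, n_sites = 1e4, depth = 100,
                                 seed = seed * 100 + i)
      as.numeric(discrepancy_ratio(sc))
    }, numeric(1))
    fit_error_model(data.frame(gain = gains, D = D))
  }
  fits <- lapply(1:40, function(s) run_sweep(1e-5, s))
  errs <- vapply(fits, function(f) f$epsilon - 1e-5, numeric(1))
  # mean signed error within 2 standard errors of zero
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)))
  # and the typical estimate is close to the truth in relative terms
  expect_lt(median(abs(errs)) / 1e-5, 0.25)
})

test_that("extracting epsilon from one measurement is arithmetic", {
  # headline scenario: duplex-corrected baseline and an amplified
  # measurement at gain ~3000
  eps <- extract_epsilon(1.93e-5, 9.7e-7, gain = 3000)
  expect_equal(as.numeric(eps), 1.587e-6, tolerance = 1e-3)
  expect_true(eps > 1e-7 && eps < 1e-5)

  expect_equal(as.numeric(extract_epsilon(1e-3, 1e-3, gain = 100)), 0)
  expect_equal(as.numeric(extract_epsilon(5e-3, 2e-3, gain = 2)),
               3e-3)
  expect_warning(neg <- extract_epsilon(1e-4, 2e-4, gain = 100),
                 "non-physical")
  expect_true(attr(neg, "nonphysical"))
  expect_error(extract_epsilon(1e-3, 1e-4, gain = 1),
               class = "wga_invalid_config")
})

test_that("Q30 maps to an error probability of 1e-3", {
  expect_equal(phred_to_error_prob(30), 1e-3)
  expect_equal(phred_to_error_prob(20), 1e-2)
})

test_that("site counts survive a TSV round trip", {
  cfg <- simulation_config(genome_length = 1e4, gain = 1e3)
  sc <- simulate_site_counts(cfg, n_sites = 500, depth = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_counts(sc, path)
  back <- read_site_counts(path)
  expect_equal(back, sc)
})
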