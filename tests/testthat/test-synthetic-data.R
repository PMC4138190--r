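test_that("zero bias amplitude yields an exactly uniform field", {
  cfg <- simulation_config(genome_length = 1e4, bias_amplitude = 0,
                           gain = 1e6, seed = 1)
  d <- simulate_bias_field(cfg)
  expect_identical(d$values, rep(1, 40))
})

test_that("bias fields have mean 1 and are seed-reproducible", {
  for (chem in c("isothermal", "pcr")) {
    for (s in 1:5) {
      cfg <- simulation_config(genome_length = 5e4, gain = 10^s,
                               chemistry = chem, seed = s)
      d1 <- simulate_bias_field(cfg)
      d2 <- simulate_bias_field(cfg)
      expect_identical(d1, d2)
      expect_lt(abs(mean(d1$values) - 1), 1e-12)
      expect_true(all(d1$values >= 0))
    }
  }
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(simulate_bias_field(
    simulation_config(genome_length = 1e4, seed = 5)))
  invisible(simulate_site_counts(
    simulation_config(genome_length = 1e4), n_sites = 10, depth = 5,
    seed = 6))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("isothermal bias variance grows with gain, pcr does not", {
  n_rep <- 100
  var_at_gain <- function(chem, gain) {
    vapply(seq_len(n_rep), function(r) {
      cfg <- simulation_config(genome_length = 1.6e4, gain = gain,
                               chemistry = chem, seed = 1000 + r)
      var(simulate_bias_field(cfg)$values)
    }, numeric(1))
  }
  iso_lo <- var_at_gain("isothermal", 1e3)
  iso_hi <- var_at_gain("isothermal", 1e6)
  # same seed family: the latent Gaussian field is shared, only its
  # scale changes, so the inequality holds replicate by replicate
  expect_true(all(iso_hi > iso_lo))
  expect_lt(wilcox.test(iso_hi, iso_lo, alternative = "greater",
                        paired = TRUE)$p.value, 0.01)
  pcr_lo <- var_at_gain("pcr", 1e3)
  pcr_hi <- var_at_gain("pcr", 1e6)
  expect_identical(pcr_lo, pcr_hi)
})

test_that("generated fields round-trip their roll-off frequency", {
  fcs <- vapply(1:20, function(s) {
    cfg <- simulation_config(genome_length = 4e5, bin_size = 50,
                             gain = 1e3, rolloff_frequency = 1e-3,
                             bias_amplitude = 0.05, seed = 200 + s)
    spectral_rolloff(simulate_bias_field(cfg))$fc
  }, numeric(1))
  expect_true(all(fcs > 0.5e-3 & fcs < 1.5e-3))
})

test_that("binned coverage sampling matches its Poisson moments", {
  d <- mapping_density(rep(1, 1000), bin_size = 250)
  depth <- 100
  counts <- simulate_binned_coverage(d, depth = depth, seed = 3)
  lambda <- depth * 250 / 500
  expect_true(all(abs(counts - lambda) <= 5 * sqrt(lambda)))
  total <- sum(counts)
  expect_lt(abs(total - 1000 * lambda), 5 * sqrt(1000 * lambda))
  expect_error(simulate_binned_coverage(d, depth = 0),
               class = "wga_invalid_config")
})

test_that("a zero-density bin never receives reads", {
  v <- rep(1, 100)
  v[37] <- 0
  d <- mapping_density(v, bin_size = 250)
  for (s in 1:10) {
    counts <- simulate_binned_coverage(d, depth = 200, seed = s)
    expect_identical(counts[37], 0L)
  }
})

test_that("site counts follow p = d0 + epsilon * log2(gain)", {
  cfg0 <- simulation_config(genome_length = 1e4, epsilon = 0, d0 = 0)
  sc0 <- simulate_site_counts(cfg0, n_sites = 1000, depth = 20,
                              seed = 1)
  expect_true(all(sc0$C == 0))

  cfg1 <- simulation_config(genome_length = 1e4, gain = 1,
                            epsilon = 1e-2, d0 = 0.05)
  sc1 <- simulate_site_counts(cfg1, n_sites = 2e5, depth = 50,
                              seed = 2)
  p_hat <- sum(sc1$C) / sum(sc1$M + sc1$C)
  n_obs <- sum(sc1$M + sc1$C)
  expect_lt(abs(p_hat - 0.05), 5 * sqrt(0.05 * 0.95 / n_obs))

  # law of large numbers at n * depth >= 1e7
  cfg2 <- simulation_config(genome_length = 1e4, gain = 2^10,
                            epsilon = 1e-6, d0 = 1e-3)
  sc2 <- simulate_site_counts(cfg2, n_sites = 1e5, depth = 100,
                              seed = 3)
  p_true <- 1e-3 + 1e-6 * 10
  n_obs <- sum(sc2$M + sc2$C)
  expect_gte(n_obs, 1e7 * 0.99)
  expect_lt(abs(sum(sc2$C) / n_obs - p_true),
            5 * sqrt(p_true * (1 - p_true) / n_obs))

  cfg_bad <- simulation_config(genome_length = 1e4, gain = 2^20,
                               epsilon = 0.05, d0 = 0.5)
  expect_error(simulate_site_counts(cfg_bad, n_sites = 10, depth = 5),
               class = "wga_invalid_config")
})

test_that("inject_duplication renormalizes and respects wrapping", {
  d <- mapping_density(rep(1, 100), bin_size = 250)
  expect_equal(inject_duplication(d, 5, 2500, copy_number = 1)$values,
               d$values)

  # 10% of the genome duplicated: 2/1.1 inside, 1/1.1 outside
  dup <- inject_duplication(d, 11, 10 * 250, copy_number = 2)
  expect_equal(dup$values[11:20], rep(2 / 1.1, 10))
  expect_equal(dup$values[-(11:20)], rep(1 / 1.1, 90))
  expect_lt(abs(mean(dup$values) - 1), 1e-12)

  # wrapping across the origin is identical to an interior region
  # after rotation
  base <- random_density(100, seed = 42)
  interior <- inject_duplication(base, 30, 20 * 250)
  rot <- function(v, k) c(v[-seq_len(k)], v[seq_len(k)])
  rotated <- mapping_density(rot(base$values, 40), bin_size = 250,
                             normalize = FALSE)
  wrapped <- inject_duplication(rotated, 100 - 10, 20 * 250)
  expect_equal(wrapped$values, rot(interior$values, 40))

  expect_error(inject_duplication(d, 1, 2500, copy_number = 0),
               class = "wga_invalid_config")
})

test_that("read-pair generator produces the configured mixture", {
  empty <- simulate_read_pair_table(0)
  expect_identical(nrow(empty), 0L)
  cls0 <- classify_read_pairs(empty)
  expect_true(all(cls0$counts == 0))

  all_contam <- simulate_read_pair_table(500,
                                         contamination_fraction = 1,
                                         seed = 1)
  expect_equal(
    unname(classify_read_pairs(all_contam)$fractions["unmapped"]), 1)

  n <- 1e5
  tab <- simulate_read_pair_table(n, contamination_fraction = 0.1,
                                  discordant_fraction = 0.2, seed = 2)
  cls <- classify_read_pairs(tab)
  for (case in list(c("unmapped", 0.1), c("discordant", 0.2),
                    c("concordant", 0.7))) {
    p <- as.numeric(case[2])
    expect_lt(abs(cls$fractions[[case[1]]] - p),
              5 * sqrt(p * (1 - p) / n))
  }
  expect_error(simulate_read_pair_table(-1),
               class = "wga_invalid_config")
  expect_error(simulate_read_pair_table(10,
                                        contamination_fraction = 0.7,
                                        discordant_fraction = 0.5),
               class = "wga_invalid_config")
})

test_that("barcoded families are noise-free at zero error rate", {
  reads <- simulate_barcode_reads(20, per_read_error_rate = 0,
                                  seed = 4)
  expect_identical(unique(reads$read), attr(reads, "truth"))
  expect_identical(length(unique(paste(reads$barcode1,
                                       reads$barcode2))), 20L)
  expect_true(all(nchar(reads$barcode1) == 9))
})

test_that("a molecule-level variant survives duplex consensus", {
  reads <- simulate_barcode_reads(
    1, variant_positions = 10, per_read_error_rate = 0.01,
    read_length = 50, seed = 5)
  cons <- call_duplex_consensuses(reads)
  expect_identical(nrow(cons), 1L)
  expect_identical(substr(cons$sequence, 10, 10),
                   substr(attr(reads, "truth"), 10, 10))
  expect_false(substr(attr(reads, "truth"), 10, 10) ==
                 substr(attr(reads, "reference"), 10, 10))
})

test_that("singleton families yield no consensus under the 3-read rule", {
  reads <- simulate_barcode_reads(
    10, family_size_distribution = function(n) rep(1L, n), seed = 6)
  cons <- call_duplex_consensuses(reads, min_family_size = 3)
  expect_identical(nrow(cons), 0L)
})
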