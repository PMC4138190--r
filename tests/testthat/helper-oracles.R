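# Independent oracles used across the suite.  These deliberately use
# naive formulations (explicit Lorenz-curve geometry, position-by-
# position window means) so they share no code path with the package.

# Gini as twice the area between the empirical Lorenz curve and the
# diagonal, computed by trapezoidal integration of the curve itself.
lorenz_gini_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  cum_share <- c(0, cumsum(x) / sum(x))
  pop_share <- (0:n) / n
  # trapezoid area under the Lorenz curve
  area_under <- sum((cum_share[-1] + cum_share[-(n + 1)]) / 2 *
                      diff(pop_share))
  2 * (0.5 - area_under)
}

# Circular moving average by explicit per-position window means.
brute_circular_ma <- function(values, w_bins) {
  n <- length(values)
  half_lead <- floor((w_bins - 1) / 2)   # stats::filter centering for
  offset <- seq_len(w_bins) - 1 - half_lead  # even/odd windows
  vapply(seq_len(n), function(i) {
    mean(values[((i - 1 + offset) %% n) + 1])
  }, numeric(1))
}

# Brute-force minimal resolvable window: scan the full grid, take the
# start of the terminal all-passing run.
brute_min_window <- function(values, bin_size, step = 1000,
                             threshold = 2,
                             max_window = bin_size * length(values) / 2) {
  grid <- seq(step, max_window, by = step)
  maxima <- vapply(grid, function(w) {
    wb <- max(1, floor(w / bin_size))
    max(brute_circular_ma(values, wb))
  }, numeric(1))
  passing <- maxima < threshold
  if (!passing[length(grid)]) {
    return(list(W = NA_real_, failed = TRUE, maxima = maxima))
  }
  last_fail <- if (all(passing)) 0 else max(which(!passing))
  list(W = grid[last_fail + 1], failed = FALSE, maxima = maxima)
}

# A random density with occasional spikes, for oracle comparisons.
random_density <- function(n_bins, bin_size = 250, seed = NULL) {
  wgametrics:::local_seed(seed, {
    v <- rgamma(n_bins, shape = 4, rate = 4)
    if (runif(1) < 0.5) {
      k <- sample(3, 1)
      at <- sample(n_bins, k)
      v[at] <- v[at] * runif(k, 2, 8)
    }
    mapping_density(v, bin_size = bin_size, normalize = TRUE)
  })
}
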