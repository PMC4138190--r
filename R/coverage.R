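#' Bin read positions and normalize to a mean density of 1
#'
#' Histograms leftmost read-mapping coordinates (conventionally the
#' first mate of each pair) into fixed-size bins and divides by the mean
#' count, producing a normalized mapping density.  Bins are 0-based
#' half-open; a trailing partial bin is dropped, and positions falling
#' in it are discarded.
#'
#' @param positions 0-based leftmost mapping coordinates in
#'   `[0, genome_length)`.
#' @param genome_length genome length in bases.
#' @param bin_size bin width in bases (default 250).
#' @return A [mapping_density()].
#' @examples
#' d <- bin_and_normalize(c(0, 100, 300, 900), genome_length = 1000,
#'                        bin_size = 250)
#' d$values
#' @export
bin_and_normalize <- function(positions, genome_length, bin_size = 250) {
  if (length(positions) == 0L) {
    wga_stop_insufficient(
      "no mapping positions: the mean density is undefined")
  }
  if (any(positions < 0 | positions >= genome_length)) {
    wga_stop_malformed("positions must lie in [0, genome_length)")
  }
  n <- floor(genome_length / bin_size)
  bin <- floor(positions / bin_size) + 1L
  keep <- bin <= n                      # drop the partial trailing bin
  counts <- tabulate(bin[keep], nbins = n)
  mapping_density(counts, bin_size = bin_size,
                  genome_length = genome_length, normalize = TRUE)
}

#' Number of read pairs corresponding to a target depth
#'
#' `floor(F * target_depth * genome_length / (2 * read_length))`: the
#' pair count that down-samples a mapped set to `F * target_depth`
#' fold-coverage, where `F` is the fraction of raw read pairs that
#' mapped (use `fraction = 1` for depth in mapped pairs directly; use
#' the post-trimming survival fraction `T` when fixing raw pre-trimming
#' depth).
#'
#' @param fraction mapped (or surviving) fraction `F` in `[0, 1]`.
#' @param target_depth target fold-coverage.
#' @param genome_length genome length in bases.
#' @param read_length read length in bases (default 250).
#' @return Integer pair count.
#' @export
pairs_for_depth <- function(fraction, target_depth, genome_length,
                            read_length = 250) {
  if (fraction < 0 || fraction > 1) {
    wga_stop_invalid("`fraction` must lie in [0, 1]")
  }
  as.integer(floor(fraction * target_depth * genome_length /
                     (2 * read_length)))
}

#' Down-sample a set of read pairs to a fixed depth
#'
#' Uniform sampling without replacement of
#' [pairs_for_depth()]`(fraction, target_depth, ...)` pairs.  Samples
#' that cannot supply the requested count raise an insufficient-data
#' error (condition class `wga_insufficient_data`), mirroring the
#' convention of excluding experiments that did not generate enough
#' properly mapped reads.
#'
#' @param pairs the available pairs: a vector (e.g. of pair start
#'   coordinates) or a data.frame with one row per pair.
#' @param fraction mapped fraction `F` in `[0, 1]`.
#' @param target_depth target fold-coverage.
#' @param genome_length genome length in bases.
#' @param read_length read length in bases (default 250).
#' @param seed integer seed.
#' @return The down-sampled subset of `pairs` (same type).
#' @export
downsample_pairs <- function(pairs, fraction, target_depth,
                             genome_length, read_length = 250,
                             seed = NULL) {
  k <- pairs_for_depth(fraction, target_depth, genome_length,
                       read_length)
  n <- NROW(pairs)
  if (k > n) {
    wga_stop_insufficient(sprintf(
      "requested %d pairs but only %d available", k, n))
  }
  idx <- local_seed(seed, sample.int(n, k))
  if (is.data.frame(pairs)) pairs[idx, , drop = FALSE] else pairs[idx]
}

#' Per-base coverage from read-pair start coordinates
#'
#' Accumulates coverage counts over a circular genome, treating each
#' pair as covering `span` contiguous bases from its start (the
#' simulator's simplification of a 2 x 250 bp pair).
#'
#' @param starts 0-based pair start coordinates.
#' @param genome_length genome length in bases.
#' @param span bases covered per pair (default 500).
#' @return Integer vector of length `genome_length` with per-base
#'   counts.
#' @export
coverage_from_pair_starts <- function(starts, genome_length,
                                      span = 500) {
  genome_length <- as.integer(genome_length)
  s <- as.integer(starts %% genome_length)
  e <- s + as.integer(span)             # exclusive ends, may wrap
  delta <- tabulate(s + 1L, nbins = genome_length)
  ends <- tabulate(pmin(e, genome_length) + 1L,
                   nbins = genome_length)
  cov <- cumsum(delta - ends)
  over <- e - genome_length
  over <- over[over > 0L]
  if (length(over)) {                   # wrapped tails cover a prefix
    tail_counts <- rev(cumsum(rev(tabulate(over,
                                           nbins = genome_length))))
    cov <- cov + tail_counts
  }
  as.integer(cov)
}

#' Fraction of the genome covered at least once
#'
#' @param site_coverage per-base coverage counts.
#' @return `(number of bases with coverage >= 1) / length`, in `[0, 1]`.
#' @examples
#' fractional_coverage(c(0, 1, 3, 0))
#' @export
fractional_coverage <- function(site_coverage) {
  if (length(site_coverage) == 0L) {
    wga_stop_insufficient("empty coverage vector")
  }
  mean(site_coverage >= 1)
}

#' Rarefaction of fractional coverage against sampled depth
#'
#' Down-samples a set of mapped read pairs to each depth in `depths` and
#' reports the fraction of the genome covered at least once.  Subsets
#' are nested (prefixes of one seeded permutation), so the curve is
#' monotone non-decreasing by construction.  The optional
#' `fraction_mapped` adjusts the depth axis to raw (pre-mapping) depth:
#' `raw_depth = depth / fraction_mapped`.
#'
#' @param starts 0-based pair start coordinates of the mapped pairs.
#' @param genome_length genome length in bases.
#' @param depths increasing grid of mapped fold-coverage values.
#' @param read_length read length in bases (default 250).
#' @param span bases covered per pair (default `2 * read_length`).
#' @param fraction_mapped fraction of raw pairs that mapped (for the
#'   adjusted axis; default 1).
#' @param seed integer seed for the permutation.
#' @return A `data.frame` with columns `depth`, `raw_depth` and
#'   `coverage`.
#' @export
rarefaction_curve <- function(starts, genome_length, depths,
                              read_length = 250,
                              span = 2 * read_length,
                              fraction_mapped = 1, seed = NULL) {
  if (any(depths < 0)) {
    wga_stop_invalid("`depths` must be non-negative")
  }
  depths <- sort(depths)
  ks <- vapply(depths, function(d) {
    pairs_for_depth(1, d, genome_length, read_length)
  }, integer(1))
  if (max(ks) > length(starts)) {
    wga_stop_insufficient(sprintf(
      "deepest grid point needs %d pairs but only %d available",
      max(ks), length(starts)))
  }
  perm <- local_seed(seed, sample.int(length(starts)))
  coverage <- vapply(ks, function(k) {
    if (k == 0L) return(0)
    fractional_coverage(
      coverage_from_pair_starts(starts[perm[seq_len(k)]],
                                genome_length, span = span))
  }, numeric(1))
  data.frame(depth = depths, raw_depth = depths / fraction_mapped,
             coverage = coverage)
}

#' Gini index of a coverage distribution
#'
#' Inequality of per-site coverage, derived from the Lorenz curve: the
#' cumulative share of reads plotted against the cumulative share of
#' genome positions, ordered from lowest- to highest-covered.  The
#' index is twice the area between the observed Lorenz curve and the
#' diagonal of perfectly uniform coverage, so 0 indicates perfect
#' uniformity and 1 maximal non-uniformity.  It is invariant under
#' uniform rescaling of coverage.
#'
#' @param site_coverage non-negative per-site coverage counts with a
#'   positive total.
#' @return Gini index in `[0, 1]`.
#' @examples
#' gini_index(rep(5, 100))        # 0: perfectly uniform
#' gini_index(c(0, 0, 0, 12))     # 0.75: all reads on one of 4 sites
#' @export
gini_index <- function(site_coverage) {
  x <- site_coverage
  if (length(x) == 0L) {
    wga_stop_insufficient("empty coverage vector")
  }
  if (anyNA(x) || any(x < 0)) {
    wga_stop_malformed("coverage must be non-negative and non-missing")
  }
  total <- sum(x)
  if (total <= 0) {
    wga_stop_insufficient(
      "all-zero coverage: the Lorenz curve is undefined")
  }
  x <- sort(x)
  n <- length(x)
  # 2 * area between Lorenz curve and diagonal, in closed form
  sum((2 * seq_len(n) - n - 1) * x) / (n * total)
}

#' Roll-off frequency of the mapping-density power spectrum
#'
#' Computes the one-sided periodogram of the mean-removed density,
#' smooths it with a moving-average filter in frequency, and fits a
#' Lorentzian with a constant floor,
#' `S(f) = A / (1 + (f / f_c)^2) + B`, by least squares.  The corner
#' (roll-off) frequency `f_c` separates chemistries by the spatial
#' range of their amplification bias: isothermal MDA-like bias rolls
#' off at low frequency (long-range), PCR-based bias at high frequency
#' (short-range).
#'
#' @param density a [mapping_density()] with at least 64 bins.
#' @param smoothing_window width of the frequency-domain moving-average
#'   window, in cycles per base (default 2.13e-6).
#' @return An object of class `rolloff_fit`: a list with `fc` (cycles
#'   per base), `fc_se` (fit standard error), `A`, `B`,
#'   `floor_dominated` (`TRUE` when the fitted floor exceeds half the
#'   Lorentzian amplitude or `fc` exceeds half the Nyquist frequency,
#'   i.e. the spectrum is effectively flat), `nyquist`, and the fitted
#'   model in `fit`.
#' @examples
#' cfg <- simulation_config(genome_length = 2e5, bin_size = 50,
#'                          gain = 1e4, rolloff_frequency = 1e-3,
#'                          bias_amplitude = 0.04, seed = 3)
#' spectral_rolloff(simulate_bias_field(cfg))$fc
#' @export
spectral_rolloff <- function(density, smoothing_window = 2.13e-6) {
  density <- as_mapping_density(density)
  n <- n_bins(density)
  if (n < 64L) {
    wga_stop_invalid("spectral fitting requires at least 64 bins")
  }
  x <- density$values - mean(density$values)
  nf <- floor(n / 2)
  power <- (Mod(fft(x))^2 / n)[2:(nf + 1L)]
  f <- seq_len(nf) / (n * density$bin_size)
  df <- f[1L]
  wpts <- max(1L, round(smoothing_window / df))
  if (wpts > 1L) {
    sm <- stats::filter(power, rep(1 / wpts, wpts), sides = 2)
    keep <- !is.na(sm)
    power <- as.numeric(sm[keep])
    f <- f[keep]
  }
  nyquist <- 1 / (2 * density$bin_size)
  a0 <- max(mean(head(power, max(3L, nf %/% 100))), .Machine$double.eps)
  b0 <- max(median(tail(power, max(3L, nf %/% 10))),
            .Machine$double.eps)
  half <- which(power <= (a0 + b0) / 2)
  fc0 <- if (length(half)) f[half[1L]] else nyquist / 2
  fc0 <- min(max(fc0, f[1L]), nyquist)
  dat <- data.frame(f = f, p = power)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ A / (1 + (f / fc)^2) + B, data = dat,
                      start = list(A = a0, fc = fc0, B = b0),
                      lower = c(A = 0, fc = df / 10, B = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    wga_stop(sprintf("Lorentzian fit did not converge: %s",
                     conditionMessage(fit)),
             "wga_fit_failure",
             diagnostics = list(start = list(A = a0, fc = fc0, B = b0),
                                n_freq = length(f)))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(fc = unname(est["fc"]),
                 fc_se = unname(se["fc"]),
                 A = unname(est["A"]),
                 B = unname(est["B"]),
                 floor_dominated = unname(est["B"] > est["A"] / 2 ||
                                            est["fc"] > nyquist / 2),
                 nyquist = nyquist,
                 smoothing_window = smoothing_window,
                 fit = fit),
            class = "rolloff_fit")
}

#' @export
print.rolloff_fit <- function(x, ...) {
  cat(sprintf("<rolloff_fit> f_c = %.4g +/- %.2g per base%s\n",
              x$fc, x$fc_se,
              if (isTRUE(x$floor_dominated))
                "  [flat spectrum: floor-dominated]" else ""))
  invisible(x)
}
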