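#' Circular moving-average filter of a mapping density
#'
#' Applies a `window`-wide moving-average filter to the periodically
#' extended (circular) mapping density.  Each output bin is the mean of
#' the `floor(window / bin_size)`-bin circular neighborhood; the output
#' mean equals the input mean exactly.
#'
#' @param density a [mapping_density()].
#' @param window window width in bases (`bin_size <= window <=`
#'   genome length); converted to whole bins by `floor`.
#' @return A [mapping_density()] (not re-normalized: filtering already
#'   preserves the mean).
#' @examples
#' d <- mapping_density(c(3, rep(1, 99)), bin_size = 250)
#' max(circular_moving_average(d, 1000)$values)
#' @export
circular_moving_average <- function(density, window) {
  density <- as_mapping_density(density)
  if (window < density$bin_size) {
    wga_stop_invalid("`window` must be at least one bin wide")
  }
  if (window > density$genome_length) {
    wga_stop_invalid("`window` exceeds the genome length")
  }
  w <- max(1L, floor(window / density$bin_size))
  values <- as.numeric(stats::filter(density$values, rep(1 / w, w),
                                     method = "convolution",
                                     sides = 2, circular = TRUE))
  mapping_density(values, bin_size = density$bin_size,
                  genome_length = density$genome_length,
                  normalize = FALSE)
}

#' Minimal resolvable duplication size W
#'
#' The minimal-resolvable-CNV statistic: the minimum width `W` of a
#' sliding-window average filter such that *all* windows of width `>= W`
#' keep the filtered relative mapping density below `threshold`
#' (default 2) at every position of the circular genome.  The rationale
#' is that a gene duplication of length `W` would be detectable in the
#' smoothed data as a mapping density of at least 2, so `W` is the noise
#' threshold above which duplications become resolvable.
#'
#' Window widths are evaluated on the grid `step, 2 * step, ...` up to
#' `max_window`.  Because the maximum filtered density is not guaranteed
#' monotone in the window width, the full grid is scanned and `W` is the
#' start of the terminal run of passing windows.  If even the largest
#' window fails, a failure marker is returned.
#'
#' @param density a [mapping_density()] normalized to mean 1.
#' @param step grid step in bases (default 1000).
#' @param threshold relative-density threshold (default 2).
#' @param max_window largest window evaluated (default half the genome).
#' @return An object of class `resolvability_result`: a list with `W`
#'   (bases, or `NA` on failure), `failed`, `window_max` (named vector
#'   of the maximum filtered density per grid window), `threshold`,
#'   `step` and `grid`.
#' @examples
#' d <- mapping_density(rep(1, 1000), bin_size = 250)
#' min_resolvable_window(d)$W      # 1000: every window passes
#' @export
min_resolvable_window <- function(density, step = 1000, threshold = 2,
                                  max_window =
                                    density$genome_length / 2) {
  density <- as_mapping_density(density)
  if (step < density$bin_size) {
    wga_stop_invalid("`step` must be at least one bin")
  }
  grid <- seq(step, max_window, by = step)
  if (length(grid) == 0L) {
    wga_stop_invalid("empty window grid: increase `max_window`")
  }
  window_max <- vapply(grid, function(w) {
    max(circular_moving_average(density, w)$values)
  }, numeric(1))
  names(window_max) <- as.character(grid)
  passing <- window_max < threshold
  n <- length(grid)
  if (!passing[n]) {
    W <- NA_real_
    failed <- TRUE
  } else {
    # start of the terminal all-passing run
    first_fail_before <- if (all(passing)) 0L else max(which(!passing))
    W <- grid[first_fail_before + 1L]
    failed <- FALSE
  }
  structure(list(W = W, failed = failed, window_max = window_max,
                 threshold = threshold, step = step, grid = grid),
            class = "resolvability_result")
}

#' @export
print.resolvability_result <- function(x, ...) {
  if (x$failed) {
    cat(sprintf(
      "<resolvability_result> failure: no window <= %g bp passes (threshold %g)\n",
      max(x$grid), x$threshold))
  } else {
    cat(sprintf("<resolvability_result> W = %g bp (threshold %g, step %g)\n",
                x$W, x$threshold, x$step))
  }
  invisible(x)
}

#' Serialize resolvability results as a TSV table
#'
#' One row per sample with columns `sample`, `gain`, `W`; failures are
#' serialized as the string `"failure"`.
#'
#' @param results list of `resolvability_result` objects.
#' @param gains numeric vector of reaction gains, parallel to `results`.
#' @param path output TSV path.
#' @param samples sample labels.
#' @return `path`, invisibly.
#' @export
write_resolvability_table <- function(results, gains, path,
                                      samples = seq_along(results)) {
  W <- vapply(results, function(r) {
    if (r$failed) "failure" else format(r$W)
  }, character(1))
  write.table(data.frame(sample = samples, gain = gains, W = W),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
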