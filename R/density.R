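#' Binned mapping density over a circular genome
#'
#' A `mapping_density` holds read-mapping density in fixed-size bins over
#' a circular genome, normalized to a mean of 1.  It is the common
#' currency of the uniformity and copy-number analyses: bias fields are
#' simulated as densities, observed read positions are binned into them,
#' and the sliding-window resolvability statistic consumes them.
#'
#' Bins are 0-based half-open `[k * bin_size, (k + 1) * bin_size)`; a
#' trailing partial bin (when `bin_size` does not divide
#' `genome_length`) is dropped.
#'
#' @param values numeric vector of non-negative per-bin densities.
#' @param bin_size bin width in bases.
#' @param genome_length genome length in bases; defaults to
#'   `bin_size * length(values)`.
#' @param normalize if `TRUE` (default) divide `values` by their mean so
#'   the stored density has mean exactly 1.
#'
#' @return An object of class `mapping_density`: a list with elements
#'   `values`, `bin_size` and `genome_length`.
#' @examples
#' d <- mapping_density(rep(1, 100), bin_size = 250)
#' mean(d$values)
#' @export
mapping_density <- function(values, bin_size,
                            genome_length = bin_size * length(values),
                            normalize = TRUE) {
  if (!is.numeric(values) || length(values) < 1L) {
    wga_stop_invalid("`values` must be a non-empty numeric vector")
  }
  if (anyNA(values) || any(values < 0)) {
    wga_stop_invalid("densities must be non-negative and non-missing")
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    wga_stop_invalid("`bin_size` must be a single positive number")
  }
  if (genome_length <= 0) {
    wga_stop_invalid("`genome_length` must be positive")
  }
  n_expected <- floor(genome_length / bin_size)
  if (length(values) != n_expected) {
    wga_stop_invalid(sprintf(
      "expected floor(genome_length / bin_size) = %d bins, got %d",
      n_expected, length(values)))
  }
  if (normalize) {
    m <- mean(values)
    if (m <= 0) {
      wga_stop_invalid("cannot normalize an all-zero density")
    }
    values <- values / m
  }
  structure(list(values = as.numeric(values),
                 bin_size = as.numeric(bin_size),
                 genome_length = as.numeric(genome_length)),
            class = "mapping_density")
}

n_bins <- function(density) length(density$values)

as_mapping_density <- function(x) {
  if (!inherits(x, "mapping_density")) {
    wga_stop_invalid("expected a `mapping_density` object")
  }
  x
}

#' @export
print.mapping_density <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<mapping_density> %d bins of %g bp over %g bp (circular)\n",
    length(v), x$bin_size, x$genome_length))
  cat(sprintf("  mean %.6f, sd %.4f, range [%.4f, %.4f]\n",
              mean(v), sd(v), min(v), max(v)))
  invisible(x)
}

#' Read and write mapping densities as BED-like text
#'
#' Densities are serialized as three tab-separated columns without a
#' header: chromosome label, 0-based half-open bin start, and normalized
#' density, matching the layout of a BED graph track.
#'
#' @param density a [mapping_density()] object.
#' @param path file path.
#' @param chrom chromosome label written to the first column.
#' @return `write_density()` returns `path` invisibly; `read_density()`
#'   returns a `mapping_density`.
#' @export
write_density <- function(density, path, chrom = "genome") {
  density <- as_mapping_density(density)
  starts <- (seq_along(density$values) - 1L) * density$bin_size
  df <- data.frame(chrom = chrom, start = starts,
                   density = density$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @param genome_length genome length in bases; if `NULL`, taken as
#'   `bin_size * number of bins`.
#' @export
read_density <- function(path, genome_length = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "density"),
                   colClasses = c("character", "numeric", "numeric"))
  if (nrow(df) < 2L) {
    wga_stop_malformed("density file must contain at least two bins")
  }
  bin_size <- df$start[2L] - df$start[1L]
  if (bin_size <= 0 ||
      any(abs(diff(df$start) - bin_size) > 1e-9)) {
    wga_stop_malformed("bin starts must be evenly spaced and increasing")
  }
  if (is.null(genome_length)) {
    genome_length <- bin_size * nrow(df)
  }
  mapping_density(df$density, bin_size = bin_size,
                  genome_length = genome_length, normalize = FALSE)
}
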