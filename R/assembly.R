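#' LG50 assembly-contiguity statistic with failure sentinel
#'
#' The minimal number of assembled contigs (after discarding contigs
#' shorter than `min_contig` bases) whose cumulative length covers
#' `target_fraction` of the reference genome.  Contigs are sorted in
#' decreasing length and accumulated; coverage is length-based
#' (QUAST-style LG50 semantics).  Assemblies whose filtered contigs
#' cannot reach the target are assigned the *failure sentinel*
#' `floor(target_fraction * reference_length / min_contig)` -- the
#' largest value LG50 could take, i.e. the LG50 of a hypothetical
#' assembly made entirely of minimum-size contigs.  With the
#' reference length of *E. coli* DH10B (4,686,137 bp) and the default
#' 500-bp filter the sentinel is 4686.
#'
#' @param contig_lengths contig lengths in bases (positive integers);
#'   may be empty.
#' @param reference_length reference genome length in bases (> 0).
#' @param min_contig minimum contig length retained (default 500).
#' @param target_fraction fraction of the reference to cover (default
#'   0.5).
#' @return An object of class `lg50_result`: a list with `value` (the
#'   LG50, or the sentinel on failure), `failed`, `sentinel`,
#'   `n_contigs` (contigs passing the filter) and `covered_length`.
#' @examples
#' lg50(c(600, 600, 600), reference_length = 3000)$value   # 3
#' lg50(integer(0), reference_length = 4686137)$value      # sentinel 4686
#' @export
lg50 <- function(contig_lengths, reference_length, min_contig = 500,
                 target_fraction = 0.5) {
  if (!is.numeric(reference_length) || length(reference_length) != 1L ||
      reference_length <= 0) {
    wga_stop_invalid("`reference_length` must be a single positive number")
  }
  if (any(contig_lengths <= 0)) {
    wga_stop_invalid("contig lengths must be positive")
  }
  if (target_fraction <= 0 || target_fraction > 1) {
    wga_stop_invalid("`target_fraction` must lie in (0, 1]")
  }
  sentinel <- as.integer(floor(target_fraction * reference_length /
                                 min_contig))
  kept <- sort(contig_lengths[contig_lengths >= min_contig],
               decreasing = TRUE)
  target <- target_fraction * reference_length
  cum <- cumsum(as.numeric(kept))
  k <- which(cum >= target)[1L]
  failed <- is.na(k)
  structure(list(value = if (failed) sentinel else as.integer(k),
                 failed = failed,
                 sentinel = sentinel,
                 n_contigs = length(kept),
                 covered_length = if (length(cum)) cum[length(cum)]
                                  else 0),
            class = "lg50_result")
}

#' @export
print.lg50_result <- function(x, ...) {
  cat(sprintf("<lg50_result> LG50 = %d%s (sentinel %d, %d contigs kept)\n",
              x$value, if (x$failed) " [failure]" else "",
              x$sentinel, x$n_contigs))
  invisible(x)
}

#' Contig lengths from a FASTA file
#'
#' @param path FASTA path.
#' @return Integer vector of sequence lengths.
#' @export
contig_lengths_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    wga_stop("reading FASTA requires the Biostrings package",
             "wga_missing_dependency")
  }
  Biostrings::width(Biostrings::readDNAStringSet(path))
}

#' Write an LG50 report table
#'
#' One row per assembly; failures carry the sentinel in the `LG50`
#' column and the string `"failure"` in the `status` column.
#'
#' @param results list of `lg50_result` objects.
#' @param path output TSV path.
#' @param samples sample labels.
#' @return `path`, invisibly.
#' @export
write_lg50_report <- function(results, path,
                              samples = seq_along(results)) {
  df <- data.frame(
    sample = samples,
    LG50 = vapply(results, function(r) r$value, integer(1)),
    status = vapply(results, function(r) {
      if (r$failed) "failure" else "ok"
    }, character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
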