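#' Classify read pairs as concordant, discordant, or unmapped
#'
#' A read pair is *unmapped* when neither mate aligned.  A pair with
#' both mates aligned is *concordant* when the mates are in the expected
#' forward-reverse (FR) orientation with an end-to-end separation of at
#' most `max_separation` bases (boundary inclusive), and *discordant*
#' otherwise; discordant alignments typically indicate chimera formation
#' during amplification or library preparation.  Pairs with exactly one
#' mapped mate are counted as discordant by default; set
#' `half_mapped = "separate"` to tally them in their own class.
#'
#' @param pairs a `data.frame` with columns `mate1_mapped`,
#'   `mate2_mapped` (logical), `orientation` (`"FR"`, `"RF"`, `"FF"`,
#'   `"RR"` or `NA`) and `separation` (bases; `NA` unless both mates
#'   mapped), as produced by [simulate_read_pair_table()],
#'   [read_pair_records()] or [read_pair_records_sam()].
#' @param max_separation largest end-to-end separation still considered
#'   concordant (default 2000 bases).
#' @param half_mapped how to count pairs with exactly one mapped mate:
#'   `"discordant"` (default) folds them into the discordant class,
#'   `"separate"` reports them as their own `half_mapped` class.
#' @return An object of class `pair_classification`: a list with
#'   `counts` (named integer vector), `fractions` (counts / total, sum
#'   1), `total` and `max_separation`.  With no input pairs all counts
#'   are zero and fractions are `NaN`.
#' @examples
#' pairs <- simulate_read_pair_table(1000, contamination_fraction = 0.1,
#'                                   discordant_fraction = 0.2, seed = 1)
#' classify_read_pairs(pairs)
#' @export
classify_read_pairs <- function(pairs, max_separation = 2000,
                                half_mapped = c("discordant",
                                                "separate")) {
  half_mapped <- match.arg(half_mapped)
  required <- c("mate1_mapped", "mate2_mapped", "orientation",
                "separation")
  if (!is.data.frame(pairs) || !all(required %in% names(pairs))) {
    wga_stop_malformed(paste(
      "`pairs` must be a data.frame with columns",
      paste(required, collapse = ", ")))
  }
  sep <- pairs$separation
  if (any(!is.na(sep) & sep < 0)) {
    wga_stop_malformed("negative end-to-end separation encountered")
  }
  both_mapped <- pairs$mate1_mapped & pairs$mate2_mapped
  if (any(both_mapped & is.na(sep))) {
    wga_stop_malformed(
      "separation must be present when both mates are mapped")
  }
  unmapped <- !pairs$mate1_mapped & !pairs$mate2_mapped
  half <- xor(pairs$mate1_mapped, pairs$mate2_mapped)
  concordant <- both_mapped & pairs$orientation %in% "FR" &
    sep <= max_separation
  discordant <- both_mapped & !concordant
  counts <- c(concordant = sum(concordant),
              discordant = sum(discordant),
              unmapped = sum(unmapped))
  if (half_mapped == "separate") {
    counts <- c(counts, half_mapped = sum(half))
  } else {
    counts["discordant"] <- counts["discordant"] + sum(half)
  }
  total <- nrow(pairs)
  structure(list(counts = counts,
                 fractions = counts / total,
                 total = total,
                 max_separation = max_separation),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("<pair_classification> %d read pairs (max separation %g bp)\n",
              x$total, x$max_separation))
  for (k in names(x$counts)) {
    cat(sprintf("  %-11s %9d  (%.4f)\n", k, x$counts[[k]],
                x$fractions[[k]]))
  }
  invisible(x)
}

#' Write a one-row specificity report
#'
#' @param classification a `pair_classification` from
#'   [classify_read_pairs()].
#' @param path output TSV path.
#' @param sample sample label for the first column.
#' @return `path`, invisibly.
#' @export
write_specificity_report <- function(classification, path,
                                     sample = "sample") {
  x <- classification
  row <- data.frame(sample = sample, total = x$total,
                    as.list(x$counts),
                    as.list(stats::setNames(
                      x$fractions,
                      paste0("frac_", names(x$fractions)))))
  write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
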