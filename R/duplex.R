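# Duplex barcode consensus calling.  Reads sharing a dual 9-bp random
# barcode derive from one source molecule; collapsing each strand
# family by strict majority and requiring the two strand consensuses to
# agree suppresses both sequencing errors (random per read) and
# first-round amplification errors (strand-specific), leaving only
# errors present on both strands of the source molecule.

#' Group barcoded reads into strand families
#'
#' Partitions reads by `(barcode1, barcode2, strand)` and discards
#' families smaller than `min_family_size` (at least three reads are
#' required for consensus building by default).  Barcodes are matched
#' exactly; error-tolerant barcode clustering is a documented
#' non-feature.
#'
#' @param reads a `data.frame` with columns `barcode1`, `barcode2`,
#'   `strand` and `read`, as from [simulate_barcode_reads()] or
#'   [read_barcode_fastq()].
#' @param min_family_size smallest family retained (default 3).
#' @return A list of `barcode_family` objects (each a list with
#'   `barcode_pair`, `strand`, `reads`), with attribute `n_discarded`
#'   giving the number of families dropped for being too small.
#' @export
group_families <- function(reads, min_family_size = 3) {
  required <- c("barcode1", "barcode2", "strand", "read")
  if (!is.data.frame(reads) || !all(required %in% names(reads))) {
    wga_stop_malformed(paste("`reads` must have columns",
                             paste(required, collapse = ", ")))
  }
  if (nrow(reads) == 0L) {
    return(structure(list(), n_discarded = 0L))
  }
  key <- paste(reads$barcode1, reads$barcode2, reads$strand,
               sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  n_discarded <- 0L
  families <- vector("list", length(groups))
  keep <- logical(length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    member_reads <- reads$read[idx]
    if (length(unique(nchar(member_reads))) != 1L) {
      wga_stop_malformed(
        "reads within a barcode family must have equal length")
    }
    if (length(idx) < min_family_size) {
      n_discarded <- n_discarded + 1L
      next
    }
    keep[i] <- TRUE
    families[[i]] <- structure(
      list(barcode_pair = c(reads$barcode1[idx[1L]],
                            reads$barcode2[idx[1L]]),
           strand = reads$strand[idx[1L]],
           reads = member_reads),
      class = "barcode_family")
  }
  structure(families[keep], n_discarded = n_discarded)
}

# Decode reads to an integer code matrix (positions x reads).
read_code_matrix <- function(reads) {
  vapply(reads, function(r) utf8ToInt(r), integer(nchar(reads[1L])),
         USE.NAMES = FALSE)
}

#' Strand consensus of a barcode family
#'
#' Per position, the base carried by a strict majority (> `majority`
#' share) of family members; positions with a tie or no majority are
#' called `N`.  Strict majority with `N` on ties is the most
#' conservative reading of consensus collapsing.
#'
#' @param family a `barcode_family` from [group_families()], or a
#'   character vector of equal-length reads.
#' @param majority required vote share, strict (default 0.5).
#' @return The consensus string over `{A, C, G, T, N}`.
#' @examples
#' strand_consensus(c("ACGT", "ACGT", "ACCT"))   # "ACGT"
#' strand_consensus(c("AA", "AC", "AG"))         # "AN"
#' @export
strand_consensus <- function(family, majority = 0.5) {
  reads <- if (inherits(family, "barcode_family")) family$reads
           else family
  if (length(reads) == 0L) {
    wga_stop_insufficient("cannot build a consensus from zero reads")
  }
  if (length(unique(nchar(reads))) != 1L) {
    wga_stop_malformed("reads must have equal length")
  }
  m <- read_code_matrix(reads)
  if (is.null(dim(m))) m <- matrix(m, ncol = length(reads))
  n <- length(reads)
  need <- majority * n               # strictly more votes than this
  best_count <- integer(nrow(m))
  best_code <- integer(nrow(m))
  for (code in utf8ToInt("ACGT")) {
    cnt <- rowSums(m == code)
    better <- cnt > best_count
    best_count[better] <- cnt[better]
    best_code[better] <- code
  }
  out <- ifelse(best_count > need, best_code, utf8ToInt("N"))
  intToUtf8(out)
}

#' Merge two strand consensuses into a duplex consensus
#'
#' Per position, the shared base when the top- and bottom-strand
#' consensuses agree and neither is `N`; otherwise `N`.  Disagreement
#' between strands indicates a first-round or strand-specific error, so
#' the position is masked rather than called.
#'
#' @param top,bottom equal-length consensus strings.
#' @return The duplex consensus string over `{A, C, G, T, N}`.
#' @examples
#' duplex_merge("ACGT", "ACTT")   # "ACNT"
#' @export
duplex_merge <- function(top, bottom) {
  if (nchar(top) != nchar(bottom)) {
    wga_stop_malformed("strand consensuses must have equal length")
  }
  a <- utf8ToInt(top)
  b <- utf8ToInt(bottom)
  nn <- utf8ToInt("N")
  intToUtf8(ifelse(a == b & a != nn, a, nn))
}

#' Call duplex consensuses for a whole read set
#'
#' Groups reads into strand families, collapses each strand by strict
#' majority, and emits a duplex consensus for every barcode pair whose
#' top and bottom families both meet `min_family_size`.
#'
#' @inheritParams group_families
#' @param majority vote share for [strand_consensus()].
#' @return A `data.frame` with columns `barcode1`, `barcode2`,
#'   `sequence`, `n_top`, `n_bottom`.
#' @export
call_duplex_consensuses <- function(reads, min_family_size = 3,
                                    majority = 0.5) {
  families <- group_families(reads, min_family_size = min_family_size)
  if (length(families) == 0L) {
    return(data.frame(barcode1 = character(0), barcode2 = character(0),
                      sequence = character(0), n_top = integer(0),
                      n_bottom = integer(0)))
  }
  pair_key <- vapply(families, function(f) {
    paste(f$barcode_pair, collapse = "\r")
  }, character(1))
  strands <- vapply(families, function(f) f$strand, character(1))
  out <- list()
  for (key in unique(pair_key)) {
    idx <- which(pair_key == key)
    top_i <- idx[strands[idx] == "top"]
    bot_i <- idx[strands[idx] == "bottom"]
    if (length(top_i) != 1L || length(bot_i) != 1L) next
    top_fam <- families[[top_i]]
    bot_fam <- families[[bot_i]]
    seq <- duplex_merge(strand_consensus(top_fam, majority),
                        strand_consensus(bot_fam, majority))
    out[[length(out) + 1L]] <- data.frame(
      barcode1 = top_fam$barcode_pair[1L],
      barcode2 = top_fam$barcode_pair[2L],
      sequence = seq,
      n_top = length(top_fam$reads),
      n_bottom = length(bot_fam$reads))
  }
  if (length(out) == 0L) {
    return(data.frame(barcode1 = character(0), barcode2 = character(0),
                      sequence = character(0), n_top = integer(0),
                      n_bottom = integer(0)))
  }
  do.call(rbind, out)
}

#' Post-consensus discrepancy against a known truth
#'
#' Fraction of non-`N` consensus bases that differ from the true
#' molecule sequence -- the validation harness for the error-correction
#' detection limit on simulated data.
#'
#' @param consensuses character vector of consensus sequences.
#' @param truth the true sequence (recycled) or a parallel vector.
#' @return The discrepancy fraction, with attributes `n_bases`
#'   (non-`N` bases compared) and `n_errors`.  When every consensus
#'   base is `N` there is no data to compare and `NA` is returned with
#'   `n_bases = 0`.
#' @export
post_consensus_error_rate <- function(consensuses, truth) {
  if (length(truth) == 1L) {
    truth <- rep(truth, length(consensuses))
  }
  if (length(truth) != length(consensuses)) {
    wga_stop_malformed("`truth` must be length 1 or match `consensuses`")
  }
  n_bases <- 0L
  n_errors <- 0L
  nn <- utf8ToInt("N")
  for (i in seq_along(consensuses)) {
    a <- utf8ToInt(consensuses[i])
    b <- utf8ToInt(truth[i])
    if (length(a) != length(b)) {
      wga_stop_malformed("consensus and truth lengths differ")
    }
    informative <- a != nn
    n_bases <- n_bases + sum(informative)
    n_errors <- n_errors + sum(a[informative] != b[informative])
  }
  rate <- if (n_bases == 0) NA_real_ else n_errors / n_bases
  attr(rate, "n_bases") <- n_bases
  attr(rate, "n_errors") <- n_errors
  rate
}

#' Duplex error-suppression experiment
#'
#' End-to-end harness: simulates barcoded duplex read families with
#' [simulate_barcode_reads()], calls duplex consensuses with
#' [call_duplex_consensuses()], and measures the post-consensus error
#' rate against the known truth.  Molecules are processed in seeded
#' chunks so arbitrarily many consensus bases can be accumulated in
#' bounded memory.
#'
#' @param n_molecules total number of source molecules.
#' @param read_length read length in bases.
#' @param family_size reads per strand family.
#' @param per_read_error_rate per-base substitution rate in `[0, 0.25]`.
#' @param variant_positions passed to [simulate_barcode_reads()].
#' @param min_family_size consensus threshold (default 3).
#' @param seed integer seed.
#' @param chunk_size molecules per chunk.
#' @return A list with `error_rate`, `n_bases`, `n_errors`,
#'   `n_consensus` (duplex consensuses emitted) and `n_molecules`.
#' @export
duplex_error_experiment <- function(n_molecules, read_length = 100,
                                    family_size = 5,
                                    per_read_error_rate = 0.01,
                                    variant_positions = integer(0),
                                    min_family_size = 3, seed = NULL,
                                    chunk_size = 2000) {
  n_bases <- 0
  n_errors <- 0
  n_consensus <- 0L
  done <- 0L
  chunk_id <- 0L
  while (done < n_molecules) {
    chunk_id <- chunk_id + 1L
    n <- min(chunk_size, n_molecules - done)
    reads <- simulate_barcode_reads(
      n, family_size_distribution = function(k) rep(family_size, k),
      variant_positions = variant_positions,
      per_read_error_rate = per_read_error_rate,
      read_length = read_length,
      seed = subseed(seed, chunk_id))
    cons <- call_duplex_consensuses(reads,
                                    min_family_size = min_family_size)
    if (nrow(cons)) {
      rate <- post_consensus_error_rate(cons$sequence,
                                        attr(reads, "truth"))
      n_bases <- n_bases + attr(rate, "n_bases")
      n_errors <- n_errors + attr(rate, "n_errors")
      n_consensus <- n_consensus + nrow(cons)
    }
    done <- done + n
  }
  list(error_rate = if (n_bases > 0) n_errors / n_bases else NA_real_,
       n_bases = n_bases, n_errors = n_errors,
       n_consensus = n_consensus, n_molecules = n_molecules)
}
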