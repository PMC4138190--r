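# Delimited-text interchange for the alignment-derived tables the
# metrics consume: per-site matched/contradicted counts, read-pair
# records, and barcoded reads as FASTQ.  BAM/SAM ingestion goes through
# Rsamtools; FASTA/FASTQ through Biostrings.

#' Read and write per-site count tables
#'
#' Site counts are serialized as a three-column TSV with header
#' `pos`, `M` (matched bases) and `C` (contradicted bases).
#'
#' @param counts a `data.frame` with columns `pos`, `M`, `C`.
#' @param path file path.
#' @return `write_site_counts()` returns `path` invisibly;
#'   `read_site_counts()` returns the `data.frame`.
#' @export
write_site_counts <- function(counts, path) {
  if (!all(c("pos", "M", "C") %in% names(counts))) {
    wga_stop_malformed("`counts` must have columns pos, M, C")
  }
  write.table(counts[, c("pos", "M", "C")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!all(c("pos", "M", "C") %in% names(df))) {
    wga_stop_malformed("site-count file must have columns pos, M, C")
  }
  df
}

#' Read and write read-pair record tables
#'
#' Read-pair records (mate mapping flags, orientation, end-to-end
#' separation) as a TSV with header; `NA` encodes absent values.
#'
#' @param pairs a `data.frame` as produced by
#'   [simulate_read_pair_table()].
#' @param path file path.
#' @return `write_read_pair_records()` returns `path` invisibly;
#'   [read_pair_records()] returns the `data.frame`.
#' @export
write_read_pair_records <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_read_pair_records
#' @export
read_pair_records <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(mate1_mapped = "logical",
                                  mate2_mapped = "logical",
                                  orientation = "character",
                                  separation = "numeric"))
  required <- c("mate1_mapped", "mate2_mapped", "orientation",
                "separation")
  if (!all(required %in% names(df))) {
    wga_stop_malformed(paste("read-pair file must have columns",
                             paste(required, collapse = ", ")))
  }
  df
}

#' Derive read-pair records from a SAM or BAM file
#'
#' Extracts one record per read pair from primary alignments: whether
#' each mate mapped, the pair orientation (`FR` when the leftmost mate
#' is on the forward strand and its mate on the reverse strand, etc.),
#' and the end-to-end (outer-coordinate) separation.  SAM input is
#' converted to BAM on the fly.
#'
#' @param path SAM or BAM path.
#' @return A `data.frame` suitable for [classify_read_pairs()].
#' @export
read_pair_records_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    wga_stop("SAM/BAM ingestion requires the Rsamtools package",
             "wga_missing_dependency")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "strand", "pos", "qwidth"))
  a <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- a$flag
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  paired <- bitwAnd(flag, 1L) != 0L
  keep <- primary & paired
  qname <- a$qname[keep]
  flag <- flag[keep]
  strand <- as.character(a$strand[keep])
  pos <- a$pos[keep]
  qwidth <- a$qwidth[keep]
  mapped <- bitwAnd(flag, 4L) == 0L
  first <- bitwAnd(flag, 64L) != 0L

  records <- lapply(split(seq_along(qname), qname), function(idx) {
    m1 <- idx[first[idx]][1L]
    m2 <- idx[!first[idx]][1L]
    m1_mapped <- !is.na(m1) && mapped[m1]
    m2_mapped <- !is.na(m2) && mapped[m2]
    orientation <- NA_character_
    separation <- NA_real_
    if (m1_mapped && m2_mapped) {
      left <- if (pos[m1] <= pos[m2]) m1 else m2
      right <- if (pos[m1] <= pos[m2]) m2 else m1
      orientation <- paste0(
        if (strand[left] == "+") "F" else "R",
        if (strand[right] == "+") "F" else "R")
      separation <- (pos[right] + qwidth[right] - 1) - pos[left] + 1
    }
    data.frame(mate1_mapped = m1_mapped, mate2_mapped = m2_mapped,
               orientation = orientation, separation = separation)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Write and read barcoded reads as FASTQ
#'
#' Reads are written as FASTQ with the barcode pair and strand encoded
#' in the read name
#' (`mol<molecule><delim><barcode1>+<barcode2><delim><strand>`) and a
#' constant placeholder quality string.
#'
#' @param reads a `data.frame` as from [simulate_barcode_reads()].
#' @param path FASTQ path.
#' @param delimiter field delimiter inside the read name (default
#'   `":"`).
#' @return `write_barcode_fastq()` returns `path` invisibly;
#'   `read_barcode_fastq()` returns a `data.frame` with columns
#'   `molecule`, `barcode1`, `barcode2`, `strand`, `read`.
#' @export
write_barcode_fastq <- function(reads, path, delimiter = ":") {
  names_ <- paste0("mol", reads$molecule, delimiter,
                   reads$barcode1, "+", reads$barcode2, delimiter,
                   reads$strand)
  lines <- character(4L * nrow(reads))
  lines[seq(1L, by = 4L, length.out = nrow(reads))] <-
    paste0("@", names_)
  lines[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$read
  lines[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = nrow(reads))] <-
    vapply(nchar(reads$read),
           function(k) strrep("I", k), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_barcode_fastq
#' @export
read_barcode_fastq <- function(path, delimiter = ":") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    wga_stop("reading FASTQ requires the Biostrings package",
             "wga_missing_dependency")
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  fields <- strsplit(names(seqs), delimiter, fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) != 3L
  if (any(bad)) {
    wga_stop_malformed(
      "read names must be <molecule><delim><tags><delim><strand>")
  }
  tags <- strsplit(vapply(fields, `[[`, character(1), 2L), "+",
                   fixed = TRUE)
  data.frame(
    molecule = sub("^mol", "", vapply(fields, `[[`, character(1), 1L)),
    barcode1 = vapply(tags, `[[`, character(1), 1L),
    barcode2 = vapply(tags, `[[`, character(1), 2L),
    strand = vapply(fields, `[[`, character(1), 3L),
    read = as.character(seqs))
}
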