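#' Configuration for the WGA sequencing simulator
#'
#' Bundles the parameters of a simulated whole-genome-amplification
#' (WGA) reaction and its sequencing readout.  The simulator emulates
#' the statistical structure of WGA-amplified bacterial-scale
#' sequencing: a multiplicative amplification-bias field with
#' chemistry-specific spectral character, an error load that grows with
#' the effective number of reaction cycles `N = log2(gain)`, a
#' contamination fraction of unmappable reads, and barcoded read
#' families for duplex consensus.
#'
#' @param genome_length genome length in bases (circular).
#' @param bin_size bin width in bases for binned densities (default 250).
#' @param gain amplification gain, the ratio of DNA output mass to input
#'   mass; must be >= 1.
#' @param chemistry `"isothermal"` for MDA-like amplification whose bias
#'   compounds with gain, or `"pcr"` for PCR-based chemistries
#'   (MALBAC-like) whose bias is insensitive to gain.
#' @param rolloff_frequency corner frequency of the Lorentzian bias
#'   power spectrum, in cycles per base.  `NULL` selects a
#'   chemistry-specific default: 4.15e-5 for isothermal (long-range
#'   bias) and 1e-3 for pcr (short-range bias).
#' @param bias_amplitude standard deviation of the log-bias field per
#'   effective amplification cycle (dimensionless).
#' @param epsilon per-base, per-cycle replication error rate of the
#'   amplifying polymerase.
#' @param d0 baseline per-base discrepancy probability (sequencing
#'   noise floor; a Q30 base-call cutoff corresponds to 1e-3).
#' @param contamination_fraction fraction of read pairs that derive from
#'   contaminating DNA and fail to map, in `[0, 1]`.
#' @param depth mean fold-coverage of the simulated sequencing run.
#' @param read_span bases covered by one read pair (2 x 250 by default,
#'   paired-end 250-bp reads).
#' @param seed integer seed; all randomness in simulations driven by
#'   this config flows from it.
#'
#' @return A `simulation_config` object (validated list).
#' @examples
#' cfg <- simulation_config(genome_length = 1e5, gain = 1000, seed = 1)
#' cfg$rolloff_frequency
#' @seealso [simulate_bias_field()], [simulate_site_counts()]
#' @export
simulation_config <- function(genome_length,
                              bin_size = 250,
                              gain = 1000,
                              chemistry = c("isothermal", "pcr"),
                              rolloff_frequency = NULL,
                              bias_amplitude = 0.05,
                              epsilon = 1e-6,
                              d0 = 1e-3,
                              contamination_fraction = 0,
                              depth = 5,
                              read_span = 500,
                              seed = NULL) {
  chemistry <- match.arg(chemistry)
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      !is.finite(genome_length) || genome_length <= 0) {
    wga_stop_invalid("`genome_length` must be a single positive number")
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    wga_stop_invalid("`bin_size` must be a single positive number")
  }
  if (!is.numeric(gain) || length(gain) != 1L || gain < 1) {
    wga_stop_invalid("`gain` must be >= 1")
  }
  if (is.null(rolloff_frequency)) {
    rolloff_frequency <- switch(chemistry,
                                isothermal = 4.15e-5,
                                pcr = 1e-3)
  }
  if (rolloff_frequency <= 0) {
    wga_stop_invalid("`rolloff_frequency` must be > 0")
  }
  if (bias_amplitude < 0) {
    wga_stop_invalid("`bias_amplitude` must be >= 0")
  }
  if (epsilon < 0 || d0 < 0) {
    wga_stop_invalid("`epsilon` and `d0` must be >= 0")
  }
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    wga_stop_invalid("`contamination_fraction` must be in [0, 1]")
  }
  if (depth <= 0) {
    wga_stop_invalid("`depth` must be > 0")
  }
  if (read_span <= 0) {
    wga_stop_invalid("`read_span` must be > 0")
  }
  structure(list(genome_length = genome_length,
                 bin_size = bin_size,
                 gain = gain,
                 chemistry = chemistry,
                 rolloff_frequency = rolloff_frequency,
                 bias_amplitude = bias_amplitude,
                 epsilon = epsilon,
                 d0 = d0,
                 contamination_fraction = contamination_fraction,
                 depth = depth,
                 read_span = read_span,
                 seed = seed),
            class = "simulation_config")
}

# Log-bias standard deviation implied by a config.  Isothermal bias
# compounds per effective doubling (worsens with gain); PCR-based bias
# is gain-independent and pinned to a fixed 10-cycle equivalent so the
# two chemistries match at gain ~ 1e3.
log_bias_sd <- function(config) {
  switch(config$chemistry,
         isothermal = config$bias_amplitude * log2(config$gain),
         pcr = config$bias_amplitude * 10)
}

#' Simulate a gain-dependent amplification-bias field
#'
#' Synthesizes the multiplicative coverage bias a WGA reaction imprints
#' on a circular genome.  The log-bias is a stationary Gaussian field
#' generated in the frequency domain with a Lorentzian target power
#' spectrum `S(f) = 1 / (1 + (f / f_c)^2)`, where `f_c` is
#' `config$rolloff_frequency`; the field is then exponentiated and
#' normalized to mean 1.  Frequency-domain synthesis against a
#' Lorentzian target reproduces the observed spectral signature of WGA
#' bias -- low roll-off frequencies (long-range bias) for isothermal
#' chemistry, high roll-off (short-range bias) for PCR-based chemistry
#' -- and the exponential guarantees positivity.
#'
#' The log-field standard deviation is `bias_amplitude * log2(gain)` for
#' `chemistry = "isothermal"` (bias compounds with every effective
#' doubling, so uniformity degrades with gain) and gain-independent for
#' `chemistry = "pcr"`.
#'
#' @param config a [simulation_config()].
#' @param seed overrides `config$seed` when given.
#' @return A [mapping_density()] with mean exactly 1.
#' @examples
#' cfg <- simulation_config(genome_length = 1e5, gain = 1e4, seed = 7)
#' field <- simulate_bias_field(cfg)
#' mean(field$values)
#' @export
simulate_bias_field <- function(config, seed = config$seed) {
  if (!inherits(config, "simulation_config")) {
    wga_stop_invalid("`config` must be a `simulation_config`")
  }
  n <- floor(config$genome_length / config$bin_size)
  if (n < 16L) {
    wga_stop_invalid(
      "bias-field synthesis requires >= 16 bins; increase genome_length")
  }
  sigma <- log_bias_sd(config)
  if (sigma == 0) {
    return(mapping_density(rep(1, n), bin_size = config$bin_size,
                           genome_length = config$genome_length,
                           normalize = FALSE))
  }
  local_seed(seed, {
    # Hermitian filtering of white noise: fft of iid normals carries an
    # exactly symmetric spectrum, so shaping it by sqrt(S) and inverse
    # transforming yields a real Gaussian field with PSD proportional
    # to the Lorentzian target.
    freq_idx <- seq_len(n) - 1L
    f <- pmin(freq_idx, n - freq_idx) / (n * config$bin_size)
    S <- 1 / (1 + (f / config$rolloff_frequency)^2)
    S[1L] <- 0                       # zero-mean field
    w <- rnorm(n)
    g <- Re(fft(fft(w) * sqrt(S), inverse = TRUE)) / n
    g <- g - mean(g)
    g <- g * (sigma / sd(g))
    values <- exp(g)
    mapping_density(values, bin_size = config$bin_size,
                    genome_length = config$genome_length,
                    normalize = TRUE)
  })
}

#' Simulate per-bin read counts from a bias field
#'
#' Draws independent Poisson read-pair counts per bin with expectation
#' `depth * bin_density * bin_size / read_span`, the sampling layer that
#' converts a normalized bias field into an observed binned coverage
#' profile at a given sequencing depth.
#'
#' @param density a [mapping_density()].
#' @param depth mean fold-coverage (> 0).
#' @param seed integer seed.
#' @param read_span bases covered by one read pair (default 500).
#' @return Integer vector of per-bin counts.
#' @export
simulate_binned_coverage <- function(density, depth, seed = NULL,
                                     read_span = 500) {
  density <- as_mapping_density(density)
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    wga_stop_invalid("`depth` must be a single value > 0")
  }
  lambda <- depth * density$values * density$bin_size / read_span
  local_seed(seed, rpois(length(lambda), lambda))
}

#' Simulate per-site matched/contradicted base counts
#'
#' At each of `n_sites` reference positions, a Poisson(`depth`) number
#' of bases is observed; each observed base contradicts the reference
#' independently with probability `p = d0 + epsilon * log2(gain)` and
#' matches it otherwise.  This is the generative counterpart of the
#' discrepancy-ratio analysis: the amplification error load grows
#' linearly with the effective cycle number `N = log2(gain)` on top of
#' the sequencing noise floor `d0`.
#'
#' @param config a [simulation_config()] supplying `gain`, `epsilon`
#'   and `d0`.
#' @param n_sites number of reference sites (>= 1).
#' @param depth mean per-site depth; defaults to `config$depth`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A `data.frame` with columns `pos`, `M` (matched) and `C`
#'   (contradicted); `M + C` is the site's sampled depth.
#' @examples
#' cfg <- simulation_config(genome_length = 1e5, gain = 1024,
#'                          epsilon = 1e-6, d0 = 1e-3)
#' sc <- simulate_site_counts(cfg, n_sites = 1000, depth = 30, seed = 2)
#' sum(sc$C) / sum(sc$M + sc$C)     # ~ 1e-3 + 10 * 1e-6
#' @export
simulate_site_counts <- function(config, n_sites, depth = config$depth,
                                 seed = config$seed) {
  if (!inherits(config, "simulation_config")) {
    wga_stop_invalid("`config` must be a `simulation_config`")
  }
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1) {
    wga_stop_invalid("`n_sites` must be >= 1")
  }
  p <- config$d0 + config$epsilon * log2(config$gain)
  if (p >= 1) {
    wga_stop_invalid(sprintf(
      "discrepancy probability d0 + epsilon * log2(gain) = %.3g >= 1", p))
  }
  local_seed(seed, {
    dep <- rpois(n_sites, depth)
    C <- rbinom(n_sites, dep, p)
    data.frame(pos = seq_len(n_sites), M = dep - C, C = C)
  })
}

#' Inject a copy-number duplication into a density
#'
#' Multiplies the density by `copy_number` over a region of the circular
#' genome (wrapping across the origin is allowed) and re-normalizes to
#' mean 1, emulating the mapping-density signature of a gene
#' duplication: a region whose smoothed relative density approaches
#' `copy_number`.
#'
#' @param density a [mapping_density()].
#' @param start_bin 1-based index of the first bin of the region.
#' @param length region length in bases (>= one bin).
#' @param copy_number copy number of the region (> 0; 1 is a no-op).
#' @return A [mapping_density()] with mean 1.
#' @export
inject_duplication <- function(density, start_bin, length,
                               copy_number = 2) {
  density <- as_mapping_density(density)
  if (copy_number <= 0) {
    wga_stop_invalid("`copy_number` must be > 0")
  }
  n <- n_bins(density)
  if (length < density$bin_size) {
    wga_stop_invalid("duplication `length` must be at least one bin")
  }
  nb <- max(1L, floor(length / density$bin_size))
  if (nb > n) {
    wga_stop_invalid("duplication does not fit on the genome")
  }
  if (start_bin < 1L || start_bin > n) {
    wga_stop_invalid("`start_bin` out of range")
  }
  idx <- ((start_bin - 1L + seq_len(nb) - 1L) %% n) + 1L
  values <- density$values
  values[idx] <- values[idx] * copy_number
  mapping_density(values, bin_size = density$bin_size,
                  genome_length = density$genome_length,
                  normalize = TRUE)
}

#' Simulate a table of read-pair mapping records
#'
#' Generates read pairs of three kinds: contaminated pairs (both mates
#' unmapped, emulating foreign DNA that fails to align), discordant
#' pairs (orientation other than forward-reverse, or end-to-end
#' separation beyond 2000 bp, emulating amplification or library
#' chimeras), and concordant pairs (forward-reverse with separation
#' <= 2000 bp).
#'
#' @param n_pairs number of pairs (>= 0).
#' @param contamination_fraction fraction of unmapped pairs.
#' @param discordant_fraction fraction of discordant pairs.
#' @param separation_distribution function of `n` returning `n`
#'   concordant end-to-end separations in bases; defaults to uniform on
#'   `[250, 1500]`.  Values are truncated at 2000.
#' @param seed integer seed.
#' @return A `data.frame` with columns `mate1_mapped`, `mate2_mapped`,
#'   `orientation` (`FR`, `RF`, `FF`, `RR`, or `NA` when unmapped) and
#'   `separation` (`NA` unless both mates mapped).
#' @seealso [classify_read_pairs()]
#' @export
simulate_read_pair_table <- function(n_pairs,
                                     contamination_fraction = 0,
                                     discordant_fraction = 0,
                                     separation_distribution = NULL,
                                     seed = NULL) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 0) {
    wga_stop_invalid("`n_pairs` must be >= 0")
  }
  n_pairs <- as.integer(n_pairs)
  if (contamination_fraction < 0 || contamination_fraction > 1 ||
      discordant_fraction < 0 || discordant_fraction > 1 ||
      contamination_fraction + discordant_fraction > 1) {
    wga_stop_invalid(
      "fractions must lie in [0, 1] and sum to at most 1")
  }
  if (is.null(separation_distribution)) {
    separation_distribution <- function(n) round(runif(n, 250, 1500))
  }
  empty <- data.frame(mate1_mapped = logical(0),
                      mate2_mapped = logical(0),
                      orientation = character(0),
                      separation = numeric(0))
  if (n_pairs == 0L) return(empty)
  local_seed(seed, {
    kind <- sample(c("unmapped", "discordant", "concordant"), n_pairs,
                   replace = TRUE,
                   prob = c(contamination_fraction, discordant_fraction,
                            1 - contamination_fraction -
                              discordant_fraction))
    mate1 <- kind != "unmapped"
    mate2 <- kind != "unmapped"
    orientation <- rep(NA_character_, n_pairs)
    separation <- rep(NA_real_, n_pairs)

    conc <- which(kind == "concordant")
    if (length(conc)) {
      orientation[conc] <- "FR"
      separation[conc] <- pmin(separation_distribution(length(conc)),
                               2000)
    }
    disc <- which(kind == "discordant")
    if (length(disc)) {
      # half violate orientation, half violate the separation bound
      bad_orient <- runif(length(disc)) < 0.5
      orientation[disc] <- ifelse(
        bad_orient, sample(c("RF", "FF", "RR"), length(disc),
                           replace = TRUE), "FR")
      separation[disc] <- ifelse(
        bad_orient, pmin(separation_distribution(length(disc)), 2000),
        2000 + ceiling(runif(length(disc), 1, 2000)))
    }
    data.frame(mate1_mapped = mate1, mate2_mapped = mate2,
               orientation = orientation, separation = separation)
  })
}

BASES <- c("A", "C", "G", "T")

random_tags <- function(n, width = 9L) {
  codes <- matrix(sample.int(4L, n * width, replace = TRUE),
                  nrow = width)
  apply(codes, 2L, function(col) paste(BASES[col], collapse = ""))
}

#' Simulate barcoded duplex read families
#'
#' Emulates a duplex molecular-barcoding experiment: each source
#' molecule receives a unique pair of random 9-bp tags, is read in
#' top-strand and bottom-strand families whose sizes are drawn from
#' `family_size_distribution`, and every read carries i.i.d. per-base
#' substitution noise.  True variants (relative to the shared reference
#' sequence) are present in every read of every molecule, so duplex
#' consensus calling must preserve them while suppressing read noise.
#'
#' @param n_molecules number of source molecules.
#' @param family_size_distribution function of `n` returning `n` family
#'   sizes (used independently for the top and bottom strands); defaults
#'   to a constant 5.
#' @param variant_positions 1-based positions (within the read) at which
#'   the molecules carry a non-reference base.
#' @param per_read_error_rate per-base substitution probability in
#'   `[0, 0.25]`.
#' @param read_length read length in bases.
#' @param seed integer seed.
#' @return A `data.frame` with columns `molecule`, `barcode1`,
#'   `barcode2`, `strand` (`"top"`/`"bottom"`) and `read`.  Attributes:
#'   `reference` (error-free reference sequence), `truth` (reference
#'   with variants applied -- the true molecule sequence) and
#'   `variant_positions`.
#' @seealso [group_families()], [duplex_merge()]
#' @export
simulate_barcode_reads <- function(n_molecules,
                                   family_size_distribution = NULL,
                                   variant_positions = integer(0),
                                   per_read_error_rate = 0,
                                   read_length = 100L,
                                   seed = NULL) {
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L ||
      n_molecules < 0) {
    wga_stop_invalid("`n_molecules` must be >= 0")
  }
  if (per_read_error_rate < 0 || per_read_error_rate > 0.25) {
    wga_stop_invalid("`per_read_error_rate` must lie in [0, 0.25]")
  }
  if (length(variant_positions) &&
      (min(variant_positions) < 1 ||
       max(variant_positions) > read_length)) {
    wga_stop_invalid("`variant_positions` must lie within the read")
  }
  if (is.null(family_size_distribution)) {
    family_size_distribution <- function(n) rep(5L, n)
  }
  n_molecules <- as.integer(n_molecules)
  empty <- data.frame(molecule = integer(0), barcode1 = character(0),
                      barcode2 = character(0), strand = character(0),
                      read = character(0))
  local_seed(seed, {
    ref_codes <- sample.int(4L, read_length, replace = TRUE)
    truth_codes <- ref_codes
    if (length(variant_positions)) {
      vp <- as.integer(variant_positions)
      truth_codes[vp] <- (ref_codes[vp] %% 4L) + 1L  # any other base
    }
    reference <- paste(BASES[ref_codes], collapse = "")
    truth <- paste(BASES[truth_codes], collapse = "")
    if (n_molecules == 0L) {
      out <- empty
    } else {
      b1 <- random_tags(n_molecules)
      b2 <- random_tags(n_molecules)
      repeat {                     # unique dual tags by construction
        dup <- duplicated(paste(b1, b2))
        if (!any(dup)) break
        b1[dup] <- random_tags(sum(dup))
        b2[dup] <- random_tags(sum(dup))
      }
      top_sizes <- as.integer(family_size_distribution(n_molecules))
      bot_sizes <- as.integer(family_size_distribution(n_molecules))
      if (any(top_sizes < 1L) || any(bot_sizes < 1L)) {
        wga_stop_invalid("family sizes must be >= 1")
      }
      sizes <- c(rbind(top_sizes, bot_sizes))
      mol <- rep(rep(seq_len(n_molecules), each = 2L), sizes)
      strand <- rep(rep(c("top", "bottom"), n_molecules), sizes)
      n_reads <- sum(sizes)
      codes <- matrix(rep(truth_codes, n_reads), nrow = read_length)
      if (per_read_error_rate > 0) {
        n_err <- rbinom(1L, n_reads * read_length,
                        per_read_error_rate)
        if (n_err > 0L) {
          at <- sample.int(n_reads * read_length, n_err)
          codes[at] <- ((codes[at] - 1L + sample.int(3L, n_err,
                                                     replace = TRUE))
                        %% 4L) + 1L
        }
      }
      reads <- vapply(seq_len(n_reads), function(j) {
        paste(BASES[codes[, j]], collapse = "")
      }, character(1))
      out <- data.frame(molecule = mol,
                        barcode1 = b1[mol],
                        barcode2 = b2[mol],
                        strand = strand,
                        read = reads)
    }
    attr(out, "reference") <- reference
    attr(out, "truth") <- truth
    attr(out, "variant_positions") <- as.integer(variant_positions)
    out
  })
}
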