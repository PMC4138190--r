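#' Combined single-nucleotide discrepancy ratio D
#'
#' For each reference site `i`, `M_i` counts the bases matching the
#' reference among proper alignments and `C_i` the bases contradicting
#' it.  After discarding sites with insufficient coverage
#' (`M_i + C_i < min_site_depth`) and sites whose contradiction fraction
#' exceeds `max_contradiction_fraction` (typically indicative of a
#' faulty reference base), the discrepancy ratio is
#' `D = sum(C_i) / sum(M_i + C_i)` over the retained sites.
#'
#' Both filter cutoffs are deliberately mandatory-by-default arguments
#' with documented defaults: the filters' purpose (coverage floor,
#' faulty-reference guard) is fixed, their exact values are tunable.
#'
#' @param counts a `data.frame` with integer columns `M` and `C`
#'   (matched / contradicted base tallies per site), as from
#'   [simulate_site_counts()] or [read_site_counts()].
#' @param min_site_depth minimum `M_i + C_i` for a site to be retained
#'   (default 10).
#' @param max_contradiction_fraction maximum `C_i / (M_i + C_i)`
#'   (default 0.5).
#' @return `D` in `[0, 1]`, with attribute `n_sites` (retained sites).
#' @examples
#' sc <- data.frame(M = c(10, 8), C = c(0, 2))
#' discrepancy_ratio(sc, min_site_depth = 10)   # 2 / 20 = 0.1
#' @export
discrepancy_ratio <- function(counts, min_site_depth = 10,
                              max_contradiction_fraction = 0.5) {
  if (!is.data.frame(counts) || !all(c("M", "C") %in% names(counts))) {
    wga_stop_malformed("`counts` must have columns `M` and `C`")
  }
  if (any(counts$M < 0) || any(counts$C < 0)) {
    wga_stop_malformed("`M` and `C` must be non-negative")
  }
  depth <- counts$M + counts$C
  keep <- depth >= min_site_depth &
    ifelse(depth > 0, counts$C / depth, 0) <= max_contradiction_fraction
  if (!any(keep)) {
    wga_stop_insufficient("no sites pass the depth/contradiction filters")
  }
  D <- sum(counts$C[keep]) / sum(depth[keep])
  attr(D, "n_sites") <- sum(keep)
  D
}

#' Effective number of amplification cycles
#'
#' `N = log2(gain)`: the number of genome doublings equivalent to the
#' observed reaction gain (output mass over input mass).
#'
#' @param gain reaction gain, `>= 1`.
#' @return `N >= 0`.
#' @examples
#' effective_cycles(3000)   # ~ 11.55
#' @export
effective_cycles <- function(gain) {
  if (any(!is.finite(gain)) || any(gain < 1)) {
    wga_stop_invalid("`gain` must be finite and >= 1")
  }
  log2(gain)
}

#' Fit the gain--error model D = D0 + epsilon * N
#'
#' For gains up to `gain_max` the discrepancy ratio grows
#' logarithmically with the reaction gain, i.e. linearly in the
#' effective cycle number `N = log2(gain)`.  Ordinary least squares of
#' `D` on `N` yields the baseline discrepancy `D0` (the intercept --
#' sequencing errors and reference inaccuracies) and the per-base,
#' per-cycle replication error rate `epsilon` (the slope).  The fit is
#' unweighted; samples with gain outside `[1, gain_max]` are excluded
#' and the range actually used is reported.  A negative fitted slope is
#' returned as-is with `negative_slope = TRUE`, never clamped.
#'
#' @param samples a `data.frame` with columns `gain` and `D`.
#' @param gain_max upper gain bound of the model's validity (default
#'   5e7).
#' @return An object of class `error_model_fit`: a list with `D0`,
#'   `epsilon`, `D0_se`, `epsilon_se`, `gain_range`, `n_used`,
#'   `negative_slope` and the underlying `lm` fit.
#' @examples
#' s <- data.frame(gain = 2^c(0, 10, 20),
#'                 D = 1e-3 + 2e-6 * c(0, 10, 20))
#' fit_error_model(s)$epsilon
#' @export
fit_error_model <- function(samples, gain_max = 5e7) {
  if (!is.data.frame(samples) ||
      !all(c("gain", "D") %in% names(samples))) {
    wga_stop_malformed("`samples` must have columns `gain` and `D`")
  }
  use <- samples$gain >= 1 & samples$gain <= gain_max &
    is.finite(samples$D)
  kept <- samples[use, , drop = FALSE]
  N <- effective_cycles(kept$gain)
  if (nrow(kept) < 3L || length(unique(N)) < 3L) {
    wga_stop_insufficient(
      "need >= 3 samples with distinct effective cycle numbers in range")
  }
  fit <- lm(D ~ N, data = data.frame(N = N, D = kept$D))
  # noiseless inputs trigger lm's perfect-fit warning; the zero SEs it
  # produces are exactly what we want to report
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(D0 = unname(cf["(Intercept)", "Estimate"]),
                 epsilon = unname(cf["N", "Estimate"]),
                 D0_se = unname(cf["(Intercept)", "Std. Error"]),
                 epsilon_se = unname(cf["N", "Std. Error"]),
                 gain_range = range(kept$gain),
                 n_used = nrow(kept),
                 negative_slope = unname(cf["N", "Estimate"] < 0),
                 fit = fit),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat(sprintf(
    "<error_model_fit> D = D0 + epsilon * log2(gain)  [n = %d, gain %g..%g]\n",
    x$n_used, x$gain_range[1], x$gain_range[2]))
  cat(sprintf("  D0      = %.4g +/- %.2g\n", x$D0, x$D0_se))
  cat(sprintf("  epsilon = %.4g +/- %.2g%s\n", x$epsilon, x$epsilon_se,
              if (x$negative_slope) "  [warning: negative slope]" else ""))
  invisible(x)
}

#' Extract a per-cycle error rate from one measurement
#'
#' Inverts the gain--error model for a single sample:
#' `epsilon = (D - D0) / log2(gain)`.  When `D < D0` the result is
#' negative and hence non-physical; it is returned unclamped with
#' attribute `nonphysical = TRUE` and a warning.
#'
#' @param D measured discrepancy ratio.
#' @param D0 baseline discrepancy (e.g. from an unamplified control).
#' @param gain reaction gain, `> 1`.
#' @return `epsilon` (per base per cycle).
#' @examples
#' extract_epsilon(1.93e-5, 9.7e-7, gain = 3000)  # ~ 1.6e-6
#' @export
extract_epsilon <- function(D, D0, gain) {
  if (gain <= 1) {
    wga_stop_invalid("`gain` must be > 1 (log2(gain) would be 0)")
  }
  eps <- (D - D0) / log2(gain)
  if (D < D0) {
    warning("D < D0: extracted epsilon is negative (non-physical)")
    attr(eps, "nonphysical") <- TRUE
  }
  eps
}

#' Phred quality score to error probability
#'
#' `p = 10^(-Q / 10)`; a Q = 30 trimming cutoff corresponds to a
#' per-base error probability of 0.001, the expected order of the
#' baseline discrepancy `D0` after Q30 quality trimming.
#'
#' @param q Phred quality score(s).
#' @return Error probability `p` in `(0, 1]`.
#' @examples
#' phred_to_error_prob(30)
#' @export
phred_to_error_prob <- function(q) {
  if (any(q < 0)) wga_stop_invalid("Phred scores must be >= 0")
  10^(-q / 10)
}
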