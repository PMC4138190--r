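# wgametrics

Quantitative quality metrics for single-cell whole-genome amplification
(WGA) sequencing.

Single-cell workflows must amplify a genome by factors of 10³–10⁹
before sequencing, and the amplification **gain** `G` (DNA output mass
over input mass) governs almost every quality trade-off.  Isothermal
chemistry (MDA) has a proofreading polymerase — low error rates — but
its coverage bias compounds with every effective doubling; PCR-based
chemistries (MALBAC-like kits) have gain-insensitive, short-range bias
but roughly tenfold higher error rates and more contamination-prone
protocols.  `wgametrics` implements the metric suite used to measure
those trade-offs from alignment-derived tables, plus a seeded simulator
so every stage runs without sequencing data:

| metric | function | meaning |
|---|---|---|
| specificity | `classify_read_pairs()` | concordant (FR, separation ≤ 2000 bp) / discordant / unmapped read-pair fractions |
| mapping density | `bin_and_normalize()` | 250-bp binned read-start density, normalized to mean 1 |
| fractional coverage | `fractional_coverage()`, `rarefaction_curve()` | genome fraction covered ≥ 1× at a fixed down-sampled depth |
| uniformity | `gini_index()` | Lorenz-curve Gini index of per-site coverage (0 uniform, 1 maximally skewed) |
| bias range | `spectral_rolloff()` | Lorentzian corner frequency `f_c` of the density power spectrum |
| CNV resolvability | `min_resolvable_window()` | `W`: smallest moving-average window keeping smoothed density < 2 everywhere |
| error load | `discrepancy_ratio()`, `fit_error_model()` | `D = D₀ + ε·N`, `N = log₂(G)`; `ε` = per-base per-cycle error rate |
| duplex consensus | `group_families()`, `duplex_merge()` | strict-majority strand consensus + strand agreement over dual 9-bp barcodes |
| assembly contiguity | `lg50()` | LG50 (≥ 500 bp contigs covering 50% of the reference) with failure sentinel |

The simulator (`simulation_config()`, `simulate_bias_field()`,
`simulate_site_counts()`, `simulate_read_pair_table()`,
`simulate_barcode_reads()`) generates gain-dependent multiplicative
bias fields with chemistry-specific Lorentzian spectra, error loads
growing as `D₀ + ε·log₂(G)`, contaminated/discordant read pairs, and
barcoded duplex read families.  See the vignette
(`vignettes/wga-quality-metrics.Rmd`) for the models, parameter
meanings and design decisions.

## Worked example

Simulate an isothermal gain sweep and compute every metric:

```r
library(wgametrics)

cfg <- list(samples = list(
  list(label = "wga_1e2", gain = 1e2, chemistry = "isothermal"),
  list(label = "wga_1e3", gain = 1e3, chemistry = "isothermal"),
  list(label = "wga_1e5", gain = 1e5, chemistry = "isothermal"),
  list(label = "wga_1e7", gain = 1e7, chemistry = "isothermal")),
  epsilon = 1e-5,          # PCR-like per-base, per-cycle error rate
  genome_length = 1e5, seed = 42)
rep <- run_report(cfg)
rep$samples[, c("sample", "gain", "N", "frac_unmapped",
                "fractional_coverage", "gini", "W", "D")]
#>    sample  gain     N frac_unmapped fractional_coverage  gini     W       D
#> 1 wga_1e2 1e+02  6.64        0.0217               0.972 0.381  2000 0.00109
#> 2 wga_1e3 1e+03  9.97        0.0204               0.976 0.429  6000 0.00109
#> 3 wga_1e5 1e+05 16.61        0.0193               0.923 0.528 15000 0.00116
#> 4 wga_1e7 1e+07 23.25        0.0196               0.837 0.643 18000 0.00122
```

Reading the table: as the gain rises from 10² to 10⁷ the bias field
compounds, so fractional coverage at fixed depth falls (0.97 → 0.84),
the Gini index rises (0.38 → 0.64), and the smallest resolvable
duplication `W` grows (2 kb → 18 kb).  The discrepancy ratio `D` climbs
with the effective cycle number `N = log₂(G)`; fitting `D = D₀ + ε·N`
across the sweep recovers the simulator's parameters:

```r
str(rep$error_model)
#> $ D0        : num 0.00102      # truth 1e-3 (the Q30 noise floor)
#> $ epsilon   : num 8.46e-06     # truth 1e-5, within 1.5 fit SE
#> $ epsilon_se: num 1.01e-06
```

Single-measurement inversion with a duplex-corrected baseline — an
error rate of 1.93×10⁻⁵ at gain ≈ 3000 over a 9.7×10⁻⁷ floor — gives
the polymerase's per-cycle error rate:

```r
extract_epsilon(1.93e-5, 9.7e-7, gain = 3000)
#> [1] 1.58691e-06
```

And LG50 with the failure convention for the *E. coli* DH10B reference:

```r
lg50(c(3e5, 2e5, rep(5e4, 40)), reference_length = 4686137)
#> <lg50_result> LG50 = 39 (sentinel 4686, 42 contigs kept)
```

A thin command-line wrapper over `run_report()` is installed at
`inst/scripts/wga_report.R`.

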