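---
title: "Quality metrics for whole-genome-amplified sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality metrics for whole-genome-amplified sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgametrics)
```

## The problem

Single-cell sequencing workflows amplify femtogram-to-picogram genomic
input by factors of $10^3$ to $10^9$ before library preparation.  The
amplification *gain* $G$ -- output DNA mass over input mass -- is the
central reaction parameter, and the two families of whole-genome
amplification (WGA) chemistry respond to it very differently.
Isothermal multiple displacement amplification (MDA) uses a
strand-displacing, proofreading polymerase: its per-base errors are
rare, but its coverage bias compounds with every effective doubling, so
uniformity degrades as $G$ grows.  PCR-based chemistries (MALBAC-like
kits) have bias that is largely insensitive to gain and concentrated at
short genomic length scales, at the price of a roughly tenfold higher
polymerase error rate and greater vulnerability to contamination.

`wgametrics` implements the metric suite needed to quantify these
trade-offs from alignment-derived tables, together with a seeded
simulator so that every metric can be validated end to end without
sequencing data.

## Metrics

**Specificity.**  A read pair is *unmapped* when neither mate aligns,
*concordant* when both mates align in forward--reverse (FR) orientation
with end-to-end separation $\le 2000$ bp (boundary inclusive), and
*discordant* otherwise.  The tallies partition the input; fractions sum
to one.  How pairs with exactly one aligned mate were tallied in the
original analyses is not documented; `classify_read_pairs()` counts
them as discordant (they are not concordant paired-end alignments, and
they are not unmapped) and exposes `half_mapped = "separate"` for users
who want them reported apart.

**Mapping density and uniformity.**  Leftmost mapping positions are
histogrammed in 250-bp bins over the circular genome and normalized to
a mean of 1 (`bin_and_normalize()`).  Coverage uniformity is summarized
three ways:

* *Fractional coverage* at a fixed down-sampled depth.  Down-sampling
  to depth $d$ uses $\lfloor F \cdot d \cdot L / (2 \cdot 250)\rfloor$
  pairs, where $F$ is the mapped (or quality-surviving) fraction and
  $L$ the genome length; samples that cannot supply that many pairs
  raise an insufficient-data error rather than being silently padded.
* The *Gini index* of the per-site coverage distribution, from the
  Lorenz curve of cumulative read share against cumulative site share
  (sites ordered poorest to richest).  The area between the observed
  curve and the diagonal has a maximum of $\tfrac12$; we report twice
  that area so the index runs over $[0,1]$ with 0 = perfect uniformity
  and 1 = maximal non-uniformity, reconciling the area definition with
  the stated endpoints.  The closed form
  $\sum_i (2i - n - 1)\,x_{(i)} / (n \sum_i x_i)$ is checked in the
  test suite against an explicit trapezoidal Lorenz-area oracle.
* The *power-spectrum roll-off*.  The periodogram of the mean-removed
  density is smoothed by a frequency-domain moving average (window
  $2.13\times10^{-6}$ cycles/base by default; the figure from which
  that constant is taken does not state its units, so the window is
  configurable) and fitted with a Lorentzian plus constant floor,
  $S(f) = A/(1 + (f/f_c)^2) + B$.  The corner frequency $f_c$
  separates long-range (isothermal) from short-range (PCR) bias.

**CNV resolvability $W$.**  The minimum width of a sliding
moving-average window such that *all* windows at least that wide keep
the filtered relative density strictly below 2 everywhere on the
circular genome.  A clean copy-number-2 duplication of length $w$
drives some $w$-window average to exactly 2, so $W$ is the noise floor
above which duplications become detectable.  The grid runs from 1000 bp
in 1000-bp steps up to half the genome (the upper cap is a package
convention; a window of half the genome is the largest for which the
statistic remains informative).  Because the per-window maximum is not
monotone in window width, the whole grid is scanned and $W$ is the
start of the terminal all-passing run -- a literal reading of the
definition, not a first-passing shortcut.  A uniform density therefore
reports $W = 1000$ bp, the grid minimum, by convention.  If even the
widest window fails, a failure marker is returned and serialized as the
string `"failure"`.

**Error model.**  For each reference site, $M_i$ counts matching and
$C_i$ contradicting bases among proper alignments; after dropping sites
with $M_i + C_i$ below a depth floor and sites whose contradiction
fraction exceeds a cap (typically a faulty reference base), the
discrepancy ratio is $D = \sum_i C_i / \sum_i (M_i + C_i)$.  The exact
published filter cutoffs are not recoverable from the available text;
the defaults `min_site_depth = 10` and
`max_contradiction_fraction = 0.5` are deliberate package choices and
both are explicit arguments.  With the effective cycle number
$N = \log_2 G$, the model is
$$D = D_0 + \varepsilon N, \qquad 1 \le G \le 5\times 10^7,$$
fitted by unweighted ordinary least squares (no weighting scheme is
documented for the original fits, so none is default).  $D_0$ absorbs
sequencing error and reference inaccuracy; after Q30 quality trimming
one expects $D_0$ of order $10^{-3}$, since Phred 30 corresponds to a
per-base error probability of $10^{-3}$.  $\varepsilon$ is the
per-base, per-cycle replication error rate.  A negative fitted slope is
reported with a flag, never clamped.  `extract_epsilon()` inverts the
model for a single measurement, e.g. a duplex-corrected baseline plus
one amplified sample.

**Duplex consensus.**  Reads sharing a dual 9-bp random barcode derive
from one source molecule.  Families are grouped per strand with exact
barcode matching; at least three reads are required for consensus
building.  The strand consensus takes the base carried by a strict
majority ($> 50\%$) per position, `N` otherwise; the duplex consensus
keeps a base only where both strand consensuses agree and neither is
`N`.  The published protocol specifies only the three-read threshold
and the duplex pairing, so strict majority plus strand agreement is
adopted as the most conservative completion; whether the three-read
minimum applies per strand or per duplex is likewise unstated, and it
is applied per strand (configurable).  Barcode-error tolerance
(clustering near-identical tags) is a documented non-feature.

**LG50.**  The minimal number of contigs, after discarding contigs
shorter than 500 bp, whose cumulative length covers half the reference.
Coverage is length-based (cumulative contig length against reference
length), not alignment-based: running an aligner on real assemblies is
out of scope here, and the published failure-sentinel arithmetic --
assemblies that cannot reach 50% are assigned
$\lfloor 0.5 \cdot L / 500 \rfloor$, the largest value LG50 can take --
is itself length-based.  For the *E. coli* DH10B reference
($L = 4{,}686{,}137$) the sentinel is 4686.  The sentinel equals the
LG50 of a hypothetical assembly made entirely of minimum-size contigs,
an identity the tests check by construction.

## The simulator

The simulator generates data with the statistical structure the metrics
assume; it is first-class, tested code, not a fixture.

**Bias field.**  The log-bias is a stationary Gaussian field
synthesized in the frequency domain with Lorentzian target PSD
$S(f) \propto 1/(1 + (f/f_c)^2)$, then exponentiated and normalized to
mean 1.  This matches the observed Lorentzian roll-off of real mapping
densities and guarantees positivity.  The log-field standard deviation
is

* `bias_amplitude` $\times \log_2 G$ for `chemistry = "isothermal"` --
  bias compounds per effective doubling, reproducing the progressive
  worsening of MDA bias with gain (including the exaggeration seen
  when an MDA product is re-amplified);
* `bias_amplitude` $\times 10$, gain-independent, for
  `chemistry = "pcr"`.  No published number pins the PCR bias level;
  the fixed 10-cycle equivalent was chosen once so that the two
  chemistries produce comparable uniformity near $G \sim 10^3$, where
  they are reported to perform similarly, and is not revisited.

Default roll-off frequencies are $4.15\times10^{-5}$ bp$^{-1}$
(isothermal) and $10^{-3}$ bp$^{-1}$ (pcr), the measured orders for
MDA and PCR-based chemistries.  The default
`bias_amplitude = 0.05` per cycle puts the simulated Gini index in the
0.3--0.6 range over gains $10^3$--$10^6$ for isothermal chemistry,
the realistic range for single-cell MDA.

**Errors.**  `simulate_site_counts()` draws a Poisson per-site depth
and contradicts each observed base with probability
$p = D_0 + \varepsilon \log_2 G$ -- the expectation form of the error
model.  The derivation behind the published model (a branching-process
appendix) is not available in the extracted text; the simulator
implements the linear-in-$N$ expectation stated in prose and does not
implement a branching-process mode.

**Read pairs, contamination, barcodes.**  Contaminated pairs have both
mates unmapped; discordant pairs violate FR orientation or the 2000-bp
separation bound (half each, on average); concordant pairs are FR with
separation drawn from a configurable distribution truncated at
2000 bp.  Barcoded molecules receive collision-free dual 9-bp tags,
strand families of configurable size, and i.i.d. per-base substitution
noise; true variants are applied to every read of every molecule
relative to a shared reference.

**What is not emulated.**  Library-preparation chimeras, PCR-duplicate
structure, MALBAC loop-suppression chemistry, GC-dependent bias,
alignment artifacts, and indels.  Passing tests therefore demonstrate
the correctness and statistical calibration of the metrics on data
satisfying the stated model assumptions -- not that real libraries
satisfy those assumptions.

**Seeding.**  Every stochastic function takes an explicit seed and
restores the caller's RNG state; compound runs derive per-stage
sub-seeds deterministically, so a single integer reproduces an entire
report byte for byte.

## Numerical choices

* Coordinates are 0-based half-open; the genome is circular; a
  trailing partial bin is dropped.
* Down-sampling uses `floor()` for pair counts and samples without
  replacement; rarefaction uses nested prefixes of one permutation so
  the curve is monotone non-decreasing by construction.
* Window-to-bin conversion is `floor(window / bin_size)`, minimum one
  bin; the circular moving average preserves the mean exactly.
* The Lorentzian fit runs Levenberg--Marquardt least squares with
  non-negativity bounds and data-driven starts (low-frequency plateau
  for $A$, half-power frequency for $f_c$, high-frequency median for
  $B$); non-convergence raises a fit-failure condition carrying the
  start values.  A fitted floor above $A/2$, or $f_c$ beyond half the
  Nyquist frequency, flags the spectrum as effectively flat
  (`floor_dominated`), the expected outcome for white noise.
* Degenerate inputs fail loudly with typed conditions:
  empty position lists (undefined mean), all-zero coverage (undefined
  Lorenz curve), zero retained sites, fewer than three usable
  gain--$D$ points.

## Validation design and problem sizes

The test suite validates each metric against an independent oracle:
Gini against explicit trapezoidal Lorenz-curve geometry; the circular
filter and $W$ against a position-by-position brute-force filter on
random densities; the spectral fit against the AR(1)/Ornstein-Uhlenbeck
correspondence $f_c = 1/(2\pi\tau \cdot \text{bin})$ (allowing for the
AR(1) spectrum's known excess over a pure Lorentzian near Nyquist);
fractional coverage against the Poisson zero class $1 - e^{-d}$; and
consensus calling against exhaustive small cases.

Calibration checks run at sizes chosen to make sampling error
negligible relative to the tested effect on a single CPU: error-model
recovery uses $10^7$ bases per gain point over a half-decade gain grid
$10^1$--$10^7$ (13 points rather than 7 decades, which stabilizes the
slope's standard error), gain-trend tests use 50 replicates of 400-bin
genomes, and the duplex-suppression check accumulates $10^7$ consensus
bases from 20,500 molecules of 500 bp.

## Limitations

* The metrics operate on alignment-derived tables; upstream trimming,
  alignment, duplicate marking and indel realignment are external, and
  only their summary fractions enter (as $F$ and $T$).
* Attribution of unmapped reads to source organisms requires external
  databases and is out of scope.
* LG50 is length-based; an alignment-based variant would require the
  assemblies and reference alignments themselves.
* The error model treats all contradictions agnostically; it is not a
  variant caller, and diploid allele-fraction analyses are not
  implemented.
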