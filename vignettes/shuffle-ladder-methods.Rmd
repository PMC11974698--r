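---
title: "The shuffle ladder: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The shuffle ladder: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapshuffle)
```

## The model of the data

The package operates on the standard "genomic image": a binary matrix with
one row per phased haplotype and one column per segregating site, columns
ordered by genomic position, 0 coding the ancestral and 1 the derived
allele. Two pieces of metadata ride along. `positions` holds the site
coordinates (base pairs, or the scaled $[0,1)$ coordinates of ms-style
simulators); every operation in the package treats them as opaque and no
operation ever reorders or rescales them. `padding_width` records how many
trailing all-zero columns are zero-padding appended so variable-width inputs
reach a fixed image width. Because padding shares the ancestral colour, it is
indistinguishable from data except through this metadata — which is
precisely the situation of a padding-blind consumer such as a convolutional
network, for which the *position of the last informative column* is the only
visible trace of the number of segregating sites. Unphased or multiallelic
input is rejected rather than heuristically coerced: the shuffles act on
haplotype identity, and fabricating phase would fabricate the very structure
they are meant to destroy. Ancestral/derived polarization is taken as given
(0/1 as read); a folded spectrum is available in `afs(..., folded = TRUE)`
for data with unknown polarization.

## The ladder and what each level provably does

Write $n$ for the haplotype count, $w$ for the data width and $d_j$ for the
derived count in column $j$ of the data region.

**`columns`** permutes the data columns uniformly. Every statistic that is a
function of the *multiset* of columns is exactly invariant: the AFS,
$\pi = \sum_j d_j(n-d_j)/\binom{n}{2}$, the segregating-site count, Garud's
$H1 = \sum_i p_i^2$ (every row is permuted identically, so haplotype identity
classes are untouched) and the multiset of pairwise $r^2$ values. What dies
is only the *association between position and content* — LD decay with
distance, operationalized here as the Spearman correlation between
$|pos_j - pos_k|$ and $r^2(j,k)$.

**`within_columns`** composes the column permutation with an independent
uniform permutation of entries inside each column — defined as a composite,
on top of the column shuffle, not as a standalone primitive. Per-column
counts survive (hence AFS, $\pi$, $S$, singleton fraction), but rows stop
being coherent haplotypes: $H1$ collapses toward its equal-frequency floor
and between-column correlations converge to the independence expectation.

**`all_pixels`** applies one uniform permutation to the whole data region.
Only the total derived count $T$ survives; column sums become exchangeable,
rewriting the AFS.

**`block_keep_padding`** and **`block_break_padding`** are deterministic:
they pack all $T$ derived alleles into a contiguous block, top-to-bottom
within columns. The first anchors the block at the padding boundary (columns
filled right-to-left from the last data column), preserving $T$, the data
width and — whenever $T > 0$ — the last informative column, i.e. the
apparent segregating-site boundary. The second packs left-to-right from
column 1 across the *full* width, padding included; the boundary ceases to
exist, so the output carries `padding_width = 0` and only $T$ survives. The
text description of block-grouping does not pin down a fill geometry; the
corner and fill order used here are a package choice, fixed and deterministic
so that every preservation claim can be tested bit-exactly. For a positioned,
padded input the boundary-breaking level necessarily leaves a positions
vector longer than the new data width — `validate_hap_matrix()` flags such
matrices, position-dependent statistics return `NA` on them, and everything
else works.

Padding columns take part in no level except the boundary-breaking one; that
is the defining distinction between the two block levels.

## Randomness and reproducibility

Every randomized operation takes an explicit integer seed, evaluates under
it, and restores the caller's RNG state. `shuffle_battery()` derives the
seed for (matrix $i$, level $\ell$) from the master seed by a counter-based
congruential mix, so one level's randomization is invariant to which other
levels are requested, and each matrix is re-randomized independently (the
alternative — one permutation reused across a dataset — would correlate
errors across examples). Dataset generators likewise derive per-matrix seeds
from `(master_seed, class, index)`, making every dataset bit-exactly
regenerable from its recorded metadata.

## Synthetic generators: what they emulate, and what they do not

The generators reproduce the *features the shuffles target*, not
evolutionary realism — no coalescent genealogies, no recombination maps, no
demographic parameters:

- `simulate_neutral(n_hap, n_sites, seed)`: each column independently draws
  derived count $k \in \{1..n-1\}$ with probability $\propto 1/k$, the
  neutral-equilibrium spectrum shape, and scatters the $k$ alleles over
  uniform rows; positions are sorted uniforms. Columns are exchangeable, so
  there is no LD structure by construction.
- `simulate_ld_mosaic(n_hap, n_sites, n_founders, switch_rate, seed)`:
  haplotypes are left-to-right copying mosaics of a few founder haplotypes,
  switching founder with probability `switch_rate` between adjacent sites.
  Low switch rates give long shared tracts — high $r^2$, distance-decaying
  LD and founder-limited haplotype diversity ($H1 \ge 1/n_{founders}$ at
  rate 0).
- `simulate_sweep_like(n_hap, n_sites, sweep_freq, flip_rate, seed)`: a
  fraction `sweep_freq` of haplotypes are near-copies of one core haplotype
  (per-site flips at `flip_rate`), the rest neutral-like — reduced haplotype
  diversity and fewer realized segregating sites, the sweep footprint.

Columns left without any derived allele (possible under mosaic copying and
sweep overwriting) are dropped with their positions: a haplotype matrix
holds sites segregating in the sample, and keeping all-zero columns would
both fabricate non-sites and detach the apparent width from the data width
that boundary analyses rely on.

The default two-class study task contrasts neutral matrices (20 haplotypes,
64 sites) against sweep matrices (20 haplotypes, 32 drawn sites, sweep
frequency 0.8), all right-padded to width 64. The asymmetric site counts are
deliberate: they give diversity-based statistics *and* the padding boundary
class signal, mirroring the situation in published pipelines where the
segregating-site count itself separates classes. Consequently passing tests
show that the machinery behaves as the theory predicts on data with these
features; they are silent about coalescent data, about genotype matrices,
and about any model trained on data whose class signal lives elsewhere.

## Oracle predictors and the degradation logic

`fit_oracle()` builds a threshold classifier on one named statistic
($\pi$, $H1$, singleton fraction, $S$, or the last informative column),
choosing the training-accuracy-maximizing threshold over midpoints of
adjacent sorted values (ties toward the lower threshold). Because the
prediction is a pure function of its statistic, its shuffle-test metrics are
bit-identical to baseline at every level that preserves the statistic. This
yields an analytically predictable degradation pattern, the package's
central correctness property: the $\pi$-oracle survives both column-level
shuffles and dies at the block levels; the $H1$-oracle survives only the
column shuffle; the $S$-oracle survives through within-column shuffling; the
boundary-oracle (last informative column) survives everything that keeps
the padding boundary — including the boundary-keeping block level — and
breaks only when the boundary is destroyed, the signature of a model that
has learned total diversity through the image width.

Two one-sided notes on that property. The converse direction ("statistic
destroyed $\Rightarrow$ metrics change") is statistical, not logical: a
destroyed statistic can still happen to rank classes identically (the
$S$-oracle under `all_pixels` on the default task is the standard example,
since the data widths differ by class), so the test suite asserts exact
equality where preservation guarantees it and asserts *change* only where
the destruction provably collapses the statistic to a class-independent
value. And the boundary statistic is guaranteed under the column-level
shuffles only because generated matrices carry a derived allele in every
column; on matrices with empty trailing data columns a column permutation
can move the apparent width, which is why the preservation matrix lists the
boundary statistic only under the boundary-keeping block level.

## Harness metrics and numerical choices

Classification reports accuracy, the confusion matrix (rows = truth), and
the no-information rate alongside, so "breakdown" is interpretable on
imbalanced data; binary tasks with scores additionally get a ROC curve by
threshold sweep over distinct scores (ties grouped) with trapezoidal AUC,
verified in the tests against the all-pairs ranking probability. Regression
reports Spearman's $r$ (average-rank ties; reported as 0 with a degeneracy
flag when either vector is constant) and RMSE. `aggregate_instances()`
summarizes repeated predictor instances by the mean and an empirical
percentile interval (2.5/97.5, linear interpolation — with few instances
these are interpolated order statistics, and they are labelled as percentile
intervals rather than claiming normal-theory coverage). Spearman
correlations involving all-tied vectors (e.g. the distance–$r^2$ correlation
when all $r^2$ are equal) return 0 by convention. $H1$ sums squared class
frequencies over *sorted* class counts so that the result is bit-identical
under column permutations rather than equal only up to floating-point
summation order.

Statistical test sizes in the suite are chosen so chance failure is
negligible at fixed seeds: permutation-uniformity checks use chi-square at
$\alpha = 0.001$ over 24\,000 (column orders) and 40\,000 (single-pixel
placement) seeds; destruction rates are required in $\ge 99\%$ of 500
seeds where the event is essentially sure, while the convergence of mean
off-diagonal $r^2$ under within-column shuffling is asserted on the *mean
over seeds* against the 99th percentile of a matched-permutation null
(asserting it per-seed would be a coin flip by construction, since each
shuffle draw is itself a draw from that null).

## Problem sizes

The shipped tests run the preservation matrix over 200 mixed-generator
matrices ($n_{hap} \le 32$, up to 128 sites, half padded) with 5 seeds each,
the destruction properties over 500 seeds, and the oracle-degradation
pattern on a 200 + 200 sweep-vs-neutral task; `scripts/acceptance.R` uses
the same task sizes with 50-matrix preservation and 200-seed destruction
summaries plus a 100-matrix regression aggregated over 10 perturbed
regressor instances. These sizes keep the full suite in the low minutes on
one core while leaving every statistical margin wide.

## Known limitations

- Haplotypes only: no genotype (unphased) mode, no missing-data codes.
- The generators make no claim of distributional match to coalescent or
  forward simulation; conclusions about a published network require running
  that network on its own data via the prediction-file interface.
- The block-grouping fill geometry is one deterministic choice among the
  layouts consistent with "group derived alleles into a block"; analyses
  that depend on the exact block shape (rather than on what is preserved)
  should not assume pixel-level agreement with other implementations.
- `read_vcf` ingests a single chromosome of biallelic SNPs with phased GT
  fields; BCF and tree-sequence formats are out of scope.
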