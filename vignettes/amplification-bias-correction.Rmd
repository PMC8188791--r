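---
title: "Correcting pooled-amplification bias with unseen-molecule estimation"
author: "umisat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting pooled-amplification bias with unseen-molecule estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umisat)
```

## The problem

In UMI-based single-cell RNA-seq, every captured mRNA molecule is tagged
with a random barcode before PCR, so duplicate reads of the same molecule
can be collapsed to one count. Collapsing removes duplication, but not a
subtler bias: molecules of different genes amplify to different copy
numbers, and a sequencing run samples only a fraction of the amplified
library. A molecule that amplified to 20 copies is almost certain to be hit
by at least one read; a molecule with 2 copies often is not. Genes whose
molecules amplify poorly therefore lose a larger fraction of their
molecules to subsampling, and at low depth this can invert the apparent
abundance ranking of two genes even when the true molecule counts say
otherwise — the *pooled amplification paradox*. The same mechanism creates
a batch effect between datasets sequenced to different depths, and can make
a gene look like a cell-type marker simply because it amplifies differently
across cell types.

All the information needed to correct this is in the *copies-per-UMI (CU)
histogram*: for each gene, pooled over cells, `h(i)` is the number of
molecules observed with exactly `i` read copies. Estimating the unseen
molecules from `h` is the classical unseen-species problem, with molecules
as species and reads as samples.

## The estimators

All three estimators answer the same question: if the total read count were
multiplied by `t + 1`, how many distinct molecules would be seen? At `t = 0`
every estimator returns the observed molecule count `N = sum h(i)`.

**Good–Toulmin.** The number of new molecules is the alternating series
`U(t) = -sum_{i>=1} (-t)^i h(i)`. It is distribution-free and accurate up to
a doubling of reads (`t <= 1`), but the series diverges violently beyond
that, so `goodToulmin()` refuses `t > 1` unless explicitly overridden. For
`t <= 1` the sum `N + U = sum h(i)(1 - (-t)^i)` is provably nonnegative;
under an override the result is floored at zero and flagged.

**Zero-truncated negative binomial (ZTNB).** Per-molecule read counts are
modelled as NB(mu, size); molecules with zero reads are unobserved, so the
histogram is a zero-truncated NB sample. An EM iteration alternates an
E step that imputes the unseen mass — `L = N / (1 - pdf(0; mu, size))`,
`z = L * pdf(0)` — and updates the mean `mu = sum i h(i) / L`, with an
M step that maximizes the complete-data log-likelihood over `size` by
L-BFGS-B using the analytic digamma gradient. Extrapolation assumes the
size parameter is depth-invariant while the mean scales with reads:
`distinct(t) = L (1 - pdf(0; mu (t+1), size))`, which saturates at the
estimated library size `L`.

**Daley–Smith (DS).** The Good–Toulmin series is stabilized by a rational
(Padé) approximant. The histogram is first truncated to copy levels
`<= mt` (default `mt = 2`), the alternating coefficients define a power
series, and a degree-`[p/q]` rational function matching the series is
evaluated instead of the series itself. With `mt = 2` the approximant is
`h(1) t / (1 + (h(2)/h(1)) t)`, saturating at `N + h(1)^2 / h(2)`.
Truncation at 2 makes the estimator usable when only the single- and
two-copy fractions are trustworthy — including pooled 3-bin histograms
built from other datasets' saturation metrics.

## From predictions to corrected matrices

Per-gene predictions `c_g` are mapped to the count matrix by rescaling each
gene's row to the total `m_g = (T/P) c_g`, where `T` is the observed grand
total and `P = sum c_g`. The `T/P` factor keeps the corrected matrix on the
observed depth scale: `sum m_g = T` exactly, so corrected counts stay
CPM-comparable with the input. We read the published `m_g` formula as a
corrected row total rather than a multiplicative factor on each entry;
that is the only reading under which the totals are conserved and CPM
normalization after correction is meaningful. Genes whose histograms are
degenerate (fewer than 2 copy levels, or fewer than `minMolecules = 20`
molecules) keep their observed counts and are flagged — prediction from
tiny histograms is unreliable, which is also why the comparison metrics
drop genes under a 100 CPM floor by default.

## Batch correction by analytic binomial downsampling

Extrapolating a shallow dataset up is harder than thinning a deep dataset
down. If each read survives independently with probability `x`, a molecule
with `i` copies survives with probability `1 - (1-x)^i`, and the expected
downsampled histogram is `h'(j) = sum_i dbinom(j, i, x) h(i)` — no
sampling noise, exact read conservation `sum j h'(j) = x sum i h(i)`, and
closure under composition (`x1` then `x2` equals `x1 x2`). Per gene,
`f_g = e_a/e_b` (CPM after over CPM before) multiplies the deep matrix's
rows. With `x = "auto"`, `batchCorrect()` scans `x` over 0.01–1.00 in steps
of 0.01 and keeps the value maximizing Lin's concordance between the two
datasets' mean log2(CPM+1) profiles, choosing the smallest `x` on ties.

## Pooling histograms across datasets

Sparse per-gene histograms can borrow strength from similar datasets.
Because datasets differ in saturation, source datasets' per-gene FSCM and
FDCM (single- and double-copy fractions) are first quantile-normalized to
the target — each source value is mapped through its empirical CDF to the
target's quantile function — then pooled with the target by per-gene
UMI-weighted means. FMCM is the complement `1 - FSCM - FDCM`; when
normalization pushes the sum above 1, FMCM is floored at 0 and the three
bins renormalized (flooring is our choice; it preserves a valid
histogram). The pooled 3-bin histogram, scaled to the target gene's UMI
count, feeds the DS estimator with `mt = 2`.

## Evaluation metrics

Dataset-level expression is the mean across cells of per-cell CPM;
comparisons use `log2(CPM + 1)`. Agreement is measured by Lin's
concordance correlation coefficient
`CCC = 2 cov(a,b) / (var(a) + var(b) + (mean(a) - mean(b))^2)` with
population (1/n) moments — the convention is fixed here so tests are exact
— alongside MSE. Detection benchmarks use the Mann–Whitney AUC with ties
counted one half.

## The simulator

`simulateDataset()` generates what the correction assumes: each of a
gene's `nMolecules` molecules draws its read count i.i.d. from
NB(`nbMean`, `nbSize`); molecules are allocated to cells uniformly (or by
given weights); each molecule gets a distinct random UMI (12-mers by
default; collisions within a cell–gene group are redrawn, and the run
aborts if the birthday-bound collision risk exceeds 1%); reads are thinned
to `readFraction` by per-molecule binomial sampling. Ground truth records
true molecule counts and pre-thinning reads, so every estimator can be
scored without external data. Where no published parameter values exist,
the defaults are this package's own choices: amplification means
log-uniform on [0.5, 16] with size 1, spanning weak to strong
amplification at realistic dispersion; users with empirical per-gene
saturation tables can substitute them via the `genes` data frame.

What the simulator does *not* emulate: cell-type structure, ambient RNA,
doublets, UMI sequencing errors (error correction is out of scope here and
collapsing is exact-match), gene-length/GC effects, or amplification that
varies across cells within a gene. Passing tests therefore show the
estimators recover truth when the amplification model holds; on real data
the NB assumption is known to fail for some genes (mixtures across cell
populations), which is precisely when DS's distribution-free truncated
series is the safer choice.

## Numerical choices

- **EM convergence.** The iteration stops when the relative change of the
  complete-data log-likelihood falls below `tol = 1e-8` (cap 10000
  iterations). Looser tolerances are unsafe: at low saturation the
  likelihood has a long ridge along which `size` drifts toward a
  quasi-Poisson fit with tiny per-iteration change, and stopping there
  badly underestimates `L`. Iterations are cheap (they touch only the
  distinct copy levels), so the tight tolerance costs fractions of a
  second even for the slowest histograms.
- **EM starts.** The canonical start is `mu = 0.5, size = 1`. The
  truncated likelihood also has a spurious boundary attractor at
  `size -> Inf` (a zero-truncated Poisson limit) that can capture the EM
  from that start at low saturation. `ztnbFit()` therefore also runs the
  EM from `size = 0.1` and keeps the candidate with the higher
  observed-data zero-truncated log-likelihood.
- **Identifiability limit.** When the histogram is almost entirely
  singletons (saturation far below ~0.3 reads per molecule for
  NB-size-1-like data), a near-Poisson fit attains essentially the same
  truncated likelihood as the true heavy-tailed fit, and no estimator can
  recover `L` reliably; this is inherent to the data, and the reason for
  the molecule-count floor and the CPM floor rather than a defect of the
  optimizer.
- **DS evaluation.** The Padé system is solved by a dense linear solve;
  the denominator is checked for real poles in `(0, t]` (degree backs off
  on defect, and an error of class `umisat_estimator_unstable` is raised
  if no stable approximant remains). For `t > 1` the rational function is
  evaluated by Horner's rule in `u = 1/t`, so the saturation regime
  (`t = 1e20`) is computed exactly without overflow; histograms with
  fewer than two usable coefficients after truncation are refused.
- **Ties and floors.** The AUTO grid picks the smallest optimal `x`;
  corrected matrices keep fractional entries (no rounding); FMCM flooring
  is described above; Good–Toulmin clamps at zero distinct molecules under
  explicit extrapolation.

## Problem sizes in the packaged tests

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen so the whole suite completes in about a minute: ZTNB
recovery on 50,000-molecule histograms; extrapolation measured as the mean
relative error over 6 replicates (a single draw has ~4% Monte-Carlo sd for
ZTNB at this size, so the mean is the quantity the 5% check meaningfully
bounds); the two-gene paradox at `readFraction = 0.3` (strong observed
separation while the fit stays identifiable); 200-gene, 30-cell depth
pairs for batch correction; 100–600 gene-pair detection benchmarks (the
larger sizes keep the Mann–Whitney AUC's Monte-Carlo sd near 0.03 so a
"no residual association" readout of 0.5 is meaningful).

## Limitations

Estimates for genes observed at very low saturation or with few molecules
are unreliable and are deliberately left uncorrected. ZTNB inherits its
model assumption; DS with `mt = 2` discards information above two copies.
The batch correction assumes the two datasets share per-gene amplification
patterns and differ mainly in depth. Nothing here addresses UMI sequencing
errors, mapping ambiguity beyond discarding multi-gene molecules, or
biological batch effects.
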