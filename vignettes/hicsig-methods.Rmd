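---
title: "hicsig: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicsig: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicsig)
```

`hicsig` measures how a chromatin perturbation reshapes the three layers of
interphase genome folding — compartments, TADs and CTCF–CTCF loops — from
binned cis Hi-C contact matrices. This vignette is the package's account of
its models and of every convention that the file formats and figures do not
pin down by themselves. Nothing here is an empirical claim beyond what the
test suite and `scripts/acceptance.R` compute.

## The generative model

Every statistic in the package is validated by parameter recovery on
synthetic maps with known structure. The generator builds a noise-free rate
matrix as a product of four components and samples Poisson counts from it:

$$\lambda_{ij} \propto B(s_{ij})\; C_{ij}\; T_{ij}\; L_{ij}, \qquad
  s_{ij} = |i - j|\,b$$

- **Decay** $B(s) = (s + s_0)^{-\alpha}$ with defaults $\alpha = 1$,
  $s_0 = 10$ kb. $\alpha \approx 1$ is the canonical mammalian interphase
  exponent at sub-Mb separations; the offset keeps the first diagonals
  finite.
- **Compartments** $C_{ij} = \max(0,\, 1 + \gamma e_i e_j)$ with a per-bin
  profile $e_i \in \{-1, +1\}$ in alternating 1-Mb blocks and contrast
  $\gamma = 0.3$. Keeping $\gamma < 1$ avoids clipping, so the ideal O/E
  corner ratio stays analytic at $(1+\gamma)/(1-\gamma)$.
- **TADs** $T_{ij} = 1 + \tau$ when $i$ and $j$ fall in the same tile
  $[b_k, b_{k+1})$ of the boundary list. Tiles (rather than interiors that
  exclude boundary bins) mean every bin belongs to exactly one TAD, so no
  bin has an artificial coverage hole that matrix filtering would remove.
  Default TAD sizes cycle through 150–400 kb (mean 275 kb, about 72 TADs on
  a 20-Mb chromosome). The default $\tau = 4$ is a *rate-level* parameter:
  because the expected profile absorbs the genome-wide average of the TAD
  signal, the apparent intra-TAD O/E enrichment is only
  $(1+\tau)/(1+\tau\bar f) \approx 1.5\text{–}2\times$ — the range seen in
  real maps.
- **Loops** $L_{ij} = 1 + \sum_k A_k [g_k(i, a_1)g_k(j, a_2) +
  g_k(i, a_2)g_k(j, a_1)]$ with Gaussian dots $g_k$ of width $\sigma = 1$
  bin and amplitude $A = 6$; 40 loops per chromosome with log-uniform
  separations between 100 kb and 1.5 Mb. The mirrored product keeps the
  matrix symmetric while a dot at $(a_1, a_2)$ contributes $1 + A$ at its
  centre. Each loop also carries a log-normal covariate (an "anchor
  acetylation change" proxy) that is independent of any loop-strength
  change by default, so the covariate-ranked loop-line trend has a
  recoverable null.

Three perturbations emulate the treatments the package compares:

| perturbation | TAD component | loop dots | background |
|---|---|---|---|
| `tsa` | $\tau \to 0.8\,\tau$ | unchanged (per-loop retention available) | $\times\,0.8$ below 2 Mb, logistic return to 1 (width 250 kb) |
| `cohesin_depleted` | $\tau = 0$ | removed | unchanged |
| `tsa_and_depleted` | $\tau = 0$ | removed | apodized as above |

Counts are independent Poisson draws on the upper triangle, normalized so
the expected total equals the configured depth (default $10^7$), with a
fixed seed per condition. What the generator deliberately does **not**
emulate: overdispersion and ligation artifacts, trans contacts, nested or
hierarchical TADs, stripe/flame features, regionally heterogeneous
acetylation (the apodization is uniform along the genome), and
translocation artifacts. Passing recovery tests therefore demonstrates the
statistics are implemented correctly and have the designed sensitivity —
not that real libraries satisfy Poisson statistics.

## Normalization: per-sample O/E versus a reference-anchored O/E

This is the one genuinely open design choice in the pipeline, and the
package resolves it per analysis:

- **Per-sample O/E** (each matrix divided by its own expected) is used for
  loop pileups, insulation, compartments and saddles. These are *shape*
  statistics, robust to each library's depth and decay.
- **Reference-anchored O/E** (`oe_vs_reference()`) is used for
  cross-condition intra-TAD intensity comparisons: every condition is
  divided by the *reference* condition's expected profile after rescaling
  so the conditions agree at large separations (default ≥ 4 Mb), where
  treatment effects on the decay have vanished.

The reason is arithmetic, not taste: a perturbation that multiplies the
decay by a purely distance-dependent factor $c(s)$ changes observed and
expected identically, so it cancels *exactly* in per-sample O/E. Intensity
measured that way is blind to chromatin-decompaction effects, which makes
the four-condition decomposition of a treatment effect into
cohesin-dependent and -independent parts degenerate. Anchoring at
separations beyond the perturbation's reach preserves the effect while
still removing the arbitrary sequencing-depth scale. The anchor starts at
4 Mb because the default apodization profile has finished its logistic
transition there; anchoring inside the transition would absorb part of the
effect into the scale factor.

With this convention the four-condition attribution has a closed form at
the rate level: for background factor $c$, enrichment $\tau$ and retention
$r$, the cohesin-independent share is
$(1-c)\,/\,[(1+\tau) - c(1+\tau r)]$. The acceptance scenario uses
$c = 0.8$, $\tau = 0.5$, $r = 0.75$, for which this is exactly $1/2$ — a
50/50 split between decompaction and cohesin loss that the pipeline must
recover from sampled counts.

## Conventions and numerical choices

**Coordinates.** Bins are 0-based; intervals half-open `[start, end)`;
position → bin by floor division. Loop anchors map by midpoint, with a
midpoint exactly on a bin edge resolved toward the lower bin.

**Balancing.** MAD-max masks bins whose log marginal coverage falls more
than 5 MADs (1.4826-scaled) below the log median; zero-coverage bins are
always masked. ICE ignores the first two diagonals, declares convergence at
marginal CV < 1e-5 within 200 iterations (both configurable; failure is an
error reporting the final CV), and scales weights to mean 1 over unmasked
bins. Masked bins carry `NA` weights, never 0.

**P(s).** Log-spaced bins (8 per decade). Within each bin, per-diagonal
means are combined by a *pair-weighted geometric mean*, with the bin centre
at the pair-weighted geometric mean separation. This estimator reproduces
any exact power law bin-for-bin, so the log-derivative carries no
within-bin binning bias; all-zero diagonals are excluded from the average.
Curves default to unit value at a reference separation; for
cross-condition difference work the pipeline anchors at 5 Mb, outside the
treatment's range. The derivative uses central differences on the raw
log-log curve followed by a 3-bin moving average of the *slopes* —
smoothing the curve first on an uneven log grid would bias even a perfectly
linear curve. The differential decomposition masks separations where the
cohesin-intact difference is below 1% of its maximum magnitude, and reports
the denominator for diagnostics.

**Insulation and boundaries.** The diamond at bin $i$ spans rows
$[i-w+1, i]$ and columns $[i+1, i+w]$, excluding pairs closer than the
ignored diagonals; partially masked diamonds are rescaled to the full entry
count and dropped when less than half defined. Scores are log2 relative to
the chromosome mean diamond. Because the diamond at $i$ separates
$[i-w+1, i]$ from $[i+1, i+w]$, a minimum at $i$ places the barrier between
$i$ and $i+1$, and the reported boundary bin is $i+1$ — the first bin of
the downstream TAD, matching the generator's boundary definition. Local
minima closer than 3 bins are merged keeping the deepest: a sharp junction
produces a flat-bottomed valley whose bottom noise would otherwise split
into twin calls. Boundary strength is valley prominence (min of the
flanking maxima within one window, minus the valley), thresholded with
Li's iterative minimum cross-entropy rule; the tests pin it against an
exhaustive cross-entropy scan.

**Intra-TAD intensity.** TADs inherit the *reference* condition's
boundaries for all comparisons. For an $m$-bin TAD, `k = max(1,
floor(0.1 m))` diagonals beyond the main one and `k` edge rows/columns are
removed; the intensity is the mean of the remaining defined O/E entries.
At 10% a 500-kb TAD at 20-kb bins loses two diagonals. A constant field
yields the constant under any `mask_scale` (masking never biases), and
TADs left with no entries are skipped and counted. Outliers beyond
`Q3 + 1.5 IQR` / `Q1 − 1.5 IQR` (type-7 quantiles) are flagged per
condition by default (a pooled mode exists) and excluded from summaries.
The Wilcoxon comparison uses the exact null when both groups have at most
25 tie-free values, otherwise the tie-corrected normal approximation; the
method is recorded in the result.

**Compartments.** E1 comes from the Pearson correlation matrix of O/E
columns over unmasked bins (a raw centred-O/E mode is available), with
undefined near-diagonal entries treated as neutral. The sign is oriented
against a covariate (gene density in real data; the true profile serves in
simulations) so that positive E1 means A. Compartment boundaries sit at E1
sign changes, except that both members of any pair of changes closer than
400 kb are removed. The saddle always ranks bins by an explicitly supplied
reference track — never recomputed per condition — using equal-occupancy
quantile bins, which makes the result invariant under monotone transforms
of the ranking; strength uses 10-bin corner means.

**Loops.** Pileups average O/E windows (default ±10 bins); windows are
dropped only when they extend past the matrix or their loop-pixel row or
column is masked — interior masked pixels are NA-averaged, since dropping
any window touching a masked flank bin discards most loops at moderate
depth. The loop-line is the pileup diagonal through the centre; ratios are
masked where the reference line falls below 5% of its maximum. Size strata
are half-open (`[100 kb, 500 kb)`, `[500 kb, 1 Mb)`, `[1 Mb, ∞)`); loops
under 100 kb are excluded and counted. The covariate trend test is the
Spearman correlation between the per-loop covariate and the per-loop
centre-pixel ratio.

## Validation design and problem sizes

The suite validates each operation against an independently coded
brute-force oracle (nested-loop expected, diamond sums, saddle
aggregation, window means, exhaustive permutation rank-sum, symmetric
Sinkhorn, exhaustive Li scan) on randomized small instances, checks
closed-form identities (exact $s^{-1}$ derivative, 2.0/0.5 checkerboard
strength 4.0, constant-TAD invariance), and then runs full parameter
recovery: one to three 2,000-bin × 10-kb chromosomes at depth $10^7$ for
boundary recall (within ±1 bin), E1 sign agreement, the intensity ratio
under 0.8 retention (pooling three chromosomes to exceed 200 TADs), the
loop-line centre ratio under the full treatment, and the 50/50 attribution
scenario. Null integrity uses 50 replicate same-model comparisons at
reduced size (400 bins, depth $2\times10^5$) and checks the Wilcoxon
p-values against uniformity. These sizes were chosen as the smallest at
which the recovery targets are comfortably powered.

## Limitations

- Counts are Poisson; real libraries are overdispersed, so real-data
  p-values will be anti-conservative relative to the simulated calibration.
- Balancing and expected profiles are strictly per-chromosome cis;
  trans contacts and genome-wide balancing are out of scope.
- Boundary calling assumes reasonably sharp insulation valleys; nested TAD
  hierarchies are not modelled or called.
- The reference-anchored O/E requires separations beyond the perturbation's
  reach to exist on the chromosome; on short chromosomes the anchor window
  shrinks (half the span) and the scale factor becomes noisier.
- De novo loop calling is out of scope; loop lists are inputs.
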