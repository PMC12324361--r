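# hicsig

Comparative statistics for binned Hi-C contact maps, built around the
question of how a chromatin perturbation reshapes the three organizational
layers of interphase genomes: A/B compartments, TADs (the diffuse
cohesin-extruded interaction domains), and focal CTCF–CTCF loops. The
motivating biology is histone hyperacetylation (e.g. by the HDAC inhibitor
TSA), which reduces short-range intra-TAD contact while leaving CTCF-anchored
loop dots largely intact — a signature that requires measuring each layer
with its own statistic and comparing conditions against a single declared
reference.

`hicsig` is an R package for analysts who have per-chromosome binned cis
contact matrices (sparse triplet text), a loop list (BEDPE) and optional
per-bin covariate tracks, and who want the full comparison pipeline with
tested, ground-truth-validated components. All tabular results are tibbles;
result objects have `autoplot()`, `tidy()` and `glance()` methods.

## What it computes

For a contact matrix `M` with bins of width `b`:

- **Balancing.** MAD-max coverage filtering, then ICE: weights `w` such that
  `(w_i w_j M_ij)` has equal marginals over unmasked bins (first two
  diagonals ignored), converged when the marginal coefficient of variation
  falls below 1e-5.
- **Expected and O/E.** Per-diagonal means `E(s)` of the balanced signal and
  the observed/expected transform `M*_ij = w_i w_j M_ij / E(|i−j| b)`.
- **P(s) scaling.** Contact probability versus separation on a log grid,
  its log-derivative `d log10 P / d log10 s`, and the differential
  decomposition across cohesin states
  `ratio(s) = ΔP_depleted(s) / ΔP_intact(s)` whose complement `1 − ratio`
  is the cohesin-attributable share of a treatment effect.
- **Compartments.** E1 as the leading eigenvector of the O/E column
  correlation matrix, sign-oriented by a gene-density-style covariate;
  boundary calls at E1 sign changes with a 400-kb close-pair exclusion; a
  50×50 equal-occupancy saddle ranked by the *reference* condition's E1,
  with compartment strength `(AA + BB)/(AB + BA)` from 10-bin corners.
- **Insulation and TADs.** Diamond insulation scores, boundary calling by
  valley prominence thresholded with Li's minimum cross-entropy rule,
  boundary pileups (±600 kb), and per-TAD intra-TAD intensity: the mean O/E
  of each TAD block after removing the diagonal and a TAD-size-scaled
  border (`k = max(1, floor(0.1 · m))` diagonals and edge rows for an
  `m`-bin TAD), IQR outlier filtering, and Wilcoxon rank-sum comparison.
- **Loops.** O/E pileups at loop anchors (20-kb convention), the
  **loop-line** — the diagonal profile through the loop pixel from the
  bottom-left to the top-right corner of the pileup — with ratio and
  difference forms, size-class stratification (100 kb–500 kb, 500 kb–1 Mb,
  > 1 Mb), and covariate-ranked loop-line trend tests.
- **Synthetic maps.** A generator with known ground truth: power-law decay,
  compartment checkerboard, multiplicative TAD tiles, Gaussian loop dots,
  Poisson counts, and treatment perturbations (intra-TAD attenuation,
  short-range background apodization, cohesin depletion). Every analysis
  stage is validated by parameter recovery against this ground truth.

## Worked example

Simulate a control/treated pair with known structure and run the full
comparison:

```r
library(hicsig)

cfg <- sim_config(n_bins = 800, bin_size = 1e4, depth = 5e6, seed = 7)
ex  <- simulate_experiment(cfg, conditions = c("dmso", "tsa"))
report <- hic_compare(
  ex$matrices, reference = "dmso", treated = "tsa",
  loops = loop_set(ex$ground_truth$loops),
  e1_covariate = ex$ground_truth$e1_truth$value[seq(1, 800, by = 10)])
report
#> <hic_report> dmso vs tsa (2 conditions)
#>   TADs from reference boundaries: 28 | intensity median ratio 0.670, Wilcoxon p = 4.49e-10
#>   loop-line centre ratio (tsa/dmso): 1.041 over 40 loops
```

The two headline numbers carry the biology: intra-TAD intensity drops to
67% of the control (the simulated treatment attenuates the cohesin
component to 80% *and* apodizes the short-range background by 0.8, and the
two effects multiply), while the loop-line centre ratio stays at 1.04 —
loop dots are spared. `glance(report)` returns these as a one-row tibble;
`tidy(report$wilcoxon)` gives the test details; `autoplot()` works on the
P(s) curves, insulation tracks, saddles, pileups and loop-lines inside the
report.

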