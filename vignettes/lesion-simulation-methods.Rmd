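---
title: "Methods: graph construction, simulated lesions and longitudinal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph construction, simulated lesions and longitudinal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the pipeline addresses

After a first ischemic stroke, does the brain's functional network
reorganize into a configuration that would better withstand a *second*
lesion? Because the timing and location of a recurrent stroke cannot be
observed prospectively, the recurrence is *simulated*: nodes are deleted
from each subject's functional connectivity graph and the network's
remaining capacity for information transfer is measured. `lesionsim`
implements that full analysis — from regional BOLD time series to the
longitudinal statistics — together with a synthetic-cohort generator so that
every stage can be exercised and validated without patient data.

# Signal processing

Regional time series (one T x N matrix per scan session) pass through:

1. **Volume discard** — the first `n_discard` volumes (default 5 for real
   acquisitions) are dropped to reach magnetization equilibrium.
2. **Linear detrending** per region, by least squares; optionally each
   region is scaled by its pre-detrend mean.
3. **Nuisance regression** — any supplied regressors (motion parameters,
   their first derivatives, mean CSF signal) are projected out by OLS. The
   regression follows detrending, mirroring the order in which the steps are
   usually described; cleaning is idempotent, so the order only matters for
   the scaling constant.
4. **Winsorization** to the 5th and 95th percentiles per region, clamping
   outlying spikes. Percentiles interpolate linearly between order
   statistics (R's default type 7); the convention is a documented choice,
   as several definitions exist.
5. **Wavelet sub-band extraction** — scale 4 of a maximal-overlap discrete
   wavelet transform (MODWT), which is shift invariant and returns a
   full-length sub-band series. The filter is the Daubechies
   least-asymmetric length-16 (sym8) filter, a near-symmetric orthogonal
   choice standing in for the cubic orthogonal B-spline family used in
   established fMRI wavelet pipelines; the swap is deliberate and recorded
   here. At a 1.2 s sampling interval the nominal scale-4 passband is
   `[fs/32, fs/16]` = 0.026–0.052 Hz. This is close to, but not identical
   with, the 0.03–0.06 Hz range often quoted for the same decomposition;
   the discrepancy is inherent to quoting dyadic bands in round numbers and
   both figures are reported in the output metadata. A Fourier bandpass
   with the same nominal passband is available (`method = "bandpass"`) and
   flagged in metadata. Empirically the MODWT detail retains ~93% of a
   band-centre sinusoid's variance and passes <1% of a 0.2 Hz signal.
6. **Motion QC** — Power-style framewise displacement, translations plus
   rotations converted to arc length on a 50 mm sphere (the cited
   framework's convention; the radius is a parameter).

Pairwise Pearson correlation of the cleaned series yields the N x N
connectivity matrix. For patients with right-sided lesions the matrix is
*flipped*: homotopic region pairs (by default region i pairs with i + N/2)
are swapped simultaneously in rows and columns, so all lesions are analyzed
on the same side. Flipping is an involution and preserves the multiset of
edge weights — graph metrics are unaffected; only region identity changes.

# Graph construction

Four steps, applied per session:

1. **Strength normalization** — weights divided by the total connectivity
   strength, defined here as the sum of absolute off-diagonal weights over
   the upper triangle. The constant is reported as global connectivity
   strength. Because proportional thresholding is scale invariant, this
   step provably never changes the binarized graphs (a property the test
   suite checks), so the exact definition, and whether it happens before or
   after the positive mask, affects reporting only.
2. **Absolute threshold w > 0** — negative and zero weights are removed.
3. **Proportional (density) thresholding** — for each density t in
   {0.1, ..., 1.0}, the `ceiling(t * E)` strongest of the E positive edges
   are retained. Ceiling rounding guarantees at least one edge at any
   positive density; ties in weight (measure zero for real correlations,
   common in toy examples) are broken by ascending (row, column) index,
   deterministically. Edge sets are nested along the sweep.
4. **Binarization** — retained edges become 1.

# Metrics

**Global efficiency** is the mean inverse shortest-path length over ordered
node pairs, `E_glob = 1/(N(N-1)) * sum_{i != j} 1/d_ij`. Disconnected pairs
contribute 0 (`1/inf`), so the metric is defined on disconnected graphs —
necessary, because node deletion disconnects them. Shortest paths are
unweighted BFS distances (boolean matrix powers for graphs up to 64 nodes,
igraph's BFS above that; both are validated against an independent
per-source BFS oracle to 1e-12). **Mean degree** `2|E|/N` is the network's
wiring cost; under proportional thresholding it equals `2*ceiling(t*E)/N`
exactly.

Because both metrics depend on density, each subject's graphs are screened
for connectedness bottom-up and analysis restricts to a density range on
which cohort graphs are connected — `[0.3, 1.0]` by default, matching the
range retained for ~240-region correlation networks. Profiles are summarized
as the **area under the curve** over that range, by the trapezoidal rule on
the 0.1-increment grid (exact for linear profiles; a left-rectangle variant
exists). The AUC is not normalized by the range width: only within-study
comparisons are made, and the convention is recorded in the serialized
metadata.

# Simulated attacks

- **Serial random attack**: nodes deleted one at a time in uniformly random
  order; efficiency recomputed after every deletion at every density;
  curves averaged over replicates (default 20, seed-controlled — the
  replicate count is a package choice, as single-order attacks are noisy),
  then over deletion steps 1..N-2 (steps leaving <2 nodes count 0 by
  convention), giving one value per density and an AUC per subject.
- **Serial targeted attack**: deletion by decreasing node degree, ties by
  ascending node id. The default order is fixed from the intact graph — the
  literal reading of attacking "by decreasing degree" — with adaptive
  re-ranking after each deletion available behind `recompute = TRUE`.
- **Clinically representative attack**: one-shot deletion of a lesion node
  set — either supplied as node ids, or derived from a lesion mask volume
  by atlas overlap (a region is hit when any of its voxels fall inside the
  mask; the overlap fraction threshold is adjustable). The reference sizes
  are 13, 13 and 54 nodes on a 240-region atlas (cortical, subcortical and
  cortico-subcortical middle-cerebral-artery patterns), scaled
  proportionally on smaller synthetic atlases.

Post-deletion efficiency is always computed on the induced subgraph (N =
remaining nodes); the test suite verifies this equals an independently
constructed subgraph, and includes an isolated-node counterexample showing
attack curves need not be monotone. Averaging over remaining nodes keeps a
complete graph at efficiency 1 through an attack; padding deleted nodes
with zeros would rescale all curves, and since the convention is not
universal it is deliberately fixed here and recorded in outputs.

# Statistics

For each outcome family (pre-attack E_glob AUC, mean-degree AUC, each
attack's AUC) the battery mirrors the longitudinal design:

- a **linear mixed model** on patients, outcome ~ timepoint + lesion volume
  + lesion side + (1 | subject), REML, with the omnibus timepoint effect
  tested by a Type-III F with Satterthwaite degrees of freedom (lmerTest).
  Constant covariates are dropped with a note; a constant outcome returns a
  degenerate result (p = 1) rather than a crash; if the Satterthwaite fit
  fails, a likelihood-ratio fallback runs and the `method` field says so.
  For mask attacks a combined model adds attack type and its interaction
  with timepoint.
- **pairwise comparisons**: paired t tests between patient timepoints;
  Welch two-sample t tests against controls (equal variances are not
  assumed — the choice is deliberate where the convention is unstated).
  Benjamini–Hochberg adjustment is applied within each family,
  one family per analysis block.
- the **cost–resilience correlation**: Spearman rank correlation between
  per-patient TP3−TP2 changes in post-attack AUC(E_glob) and changes in
  AUC(mean degree); exact p below n = 10, t approximation above.

# The synthetic cohort generator

The generator emulates exactly what the analysis consumes — second-order
structure — and nothing more. Regional series are stationary vector AR(1)
processes: `x_t = phi * x_{t-1} + e_t` with innovation covariance
`(1 - phi^2) * Sigma`, so the stationary correlation is the block matrix
`Sigma` (within-community correlation 0.5, between 0.1, AR coefficient 0.3
by default — values typical of band-limited BOLD correlations). Communities
are mirrored across hemispheres so homotopic flipping preserves community
labels. Patients are scanned at TP1/TP2/TP3, controls once; the defaults
(16 + 16 subjects, 240 regions, 395 volumes at 1.2 s) mirror the reference
longitudinal design of a motor-stroke cohort with matched controls. Each
patient draws a lesion side (right with probability 0.25) and a log-normal
lesion volume, independent of the planted effect, since only their role as
covariates matters.

The planted longitudinal effect raises the **between-community**
correlation at patient TP3 by `tp3_effect`. This was chosen over a uniform
increase because it raises global integration — positive-edge count, mean
degree and global efficiency move together — which is what makes the
cost–resilience correlation testable. Positive semi-definiteness of both
implied covariances is checked before any sampling, and generation is
bit-reproducible under the spec's seed.

What the generator does **not** emulate: spatial autocorrelation and
hemodynamic smoothing beyond AR(1), scanner drift and motion artifacts,
physiological noise, inter-subject anatomical variability, or any
behavioral covariate. Passing tests therefore demonstrate that the pipeline
recovers planted second-order effects under idealized noise — not that it
would detect effects of a given size in real BOLD data.

# Validation design and problem sizes

The suite validates each stage against independent oracles (per-source BFS
for distances; brute-force sorting for thresholding; exact enumeration for
step-1 random attacks; the step-up definition for BH; paired-t equivalence
for the two-timepoint mixed model), then two cohort-level properties at a
reduced size chosen to keep the full suite fast while leaving the power to
detect miscalibration — 8 patients, 60 regions, 120 volumes, 6 communities:

- **Null calibration**: over 200 cohorts with `tp3_effect = 0`, the raw
  TP2-vs-TP3 paired-test rejection rate at 0.05 must fall inside the
  two-sided binomial 95% envelope, and BH-adjusted rejections must not
  exceed its upper bound.
- **Effect recovery**: over 50 cohorts with `tp3_effect = 0.1` (the suite's
  stated effect size, roughly a 20% relative increase in mean between-block
  correlation), the qualitative headline pattern — TP1 ≈ TP2, TP3 > TP2 and
  TP3 > controls in pre-attack AUC(E_glob) and in post-attack AUC for all
  three scaled lesion sizes, plus a positive cost–resilience rank
  correlation — must appear in at least 80% of simulations.

`scripts/acceptance.R` recomputes the same kinds of quantities end to end
at these sizes and writes them as JSON.

# Known limitations

- Serial attacks recompute all-pairs BFS after every deletion; at 240
  regions and 10 densities a 20-replicate random attack is the pipeline's
  slowest stage. Replicates are embarrassingly parallel if needed.
- The MODWT uses circular boundary conditions; the first and last ~2^scale
  filter widths of the sub-band series mix signal from both ends. For
  correlation estimates over hundreds of volumes the effect is negligible.
- With small cohorts the random-intercept variance often sits at the
  boundary (singular fits); the omnibus F remains well-defined and the
  condition is noted in the output rather than hidden.
- The exact wavelet family and the step range of the attack-curve
  averaging in the reference analyses are unstated; both choices here are
  documented above and flagged in serialized outputs.
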