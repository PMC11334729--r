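---
title: "Single-subject gray-matter networks: models, metrics and design choices"
author: "gmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject gray-matter networks: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

## The method

`gmnet` implements an individual (single-subject) morphometric network
analysis for gray-matter (GM) volume images, of the kind used to study
network disruption across the Alzheimer's disease continuum (cognitively
normal, CN; mild cognitive impairment, MCI; Alzheimer's disease, AD).

Each subject's 3D GM volume is partitioned into non-overlapping
3×3×3-voxel cubes (6 mm cubes at the default 2 mm voxel size). Cubes
containing any GM above a small threshold (`gm_eps = 0.05`) become network
nodes; empty background cubes are dropped, so network size varies by
subject. For every node pair, the Pearson correlation between the 27
aligned voxel values is computed — structural covariance carried by both
tissue density and the spatial pattern within the cube. The similarity
matrix is binarized by a one-sided test for positive association: each
correlation is converted to \(t = r\sqrt{(n-2)/(1-r^2)}\) with \(n = 27\),
and Benjamini–Hochberg FDR control at \(q = 0.05\) across all unique pairs
of that network sets the edges. Negative correlations never form edges.

From the resulting unweighted, undirected graph, seven global metrics are
computed: network size \(N\), mean degree \(\bar k = 2E/N\), connectivity
density \(100\,E/\binom{N}{2}\), mean clustering coefficient \(C\)
(nodes with degree < 2 contribute 0), characteristic path length \(L\)
(mean shortest path over pairs within the largest connected component,
whose coverage is reported as a diagnostic), and the small-world
coefficients: \(\gamma = C/\langle C_{\mathrm{rand}}\rangle\),
\(\lambda = L/\langle L_{\mathrm{rand}}\rangle\), and
\(\sigma = \gamma/\lambda\), normalized against 20 degree-preserving
(Maslov–Sneppen double-edge-swap) random reference graphs with 10
attempted swaps per edge. A network is called small-world when
\(\gamma > 1\), \(\lambda \approx 1\), and \(\sigma > 1\).

Downstream, the package reproduces the full statistical battery of such
studies: demographics tests (chi-squared for sex, one-way ANOVA for age,
education, MMSE, MoCA, Kruskal–Wallis for CDR), covariate-adjusted group
comparisons of each metric (least squares with CN as reference, the group
effect tested by a nested-model F test, pairwise Welch t-tests on
covariate-adjusted residuals with BH correction per metric), regressions
of each metric on MoCA controlling for age, sex, education and TIV, and a
voxel-wise map of the partial correlation between \(\sigma\) and GM volume
controlling for age, sex and TIV, Fisher-transformed to
\(z = \operatorname{atanh}(r)\sqrt{n - c - 3}\) and cluster-corrected.

## Why a synthetic cohort, and what it emulates

The motivating studies draw on access-restricted clinical imaging archives.
`gmnet` therefore ships a first-class synthetic-cohort generator so every
stage of the pipeline is testable end to end against known ground truth,
at desk scale. The generator emulates:

* **Three diagnostic groups** with demographic and cognitive score
  distributions calibrated to a typical AD-continuum cohort
  (`default_demographics()`): groups matched on age and sex, but differing
  in education, CDR, MMSE and MoCA. MoCA is missing for a per-group
  fraction of subjects, mirroring incomplete neuropsychological batteries.
  Scores are kept continuous and clamped to their scale bounds (a
  deliberate simplification: with all sds set to 0 the generator
  reproduces group means exactly, which integer rounding would break).
* **Spatially covarying GM volumes** whose covariance structure degrades
  with diagnosis (below).
* **An atrophy–cognition coupling**: each subject has a latent atrophy
  severity (group mean rising CN → MCI → AD), which multiplicatively
  reduces GM inside a recorded "vulnerable" mask (bilateral
  inferior-lateral regions of the template, emulating temporal/parietal
  vulnerability) and enters the subject's MoCA mean with slope
  `moca_coupling` (default −12 MoCA points per unit atrophy), so
  metric–MoCA regressions have planted effects.

## The generative image model

A subject image is

\[
I \;=\; T \,(1 - a\,A)\,(1 + s\,S) \;+\; \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, \texttt{noise\_sd}^2),
\]

clipped at zero, where \(T\) is the cohort template, \(A\) its atrophy
mask, \(a\) the subject's atrophy severity, and \(s\) the signal
amplitude (default 0.4).

**Template.** \(T\) is a deterministic ellipsoidal GM volume with gently
varying deep-GM density and zero background. It is piecewise-constant at
cube granularity with cube-aligned support. This is intentional: a
template with strong within-cube gradients would imprint the same local
pattern on every subject, dominating the inter-cube correlations and
making the network topology insensitive to the generative covariance
model. With a per-cube-constant template, correlations are carried
entirely by the model below, and signal-to-noise is homogeneous across
nodes.

**Structured covariance.** The signal \(S\) is built from \(K = 6\)
cohort-shared 3×3×3 micro-patterns \(p_k\) realized identically at every
cube, weighted by cohort-shared smooth loading fields \(W_k\) (Gaussian
random fields smoothed at three times `smoothing_fwhm_mm`, i.e. 24 mm by
default). Two cubes correlate to the extent that their loading vectors
align — nearby cubes align because the loading fields are smooth (local,
lattice-like edges), and distant cubes align when they share a covariance
module (long-range edges). This construction was chosen after the direct
alternative — smooth random fields added to the image — proved unable to
carry controllable long-range covariance: a field that is smooth at the
cube scale is nearly constant within a cube and cancels out of the
(scale-invariant) Pearson correlation, while distant locations of any
stationary field are simply independent.

**Decoherence.** The disease knob \(d\) (`decoherence_level`, defaults
0.05/0.12/0.20 for CN/MCI/AD) blends the structured signal with

* a cohort-shared **common-mode pattern** \(p_0\), weight
  \(2.2\,d(1-d)^2\) — a dedifferentiation term: correlations become less
  selective, so edges appear between previously unrelated cubes,
  randomizing edge placement and degrading clustering, \(\gamma\),
  \(\lambda\) and \(\sigma\) toward their random-graph values; and
* subject-independent per-cube **pattern noise** \(Q\), weight
  \(\sqrt{1-0.7^2}\,d\) — attenuating all correlations so the mean
  inter-cube similarity declines monotonically with \(d\).

The blended signal is renormalized to unit variance, so global image
statistics (notably TIV, computed from the image as the volume of voxels
with GM > 0.05) carry no group signature — as with real total
intracranial volume, which measures head size, not atrophy. Subject
brain-size variability (`brain_size_sd`) scales the GM support radius,
giving realistic TIV and network-size variation that is independent of
diagnosis and must be handled by the covariate adjustment, not by the
group labels.

The two weight shapes were fixed once, by their limiting behavior: the
common-mode weight vanishes at both \(d = 0\) and \(d \to 1\) (a
fully decoherent image is noise, not a giant common mode), and at the
working range \(d \le 0.25\) the dedifferentiation term dominates the
attenuation term, which is what makes the direction of the group effect
on \(\sigma\) stable across cohort realizations. With these defaults,
group-mean \(\sigma\) is ordered CN > MCI > AD with a significant
covariate-adjusted CN-vs-AD contrast in 10/10 cohort seeds at 10
subjects per group, while connectivity density moves only mildly (it
rises slightly with \(d\); in the motivating data it declines slightly —
density behavior is reported and plotted but never asserted).

### What the generator does *not* emulate

No scanner physics, no bias fields or gradient distortions, no
registration or segmentation error, no anatomical detail (the template is
an ellipsoid, coordinates are synthetic-space mm, not MNI), no spatial
autocorrelation of the additive noise, and no longitudinal structure.
Consequently, passing tests demonstrate that the *pipeline machinery* —
construction, metrics, statistics, mapping — behaves correctly on data
with known structure; they are not evidence about effect sizes in real
cohorts. Synthetic \(\sigma\) values (≈1.4–2.2 depending on the field
realization) sit above the ≈1.3 typical of real whole-brain GM networks,
because the synthetic covariance is cleaner than real anatomy.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `cube_edge` | 3 | voxels | node size (6 mm at 2 mm voxels) |
| `gm_eps` | 0.05 | GM units | cube retention threshold (any voxel above) |
| `q` | 0.05 | — | BH-FDR level for binarization |
| `n_random` | 20 | graphs | reference graphs for \(\gamma, \lambda, \sigma\) |
| `n_swaps_per_edge` | 10 | — | rewiring budget per reference graph |
| `smoothing_fwhm_mm` | 8 | mm | pattern-field smoothness (VBM practice) |
| `signal_amplitude` | 0.4 | — | structured signal sd relative to GM |
| `noise_sd` | 0.01 | GM units | additive voxel noise |
| `decoherence_level` | .05/.12/.20 | — | per-group covariance degradation |
| `atrophy_level` | .02/.12/.25 | — | per-group GM reduction in the mask |
| `voxel_z` | 3.29 | — | voxel threshold (two-tailed p < 0.001) |
| `cluster_p` | 0.05 | — | cluster-level significance |
| `n_perm` | 1000 | — | permutations for the cluster null |

## Numerical and procedural choices

* **FDR reading of the binarization threshold.** "5% threshold with FDR
  correction" is read as BH-FDR at \(q = 0.05\) over each network's unique
  pairs, not as a fixed 5% density: observed connectivity densities near
  17% in the motivating work are only consistent with the FDR reading. A
  fixed-density mode (`threshold_density()`) is provided for sensitivity
  analyses.
* **Aligned-voxel correlation by default.** The similarity of two cubes is
  the Pearson correlation of their voxel values in corresponding
  positions. An optional `max_rotation` mode takes the maximum over the 48
  rotation/reflection symmetries of the cube, the orientation-invariant
  variant used by some implementations of the method; it is off by default
  and roughly 48× more expensive.
* **Zero-variance cubes** have undefined correlations; they are recorded
  as 0 (no edge possible) and counted on the similarity matrix.
* **Disconnected graphs.** \(L\) is averaged over pairs within the largest
  connected component — the common convention for FDR-binarized graphs —
  and the component's node fraction is attached so near-disconnected
  networks are visible. Reference graphs whose path length cannot be
  computed are skipped and counted; if all 20 are skipped an error is
  raised.
* **Pairwise tests on adjusted residuals.** Whether pairwise t-tests
  should use raw or covariate-adjusted values is a genuinely open choice;
  the default adjusts (residuals of metric ~ age + sex + education + TIV
  fitted on the whole sample), consistent with the covariate-controlled
  framing of the group models; `adjust = FALSE` gives raw tests. Welch
  (unequal-variance) t-tests are used throughout since group sizes and
  variances differ.
* **Permutation cluster null instead of Gaussian-random-field
  correction.** The GRF correction used by neuroimaging toolboxes needs a
  smoothness (RESEL) estimate whose provenance is toolbox-specific. The
  default here is a seeded permutation null: sigma residuals are permuted
  across subjects, the maximal suprathreshold (|z| > 3.29, two-tailed)
  6-connectivity cluster size is recorded per permutation, and clusters
  with permutation \(p <\) `cluster_p` survive. An extent-only mode
  (`n_perm = 0` with a fixed minimum cluster size) is available for
  report parity with GRF-style thresholds.
* **Seeds.** Every stochastic step (covariates, fields, subject noise,
  rewiring replicates, permutations) draws its seed from a per-stage
  master seed, so whole-pipeline runs are bit-reproducible.

## Problem sizes used in the tests

The test-suite study conditions are chosen to run on one CPU in minutes:
the small-world bound cohort is 15 subjects at 30³ voxels (≈370-node
networks); direction recovery uses 10 cohorts of 30 subjects; regression
calibration uses 200 simulated tabular cohorts of 150 subjects; voxel-map
calibration uses 50 null replicates (200 permutations each) over a fixed
30-subject image stack and one planted-coupling cohort of 120 subjects.
The covariance-contract checks run on 24³-voxel images, where cube
statistics are identical in structure to the 30³ case.

## Known limitations

* The synthetic template is an ellipsoid with blocky (cube-aligned)
  support; peak coordinates in cluster reports are synthetic-space mm.
* The generator's decoherence acts at the cube scale; it does not model
  partial-volume effects at cube boundaries.
* \(\gamma\) is strongly coupled to connectivity density in FDR-binarized
  graphs (the reference-graph clustering tracks density); comparisons of
  \(\gamma\) across thresholds or cohorts with different densities should
  be interpreted with this in mind.
* MoCA missingness is missing-completely-at-random; real missingness is
  likely informative.
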