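---
title: "Methods: comparative analysis of multi-domain MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of multi-domain MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pincerMD)
```

pincerMD compares the dynamics of structurally homologous multi-domain
proteins — the motivating case being paralog families like the human
Argonautes, whose shared N/L1/PAZ/L2/MID/PIWI architecture hides
protein-specific flexibility, open/close behaviour and interaction
repertoires. This vignette documents the models and conventions the
package commits to, the parameters that matter, and the places where a
design choice was genuinely open.

## The synthetic pincer model

Real comparative MD data is large and engine-specific, so the package
ships a generator that reproduces the *statistical structure* the
analysis relies on, not the physics. A `pincer_spec()` defines K
internally rigid domains, one pseudo-atom (CA, mass 1) per residue on a
3.8 Å cubic lattice. Two designated jaw domains oscillate along their
connecting axis so that their center-of-mass separation is, before
noise,

$$ d(t) = d_\text{closed} + A\,\bigl(1 - \cos 2\pi (t - \phi)/T\bigr), $$

a raised cosine with peak-to-trough span $2A$. On top of this every
atom receives i.i.d. isotropic Gaussian displacement with a per-domain
standard deviation $\sigma$ per axis, so the per-residue RMSF of a
static domain has the known value $\sigma\sqrt{3}$.

Default conditions mirror microsecond-scale sampling of Argonaute-sized
systems: 1 frame / 10 ps (100,000 frames per μs at full scale), six
domains named N, L1, PAZ, L2, MID, PIWI with the PAZ/MID pair as jaws,
closed separation 30 Å and amplitude 12 Å so the open state exceeds
50 Å — the magnitude of pincer opening reported for these proteins.
σ defaults to 0.5 Å per axis (≈ 0.87 Å RMSF), the order of magnitude of
a stable domain's local flexibility. Replicates share the spec and
differ only in the noise seed, mirroring independent simulation
replicas.

What the generator deliberately does **not** emulate: anharmonic and
correlated fluctuations, secondary-structure mechanics, solvent,
kinetic (two-state jump) open/close transitions — dwell asymmetry can
only be approximated by long periods. Tests passing on this model
therefore validate the *estimators* (their algebra, conventions and
statistical calibration), not any claim about real Argonaute dynamics.

Two practical consequences are worth knowing. First, rigid-body fitting
absorbs six degrees of freedom: for a 64-atom system the Gaussian-noise
RMSF recovers $\sigma\sqrt{3}\cdot\sqrt{1 - 6/(3N)} \approx 0.985
\cdot \sigma\sqrt{3}$, which is why the calibration test uses a 3%
band. Second, a raised cosine sampled uniformly in time has an arcsine
marginal: frames pile up near both extremes, and the medoids of a
DB-optimal 2-cluster split sit near the *conditional means* of each
half (≈ 0.64·A from each extreme), not at the extremes themselves. The
open/closed state-span check therefore feeds the representative
selection rule with candidates spanning the trajectory; the clustering
path is validated separately on planted discrete conformers, where
medoids are well defined.

## Structural metrics: conventions

* **Superposition** is Kabsch least-squares (SVD with a determinant
  sign fix, proper rotations only). Two-point or collinear selections
  are accepted — their minimal RMSD is well defined even though the
  optimal rotation is not unique; fewer than two atoms is an error.
* **RMSD series**: each frame is fitted to the reference frame (frame 1
  by default) over the fit selection, then measured over the metric
  selection — "fit on whole, measure on domain" by default, matching
  common practice; both selections are explicit arguments because the
  convention genuinely varies between tools.
* **RMSF** uses the time-averaged structure as reference, with two
  average-and-refit passes; the initial reference is the raw
  time-average, which makes the result invariant to frame order.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral point
  set (960 points/atom by default), Bondi van der Waals radii and a
  1.4 Å water probe. The quadrature is exact for an isolated atom and
  converges as 1/n_points otherwise; the two-sphere case is tested
  against the closed-form lens formula at 2%.
* **Interdomain distances** are Euclidean distances between
  mass-weighted domain centers of mass (geometric centers for the
  unit-mass pseudo-atoms), reported for all domain pairs with
  mean/median/variance summaries.

## The cross-replicate significance protocol

Metric series are smoothed with the recursive EWMA
$y_t = \alpha x_t + (1-\alpha) y_{t-1}$, $y_1 = x_1$,
$\alpha = 2/(\text{span}+1)$, span = 10% of the series length (span
1000 for interdomain distances at the full 100,000-point scale; scaled
proportionally for shorter series). Smoothed series are compared with
the two-sample Kolmogorov–Smirnov statistic D, and the verdict over
replicates is:

* **significant** — every replicate has D > 0.55 *and* p < 0.001;
* **insignificant** — every replicate has D < 0.45;
* **inconclusive** — anything else.

The "K-test metric" thresholds 0.55/0.45 only make sense for the
bounded two-sample D statistic, which is how the rule is implemented.
The conjunction over replicates is the rule's real safeguard: applying
KS to heavily smoothed, autocorrelated series grossly inflates nominal
significance per replicate, but requiring three independent replicates
to each clear D > 0.55 keeps the measured null rate at 0 in 1000 trials
while a one-standard-deviation mean shift is detected in 100% of
trials (both recomputed by `scripts/acceptance.R`). For users who want
honestly calibrated per-comparison p-values, `ks_compare(...,
effective_p = TRUE)` also reports a p-value recomputed with
lag-1-autocorrelation effective sample sizes; it is off by default
because the verdict rule is defined on the nominal p. No
multiple-testing correction is applied across the comparison grid; the
report manifest says so.

Residue-level (RMSF) curves mapped across paralogs are compared with
the paired two-sided Wilcoxon signed-rank test — sidedness was an open
choice and two-sided is the conservative one; "significant" is
operationalized as p < 0.001 with a nonzero statistic, and all-zero
differences are insignificant by convention. Curve geometry is
compared with the discrete Fréchet distance, computed by the standard
dynamic program and validated against an exhaustive coupling recursion
on short curves. RMSF curves are compared in value-only mode on the
positions paired by the residue mapping; a uniform offset of c between
two curves yields exactly |c|.

**Equilibration cut**: the suggested production start is the first
frame at which the least-squares slope of the EWMA-smoothed RMSD over
the trailing window (10% of the length) drops to `slope_tol`
(10⁻⁴ Å/frame) or below. The EWMA's exponential relaxation after a
drift ends keeps the smoothed slope above a tight tolerance for a
while, so the suggested cut lands conservatively *after* the drift —
the unit tests assert exactly this qualitative behaviour (flat series
cut at 0, ramp-then-flat cut after the ramp, monotone ramp flagged not
converged).

## Conformational states

**Synchronization.** Jaw-distance series are EWMA-smoothed and
z-normalized (`smooth_normalize`), then `time_lag` scans integer lags
in ±max_lag maximizing the cross-correlation. The correlation is
evaluated on a fixed central window of the first series with a constant
denominator: with a varying-overlap estimator the denominator shrinks
with |lag| and drags the argmax toward zero by a frame or two, which
would break exact recovery of planted shifts. Ties break toward the
smallest |lag|, making `time_lag(a,b)` and `time_lag(b,a)` exact
negatives. Periodic signals alias at lag ± period, so max_lag should be
kept below half the dominant period.

**Clustering.** Frames are featurized as alpha-carbon coordinates
after one superposition onto the trajectory's average structure —
Euclidean distance on these features equals the square root of
(3N × mean-square deviation), so k-means on them is k-means in the MSD
metric. k is scanned over 2–20 (bounded by n_frames − 1) with
`stats::kmeans` (10 restarts, fixed seed; deterministic given the
seed). The Davies–Bouldin score selects k; among candidates within 5%
of the best score, the k whose average within-cluster RMSD is nearest
4 Å wins. The printed preference ("average inter-cluster mean square
deviation of 4 Å") is ambiguous about inter/within and about MSD vs
RMSD units; treating it as a within-cluster RMSD target used only as a
near-tie-break keeps the selection driven by the well-defined DB score.
An all-identical-frames trajectory short-circuits to a single cluster
with a warning. Medoids minimize the summed within-cluster squared
feature distance, with ties going to the lowest frame index.

**States and projection.** Open/closed representatives are the medoids
with maximal/minimal jaw separation (first index on exact ties; a
single medoid yields a warning and identical states). For the
cross-paralog map, every protein's medoids are restricted to residues
commonly mapped to the reference (global Needleman–Wunsch alignments,
BLOSUM62, gap open 10 / extend 0.5 — the EMBOSS Needle defaults),
rigidly superposed onto the first reference medoid, stacked one row per
(medoid, residue) alpha-carbon, and embedded in 2D. The embedding
method is pluggable and its parameters (min_dist = 1,
n_neighbours = 1000 in the UMAP parameterization) are recorded with
every output; the default embedder is deterministic PCA, which is what
the tests exercise — a stochastic manifold method cannot anchor
regression tests, and for the planar synthetic fixtures PCA recovers
the configuration exactly.

## Weak interactions

The detector implements fixed geometric rules (boundaries inclusive):
hydrogen bonds at donor–acceptor heavy-atom distance ≤ 3.5 Å with a
D–H···A angle ≥ 110° required only when explicit hydrogens are present,
subtyped hbbb/hbsb/hbss by backbone vs side-chain membership of donor
and acceptor; salt bridges at anionic-O–cationic-N ≤ 4.0 Å; pi-cation
at cation-N within 6.0 Å of the ring centroid and ≤ 60° off the ring
normal; pi-stacking at centroid distance ≤ 7.0 Å with ring normals
≤ 30°; t-stacking at the same distance with normals 60–90°. Ring
normals come from the smallest singular vector of the centered ring
atoms; aromatic residues with missing ring atoms are skipped with a
warning. Contacts between residues fewer than two sequence positions
apart are suppressed (covalent neighbours). These thresholds are the
common defaults of the geometric contact-analysis tool family; absolute
hydrogen-bond counts are convention-dependent (angle definitions
differ between tools), so only orderings and catalogues — not absolute
counts — should be compared across software. Catalogues over medoids
deduplicate on (type, residue pair) with the lower residue number
first, making them invariant to atom order and idempotent under
repeated medoids.

## Conserved segments

The paralog-conserved segments of interest are contiguous blocks
(their reported coordinate ranges are intervals), so the search
implements the longest common *substring* across k sequences:
case-sensitive exact matching, binary search over the segment length
with hashed substring-set intersection at each probe
(O(total length × log min-length) set operations in C-level hashing).
All tied longest segments are returned and every hit is re-verified
against every sequence before return. A generalized suffix automaton
would reach the same answer in linear time, but at protein-family
sizes (k ≤ 10, n ≈ 10³) the set-intersection search is already
instantaneous and is far easier to audit; the exhaustive enumeration
oracle in the test suite guards its correctness on 200 random cases
per run. Percent identity is positionwise in ungapped mode; in global
mode it is computed over the alignment's columns with gap columns
counting as mismatches.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for a single CPU: Fréchet
and segment oracles at curve length ≤ 8 and sequence length ≤ 200 (200
cases each); RMSF calibration on 64 atoms × 10,000 frames (3% band,
covering the rigid-body-fit bias above); SASA at 960 quadrature points
(1% for the isolated atom, 2% vs the two-sphere closed form); verdict
calibration with 1000 null and 300 alternative triples at n = 1000;
time-lag recovery on 1000-frame series (exact noiseless, ±3 frames at
SNR 5 over 100 seeds); clustering on 80-frame planted-conformer
trajectories. Floating-point identities (Rg closed forms, Fréchet
offsets, oracle agreement) are asserted at 10⁻¹² ; geometric
constructions at 10⁻⁹.

## Known limitations

* Binary MD formats (XTC/DCD) are not read; convert to multi-model PDB
  or the CSV dialect first. Multi-chain PDBs must be pre-split.
* The verdict rule inherits the autocorrelation-inflated nominal
  p-values of its inputs; its calibration rests on the all-replicates
  conjunction, and the optional effective-sample-size p is the honest
  per-comparison alternative.
* SASA uses a fixed element-radius table (H, C, N, O, S, P) and errors
  on unknown elements rather than guessing.
* The hydrogen-bond detector without explicit hydrogens is
  distance-only and will over-count relative to angle-aware detectors.
* Cluster count selection near-degenerates when conformational change
  is continuous rather than discrete; the DB score then prefers few
  clusters and medoids summarize density, not extremes (see the
  arcsine discussion above).
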