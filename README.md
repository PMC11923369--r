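# pincerMD

Comparative analysis of molecular-dynamics trajectories of multi-domain
proteins, built around the kind of question raised by the four human
Argonaute (AGO1–4) paralogs: proteins that share domain architecture
(N, L1, PAZ, L2, MID, PIWI) and most of their sequence, yet move
differently. Given per-replicate trajectories for several such paralogs,
the package asks: which domains fluctuate differently, and with what
statistical support? Are the global open/close "pincer" motions of the
nucleic-acid binding channel synchronized between proteins? Which
conformational states and weak-interaction patterns does each protein
visit? Which contiguous sequence segments are common to all paralogs, and
do they move alike?

It is aimed at structural bioinformaticians who already have trajectories
(from any MD engine, exported as multi-model PDB or a simple columnar CSV)
and want the comparative statistics, not the simulation itself.

## What it computes

**Structural metrics** (`rmsd_series`, `rmsf`, `radius_of_gyration`,
`sasa`, `interdomain_distances`): Kabsch least-squares superposition, then
the standard curves — RMSD per frame

```
RMSD(t) = sqrt( (1/N) * sum_i || R x_i(t) + t - x_i(ref) ||^2 )
```

per-residue RMSF about the time-averaged structure, mass-weighted radius
of gyration, Shrake–Rupley solvent-accessible surface area on a
deterministic golden-spiral quadrature (960 points/atom, Bondi radii,
1.4 Å probe), and mass-weighted center-of-mass distances between all
domain pairs.

**Cross-replicate significance protocol** (`ewma`, `ks_compare`,
`replicate_verdict`, `wilcoxon_compare`): metric series are smoothed with
an exponentially weighted moving average (α = 2/(span+1), span = 10% of
the series length; span 1000 for interdomain distances at 100,000 points),
compared pairwise with the two-sample Kolmogorov–Smirnov test, and a
comparison is called **significant** only when *every* replicate pair has
D > 0.55 with p < 0.001, **insignificant** only when every replicate has
D < 0.45, otherwise **inconclusive**. RMSF curves mapped across paralogs
are compared with the paired Wilcoxon signed-rank test and with the
discrete Fréchet distance (dynamic programming over monotone couplings).

**Conformational states** (`smooth_normalize`, `time_lag`,
`cluster_frames`, `extract_medoids`, `select_state_representatives`,
`stack_and_project`): time-lagged cross-correlation between jaw-distance
series quantifies open/close synchronization; frames are clustered with
k-means on superposed alpha-carbon coordinates, k chosen by the
Davies–Bouldin score with a 4 Å average within-cluster preference as
tie-break; cluster medoids yield open/closed state representatives
(max/min jaw separation) and, after residue mapping from global sequence
alignments, a 2D projection of the stacked medoid coordinates.

**Weak interactions** (`detect_contacts`, `hbond_count_series`,
`unique_contact_catalog`): geometric rules for hydrogen bonds
(backbone/side-chain subtypes hbbb/hbsb/hbss), salt bridges, pi-cation,
pi-stacking and t-stacking, catalogued over cluster medoids.

**Conserved segments** (`longest_common_segments`, `percent_identity`,
`map_segment`): the longest contiguous substring present in all input
sequences (LCS1/LCS2-style), its coordinates in each sequence, and percent
identity of companion nucleotide segments.

**Synthetic data** (`pincer_spec`, `generate_pincer_trajectory`,
`generate_replicates`, `plant_lcs_sequences`): rigid-domain trajectories
whose two jaw domains follow a raised-cosine open/close oscillation plus
i.i.d. Gaussian residue noise, and random sequences with planted common
segments — every analysis stage is testable end to end without downloads.

`run_study()` composes all of the above over proteins × replicates into a
CSV/JSON report bundle with a reproducibility manifest;
`inst/scripts/pincer-md.R` is a thin command-line wrapper.

## Worked example

```r
library(pincerMD)

spec <- pincer_spec(n_frames = 600, period = 150, amplitude = 10,
                    fluctuation_sigma = 0.5, seed = 1)
traj <- generate_pincer_trajectory(spec)
map  <- pincer_domain_map(spec)

jaw  <- pair_distance(interdomain_distances(traj, map), "PAZ", "MID")
reps <- select_state_representatives(jaw)
cat(sprintf("jaw separation: %.1f-%.1f A (planted span %.0f A)\n",
            reps$closed_distance, reps$open_distance, 2 * spec$amplitude))
#> jaw separation: 29.7-50.1 A (planted span 20 A)

rf <- rmsf(traj)
round(tapply(rf$values, assign_domains(map, rf$index), mean), 2)
#>   L1   L2  MID    N  PAZ PIWI
#> 0.87 0.86 3.63 0.86 3.64 0.86
```

The closed/open representatives bracket the planted 20 Å span (29.7 to
50.1 Å), and the jaw domains (PAZ, MID) show the large apparent RMSF their
oscillation implies while the static domains sit at the noise floor
(0.5 Å per axis ≈ 0.87 Å RMSF).

```r
specB <- pincer_spec(n_frames = 600, period = 150, amplitude = 10,
                     fluctuation_sigma = 1.5, seed = 2)
repsA <- generate_replicates(spec,  3, seeds = 11:13)
repsB <- generate_replicates(specB, 3, seeds = 21:23)
nsel  <- domain_residues(map, "N")
recs  <- mapply(function(a, b) {
  sa <- rmsd_series(a, sel = nsel)$values
  sb <- rmsd_series(b, sel = nsel)$values
  ks_compare(ewma(sa, default_span(600)), ewma(sb, default_span(600)))
}, repsA, repsB, SIMPLIFY = FALSE)
replicate_verdict(recs, comparison = "A|B|N")
#> verdict [A|B|N]: significant (3 replicates)
```

A 3-fold difference in the N domain's fluctuation amplitude is flagged
significant in all three replicates (D ≈ 0.98, p ≈ 0), exercising the
0.55/0.45, p < 0.001 cross-replicate rule.

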