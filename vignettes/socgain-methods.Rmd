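---
title: "Methods: co-gain detection and supra-operonic cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-gain detection and supra-operonic cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socgain)
```

## The scientific question

Bacterial adaptation is dominated by horizontal gene transfer (HGT), and
transferred DNA segments usually carry several genes at once. Two questions
follow: how large are the segments that are successfully transferred and
retained, and what determines that size? `socgain` implements an inference
chain that answers both on gene presence/absence data over a strain
phylogeny:

1. reconstruct ancestral gene content and call per-branch **gains**;
2. find family pairs that are **co-gained** on the same branches far more
   often than chance allows;
3. measure the **genomic distances** of those pairs on the circular
   chromosome, separating phage-mediated recent acquisitions from stable
   transfers;
4. estimate the within-cluster distance distribution of **supra-operonic
   clusters** (SOCs) — groups of co-occurring and co-functioning genes that
   extend beyond operons — from genomic autocovariance; and
5. test whether operons or SOCs explain the co-gain distance distribution.

Because the original genome panel is not redistributable, the package ships
a ground-truthed forward simulator that generates all inputs with the
statistical structure the analysis assumes, so every stage is testable
end-to-end and against known truth.

## Gain/loss reconstruction

Gene content evolves on the rooted, bifurcating strain tree under a
two-state continuous-time Markov model with gain rate `alpha`
(absent → present) and loss rate `beta` (present → absent), per unit branch
length. `fit_gain_loss()` maximises the product over families of pruning
likelihoods; the root prior is the stationary distribution. Optimisation is
bounded in log-rate space with three fixed starts.

A single global gain/loss ratio is not enough: most families are vertically
inherited and slowly lost, so the global fit is loss-dominated, and a
loss-dominated model explains a family present in several scattered strains
as ancestral presence followed by many losses — exactly the opposite of the
repeated-acquisition signal the analysis looks for. `fit_gain_loss(...,
per_family = TRUE)` therefore adds a per-family gain-rate multiplier chosen
from a fixed grid (0.25–64) by maximum likelihood, a discrete analog of the
variable gain/loss-ratio mixtures used by ancestral content reconstruction
tools. The pipeline enables this by default; the plain global model remains
the default of `fit_gain_loss()` itself and is what the rate-recovery
checks exercise.

`posterior_presence()` computes marginal posteriors at every node with an
upward/downward pass (leaves pinned to observations); it is verified
against brute-force enumeration over all internal-state assignments on
small trees. `call_events()` thresholds the posteriors along each branch:
in the *inclusive* tier a gene is present where P ≥ 0.5, so a gain is
called when the parent is below 0.5 and the child at or above it; the
*high-confidence* tier requires P ≤ 0.2 in the parent and P ≥ 0.8 in the
child (losses symmetric). Ties at exactly 0.5 count as present.

## Co-gain association and the empirical FDR

Each family's gain history is a binary vector over the `2n − 2` branches
(branch = child node, cladewise order). For a pair of families the
branch-wise patterns `[0,0] [0,1] [1,0] [1,1]` form a 2×2 table, and the
association score is

> t = log10 P(X ≥ n11 | margins)

the decadic log of the right-tail Fisher exact (hypergeometric) p-value;
more negative means stronger co-gain. Families without any gain are
excluded (they contribute only `[0,0]`).

Branch-wise gains are not independent observations, so `t` has no direct
sampling interpretation. Significance comes from a permutation null:
`shuffle_null()` shuffles each family's presences across the extant
genomes (preserving its frequency), reruns the reconstruction and scoring
with the already-fitted global rates (per-family multipliers are
re-estimated on the shuffled matrix, since they are part of the
reconstruction procedure, not of the data), and collects the null score
multiset. The empirical false discovery rate is

> FDR(t) = N_null(t) / N_data(t)

with both counts over pairs scoring strictly below `t`, the null count
averaged over replicates and rescaled to the empirical pair-universe size.
`fdr_threshold()` returns the largest `t*` with FDR ≤ α and the pairs below
it. The pipeline uses three null replicates; a single replicate is the
`shuffle_null()` default. The supplementary probability-product score
(`prob_product_score()`) is retained for comparison but is known to be less
selective.

## Distances on the circular chromosome

Distances between gene pairs use, by default, the **midpoint** convention
(shorter-arc distance between feature midpoints). At distances much larger
than a gene the midpoint and boundary-gap conventions coincide; at cluster
scale the midpoint convention matches the site-offset scale on which
autocovariance-based distributions live, which keeps gene-pair and
site-pair distributions comparable. The boundary-gap convention
(`circular_distance()`, `convention = "gap"`) is retained for sensitivity
analysis and for the intervening-gene logic, where "zero genes between"
must correspond to a small gap.

For a family pair, the distance in one genome is the minimum over allele
(paralog) pairs; `min_family_distance()` takes the minimum over genomes —
a lower bound on the distance at transfer time, because partial loss can
only shrink it. `per_occurrence_distances()` keeps one value per co-occupied
genome instead. `intervening_phage_stats()` compares close
(< `segment_cap`) and distant (between the caps) allele pairs by the
fraction of genes between them (shorter arc, midpoint-inside rule) that are
phage-associated, with a two-sided Wilcoxon rank-sum test; occurrences with
no gene in between are excluded.

Phage association is classified per family from two evidence sources:
a phage keyword in any allele's product text (case-insensitive substring)
or a phage-related GO term; families with GO terms but no phage evidence
are `not_associated`, families with neither are `uncertain`. The shipped
GO list (`extdata/phage_go_terms.tsv`) is a small synthetic stand-in for a
curated phage vocabulary and should be replaced for real data. "Non-phage"
distance distributions require both members strictly `not_associated`.

## Co-occurrence and co-functioning

`profile_mi()` computes the mutual information of two binary phylogenetic
profiles over a species panel from plug-in pattern probabilities with
base-2 entropies (`0·log 0 := 0`). Base 2 is the only base for which the
bound `0 ≤ I ≤ 1` is tight for binary profiles. No small-sample bias
correction is applied; with a couple of hundred species the plug-in bias
floor is ≈ `1/(2 n ln 2)` bits, which matters when choosing MI cutoffs
(cutoffs below the floor qualify essentially all pairs and only the
background remains after rescaling). `shared_go_counts()` counts common GO
terms per pair; `go_mi_correlation()` reports their Spearman correlation
with profile MI over pairs sharing at least one term.

## SOC delineation by autocovariance

For sites `i` on a `frame` bp lattice (default 10 bp) inside eligible
genes, `g_i(x) = 1` when site `i + x` (circular) falls in a different gene
forming a *qualifying* pair with the gene at `i`; `G(x)` is the mean over
the `n` sites. Qualifying pairs are co-occurring (MI above a cutoff,
CO-AC) or co-functioning (shared GO terms above a cutoff, GO-AC); pairs
with a phage-associated or mobile-element member are excluded, and
`operon_restricted = TRUE` additionally requires shared operon membership.

`compute_ac()` evaluates `G(x)` exactly from gene-pair geometry: each
ordered qualifying pair contributes a trapezoidal lag profile. When the
qualifying set is dense, the same quantity is obtained as the FFT
autocorrelation of the site-occupancy indicator minus same-gene lags and
the sparse complement. Both paths are verified against site-by-site
enumeration. `x_max` defaults to 1/40 of the genome, comfortably beyond
the cluster scale so that the grid mean approximates the background level.

`rescale_and_bin()` converts the curve into a distance distribution:
`(G − ⟨G⟩)/(max G − ⟨G⟩)` maps the background to 0 and the peak to 1; the
curve is averaged in geometric bins (25 per decade); leading bins below 5%
of the peak are dropped (below that level the cross-gene pair count is
dominated by discretisation noise); the curve is truncated at the first
non-positive bin after the peak; and the remaining mass is renormalised.
An earlier rule that dropped everything below the first local maximum was
abandoned: at the simulated cluster scale the rising flank of the curve
holds a large share of genuine mass (clusters span only a few gene
lengths), and cutting it right-biases the estimate — the flank-preserving
floor reproduces the known operon distance distribution to KS < 0.15,
which the local-maximum rule did not.

`compare_distributions()` computes the two-sample Kolmogorov–Smirnov
statistic between cumulative distributions on the merged support grid.
For the headline comparison the co-gained pair set is itself pushed
through the autocovariance machinery (`qualifier_from_pairs()`), so the
co-gain, SOC and operon curves share one representation; comparing a
point-mass gene-distance CDF against a site-pair CDF would otherwise carry
an irreducible kernel-width discrepancy of the order of a gene length,
which is negligible at tens of kilobases but not at the simulated scale.

## The simulator

`simulate_hgt_dataset()` generates, from one `sim_config()`:

* a rooted bifurcating tree shaped like a bacterial strain phylogeny —
  long basal branches, a rapid radiation of short internal branches, long
  tips (weights 2 : 0.1 : 1), rescaled to `tree_depth`;
* a circular ancestral genome in which cluster members are contiguous
  (truncated-exponential gaps), subdivided into operon blocks, flanked by
  guaranteed intergenic space of `0.3 × segment_cap` so that clusters are
  spatially delimited transfer units; gene lengths are lognormal around
  ~0.9 kb;
* GO terms shared cluster-wide plus extra terms shared within operon
  blocks, so the number of shared terms increases with organisational
  tightness; private terms for ordinary singletons; a viral-process term
  for phage genes; annotation withheld for an `uncertain_fraction`;
* evolution along the tree: block deletions (geometric size, cluster
  losses all-or-none, since a partially deleted co-functioning unit is
  selected against) and segmental acquisitions whose cargo is a contiguous
  donor-genome interval grown greedily across the smallest flanking gaps
  (recombination breakpoints fall in long intergenic stretches), capped at
  `segment_cap`; phage-mediated events (probability
  `phage_event_fraction`) insert a prophage block of phage genes between
  the cargo halves and extend to `phage_segment_cap`;
* a cross-species panel in which clusters are present per species with
  probability `panel_cluster_prob`, operon blocks deviate with probability
  `panel_block_flip` and genes flip with `panel_gene_flip`.

Ground truth records every event (branch, families, phage flag, segment
span), the co-transfer pair sets, cluster/operon membership and the
intra-cluster distance samples.

### Default parameters and why

The defaults are the package's reference study conditions: 16 genomes, a
2 Mb chromosome, 1500 families, 90 four-gene clusters, and 5 kb / 12 kb
segment caps (scaled-down analogs of the ~30 kb bound on stably
transferred segments and the ~70 kb phage-capsid bound). The remaining
rates were chosen once to create the regime the method is designed for —
repeated re-acquisition of the same functional units across independent
lineages:

* `gain_rate = 50` events and `loss_rate = 2.6` per-gene losses per unit
  branch length, with `tree_depth = 2.5`, give roughly 600 acquisition
  events, an accessory-genome presence frequency around 10–15%, and five
  or more independent re-acquisitions for a typical cluster;
* `cluster_transfer_weight = 100` concentrates acquisitions on cluster
  seeds, reflecting the premise that co-functioning units are the cargo
  whose transfer is selectively retained;
* cluster span (≈ 4.2 kb) sits just under `segment_cap`, mirroring the
  real system where SOC extent coincides with the transfer-size bound;
* the panel noise levels put within-operon MI above 0.8, within-cluster
  MI near 0.2 and unrelated-pair MI at the plug-in floor, so the published
  cutoff ladder (10⁻⁴ … 0.8) spans the structure.

On a 16-leaf tree there are only 30 branches, so a detectable pair must be
co-gained on four to six of them; with fewer events, deeper presence, or
partial-unit transfer the Fisher scores never separate from the
permutation-null floor (the null's most extreme score is roughly the
reciprocal of its pair-universe size). The defaults are therefore not
arbitrary: they are close to the weakest regime in which the published
inference chain can work at this problem size.

### What the simulator does not model

No nucleotide sequences (hence no homologous recombination or codon-bias
signal), no within-population dynamics, no genome rearrangements other
than insertion and deletion, no macrodomain structure, and no paralog
amplification (the distance code nevertheless handles multi-allele
families). Passing tests demonstrate that the inference chain recovers the
structure this generator plants; they cannot certify behaviour on real
data with, for example, annotation errors, assembly artefacts or
phylogenetic uncertainty.

## Problem sizes and determinism

The reference run (16 genomes, 1500 families, three null replicates,
10 bp autocovariance frame, 50 kb maximum offset) completes in well under
a minute; tests and the acceptance script use it directly. All randomness
derives from the configuration seed: each simulator stage seeds its own
sub-stream, and the shuffle null takes an explicit seed, so a rerun with
the same configuration is bit-identical.

## Known limitations

* The two-state model with a scalar per-family gain multiplier is a
  deliberate simplification of branch- and gene-specific rate mixtures;
  the high-confidence tier exists to guard the calls against model
  mismatch.
* The empirical FDR compares pair universes of different sizes by
  rescaling, which assumes the null universe is representative.
* The autocovariance estimate of the within-cluster distance distribution
  is right-biased below its peak (the low-distance flank mixes with the
  same-gene exclusion region); the bulk is approximate, the peak and right
  tail are reliable.
* At the simulated scale a gene length is a non-negligible fraction of a
  cluster, so distance-convention choices matter; all of them are explicit
  arguments.
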