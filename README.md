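# socgain

Detection of consistently co-gained gene-family pairs on a bacterial
strain phylogeny, and analysis of whether operons or larger
**supra-operonic clusters** (SOCs) of co-occurring, co-functioning genes
are the unit of horizontal gene co-transfer.

Bacteria adapt largely by horizontal gene transfer (HGT), and transferred
segments usually carry several genes. Given a rooted strain tree and a
binary gene-family presence/absence matrix, `socgain`:

* fits a two-state gain/loss Markov model (gain rate α, loss rate β per
  unit branch length; optional per-family gain-rate multipliers, the
  analog of a variable gain/loss-ratio mixture) and reconstructs marginal
  posterior presence at every ancestral node by the pruning algorithm;
* calls per-branch gains (inclusive tier: presence at P ≥ 0.5;
  high-confidence tier: P ≤ 0.2 → P ≥ 0.8) and scores every family pair by
  **t = log₁₀ of the right-tail Fisher exact p-value** of the 2×2 table of
  branch-wise gain patterns;
* assesses significance with an empirical false discovery rate against a
  permutation null (each family's presences shuffled across genomes):
  FDR(t) = N_null(t)/N_data(t);
* measures genomic distances of significant pairs on the circular
  chromosome (minimum over allele pairs and genomes), classifies families
  as phage-associated / not / uncertain, and compares close vs distant
  allele pairs by their fraction of intervening phage genes (Wilcoxon
  rank-sum);
* estimates the within-SOC distance distribution from the genomic
  **autocovariance** G(x) of co-occurring (profile mutual information
  above a cutoff) or co-functioning (shared GO terms above a cutoff) gene
  pairs, rescaled by its background level, log-binned and normalised;
* compares the co-gain, SOC and operon distance distributions by
  Kolmogorov–Smirnov distance.

A ground-truthed forward simulator (`simulate_hgt_dataset()`) generates
all inputs — tree, circular genomes with clustered organisation, segmental
and phage-mediated co-transfer with caps on segment size, GO annotation,
operon tables, and a cross-species co-occurrence panel — so the whole
chain is testable against known truth without any external data.

## Worked example

```r
library(socgain)

pl <- run_pipeline(sim_config(seed = 1))
print(pl)
#> Co-gain / SOC pipeline
#>   gain/loss rates: alpha = 0.0775, beta = 0.652
#>   30 branches, 562 gained families, 157641 pairs scored
#>   alpha_0.05: t* = -4.4378, significant pairs = 108
#>   alpha_0.005: t* = -5.1538, significant pairs = 60
#>   medians (bp): co-gain 1404 | SOC(CO) 1413 | SOC(GO) 1413 | operon 1067
#>   KS co-gain vs SOC(CO) 0.014 | vs operon 0.281
```

Reading: on the simulated 16-genome panel, 108 family pairs are co-gained
more often than the shuffle null allows at FDR 0.05 (score threshold
t\* = −4.44, i.e. a right-tail Fisher p below 10⁻⁴·⁴); the median genomic
distance of those pairs (~1.4 kb) and the shape of their whole distance
distribution match the SOC estimate from co-occurrence autocovariance
(KS = 0.014) and not the operon distribution (KS = 0.281) — the simulated
clusters, not operons, are the unit of co-transfer, which is the planted
truth. `pl$phage_stats` shows the companion phage signal: distant allele
pairs (beyond the ordinary segment cap) have on average ~44% intervening
phage-associated genes versus ~2.5% for close pairs (rank-sum
p ≈ 10⁻²⁷), the signature of transduction-borne recent acquisitions.

All tables can be written with provenance headers via
`write_pipeline_results(pl, "out/")`, and a complete simulated dataset in
plain-text formats (Newick, TSV, GFF3, JSON truth) via
`write_hgt_dataset(pl$dataset, "data/")`.

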