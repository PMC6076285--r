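# metadiv

Conservation prioritization of livestock breeds from genome-wide SNP
panels. Given multi-breed PED/MAP genotypes (or its own simulators),
`metadiv` computes the per-breed statistics used to flag endangered
populations — observed/expected heterozygosity, F<sub>IS</sub>, LD-based
effective population size N<sub>e</sub>, runs of homozygosity and
F<sub>ROH</sub> — and ranks breeds by what the world's metapopulation loses
without them.

The ranking rests on two partitions of total genomic diversity into
within- and between-breed components:

* **Molecular coancestry.** With f<sub>xy</sub> the probability that two
  randomly drawn alleles (one per individual) are identical in state, the
  average global coancestry f̄ (equal breed weights) gives
  GD<sub>T</sub> = 1 − f̄ = GD<sub>WS</sub> + GD<sub>BS</sub>, with the
  within part further split into within- and between-individual terms.
* **Rarefaction allelic richness.** With P<sub>ik</sub> =
  C(N<sub>i</sub>−N<sub>ik</sub>, g)/C(N<sub>i</sub>, g) the probability an
  allele is missed in g genes, a<sub>i</sub> = Σ<sub>k</sub>(1−P<sub>ik</sub>)
  gives A<sub>T</sub> = A<sub>S</sub> + D<sub>A</sub> with
  A<sub>S</sub> = mean(a<sub>i</sub>) − 1 and D<sub>A</sub> the mean
  pairwise rarefied allelic distance.

Removing each breed (or each region's breeds) in turn and recomputing the
partition yields contribution scores ΔGD<sub>WS</sub>, ΔGD<sub>BS</sub>,
ΔGD<sub>T</sub> (percent of the full total; positive = the unit adds
diversity), which the package averages across the two methods, bins,
ranks, relates to Reynolds-distance/neighbor-joining structure, and — for
region-level units — associates with 1993–2013 GDP-per-capita levels and
growth (economic categories, Kolmogorov–Smirnov comparisons, dual OLS
regressions).

## Worked example

```r
library(metadiv)
sim <- simulate_metapopulation(n_breeds = 4, n_per_breed = 20, n_snps = 1000,
                               F_pop = c(0.05, 0.1, 0.1, 0.3), seed = 42)
gt <- qc_filter(sim$gt)$gt
partition_diversity(gt)
#> Coancestry diversity partition (4 populations):
#>   GD_T = 0.36478 = GD_WS (0.31869) + GD_BS (0.04609)
#>   GD_WS = GD_WI (0.16170) + GD_BI (0.15699)
allelic_partition(gt)
#> Rarefaction allelic diversity (g = 40 genes, 4 populations):
#>   A_T = 0.97700 = A_S (0.93007) + D_A (0.04692)
avg <- average_methods(leave_one_out_contributions(gt),
                       leave_one_out_allelic(gt))
avg[, c("unit", "dGD_WS", "dGD_BS", "dGD_T", "dGD_T_bin", "rank")]
#>   unit     dGD_WS     dGD_BS      dGD_T dGD_T_bin rank
#> 1  B01  2.5092878 -0.5896737  1.9196141      >0.1    1
#> 2  B03  1.1748738  0.3748363  1.5497101      >0.1    2
#> 3  B02  0.8922945  0.1424831  1.0347777      >0.1    3
#> 4  B04 -4.5764561  3.9474222 -0.6290339     <-0.1    4
```

Most of the metapopulation's diversity sits within breeds
(GD<sub>WS</sub> = 0.319 of GD<sub>T</sub> = 0.365). Breed B04 was
simulated with the strongest drift (F = 0.3): it is the most distinct —
removing it costs the most between-breed diversity (ΔGD<sub>BS</sub> =
+3.95% of GD<sub>T</sub>) — but it is also the least diverse internally
(ΔGD<sub>WS</sub> = −4.58%), so its net contribution to total diversity is
negative and it ranks last; B01 (weakest drift, most internal variation)
ranks first. The same trade-off drives real prioritization decisions
between distinct-but-inbred and diverse-but-ordinary breeds.

The full pipeline — QC, breed statistics, ROH, N<sub>e</sub>, both
partitions at breed and region level, method averaging with paired
t-tests, NJ tree, priority report, economics — runs from one config:

```r
res <- run_pipeline(list(species = "sheep", seed = 42,
                         out_dir = "run1"))   # TSV/newick/JSON artifacts
res$priority
```

A YAML config plus `inst/scripts/run_pipeline.R` provides the same from a
shell.

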