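# clonalscape

Clonal and spatial population genetics for partially clonal plants sampled
along rivers.

Many aquatic plants mix clonal (vegetative) and sexual reproduction, and the
balance between the two shapes how genetic diversity is distributed along a
river — especially where the river spans contrasting hydrologic regimes
(free-flowing nontidal reaches versus bidirectional tidal ones).
`clonalscape` implements the full analysis chain such a survey needs, from
raw codominant microsatellite calls to regime-level inference:

- **Clone discrimination.** Samples are grouped into multilocus genotypes
  (MLGs) by complete multilocus match; samples with missing data are merged
  only when they are compatible with exactly one MLG (otherwise excluded as
  ambiguous). MLGs differing by a single allele at a single locus are
  collapsed into multilocus lineages (MLLs) when the rarer MLG is a
  singleton. For every repeated MLL, `psex` — the probability of observing
  that many copies of the genotype through independent sexual events — is
  the binomial tail `P(X >= i-1)`, `X ~ Bin(N-1, pgen)`, with
  `pgen = prod_l P_HWE(genotype_l)`.
- **Genotypic diversity.** Richness `R = (G-1)/(N-1)`; Shannon and Simpson
  effective numbers of MLLs (`exp(H)`, `1/sum p^2`) and their richness
  analogues; Pareto beta (negative slope of the log–log reverse cumulative
  clone-size distribution); rarefaction to a common sample size; clone
  spatial extents through water.
- **Relatedness.** Wang's (2002) moment estimator of pairwise relatedness
  from locus-wise genotype-similarity categories, with small-sample
  corrected allele-frequency moments and inverse-variance locus weights;
  within-site (`r_W`) and among-site (`r_A`) summaries; group permutation
  tests that shuffle samples between groups holding sizes fixed.
- **Genetic diversity and differentiation.** Polymorphism, alleles per
  locus, hypergeometric rarefied allelic richness, Nei's unbiased `H_s`,
  `F_IS` with locus-bootstrap CIs, and clone-correction deltas;
  Weir–Cockerham theta, Hedrick's `G''_ST` and Jost's `D_est` with
  bootstrap CIs and pairwise matrices.
- **Riverscape distances and structure.** Least-cost distances through a
  water-conductance raster (8-neighbour Dijkstra, diagonal steps
  `cellsize * sqrt(2)`), the larger-of-Euclidean-and-cost rule, Edwards'
  chord distance, Mantel isolation-by-distance tests, correspondence
  analysis of the site-by-allele table, and Spearman correlations of site
  statistics with river km.
- **Regime contrasts.** Two-group permutation tests (absolute difference of
  regime means, 10,000 permutations) over the whole site-statistic battery.
- **Synthetic data.** A generator that emulates the survey design — two
  regimes with contrasting clonality, widespread heterozygous dominant
  clones, drift-induced isolation by distance, a meandering water corridor —
  so every stage is testable without field data.

## Worked example

```r
library(clonalscape)

cfg <- sim_config("survey")          # 24 nontidal + 12 tidal sites
rs  <- simulate_riverscape(cfg, seed = 1)
sim <- simulate_genotypes(cfg, rs$sites, seed = 2)

report <- run_full_analysis(sim$gt, rs$sites, rs$grid, seed = 3)
print(report)
#> stats_report: 936 samples, 36 sites, 10 loci
#>   MLGs: 454  MLLs: 407  ambiguous: 2
#>   theta = 0.1942  G''ST = 0.3532  D_est = 0.1763

subset(report$regime_tests, statistic == "R",
       c(statistic, mean_1, mean_2, p, exceeds_all_permutations))
#>   statistic    mean_1 mean_2 p exceeds_all_permutations
#> R         R 0.2804167   0.93 0                     TRUE

report$mantel$all[c("r", "p")]
#> $r
#> [1] 0.7292722
#> $p
#> [1] 0.001

write_reports(report, "run1")   # CSV tables + JSON run summary
```

Reading the output: genotypic richness `R` averages 0.28 in nontidal sites
versus 0.93 in tidal ones, a difference larger than all 10,000 permutations
(`p = 0`, exceeds-all flag) — the clonality contrast between regimes. The
positive river-wide Mantel correlation (`r = 0.73`, `p = 0.001`) is
isolation by distance over water-constrained distances. Heavily clonal sites
show negative `F_IS` (heterozygote excess carried by dominant clones), and
clone correction generally lowers `H_s` there
(`report$locus_site$delta_H_s`).

Real data enter through `read_genotype_table()` (CSV: `sample_id, site_id,
<locus>_1, <locus>_2, ...`; `0`/empty = missing), `read_site_meta()` (site
coordinates, river km, regime, year) and `read_water_grid()` (ESRI ASCII
conductance raster, 1 = water, 0 = land).

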