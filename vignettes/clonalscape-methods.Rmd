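---
title: "Methods and design notes for clonalscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for clonalscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonalscape` analyses codominant microsatellite surveys of partially clonal
plants sampled along a river that spans contrasting hydrologic regimes. This
vignette records the statistical models implemented, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where several
defensible options existed.

## Clone discrimination

Samples are assigned to multilocus genotypes (MLGs) by complete multilocus
match over their resolved loci. Missing data are handled conservatively:

* a sample missing every locus is excluded;
* a sample with partial data is merged into an existing MLG only when its
  resolved loci are compatible with exactly **one** MLG; compatibility with
  several MLGs leaves it unassigned and excluded downstream (reported in the
  assignment object), and compatibility with none founds a new MLG.

Partial samples are processed in order of increasing missingness, then
sample id, which makes the procedure deterministic. Two caveats are
inherent to any complete-match procedure and worth stating plainly: distinct
genets that happen to draw the same multilocus genotype are one MLG by
definition and cannot be separated; and a partial sample whose true genotype
differs from an MLG only at its masked loci will be merged silently when it
is compatible with that single MLG. Both events become more likely as local
allele frequencies become skewed; with ten loci of realistic polymorphism
they affect on the order of 1–2% of genets and well under 1% of samples.

MLGs are collapsed into multilocus lineages (MLLs) — groups attributable to
scoring error or somatic mutation — when a pair differs by at most one
allele at one locus (`mll_distance_threshold = 1`, configurable) *and* the
rarer MLG holds exactly one sample. The rule is iterated to a fixed point,
so chains of singletons collapse into the abundant core; the MLL
representative is the most abundant member MLG (ties broken
lexicographically). Allele distance between MLGs is the per-locus diploid
multiset difference (0, 1 or 2), summed over loci resolved in both.

For repeated MLLs, `pgen` is the Hardy–Weinberg probability of the genotype
(`p^2` homozygous, `2pq` heterozygous, product over resolved loci) and
`psex_i = P(X >= i - 1)` with `X ~ Binomial(N - 1, pgen)` is the probability
that the i-th encounter still reflects an independent sexual event. An MLL
is called clonal when the final encounter's psex falls below 0.001
(configurable). Allele frequencies for `pgen` are clone-corrected — one
representative per MLL, pooled river-wide — because frequencies estimated
from all ramets would be inflated by the very clones being tested. No
F_IS-adjusted pgen variant is applied; that refinement changes psex by far
less than the orders of magnitude that separate observed values from the
0.001 threshold.

## Genotypic diversity

Richness is `R = (G - 1)/(N - 1)`, zero for a monoclonal stand and one when
every shoot is distinct. The same transform applied to the effective numbers
of MLLs — `exp(H)` for Shannon, `1/sum(p_i^2)` for Simpson — gives
`R_Shannon` and `R_Simpson`, which decline from `R` as clone-size
distributions become uneven (Hill-number ordering). Simpson's index is used
as `lambda = sum(p_i^2)` with effective number `1/lambda`; the Gini–Simpson
complement `1 - lambda` has no effective-number reciprocal and is not used.
No small-sample correction is applied to `lambda` by default.

Pareto beta is the negative OLS slope of `log N(size >= x)` on `log x` over
the observed clone sizes. It is undefined — flagged, not imputed — when all
clones share one size class (all singletons, or a single clone).

Rarefaction draws `n_raref = 5` shoots (the smallest site sample size of
the emulated design) without replacement, `rarefaction_reps = 1000` times,
and averages each statistic. The subsample size is deliberately the minimum
observed so every site is comparable.

## Wang's relatedness estimator

Pairwise relatedness uses the moment estimator built from the proportions of
locus-wise genotype-similarity categories (identical; one homozygote sharing
an allele with a heterozygote; two heterozygotes sharing one allele; no
sharing). Writing `a_m` for the m-th moments of the reference allele
frequencies and `b..g` for the standard composite coefficients, the category
expectations are linear in the two-gene (`phi`) and four-gene (`Delta`)
identity coefficients, and `r = phi/2 + Delta`. The implementation:

* corrects `a_2, a_3, a_4` for the finite reference sample (unbiased
  multinomial moment estimators at `n` sampled gene copies);
* weights loci by `1/u`, `u = 2 a_2 - a_3`, renormalized per pair over the
  loci resolved in both samples;
* solves the three moment equations exactly: the `phi` estimator is the
  standard closed form, and the `Delta` estimator is the unique linear
  combination of the category proportions that (i) keeps the standard
  coefficient on the first category and (ii) returns `(phi, Delta)` exactly
  whenever the observed proportions sit at their expectations. That
  consistency was verified symbolically during development.

The reference frequency set defaults to the full analysed sample set (the
convention of the widely used implementations); a clone-corrected reference
can be supplied. Pairs sharing fewer than five resolved loci are flagged
low-confidence. Estimates are not clipped to [-1, 1]: truncation would bias
group means, and the permutation machinery is scale-free.

Validation is by pedigree simulation: Mendelian pairs at ten loci with eight
equifrequent alleles recover mean r of 0 (unrelated), 0.25 (half sib), 0.5
(full sib and parent–offspring) and 1.0 (clones) within ±0.05 at 500 pairs
per class, and a scalar straight-from-the-equations implementation agrees
with the vectorized one to 1e-10.

## Locus diversity and clone correction

`H_s` is Nei's unbiased within-population gene diversity
`n/(n-1) (1 - sum p^2 - H_o/(2n))`; `F_IS = 1 - H_o/H_s` with the negative
sign marking heterozygote excess — the signature of clonal amplification of
heterozygous genets. The across-locus mean F_IS follows the ratio-of-means
convention (`1 - mean(H_o)/mean(H_s)`), with per-locus values and their
across-locus variance also reported; monomorphic loci (H_s = 0) are excluded
from the mean. Bootstrap CIs resample **loci** with replacement (1000
replicates, percentile 2.5/97.5) and recompute the ratio-of-means.

Rarefied allelic richness uses the exact hypergeometric expectation
`sum_a [1 - C(N_l - N_a, g)/C(N_l, g)]` at `g = 15` gene copies. The
rarefaction unit is gene copies, not individuals; `g` is configurable, and
the default corresponds to the conventional `2 x` smallest sample size
adjusted for missingness in surveys of this shape.

Clone correction retains one sample per MLL per site — the member with the
fewest missing loci, ties broken by sample id — and the per-site table
reports `delta = stat(all) - stat(clone corrected)` for H_o, H_s and F_IS.
In heavily clonal sites dominated by heterozygous clones, the all-sample
H_s typically exceeds the clone-corrected value (the dominant heterozygote
pulls its two alleles toward equal frequency); this direction is typical
but not universal in synthetic data — see Limitations.

## Differentiation

Weir–Cockerham theta sums per-allele, per-locus variance components
(`a` among populations, `b` among individuals within, `c` within
individuals): `theta = sum a / sum(a + b + c)`. Loci monomorphic over the
whole sample contribute nothing; negative estimates are reported as-is,
since truncation at zero would wreck CI honesty.

`H_S` and `H_T` follow Nei–Chesser's unbiased forms with harmonic-mean
sample size; `G''_ST = k (H_T - H_S) / ((k H_T - H_S)(1 - H_S))` and
`D_est = (k/(k-1)) (H_T - H_S)/(1 - H_S)`. Multi-locus combination: theta by
summed components; `G''_ST` from across-locus means of H_S and H_T; `D_est`
by the harmonic mean of per-locus values (the convention of the standard
implementation), falling back to the arithmetic mean with a warning when a
per-locus D is non-positive (harmonic means are undefined there), with the
arithmetic alternative also selectable. Pairwise matrices re-estimate
components per population pair rather than slicing the global fit.

Bootstrap CIs: theta over loci (resampling per-locus variance-component
triples), `G''_ST`/`D_est` over individuals within populations. A known
property worth stating: percentile bootstrap intervals over as few as ten
loci undercover — about 89% observed coverage at nominal 95% under a
single-gene-pool null — so locus-bootstrap CIs at typical microsatellite
panel sizes should be read as approximate.

## Riverscape distances

The water mask is a binary conductance raster (ESRI ASCII). Cost distance is
the Dijkstra shortest path on the 8-neighbour graph of water cells,
orthogonal steps costing one cell size and diagonal steps `sqrt(2)` times
that; land is impassable and unreachable pairs are infinite. Distances are
measured between cell centers after snapping points to their containing
cell (off-water points snap to the Euclidean-nearest water cell, ties broken
in row-major order — the same rule used for land-bound site centroids).
Because rasterization underestimates short direct paths while Euclidean
distance underestimates paths around shorelines, pairwise analyses use the
entrywise **maximum** of the two matrices.

## Spatial structure

Edwards' chord distance uses the angular form
`sqrt(1 - mean_l sum_a sqrt(p_A p_B))`; several formulas share the "chord"
name, so the choice is recorded here — this is the one used by the standard
allele-frequency ordination tools. The Mantel test correlates off-diagonal
pairs and permutes one matrix's rows and columns jointly; it is one-sided
for positive association, the orientation in which isolation by distance is
posed. Correspondence analysis runs on the site-by-allele **count** table
(rows mass-weighted), via SVD of the standardized residual matrix, with site
scores in principal coordinates and axis inertias summing to chi-square over
the grand total. Spearman correlations with river km use midranks and the
t-approximation.

## Regime contrasts

Site-level statistics are compared between regimes by permuting values
across sites 10,000 times with group sizes fixed; the statistic is the
absolute difference of regime means and the p-value is the proportion of
permuted differences **strictly larger** than observed. Under that rule the
smallest attainable Monte-Carlo p is 0; the `exceeds_all_permutations` flag
marks that case explicitly. A degenerate input with zero observed
difference returns p = 1 with the flag off — ties cannot be evidence. No
multiple-testing correction is applied across the battery; the output is a
table of per-statistic tests and should be read as such.

## The synthetic-data generator

`sim_config("survey")` encodes the emulated survey: 36 sites (24
nontidal upstream, 12 tidal downstream) spanning river km 462 to 89, ten
loci with 5–13 alleles, about 26 shoots per site, clonality probability 0.75
in nontidal sites versus 0.05 in tidal ones, and two widespread nontidal
clones spanning ~15 sites. Site allele frequencies follow a logistic-normal
random walk along river order (`drift_sd = 0.18` per step), which produces
isolation by distance without coalescent machinery. Within a site each
shoot is, with the regime's clonality probability, a ramet of an existing
local genet chosen proportionally to its current ramet count
(rich-get-richer, yielding Pareto-like clone-size spectra); otherwise a new
genet drawn by Hardy–Weinberg from the site frequencies.

Two regime-dependent features emulate the within-site structure of real
long-clonal river reaches: nontidal site frequencies are concentrated
(exponent 4 versus 2 tidal, applied on the log scale), giving the observed
allele-poor nontidal pools (about 2.6 versus 4.3 alleles per locus within
sites), and dominant genets — the widespread clones and each nontidal
site's first founder — are heterozygous-biased (two distinct alleles drawn
without replacement per polymorphic locus), reflecting the fixed
heterozygosity of persistent clones. Together these reproduce the
characteristic pattern of clonal reaches: high observed heterozygosity with
modest gene diversity, strongly negative F_IS, and lower allelic richness
upstream.

What the generator does **not** emulate: real dispersal mechanics (pollen,
seed, turion), temporal genet turnover, null alleles and genotyping error
beyond symmetric missingness, uneven within-site sampling geometry, and
fine-scale spatial autocorrelation within sites. Passing tests therefore
demonstrate that the estimators and the pipeline behave correctly under a
realistic, structured null — not that any particular field dataset will
show the same effect sizes.

## Problem sizes used in the test suite

Module tests run on 4-site `tiny` fixtures (8 shoots per site). The
acceptance-style checks use: 20 survey-scale replicates for clone-discrimination
recovery; 500 pairs per pedigree class for relatedness; 200 null replicates
(two populations of 200, ten loci) for differentiation calibration; 50
random 30x30 rasters against an explicit-graph Dijkstra; 200 replicates for
permutation-uniformity checks; and one full survey-scale run (936 shoots) for
the end-to-end regime contrast. These sizes were chosen to keep Monte-Carlo
error well below each assertion's tolerance.

## Known limitations

* Percentile bootstrap CIs over few loci undercover (see Differentiation);
  coverage-sensitive conclusions should use more loci or interval methods
  beyond the percentile rule.
* The clone-correction inequality (all-sample H_s above clone-corrected) is
  a strong empirical regularity of heavily clonal sites but not a theorem:
  synthetic sites whose surviving founders happen to span a diverse local
  pool can reverse it, and roughly one heavily clonal site in six does so
  under the default generator conditions.
* Complete-match clone discrimination cannot separate coincidentally
  identical genets nor detect a wrong unique-match merge masked by missing
  data; both are properties of the method, not the implementation.
* The MLL collapse is deterministic but its order-independence is exact only
  up to ties in the merge-target choice; ties are broken by abundance then
  lexicographic id.
* Cost distances are grid distances: they overestimate straight paths by up
  to the usual 8-neighbour metric distortion (~8%) and depend on cell size;
  the max-of-Euclidean rule removes the short-range underestimate but not
  the metric distortion.
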