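# Allelic statistics, rarefied richness, heterozygosity/F_IS, bootstrap CI,
# clone correction.

test_that("P and A count observed alleles with missing calls excluded", {
  gt <- make_gt(list(c(1L, 1L, 5L, 6L, 9L, 9L),
                     c(1L, 1L, 5L, 5L, NA, NA),
                     c(1L, 1L, 6L, 6L, 9L, 9L)),
                loci = c("A", "B", "C"))
  st <- allele_stats(gt)
  expect_equal(st$P, mean(c(FALSE, TRUE, FALSE)))  # only B polymorphic
  expect_equal(st$A, mean(c(1, 2, 1)))
  # brute-force set cardinality oracle on random tables
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(sample(c(1:4, NA), 36, TRUE, prob = c(rep(.22, 4), .12)),
                6, 6)
    suppressWarnings(gt <- genotype_table(m, paste0("s", 1:6), rep("x", 6),
                                          c("A", "B", "C")))
    st <- allele_stats(gt)
    per_locus <- vapply(1:3, function(l) {
      v <- c(gt$calls[, 2 * l - 1], gt$calls[, 2 * l])
      length(unique(v[!is.na(v)]))
    }, numeric(1))
    scored <- per_locus > 0
    expect_equal(st$A, mean(per_locus[scored]))
    expect_equal(st$P, mean(per_locus[scored] >= 2))
  }
})

test_that("hypergeometric rarefaction equals exhaustive enumeration", {
  # counts (10, 5, 1), g = 2: expectation over all C(16,2) subsamples
  ct <- c(10, 5, 1)
  subs <- utils::combn(16, 2)
  pool <- rep(1:3, ct)
  exact <- mean(apply(subs, 2, function(ss) length(unique(pool[ss]))))
  expect_equal(rarefied_richness(ct, g = 2), exact, tolerance = 1e-12)
  expect_equal(rarefied_richness(ct, g = 2), 0.875 + 6.5 / 12 + 0.125,
               tolerance = 1e-3)
  # endpoints
  expect_equal(rarefied_richness(c(3, 4, 5), g = 1), 1)
  expect_equal(rarefied_richness(c(3, 4, 5), g = 12), 3)
  expect_error(rarefied_richness(c(3, 4), g = 0), "g must")
  # A_r non-decreasing in g and bounded by A
  ct <- c(7, 4, 3, 2)
  ar <- vapply(1:16, function(g) rarefied_richness(ct, g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_true(all(ar <= 4 + 1e-12))
})

test_that("heterozygosity and F_IS carry the right signs and formulas", {
  # all heterozygotes A/B -> H_o = 1, F_IS < 0
  gt <- make_gt(rep(list(c(1L, 2L)), 10), loci = "A")
  het <- heterozygosity_stats(gt)
  expect_equal(het$H_o, 1)
  expect_lt(het$F_IS, 0)
  # all homozygotes at a 50/50 biallelic locus -> F_IS > 0
  gt <- make_gt(c(rep(list(c(1L, 1L)), 5), rep(list(c(2L, 2L)), 5)),
                loci = "A")
  het <- heterozygosity_stats(gt)
  expect_equal(het$H_o, 0)
  expect_gt(het$F_IS, 0)
  # worked 6-sample locus against the unbiased formula computed directly
  gt <- make_gt(list(c(1L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 3L), c(1L, 3L),
                     c(2L, 2L)), loci = "A")
  het <- heterozygosity_stats(gt)
  n <- 6
  p <- c(4, 4, 4) / 12   # alleles 1, 2, 3 each appear four times
  ho <- 3 / 6
  hs <- n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
  expect_equal(het$per_locus$H_s[1], hs, tolerance = 1e-12)
  expect_equal(het$F_IS, 1 - ho / hs, tolerance = 1e-12)
})

test_that("monomorphic loci drop out of the F_IS mean", {
  gt <- make_gt(list(c(1L, 1L, 5L, 6L), c(1L, 1L, 5L, 5L),
                     c(1L, 1L, 6L, 6L)), loci = c("A", "B"))
  het <- heterozygosity_stats(gt)
  expect_true(is.na(het$per_locus$F_IS[1]))
  expect_false(is.na(het$F_IS))
})

test_that("F_IS bootstrap CI is seed-reproducible and covers the estimate", {
  set.seed(101)
  cfg <- sim_config("tiny")
  rs <- simulate_riverscape(cfg, seed = 102)
  covered <- 0
  for (rep in 1:20) {
    sim <- simulate_genotypes(cfg, rs$sites, seed = 1020 + rep)
    het <- heterozygosity_stats(sim$gt)
    ci <- fis_bootstrap_ci(het, n_boot = 300)
    if (het$F_IS >= ci$lower && het$F_IS <= ci$upper) covered <- covered + 1
  }
  expect_gte(covered, 19)   # point estimate inside its CI in >= 95% of runs
  # identical per-locus values give a zero-width interval
  het0 <- list(per_locus = data.frame(locus = c("A", "B", "C"), n = 10,
                                      H_o = 0.4, H_s = 0.5, F_IS = 0.2))
  ci <- fis_bootstrap_ci(het0, n_boot = 200)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, 1 - 0.4 / 0.5)
  # fixed seed reproducibility
  set.seed(7); c1 <- fis_bootstrap_ci(het, n_boot = 150)
  set.seed(7); c2 <- fis_bootstrap_ci(het, n_boot = 150)
  expect_identical(c1, c2)
  expect_warning(fis_bootstrap_ci(het, n_boot = 50), "100")
})

test_that("clone correction keeps one representative per MLL per site", {
  # monoclonal site of 20 -> one sample kept
  rows <- rep(list(c(1L, 2L, 5L, 6L)), 20)
  gt <- make_gt(rows, loci = c("A", "B"))
  a <- collapse_to_mlls(assign_mlgs(gt))
  cc <- clone_correct(gt, a)
  expect_equal(n_samples(cc), 1L)
  # all-unique site -> unchanged
  set.seed(33)
  rows <- lapply(1:8, function(i) c(2L * i, 2L * i, 100L + i, 100L + i))
  gt <- make_gt(rows, loci = c("A", "B"))
  a <- collapse_to_mlls(assign_mlgs(gt))
  cc <- clone_correct(gt, a)
  expect_equal(n_samples(cc), 8L)
  expect_identical(cc$calls, gt$calls)
  # representative = fewest missing loci, then lexicographic id
  calls <- rbind(c(1L, 2L, NA, NA), c(1L, 2L, 5L, 6L), c(1L, 2L, 5L, 6L))
  suppressWarnings(gt <- genotype_table(calls, c("s1", "s2", "s3"),
                                        rep("x", 3), c("A", "B")))
  a <- collapse_to_mlls(assign_mlgs(gt))
  if (length(a$mll_members) == 1L) {
    cc <- clone_correct(gt, a)
    expect_equal(cc$sample_id, "s2")
  }
})

test_that("per-site table reports clone-correction deltas", {
  cfg <- sim_config("tiny", c_nontidal = 0.8)
  rs <- simulate_riverscape(cfg, seed = 111)
  sim <- simulate_genotypes(cfg, rs$sites, seed = 112)
  a <- collapse_to_mlls(assign_mlgs(sim$gt))
  tab <- suppressWarnings(locus_diversity_table(sim$gt, a, n_boot = 120))
  expect_equal(nrow(tab), 4L)
  ok <- !is.na(tab$delta_H_s)
  expect_equal(tab$delta_H_s[ok], tab$H_s[ok] - tab$H_s_cc[ok])
  expect_true(all(tab$H_o >= 0 & tab$H_o <= 1, na.rm = TRUE))
  expect_true(all(tab$F_IS >= -1 & tab$F_IS <= 1, na.rm = TRUE))
})
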