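# Clone discrimination: MLG matching, missing-data handling, MLL collapse,
# pgen/psex, accumulation curves.

two_locus <- function(...) make_gt(list(...), loci = c("A", "B"))

test_that("complete-match grouping splits and lumps correctly", {
  gt <- make_gt(list(c(148L, 150L, 200L, 202L, 300L, 300L),
                     c(150L, 148L, 202L, 200L, 300L, 300L),
                     c(148L, 150L, 200L, 204L, 300L, 300L)),
                loci = c("A", "B", "C"))
  a <- assign_mlgs(gt)
  expect_equal(unname(a$mlg[1]), unname(a$mlg[2]))
  expect_false(a$mlg[1] == a$mlg[3])
  expect_equal(nrow(a$mlg_profile), 2L)
})

test_that("missing-data samples merge, found, or are excluded as ambiguous", {
  base <- list(c(148L, 150L, 200L, 202L),   # MLG1
               c(148L, 150L, 204L, 204L),   # MLG2
               c(160L, 160L, 210L, 212L))   # MLG3
  # resolved locus A matches only MLG3 -> merged
  gt <- two_locus(base[[1]], base[[2]], base[[3]],
                  c(160L, 160L, NA, NA))
  a <- assign_mlgs(gt)
  expect_equal(unname(a$mlg[4]), unname(a$mlg[3]))
  expect_true(a$flag_missing[a$mlg[4]])
  # resolved locus A matches MLG1 and MLG2 -> ambiguous, excluded
  gt <- two_locus(base[[1]], base[[2]], base[[3]],
                  c(148L, 150L, NA, NA))
  a <- assign_mlgs(gt)
  expect_equal(a$ambiguous, "ind4")
  expect_true(is.na(a$mlg[4]))
  # matches none -> founds a new MLG
  gt <- two_locus(base[[1]], base[[2]], base[[3]],
                  c(170L, 172L, NA, NA))
  a <- assign_mlgs(gt)
  expect_equal(nrow(a$mlg_profile), 4L)
  # brute-force check of the compatible-MLG count logic on random data
  set.seed(19)
  for (rep in 1:20) {
    profs <- lapply(1:4, function(i) sort(sample(100:106, 2)))
    rows <- lapply(profs, function(p) c(p, sort(sample(200:206, 2))))
    probe <- c(rows[[sample(4, 1)]][1:2], NA, NA)
    gt <- two_locus(rows[[1]], rows[[2]], rows[[3]], rows[[4]], probe)
    a <- assign_mlgs(gt)
    n_match <- sum(vapply(seq_len(4), function(i)
      all(gt$calls[i, 1:2] == probe[1:2]), logical(1)))
    # count distinct matching MLGs (identical rows collapse first)
    complete_mlgs <- a$mlg[1:4]
    match_mlgs <- unique(complete_mlgs[vapply(seq_len(4), function(i)
      all(gt$calls[i, 1:2] == probe[1:2]), logical(1))])
    if (length(match_mlgs) == 1L) {
      expect_equal(unname(a$mlg[5]), unname(match_mlgs))
    } else if (length(match_mlgs) > 1L) {
      expect_true(is.na(a$mlg[5]))
      expect_equal(a$ambiguous, "ind5")
    } else {
      expect_false(a$mlg[5] %in% complete_mlgs)
    }
  }
})

test_that("samples missing every locus are excluded with a warning", {
  gt <- two_locus(c(148L, 150L, 200L, 202L), c(NA, NA, NA, NA))
  expect_warning(a <- assign_mlgs(gt), "all loci")
  expect_true(is.na(a$mlg[2]))
})

test_that("mlg_distance counts allele differences as multiset difference", {
  p1 <- c(148L, 150L, 200L, 202L)
  expect_equal(mlg_distance(p1, p1), 0L)
  expect_equal(mlg_distance(p1, c(148L, 152L, 200L, 202L)), 1L)
  expect_equal(mlg_distance(p1, c(152L, 154L, 200L, 202L)), 2L)
  # missing loci are skipped
  expect_equal(mlg_distance(p1, c(148L, 150L, NA, NA)), 0L)
  expect_error(mlg_distance(c(NA, NA), c(1L, 2L)), "comparable")
  # random profiles against an independent multiset oracle
  set.seed(7)
  for (rep in 1:50) {
    a <- unlist(lapply(1:3, function(l) sort(sample(1:4, 2, TRUE))))
    b <- unlist(lapply(1:3, function(l) sort(sample(1:4, 2, TRUE))))
    oracle <- sum(vapply(1:3, function(l) {
      x <- a[c(2 * l - 1, 2 * l)]; y <- b[c(2 * l - 1, 2 * l)]
      ta <- table(factor(x, 1:4)); tb <- table(factor(y, 1:4))
      as.integer(2 - sum(pmin(ta, tb)))
    }, integer(1)))
    expect_equal(mlg_distance(a, b), oracle)
  }
})

test_that("MLL collapse follows the rarer-is-singleton rule to a fixed point", {
  # MLG A (n=5) and MLG B (n=1) at distance 1 -> one MLL of 6
  rows <- c(rep(list(c(148L, 150L, 200L, 202L)), 5),
            list(c(148L, 152L, 200L, 202L)))
  a <- collapse_to_mlls(assign_mlgs(do.call(two_locus, rows)))
  expect_equal(length(a$mll_members), 1L)
  expect_equal(length(a$mll_members[[1]]), 6L)

  # both MLGs n = 2 at distance 1 -> NOT merged
  rows <- c(rep(list(c(148L, 150L, 200L, 202L)), 2),
            rep(list(c(148L, 152L, 200L, 202L)), 2))
  a <- collapse_to_mlls(assign_mlgs(do.call(two_locus, rows)))
  expect_equal(length(a$mll_members), 2L)

  # chain A(3)-B(1)-C(1) at successive distance 1 -> one MLL of 5
  rows <- c(rep(list(c(148L, 148L, 200L, 200L)), 3),
            list(c(148L, 150L, 200L, 200L)),
            list(c(150L, 150L, 200L, 200L)))
  a <- collapse_to_mlls(assign_mlgs(do.call(two_locus, rows)))
  expect_equal(length(a$mll_members), 1L)
  expect_equal(length(a$mll_members[[1]]), 5L)
})

test_that("MLL collapse is invariant to sample order", {
  set.seed(11)
  cfg <- sim_config("tiny", c_nontidal = 0.6, missing_rate = 0)
  rs <- simulate_riverscape(cfg, seed = 31)
  sim <- simulate_genotypes(cfg, rs$sites, seed = 32)
  gt <- sim$gt
  a1 <- collapse_to_mlls(assign_mlgs(gt))
  part1 <- vapply(gt$sample_id, function(s)
    names(which(vapply(a1$mll_members, function(m) s %in% m, logical(1)))),
    character(1))
  for (rep in 1:3) {
    p <- sample(n_samples(gt))
    gtp <- genotype_table(gt$calls[p, ], gt$sample_id[p], gt$site_id[p],
                          gt$loci)
    a2 <- collapse_to_mlls(assign_mlgs(gtp))
    part2 <- vapply(gt$sample_id, function(s)
      names(which(vapply(a2$mll_members, function(m) s %in% m, logical(1)))),
      character(1))
    expect_equal(rand_index(part1, part2), 1.0)
  }
})

test_that("pgen multiplies HWE genotype probabilities over resolved loci", {
  freqs <- list(A = c("148" = 1), B = c("200" = 0.5, "202" = 0.5))
  expect_equal(pgen(c(148L, 148L, NA, NA), freqs), 1)
  expect_equal(pgen(c(148L, 148L, 200L, 202L), freqs), 0.5)
  # product over loci equals exp of summed logs (independent arithmetic)
  freqs <- list(A = c("1" = 0.2, "2" = 0.8), B = c("5" = 0.3, "6" = 0.7))
  p <- pgen(c(1L, 2L, 5L, 5L), freqs)
  expect_equal(p, exp(log(2 * 0.2 * 0.8) + log(0.3^2)), tolerance = 1e-12)
  expect_error(pgen(c(3L, 3L, 5L, 5L), freqs), "absent")
})

test_that("psex is the binomial tail of repeat encounters", {
  expect_equal(psex(1, 4, 10)$psex, rep(1, 3))
  expect_equal(psex(0.1, 2, 10)$psex, 1 - 0.9^9, tolerance = 1e-12)
  # enumeration oracle: P(X >= i-1), X ~ Binom(N-1, p)
  N <- 8; p <- 0.3
  x <- 0:(N - 1)
  pmf <- choose(N - 1, x) * p^x * (1 - p)^(N - 1 - x)
  for (i in 2:5)
    expect_equal(psex(p, i, N)$psex[i - 1], sum(pmf[x >= i - 1]),
                 tolerance = 1e-12)
  expect_true(psex(1e-9, 2, 1000)$clonal)
  expect_false(psex(0.9, 2, 10)$clonal)
  expect_error(psex(0, 2, 10), "pgen")
})

test_that("genotype accumulation matches exhaustive subset enumeration", {
  set.seed(5)
  rows <- lapply(1:12, function(i)
    unlist(lapply(1:4, function(l) sort(sample(1:3, 2, TRUE)))))
  gt <- make_gt(rows, loci = paste0("L", 1:4))
  a <- assign_mlgs(gt)
  curve <- genotype_accumulation(a, n_reps = 2000L)
  # exhaustive means over all m-subsets of loci
  prof <- a$mlg_profile[a$mlg, ]
  key <- function(cols) apply(prof[, cols, drop = FALSE], 1, paste,
                              collapse = "/")
  for (m in 1:4) {
    subsets <- utils::combn(4, m)
    exact <- mean(apply(subsets, 2, function(ss)
      length(unique(key(as.vector(rbind(2 * ss - 1, 2 * ss)))))))
    tol <- if (m == 4) 1e-12 else 0.15
    expect_equal(curve$mean[m], exact, tolerance = tol)
  }
  # monotone non-decreasing means; endpoint equals the MLG count
  expect_true(all(diff(curve$mean) >= -1e-9))
  expect_equal(curve$mean[4], nrow(a$mlg_profile))
})

test_that("fully discriminating loci give a flat accumulation curve", {
  rows <- lapply(1:6, function(i)
    c(100L + 2L * i, 100L + 2L * i, 200L + 2L * i, 200L + 2L * i))
  gt <- make_gt(rows, loci = c("A", "B"))
  a <- assign_mlgs(gt)
  curve <- genotype_accumulation(a, n_reps = 50L)
  expect_equal(curve$mean, c(6, 6))
})
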