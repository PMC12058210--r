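# Weir-Cockerham theta, Nei-Chesser components, Hedrick G''ST, Jost D,
# bootstrap CIs.

# k populations of n HWE individuals at L loci from given frequency lists
sim_pops <- function(freq_by_pop, n, L_names = NULL) {
  rows <- list(); pops <- character(0)
  for (p in seq_along(freq_by_pop)) {
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- unlist(lapply(freq_by_pop[[p]],
        function(f) sort(sample(as.integer(names(f)), 2, TRUE, prob = f))))
      pops <- c(pops, paste0("pop", p))
    }
  }
  m <- do.call(rbind, rows)
  L <- ncol(m) / 2
  if (is.null(L_names)) L_names <- paste0("L", seq_len(L))
  genotype_table(m, paste0("i", seq_along(pops)), pops, L_names)
}

fixed_pops <- function(n = 20) {
  # two populations fixed for alternative alleles at every locus
  rows <- c(rep(list(c(1L, 1L, 10L, 10L)), n), rep(list(c(2L, 2L, 12L, 12L)), n))
  gt <- make_gt(rows, site = rep(c("p1", "p2"), each = n),
                loci = c("A", "B"))
  gt
}

test_that("complete fixation drives theta, G''ST and D to 1", {
  gt <- fixed_pops()
  expect_equal(wc_fst(gt, gt$site_id)$theta, 1)
  d <- suppressWarnings(differentiation_stats(gt, gt$site_id))
  expect_equal(d$gst_hedrick, 1, tolerance = 1e-9)
  expect_equal(d$d_est, 1, tolerance = 1e-9)
})

test_that("one gene pool split into two labels gives near-zero estimates", {
  set.seed(121)
  freqs <- lapply(1:10, function(l) {
    f <- rep(1 / 8, 8); names(f) <- as.character(100 + 2 * (1:8)); f
  })
  gt <- sim_pops(list(freqs, freqs), n = 200)
  # the harmonic-mean D combination falls back (with a warning) when
  # per-locus D dips negative, as it does under the null
  d <- suppressWarnings(differentiation_stats(gt, gt$site_id))
  expect_lt(abs(d$theta), 0.02)
  expect_lt(abs(d$gst_hedrick), 0.02)
  expect_lt(abs(d$d_est), 0.02)
})

test_that("Nei-Chesser components match a direct scalar implementation", {
  set.seed(131)
  freqs1 <- list(A = c("1" = .5, "2" = .3, "3" = .2))
  freqs2 <- list(A = c("1" = .1, "2" = .6, "3" = .3))
  gt <- sim_pops(list(freqs1, freqs2), n = 15, L_names = "A")
  nc <- nei_chesser_components(gt, gt$site_id)
  # independent scalar computation from raw counts
  pops <- gt$site_id
  lev <- sort(unique(pops))
  n_i <- ho_i <- numeric(2)
  p_i <- matrix(0, 2, 3)
  alleles <- sort(unique(c(gt$calls[, 1], gt$calls[, 2])))
  for (i in 1:2) {
    rows <- which(pops == lev[i])
    a1 <- gt$calls[rows, 1]; a2 <- gt$calls[rows, 2]
    n_i[i] <- length(rows)
    ho_i[i] <- mean(a1 != a2)
    for (j in seq_along(alleles))
      p_i[i, j] <- sum(c(a1, a2) == alleles[j]) / (2 * n_i[i])
  }
  ntilde <- 2 / sum(1 / n_i)
  ho <- mean(ho_i)
  hs <- ntilde / (ntilde - 1) *
    (1 - mean(rowSums(p_i^2)) - ho / (2 * ntilde))
  ht <- 1 - sum(colMeans(p_i)^2) + hs / (2 * ntilde) - ho / (2 * 2 * ntilde)
  expect_equal(nc$H_S[1], hs, tolerance = 1e-12)
  expect_equal(nc$H_T[1], ht, tolerance = 1e-12)
})

test_that("identical allele frequencies give H_T ~ H_S and all-homozygous
           single-allele data give zero heterozygosity", {
  set.seed(141)
  freqs <- list(A = c("1" = .4, "2" = .6))
  gt <- sim_pops(list(freqs, freqs), n = 400, L_names = "A")
  nc <- nei_chesser_components(gt, gt$site_id)
  expect_lt(abs(nc$H_T[1] - nc$H_S[1]), 0.01)
  rows <- rep(list(c(1L, 1L)), 10)
  gt0 <- make_gt(rows, site = rep(c("p1", "p2"), 5), loci = "A")
  nc0 <- nei_chesser_components(gt0, gt0$site_id)
  expect_equal(nc0$H_S[1], 0)
  expect_equal(nc0$H_T[1], 0)
})

test_that("Hedrick and Jost formulas behave at the boundaries", {
  expect_equal(hedrick_gst(0.3, 0.3, 5), 0)
  expect_equal(jost_d(0.3, 0.3, 5), 0)
  # complete fixation: H_S = 0, H_T = (k-1)/k * 1 + corrections -> both 1
  gt <- fixed_pops(50)
  nc <- suppressWarnings(nei_chesser_components(gt, gt$site_id))
  expect_equal(hedrick_gst(nc$H_S[1], nc$H_T[1], 2), 1, tolerance = 1e-9)
  expect_equal(jost_d(nc$H_S[1], nc$H_T[1], 2), 1, tolerance = 1e-9)
  expect_error(hedrick_gst(1, 1.1, 2), "undefined")
  # G''ST >= G_ST whenever H_S > 0
  set.seed(151)
  for (rep in 1:50) {
    hs <- runif(1, 0.05, 0.9)
    ht <- hs + runif(1, 0, 1 - hs) * 0.9
    k <- sample(2:10, 1)
    gst <- (ht - hs) / ht
    expect_gte(hedrick_gst(hs, ht, k) + 1e-12, gst)
  }
  # scalar oracle for D on random triples
  for (rep in 1:20) {
    hs <- runif(1, 0, 0.9); ht <- hs + runif(1, 0, 0.09)
    k <- sample(2:10, 1)
    expect_equal(jost_d(hs, ht, k), (k / (k - 1)) * (ht - hs) / (1 - hs),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are reproducible and tighten with more loci", {
  set.seed(161)
  make_freqs <- function(L) lapply(seq_len(L), function(l) {
    f <- as.numeric(stats::rgamma(6, 1)); f <- f / sum(f)
    names(f) <- as.character(100 + 2 * (1:6)); f
  })
  fr <- make_freqs(20)
  drifted <- lapply(fr, function(f) {
    g <- f * exp(rnorm(length(f), 0, 0.5)); g <- g / sum(g)
    names(g) <- names(f); g
  })
  gt20 <- sim_pops(list(fr, drifted), n = 60)
  sub <- function(gt, L) genotype_table(
    gt$calls[, 1:(2 * L)], gt$sample_id, gt$site_id, gt$loci[1:L])
  gt5 <- sub(gt20, 5)
  set.seed(9); ci_a <- differentiation_bootstrap(gt5, gt5$site_id, "theta",
                                                 "loci", n_boot = 300)
  set.seed(9); ci_b <- differentiation_bootstrap(gt5, gt5$site_id, "theta",
                                                 "loci", n_boot = 300)
  expect_identical(ci_a$boot, ci_b$boot)
  ci20 <- differentiation_bootstrap(gt20, gt20$site_id, "theta", "loci",
                                    n_boot = 300)
  expect_lt(ci20$upper - ci20$lower, ci_a$upper - ci_a$lower)
  # individual-resampling route works for the heterozygosity-based measures
  ci_ind <- differentiation_bootstrap(gt5, gt5$site_id, "gst_hedrick",
                                      "individuals", n_boot = 60)
  expect_true(ci_ind$lower <= ci_ind$upper)
})

test_that("pairwise matrices are symmetric with empty diagonals", {
  set.seed(171)
  freqs <- lapply(1:4, function(l) {
    f <- as.numeric(stats::rgamma(5, 1)); f <- f / sum(f)
    names(f) <- as.character(100 + 2 * (1:5)); f
  })
  drift <- function(f, s) lapply(f, function(x) {
    g <- x * exp(rnorm(length(x), 0, s)); g <- g / sum(g)
    names(g) <- names(x); g
  })
  gt <- sim_pops(list(freqs, drift(freqs, .4), drift(freqs, .8)), n = 25)
  for (ms in c("theta", "gst_hedrick", "d_est")) {
    m <- pairwise_differentiation(gt, gt$site_id, ms)
    expect_equal(m, t(m))
    expect_true(all(is.na(diag(m))))
    expect_equal(dim(m), c(3L, 3L))
  }
})
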