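# Among-population differentiation: Weir-Cockerham theta, Nei-Chesser
# unbiased heterozygosity components, Hedrick's G''ST, Jost's D, and
# bootstrap confidence intervals.

# per-locus, per-population allele/heterozygote summaries
.pop_locus_summary <- function(gt, pops, l) {
  a1 <- gt$calls[, 2L * l - 1L]; a2 <- gt$calls[, 2L * l]
  ok <- !is.na(a1)
  pops <- as.character(pops)
  lev <- sort(unique(pops))
  alleles <- sort(unique(c(a1[ok], a2[ok])))
  k <- length(lev)
  n <- integer(k)
  p <- matrix(0, k, length(alleles), dimnames = list(lev, alleles))
  hom <- matrix(0, k, length(alleles), dimnames = list(lev, alleles))
  ho <- numeric(k)
  for (i in seq_len(k)) {
    rows <- which(pops == lev[i] & ok)
    n[i] <- length(rows)
    if (!n[i]) next
    x1 <- a1[rows]; x2 <- a2[rows]
    cnt <- table(factor(c(x1, x2), levels = alleles))
    p[i, ] <- as.numeric(cnt) / (2 * n[i])
    homc <- table(factor(x1[x1 == x2], levels = alleles))
    hom[i, ] <- as.numeric(homc) / n[i]
    ho[i] <- mean(x1 != x2)
  }
  list(pop = lev, n = n, p = p, hom = hom, ho = ho, alleles = alleles)
}

#' Weir-Cockerham variance components and theta
#'
#' Computes the Weir-Cockerham (1984) estimator of F_ST from per-allele,
#' per-locus variance components: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals);
#' `theta = sum(a) / sum(a + b + c)` over all alleles and loci. Individuals
#' missing a locus are excluded at that locus only. Loci monomorphic over
#' the whole sample contribute zero components.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per sample.
#' @return list with `theta` and `components` (data frame per locus: a, b, c).
#' @export
wc_fst <- function(gt, pops) {
  pops <- as.character(pops)
  if (length(unique(pops)) < 2L) stop("need >= 2 populations")
  L <- n_loci(gt)
  comp <- data.frame(locus = gt$loci, a = 0, b = 0, c = 0)
  for (l in seq_len(L)) {
    s <- .pop_locus_summary(gt, pops, l)
    use <- s$n > 0L
    if (sum(use) < 2L || length(s$alleles) < 2L) next
    n <- s$n[use]; p <- s$p[use, , drop = FALSE]
    r <- length(n)
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    # per-allele heterozygote frequency: proportion of individuals in pop i
    # carrying exactly one copy of the allele
    hom <- s$hom[use, , drop = FALSE]
    h <- 2 * (p - hom)          # P(het for allele) = 2p_i - 2*P(hom allele)
    for (al in seq_along(s$alleles)) {
      pbar <- sum(n * p[, al]) / (r * nbar)
      s2 <- sum(n * (p[, al] - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h[, al]) / (r * nbar)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      comp$a[l] <- comp$a[l] + a
      comp$b[l] <- comp$b[l] + b
      comp$c[l] <- comp$c[l] + cc
    }
  }
  tot <- sum(comp$a + comp$b + comp$c)
  list(theta = if (tot > 0) sum(comp$a) / tot else NA_real_,
       components = comp)
}

#' Nei-Chesser unbiased heterozygosity components
#'
#' Per locus: `H_S = ntilde/(ntilde-1) * (1 - mean_i(sum_a p_ia^2) -
#' H_o/(2*ntilde))` and `H_T = 1 - sum_a pbar_a^2 + H_S/(k*ntilde) -
#' H_o/(2*k*ntilde)`, with `ntilde` the harmonic mean sample size, `pbar`
#' the unweighted mean allele frequency across the `k` populations and `H_o`
#' the mean observed heterozygosity. Populations with fewer than two
#' genotyped individuals at a locus are excluded there with a warning.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per sample.
#' @return data frame per locus: `locus`, `k`, `H_o`, `H_S`, `H_T`.
#' @export
nei_chesser_components <- function(gt, pops) {
  pops <- as.character(pops)
  L <- n_loci(gt)
  out <- data.frame(locus = gt$loci, k = NA_integer_, H_o = NA_real_,
                    H_S = NA_real_, H_T = NA_real_)
  dropped <- 0L
  for (l in seq_len(L)) {
    s <- .pop_locus_summary(gt, pops, l)
    use <- s$n >= 2L
    dropped <- dropped + sum(s$n == 1L)
    if (sum(use) < 2L) next
    n <- s$n[use]; p <- s$p[use, , drop = FALSE]; ho <- mean(s$ho[use])
    k <- length(n)
    ntilde <- k / sum(1 / n)
    hs <- ntilde / (ntilde - 1) *
      (1 - mean(rowSums(p^2)) - ho / (2 * ntilde))
    pbar <- colMeans(p)
    ht <- 1 - sum(pbar^2) + hs / (k * ntilde) - ho / (2 * k * ntilde)
    out[l, 2:5] <- list(k, ho, hs, ht)
  }
  if (dropped) warning(dropped,
    " single-individual population-locus combination(s) excluded")
  out
}

#' Hedrick's standardized G''ST
#'
#' `G''ST = k*(H_T - H_S) / ((k*H_T - H_S) * (1 - H_S))`: G_ST rescaled to
#' its maximum attainable value given the within-population heterozygosity.
#'
#' @param H_S,H_T heterozygosity components.
#' @param k number of populations.
#' @return G''ST.
#' @export
hedrick_gst <- function(H_S, H_T, k) {
  if (any(H_T <= 0)) stop("H_T must be positive")
  if (any(H_S >= 1)) stop("G''ST undefined at H_S = 1")
  k * (H_T - H_S) / ((k * H_T - H_S) * (1 - H_S))
}

#' Jost's D
#'
#' `D = (k/(k-1)) * (H_T - H_S)/(1 - H_S)`, differentiation in terms of
#' effective allele numbers.
#'
#' @param H_S,H_T heterozygosity components.
#' @param k number of populations.
#' @return D.
#' @export
jost_d <- function(H_S, H_T, k) {
  if (any(H_S >= 1)) stop("D undefined at H_S = 1")
  (k / (k - 1)) * (H_T - H_S) / (1 - H_S)
}

#' Global differentiation statistics
#'
#' Multi-locus combination: theta by summed variance components; G''ST from
#' across-locus means of H_S and H_T; D_est by the harmonic mean of
#' per-locus D values (arithmetic mean, or the across-locus-components form,
#' via `d_mean`). The harmonic mean is only defined when every per-locus D
#' is positive; otherwise the arithmetic mean is used with a warning.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per sample.
#' @param d_mean `"harmonic"` (default) or `"arithmetic"` across-locus
#'   combination for D_est.
#' @return list: `theta`, `gst_hedrick`, `d_est`, `H_S`, `H_T`, `k`,
#'   `per_locus` (data frame), `wc` (full [wc_fst()] result).
#' @export
differentiation_stats <- function(gt, pops, d_mean = c("harmonic",
                                                       "arithmetic")) {
  d_mean <- match.arg(d_mean)
  wc <- wc_fst(gt, pops)
  nc <- nei_chesser_components(gt, pops)
  ok <- !is.na(nc$H_S)
  k <- max(nc$k[ok])
  HS <- mean(nc$H_S[ok]); HT <- mean(nc$H_T[ok])
  d_locus <- jost_d(nc$H_S[ok], nc$H_T[ok], nc$k[ok])
  d_est <- if (d_mean == "harmonic") {
    if (all(d_locus > 0)) 1 / mean(1 / d_locus)
    else {
      warning("non-positive per-locus D; falling back to arithmetic mean")
      mean(d_locus)
    }
  } else mean(d_locus)
  list(theta = wc$theta,
       gst_hedrick = hedrick_gst(HS, HT, k),
       d_est = d_est, H_S = HS, H_T = HT, k = k,
       per_locus = cbind(nc, D = ifelse(ok, jost_d(pmin(nc$H_S, 1 - 1e-12),
                                                   nc$H_T, nc$k), NA)),
       wc = wc)
}

#' Pairwise differentiation matrices
#'
#' Re-estimates components for every pair of populations (not extracted from
#' the global fit).
#'
#' @param gt a [genotype_table()].
#' @param pops population label per sample.
#' @param measure one of `"theta"`, `"gst_hedrick"`, `"d_est"`.
#' @return symmetric matrix with `NA` diagonal.
#' @export
pairwise_differentiation <- function(gt, pops,
                                     measure = c("theta", "gst_hedrick",
                                                 "d_est")) {
  measure <- match.arg(measure)
  pops <- as.character(pops)
  lev <- sort(unique(pops))
  k <- length(lev)
  m <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rows <- pops %in% c(lev[i], lev[j])
    sub <- genotype_table(gt$calls[rows, , drop = FALSE],
                          gt$sample_id[rows], gt$site_id[rows], gt$loci)
    val <- try(suppressWarnings(
      differentiation_stats(sub, pops[rows])[[measure]]), silent = TRUE)
    if (!inherits(val, "try-error"))
      m[i, j] <- m[j, i] <- val
  }
  m
}

#' Bootstrap confidence interval for a differentiation measure
#'
#' `unit = "loci"` resamples loci with replacement (theta from resampled
#' per-locus variance components; G''ST/D from resampled per-locus
#' heterozygosity components). `unit = "individuals"` resamples individuals
#' with replacement within each population and recomputes the measure.
#'
#' @param gt a [genotype_table()].
#' @param pops population label per sample.
#' @param measure `"theta"`, `"gst_hedrick"` or `"d_est"`.
#' @param unit `"loci"` or `"individuals"`.
#' @param n_boot replicates (default 1000).
#' @return list with `lower`, `upper` (percentile 2.5/97.5), `boot` (vector).
#' @export
differentiation_bootstrap <- function(gt, pops,
                                      measure = c("theta", "gst_hedrick",
                                                  "d_est"),
                                      unit = c("loci", "individuals"),
                                      n_boot = 1000L) {
  measure <- match.arg(measure)
  unit <- match.arg(unit)
  pops <- as.character(pops)
  if (unit == "loci") {
    if (n_loci(gt) < 2L) stop("need >= 2 loci to bootstrap over loci")
    if (measure == "theta") {
      comp <- wc_fst(gt, pops)$components
      boot <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(comp), replace = TRUE)
        tot <- sum(comp$a[i] + comp$b[i] + comp$c[i])
        if (tot > 0) sum(comp$a[i]) / tot else NA_real_
      }, numeric(1))
    } else {
      nc <- suppressWarnings(nei_chesser_components(gt, pops))
      nc <- nc[!is.na(nc$H_S), ]
      boot <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(nc), replace = TRUE)
        HS <- mean(nc$H_S[i]); HT <- mean(nc$H_T[i]); k <- max(nc$k[i])
        if (measure == "gst_hedrick") hedrick_gst(HS, HT, k)
        else jost_d(HS, HT, k)
      }, numeric(1))
    }
  } else {
    lev <- unique(pops)
    if (any(table(pops) < 2L)) stop("need >= 2 samples per population")
    rows_by_pop <- split(seq_along(pops), pops)
    boot <- vapply(seq_len(n_boot), function(b) {
      rows <- unlist(lapply(rows_by_pop, function(rr)
        rr[sample.int(length(rr), replace = TRUE)]))
      sub <- genotype_table(gt$calls[rows, , drop = FALSE],
                            paste0("b", seq_along(rows)),
                            gt$site_id[rows], gt$loci)
      suppressWarnings(differentiation_stats(sub, pops[rows])[[measure]])
    }, numeric(1))
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lower = ci[1], upper = ci[2], boot = boot)
}
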