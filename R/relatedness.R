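# Pairwise relatedness: Wang's (2002) moment estimator, group permutation
# tests, and within/among-site summaries.
#
# The estimator works from the proportions of locus-wise genotype similarity
# categories between a pair of diploids:
#   S1: identical genotypes; S2: one homozygote, one heterozygote sharing an
#   allele; S3: two heterozygotes sharing exactly one allele; S4: no allele
#   shared.
# With reference-population allele-frequency moments a2, a3, a4 and the
# composite coefficients
#   b = 2a2^2 - a4        c = a2 - 2a2^2 + a4
#   d = 4(a3 - a4)        e = 2(a2 - 3a3 + 2a4)
#   f = 4(a2 - a2^2 - 2a3 + 2a4)
#   g = 1 - 7a2 + 4a2^2 + 10a3 - 8a4
# the category expectations are linear in the two-gene (phi) and four-gene
# (Delta) identity coefficients:
#   E[P1] = b + c*phi + (1-b)*Delta
#   E[P2] = d + e*phi - d*Delta
#   E[P3] = f + g*phi - f*Delta
# and relatedness is r = phi/2 + Delta. Loci are combined by weighted
# averages of the P's and of b..g with weights proportional to 1/u,
# u = 2a2 - a3. Allele-frequency moments carry Wang's small-sample
# corrections for the finite reference sample.

# unbiased moments of allele frequencies from n sampled gene copies
.wang_moments <- function(p, n) {
  s2 <- sum(p^2); s3 <- sum(p^3); s4 <- sum(p^4)
  if (n < 4) stop("reference sample too small for moment correction")
  a2 <- (n * s2 - 1) / (n - 1)
  a3 <- (n^2 * s3 - 3 * (n - 1) * a2 - 1) / ((n - 1) * (n - 2))
  a4 <- (n^3 * s4 - 6 * (n - 1) * (n - 2) * a3 - 7 * (n - 1) * a2 - 1) /
    ((n - 1) * (n - 2) * (n - 3))
  c(a2 = a2, a3 = a3, a4 = a4)
}

# per-locus coefficient table for the estimator
.wang_coefficients <- function(gt, samples = NULL, correct = TRUE) {
  calls <- gt$calls
  if (!is.null(samples)) calls <- calls[gt$sample_id %in% samples, ,
                                        drop = FALSE]
  L <- length(gt$loci)
  out <- data.frame(locus = gt$loci, a2 = NA_real_, a3 = NA_real_,
                    a4 = NA_real_)
  for (l in seq_len(L)) {
    a <- c(calls[, 2L * l - 1L], calls[, 2L * l])
    a <- a[!is.na(a)]
    p <- as.numeric(table(a)) / length(a)
    m <- if (correct) .wang_moments(p, length(a))
      else c(a2 = sum(p^2), a3 = sum(p^3), a4 = sum(p^4))
    out[l, 2:4] <- m
  }
  a2 <- out$a2; a3 <- out$a3; a4 <- out$a4
  out$b <- 2 * a2^2 - a4
  out$c <- a2 - 2 * a2^2 + a4
  out$d <- 4 * (a3 - a4)
  out$e <- 2 * (a2 - 3 * a3 + 2 * a4)
  out$f <- 4 * (a2 - a2^2 - 2 * a3 + 2 * a4)
  out$g <- 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4
  out$u <- 2 * a2 - a3
  out$w <- (1 / out$u) / sum(1 / out$u)
  out
}

# estimator from weighted-average category proportions and coefficients;
# all arguments are vectors over pairs
.wang_estimate <- function(P1, P2, P3, b, c, d, e, f, g) {
  V <- (1 - b)^2 * (e^2 * f + d * g^2) - (1 - b) * (e * f - d * g)^2 +
    2 * c * d * f * (1 - b) * (g + e) + c^2 * d * f * (d + f)
  phi <- (d * f * ((e + g) * (1 - b) + c * (d + f)) * (P1 - 1) +
            d * (1 - b) * (g * (1 - b - d) + f * (c + e)) * P3 +
            f * (1 - b) * (e * (1 - b - f) + d * (c + g)) * P2) / V
  A <- c * d * f * (e + g) + (1 - b) * (f * e^2 + d * g^2) -
    (e * f - d * g)^2
  B <- c * f * (b * e - c * d - d * g + e * f - e)
  C <- c * d * (b * g - c * f + d * g - e * f - g)
  delta <- (A * (P1 - b) + B * (P2 - d) + C * (P3 - f)) / V
  phi / 2 + delta
}

# classify pair-locus similarity categories; returns list of logical matrices
# pairs x loci: valid, s1, s2, s3
.pair_categories <- function(calls, ii, jj, L) {
  P <- length(ii)
  valid <- s1 <- s2 <- s3 <- matrix(FALSE, P, L)
  for (l in seq_len(L)) {
    a1 <- calls[, 2L * l - 1L]; a2 <- calls[, 2L * l]
    x1 <- a1[ii]; x2 <- a2[ii]; y1 <- a1[jj]; y2 <- a2[jj]
    ok <- !is.na(x1) & !is.na(y1)
    ident <- ok & x1 == y1 & x2 == y2
    share <- ok & (x1 == y1 | x1 == y2 | x2 == y1 | x2 == y2)
    homx <- x1 == x2; homy <- y1 == y2
    valid[, l] <- ok
    s1[, l] <- ident
    s2[, l] <- !ident & share & (homx | homy) & ok
    s3[, l] <- !ident & share & !(homx | homy) & ok
  }
  list(valid = valid, s1 = s1, s2 = s2, s3 = s3)
}

# vectorized estimate for arbitrary pair index vectors (ii, jj) into calls;
# returns r and the shared-locus count per pair
.wang_r_vector <- function(calls, ii, jj, coefs) {
  L <- nrow(coefs)
  cat_ <- .pair_categories(calls, ii, jj, L)
  w <- coefs$w
  sw <- as.vector(cat_$valid %*% w)
  P1 <- as.vector(cat_$s1 %*% w) / sw
  P2 <- as.vector(cat_$s2 %*% w) / sw
  P3 <- as.vector(cat_$s3 %*% w) / sw
  avg <- function(col) as.vector(cat_$valid %*% (w * coefs[[col]])) / sw
  r <- .wang_estimate(P1, P2, P3, avg("b"), avg("c"), avg("d"), avg("e"),
                      avg("f"), avg("g"))
  list(r = r, n_loci = rowSums(cat_$valid))
}

#' Pairwise Wang relatedness matrix
#'
#' Moment estimator of pairwise relatedness for codominant markers,
#' combining loci with weights proportional to the inverse expected
#' similarity variance (1/u) and applying small-sample corrections to the
#' reference allele-frequency moments. Loci missing in either member of a
#' pair are excluded with the weights renormalized over the remaining loci.
#'
#' @param gt a [genotype_table()].
#' @param reference_samples sample ids for the allele-frequency reference set
#'   (default: all samples of `gt`).
#' @param min_loci pairs sharing fewer resolved loci are flagged
#'   low-confidence (default 5).
#' @return list with `r` (symmetric matrix, `NA` diagonal), `n_loci`
#'   (shared resolved loci per pair), `low_confidence` (logical matrix).
#'   Pairs with zero comparable loci are `NA` with a warning.
#' @export
wang_r_matrix <- function(gt, reference_samples = NULL, min_loci = 5L) {
  coefs <- .wang_coefficients(gt, samples = reference_samples)
  n <- n_samples(gt)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  est <- .wang_r_vector(gt$calls, idx[, 1], idx[, 2], coefs)
  r <- est$r; nl <- est$n_loci
  if (any(nl == 0L)) {
    warning(sum(nl == 0L), " pair(s) with no comparable loci set to NA")
    r[nl == 0L] <- NA_real_
  }
  rmat <- matrix(NA_real_, n, n, dimnames = list(gt$sample_id, gt$sample_id))
  rmat[idx] <- r; rmat[idx[, 2:1]] <- r
  nmat <- matrix(NA_integer_, n, n, dimnames = dimnames(rmat))
  nmat[idx] <- nl; nmat[idx[, 2:1]] <- nl
  list(r = rmat, n_loci = nmat, low_confidence = nmat < min_loci)
}

#' Wang relatedness for a single pair of genotypes
#'
#' @param a,b integer vectors of length 2L (paired allele columns of the two
#'   samples, low allele first within each locus).
#' @param gt the `genotype_table` providing the allele-frequency reference.
#' @return scalar relatedness estimate.
#' @export
wang_r <- function(a, b, gt) {
  coefs <- .wang_coefficients(gt)
  .wang_r_vector(rbind(a, b), 1L, 2L, coefs)$r
}

#' Permutation test of within-group mean relatedness
#'
#' Compares the observed mean pairwise relatedness within each group against
#' a null distribution obtained by shuffling samples between groups while
#' holding group sizes constant.
#'
#' @param rmat symmetric relatedness matrix (NA diagonal).
#' @param groups factor/character vector of group labels, one per row of
#'   `rmat`.
#' @param n_shuffles number of shuffles (default 1000).
#' @return data frame per group: `group`, `n`, `observed` (mean within-group
#'   r), `p_high` = (#\{null >= obs\} + 1)/(n_shuffles + 1), `p_low` mirror.
#' @export
group_relatedness_test <- function(rmat, groups, n_shuffles = 1000L) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 members")
  within_means <- function(g) {
    vapply(lev, function(lv) {
      sub <- rmat[g == lv, g == lv]
      mean(sub[upper.tri(sub)], na.rm = TRUE)
    }, numeric(1))
  }
  obs <- within_means(groups)
  null <- matrix(NA_real_, n_shuffles, length(lev))
  for (k in seq_len(n_shuffles))
    null[k, ] <- within_means(sample(groups))
  p_high <- vapply(seq_along(lev), function(j)
    (sum(null[, j] >= obs[j]) + 1) / (n_shuffles + 1), numeric(1))
  p_low <- vapply(seq_along(lev), function(j)
    (sum(null[, j] <= obs[j]) + 1) / (n_shuffles + 1), numeric(1))
  data.frame(group = lev, n = as.integer(table(groups)[lev]),
             observed = obs, p_high = p_high, p_low = p_low,
             row.names = NULL)
}

#' Within-site (r_W) and among-site (r_A) relatedness summaries
#'
#' For each sample: mean relatedness to all other samples at the same site
#' (r_W) and to samples from other sites within the same tidal regime (r_A);
#' both are then averaged to the site level.
#'
#' @param rmat symmetric relatedness matrix.
#' @param site_id site label per row of `rmat`.
#' @param regime regime label per row of `rmat`.
#' @return data frame per site: `site_id`, `regime`, `n`, `r_w`, `r_a`
#'   (single-sample sites give `NA` r_w).
#' @export
within_among_summaries <- function(rmat, site_id, regime) {
  site_id <- as.character(site_id); regime <- as.character(regime)
  n <- nrow(rmat)
  rw <- ra <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same_site <- site_id == site_id[i] & seq_len(n) != i
    other_site <- site_id != site_id[i] & regime == regime[i]
    if (any(same_site)) rw[i] <- mean(rmat[i, same_site], na.rm = TRUE)
    if (any(other_site)) ra[i] <- mean(rmat[i, other_site], na.rm = TRUE)
  }
  sites <- unique(site_id)
  data.frame(
    site_id = sites,
    regime = regime[match(sites, site_id)],
    n = as.integer(table(site_id)[sites]),
    r_w = vapply(sites, function(s) {
      v <- rw[site_id == s]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)),
    r_a = vapply(sites, function(s) mean(ra[site_id == s], na.rm = TRUE),
                 numeric(1)),
    row.names = NULL)
}
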