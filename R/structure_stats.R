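# Edwards' chord genetic distance, Mantel IBD tests, correspondence
# analysis of site-by-allele counts, and Spearman correlations with river km.

#' Edwards' chord distance between two allele-frequency profiles
#'
#' Angular form: `D = sqrt(1 - (1/L) * sum_l sum_a sqrt(p_Ala * p_Bla))`
#' (several formulas share the name "chord distance"; this is the
#' Bhattacharyya-affinity variant used for allele-frequency ordination).
#' Loci absent (no scored copies) in either profile are excluded with `L`
#' renormalized.
#'
#' @param freq_a,freq_b lists of per-locus named allele-frequency vectors
#'   (as from [allele_frequencies()]).
#' @return distance in `[0, 1]`.
#' @export
edwards_chord <- function(freq_a, freq_b) {
  L <- length(freq_a)
  aff <- numeric(0)
  for (l in seq_len(L)) {
    pa <- freq_a[[l]]; pb <- freq_b[[l]]
    if (!length(pa) || !length(pb)) next
    alleles <- union(names(pa), names(pb))
    a <- rep(0, length(alleles)); names(a) <- alleles; a[names(pa)] <- pa
    b <- rep(0, length(alleles)); names(b) <- alleles; b[names(pb)] <- pb
    aff <- c(aff, sum(sqrt(a * b)))
  }
  if (!length(aff)) stop("no locus scored in both profiles")
  sqrt(max(0, 1 - mean(aff)))
}

#' Pairwise chord-distance matrix between sites
#'
#' @param gt a [genotype_table()].
#' @param site_id grouping vector (defaults to `gt$site_id`).
#' @return symmetric matrix of chord distances.
#' @export
chord_distance_matrix <- function(gt, site_id = gt$site_id) {
  sites <- sort(unique(site_id))
  freqs <- lapply(sites, function(s)
    allele_frequencies(gt, samples = gt$sample_id[site_id == s]))
  k <- length(sites)
  m <- matrix(0, k, k, dimnames = list(sites, sites))
  if (k < 2L) return(m)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    m[i, j] <- m[j, i] <- edwards_chord(freqs[[i]], freqs[[j]])
  m
}

#' Mantel test of matrix association
#'
#' Pearson correlation over the `n(n-1)/2` off-diagonal pairs; significance
#' by jointly permuting rows and columns of one matrix. One-sided (positive
#' association), the usual orientation for isolation-by-distance:
#' `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices with matching ids.
#' @param n_perm permutations (default 999).
#' @return list: `r`, `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L) {
  if (!identical(dim(m1), dim(m2))) stop("matrix dimensions differ")
  n <- nrow(m1)
  if (n < 4L) stop("need at least 4 entities")
  ut <- upper.tri(m1)
  v1 <- m1[ut]; v2 <- m2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(v1, v2)
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(m1[p, p][ut], v2)
    if (rp >= r_obs) cnt <- cnt + 1L
  }
  list(r = r_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm, n = n)
}

#' Site-by-allele count table
#'
#' Two-way contingency table of allele copy counts (rows = sites, columns =
#' locus/allele combinations); the input for correspondence analysis.
#'
#' @param gt a [genotype_table()].
#' @param site_id grouping vector.
#' @return integer matrix.
#' @export
site_allele_table <- function(gt, site_id = gt$site_id) {
  sites <- sort(unique(site_id))
  cols <- list()
  for (l in seq_along(gt$loci)) {
    a <- c(gt$calls[, 2L * l - 1L], gt$calls[, 2L * l])
    s <- c(site_id, site_id)
    ok <- !is.na(a)
    tb <- table(factor(s[ok], levels = sites), a[ok])
    colnames(tb) <- paste0(gt$loci[l], ".", colnames(tb))
    cols[[l]] <- as.matrix(tb)
  }
  do.call(cbind, cols)
}

#' Correspondence analysis of a contingency table
#'
#' Classic CA by singular value decomposition of the standardized residual
#' matrix `S = Dr^{-1/2} (P - r c^T) Dc^{-1/2}` of the relative-frequency
#' table `P`; site (row) scores are returned in principal coordinates
#' `Dr^{-1/2} U Sigma`. Total inertia equals the table's chi-square statistic
#' divided by the grand total. All-zero rows/columns are dropped with a
#' warning.
#'
#' @param tab nonnegative count matrix (sites x alleles).
#' @return list: `site_scores` (principal coordinates), `inertia` (per-axis),
#'   `inertia_pct`, `total_inertia`, `sv` (singular values).
#' @export
correspondence_analysis <- function(tab) {
  tab <- as.matrix(tab)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " column(s)")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (!nrow(tab) || !ncol(tab)) stop("empty table")
  P <- tab / sum(tab)
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% c) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  if (!length(keep)) stop("rank-0 table: no variation among rows")
  d <- sv$d[keep]
  scores <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*% diag(d,
    nrow = length(d))
  rownames(scores) <- rownames(tab)
  colnames(scores) <- paste0("Axis", seq_along(d))
  inertia <- d^2
  list(site_scores = scores, inertia = inertia,
       inertia_pct = 100 * inertia / sum(inertia),
       total_inertia = sum(inertia), sv = d)
}

#' Spearman correlation of a site statistic with river km
#'
#' Midrank-tied Spearman rho with the t-distribution approximation for the
#' p-value.
#'
#' @param stat numeric site-statistic vector.
#' @param river_km matching river-km vector.
#' @return list: `rho`, `p`, `n` (pairs with both values present).
#' @export
spearman_vs_riverkm <- function(stat, river_km) {
  ok <- !is.na(stat) & !is.na(river_km)
  if (sum(ok) < 4L) stop("need at least 4 paired sites")
  if (stats::sd(stat[ok]) == 0 || stats::sd(river_km[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(stats::cor.test(stat[ok], river_km[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
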