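# Per-site allelic and heterozygosity statistics, rarefied allelic richness,
# F_IS bootstrap confidence intervals, and clone correction.

# per-locus allele count tables for one set of samples
.locus_counts <- function(gt, rows = NULL) {
  calls <- gt$calls
  if (!is.null(rows)) calls <- calls[rows, , drop = FALSE]
  lapply(seq_along(gt$loci), function(l) {
    a <- c(calls[, 2L * l - 1L], calls[, 2L * l])
    table(a[!is.na(a)])
  })
}

#' Polymorphism and allele counts per site
#'
#' `P` is the fraction of loci with two or more observed alleles; `A` the
#' mean number of alleles per locus. Loci with no genotyped call in a site
#' are excluded from both denominators.
#'
#' @param gt a [genotype_table()].
#' @param site_id optional grouping vector (defaults to `gt$site_id`).
#' @return data frame per site: `site_id`, `n`, `P`, `A`, `n_loci_scored`.
#' @export
allele_stats <- function(gt, site_id = gt$site_id) {
  sites <- unique(site_id)
  out <- data.frame(site_id = sites, n = NA_integer_, P = NA_real_,
                    A = NA_real_, n_loci_scored = NA_integer_)
  for (k in seq_along(sites)) {
    rows <- which(site_id == sites[k])
    cnt <- .locus_counts(gt, rows)
    n_all <- vapply(cnt, length, integer(1))
    scored <- n_all > 0L
    out$n[k] <- length(rows)
    out$n_loci_scored[k] <- sum(scored)
    out$P[k] <- mean(n_all[scored] >= 2L)
    out$A[k] <- mean(n_all[scored])
  }
  out
}

#' Rarefied allelic richness
#'
#' Expected number of alleles observed in a random subsample of `g` gene
#' copies, by the hypergeometric expectation
#' \eqn{\sum_a [1 - C(N_l - N_a, g) / C(N_l, g)]}, averaged over loci.
#'
#' @param counts either a single named allele-count vector for one locus, or
#'   a list of such vectors (one per locus).
#' @param g number of gene copies to rarefy to (default 15).
#' @return mean rarefied richness over loci with at least `g` copies; loci
#'   with fewer copies are excluded with a warning.
#' @export
rarefied_richness <- function(counts, g = 15L) {
  if (g < 1L) stop("g must be >= 1")
  if (!is.list(counts)) counts <- list(counts)
  per_locus <- vapply(counts, function(ct) {
    ct <- as.numeric(ct)
    N <- sum(ct)
    if (N < g) return(NA_real_)
    sum(1 - exp(lchoose(N - ct, g) - lchoose(N, g)))
  }, numeric(1))
  if (anyNA(per_locus)) {
    warning(sum(is.na(per_locus)), " locus/loci with fewer than ", g,
            " gene copies excluded from rarefied richness")
    per_locus <- per_locus[!is.na(per_locus)]
  }
  if (!length(per_locus)) return(NA_real_)
  mean(per_locus)
}

#' Observed and expected heterozygosity and F_IS
#'
#' Per locus within one sample set: `H_o` is the proportion of heterozygous
#' genotypes; `H_s` is Nei's (1987) unbiased gene diversity
#' `n/(n-1) * (1 - sum p^2 - H_o/(2n))`; `F_IS = 1 - H_o/H_s` (negative
#' values flag heterozygote excess, a clonality signature). The across-locus
#' mean `F_IS` follows the ratio-of-means convention
#' `1 - mean(H_o)/mean(H_s)`; the across-locus variance of the per-locus
#' values is also reported.
#'
#' @param gt a [genotype_table()].
#' @param rows optional row subset (sample indices).
#' @return list with `per_locus` (data frame: locus, n, H_o, H_s, F_IS),
#'   `H_o`, `H_s` (means), `F_IS` (ratio of means), `F_IS_var`
#'   (across-locus variance, monomorphic loci excluded).
#' @export
heterozygosity_stats <- function(gt, rows = NULL) {
  calls <- gt$calls
  if (!is.null(rows)) calls <- calls[rows, , drop = FALSE]
  L <- length(gt$loci)
  per <- data.frame(locus = gt$loci, n = NA_integer_, H_o = NA_real_,
                    H_s = NA_real_, F_IS = NA_real_)
  for (l in seq_len(L)) {
    a1 <- calls[, 2L * l - 1L]; a2 <- calls[, 2L * l]
    ok <- !is.na(a1)
    n <- sum(ok)
    per$n[l] <- n
    if (n < 2L) next
    ho <- mean(a1[ok] != a2[ok])
    p <- as.numeric(table(c(a1[ok], a2[ok]))) / (2 * n)
    hs <- n / (n - 1) * (1 - sum(p^2) - ho / (2 * n))
    per$H_o[l] <- ho
    per$H_s[l] <- hs
    per$F_IS[l] <- if (hs > 0) 1 - ho / hs else NA_real_
  }
  ok <- !is.na(per$H_s)
  list(per_locus = per,
       H_o = mean(per$H_o[ok]),
       H_s = mean(per$H_s[ok]),
       F_IS = 1 - mean(per$H_o[ok]) / mean(per$H_s[ok]),
       F_IS_var = stats::var(per$F_IS[!is.na(per$F_IS)]))
}

#' Bootstrap confidence interval for mean F_IS
#'
#' Resamples loci with replacement and recomputes the ratio-of-means F_IS
#' (`1 - mean(H_o)/mean(H_s)` over the resampled loci); percentile 2.5/97.5
#' bounds. F_IS is significant when the interval excludes zero.
#'
#' @param het result of [heterozygosity_stats()].
#' @param n_boot bootstrap replicates (default 1000; below 100 warns).
#' @return list with `lower`, `upper`, `significant`.
#' @export
fis_bootstrap_ci <- function(het, n_boot = 1000L) {
  if (n_boot < 100L) warning("fewer than 100 bootstrap replicates")
  per <- het$per_locus
  per <- per[!is.na(per$H_s) & per$H_s > 0, ]
  L <- nrow(per)
  if (L < 2L) stop("need at least two informative loci")
  vals <- vapply(seq_len(n_boot), function(k) {
    i <- sample.int(L, L, replace = TRUE)
    1 - mean(per$H_o[i]) / mean(per$H_s[i])
  }, numeric(1))
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(lower = ci[1], upper = ci[2],
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Clone-correct a genotype table
#'
#' Retains one sample per MLL per site (the member with the fewest missing
#' loci, ties broken by lexicographic sample id), so that downstream
#' statistics reflect sexual variation only.
#'
#' @param gt a [genotype_table()].
#' @param assignment a collapsed `clonal_assignment` on `gt`.
#' @return a clone-corrected `genotype_table` (ambiguous/excluded samples are
#'   dropped).
#' @export
clone_correct <- function(gt, assignment) {
  if (is.null(assignment$mll_id)) stop("run collapse_to_mlls() first")
  mll <- assignment$mll_id[gt$sample_id]
  keep <- character(0)
  L <- length(gt$loci)
  n_missing <- rowSums(is.na(gt$calls[, seq(1L, 2L * L, 2L), drop = FALSE]))
  for (s in unique(gt$site_id)) {
    rows <- which(gt$site_id == s & !is.na(mll))
    for (m in unique(mll[rows])) {
      cand <- rows[mll[rows] == m]
      o <- order(n_missing[cand], gt$sample_id[cand])
      keep <- c(keep, gt$sample_id[cand[o[1]]])
    }
  }
  rows <- which(gt$sample_id %in% keep)
  genotype_table(gt$calls[rows, , drop = FALSE], gt$sample_id[rows],
                 gt$site_id[rows], gt$loci)
}

#' Per-site locus diversity table with clone-correction deltas
#'
#' Computes P, A, rarefied richness, H_o, H_s, F_IS (with across-locus
#' variance) per site on all samples and on the clone-corrected table, and
#' reports the deltas `stat(all) - stat(clone-corrected)`.
#'
#' @param gt a [genotype_table()].
#' @param assignment a collapsed `clonal_assignment`.
#' @param g_rarefaction gene copies for rarefied richness (default 15).
#' @param n_boot bootstrap replicates for the F_IS CI (default 1000).
#' @return data frame per site.
#' @export
locus_diversity_table <- function(gt, assignment, g_rarefaction = 15L,
                                  n_boot = 1000L) {
  cc <- clone_correct(gt, assignment)
  base <- allele_stats(gt)
  sites <- base$site_id
  out <- base
  out[, c("A_r", "H_o", "H_s", "F_IS", "F_IS_var", "F_IS_lo", "F_IS_hi",
          "H_o_cc", "H_s_cc", "F_IS_cc", "delta_H_o", "delta_H_s",
          "delta_F_IS")] <- NA_real_
  for (k in seq_along(sites)) {
    rows <- which(gt$site_id == sites[k])
    cnt <- .locus_counts(gt, rows)
    cnt <- cnt[vapply(cnt, length, integer(1)) > 0L]
    out$A_r[k] <- suppressWarnings(rarefied_richness(cnt, g = g_rarefaction))
    het <- heterozygosity_stats(gt, rows)
    out$H_o[k] <- het$H_o; out$H_s[k] <- het$H_s
    out$F_IS[k] <- het$F_IS; out$F_IS_var[k] <- het$F_IS_var
    ci <- try(fis_bootstrap_ci(het, n_boot = n_boot), silent = TRUE)
    if (!inherits(ci, "try-error")) {
      out$F_IS_lo[k] <- ci$lower; out$F_IS_hi[k] <- ci$upper
    }
    rows_cc <- which(cc$site_id == sites[k])
    if (length(rows_cc) >= 2L) {
      het_cc <- heterozygosity_stats(cc, rows_cc)
      out$H_o_cc[k] <- het_cc$H_o; out$H_s_cc[k] <- het_cc$H_s
      out$F_IS_cc[k] <- het_cc$F_IS
      out$delta_H_o[k] <- het$H_o - het_cc$H_o
      out$delta_H_s[k] <- het$H_s - het_cc$H_s
      out$delta_F_IS[k] <- het$F_IS - het_cc$F_IS
    }
  }
  out
}
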