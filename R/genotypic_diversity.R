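# Genotypic richness, effective numbers of lineages, Pareto beta,
# rarefaction, and clone spatial extents.

#' Genotypic richness R = (G - 1) / (N - 1)
#'
#' Scaled count of distinct lineages among sampled shoots: 0 when all samples
#' are one genet, 1 when every sample is unique. Also applied with effective
#' numbers of MLLs in place of `G` (Shannon- and Simpson-based richness).
#'
#' @param G number (or effective number) of MLLs.
#' @param N number of genotyped samples (>= 2).
#' @return richness in `[0, 1]`.
#' @export
genotypic_richness <- function(G, N) {
  if (N < 2) stop("richness undefined for N < 2")
  if (G > N * (1 + 1e-9)) stop("G cannot exceed N")
  (min(G, N) - 1) / (N - 1)
}

#' Shannon/Simpson indices and effective numbers of MLLs
#'
#' @param counts positive integer abundances (ramets per MLL).
#' @return list with `H` (Shannon, nats), `lambda` (Simpson
#'   \eqn{\sum p_i^2}), `eff_shannon` (`exp(H)`), `eff_simpson`
#'   (`1 / lambda`).
#' @export
effective_numbers <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty abundance vector")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  lambda <- sum(p^2)
  list(H = H, lambda = lambda, eff_shannon = exp(H), eff_simpson = 1 / lambda)
}

#' Pareto beta of the clonal size distribution
#'
#' Negative OLS slope of `log(N >= x)` against `log(x)` over the observed
#' clone sizes `x` (reverse cumulative distribution). Small beta indicates
#' dominance by large clones. Undefined (NA with `defined = FALSE`) when all
#' clones have the same size — including the all-singleton and single-clone
#' cases.
#'
#' @param counts positive integer abundances (ramets per MLL).
#' @return list with `beta`, `defined`.
#' @export
pareto_beta <- function(counts) {
  counts <- counts[counts > 0]
  x <- sort(unique(counts))
  if (length(x) < 2L) return(list(beta = NA_real_, defined = FALSE))
  n_ge <- vapply(x, function(k) sum(counts >= k), numeric(1))
  fit <- stats::lm.fit(cbind(1, log(x)), log(n_ge))
  list(beta = -unname(fit$coefficients[2]), defined = TRUE)
}

#' Genotypic diversity statistics for one scope
#'
#' @param mll_labels vector of MLL labels, one per sample in the scope.
#' @return one-row data frame: N, G, R, H, lambda, effective numbers,
#'   effective-number richness variants, Pareto beta.
#' @export
genotypic_stats <- function(mll_labels) {
  mll_labels <- mll_labels[!is.na(mll_labels)]
  N <- length(mll_labels)
  counts <- as.numeric(table(mll_labels))
  G <- length(counts)
  en <- effective_numbers(counts)
  pb <- pareto_beta(counts)
  data.frame(
    N = N, G = G,
    R = if (N >= 2) genotypic_richness(G, N) else NA_real_,
    H_shannon = en$H, lambda_simpson = en$lambda,
    eff_shannon = en$eff_shannon, eff_simpson = en$eff_simpson,
    R_shannon = if (N >= 2) genotypic_richness(en$eff_shannon, N) else NA_real_,
    R_simpson = if (N >= 2) genotypic_richness(en$eff_simpson, N) else NA_real_,
    pareto_beta = pb$beta, pareto_defined = pb$defined)
}

#' Rarefied genotypic diversity
#'
#' Mean of each genotypic statistic over repeated subsamples of fixed size
#' drawn without replacement, controlling for unequal site sample sizes.
#'
#' @param mll_labels vector of MLL labels, one per sample.
#' @param n_raref subsample size (default 5, the smallest site sample size
#'   of the emulated design).
#' @param n_reps number of subsamples (default 1000).
#' @return one-row data frame of rarefied means (columns as
#'   [genotypic_stats()], Pareto beta averaged over subsamples where defined).
#' @export
rarefy_genotypic <- function(mll_labels, n_raref = 5L, n_reps = 1000L) {
  mll_labels <- mll_labels[!is.na(mll_labels)]
  N <- length(mll_labels)
  if (n_raref > N) stop("n_raref exceeds sample count")
  acc <- NULL
  for (k in seq_len(n_reps)) {
    s <- genotypic_stats(mll_labels[sample.int(N, n_raref)])
    acc <- if (is.null(acc)) s else rbind(acc, s)
  }
  out <- as.data.frame(lapply(acc[, c("N", "G", "R", "H_shannon",
                                      "lambda_simpson", "eff_shannon",
                                      "eff_simpson", "R_shannon",
                                      "R_simpson")], mean))
  out$pareto_beta <- if (any(acc$pareto_defined))
    mean(acc$pareto_beta[acc$pareto_defined]) else NA_real_
  out$prop_pareto_defined <- mean(acc$pareto_defined)
  out
}

#' Spatial extents of multi-sample MLLs
#'
#' @param assignment a collapsed `clonal_assignment`.
#' @param sample_dist sample-by-sample distance matrix (m), typically the
#'   combined (max of Euclidean and water-cost) matrix.
#' @return data frame: `mll_id`, `n_samples`, `n_sites`, `max_extent_m`.
#' @export
clone_extents <- function(assignment, sample_dist) {
  gt <- assignment$gt
  n_mll <- length(assignment$mll_members)
  out <- data.frame(mll_id = names(assignment$mll_members),
                    n_samples = NA_integer_, n_sites = NA_integer_,
                    max_extent_m = NA_real_)
  for (k in seq_len(n_mll)) {
    members <- assignment$mll_members[[k]]
    idx <- match(members, gt$sample_id)
    out$n_samples[k] <- length(members)
    out$n_sites[k] <- length(unique(gt$site_id[idx]))
    out$max_extent_m[k] <- if (length(members) > 1L)
      max(sample_dist[members, members]) else 0
  }
  out
}
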