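# Two-group permutation contrasts of site-level statistics between tidal
# regimes.

#' Permutation test of a site statistic between two regimes
#'
#' Statistic: absolute difference of regime means. Values are permuted across
#' sites with group sizes held fixed; the p-value is the proportion of
#' permuted differences strictly larger than the observed one (so the
#' minimum attainable Monte-Carlo p is 0; `exceeds_all_permutations` conveys
#' that case). Sites with missing values are dropped pairwise.
#'
#' @param values numeric site-statistic vector.
#' @param regime two-level label vector aligned with `values`.
#' @param n_perm permutations (default 10000).
#' @return list: `mean_by_group` (named), `delta_obs`, `p`,
#'   `exceeds_all_permutations`, `n_perm`, `n_sites`.
#' @export
regime_permutation_test <- function(values, regime, n_perm = 10000L) {
  ok <- !is.na(values)
  values <- values[ok]; regime <- as.character(regime)[ok]
  lev <- sort(unique(regime))
  if (length(lev) != 2L) stop("need exactly two regimes with data")
  n1 <- sum(regime == lev[1])
  if (n1 < 2L || length(values) - n1 < 2L)
    stop("each regime needs >= 2 sites with values")
  mg <- tapply(values, regime, mean)
  delta <- abs(mg[lev[1]] - mg[lev[2]])
  n <- length(values)
  if (delta == 0) {
    # a zero observed difference is never evidence: every permutation ties it
    return(list(mean_by_group = mg, delta_obs = 0, p = 1,
                exceeds_all_permutations = FALSE, n_perm = n_perm,
                n_sites = n))
  }
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    d <- abs(mean(values[idx]) - mean(values[-idx]))
    if (d > delta) cnt <- cnt + 1L
  }
  list(mean_by_group = mg, delta_obs = unname(delta), p = cnt / n_perm,
       exceeds_all_permutations = cnt == 0L, n_perm = n_perm, n_sites = n)
}

#' Regime-contrast battery over a site-statistics table
#'
#' Applies [regime_permutation_test()] to each named statistic column.
#'
#' @param site_stats data frame with one row per site, containing a `regime`
#'   column plus statistic columns.
#' @param statistics character vector of column names to test (default: all
#'   numeric columns except `regime`).
#' @param n_perm permutations per statistic (default 10000).
#' @return data frame: one row per statistic with group means, observed
#'   absolute difference, p, and the exceeds-all flag. Statistics that
#'   cannot be tested (too few sites with values) are skipped.
#' @export
regime_test_battery <- function(site_stats, statistics = NULL,
                                n_perm = 10000L) {
  if (is.null(statistics))
    statistics <- names(site_stats)[vapply(site_stats, is.numeric,
                                           logical(1))]
  statistics <- setdiff(statistics, c("n", "n_sites"))
  rows <- list()
  for (st in statistics) {
    res <- try(regime_permutation_test(site_stats[[st]], site_stats$regime,
                                       n_perm = n_perm), silent = TRUE)
    if (inherits(res, "try-error")) next
    lev <- names(res$mean_by_group)
    rows[[st]] <- data.frame(
      statistic = st,
      mean_1 = res$mean_by_group[1], group_1 = lev[1],
      mean_2 = res$mean_by_group[2], group_2 = lev[2],
      delta_obs = res$delta_obs, p = res$p,
      exceeds_all_permutations = res$exceeds_all_permutations,
      n_sites = res$n_sites, row.names = NULL)
  }
  do.call(rbind, rows)
}
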