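# End-to-end orchestration: distances -> clone discrimination -> diversity,
# relatedness, differentiation, IBD, ordination, regime contrasts.

#' Analysis configuration with survey defaults
#'
#' All thresholds and replicate counts in one place: psex clonality threshold
#' 0.001; MLL collapse distance 1 allele; 999 Mantel permutations; 1000
#' group-relatedness shuffles; 1000 bootstrap replicates; 10,000 regime
#' permutations; rarefaction to n = 5 samples and g = 15 gene copies.
#'
#' @param ... named overrides.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    psex_threshold = 0.001,
    mll_distance_threshold = 1L,
    n_perm_mantel = 999L,
    n_shuffles_grouprel = 1000L,
    n_boot = 1000L,
    n_perm_regime = 10000L,
    rarefaction_n = 5L,
    rarefaction_reps = 1000L,
    rarefaction_g = 15L,
    accumulation_reps = 100L,
    compute_relatedness = TRUE,
    compute_ca = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Run the full riverscape clonal-diversity analysis
#'
#' Sequences: site distances (Euclidean, water-cost when a raster is given,
#' and their entrywise max) -> MLG assignment and MLL collapse with psex ->
#' genotypic diversity with rarefaction -> Wang relatedness with r_W/r_A and
#' regime shuffling -> per-site locus diversity with clone-corrected deltas
#' -> global differentiation (theta, G''ST, D_est) with bootstrap CIs ->
#' chord distance and Mantel IBD (all sites and per regime) ->
#' correspondence analysis -> Spearman correlations with river km -> regime
#' permutation battery.
#'
#' @param gt a [genotype_table()].
#' @param sites a `site_meta` data frame covering all sites of `gt`.
#' @param grid optional `water_grid`; without it distances are
#'   Euclidean-only (with a warning) and combined = Euclidean.
#' @param config an [analysis_config()].
#' @param seed integer seed recorded in the provenance block and applied
#'   before the stochastic stages.
#' @return list of class `stats_report`.
#' @export
run_full_analysis <- function(gt, sites, grid = NULL,
                              config = analysis_config(), seed = 1L) {
  sites <- site_meta(as.data.frame(sites), gt = gt)
  set.seed(seed)
  report <- list(provenance = list(
    seed = seed, config = unclass(config), n_samples = n_samples(gt),
    n_sites = nrow(sites), n_loci = n_loci(gt)))

  # --- distances among site centroids
  pts <- data.frame(id = sites$site_id, x = sites$x, y = sites$y)
  euc <- euclidean_distance(pts)
  if (is.null(grid)) {
    warning("no water raster supplied: Euclidean-only distances")
    combined <- euc
    cost <- NULL
  } else {
    cost <- cost_distance(grid, pts, snap = TRUE)
    combined <- combined_distance(euc, cost)
  }
  report$distances <- list(euclidean = euc, cost = cost, combined = combined)

  # --- clone discrimination
  assignment <- assign_mlgs(gt)
  assignment <- collapse_to_mlls(assignment,
                                 threshold = config$mll_distance_threshold)
  report$assignment <- assignment
  report$provenance$n_mlg <- nrow(assignment$mlg_profile)
  report$provenance$n_mll <- length(assignment$mll_members)
  report$provenance$n_ambiguous <- length(assignment$ambiguous)

  smpl_sites <- data.frame(id = gt$sample_id, x = sites$x[match(
    gt$site_id, sites$site_id)], y = sites$y[match(gt$site_id,
                                                   sites$site_id)])
  sample_dist <- combined[gt$site_id, gt$site_id]
  dimnames(sample_dist) <- list(gt$sample_id, gt$sample_id)
  report$mll_registry <- mll_registry(assignment, sample_dist = sample_dist,
                                      psex_threshold = config$psex_threshold)
  report$clone_extents <- clone_extents(assignment, sample_dist)

  # --- genotypic diversity per scope and site
  mll <- assignment$mll_id[gt$sample_id]
  regime_of_sample <- sites$regime[match(gt$site_id, sites$site_id)]
  scopes <- list(river = rep(TRUE, n_samples(gt)),
                 nontidal = regime_of_sample == "nontidal",
                 tidal = regime_of_sample == "tidal")
  gscope <- do.call(rbind, lapply(names(scopes), function(sc) {
    rows <- scopes[[sc]] & !is.na(mll)
    if (sum(rows) < 2L) return(NULL)
    cbind(scope = sc, genotypic_stats(mll[rows]))
  }))
  report$genotypic_scope <- gscope

  gsite <- do.call(rbind, lapply(sites$site_id, function(s) {
    rows <- gt$site_id == s & !is.na(mll)
    if (sum(rows) < 2L) return(NULL)
    st <- cbind(site_id = s, genotypic_stats(mll[rows]))
    if (sum(rows) >= config$rarefaction_n) {
      rar <- rarefy_genotypic(mll[rows], n_raref = config$rarefaction_n,
                              n_reps = config$rarefaction_reps)
      st$R_rarefied <- rar$R
      st$eff_shannon_rarefied <- rar$eff_shannon
    } else {
      st$R_rarefied <- NA_real_; st$eff_shannon_rarefied <- NA_real_
    }
    st
  }))
  gsite$regime <- sites$regime[match(gsite$site_id, sites$site_id)]
  report$genotypic_site <- gsite

  # --- relatedness
  if (config$compute_relatedness) {
    rmat <- wang_r_matrix(gt)$r
    rel_site <- within_among_summaries(rmat, gt$site_id, regime_of_sample)
    # clone-corrected variant: one representative per MLL per site
    cc <- clone_correct(gt, assignment)
    rmat_cc <- wang_r_matrix(cc)$r
    rel_site_cc <- within_among_summaries(
      rmat_cc, cc$site_id, sites$regime[match(cc$site_id, sites$site_id)])
    names(rel_site_cc)[names(rel_site_cc) %in% c("r_w", "r_a")] <-
      c("r_w_mll", "r_a_mll")
    rel_site <- merge(rel_site, rel_site_cc[, c("site_id", "r_w_mll",
                                                "r_a_mll")], by = "site_id")
    report$relatedness_site <- rel_site
    report$grouprel <- group_relatedness_test(
      rmat, regime_of_sample, n_shuffles = config$n_shuffles_grouprel)
  }

  # --- locus diversity with clone correction
  report$locus_site <- locus_diversity_table(
    gt, assignment, g_rarefaction = config$rarefaction_g,
    n_boot = config$n_boot)
  report$locus_site$regime <- sites$regime[match(report$locus_site$site_id,
                                                 sites$site_id)]

  # --- differentiation
  multi <- names(which(table(gt$site_id) >= 2))
  rows <- gt$site_id %in% multi
  sub <- genotype_table(gt$calls[rows, , drop = FALSE], gt$sample_id[rows],
                        gt$site_id[rows], gt$loci)
  diff_global <- differentiation_stats(sub, sub$site_id)
  boot_theta <- differentiation_bootstrap(sub, sub$site_id, "theta",
                                          unit = "loci",
                                          n_boot = config$n_boot)
  report$differentiation_global <- list(
    theta = diff_global$theta, gst_hedrick = diff_global$gst_hedrick,
    d_est = diff_global$d_est, H_S = diff_global$H_S, H_T = diff_global$H_T,
    k = diff_global$k,
    theta_ci = c(boot_theta$lower, boot_theta$upper))

  # --- chord distance + Mantel IBD per scope
  report$chord <- chord_distance_matrix(gt)
  geo <- combined[rownames(report$chord), colnames(report$chord)]
  report$mantel <- list()
  for (sc in c("all", "nontidal", "tidal")) {
    ids <- if (sc == "all") sites$site_id
      else sites$site_id[sites$regime == sc]
    ids <- intersect(ids, rownames(report$chord))
    if (length(ids) >= 4L && all(is.finite(geo[ids, ids])))
      report$mantel[[sc]] <- mantel_test(geo[ids, ids],
                                         report$chord[ids, ids],
                                         n_perm = config$n_perm_mantel)
  }

  # --- correspondence analysis
  if (config$compute_ca)
    report$ca <- correspondence_analysis(site_allele_table(gt))

  # --- site-statistic table for river-km and regime contrasts
  stats_tab <- merge(gsite[, c("site_id", "regime", "R", "eff_shannon",
                               "eff_simpson", "R_shannon", "R_simpson",
                               "pareto_beta")],
                     report$locus_site[, c("site_id", "P", "A", "A_r", "H_o",
                                           "H_s", "F_IS", "F_IS_var")],
                     by = "site_id")
  if (config$compute_relatedness)
    stats_tab <- merge(stats_tab, report$relatedness_site[, c("site_id",
                                                              "r_w", "r_a")],
                       by = "site_id")
  stats_tab$river_km <- sites$river_km[match(stats_tab$site_id,
                                             sites$site_id)]
  report$site_stats <- stats_tab

  report$spearman <- lapply(
    setdiff(names(stats_tab), c("site_id", "regime", "river_km")),
    function(st) {
      res <- try(spearman_vs_riverkm(stats_tab[[st]], stats_tab$river_km),
                 silent = TRUE)
      if (inherits(res, "try-error")) NULL else c(statistic = st, res)
    })
  report$spearman <- report$spearman[!vapply(report$spearman, is.null,
                                             logical(1))]

  report$regime_tests <- regime_test_battery(
    stats_tab[, setdiff(names(stats_tab), c("site_id", "river_km"))],
    n_perm = config$n_perm_regime)

  class(report) <- "stats_report"
  report
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report:", x$provenance$n_samples, "samples,",
      x$provenance$n_sites, "sites,", x$provenance$n_loci, "loci\n")
  cat("  MLGs:", x$provenance$n_mlg, " MLLs:", x$provenance$n_mll,
      " ambiguous:", x$provenance$n_ambiguous, "\n")
  d <- x$differentiation_global
  cat(sprintf("  theta = %.4f  G''ST = %.4f  D_est = %.4f\n",
              d$theta, d$gst_hedrick, d$d_est))
  invisible(x)
}
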