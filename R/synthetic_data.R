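# Synthetic riverscape, genotypes and pedigree pairs with the statistical
# structure the analysis assumes: regime-dependent clonality, uneven clone
# sizes, drift-induced isolation by distance, and a water-constrained
# corridor raster.

#' Simulation configuration
#'
#' Presets: `"survey"` emulates a two-regime river survey (24 nontidal +
#' 12 tidal sites spanning river km 462 down to 89, 10 microsatellite loci
#' with 5-13 alleles, ~26 shoots per site, strong nontidal clonality
#' `c = 0.75` vs near-zero tidal `c = 0.05`, two widespread nontidal clones);
#' `"tiny"` is a 4-site smoke-test scale.
#'
#' @param preset `"survey"` or `"tiny"`.
#' @param ... named overrides of any field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(preset = c("survey", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_sites_nontidal = 24L, n_sites_tidal = 12L,
    river_km_max = 462, river_km_min = 89,
    L = 10L, alleles_min = 5L, alleles_max = 13L,
    c_nontidal = 0.75, c_tidal = 0.05,
    n_widespread = 2L, widespread_span = 15L, widespread_bias = 3L,
    drift_sd = 0.18,
    concentration_nontidal = 4, concentration_tidal = 2,
    dominant_het_bias = TRUE,
    samples_per_site = 26L,
    missing_rate = 0.005,
    corridor_width = 5L, cell_size = 500, meander_amplitude = 8L,
    barrier = FALSE)
  if (preset == "tiny") {
    cfg$n_sites_nontidal <- 2L; cfg$n_sites_tidal <- 2L
    cfg$samples_per_site <- 8L
    cfg$n_widespread <- 0L
    cfg$river_km_max <- 120; cfg$river_km_min <- 90
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$corridor_width < 1L) stop("corridor width must be >= 1 cell")
  if (any(unlist(cfg[c("c_nontidal", "c_tidal", "missing_rate")]) < 0) ||
      any(unlist(cfg[c("c_nontidal", "c_tidal", "missing_rate")]) > 1))
    stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Simulate the riverscape: site metadata and water raster
#'
#' A meandering water corridor through land, with sites placed in-channel at
#' evenly spaced river-km positions, nontidal sites upstream of tidal ones.
#' With `barrier = TRUE`, a land band severs the corridor between the two
#' regimes (fall-line analog), making cross-regime cost distances infinite.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list: `sites` (a `site_meta` data frame), `grid` (a `water_grid`),
#'   `site_cells` (row/col of each site's cell).
#' @export
simulate_riverscape <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- cfg$n_sites_nontidal + cfg$n_sites_tidal
  span_m <- (cfg$river_km_max - cfg$river_km_min) * 1000
  ncols <- ceiling(span_m / cfg$cell_size) + 20L
  amp <- cfg$meander_amplitude
  nrows <- 2L * amp + cfg$corridor_width + 10L
  m <- matrix(0, nrows, ncols)
  center <- function(col)
    round(nrows / 2 + amp * sin(2 * pi * col / (ncols / 3)))
  half <- floor(cfg$corridor_width / 2)
  for (col in seq_len(ncols)) {
    rc <- center(col)
    rows <- max(1L, rc - half):min(nrows, rc + half)
    m[rows, col] <- 1
    if (col > 1L) {       # keep the channel 8-connected across meanders
      rc_prev <- center(col - 1L)
      rows <- max(1L, min(rc, rc_prev) - half):min(nrows,
                                                   max(rc, rc_prev) + half)
      m[rows, col] <- 1
    }
  }
  # upstream = high river km = left edge; downstream/tidal = right
  km <- seq(cfg$river_km_max, cfg$river_km_min, length.out = S)
  site_col <- 10L + round((cfg$river_km_max - km) * 1000 / cfg$cell_size)
  regime <- c(rep("nontidal", cfg$n_sites_nontidal),
              rep("tidal", cfg$n_sites_tidal))
  if (cfg$barrier) {
    bcol <- round(mean(site_col[c(cfg$n_sites_nontidal,
                                  cfg$n_sites_nontidal + 1L)]))
    m[, bcol] <- 0
  }
  grid <- water_grid(m, xll = 0, yll = 0, cell_size = cfg$cell_size)
  site_row <- vapply(site_col, center, numeric(1))
  ctr <- .cell_center(grid, site_row, site_col)
  sites <- site_meta(data.frame(
    site_id = sprintf("S%02d", seq_len(S)),
    x = ctr[, 1], y = ctr[, 2], river_km = km, regime = regime,
    year = rep(c(2011L, 2013L), length.out = S)))
  list(sites = sites, grid = grid,
       site_cells = cbind(row = site_row, col = site_col))
}

# one HWE genotype (2L vector) from per-locus frequency list
.hwe_draw <- function(freqs) {
  unlist(lapply(freqs, function(f) {
    a <- sample(as.integer(names(f)), 2L, replace = TRUE, prob = f)
    sort(a)
  }))
}

# heterozygous-biased genotype: two distinct alleles per polymorphic locus
# (emulates the fixed heterozygosity of persistent dominant clones)
.het_draw <- function(freqs) {
  unlist(lapply(freqs, function(f) {
    if (length(f) < 2L) return(rep(as.integer(names(f)), 2L))
    a <- sample(as.integer(names(f)), 2L, replace = FALSE, prob = f)
    sort(a)
  }))
}

#' Simulate genotypes along the riverscape
#'
#' Ancestral allele frequencies per locus are Dirichlet draws over 5-13
#' alleles; site frequencies evolve by a logistic-normal random walk along
#' the river order (per-step standard deviation `drift_sd` on the log scale),
#' inducing isolation by distance. Within a site, each sampled shoot is,
#' with probability `c(regime)`, a ramet of an existing local genet chosen
#' proportionally to its current ramet count (rich-get-richer, producing
#' uneven clone-size spectra); otherwise a new genet drawn by
#' Hardy-Weinberg from the site frequencies. Configured widespread clones
#' are seeded with a head-start weight into a span of nontidal sites.
#' Missing calls are injected per locus-call at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param sites `site_meta` from [simulate_riverscape()].
#' @param seed optional integer seed.
#' @return list: `gt` (a `genotype_table`), `truth` (data frame `sample_id`,
#'   `genet_id`), `site_freqs` (per-site frequency lists), `coords`
#'   (per-sample x/y jittered near the site).
#' @export
simulate_genotypes <- function(cfg, sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(sites)
  L <- cfg$L
  loci <- sprintf("loc%02d", seq_len(L))
  anc <- lapply(seq_len(L), function(l) {
    k <- sample(cfg$alleles_min:cfg$alleles_max, 1L)
    f <- stats::rgamma(k, 1)
    f <- f / sum(f)
    names(f) <- as.character(100L + 2L * seq_len(k))
    f
  })
  # logistic-normal walk along river order
  site_freqs <- vector("list", S)
  prev <- lapply(anc, log)
  for (s in seq_len(S)) {
    prev <- lapply(prev, function(lf)
      lf + stats::rnorm(length(lf), 0, cfg$drift_sd))
    # regime-dependent concentration: long-clonal (nontidal) reaches hold
    # skewed, allele-poor local gene pools; exponent > 1 sharpens freqs
    alpha <- if (sites$regime[s] == "nontidal") cfg$concentration_nontidal
      else cfg$concentration_tidal
    site_freqs[[s]] <- lapply(prev, function(lf) {
      f <- exp(alpha * (lf - max(lf))); f <- f / sum(f)
      names(f) <- names(lf)
      f
    })
    names(site_freqs[[s]]) <- loci
  }
  names(site_freqs) <- sites$site_id

  # widespread clones: genets seeded across a span of nontidal sites
  nons <- which(sites$regime == "nontidal")
  widespread <- list()
  if (cfg$n_widespread > 0L) {
    if (!length(nons)) stop("widespread clones require nontidal sites")
    for (w in seq_len(cfg$n_widespread)) {
      start <- sample(seq_len(max(1L, length(nons) - cfg$widespread_span +
                                    1L)), 1L)
      span <- nons[start:min(length(nons), start + cfg$widespread_span - 1L)]
      origin <- span[ceiling(length(span) / 2)]
      widespread[[w]] <- list(
        genet_id = sprintf("WSP%02d", w),
        genotype = if (cfg$dominant_het_bias)
          .het_draw(site_freqs[[origin]]) else .hwe_draw(site_freqs[[origin]]),
        sites = sites$site_id[span])
    }
  }

  sample_id <- site_id <- genet_id <- character(0)
  calls <- NULL
  xs <- ys <- numeric(0)
  genet_counter <- 0L
  for (s in seq_len(S)) {
    regime <- sites$regime[s]
    cprob <- if (regime == "nontidal") cfg$c_nontidal else cfg$c_tidal
    pool_id <- character(0); pool_geno <- list(); pool_count <- numeric(0)
    for (w in seq_along(widespread)) {
      if (sites$site_id[s] %in% widespread[[w]]$sites) {
        pool_id <- c(pool_id, widespread[[w]]$genet_id)
        pool_geno[[length(pool_geno) + 1L]] <- widespread[[w]]$genotype
        pool_count <- c(pool_count, cfg$widespread_bias)
      }
    }
    for (i in seq_len(cfg$samples_per_site)) {
      clonal <- length(pool_id) > 0L && stats::runif(1) < cprob
      if (clonal) {
        j <- sample.int(length(pool_id), 1L, prob = pool_count)
        gid <- pool_id[j]
        geno <- pool_geno[[j]]
        pool_count[j] <- pool_count[j] + 1
      } else {
        genet_counter <- genet_counter + 1L
        gid <- sprintf("G%05d", genet_counter)
        # the first local genet of a clonal (nontidal) site is het-biased:
        # persistent dominant clones show fixed heterozygosity
        first_local <- !any(startsWith(pool_id, "G"))
        geno <- if (cfg$dominant_het_bias && regime == "nontidal" &&
                      first_local)
          .het_draw(site_freqs[[s]]) else .hwe_draw(site_freqs[[s]])
        pool_id <- c(pool_id, gid)
        pool_geno[[length(pool_geno) + 1L]] <- geno
        pool_count <- c(pool_count, 1)
      }
      sample_id <- c(sample_id, sprintf("%s_%03d", sites$site_id[s], i))
      site_id <- c(site_id, sites$site_id[s])
      genet_id <- c(genet_id, gid)
      calls <- rbind(calls, geno)
      xs <- c(xs, sites$x[s] + stats::runif(1, -50, 50))
      ys <- c(ys, sites$y[s] + stats::runif(1, -50, 50))
    }
  }
  if (cfg$missing_rate > 0) {
    n <- nrow(calls)
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    for (l in seq_len(L)) {
      calls[miss[, l], 2L * l - 1L] <- NA_integer_
      calls[miss[, l], 2L * l] <- NA_integer_
    }
  }
  gt <- genotype_table(calls, sample_id, site_id, loci)
  list(gt = gt,
       truth = data.frame(sample_id = sample_id, genet_id = genet_id),
       site_freqs = site_freqs,
       coords = data.frame(id = sample_id, x = xs, y = ys))
}

#' Simulate genotype pairs of known kinship
#'
#' Mendelian sampling from Hardy-Weinberg parents: clones (identical
#' genotypes), parent-offspring, full sibs, half sibs and unrelated pairs,
#' for validating relatedness estimators.
#'
#' @param n_pairs pairs per relationship class (default 500).
#' @param L loci (default 10).
#' @param n_alleles alleles per locus, equifrequent (default 8).
#' @param classes subset of `c("clone", "parent_offspring", "full_sib",
#'   "half_sib", "unrelated")`.
#' @param seed optional integer seed.
#' @return list: `a`, `b` (genotype tables; row i of each is pair i),
#'   `relationship` (factor per pair).
#' @export
simulate_pedigree_pairs <- function(n_pairs = 500L, L = 10L, n_alleles = 8L,
                                    classes = c("clone", "parent_offspring",
                                                "full_sib", "half_sib",
                                                "unrelated"),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- lapply(seq_len(L), function(l) {
    f <- rep(1 / n_alleles, n_alleles)
    names(f) <- as.character(100L + 2L * seq_len(n_alleles))
    f
  })
  names(freqs) <- sprintf("loc%02d", seq_len(L))
  gamete <- function(geno) {
    vapply(seq_len(L), function(l)
      geno[2L * l - 2L + sample.int(2L, 1L)], integer(1))
  }
  child <- function(p1, p2) {
    g1 <- gamete(p1); g2 <- gamete(p2)
    unlist(lapply(seq_len(L), function(l) sort(c(g1[l], g2[l]))))
  }
  rel <- rep(classes, each = n_pairs)
  A <- B <- matrix(NA_integer_, length(rel), 2L * L)
  for (i in seq_along(rel)) {
    switch(rel[i],
      clone = {
        g <- .hwe_draw(freqs); A[i, ] <- g; B[i, ] <- g
      },
      parent_offspring = {
        p1 <- .hwe_draw(freqs); p2 <- .hwe_draw(freqs)
        A[i, ] <- p1; B[i, ] <- child(p1, p2)
      },
      full_sib = {
        p1 <- .hwe_draw(freqs); p2 <- .hwe_draw(freqs)
        A[i, ] <- child(p1, p2); B[i, ] <- child(p1, p2)
      },
      half_sib = {
        p1 <- .hwe_draw(freqs); p2 <- .hwe_draw(freqs); p3 <- .hwe_draw(freqs)
        A[i, ] <- child(p1, p2); B[i, ] <- child(p1, p3)
      },
      unrelated = {
        A[i, ] <- .hwe_draw(freqs); B[i, ] <- .hwe_draw(freqs)
      })
  }
  loci <- names(freqs)
  n <- length(rel)
  list(a = genotype_table(A, sprintf("a%04d", seq_len(n)),
                          rep("pairs", n), loci),
       b = genotype_table(B, sprintf("b%04d", seq_len(n)),
                          rep("pairs", n), loci),
       relationship = factor(rel, levels = classes))
}

#' Wang relatedness for labelled pairs
#'
#' Convenience wrapper: estimates r for each (a_i, b_i) pair from
#' [simulate_pedigree_pairs()], using the pooled pair members as the
#' allele-frequency reference set.
#'
#' @param pairs result of [simulate_pedigree_pairs()].
#' @return numeric vector of r estimates, one per pair.
#' @export
wang_r_pairs <- function(pairs) {
  n <- n_samples(pairs$a)
  L <- length(pairs$a$loci)
  pooled <- genotype_table(rbind(pairs$a$calls, pairs$b$calls),
                           c(pairs$a$sample_id, pairs$b$sample_id),
                           rep("pairs", 2L * n), pairs$a$loci)
  coefs <- .wang_coefficients(pooled)
  .wang_r_vector(pooled$calls, seq_len(n), n + seq_len(n), coefs)$r
}
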