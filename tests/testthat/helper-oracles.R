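# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: plain loops, explicit enumeration, or a different
# library, so that agreement is informative.

# --- quick genotype-table builder from a list of per-sample allele vectors
make_gt <- function(rows, site = NULL, loci = NULL) {
  m <- do.call(rbind, rows)
  L <- ncol(m) / 2
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(site)) site <- rep("s1", nrow(m))
  genotype_table(m, paste0("ind", seq_len(nrow(m))), site, loci)
}

# --- explicit-edge-list Dijkstra on a water grid (no igraph)
oracle_cost_dist <- function(grid, cells) {
  m <- grid$conductance
  nr <- nrow(m); nc <- ncol(m)
  id <- function(r, c) (c - 1L) * nr + r
  # adjacency lists
  nbr <- vector("list", nr * nc)
  wts <- vector("list", nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] != 1) next
    ns <- integer(0); ws <- numeric(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (m[r2, c2] != 1) next
      ns <- c(ns, id(r2, c2))
      ws <- c(ws, grid$cell_size * sqrt(abs(dr) + abs(dc)))
    }
    nbr[[id(r, c)]] <- ns
    wts[[id(r, c)]] <- ws
  }
  src <- id(cells[, 1], cells[, 2])
  n_pts <- length(src)
  out <- matrix(Inf, n_pts, n_pts)
  for (k in seq_len(n_pts)) {
    dist <- rep(Inf, nr * nc)
    done <- rep(FALSE, nr * nc)
    dist[src[k]] <- 0
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      ns <- nbr[[u]]
      if (length(ns)) {
        alt <- dist[u] + wts[[u]]
        upd <- alt < dist[ns]
        dist[ns[upd]] <- alt[upd]
      }
    }
    out[k, ] <- dist[src]
  }
  out
}

# --- scalar straight-from-the-equations Wang estimator for one pair.
# freqs: list of named per-locus frequency vectors of the reference set;
# n_genes: gene copies behind each frequency vector.
oracle_wang_scalar <- function(a, b, freqs, n_genes) {
  L <- length(freqs)
  P1 <- P2 <- P3 <- bb <- cc <- dd <- ee <- ff <- gg <- ww <- numeric(0)
  for (l in seq_len(L)) {
    ia <- a[c(2 * l - 1, 2 * l)]; ib <- b[c(2 * l - 1, 2 * l)]
    if (anyNA(ia) || anyNA(ib)) next
    p <- as.numeric(freqs[[l]])
    n <- n_genes[l]
    s2 <- sum(p^2); s3 <- sum(p^3); s4 <- sum(p^4)
    a2 <- (n * s2 - 1) / (n - 1)
    a3 <- (n^2 * s3 - 3 * (n - 1) * a2 - 1) / ((n - 1) * (n - 2))
    a4 <- (n^3 * s4 - 6 * (n - 1) * (n - 2) * a3 - 7 * (n - 1) * a2 - 1) /
      ((n - 1) * (n - 2) * (n - 3))
    # similarity category of the pair at this locus
    shared <- 0
    y <- ib
    for (al in ia) {
      j <- match(al, y)
      if (!is.na(j)) { y <- y[-j]; shared <- shared + 1 }
    }
    ident <- shared == 2
    homa <- ia[1] == ia[2]; homb <- ib[1] == ib[2]
    P1 <- c(P1, as.numeric(ident))
    P2 <- c(P2, as.numeric(!ident & shared >= 1 & (homa || homb)))
    P3 <- c(P3, as.numeric(!ident & shared >= 1 & !homa & !homb))
    bb <- c(bb, 2 * a2^2 - a4)
    cc <- c(cc, a2 - 2 * a2^2 + a4)
    dd <- c(dd, 4 * (a3 - a4))
    ee <- c(ee, 2 * (a2 - 3 * a3 + 2 * a4))
    ff <- c(ff, 4 * (a2 - a2^2 - 2 * a3 + 2 * a4))
    gg <- c(gg, 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4)
    ww <- c(ww, 1 / (2 * a2 - a3))
  }
  if (!length(ww)) return(NA_real_)
  w <- ww / sum(ww)
  P1 <- sum(w * P1); P2 <- sum(w * P2); P3 <- sum(w * P3)
  b <- sum(w * bb); c <- sum(w * cc); d <- sum(w * dd)
  e <- sum(w * ee); f <- sum(w * ff); g <- sum(w * gg)
  # denominator in its expanded (alternative) algebraic arrangement
  V <- (1 - b)^2 * (e^2 * f + d * g^2) - (1 - b) * (e * f - d * g)^2 +
    2 * c * d * f * (1 - b) * (g + e) + c^2 * d * f * (d + f)
  phi <- (d * f * ((e + g) * (1 - b) + c * (d + f)) * (P1 - 1) +
            d * (1 - b) * (g * (1 - b - d) + f * (c + e)) * P3 +
            f * (1 - b) * (e * (1 - b - f) + d * (c + g)) * P2) / V
  A <- c * d * f * (e + g) + (1 - b) * (f * e^2 + d * g^2) -
    (e * f - d * g)^2
  B <- c * f * (b * e - c * d - d * g + e * f - e)
  C <- c * d * (b * g - c * f + d * g - e * f - g)
  delta <- (A * P1 + B * P2 + C * P3 - (A * b + B * d + C * f)) / V
  phi / 2 + delta
}

# allele frequencies + gene-copy counts of a genotype table, plain loops
oracle_freqs <- function(gt) {
  L <- length(gt$loci)
  freqs <- vector("list", L)
  n_genes <- integer(L)
  for (l in seq_len(L)) {
    v <- c(gt$calls[, 2 * l - 1], gt$calls[, 2 * l])
    v <- v[!is.na(v)]
    tb <- table(v)
    freqs[[l]] <- as.numeric(tb) / sum(tb)
    names(freqs[[l]]) <- names(tb)
    n_genes[l] <- sum(tb)
  }
  list(freqs = freqs, n_genes = n_genes)
}

# --- Rand index between two partitions (vectors of labels)
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(matrix(0, n, n))]
  same_y <- outer(y, y, "==")[upper.tri(matrix(0, n, n))]
  mean(same_x == same_y)
}

# --- exhaustive regime-permutation p-value on a small site set
oracle_exhaustive_regime_p <- function(values, regime) {
  lev <- sort(unique(regime))
  n1 <- sum(regime == lev[1])
  obs <- abs(mean(values[regime == lev[1]]) - mean(values[regime == lev[2]]))
  combos <- utils::combn(length(values), n1)
  deltas <- apply(combos, 2, function(idx)
    abs(mean(values[idx]) - mean(values[-idx])))
  mean(deltas > obs)
}
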