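# Clone discrimination: multilocus genotypes (MLGs), collapse to multilocus
# lineages (MLLs), pgen/psex, and genotype accumulation curves.

locus_cols <- function(l) c(2L * l - 1L, 2L * l)

# genotype key over chosen loci; NA kept distinct ("." token)
.geno_key <- function(calls, loci_idx = NULL) {
  if (is.null(loci_idx)) cols <- seq_len(ncol(calls))
  else cols <- as.vector(vapply(loci_idx, locus_cols, integer(2)))
  m <- calls[, cols, drop = FALSE]
  m[is.na(m)] <- -1L
  apply(m, 1L, paste, collapse = "/")
}

#' Assign samples to multilocus genotypes (MLGs)
#'
#' Samples with complete genotypes are grouped by exact multilocus match.
#' Each sample with missing data is then compared against the existing MLGs
#' on its resolved loci: if it matches exactly one MLG it is merged into it;
#' if it matches several it is left unassigned (ambiguous) and excluded from
#' downstream analyses; if it matches none it founds a new MLG. Samples
#' missing at every locus are excluded with a warning.
#'
#' @param gt a [genotype_table()].
#' @return An object of class `clonal_assignment`: list with `mlg` (named
#'   integer vector, sample -> MLG index; `NA` for excluded samples),
#'   `mlg_profile` (MLG x 2L matrix of consensus calls), `ambiguous`
#'   (character vector of excluded sample ids), `flag_missing` (logical per
#'   MLG: founded or joined by a missing-data sample), plus the originating
#'   `gt`. The MLL layer (`mll`, `mll_members`) is added by
#'   [collapse_to_mlls()].
#' @export
assign_mlgs <- function(gt) {
  calls <- gt$calls
  n <- nrow(calls)
  L <- length(gt$loci)
  miss_locus <- is.na(calls[, seq(1L, 2L * L, by = 2L), drop = FALSE])
  n_miss <- rowSums(miss_locus)

  all_missing <- n_miss == L
  if (any(all_missing))
    warning(sum(all_missing), " sample(s) missing at all loci excluded: ",
            paste(gt$sample_id[all_missing], collapse = ", "))

  mlg <- rep(NA_integer_, n)
  names(mlg) <- gt$sample_id
  profiles <- NULL   # grows as a matrix of MLG consensus calls
  flag_missing <- logical(0)

  complete <- which(n_miss == 0L)
  if (length(complete)) {
    keys <- .geno_key(calls[complete, , drop = FALSE])
    grp <- match(keys, unique(keys))
    mlg[complete] <- grp
    first <- complete[!duplicated(grp)]
    profiles <- calls[first, , drop = FALSE]
    flag_missing <- rep(FALSE, nrow(profiles))
  } else {
    profiles <- calls[0, , drop = FALSE]
  }

  ambiguous <- character(0)
  partial <- which(n_miss > 0L & !all_missing)
  # deterministic order: least missing first, then sample id
  partial <- partial[order(n_miss[partial], gt$sample_id[partial])]
  for (i in partial) {
    res <- which(!miss_locus[i, ])  # resolved loci
    cols <- as.vector(vapply(res, locus_cols, integer(2)))
    if (nrow(profiles)) {
      cand <- profiles[, cols, drop = FALSE]
      tgt <- calls[rep(i, nrow(cand)), cols, drop = FALSE]
      same <- cand == tgt
      same[is.na(same)] <- FALSE     # profile missing there: not a match
      hits <- which(rowSums(same) == length(cols))
    } else hits <- integer(0)
    if (length(hits) == 1L) {
      mlg[i] <- hits
      flag_missing[hits] <- TRUE
    } else if (length(hits) > 1L) {
      ambiguous <- c(ambiguous, gt$sample_id[i])
    } else {
      profiles <- rbind(profiles, calls[i, , drop = FALSE])
      flag_missing <- c(flag_missing, TRUE)
      mlg[i] <- nrow(profiles)
    }
  }
  rownames(profiles) <- paste0("MLG", seq_len(nrow(profiles)))
  structure(list(mlg = mlg, mlg_profile = profiles, ambiguous = ambiguous,
                 flag_missing = flag_missing, gt = gt),
            class = "clonal_assignment")
}

#' @export
print.clonal_assignment <- function(x, ...) {
  cat("clonal_assignment:", sum(!is.na(x$mlg)), "samples in",
      nrow(x$mlg_profile), "MLGs")
  if (!is.null(x$mll)) cat(",", length(unique(x$mll)), "MLLs")
  if (length(x$ambiguous)) cat(";", length(x$ambiguous),
                               "ambiguous sample(s) excluded")
  cat("\n")
  invisible(x)
}

#' Allele-difference distance between two MLG profiles
#'
#' Counts differing allele copies per locus as the diploid multiset
#' difference (0, 1 or 2), summed over loci resolved in both profiles.
#'
#' @param a,b integer vectors of length 2L (paired allele columns).
#' @return integer distance; error if no locus is comparable.
#' @export
mlg_distance <- function(a, b) {
  L <- length(a) / 2L
  tot <- 0L
  comparable <- FALSE
  for (l in seq_len(L)) {
    ia <- a[locus_cols(l)]; ib <- b[locus_cols(l)]
    if (anyNA(ia) || anyNA(ib)) next
    comparable <- TRUE
    # multiset difference of two sorted pairs
    shared <- if (ia[1] == ib[1] && ia[2] == ib[2]) 2L
      else if (any(ia %in% ib)) {
        # count multiset intersection
        x <- ia; y <- ib; s <- 0L
        for (al in x) {
          j <- match(al, y)
          if (!is.na(j)) { y <- y[-j]; s <- s + 1L }
        }
        s
      } else 0L
    tot <- tot + (2L - shared)
  }
  if (!comparable) stop("no comparable loci between profiles")
  tot
}

#' Pairwise MLG distance matrix
#' @param assignment a `clonal_assignment`.
#' @return symmetric integer matrix of allele differences between MLG
#'   consensus profiles.
#' @export
mlg_distance_matrix <- function(assignment) {
  p <- assignment$mlg_profile
  g <- nrow(p)
  d <- matrix(0L, g, g, dimnames = list(rownames(p), rownames(p)))
  if (g < 2L) return(d)
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g)
    d[i, j] <- d[j, i] <- mlg_distance(p[i, ], p[j, ])
  d
}

#' Collapse MLGs into multilocus lineages (MLLs)
#'
#' Pairs of MLGs at allele distance `threshold` (default 1: one allele at one
#' locus) are merged when the rarer MLG has exactly one member sample, the
#' rule being applied iteratively to a fixed point. The MLL representative is
#' the most abundant member MLG (ties broken lexicographically by MLG id).
#' MLGs not merged become singleton MLLs.
#'
#' @param assignment a `clonal_assignment` from [assign_mlgs()].
#' @param distances optional precomputed [mlg_distance_matrix()].
#' @param threshold maximum allele difference for merging (default 1).
#' @return the assignment with `mll` (MLG -> MLL index), `mll_id` (sample ->
#'   MLL), and `mll_members` (list of sample ids per MLL) layers added.
#' @export
collapse_to_mlls <- function(assignment, distances = NULL, threshold = 1L) {
  if (is.null(distances)) distances <- mlg_distance_matrix(assignment)
  g <- nrow(assignment$mlg_profile)
  cluster <- seq_len(g)                      # MLG -> provisional MLL
  sizes <- tabulate(assignment$mlg[!is.na(assignment$mlg)], nbins = g)

  repeat {
    changed <- FALSE
    # only a single-sample MLG may be absorbed (it is the rarer of any pair)
    singles <- which(sizes == 1L)
    singles <- singles[order(rownames(assignment$mlg_profile)[singles])]
    for (s in singles) {
      if (sum(cluster == cluster[s]) > 1L) next  # already absorbed
      near <- which(distances[s, ] <= threshold & seq_len(g) != s &
                      cluster != cluster[s])
      if (!length(near)) next
      # target cluster: most member samples, then lowest cluster index
      tgt_cl <- unique(cluster[near])
      tgt_sz <- vapply(tgt_cl, function(cl) sum(sizes[cluster == cl]),
                       numeric(1))
      o <- order(-tgt_sz, tgt_cl)
      cluster[cluster == cluster[s]] <- tgt_cl[o[1]]
      changed <- TRUE
    }
    if (!changed) break
  }

  # relabel clusters; representative = most abundant MLG, tie lexicographic
  mll <- integer(g)
  reps <- character(0)
  for (cl in unique(cluster)) {
    members <- which(cluster == cl)
    o <- order(-sizes[members], rownames(assignment$mlg_profile)[members])
    reps <- c(reps, rownames(assignment$mlg_profile)[members[o[1]]])
  }
  o <- order(reps)
  reps <- reps[o]
  cls <- unique(cluster)[o]
  for (k in seq_along(cls)) mll[cluster == cls[k]] <- k

  assignment$mll <- mll
  names(assignment$mll) <- rownames(assignment$mlg_profile)
  smpl_mll <- mll[assignment$mlg]
  names(smpl_mll) <- assignment$gt$sample_id
  assignment$mll_id <- smpl_mll
  assignment$mll_members <- lapply(seq_along(cls), function(k)
    assignment$gt$sample_id[!is.na(smpl_mll) & smpl_mll == k])
  names(assignment$mll_members) <- paste0("MLL", seq_along(cls))
  assignment$mll_representative <- reps
  assignment
}

#' Allele frequencies from a genotype table
#'
#' @param gt a `genotype_table`.
#' @param samples optional subset of sample ids (e.g. one per MLL for
#'   clone-corrected frequencies).
#' @return list per locus of named frequency vectors (missing calls excluded).
#' @export
allele_frequencies <- function(gt, samples = NULL) {
  calls <- gt$calls
  if (!is.null(samples)) calls <- calls[gt$sample_id %in% samples, ,
                                        drop = FALSE]
  out <- vector("list", length(gt$loci))
  names(out) <- gt$loci
  for (l in seq_along(gt$loci)) {
    a <- c(calls[, 2L * l - 1L], calls[, 2L * l])
    a <- a[!is.na(a)]
    tb <- table(a)
    out[[l]] <- as.numeric(tb) / sum(tb)
    names(out[[l]]) <- names(tb)
  }
  out
}

#' HWE probability of a multilocus genotype (pgen)
#'
#' Product over resolved loci of the Hardy-Weinberg genotype probability:
#' `p^2` for a homozygote, `2*p*q` for a heterozygote. Missing loci contribute
#' a factor of 1.
#'
#' @param profile integer vector of length 2L (paired allele columns).
#' @param freqs allele frequency list as from [allele_frequencies()].
#' @return probability in (0, 1].
#' @export
pgen <- function(profile, freqs) {
  L <- length(freqs)
  logp <- 0
  for (l in seq_len(L)) {
    al <- profile[locus_cols(l)]
    if (anyNA(al)) next
    f <- freqs[[l]]
    p1 <- f[as.character(al[1])]
    p2 <- f[as.character(al[2])]
    if (anyNA(c(p1, p2)))
      stop("allele absent from frequency table at locus ", names(freqs)[l])
    logp <- logp + if (al[1] == al[2]) 2 * log(p1) else log(2 * p1 * p2)
  }
  exp(unname(logp))
}

#' Probability of repeated sexual origin (psex)
#'
#' For an MLL observed `n_encounters` times among `N` genotyped samples,
#' returns the probability series for the 2nd..nth encounter that at least
#' that many further independent sexual events produced the same genotype:
#' `psex_i = P(X >= i - 1)` with `X ~ Binomial(N - 1, pgen)`.
#'
#' @param pgen_value HWE genotype probability in (0, 1].
#' @param n_encounters number of times the MLL was sampled (>= 2).
#' @param N total genotyped samples.
#' @param threshold clonality call threshold on the final encounter
#'   (default 0.001).
#' @return list with `psex` (numeric vector for encounters 2..n) and `clonal`
#'   (logical: final psex below `threshold`).
#' @export
psex <- function(pgen_value, n_encounters, N, threshold = 0.001) {
  if (pgen_value <= 0 || pgen_value > 1)
    stop("pgen must be in (0, 1]")
  if (n_encounters < 2L) stop("psex defined for encounters beyond the first")
  i <- 2:n_encounters
  p <- stats::pbinom(i - 2L, size = N - 1L, prob = pgen_value,
                     lower.tail = FALSE)
  list(psex = p, clonal = p[length(p)] < threshold)
}

#' Genotype accumulation curve
#'
#' For each number of loci `m = 1..L`, counts the distinct multilocus
#' genotypes resolvable from random `m`-subsets of loci. Samples are first
#' replaced by their MLG consensus profiles (so missing-data samples merged
#' into an MLG inherit its profile; ambiguous samples are excluded), keeping
#' the curve's endpoint equal to the MLG count. `m = L` is computed exactly.
#'
#' @param assignment a `clonal_assignment`.
#' @param n_reps random locus subsets per `m` (default 100).
#' @return data frame with `m`, `mean`, `q025`, `q975`.
#' @export
genotype_accumulation <- function(assignment, n_reps = 100L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  L <- length(assignment$gt$loci)
  if (L < 2L) stop("need at least two loci")
  prof <- assignment$mlg_profile[assignment$mlg[!is.na(assignment$mlg)], ,
                                 drop = FALSE]
  count_distinct <- function(loci_idx)
    length(unique(.geno_key(prof, loci_idx)))
  out <- data.frame(m = seq_len(L), mean = NA_real_, q025 = NA_real_,
                    q975 = NA_real_)
  for (m in seq_len(L)) {
    if (m == L) {
      v <- count_distinct(seq_len(L))
      out[m, 2:4] <- c(v, v, v)
    } else {
      v <- vapply(seq_len(n_reps), function(k)
        count_distinct(sample.int(L, m)), numeric(1))
      out[m, 2:4] <- c(mean(v), stats::quantile(v, c(0.025, 0.975),
                                                names = FALSE))
    }
  }
  out
}

#' MLL registry table
#'
#' One row per MLL: member MLGs, sample count, sites, maximum spatial extent
#' (largest pairwise combined distance among member samples, when a distance
#' matrix is supplied) and the final-encounter psex.
#'
#' @param assignment a collapsed `clonal_assignment`.
#' @param sample_dist optional sample-by-sample distance matrix (m).
#' @param freqs optional allele frequencies for psex (defaults to
#'   clone-corrected frequencies: one representative per MLL).
#' @param psex_threshold clonality threshold (default 0.001).
#' @return data frame registry.
#' @export
mll_registry <- function(assignment, sample_dist = NULL, freqs = NULL,
                         psex_threshold = 0.001) {
  if (is.null(assignment$mll)) stop("run collapse_to_mlls() first")
  gt <- assignment$gt
  N <- sum(!is.na(assignment$mll_id))
  if (is.null(freqs)) {
    reps <- vapply(assignment$mll_members, function(s) sort(s)[1],
                   character(1))
    freqs <- allele_frequencies(gt, samples = reps)
  }
  n_mll <- length(assignment$mll_members)
  out <- data.frame(mll_id = names(assignment$mll_members),
                    mlg_ids = NA_character_, n_samples = NA_integer_,
                    n_sites = NA_integer_, max_extent_m = NA_real_,
                    psex_final = NA_real_, clonal = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_mll)) {
    members <- assignment$mll_members[[k]]
    idx <- match(members, gt$sample_id)
    out$mlg_ids[k] <- paste(names(assignment$mll)[assignment$mll == k],
                            collapse = ";")
    out$n_samples[k] <- length(members)
    out$n_sites[k] <- length(unique(gt$site_id[idx]))
    if (!is.null(sample_dist)) {
      out$max_extent_m[k] <- if (length(members) > 1L)
        max(sample_dist[members, members]) else 0
    }
    if (length(members) > 1L) {
      rep_mlg <- assignment$mll_representative[k]
      prof <- assignment$mlg_profile[rep_mlg, ]
      ps <- psex(pgen(prof, freqs), length(members), N,
                 threshold = psex_threshold)
      out$psex_final[k] <- ps$psex[length(ps$psex)]
      out$clonal[k] <- ps$clonal
    }
  }
  out
}
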