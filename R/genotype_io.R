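# Data model and readers/writers for genotype tables, site metadata and
# water-mask rasters.

#' Construct a genotype table
#'
#' The central container of the package: diploid codominant microsatellite
#' calls for a set of samples. Alleles are stored as positive integers
#' (fragment sizes) in an `n x 2L` matrix with two adjacent columns per locus;
#' each locus call is order-normalized (low allele first) and missing data is
#' a pair of `NA`s — a half-missing call is never stored.
#'
#' @param calls integer matrix with `2 * length(loci)` columns; row per sample.
#' @param sample_id character vector of unique sample identifiers.
#' @param site_id character vector mapping each sample to a site.
#' @param loci character vector of locus names.
#' @return An object of class `genotype_table` with elements `calls`
#'   (normalized matrix), `sample_id`, `site_id`, `loci`.
#' @export
genotype_table <- function(calls, sample_id, site_id, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  L <- length(loci)
  if (L < 1L) stop("at least one locus is required")
  if (ncol(calls) != 2L * L)
    stop("calls must have two columns per locus")
  if (nrow(calls) != length(sample_id) || length(sample_id) != length(site_id))
    stop("sample_id, site_id and calls rows must align")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(calls <= 0L, na.rm = TRUE))
    stop("allele sizes must be positive integers (use NA or 0 for missing)")
  for (l in seq_len(L)) {
    a <- calls[, 2L * l - 1L]
    b <- calls[, 2L * l]
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      warning(sum(half), " half-missing call(s) at locus '", loci[l],
              "' promoted to fully missing")
      a[half] <- NA_integer_
      b[half] <- NA_integer_
    }
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    calls[, 2L * l - 1L] <- lo
    calls[, 2L * l] <- hi
  }
  colnames(calls) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  rownames(calls) <- sample_id
  structure(
    list(calls = calls, sample_id = as.character(sample_id),
         site_id = as.character(site_id), loci = as.character(loci)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$sample_id), "samples x",
      length(x$loci), "loci;",
      length(unique(x$site_id)), "sites;",
      sum(is.na(x$calls)) / 2L, "missing locus-calls\n")
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param gt a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(gt) length(gt$sample_id)

#' @rdname n_samples
#' @export
n_loci <- function(gt) length(gt$loci)

#' Read a genotype table from CSV
#'
#' Expected dialect: a header row `sample_id, site_id, <locus>_1, <locus>_2,
#' ...` with two integer allele columns per locus. Missing alleles are coded
#' `0` or left empty. Half-missing calls (one allele of a pair) are promoted
#' to fully missing with a warning.
#'
#' @param path CSV file path.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  need <- c("sample_id", "site_id")
  if (!all(need %in% names(df)[1:2]))
    stop("genotype CSV must start with columns sample_id, site_id")
  acol <- setdiff(names(df), need)
  if (length(acol) %% 2L != 0L)
    stop("odd number of allele columns: ", length(acol))
  loci <- unique(sub("_[12]$", "", acol))
  if (!identical(paste0(rep(loci, each = 2L), c("_1", "_2")), acol))
    stop("allele columns must come in <locus>_1,<locus>_2 adjacent pairs")
  m <- as.matrix(df[, acol, drop = FALSE])
  m[m == "" | is.na(m)] <- "0"
  m <- suppressWarnings(matrix(as.integer(m), nrow = nrow(df)))
  if (anyNA(m)) stop("non-integer allele entry in ", path)
  m[m == 0L] <- NA_integer_
  genotype_table(m, df$sample_id, df$site_id, loci)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; missing calls are written as `0`.
#'
#' @param gt a `genotype_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  m <- gt$calls
  m[is.na(m)] <- 0L
  df <- data.frame(sample_id = gt$sample_id, site_id = gt$site_id, m,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site metadata from CSV
#'
#' Columns: `site_id`, `x`, `y` (projected metric coordinates), `river_km`
#' (distance from the river mouth along the channel), `regime`
#' (`nontidal`/`tidal`), `year`.
#'
#' @param path CSV file path.
#' @param gt optional `genotype_table`; if given, every site referenced by the
#'   genotypes must resolve in the metadata.
#' @return A `data.frame` of class `site_meta`.
#' @export
read_site_meta <- function(path, gt = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  site_meta(df, gt = gt)
}

#' Validate a site-metadata data frame
#' @param df data frame with site_id, x, y, river_km, regime, year.
#' @param gt optional `genotype_table` whose site references must resolve.
#' @return the validated data frame, class `site_meta`.
#' @export
site_meta <- function(df, gt = NULL) {
  need <- c("site_id", "x", "y", "river_km", "regime", "year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("site metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in metadata")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("site coordinates must be finite")
  if (any(df$river_km < 0)) stop("river_km must be >= 0")
  if (!all(df$regime %in% c("nontidal", "tidal")))
    stop("regime must be 'nontidal' or 'tidal'")
  if (!is.null(gt)) {
    unresolved <- setdiff(unique(gt$site_id), df$site_id)
    if (length(unresolved))
      stop("site(s) referenced by genotypes absent from metadata: ",
           paste(unresolved, collapse = ", "))
  }
  class(df) <- c("site_meta", "data.frame")
  df
}

#' Read a water-mask raster (ESRI ASCII grid)
#'
#' The grid codes conductance: 1 = water (passable), 0 = land. `NODATA`
#' cells are mapped to land.
#'
#' @param path `.asc` file with the standard six-line header
#'   (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`).
#' @return An object of class `water_grid`: list with `conductance`
#'   (`nrows x ncols` 0/1 matrix, row 1 = northernmost), `xll`, `yll`,
#'   `cell_size`, `nrows`, `ncols`.
#' @export
read_water_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("malformed ESRI ASCII grid: too short")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop("malformed ESRI ASCII grid header")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[-(1:6)]), "\\s+"))))
  vals <- vals[!is.na(vals) | FALSE]
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values; expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- 0
  if (!all(m %in% c(0, 1))) stop("conductance values must be 0 or 1")
  water_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cell_size = hdr$cellsize)
}

#' Construct a water grid in memory
#' @param conductance 0/1 matrix, row 1 = northernmost row.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cell_size cell edge length (m).
#' @return A `water_grid` object.
#' @export
water_grid <- function(conductance, xll = 0, yll = 0, cell_size = 10) {
  conductance <- as.matrix(conductance)
  if (cell_size <= 0) stop("cell_size must be positive")
  if (!all(conductance %in% c(0, 1)))
    stop("conductance must be binary (0 = land, 1 = water)")
  structure(list(conductance = conductance, xll = xll, yll = yll,
                 cell_size = cell_size, nrows = nrow(conductance),
                 ncols = ncol(conductance)),
            class = "water_grid")
}

#' Write a water grid as an ESRI ASCII raster
#' @param grid a `water_grid`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_water_grid <- function(grid, path) {
  hdr <- c(paste("ncols", grid$ncols), paste("nrows", grid$nrows),
           paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
           paste("cellsize", grid$cell_size), "NODATA_value -9999")
  body <- apply(grid$conductance, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write analysis reports to a directory
#'
#' Emits deterministic CSV tables (per-site statistics, pairwise matrices,
#' MLL registry, regime-test battery) plus a JSON run summary recording the
#' seed and parameter values, so that a rerun with identical inputs and seed
#' is byte-identical.
#'
#' @param report a `stats_report` from [run_full_analysis()].
#' @param outdir output directory (created if needed).
#' @return character vector of file paths written, invisibly.
#' @export
write_reports <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character()
  wcsv <- function(x, name) {
    p <- file.path(outdir, name)
    utils::write.csv(x, p, row.names = FALSE, quote = FALSE)
    written[[length(written) + 1L]] <<- p
  }
  wmat <- function(m, name) {
    p <- file.path(outdir, name)
    utils::write.csv(data.frame(id = rownames(m), m, check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    written[[length(written) + 1L]] <<- p
  }
  wcsv(report$mll_registry, "mll_registry.csv")
  wcsv(report$genotypic_site, "genotypic_diversity_sites.csv")
  wcsv(report$genotypic_scope, "genotypic_diversity_scopes.csv")
  wcsv(report$locus_site, "locus_diversity_sites.csv")
  wcsv(report$relatedness_site, "relatedness_sites.csv")
  wcsv(report$regime_tests, "regime_tests.csv")
  if (!is.null(report$distances$combined))
    wmat(report$distances$combined, "site_distance_combined.csv")
  if (!is.null(report$chord)) wmat(report$chord, "chord_distance.csv")
  if (!is.null(report$ca)) wmat(report$ca$site_scores, "ca_site_scores.csv")
  summary <- list(
    seed = report$provenance$seed,
    config = report$provenance$config,
    n_samples = report$provenance$n_samples,
    n_sites = report$provenance$n_sites,
    n_loci = report$provenance$n_loci,
    n_mlg = report$provenance$n_mlg,
    n_mll = report$provenance$n_mll,
    differentiation = report$differentiation_global,
    mantel = report$mantel,
    spearman = report$spearman)
  p <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  written[[length(written) + 1L]] <- p
  invisible(unlist(written))
}
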