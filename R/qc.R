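## Cell- and read-level quality control: polyA masking for RNA reads,
## two-fragment depth QC for the long-range-PCR DNA arm, and the scRNA-seq
## cell filters. Threshold semantics follow the printed rules literally:
## "< 1000", "< 50" and "< 17%" are strict, as are both feature-count
## bounds, so equality at a bound fails; fragment windows are inclusive on
## both ends.

#' Mask polyA runs in read sequences
#'
#' Every maximal run of at least `k` consecutive A's is replaced by N's.
#' Masking (rather than clipping) preserves read length and coordinates,
#' so downstream pileup arithmetic needs no realignment; masked bases
#' contribute to no allele count. Internal runs are masked as well as
#' terminal ones. The operation is idempotent and never alters a non-A
#' base.
#'
#' @param read_sequence character vector of read sequences over A/C/G/T/N.
#' @param k minimum run length to mask (default 5).
#' @return character vector of masked sequences, same lengths.
#' @examples
#' maskPolyA("ACGTAAAAAGCT")  # "ACGTNNNNNGCT"
#' @export
maskPolyA <- function(read_sequence, k = 5L) {
  stopifnot(k >= 1L)
  pattern <- sprintf("A{%d,}", k)
  vapply(read_sequence, function(s) {
    m <- gregexpr(pattern, s)[[1]]
    if (m[1] == -1L) return(s)
    lens <- attr(m, "match.length")
    regmatches(s, gregexpr(pattern, s)) <- list(strrep("N", lens))
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Two-fragment depth QC for one DNA-arm cell
#'
#' The DNA arm amplifies the circular genome as two long-range-PCR
#' fragments which may amplify unevenly. Depth is averaged over an
#' interior window of each fragment (inclusive bounds; interior windows
#' avoid the overlapping primer regions) and the cell fails with tag
#' `low_fragment_depth` when either window mean falls strictly below
#' `min_mean_depth`. A fragment imbalance above 0.8 in either direction
#' is recorded as a non-fatal `fragment_imbalance` flag — such cells are
#' kept, but flagged.
#'
#' @param depth_profile numeric vector of per-position depth for one cell
#'   (index = 1-based position).
#' @param cell_id identifier recorded in the output.
#' @param window_x,window_y inclusive `(start, end)` windows for fragments
#'   X and Y; defaults 2000-7000 and 10000-15000.
#' @param min_mean_depth strict lower bound on each window mean.
#' @return one-row data.frame: cell_id, mean_depth_X, mean_depth_Y,
#'   fragment_proportion_Y, passed, fail_reasons (comma-joined tags),
#'   flags.
#' @export
fragmentDepthQC <- function(depth_profile, cell_id = "cell",
                            window_x = c(2000L, 7000L),
                            window_y = c(10000L, 15000L),
                            min_mean_depth = 1000) {
  np <- length(depth_profile)
  if (window_x[2] > np || window_y[2] > np ||
      window_x[1] < 1L || window_y[1] < 1L) {
    stop("QC windows fall outside the depth profile (length ", np, ")")
  }
  mean_x <- mean(depth_profile[window_x[1]:window_x[2]])
  mean_y <- mean(depth_profile[window_y[1]:window_y[2]])
  prop_y <- if (mean_x + mean_y > 0) mean_y / (mean_x + mean_y) else NA_real_
  fails <- character()
  if (mean_x < min_mean_depth || mean_y < min_mean_depth) {
    fails <- c(fails, "low_fragment_depth")
  }
  flags <- character()
  if (!is.na(prop_y) && (prop_y > 0.8 || prop_y < 0.2)) {
    flags <- c(flags, "fragment_imbalance")
  }
  data.frame(cell_id = cell_id, mean_depth_X = mean_x, mean_depth_Y = mean_y,
             fragment_proportion_Y = prop_y,
             passed = length(fails) == 0L,
             fail_reasons = paste(fails, collapse = ","),
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Fragment depth QC over a whole depth-profile matrix
#' @param depths numeric matrix positions x cells.
#' @param ... passed to [fragmentDepthQC()].
#' @return data.frame with one row per cell.
#' @export
fragmentDepthQCMatrix <- function(depths, ...) {
  out <- lapply(seq_len(ncol(depths)), function(j) {
    fragmentDepthQC(depths[, j], cell_id = colnames(depths)[j], ...)
  })
  do.call(rbind, out)
}

#' Mean and SD of the absolute fragment depth differential
#'
#' Summarizes |mean_depth_X - mean_depth_Y| over passing cells — the
#' population-level view of amplification bias between the two fragments.
#'
#' @param records data.frame of [fragmentDepthQC()] rows.
#' @return list with `mean` and `sd` (sample SD) of the absolute
#'   differential, and `n` cells used.
#' @export
absoluteFragmentDifferential <- function(records) {
  keep <- records[records$passed, , drop = FALSE]
  if (nrow(keep) < 2L) {
    stop("at least 2 passing cells are required, have ", nrow(keep))
  }
  d <- abs(keep$mean_depth_X - keep$mean_depth_Y)
  list(mean = mean(d), sd = stats::sd(d), n = nrow(keep))
}

#' RNA-arm cell QC
#'
#' A cell passes only if its mitochondrial read fraction is strictly below
#' `max_mito_fraction`, its expressed-feature count lies strictly inside
#' `feature_bounds`, and its mean mitochondrial per-base depth is at least
#' `min_mean_mito_depth`. All violated rules are listed in `fail_reasons`.
#'
#' @param gene_counts non-negative count vector for one cell, named by
#'   gene; mitochondrial genes are identified by `mito_genes` (names) or,
#'   by default, a `mt-` name prefix.
#' @param mito_depth_profile per-position mitochondrial depth for the cell
#'   (over transcribed positions).
#' @param max_mito_fraction strict upper bound on the mitochondrial read
#'   fraction (default 0.17).
#' @param feature_bounds strict open interval for the expressed-gene count
#'   (default (2100, 4000)).
#' @param min_mean_mito_depth inclusive lower bound on mean mitochondrial
#'   depth (a cell fails when strictly below; default 50).
#' @param mito_genes optional character vector naming mitochondrial genes.
#' @param cell_id identifier recorded in the output.
#' @return one-row data.frame: cell_id, mito_fraction, n_features,
#'   mean_mito_depth, passed, fail_reasons.
#' @export
rnaCellQC <- function(gene_counts, mito_depth_profile,
                      max_mito_fraction = 0.17,
                      feature_bounds = c(2100L, 4000L),
                      min_mean_mito_depth = 50,
                      mito_genes = NULL, cell_id = "cell") {
  if (any(gene_counts < 0)) stop("gene counts must be non-negative")
  if (is.null(mito_genes)) {
    mito_genes <- names(gene_counts)[startsWith(names(gene_counts), "mt-")]
  }
  total <- sum(gene_counts)
  mito_fraction <- if (total > 0) {
    sum(gene_counts[names(gene_counts) %in% mito_genes]) / total
  } else NA_real_
  n_features <- sum(gene_counts > 0)
  mean_mito_depth <- mean(mito_depth_profile)
  fails <- character()
  if (is.na(mito_fraction) || mito_fraction >= max_mito_fraction) {
    fails <- c(fails, "high_mito_fraction")
  }
  if (!(n_features > feature_bounds[1] && n_features < feature_bounds[2])) {
    fails <- c(fails, "feature_count_out_of_bounds")
  }
  if (mean_mito_depth < min_mean_mito_depth) {
    fails <- c(fails, "low_mito_depth")
  }
  data.frame(cell_id = cell_id, mito_fraction = mito_fraction,
             n_features = n_features, mean_mito_depth = mean_mito_depth,
             passed = length(fails) == 0L,
             fail_reasons = paste(fails, collapse = ","),
             stringsAsFactors = FALSE)
}

#' RNA-arm cell QC over a whole study arm
#' @param gene_counts genes x cells matrix (dense or sparse), mitochondrial
#'   genes prefixed `mt-`.
#' @param mito_depths transcribed-position depth matrix (positions x
#'   cells).
#' @param ... passed to [rnaCellQC()].
#' @return data.frame with one row per cell.
#' @export
rnaCellQCMatrix <- function(gene_counts, mito_depths, ...) {
  out <- lapply(seq_len(ncol(gene_counts)), function(j) {
    v <- gene_counts[, j]
    names(v) <- rownames(gene_counts)
    rnaCellQC(v, mito_depths[, j], cell_id = colnames(gene_counts)[j], ...)
  })
  do.call(rbind, out)
}
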