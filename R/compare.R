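## Condition and modality comparison statistics: bulk-vs-single-cell mean
## AF, induced/noninduced tests, AF-expression correlation, quartile-based
## differential expression and bulk time-course summaries.

#' Single-cell mean allele frequency with sub-threshold zeroing
#'
#' Any per-cell AF strictly below `zero_below` is counted as 0 before
#' averaging over cells with a defined AF — mirroring how per-cell calls
#' below the heteroplasmy floor are reported as absent, which makes the
#' single-cell average systematically lower than the pseudobulk AF for
#' mutations hovering near the floor.
#'
#' @param af numeric vector of per-cell AFs (NA = undefined, excluded).
#' @param zero_below strict zeroing threshold (default 0.04).
#' @return the zeroed mean AF.
#' @examples
#' singleCellMeanAF(c(0.02, 0.50))  # 0.25
#' @export
singleCellMeanAF <- function(af, zero_below = 0.04) {
  af <- af[!is.na(af)]
  if (!length(af)) stop("no cells with a defined allele frequency")
  mean(ifelse(af < zero_below, 0, af))
}

# pooled-variance two-sample t-test that tolerates zero-variance input:
# identical constant groups give statistic 0, p 1; distinct constant
# groups give +/-Inf and p 0
.pooledT <- function(x, y) {
  res <- tryCatch(
    stats::t.test(x, y, var.equal = TRUE),
    error = function(e) NULL)
  if (!is.null(res)) {
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  if (isTRUE(all.equal(mean(x), mean(y)))) {
    list(statistic = 0, p_value = 1)
  } else {
    list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0)
  }
}

#' Compare allele frequencies between culture conditions
#'
#' For every mutation with at least `min_per_group` cells with a defined
#' AF in each condition, a two-sided pooled-variance (Student's) t-test of
#' the per-cell AFs; mutations below that are skipped and listed with a
#' reason. A final row tests heteroplasmic events per cell between the
#' conditions. No across-mutation multiple-testing correction is applied
#' (`adjusted_p` is NA for these rows): the comparison is reported per
#' mutation, unadjusted, and readers should treat marginal p-values
#' accordingly.
#'
#' @param vcs a [VariantCallSet-class].
#' @param conditions named character vector mapping cell -> condition
#'   label (exactly two distinct labels).
#' @param min_per_group minimum defined AFs per group (default 2).
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   test (default FALSE).
#' @return data.frame with one row per tested quantity: mutation,
#'   group_a, group_b, n_a, n_b, mean_af_a, mean_af_b, statistic,
#'   p_value, adjusted_p, skipped, reason.
#' @export
compareConditions <- function(vcs, conditions, min_per_group = 2L,
                              welch = FALSE) {
  cells <- colnames(afMatrix(vcs))
  missing_cells <- setdiff(cells, names(conditions))
  if (length(missing_cells)) {
    stop("no condition label for cell(s): ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  }
  cond <- conditions[cells]
  groups <- sort(unique(cond))
  if (length(groups) != 2L) stop("exactly two condition labels required")
  af <- afMatrix(vcs)
  labels <- variantLabels(vcs)
  test_one <- function(x, y, label) {
    n_a <- sum(!is.na(x)); n_b <- sum(!is.na(y))
    row <- data.frame(mutation = label, group_a = groups[1],
                      group_b = groups[2], n_a = n_a, n_b = n_b,
                      mean_af_a = mean(x, na.rm = TRUE),
                      mean_af_b = mean(y, na.rm = TRUE),
                      statistic = NA_real_, p_value = NA_real_,
                      adjusted_p = NA_real_, skipped = FALSE,
                      reason = "", stringsAsFactors = FALSE)
    if (n_a < min_per_group || n_b < min_per_group) {
      row$skipped <- TRUE
      row$reason <- sprintf("fewer than %d cells in a group", min_per_group)
      return(row)
    }
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    t_res <- if (welch) {
      res <- stats::t.test(x, y)
      list(statistic = unname(res$statistic), p_value = res$p.value)
    } else .pooledT(x, y)
    row$statistic <- t_res$statistic
    row$p_value <- t_res$p_value
    row
  }
  out <- lapply(seq_len(length(vcs)), function(i) {
    test_one(af[i, cond == groups[1]], af[i, cond == groups[2]], labels[i])
  })
  epc <- eventsPerCell(vcs)
  out <- c(out, list(test_one(
    ifelse(cond == groups[1], epc, NA_real_)[cond == groups[1]],
    ifelse(cond == groups[2], epc, NA_real_)[cond == groups[2]],
    "events_per_cell")))
  do.call(rbind, out)
}

#' Pearson correlation between allele frequency and transcript abundance
#'
#' Computed over cells with both values defined; an optional strict AF
#' filter (`min_af`) restricts to high-frequency cells, in which case the
#' returned `n` matters — correlations from a handful of cells are easily
#' spurious and should be flagged by their low n.
#'
#' @param af named numeric vector, cell -> AF.
#' @param transcript named numeric vector, cell -> transcript count.
#' @param min_af optional strict lower AF bound applied before
#'   correlating.
#' @return list with r, n and reason (`"low_n"` with `r = NA` when fewer
#'   than 3 pairs remain).
#' @export
afExpressionCorrelation <- function(af, transcript, min_af = NULL) {
  shared <- intersect(names(af), names(transcript))
  x <- af[shared]; y <- transcript[shared]
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(min_af)) keep <- keep & x > min_af
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    return(list(r = NA_real_, n = length(x), reason = "low_n"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = length(x), reason = "zero_variance"))
  }
  list(r = stats::cor(x, y, method = "pearson"), n = length(x),
       reason = NA_character_)
}

#' Quartile-split differential expression against allele frequency
#'
#' Cells with a defined AF are split at the 25th and 75th AF percentiles;
#' cells exactly on a boundary go to the extreme group (deterministic and
#' maximizes n). Each gene is then compared between the top and bottom
#' quartile groups with a two-sided Wilcoxon rank-sum test, and p-values
#' are Benjamini-Hochberg adjusted across genes (within this one
#' mutation).
#'
#' @param expression genes x cells matrix (dense or sparse).
#' @param af named numeric vector, cell -> AF for one mutation.
#' @param alpha adjusted-p threshold used for the `significant` flag.
#' @return list with `results` (data.frame gene, mean_bottom, mean_top,
#'   statistic, p_value, adjusted_p, significant), `n_top`, `n_bottom`,
#'   and `skipped`/`reason` when the split is degenerate.
#' @export
quartileExpressionTest <- function(expression, af, alpha = 0.05) {
  af <- af[!is.na(af)]
  af <- af[names(af) %in% colnames(expression)]
  if (length(af) < 4L) {
    stop("at least 4 cells with defined AF are required")
  }
  q <- stats::quantile(af, c(0.25, 0.75), names = FALSE)
  bottom <- names(af)[af <= q[1]]
  top <- names(af)[af >= q[2]]
  overlap <- intersect(top, bottom)
  if (length(overlap)) {
    # only possible when the two quartile boundaries coincide (mass ties)
    return(list(results = NULL, n_top = length(top),
                n_bottom = length(bottom), skipped = TRUE,
                reason = "degenerate_quartiles"))
  }
  expr_top <- as.matrix(expression[, top, drop = FALSE])
  expr_bot <- as.matrix(expression[, bottom, drop = FALSE])
  res <- lapply(seq_len(nrow(expression)), function(g) {
    w <- suppressWarnings(
      stats::wilcox.test(expr_top[g, ], expr_bot[g, ], exact = FALSE))
    data.frame(gene = rownames(expression)[g],
               mean_bottom = mean(expr_bot[g, ]),
               mean_top = mean(expr_top[g, ]),
               statistic = unname(w$statistic), p_value = w$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$adjusted_p < alpha
  list(results = res, n_top = length(top), n_bottom = length(bottom),
       skipped = FALSE, reason = NA_character_)
}

#' Summarize bulk heteroplasmy over a time course
#'
#' Per site: the AF at each time point, its minimum, maximum and range,
#' and a stability flag (range at or below `stable_range`; the flag is a
#' reporting convenience, not a test).
#'
#' @param bulk_afs data.frame with columns time, site, af (site = any
#'   mutation label).
#' @param stable_range range threshold for the `stable` flag
#'   (default 0.10).
#' @return data.frame per site: site, n_timepoints, min_af, max_af,
#'   range_af, stable.
#' @export
bulkTimecourseSummary <- function(bulk_afs, stable_range = 0.10) {
  if (length(unique(bulk_afs$time)) < 2L) {
    stop("at least 2 time points are required")
  }
  out <- lapply(split(bulk_afs, bulk_afs$site), function(d) {
    data.frame(site = d$site[1], n_timepoints = nrow(d),
               min_af = min(d$af), max_af = max(d$af),
               range_af = max(d$af) - min(d$af),
               stable = (max(d$af) - min(d$af)) <= stable_range,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
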