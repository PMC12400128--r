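## Variant core: per-cell allele frequencies from allele counts, the
## shifted-reference merge that restores calls across the circular origin,
## pseudobulk aggregation, and DNA/RNA modality comparison.

#' Call per-cell variants from an allele-count matrix
#'
#' For every position and every non-reference allele with a non-zero count
#' in at least one cell, the per-cell allele frequency is
#' `alt_count / depth` wherever the cell's depth at the site is at least
#' `min_depth`, and undefined (`NA`) otherwise. A site/allele is emitted
#' only if some cell has a defined AF at or above `emission_floor`; the
#' floor sits deliberately below the 0.04 heteroplasmy floor so that
#' sub-threshold frequencies remain available to downstream "counted as
#' 0" comparisons. Multi-allelic sites yield one call per alt allele.
#'
#' @param acm an [AlleleCountMatrix-class].
#' @param ref a [CircularReference-class]; supplies the reference base
#'   where the matrix does not carry one.
#' @param min_depth minimum per-cell site depth for a defined AF. The
#'   DNA-arm default is 100 (long-range-PCR coverage is deep); use 50 for
#'   the RNA arm, where the retention rule is "depth above 49".
#' @param emission_floor minimum defined AF in at least one cell for a
#'   call to be emitted.
#' @param source label recorded on each call; defaults to `shifted` when
#'   `refShift(ref) > 0`, else `unshifted`.
#' @return a [VariantCallSet-class].
#' @export
callVariants <- function(acm, ref, min_depth = 100L, emission_floor = 0.01,
                         source = NULL) {
  pos <- acmPositions(acm)
  L <- refLength(ref)
  if (any(pos < 1L | pos > L)) {
    stop("allele-count position outside the reference [1, ", L, "]")
  }
  ref_base <- SummarizedExperiment::rowData(acm)$ref
  missing_ref <- is.na(ref_base)
  if (any(missing_ref)) ref_base[missing_ref] <- refBaseAt(ref, pos[missing_ref])
  if (is.null(source)) {
    source <- if (refShift(ref) > 0L) "shifted" else "unshifted"
  }
  depth <- alleleDepth(acm)
  cells <- acmCells(acm)
  rows <- list(); af_rows <- list(); dp_rows <- list()
  for (a in ALLELES) {
    m <- SummarizedExperiment::assay(acm, a)
    for (i in which(ref_base != a & rowSums(m) > 0L)) {
      af <- ifelse(depth[i, ] >= min_depth, m[i, ] / depth[i, ], NA_real_)
      if (!any(af >= emission_floor, na.rm = TRUE)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos[i], ref = ref_base[i], alt = a, source = source,
        stringsAsFactors = FALSE)
      af_rows[[length(af_rows) + 1L]] <- af
      dp_rows[[length(dp_rows) + 1L]] <- depth[i, ]
    }
  }
  if (!length(rows)) {
    return(VariantCallSet(
      S4Vectors::DataFrame(pos = integer(), ref = character(),
                           alt = character(), source = character()),
      matrix(numeric(), 0L, length(cells), dimnames = list(NULL, cells)),
      matrix(numeric(), 0L, length(cells), dimnames = list(NULL, cells))))
  }
  info <- do.call(rbind, rows)
  af <- do.call(rbind, af_rows)
  dp <- do.call(rbind, dp_rows)
  colnames(af) <- colnames(dp) <- cells
  ord <- order(info$pos, match(info$alt, ALLELES))
  VariantCallSet(info[ord, , drop = FALSE], af[ord, , drop = FALSE],
                 dp[ord, , drop = FALSE])
}

#' Merge unshifted and shifted-reference variant calls
#'
#' Shifted-reference calls are first mapped back to original coordinates
#' with [shiftedToOriginal()]. For positions within `junction_halfwidth`
#' of the origin (pos <= halfwidth or pos > L - halfwidth) the
#' shifted-derived call wins — the linear mapper cannot cover that zone on
#' the unshifted reference — and elsewhere the unshifted call wins. Calls
#' present in only one input are kept as-is; duplicates collapse to a
#' single record with `source = "merged"`. Output is sorted by position.
#' The merge is idempotent and does not depend on the row order of its
#' inputs.
#'
#' @param calls_unshifted,calls_shifted [VariantCallSet-class] objects;
#'   the shifted set is in shifted coordinates.
#' @param s rotation offset used for the shifted run.
#' @param L circular genome length.
#' @param junction_halfwidth bp around the origin in which the shifted
#'   call is authoritative (default 1000).
#' @return a merged [VariantCallSet-class] in original coordinates.
#' @export
mergeShiftedCalls <- function(calls_unshifted, calls_shifted, s, L,
                              junction_halfwidth = 1000L) {
  un <- calls_unshifted
  sh <- calls_shifted
  if (length(sh)) {
    sh@info$pos <- shiftedToOriginal(sh@info$pos, s, L)
  }
  if (ncol(un@af) != ncol(sh@af) ||
      !identical(colnames(un@af), colnames(sh@af))) {
    stop("unshifted and shifted call sets must cover the same cells")
  }
  key_u <- paste(un@info$pos, un@info$alt)
  key_s <- paste(sh@info$pos, sh@info$alt)
  near_origin <- function(pos) pos <= junction_halfwidth |
    pos > L - junction_halfwidth
  common <- intersect(key_u, key_s)
  iu <- match(common, key_u)
  is_ <- match(common, key_s)
  if (length(common) &&
      any(un@info$ref[iu] != sh@info$ref[is_])) {
    bad <- common[un@info$ref[iu] != sh@info$ref[is_]]
    stop("conflicting reference alleles after coordinate mapping at: ",
         paste(bad, collapse = ", "),
         " (likely a shift/coordinate bug)")
  }
  pick_shifted <- near_origin(un@info$pos[iu])
  take <- function(vcs, idx, src) {
    info <- vcs@info[idx, , drop = FALSE]
    if (!is.null(src)) info$source <- rep(src, nrow(info))
    list(info = info, af = vcs@af[idx, , drop = FALSE],
         dp = vcs@depth[idx, , drop = FALSE])
  }
  parts <- list(
    take(un, setdiff(seq_along(key_u), iu), NULL),
    take(sh, setdiff(seq_along(key_s), is_), NULL),
    if (length(common)) {
      merged_u <- take(un, iu[!pick_shifted], "merged")
      merged_s <- take(sh, is_[pick_shifted], "merged")
      list(info = rbind(merged_u$info, merged_s$info),
           af = rbind(merged_u$af, merged_s$af),
           dp = rbind(merged_u$dp, merged_s$dp))
    })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  info <- do.call(rbind, lapply(parts, `[[`, "info"))
  af <- do.call(rbind, lapply(parts, `[[`, "af"))
  dp <- do.call(rbind, lapply(parts, `[[`, "dp"))
  ord <- order(info$pos, match(info$alt, ALLELES))
  VariantCallSet(info[ord, , drop = FALSE], af[ord, , drop = FALSE],
                 dp[ord, , drop = FALSE])
}

#' Pool cells into a pseudobulk allele-frequency profile
#'
#' Concatenates the selected cells' reads: for every site/alt allele the
#' pseudobulk AF is (sum of alt counts) / (sum of depths), which equals
#' the depth-weighted mean of per-cell AFs (and the plain mean when
#' depths are equal). Sites with zero pooled depth get `NA`.
#'
#' @param acm an [AlleleCountMatrix-class].
#' @param ref a [CircularReference-class].
#' @param cells character vector of cells to pool (default: all).
#' @return data.frame with columns pos, ref, alt, af, depth, alt_count
#'   for every non-reference allele with a non-zero pooled count.
#' @export
pseudobulk <- function(acm, ref, cells = acmCells(acm)) {
  if (!length(cells)) stop("cell subset must be non-empty")
  missing_cells <- setdiff(cells, acmCells(acm))
  if (length(missing_cells)) {
    stop("unknown cell(s): ", paste(missing_cells, collapse = ", "))
  }
  pos <- acmPositions(acm)
  ref_base <- SummarizedExperiment::rowData(acm)$ref
  na_ref <- is.na(ref_base)
  if (any(na_ref)) ref_base[na_ref] <- refBaseAt(ref, pos[na_ref])
  depth <- rowSums(alleleDepth(acm)[, cells, drop = FALSE])
  out <- list()
  for (a in ALLELES) {
    alt_count <- rowSums(
      SummarizedExperiment::assay(acm, a)[, cells, drop = FALSE])
    keep <- which(ref_base != a & alt_count > 0)
    if (!length(keep)) next
    out[[a]] <- data.frame(
      pos = pos[keep], ref = ref_base[keep], alt = a,
      af = ifelse(depth[keep] > 0, alt_count[keep] / depth[keep], NA_real_),
      depth = depth[keep], alt_count = alt_count[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      af = numeric(), depth = numeric(),
                      alt_count = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$pos, match(res$alt, ALLELES)), , drop = FALSE]
}

#' Compare DNA and RNA allele-frequency profiles site by site
#'
#' Classifies each site/alt allele seen in either modality:
#' `joint` if both AFs reach `het_floor`; `DNA_specific` if only the DNA
#' AF does (including sites that are untranscribed or absent from the RNA
#' profile); `RNA_specific` for the reverse (RNA-editing candidates);
#' `absent` if neither reaches the floor.
#'
#' @param dna_af,rna_af data.frames with columns pos, alt, af (e.g. from
#'   [pseudobulk()]), both in original coordinates.
#' @param het_floor minimum AF for presence in a modality (default 0.04).
#' @return data.frame with pos, alt, dna_af, rna_af, class.
#' @export
modalityCompare <- function(dna_af, rna_af, het_floor = 0.04) {
  key_d <- paste(dna_af$pos, dna_af$alt)
  key_r <- paste(rna_af$pos, rna_af$alt)
  keys <- union(key_d, key_r)
  id <- match(keys, key_d)
  ir <- match(keys, key_r)
  d <- dna_af$af[id]
  r <- rna_af$af[ir]
  pos <- ifelse(is.na(id), rna_af$pos[ir], dna_af$pos[id])
  alt <- ifelse(is.na(id), rna_af$alt[ir], dna_af$alt[id])
  d_in <- !is.na(d) & d >= het_floor
  r_in <- !is.na(r) & r >= het_floor
  cls <- ifelse(d_in & r_in, "joint",
         ifelse(d_in, "DNA_specific",
         ifelse(r_in, "RNA_specific", "absent")))
  out <- data.frame(pos = pos, alt = alt, dna_af = d, rna_af = r,
                    class = cls, stringsAsFactors = FALSE)
  out[order(out$pos, out$alt), , drop = FALSE]
}

#' Write a VariantCallSet as a VCF with per-sample AF and DP
#'
#' One record per site/alt allele; sample fields carry the per-cell
#' allele frequency and depth (`.` where the AF is undefined).
#' Coordinates are 1-based inclusive, as documented in the header.
#'
#' @param vcs a [VariantCallSet-class].
#' @param ref a [CircularReference-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeVariantVcf <- function(vcs, ref, path) {
  info <- as.data.frame(variantInfo(vcs))
  af <- afMatrix(vcs)
  dp <- depthMatrix(vcs)
  cells <- colnames(af)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", refName(ref), refLength(ref)),
    "##source=scMitoHet (coordinates 1-based inclusive)",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Call source\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cells), collapse = "\t")), con)
  for (i in seq_len(nrow(info))) {
    samp <- paste(ifelse(is.na(af[i, ]), ".",
                         formatC(af[i, ], format = "g", digits = 8)),
                  dp[i, ], sep = ":")
    writeLines(paste(c(refName(ref), info$pos[i], ".", info$ref[i],
                       .vcfAlt(info$alt[i]), ".", "PASS",
                       paste0("SRC=", info$source[i]), "AF:DP", samp),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# single-base DEL/INS alleles have no sequence context in the count matrix;
# encode them as symbolic alleles
.vcfAlt <- function(alt) {
  ifelse(alt == "DEL", "<DEL>", ifelse(alt == "INS", "<INS>", alt))
}
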