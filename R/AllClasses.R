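#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

ALLELES <- c("A", "C", "G", "T", "DEL", "INS")
BASES <- c("A", "C", "G", "T")

#' Circular mitochondrial reference
#'
#' Holds a single circular DNA sequence with its gene annotation and the
#' rotation offset used for shifted-reference variant calling. Position 1 is
#' the origin; all coordinates are 1-based and inclusive. Genes that span the
#' origin are stored as ordered sub-intervals (rows sharing a `gene` name,
#' ordered by `part`) so that interval arithmetic stays linear.
#'
#' @slot refname character(1), sequence name; rotation is recorded here too.
#' @slot sequence a [Biostrings::DNAString] over the alphabet A/C/G/T/N.
#' @slot genes a [GenomicRanges::GRanges] with metadata columns `gene`,
#'   `feature_type` (one of `protein_coding`, `tRNA`, `rRNA`, `noncoding`)
#'   and `part` (integer rank of the sub-interval within its gene).
#' @slot shift integer(1), the rotation offset s in bp relative to the
#'   original origin (0 for an unrotated reference).
#'
#' @seealso [CircularReference()], [rotateReference()], [loadReference()]
#' @export
setClass("CircularReference",
  slots = c(
    refname = "character",
    sequence = "DNAString",
    genes = "GRanges",
    shift = "integer"
  )
)

setValidity("CircularReference", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  letters <- Biostrings::uniqueLetters(object@sequence)
  if (!all(letters %in% c("A", "C", "G", "T", "N"))) {
    msg <- c(msg, "sequence letters must be in {A,C,G,T,N}")
  }
  if (length(object@shift) != 1L || is.na(object@shift) ||
      object@shift < 0L || object@shift >= L) {
    msg <- c(msg, "shift must be a single integer in [0, L)")
  }
  g <- object@genes
  if (length(g)) {
    need <- c("gene", "feature_type", "part")
    if (!all(need %in% colnames(S4Vectors::mcols(g)))) {
      msg <- c(msg, "genes must carry mcols gene, feature_type, part")
    } else {
      if (any(GenomicRanges::start(g) < 1L) ||
          any(GenomicRanges::end(g) > L)) {
        msg <- c(msg, "gene coordinates must lie within [1, L]")
      }
      ok_type <- S4Vectors::mcols(g)$feature_type %in%
        c("protein_coding", "tRNA", "rRNA", "noncoding")
      if (!all(ok_type)) {
        msg <- c(msg,
          "feature_type must be protein_coding, tRNA, rRNA or noncoding")
      }
      if (any(!as.character(GenomicRanges::strand(g)) %in% c("+", "-"))) {
        msg <- c(msg, "gene strand must be + or -")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell allele count matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one integer assay per
#' allele (A, C, G, T, DEL, INS), rows = reference positions and columns =
#' cells. `rowData` carries the 1-based position (`pos`) and the reference
#' base (`ref`). The per-(cell, position) depth is the sum of the six allele
#' counts, and every allele-frequency computation in the package reduces to
#' arithmetic on these assays.
#'
#' @seealso [AlleleCountMatrix()], [alleleDepth()], [callVariants()]
#' @export
setClass("AlleleCountMatrix", contains = "SummarizedExperiment")

setValidity("AlleleCountMatrix", function(object) {
  msg <- character()
  if (!all(ALLELES %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, sprintf("assays must include %s",
                          paste(ALLELES, collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("pos", "ref") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain pos and ref")
  }
  for (a in intersect(ALLELES, SummarizedExperiment::assayNames(object))) {
    m <- SummarizedExperiment::assay(object, a)
    if (any(m < 0) || any(m != round(m))) {
      msg <- c(msg, sprintf("assay %s must hold non-negative integers", a))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Set of site-level variant calls with per-cell allele frequencies
#'
#' One row per (position, alt allele). `info` holds `pos`, `ref`, `alt` and
#' `source` (`unshifted`, `shifted` or `merged`); `af` and `depth` are
#' variant-by-cell matrices. An allele frequency is `NA` wherever the cell's
#' depth at the site is below the caller's `min_depth` — downstream
#' statistics treat those cells as "undefined", not as zero.
#'
#' @slot info a [S4Vectors::DataFrame] with columns pos, ref, alt, source.
#' @slot af numeric matrix (variants x cells), values in [0,1] or NA.
#' @slot depth numeric matrix (variants x cells), site depth per cell.
#' @seealso [callVariants()], [mergeShiftedCalls()], [mostVariable()]
#' @export
setClass("VariantCallSet",
  slots = c(info = "DataFrame", af = "matrix", depth = "matrix")
)

setValidity("VariantCallSet", function(object) {
  msg <- character()
  n <- nrow(object@info)
  if (!all(c("pos", "ref", "alt", "source") %in% colnames(object@info))) {
    msg <- c(msg, "info must have columns pos, ref, alt, source")
  }
  if (nrow(object@af) != n || nrow(object@depth) != n) {
    msg <- c(msg, "af and depth must have one row per variant")
  }
  if (!identical(dim(object@af), dim(object@depth))) {
    msg <- c(msg, "af and depth must have identical dimensions")
  }
  af <- object@af
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated clonal cell population
#'
#' The simulator's record of what is actually true in each synthetic cell:
#' lineage identity, condition label, and the exact per-variant allele
#' frequency (mutant copies / N) before any sequencing noise.
#'
#' @slot cells a [S4Vectors::DataFrame] with columns cell_id, parent_id,
#'   condition.
#' @slot variants a [S4Vectors::DataFrame] with columns pos, ref, alt,
#'   haplotype, origin (founder / denovo).
#' @slot af numeric matrix (cells x variants) of true allele frequencies.
#' @seealso [simulateLineage()], [simulateDnaCounts()]
#' @export
setClass("CellTruthSet",
  slots = c(cells = "DataFrame", variants = "DataFrame", af = "matrix")
)

setValidity("CellTruthSet", function(object) {
  msg <- character()
  if (nrow(object@af) != nrow(object@cells)) {
    msg <- c(msg, "af must have one row per cell")
  }
  if (ncol(object@af) != nrow(object@variants)) {
    msg <- c(msg, "af must have one column per variant")
  }
  if (any(object@af < 0 | object@af > 1, na.rm = TRUE)) {
    msg <- c(msg, "true allele frequencies must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
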