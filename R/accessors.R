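#' Construct a CircularReference
#'
#' @param refname sequence name.
#' @param sequence a [Biostrings::DNAString] or a character string over
#'   A/C/G/T/N.
#' @param genes gene annotation as a [GenomicRanges::GRanges] (mcols `gene`,
#'   `feature_type`, `part`) or a data.frame with columns `gene`, `start`,
#'   `end`, `strand`, `feature_type` and optionally `part`.
#' @param shift rotation offset in bp already applied to `sequence`
#'   (0 for an unrotated reference).
#' @return A [CircularReference-class] object.
#' @examples
#' ref <- CircularReference("toy", "ACGTACGTACGT")
#' refLength(ref)
#' @export
CircularReference <- function(refname, sequence, genes = NULL, shift = 0L) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is.null(genes)) {
    genes <- GenomicRanges::GRanges()
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene = character(), feature_type = character(), part = integer())
  } else if (is.data.frame(genes)) {
    genes <- .genesFromTable(genes, length(sequence))
  }
  methods::new("CircularReference",
    refname = as.character(refname), sequence = sequence,
    genes = genes, shift = as.integer(shift))
}

.genesFromTable <- function(tab, L) {
  need <- c("gene", "start", "end", "strand", "feature_type")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- as.integer(tab$start)
  end <- as.integer(tab$end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("annotation start/end must be integers")
  }
  if (any(start < 1L) || any(end > L)) {
    stop("annotation coordinates outside [1, ", L, "]")
  }
  if (any(start > end)) {
    stop("annotation start > end (origin-spanning genes must be split ",
         "into two sub-intervals)")
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    stop("unknown strand value; must be '+' or '-'")
  }
  part <- if ("part" %in% colnames(tab)) as.integer(tab$part) else
    stats::ave(seq_len(nrow(tab)), tab$gene, FUN = seq_along)
  gr <- GenomicRanges::GRanges(
    seqnames = "mt",
    ranges = IRanges::IRanges(start = start, end = end),
    strand = tab$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = as.character(tab$gene),
    feature_type = as.character(tab$feature_type),
    part = part)
  gr
}

#' @describeIn CircularReference-class length of the circular genome (bp).
#' @param ref a CircularReference.
#' @export
refLength <- function(ref) length(ref@sequence)

#' @describeIn CircularReference-class the sequence as a DNAString.
#' @export
refSequence <- function(ref) ref@sequence

#' @describeIn CircularReference-class the sequence name.
#' @export
refName <- function(ref) ref@refname

#' @describeIn CircularReference-class rotation offset (bp) of this
#'   reference relative to the original origin.
#' @export
refShift <- function(ref) ref@shift

#' @describeIn CircularReference-class gene annotation as a GRanges.
#' @export
geneAnnotations <- function(ref) ref@genes

#' Reference base at 1-based positions
#' @param ref a CircularReference.
#' @param pos integer vector of 1-based positions in [1, L].
#' @return character vector of single bases.
#' @export
refBaseAt <- function(ref, pos) {
  L <- refLength(ref)
  if (any(pos < 1L | pos > L)) stop("position outside [1, ", L, "]")
  strsplit(as.character(ref@sequence), "")[[1]][pos]
}

setMethod("show", "CircularReference", function(object) {
  cat("CircularReference '", object@refname, "': ",
      refLength(object), " bp circular", sep = "")
  if (object@shift != 0L) cat(" (rotated by ", object@shift, " bp)", sep = "")
  cat("\n", length(object@genes), " annotated feature interval(s), ",
      length(unique(S4Vectors::mcols(object@genes)$gene)), " gene(s)\n",
      sep = "")
})

#' Construct an AlleleCountMatrix
#'
#' @param counts named list of integer matrices (one per allele among
#'   A, C, G, T, DEL, INS; missing alleles are filled with zeros), each
#'   positions x cells.
#' @param positions integer vector of 1-based reference positions (rows).
#' @param cells character vector of cell identifiers (columns).
#' @param ref optional [CircularReference-class] used to record the
#'   reference base per position; otherwise supply `ref_base`.
#' @param ref_base optional character vector of reference bases per row.
#' @return An [AlleleCountMatrix-class].
#' @export
AlleleCountMatrix <- function(counts, positions, cells, ref = NULL,
                              ref_base = NULL) {
  positions <- as.integer(positions)
  n <- length(positions)
  m <- length(cells)
  assays <- lapply(ALLELES, function(a) {
    if (!is.null(counts[[a]])) {
      x <- counts[[a]]
      storage.mode(x) <- "integer"
      x
    } else {
      matrix(0L, n, m)
    }
  })
  names(assays) <- ALLELES
  assays <- lapply(assays, function(x) {
    dimnames(x) <- list(as.character(positions), cells)
    x
  })
  if (is.null(ref_base)) {
    ref_base <- if (!is.null(ref)) refBaseAt(ref, positions) else
      rep(NA_character_, n)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(pos = positions, ref = ref_base),
    colData = S4Vectors::DataFrame(row.names = cells))
  methods::new("AlleleCountMatrix", se)
}

#' Total read depth per (position, cell)
#'
#' Depth is by definition the sum of the six allele-count assays, so
#' counts conservation holds exactly.
#' @param acm an [AlleleCountMatrix-class].
#' @return integer matrix positions x cells.
#' @export
alleleDepth <- function(acm) {
  Reduce(`+`, lapply(ALLELES, function(a) SummarizedExperiment::assay(acm, a)))
}

#' @describeIn AlleleCountMatrix-class 1-based reference positions (rows).
#' @param acm an AlleleCountMatrix.
#' @export
acmPositions <- function(acm) SummarizedExperiment::rowData(acm)$pos

#' @describeIn AlleleCountMatrix-class cell identifiers (columns).
#' @export
acmCells <- function(acm) colnames(acm)

setMethod("show", "AlleleCountMatrix", function(object) {
  cat("AlleleCountMatrix: ", nrow(object), " position(s) x ",
      ncol(object), " cell(s); alleles ",
      paste(SummarizedExperiment::assayNames(object), collapse = "/"),
      "\n", sep = "")
})

#' Construct a VariantCallSet
#' @param info DataFrame/data.frame with columns pos, ref, alt, source.
#' @param af numeric matrix variants x cells (NA = undefined).
#' @param depth numeric matrix variants x cells.
#' @return a [VariantCallSet-class].
#' @export
VariantCallSet <- function(info, af, depth) {
  info <- S4Vectors::DataFrame(info)
  rownames(af) <- rownames(depth) <- NULL
  methods::new("VariantCallSet", info = info, af = af, depth = depth)
}

#' @describeIn VariantCallSet-class variant table (pos, ref, alt, source).
#' @param x a VariantCallSet.
#' @export
variantInfo <- function(x) x@info

#' @describeIn VariantCallSet-class allele-frequency matrix (variants x
#'   cells); NA marks cells where depth was below the calling threshold.
#' @export
afMatrix <- function(x) x@af

#' @describeIn VariantCallSet-class per-cell site depth matrix.
#' @export
depthMatrix <- function(x) x@depth

#' @describeIn VariantCallSet-class mutation labels in the conventional
#'   "pos ref>alt" notation, e.g. "6790 G>A".
#' @export
variantLabels <- function(x) {
  if (nrow(x@info) == 0L) return(character())
  paste0(x@info$pos, " ", x@info$ref, ">", x@info$alt)
}

setMethod("length", "VariantCallSet", function(x) nrow(x@info))

setMethod("[", "VariantCallSet", function(x, i, j, ..., drop = FALSE) {
  VariantCallSet(x@info[i, , drop = FALSE],
                 x@af[i, , drop = FALSE],
                 x@depth[i, , drop = FALSE])
})

setMethod("show", "VariantCallSet", function(object) {
  cat("VariantCallSet: ", nrow(object@info), " variant(s) x ",
      ncol(object@af), " cell(s)\n", sep = "")
  if (nrow(object@info)) {
    lab <- variantLabels(object)
    k <- min(5L, length(lab))
    cat("  ", paste(lab[seq_len(k)], collapse = ", "),
        if (length(lab) > k) ", ..." else "", "\n", sep = "")
  }
})

#' @describeIn CellTruthSet-class per-cell metadata (cell_id, parent_id,
#'   condition).
#' @param truth a CellTruthSet.
#' @export
truthCells <- function(truth) truth@cells

#' @describeIn CellTruthSet-class simulated variant table.
#' @export
truthVariants <- function(truth) truth@variants

#' @describeIn CellTruthSet-class true allele-frequency matrix
#'   (cells x variants).
#' @export
truthAF <- function(truth) truth@af

setMethod("show", "CellTruthSet", function(object) {
  tab <- table(object@cells$condition)
  cat("CellTruthSet: ", nrow(object@cells), " cell(s) (",
      paste(paste0(names(tab), "=", tab), collapse = ", "), "), ",
      nrow(object@variants), " variant(s)\n", sep = "")
})
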