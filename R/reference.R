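#' Rotate a circular reference by s base pairs
#'
#' Produces the "shifted" reference used to call variants across the origin
#' of a circular genome: linear aligners lose coverage at the two ends of
#' the reference, so calling is repeated on a rotated copy whose junction
#' falls mid-molecule and the two call sets are merged
#' ([mergeShiftedCalls()]).
#'
#' The returned sequence is `sequence[s+1..L] + sequence[1..s]`; the name
#' records the rotation. Gene annotations are remapped into the rotated
#' coordinate system (intervals that come to span the new junction are split
#' into two sub-intervals).
#'
#' @param ref a [CircularReference-class].
#' @param s rotation offset in bp, `0 <= s < L`.
#' @return a rotated [CircularReference-class] with `refShift(ref) == s`.
#' @examples
#' r <- CircularReference("toy", "AACCGGTT")
#' as.character(refSequence(rotateReference(r, 2)))  # "CCGGTTAA"
#' @export
rotateReference <- function(ref, s) {
  L <- refLength(ref)
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 0L || s >= L) {
    stop("invalid shift: s must satisfy 0 <= s < L = ", L)
  }
  if (s == 0L) {
    rotated_seq <- ref@sequence
  } else {
    rotated_seq <- Biostrings::xscat(
      Biostrings::subseq(ref@sequence, s + 1L, L),
      Biostrings::subseq(ref@sequence, 1L, s))
    rotated_seq <- Biostrings::DNAString(rotated_seq)
  }
  genes <- .rotateGenes(ref@genes, s, L)
  nm <- if (s == 0L) ref@refname else
    paste0(ref@refname, "|shift=", s)
  methods::new("CircularReference", refname = nm, sequence = rotated_seq,
               genes = genes, shift = (ref@shift + s) %% L)
}

.rotateGenes <- function(genes, s, L) {
  if (length(genes) == 0L || s == 0L) return(genes)
  rows <- lapply(seq_along(genes), function(i) {
    a <- originalToShifted(GenomicRanges::start(genes)[i], s, L)
    len <- GenomicRanges::width(genes)[i]
    b <- a + len - 1L
    mc <- S4Vectors::mcols(genes)[i, , drop = FALSE]
    if (b <= L) {
      data.frame(start = a, end = b, strand =
                   as.character(GenomicRanges::strand(genes)[i]),
                 gene = mc$gene, feature_type = mc$feature_type,
                 part = mc$part, sub = 1:1)
    } else {
      # interval wraps the rotated junction: split, preserving order
      data.frame(start = c(a, 1L), end = c(L, b - L),
                 strand = as.character(GenomicRanges::strand(genes)[i]),
                 gene = mc$gene, feature_type = mc$feature_type,
                 part = mc$part, sub = 1:2)
    }
  })
  tab <- do.call(rbind, rows)
  # renumber parts so rank order still follows transcription order
  tab <- tab[order(match(tab$gene, unique(tab$gene)), tab$part, tab$sub), ]
  tab$part <- stats::ave(seq_len(nrow(tab)), tab$gene, FUN = seq_along)
  gr <- GenomicRanges::GRanges("mt",
    IRanges::IRanges(tab$start, tab$end), strand = tab$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene = tab$gene, feature_type = tab$feature_type,
    part = as.integer(tab$part))
  gr
}

#' Map positions between shifted and original circular coordinates
#'
#' `shiftedToOriginal()` maps a 1-based position on a reference rotated by
#' `s` back to the original coordinate system:
#' `((pos_shifted - 1 + s) mod L) + 1`. `originalToShifted()` is its
#' inverse. Both are bijections on `1..L` for every `s`.
#'
#' @param pos 1-based position vector in `[1, L]`.
#' @param s rotation offset in bp.
#' @param L circular genome length.
#' @return integer vector of mapped 1-based positions.
#' @examples
#' shiftedToOriginal(1, 50, 100)   # 51
#' shiftedToOriginal(51, 50, 100)  # 1
#' @export
shiftedToOriginal <- function(pos, s, L) {
  .checkPos(pos, L)
  as.integer((pos - 1L + s) %% L + 1L)
}

#' @rdname shiftedToOriginal
#' @export
originalToShifted <- function(pos, s, L) {
  .checkPos(pos, L)
  as.integer((pos - 1L - s) %% L + 1L)
}

.checkPos <- function(pos, L) {
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > L)) {
    stop("position out of range [1, ", L, "]")
  }
}

#' Load a circular reference and its gene annotation from files
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param annotation_path optional path to a gene table: either a GFF3 file
#'   (`.gff`/`.gff3`, requires the rtracklayer package; `gene` taken from
#'   the Name/ID/gene attribute, `feature_type` from the type column) or a
#'   tab-separated table with columns `gene`, `start`, `end`, `strand`,
#'   `feature_type` and optionally `part`. `NULL` loads a reference with no
#'   annotation, so every position is later classed noncoding.
#' @return a [CircularReference-class].
#' @export
loadReference <- function(fasta_path, annotation_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(seqs))
  }
  nm <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- seqs[[1]]
  genes <- NULL
  if (!is.null(annotation_path)) {
    genes <- .readAnnotationTable(annotation_path, length(sequence))
  }
  CircularReference(nm, sequence, genes = genes)
}

.readAnnotationTable <- function(path, L) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 annotation requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    mc <- S4Vectors::mcols(gr)
    gene <- if (!is.null(mc$Name)) as.character(mc$Name)
      else if (!is.null(mc$ID)) as.character(mc$ID)
      else if (!is.null(mc$gene)) as.character(mc$gene)
      else stop("GFF3 records need a Name, ID or gene attribute")
    type_map <- c(CDS = "protein_coding", gene = "protein_coding",
                  mRNA = "protein_coding", tRNA = "tRNA", rRNA = "rRNA",
                  D_loop = "noncoding", region = "noncoding",
                  sequence_feature = "noncoding")
    ft <- as.character(mc$type)
    feature_type <- ifelse(ft %in% names(type_map), type_map[ft], "noncoding")
    tab <- data.frame(gene = gene,
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      feature_type = feature_type)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0L) return(NULL)
  .genesFromTable(tab, L)
}
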