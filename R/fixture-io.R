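## Plain-text fixture serialization: everything a downstream run needs is
## written as FASTA / TSV / VCF / MTX / JSON so fixtures stay inspectable
## and diff-able. Writing is deterministic: the same study object produces
## byte-identical files.

#' Write a simulated study to a fixture directory
#'
#' Files written: `reference.fasta`, `annotation.tsv`, `truth.vcf`
#' (founder + de novo variants with per-cell true AF as sample fields),
#' `dna_allele_counts.tsv`, `dna_depth_profile.tsv`,
#' `rna_allele_counts.tsv`, `gene_counts.mtx` (+ `gene_rows.tsv`,
#' `gene_cols.tsv`), `rna_reads.tsv` and `manifest.json` (config + seed +
#' package version).
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeFixture <- function(study, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  ref <- study$ref
  paths <- character()
  p <- file.path(dir, "reference.fasta")
  seqs <- Biostrings::DNAStringSet(refSequence(ref))
  names(seqs) <- refName(ref)
  Biostrings::writeXStringSet(seqs, p)
  paths <- c(paths, p)

  p <- file.path(dir, "annotation.tsv")
  utils::write.table(annotationTable(ref), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "truth.vcf")
  .writeTruthVcf(study$dna$truth, ref, p)
  paths <- c(paths, p)

  p <- file.path(dir, "dna_allele_counts.tsv")
  writeAlleleCounts(study$dna$counts, p)
  paths <- c(paths, p)

  p <- file.path(dir, "dna_depth_profile.tsv")
  dp <- study$dna$depths
  utils::write.table(
    data.frame(pos = seq_len(nrow(dp)), dp, check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "rna_allele_counts.tsv")
  writeAlleleCounts(study$rna$counts, p)
  paths <- c(paths, p)

  p <- file.path(dir, "gene_counts.mtx")
  Matrix::writeMM(study$rna$gene_counts, p)
  writeLines(rownames(study$rna$gene_counts),
             file.path(dir, "gene_rows.tsv"))
  writeLines(colnames(study$rna$gene_counts),
             file.path(dir, "gene_cols.tsv"))
  paths <- c(paths, p, file.path(dir, c("gene_rows.tsv", "gene_cols.tsv")))

  p <- file.path(dir, "rna_reads.tsv")
  utils::write.table(study$rna$reads, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "manifest.json")
  cfg <- study$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         package = "scMitoHet",
         version = as.character(utils::packageVersion("scMitoHet"))),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @describeIn writeFixture gene annotation of a reference as a plain table.
#' @param ref a [CircularReference-class].
#' @export
annotationTable <- function(ref) {
  g <- geneAnnotations(ref)
  data.frame(gene = S4Vectors::mcols(g)$gene,
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             feature_type = S4Vectors::mcols(g)$feature_type,
             part = S4Vectors::mcols(g)$part,
             stringsAsFactors = FALSE)
}

.writeTruthVcf <- function(truth, ref, path) {
  variants <- as.data.frame(truthVariants(truth))
  af <- truthAF(truth)
  cells <- truthCells(truth)$cell_id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", refName(ref), refLength(ref)),
    "##INFO=<ID=HAP,Number=1,Type=String,Description=\"Haplotype group\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"founder or denovo\">",
    paste0("##FORMAT=<ID=AF,Number=1,Type=Float,",
           "Description=\"True allele frequency\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cells), collapse = "\t")), con)
  ord <- order(variants$pos)
  for (i in ord) {
    info <- sprintf("HAP=%s;ORIGIN=%s",
                    ifelse(is.na(variants$haplotype[i]), ".",
                           variants$haplotype[i]),
                    variants$origin[i])
    fields <- c(refName(ref), variants$pos[i], ".", variants$ref[i],
                variants$alt[i], ".", "PASS", info, "AF",
                formatC(af[, i], format = "g", digits = 8))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read an allele-count matrix as a wide TSV
#'
#' One row per (cell, position) with the six allele counts as columns —
#' the package's plain-text pileup interchange format.
#'
#' @param acm an [AlleleCountMatrix-class].
#' @param path file path.
#' @export
writeAlleleCounts <- function(acm, path) {
  pos <- acmPositions(acm)
  cells <- acmCells(acm)
  ref <- SummarizedExperiment::rowData(acm)$ref
  long <- data.frame(
    cell = rep(cells, each = length(pos)),
    pos = rep(pos, times = length(cells)),
    ref = rep(ref, times = length(cells)))
  for (a in ALLELES) {
    long[[a]] <- as.vector(SummarizedExperiment::assay(acm, a))
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlleleCounts
#' @return `readAlleleCounts()` returns an [AlleleCountMatrix-class].
#' @export
readAlleleCounts <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell", "pos", "ref", ALLELES)
  if (!all(need %in% colnames(long))) {
    stop("allele-count table must have columns ",
         paste(need, collapse = ", "))
  }
  cells <- unique(long$cell)
  pos <- unique(long$pos)  # preserve the writer's row order
  idx_r <- match(long$pos, pos)
  idx_c <- match(long$cell, cells)
  counts <- lapply(ALLELES, function(a) {
    m <- matrix(0L, length(pos), length(cells))
    m[cbind(idx_r, idx_c)] <- as.integer(long[[a]])
    m
  })
  names(counts) <- ALLELES
  ref_base <- rep(NA_character_, length(pos))
  ref_base[idx_r] <- long$ref
  AlleleCountMatrix(counts, positions = pos, cells = cells,
                    ref_base = ref_base)
}
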