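## Heteroplasmy classification: the 0.04-0.96 window, the "most variable"
## and "most impactful" mutation lists, the DNA-RNA joint list, per-cell
## event counts, and the internal mitochondrial variant-effect annotator.

#' Is an allele frequency heteroplasmic?
#'
#' A variant is heteroplasmic in a cell when its allele frequency lies
#' inside the window `[floor, ceiling]` (both bounds inclusive); outside
#' it the site is treated as effectively homoplasmic wild-type or mutant.
#' `NA` (undefined AF) is not heteroplasmic.
#'
#' @param af numeric vector of allele frequencies in [0, 1] (NA allowed).
#' @param floor,ceiling window bounds, default 0.04 and 0.96.
#' @return logical vector.
#' @examples
#' isHeteroplasmic(c(0.5, 0.039, 0.97))  # TRUE FALSE FALSE
#' @export
isHeteroplasmic <- function(af, floor = 0.04, ceiling = 0.96) {
  !is.na(af) & af >= floor & af <= ceiling
}

#' Per-variant heteroplasmy summary
#'
#' For each call: the number and fraction of cells in which it is
#' heteroplasmic (the denominator is cells with a *defined* AF at the
#' site, so low-depth sites are not penalized twice) and the maximum
#' per-cell AF.
#'
#' @param vcs a [VariantCallSet-class].
#' @inheritParams isHeteroplasmic
#' @return data.frame: pos, ref, alt, n_cells_defined,
#'   n_cells_heteroplasmic, frac_cells_heteroplasmic, max_af.
#' @export
heteroplasmySummary <- function(vcs, floor = 0.04, ceiling = 0.96) {
  af <- afMatrix(vcs)
  info <- as.data.frame(variantInfo(vcs))
  n_def <- rowSums(!is.na(af))
  n_het <- rowSums(isHeteroplasmic(af, floor, ceiling))
  max_af <- apply(af, 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  data.frame(pos = info$pos, ref = info$ref, alt = info$alt,
             n_cells_defined = n_def, n_cells_heteroplasmic = n_het,
             frac_cells_heteroplasmic = ifelse(n_def > 0, n_het / n_def,
                                               NA_real_),
             max_af = max_af, stringsAsFactors = FALSE)
}

#' The "most variable" mutation list
#'
#' Keeps calls that are heteroplasmic (AF inside the 0.04-0.96 window) in
#' at least `min_cell_fraction` of cells with a defined AF — the filter
#' behind the "most variable" heteroplasmic mutation list. The 5% bound is
#' inclusive.
#'
#' @param vcs a [VariantCallSet-class].
#' @param min_cell_fraction inclusive lower bound on the heteroplasmic
#'   cell fraction (default 0.05).
#' @inheritParams isHeteroplasmic
#' @return the qualifying subset of `vcs` (a [VariantCallSet-class]).
#' @export
mostVariable <- function(vcs, min_cell_fraction = 0.05,
                         floor = 0.04, ceiling = 0.96) {
  if (ncol(afMatrix(vcs)) == 0L) stop("call set covers zero cells")
  s <- heteroplasmySummary(vcs, floor, ceiling)
  keep <- !is.na(s$frac_cells_heteroplasmic) &
    s$frac_cells_heteroplasmic >= min_cell_fraction
  vcs[which(keep), ]
}

#' The predicted "most impactful" mutation list
#'
#' Keeps calls satisfying both criteria: (1) present in at least one cell
#' strictly above `af_threshold` allele frequency (a modest phenotypic
#' threshold), and (2) a HIGH or MODERATE predicted impact — i.e.
#' stop-gained, frameshift or missense.
#'
#' @param vcs a [VariantCallSet-class].
#' @param effects effect table from [annotateEffect()], aligned row-wise
#'   with `vcs`.
#' @param af_threshold strict per-cell AF threshold (default 0.30).
#' @return the qualifying subset of `vcs`.
#' @export
mostImpactful <- function(vcs, effects, af_threshold = 0.30) {
  if (nrow(effects) != length(vcs)) {
    stop("effects must have one row per variant in the call set")
  }
  s <- heteroplasmySummary(vcs)
  keep <- !is.na(s$max_af) & s$max_af > af_threshold &
    effects$impact %in% c("HIGH", "MODERATE")
  vcs[which(keep), ]
}

#' The DNA-RNA "joint most impactful" mutation list
#'
#' Intersection of the DNA-arm "most impactful" list with RNA evidence:
#' a site qualifies if at least one RNA-arm cell is heteroplasmic there
#' (same alt allele). Untranscribed sites have no defined RNA AF and drop
#' out.
#'
#' @param dna_most_impactful a [VariantCallSet-class] (output of
#'   [mostImpactful()] on the DNA arm).
#' @param rna_calls a [VariantCallSet-class] from the RNA arm, in original
#'   coordinates.
#' @param het_floor,het_ceiling heteroplasmy window applied to RNA cells.
#' @return the qualifying subset of `dna_most_impactful`.
#' @export
jointImpactful <- function(dna_most_impactful, rna_calls,
                           het_floor = 0.04, het_ceiling = 0.96) {
  if (!length(dna_most_impactful)) return(dna_most_impactful)
  rna_info <- variantInfo(rna_calls)
  rna_het <- rowSums(isHeteroplasmic(afMatrix(rna_calls),
                                     het_floor, het_ceiling)) > 0
  rna_keys <- paste(rna_info$pos, rna_info$alt)[rna_het]
  dna_keys <- paste(variantInfo(dna_most_impactful)$pos,
                    variantInfo(dna_most_impactful)$alt)
  dna_most_impactful[which(dna_keys %in% rna_keys), ]
}

#' Heteroplasmic events per cell
#'
#' The number of calls whose AF in the given cell lies inside the
#' heteroplasmy window.
#'
#' @param vcs a [VariantCallSet-class].
#' @param cell_id one cell identifier, or NULL for all cells.
#' @inheritParams isHeteroplasmic
#' @return named integer vector (length 1 for a single cell).
#' @export
eventsPerCell <- function(vcs, cell_id = NULL, floor = 0.04,
                          ceiling = 0.96) {
  af <- afMatrix(vcs)
  if (!is.null(cell_id)) {
    if (!all(cell_id %in% colnames(af))) {
      stop("unknown cell(s): ",
           paste(setdiff(cell_id, colnames(af)), collapse = ", "))
    }
    af <- af[, cell_id, drop = FALSE]
  }
  if (nrow(af) == 0L) {
    return(stats::setNames(integer(ncol(af)), colnames(af)))
  }
  colSums(isHeteroplasmic(af, floor, ceiling))
}

## ---- effect annotation --------------------------------------------------

.mitoCode <- function() Biostrings::getGeneticCode("2")

# CDS model for one protein gene: genomic positions in mRNA (5'->3') order
# plus the mRNA sequence. Sub-intervals are concatenated in `part` order;
# on the minus strand the concatenated genomic sequence is
# reverse-complemented.
.cdsModel <- function(ref, gene_rows) {
  ord <- order(S4Vectors::mcols(gene_rows)$part)
  gene_rows <- gene_rows[ord]
  genomic_pos <- unlist(lapply(seq_along(gene_rows), function(i) {
    seq(GenomicRanges::start(gene_rows)[i], GenomicRanges::end(gene_rows)[i])
  }))
  strand <- as.character(GenomicRanges::strand(gene_rows))[1]
  seq_chr <- strsplit(as.character(refSequence(ref)), "")[[1]]
  fwd <- seq_chr[genomic_pos]
  if (strand == "-") {
    mrna <- rev(chartr("ACGT", "TGCA", fwd))
    mrna_pos <- rev(genomic_pos)
  } else {
    mrna <- fwd
    mrna_pos <- genomic_pos
  }
  list(mrna = mrna, mrna_pos = mrna_pos, strand = strand)
}

#' Predict the coding effect of mitochondrial variants
#'
#' An internal variant-effect annotator for circular mitochondrial
#' genomes, using the vertebrate mitochondrial genetic code (TGA = Trp,
#' AGA/AGG = stop, ATA = Met). A variant outside any protein-coding gene
#' (including tRNA and rRNA positions) is `noncoding` with impact
#' MODIFIER. Inside a protein gene, the affected codon is translated
#' before and after the substitution — honoring strand, i.e. the alt base
#' is complemented for minus-strand genes — and the verdict is
#' `stop_gained` (HIGH), `missense` (MODERATE) or `synonymous` (LOW).
#' Single-base DEL/INS alleles in coding sequence shift the frame:
#' `frameshift` (HIGH). Loss of a start or stop codon is collapsed into
#' the missense/stop-gained taxonomy.
#'
#' @param vcs a [VariantCallSet-class], or a data.frame with columns pos
#'   and alt (plus optional ref).
#' @param ref a [CircularReference-class] carrying protein-coding gene
#'   annotation.
#' @return data.frame with one row per variant: gene, effect
#'   (stop_gained / frameshift / missense / synonymous / noncoding),
#'   impact (HIGH / MODERATE / LOW / MODIFIER), codon_change, aa_change.
#' @export
annotateEffect <- function(vcs, ref) {
  info <- if (methods::is(vcs, "VariantCallSet")) {
    as.data.frame(variantInfo(vcs))
  } else {
    as.data.frame(vcs)
  }
  genes <- geneAnnotations(ref)
  coding <- genes[S4Vectors::mcols(genes)$feature_type == "protein_coding"]
  code <- .mitoCode()
  models <- list()
  out <- data.frame(gene = NA_character_, effect = "noncoding",
                    impact = "MODIFIER", codon_change = NA_character_,
                    aa_change = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, nrow(info)), ]
  rownames(out) <- NULL
  if (nrow(info) == 0L) return(out[0L, ])
  # record tRNA/rRNA/noncoding feature names for context
  for (i in seq_len(nrow(info))) {
    pos <- info$pos[i]
    hit_any <- which(GenomicRanges::start(genes) <= pos &
                       GenomicRanges::end(genes) >= pos)
    if (length(hit_any)) {
      out$gene[i] <- S4Vectors::mcols(genes)$gene[hit_any[1]]
    }
    hit <- which(GenomicRanges::start(coding) <= pos &
                   GenomicRanges::end(coding) >= pos)
    if (!length(hit)) next
    gene_name <- S4Vectors::mcols(coding)$gene[hit[1]]
    out$gene[i] <- gene_name
    if (is.null(models[[gene_name]])) {
      rows <- coding[S4Vectors::mcols(coding)$gene == gene_name]
      if (sum(GenomicRanges::width(rows)) %% 3L != 0L) {
        stop("protein-coding gene '", gene_name,
             "' has length not divisible by 3; cannot annotate")
      }
      models[[gene_name]] <- .cdsModel(ref, rows)
    }
    model <- models[[gene_name]]
    alt <- info$alt[i]
    if (alt %in% c("DEL", "INS")) {
      # single-base indel: frame shift by construction
      out$effect[i] <- "frameshift"
      out$impact[i] <- "HIGH"
      next
    }
    cds_i <- match(pos, model$mrna_pos)
    alt_base <- if (model$strand == "-") chartr("ACGT", "TGCA", alt) else alt
    codon_idx <- (cds_i - 1L) %/% 3L
    cpos <- codon_idx * 3L + 1:3
    codon_ref <- paste(model$mrna[cpos], collapse = "")
    codon_alt_vec <- model$mrna[cpos]
    codon_alt_vec[cds_i - codon_idx * 3L] <- alt_base
    codon_alt <- paste(codon_alt_vec, collapse = "")
    aa_ref <- unname(code[codon_ref])
    aa_alt <- unname(code[codon_alt])
    out$codon_change[i] <- paste0(codon_ref, ">", codon_alt)
    out$aa_change[i] <- paste0(aa_ref, codon_idx + 1L, aa_alt)
    if (aa_ref == aa_alt) {
      out$effect[i] <- "synonymous"; out$impact[i] <- "LOW"
    } else if (aa_alt == "*") {
      out$effect[i] <- "stop_gained"; out$impact[i] <- "HIGH"
    } else {
      out$effect[i] <- "missense"; out$impact[i] <- "MODERATE"
    }
  }
  out
}

#' Full classification table for a call set
#'
#' One row per mutation with its effect annotation, heteroplasmy summary
#' and list memberships — the package's main classification output.
#'
#' @param vcs a [VariantCallSet-class] (DNA arm, merged coordinates).
#' @param ref a [CircularReference-class].
#' @param rna_calls optional RNA-arm [VariantCallSet-class] for the joint
#'   list.
#' @param min_cell_fraction,af_threshold,floor,ceiling thresholds passed
#'   to the list builders.
#' @return data.frame with columns pos, ref, alt, gene, effect, impact,
#'   n_cells_defined, n_cells_heteroplasmic, frac_cells_heteroplasmic,
#'   max_af, in_most_variable, in_most_impactful, in_joint_impactful.
#' @export
classifyMutations <- function(vcs, ref, rna_calls = NULL,
                              min_cell_fraction = 0.05,
                              af_threshold = 0.30,
                              floor = 0.04, ceiling = 0.96) {
  s <- heteroplasmySummary(vcs, floor, ceiling)
  eff <- annotateEffect(vcs, ref)
  mv <- mostVariable(vcs, min_cell_fraction, floor, ceiling)
  mi <- mostImpactful(vcs, eff, af_threshold)
  key <- paste(s$pos, s$alt)
  out <- cbind(s[, c("pos", "ref", "alt")],
               eff[, c("gene", "effect", "impact")],
               s[, c("n_cells_defined", "n_cells_heteroplasmic",
                     "frac_cells_heteroplasmic", "max_af")])
  out$in_most_variable <- key %in%
    paste(variantInfo(mv)$pos, variantInfo(mv)$alt)
  out$in_most_impactful <- key %in%
    paste(variantInfo(mi)$pos, variantInfo(mi)$alt)
  out$in_joint_impactful <- FALSE
  if (!is.null(rna_calls)) {
    ji <- jointImpactful(mi, rna_calls, floor, ceiling)
    out$in_joint_impactful <- key %in%
      paste(variantInfo(ji)$pos, variantInfo(ji)$alt)
  }
  out
}
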