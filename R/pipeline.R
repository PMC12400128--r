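## End-to-end analysis of a (simulated or loaded) two-arm study: QC, cell
## filtering, circular-aware calling, classification, and condition /
## modality comparisons.

#' Analyze a two-arm heteroplasmy study
#'
#' Runs the full pipeline on a study object (typically from
#' [simulateStudy()]):
#' \enumerate{
#'   \item DNA-arm fragment-depth QC; failing cells are dropped.
#'   \item RNA-arm cell QC (mitochondrial fraction, feature count, mean
#'     mitochondrial depth); failing cells are dropped.
#'   \item Circular-aware DNA calling: the allele counts are viewed
#'     through an unshifted and a shifted linear reference
#'     ([splitCircularViews()]), called separately and merged with
#'     [mergeShiftedCalls()].
#'   \item RNA-arm calling at the RNA depth threshold.
#'   \item Classification: heteroplasmy summaries, "most variable",
#'     "most impactful" (internal effect annotator) and the DNA-RNA
#'     joint list.
#'   \item Induced/noninduced comparisons per mutation and for
#'     heteroplasmic events per cell; DNA vs RNA pseudobulk modality
#'     table.
#' }
#'
#' @param study list from [simulateStudy()] (or assembled from loaded
#'   data with the same shape).
#' @param dna_min_depth per-cell depth threshold for a defined DNA AF.
#' @param rna_min_depth same for the RNA arm (50 = "above 49" retention).
#' @param junction_halfwidth merge zone around the circular origin (bp).
#' @param shift rotation offset for the shifted calling pass.
#' @param loss_halfwidth linear-mapper coverage loss emulated at each
#'   reference end when splitting views.
#' @return list with qc_dna, qc_rna, fragment_differential, calls_dna,
#'   calls_rna, classification, most_variable, most_impactful,
#'   joint_impactful, condition_tests, modality, events_per_cell.
#' @export
analyzeStudy <- function(study,
                         dna_min_depth = 100L,
                         rna_min_depth = 50L,
                         junction_halfwidth = 1000L,
                         shift = refLength(study$ref) %/% 2L,
                         loss_halfwidth = 50L) {
  ref <- study$ref
  L <- refLength(ref)

  qc_dna <- fragmentDepthQCMatrix(study$dna$depths)
  dna_cells <- qc_dna$cell_id[qc_dna$passed]
  frag_diff <- absoluteFragmentDifferential(qc_dna)

  qc_rna <- rnaCellQCMatrix(study$rna$gene_counts, study$rna$depths)
  rna_cells <- qc_rna$cell_id[qc_rna$passed]

  dna_acm <- study$dna$counts[, dna_cells]
  views <- splitCircularViews(dna_acm, ref, s = shift,
                              loss_halfwidth = loss_halfwidth)
  calls_un <- callVariants(views$unshifted, ref, min_depth = dna_min_depth)
  calls_sh <- callVariants(views$shifted, views$shifted_ref,
                           min_depth = dna_min_depth)
  calls_dna <- mergeShiftedCalls(calls_un, calls_sh, s = views$s, L = L,
                                 junction_halfwidth = junction_halfwidth)

  rna_acm <- study$rna$counts[, rna_cells]
  calls_rna <- callVariants(rna_acm, ref, min_depth = rna_min_depth)

  classification <- classifyMutations(calls_dna, ref,
                                      rna_calls = calls_rna)
  eff <- annotateEffect(calls_dna, ref)
  mv <- mostVariable(calls_dna)
  mi <- mostImpactful(calls_dna, eff)
  ji <- jointImpactful(mi, calls_rna)

  cond_dna <- stats::setNames(
    as.character(truthCells(study$dna$truth)$condition),
    truthCells(study$dna$truth)$cell_id)
  condition_tests <- if (length(mv)) {
    compareConditions(mv, cond_dna)
  } else NULL

  pb_dna <- pseudobulk(dna_acm, ref)
  noninduced_rna <- intersect(
    rna_cells,
    truthCells(study$rna$truth)$cell_id[
      truthCells(study$rna$truth)$condition == "noninduced"])
  pb_rna <- pseudobulk(rna_acm, ref, cells = noninduced_rna)
  modality <- modalityCompare(pb_dna, pb_rna)

  list(qc_dna = qc_dna, qc_rna = qc_rna,
       fragment_differential = frag_diff,
       calls_dna = calls_dna, calls_rna = calls_rna,
       classification = classification,
       most_variable = mv, most_impactful = mi, joint_impactful = ji,
       condition_tests = condition_tests, modality = modality,
       events_per_cell = eventsPerCell(calls_dna),
       dna_cells = dna_cells, rna_cells = rna_cells)
}
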