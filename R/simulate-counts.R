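## Read-count simulation for the DNA and RNA arms, circular "views" that
## emulate linear-mapper coverage loss, and fixture I/O.

.rnbinomDepth <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(as.integer(round(rep_len(mu, n))))
  as.integer(stats::rnbinom(n, size = 1 / dispersion, mu = mu))
}

# fill in ref (from the reference sequence) and alt (random non-ref base)
# for variants the lineage simulator created without alleles
.completeVariantAlleles <- function(variants, ref) {
  variants <- as.data.frame(variants)
  na_ref <- is.na(variants$ref)
  if (any(na_ref)) variants$ref[na_ref] <- refBaseAt(ref, variants$pos[na_ref])
  mismatch <- !is.na(variants$ref) &
    variants$ref != refBaseAt(ref, variants$pos)
  if (any(mismatch)) {
    stop("founder variant reference allele does not match the reference ",
         "sequence at position(s) ",
         paste(variants$pos[mismatch], collapse = ", "))
  }
  na_alt <- is.na(variants$alt)
  for (i in which(na_alt)) {
    variants$alt[i] <- sample(setdiff(BASES, variants$ref[i]), 1L)
  }
  variants
}

# multinomial read counts at one site, vectorized across cells: alt reads
# at af(1-e) + (1-af)e/3, each non-ref non-alt base at e/3, remainder ref.
# The multinomial is drawn as sequential conditional binomials.
.sampleSiteCounts <- function(depth, af, ref, alt, error_rate) {
  e <- error_rate
  n <- length(depth)
  others <- setdiff(BASES, c(ref, alt))
  p_alt <- af * (1 - e) + (1 - af) * e / 3
  alt_c <- stats::rbinom(n, depth, pmin(pmax(p_alt, 0), 1))
  rem <- depth - alt_c
  p_rem <- 1 - p_alt
  counts <- matrix(0L, 4L, n, dimnames = list(BASES, NULL))
  counts[alt, ] <- alt_c
  for (b in others) {
    p_cond <- ifelse(p_rem > 0, (e / 3) / p_rem, 0)
    o <- stats::rbinom(n, rem, pmin(pmax(p_cond, 0), 1))
    counts[b, ] <- o
    rem <- rem - o
    p_rem <- p_rem - e / 3
  }
  counts[ref, ] <- rem
  counts
}

#' Simulate DNA-arm allele counts with two-fragment amplification bias
#'
#' Models the two-amplicon long-range-PCR design: the genome is tiled by
#' fragment X (positions 1..floor(L/2)) and fragment Y (the rest). Each
#' cell draws a lognormal amplification factor b; X positions are covered
#' at `mean_depth * b` and Y positions at `mean_depth / b` (reciprocal
#' bias), with negative-binomial noise per base. A configured number of
#' cells get fragment-X coverage scaled by `low_depth_factor` (these are
#' the cells the fragment-depth QC should remove), and optionally one cell
#' is given a fixed extreme-but-passing imbalance. Allele counts at every
#' variant position are multinomial given the cell's true allele frequency
#' and the sequencing error rate, so the total at each (cell, position)
#' equals the drawn depth exactly.
#'
#' @param truth a [CellTruthSet-class] (from [simulateLineage()] or
#'   [cellTruthSet()]).
#' @param ref a [CircularReference-class].
#' @param config a [simulationConfig()].
#' @return list with elements `counts` (an [AlleleCountMatrix-class] over
#'   the variant positions), `depths` (full L x cells per-base depth
#'   matrix), `truth` (the input truth with de novo alleles filled in) and
#'   `engineered` (data.frame recording which cells carry constructed QC
#'   defects).
#' @export
simulateDnaCounts <- function(truth, ref, config) {
  set.seed(config$seed + 1L)
  L <- refLength(ref)
  variants <- .completeVariantAlleles(truthVariants(truth), ref)
  if (nrow(variants) && any(variants$pos > L)) {
    stop("variant position outside the reference")
  }
  cells <- truthCells(truth)$cell_id
  n <- length(cells)
  bias <- stats::rlnorm(n, 0, config$fragment_bias_sd)

  engineered <- data.frame(cell_id = character(), role = character(),
                           stringsAsFactors = FALSE)
  cond <- truthCells(truth)$condition
  low_cells <- integer(0)
  if (config$n_low_depth_cells > 0L) {
    # split the constructed low-coverage cells evenly across conditions
    per_cond <- split(seq_len(n), cond)
    quota <- rep(config$n_low_depth_cells %/% length(per_cond),
                 length(per_cond))
    extra <- config$n_low_depth_cells - sum(quota)
    if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    low_cells <- unlist(mapply(function(idx, k) {
      sample(idx, min(k, length(idx)))
    }, per_cond, quota, SIMPLIFY = FALSE), use.names = FALSE)
    engineered <- rbind(engineered, data.frame(
      cell_id = cells[low_cells], role = "low_fragment_depth"))
  }
  if (config$n_imbalanced_cells > 0L) {
    pool <- setdiff(seq_len(n), low_cells)
    imb <- sample(pool, min(config$n_imbalanced_cells, length(pool)))
    bias[imb] <- 0.45  # ~83% of depth on fragment Y, both fragments >= 1000x
    engineered <- rbind(engineered, data.frame(
      cell_id = cells[imb], role = "fragment_imbalance"))
  }

  half <- L %/% 2L
  in_x <- seq_len(L) <= half
  depths <- matrix(0L, L, n, dimnames = list(NULL, cells))
  for (j in seq_len(n)) {
    mu_x <- config$mean_depth * bias[j]
    if (j %in% low_cells) mu_x <- mu_x * config$low_depth_factor
    mu_y <- config$mean_depth / bias[j]
    mu <- ifelse(in_x, mu_x, mu_y)
    depths[, j] <- .rnbinomDepth(L, mu, config$depth_dispersion)
  }

  nv <- nrow(variants)
  assays <- lapply(ALLELES, function(a) matrix(0L, nv, n))
  names(assays) <- ALLELES
  af <- truthAF(truth)
  for (i in seq_len(nv)) {
    counts <- .sampleSiteCounts(depths[variants$pos[i], ], af[, i],
                                variants$ref[i], variants$alt[i],
                                config$error_rate)
    for (b in BASES) assays[[b]][i, ] <- counts[b, ]
  }
  acm <- AlleleCountMatrix(assays, positions = variants$pos, cells = cells,
                           ref = ref)
  truth@variants <- S4Vectors::DataFrame(variants)
  list(counts = acm, depths = depths, truth = truth,
       engineered = engineered)
}

#' Split circularly complete counts into unshifted and shifted mapper views
#'
#' Emulates what a linear aligner delivers from a circular genome: the
#' unshifted view loses all coverage within `loss_halfwidth` of the origin
#' (positions <= loss_halfwidth or > L - loss_halfwidth), and the shifted
#' view — the same counts re-coordinated onto a reference rotated by `s` —
#' loses coverage near its own junction. Calling each view and merging with
#' [mergeShiftedCalls()] should recover exactly the allele frequencies
#' implied by the complete matrix.
#'
#' @param acm a circularly complete [AlleleCountMatrix-class].
#' @param ref the [CircularReference-class] the counts are expressed on.
#' @param s rotation offset; defaults to floor(L/2).
#' @param loss_halfwidth bp of coverage lost at each linear reference end.
#' @return list with `unshifted` and `shifted` AlleleCountMatrix objects
#'   (the latter in shifted coordinates), the rotated reference
#'   `shifted_ref`, and `s`.
#' @export
splitCircularViews <- function(acm, ref, s = refLength(ref) %/% 2L,
                               loss_halfwidth = 50L) {
  L <- refLength(ref)
  pos <- acmPositions(acm)
  zero_rows <- function(obj, rows) {
    for (a in ALLELES) {
      m <- SummarizedExperiment::assay(obj, a)
      m[rows, ] <- 0L
      SummarizedExperiment::assay(obj, a) <- m
    }
    obj
  }
  near_end <- function(p) p <= loss_halfwidth | p > L - loss_halfwidth
  unshifted <- zero_rows(acm, which(near_end(pos)))

  spos <- originalToShifted(pos, s, L)
  ord <- order(spos)
  shifted <- acm[ord, ]
  rd <- SummarizedExperiment::rowData(shifted)
  rd$pos <- spos[ord]
  SummarizedExperiment::rowData(shifted) <- rd
  rownames(shifted) <- as.character(spos[ord])
  shifted <- zero_rows(shifted, which(near_end(spos[ord])))
  list(unshifted = unshifted, shifted = shifted,
       shifted_ref = rotateReference(ref, s), s = as.integer(s))
}

#' Simulate the scRNA-seq arm of a synthetic study
#'
#' Generates, for the cells of `truth`: (i) a sparse cell-by-gene count
#' matrix with configurable mitochondrial-fraction and feature-count
#' structure, including cells engineered to violate the RNA QC bounds and
#' a recombinant-antibody transcript whose abundance is higher in induced
#' cells; (ii) mitochondrial allele counts restricted to transcribed
#' intervals at RNA depth, carrying the lineage's true variants plus the
#' configured RNA-specific variants (injected into RNA counts only); and
#' (iii) raw read records of which a configurable fraction carry internal
#' or terminal runs of >= 5 A's, for exercising polyA masking.
#'
#' @param truth a [CellTruthSet-class] for the RNA-arm cells.
#' @param ref a [CircularReference-class].
#' @param config a [simulationConfig()]; the `rna` sublist is used.
#' @return list with `gene_counts` (dgCMatrix genes x cells), `counts`
#'   (an [AlleleCountMatrix-class]), `depths` (transcribed-position depth
#'   matrix), `reads` (data.frame cell_id, read), `truth` (alleles filled
#'   in), `engineered` and `transcribed` (IRanges of transcribed
#'   intervals).
#' @export
simulateRnaArm <- function(truth, ref, config) {
  set.seed(config$seed + 2L)
  rc <- config$rna
  cells <- truthCells(truth)$cell_id
  cond <- truthCells(truth)$condition
  n <- length(cells)
  L <- refLength(ref)

  genes_gr <- geneAnnotations(ref)
  transcribed_gr <- genes_gr[S4Vectors::mcols(genes_gr)$feature_type %in%
                               c("protein_coding", "tRNA", "rRNA")]
  transcribed <- IRanges::reduce(IRanges::ranges(transcribed_gr))
  tr_pos <- unlist(lapply(seq_along(transcribed), function(i) {
    seq(IRanges::start(transcribed)[i], IRanges::end(transcribed)[i])
  }))

  # engineered QC defects on disjoint cells
  shuffled <- sample.int(n)
  take <- function(k) {
    idx <- shuffled[seq_len(min(k, length(shuffled)))]
    shuffled <<- shuffled[-seq_len(min(k, length(shuffled)))]
    idx
  }
  mito_out <- take(rc$n_mito_outliers)
  low_feat <- take(rc$n_low_feature_cells)
  high_feat <- take(rc$n_high_feature_cells)
  low_depth <- take(rc$n_low_depth_cells)
  engineered <- rbind(
    data.frame(cell_id = cells[mito_out], role = "high_mito_fraction"),
    data.frame(cell_id = cells[low_feat], role = "low_feature_count"),
    data.frame(cell_id = cells[high_feat], role = "high_feature_count"),
    data.frame(cell_id = cells[low_depth], role = "low_mito_depth"))

  # --- cell-by-gene matrix ------------------------------------------------
  mito_names <- unique(S4Vectors::mcols(transcribed_gr)$gene)
  n_mito <- max(rc$n_mito_genes, length(mito_names))
  if (length(mito_names) < n_mito) {
    mito_names <- c(mito_names,
                    sprintf("mt-x%02d", seq_len(n_mito - length(mito_names))))
  }
  mito_names <- paste0("mt-", mito_names[seq_len(n_mito)])
  nuc_names <- sprintf("gene%05d", seq_len(rc$n_genes - n_mito))
  gene_names <- c(mito_names, nuc_names, "pvz_igg")
  ng <- length(gene_names)

  mito_frac <- stats::rbeta(n, rc$mito_fraction_shape1,
                            rc$mito_fraction_shape2)
  mito_frac[mito_out] <- rc$mito_outlier_fraction
  nf <- round(stats::rnorm(n, rc$feature_count_mean, rc$feature_count_sd))
  nf[low_feat] <- rc$low_feature_count
  nf[high_feat] <- rc$high_feature_count
  nf <- pmin(pmax(nf, n_mito + 2L), rc$n_genes)
  totals <- round(stats::rlnorm(n, log(rc$total_reads_mean) - 0.02, 0.2))
  mito_w <- stats::rgamma(n_mito, 2, 1) + 0.1
  nuc_w <- stats::rgamma(length(nuc_names), 0.8, 1) + 0.05

  counts_list <- vector("list", n)
  for (j in seq_len(n)) {
    v <- integer(ng)
    m_reads <- round(totals[j] * mito_frac[j])
    v[seq_len(n_mito)] <- as.integer(
      stats::rmultinom(1L, m_reads, mito_w))
    k_nuc <- nf[j] - n_mito
    picked <- sample(length(nuc_names), k_nuc, prob = nuc_w)
    nuc_reads <- totals[j] - m_reads
    extra <- as.integer(stats::rmultinom(1L, max(nuc_reads - k_nuc, 0),
                                         nuc_w[picked]))
    v[n_mito + picked] <- 1L + extra
    igg_mu <- rc$igg_mean_noninduced *
      ifelse(cond[j] == "induced", rc$igg_fold_induced, 1)
    v[ng] <- stats::rnbinom(1L, size = 5, mu = igg_mu)
    counts_list[[j]] <- v
  }
  gene_counts <- Matrix::Matrix(
    do.call(cbind, counts_list), sparse = TRUE,
    dimnames = list(gene_names, cells))

  # --- mitochondrial depth and allele counts ------------------------------
  variants <- .completeVariantAlleles(truthVariants(truth), ref)
  rsv <- rc$rna_specific_variants
  if (!is.null(rsv) && nrow(rsv)) {
    rsv <- data.frame(pos = as.integer(rsv$pos),
                      ref = as.character(rsv$ref),
                      alt = as.character(rsv$alt),
                      haplotype = NA_character_, origin = "rna_specific",
                      af = rsv$af, stringsAsFactors = FALSE)
    rsv[c("ref", "alt")] <-
      .completeVariantAlleles(rsv[, 1:5], ref)[c("ref", "alt")]
  } else {
    rsv <- data.frame(pos = integer(), ref = character(), alt = character(),
                      haplotype = character(), origin = character(),
                      af = numeric(), stringsAsFactors = FALSE)
  }
  # one count row per position: an injected RNA-only variant overrides any
  # lineage variant that happens to share its position
  keep <- !(variants$pos %in% rsv$pos)
  all_pos <- c(variants$pos[keep], rsv$pos)
  all_ref <- c(variants$ref[keep], rsv$ref)
  all_alt <- c(variants$alt[keep], rsv$alt)
  af_mat <- cbind(truthAF(truth)[, keep, drop = FALSE],
                  matrix(rep(rsv$af, each = n), nrow = n))

  mu_depth <- rep(rc$mito_mean_depth, n)
  mu_depth[low_depth] <- rc$low_depth_mean
  depths <- matrix(0L, length(tr_pos), n,
                   dimnames = list(as.character(tr_pos), cells))
  for (j in seq_len(n)) {
    depths[, j] <- .rnbinomDepth(length(tr_pos), mu_depth[j],
                                 rc$mito_depth_dispersion)
  }

  nv <- length(all_pos)
  assays <- lapply(ALLELES, function(a) matrix(0L, nv, n))
  names(assays) <- ALLELES
  tr_index <- match(all_pos, tr_pos)  # NA => untranscribed, depth 0
  for (i in seq_len(nv)) {
    if (is.na(tr_index[i])) next
    counts <- .sampleSiteCounts(depths[tr_index[i], ], af_mat[, i],
                                all_ref[i], all_alt[i], config$error_rate)
    for (b in BASES) assays[[b]][i, ] <- counts[b, ]
  }
  ord <- order(all_pos)
  acm <- AlleleCountMatrix(lapply(assays, function(m) m[ord, , drop = FALSE]),
                           positions = all_pos[ord], cells = cells,
                           ref = ref)

  # --- raw reads with polyA contamination ---------------------------------
  reads <- .simulateReads(rc$n_reads, rc$read_length, rc$polyA_rate, cells)

  truth@variants <- S4Vectors::DataFrame(variants)
  list(gene_counts = gene_counts, counts = acm, depths = depths,
       reads = reads, truth = truth, engineered = engineered,
       transcribed = transcribed,
       rna_specific = rsv[, c("pos", "ref", "alt", "af")])
}

.simulateReads <- function(n_reads, read_length, polyA_rate, cells) {
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste(sample(BASES, read_length, replace = TRUE), collapse = "")
  }, character(1))
  # break any chance runs of >= 5 A so only injected contamination remains
  seqs <- gsub("(AAAA)A", "\\1C", seqs)
  while (any(grepl("AAAAA", seqs))) seqs <- gsub("(AAAA)A", "\\1C", seqs)
  n_poly <- round(polyA_rate * n_reads)
  if (n_poly > 0) {
    idx <- sample.int(n_reads, n_poly)
    for (i in idx) {
      run <- strrep("A", sample(5:30, 1L))
      at <- sample.int(read_length - 1L, 1L)
      s <- seqs[i]
      s <- paste0(substr(s, 1L, at), run,
                  substr(s, at + 1L, read_length))
      seqs[i] <- substr(s, 1L, read_length)
    }
  }
  data.frame(cell_id = sample(cells, n_reads, replace = TRUE),
             read = seqs, stringsAsFactors = FALSE)
}

#' Simulate a complete two-arm synthetic study
#'
#' Runs the whole generator: the synthetic circular reference, a DNA-arm
#' lineage with deep two-fragment counts, and an independently drawn
#' RNA-arm lineage (the two arms come from different culture batches, so
#' their cells are distinct) with gene counts, RNA allele counts and raw
#' reads.
#'
#' @param config a [simulationConfig()].
#' @return list with `config`, `ref`, `dna` (see [simulateDnaCounts()])
#'   and `rna` (see [simulateRnaArm()]).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  ref <- syntheticReference(L = config$genome_length)
  dna_truth <- simulateLineage(config)
  dna <- simulateDnaCounts(dna_truth, ref, config)
  rna_config <- config
  rna_config$n_cells <- config$rna$n_cells
  rna_config$seed <- config$seed + 1000L
  class(rna_config) <- class(config)
  rna_truth <- simulateLineage(rna_config)
  rna <- simulateRnaArm(rna_truth, ref, config)
  list(config = config, ref = ref, dna = dna, rna = rna)
}
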