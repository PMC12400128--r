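#' Simulation configuration for a synthetic heteroplasmy study
#'
#' Bundles, with validation, every parameter of the synthetic-data
#' generator. The defaults describe a clonally derived CHO-like cell
#' population profiled on two arms: 88 DNA-arm single cells (44 induced /
#' 44 noninduced) with deep two-fragment long-range-PCR coverage of a
#' 16.3 kb circular mitochondrial genome, of which 4 cells are constructed
#' with sub-threshold coverage in one fragment; and a 300-cell RNA arm with
#' shallower, transcript-restricted coverage, engineered QC outliers,
#' RNA-only variants and polyA-contaminated reads.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param n_cells number of DNA-arm cells to sample from the lineage.
#' @param generations number of cell divisions separating the sampled cells
#'   from the founder cell.
#' @param mtdna_copies effective mtDNA copy number N per cell (the
#'   segregation bottleneck size).
#' @param founder_variants data.frame with columns pos, ref, alt, af and
#'   optionally haplotype (variants sharing a haplotype label sit on the
#'   same mtDNA molecules and therefore co-segregate).
#' @param mutation_rate de novo mutation probability per mtDNA copy per
#'   generation.
#' @param genome_length circular genome length L (bp).
#' @param mean_depth DNA-arm mean per-base read depth.
#' @param depth_dispersion negative-binomial overdispersion of depth
#'   (variance = mu + dispersion * mu^2); 0 gives deterministic depth.
#' @param error_rate per-base sequencing miscall probability.
#' @param fragment_bias_sd sd of the per-cell lognormal amplification
#'   log-factor between the two long-range-PCR fragments.
#' @param condition_fractions named fractions of cells labelled induced /
#'   noninduced.
#' @param n_low_depth_cells number of DNA-arm cells constructed with
#'   sub-threshold fragment-X coverage (split evenly across conditions).
#' @param low_depth_factor multiplier applied to fragment-X depth of those
#'   cells.
#' @param n_imbalanced_cells number of otherwise-passing cells given an
#'   extreme (but non-fatal) fragment imbalance.
#' @param rna list of RNA-arm parameters: n_cells, n_genes, n_mito_genes,
#'   mito_fraction_shape1/2 (Beta parameters of the mitochondrial read
#'   fraction), feature_count_mean/sd, total_reads_mean,
#'   mito_mean_depth, mito_depth_dispersion, n_mito_outliers +
#'   mito_outlier_fraction, n_low_feature_cells / low_feature_count,
#'   n_high_feature_cells / high_feature_count, n_low_depth_cells /
#'   low_depth_mean, polyA_rate, n_reads, read_length,
#'   rna_specific_variants (data.frame pos, ref, alt, af),
#'   igg_mean_noninduced, igg_fold_induced.
#' @return a validated list of class `simulation_config`.
#' @seealso [simulateLineage()], [simulateStudy()]
#' @export
simulationConfig <- function(seed = 1L,
                             n_cells = 88L,
                             generations = 30L,
                             mtdna_copies = 500L,
                             founder_variants = defaultFounderVariants(),
                             mutation_rate = 2e-4,
                             genome_length = 16300L,
                             mean_depth = 2500,
                             depth_dispersion = 0.15,
                             error_rate = 0.001,
                             fragment_bias_sd = 0.2,
                             condition_fractions = c(induced = 0.5,
                                                     noninduced = 0.5),
                             n_low_depth_cells = 4L,
                             low_depth_factor = 0.12,
                             n_imbalanced_cells = 1L,
                             rna = list()) {
  rna_defaults <- list(
    n_cells = 300L,
    n_genes = 5000L,
    n_mito_genes = 13L,
    mito_fraction_shape1 = 4,
    mito_fraction_shape2 = 46,
    feature_count_mean = 3000,
    feature_count_sd = 350,
    total_reads_mean = 20000,
    mito_mean_depth = 80,
    mito_depth_dispersion = 0.3,
    n_mito_outliers = 5L,
    mito_outlier_fraction = 0.30,
    n_low_feature_cells = 2L,
    low_feature_count = 1500L,
    n_high_feature_cells = 2L,
    high_feature_count = 4500L,
    n_low_depth_cells = 2L,
    low_depth_mean = 30,
    polyA_rate = 0.15,
    n_reads = 2000L,
    read_length = 90L,
    rna_specific_variants = data.frame(
      pos = c(2500L, 9900L), ref = NA_character_, alt = NA_character_,
      af = c(0.15, 0.30)),
    igg_mean_noninduced = 30,
    igg_fold_induced = 9)
  # data.frame entries must be replaced whole, not merged column-wise
  rsv_user <- rna$rna_specific_variants
  rna$rna_specific_variants <- NULL
  rna <- utils::modifyList(rna_defaults, rna)
  if (!is.null(rsv_user)) rna$rna_specific_variants <- rsv_user
  cfg <- list(seed = as.integer(seed), n_cells = as.integer(n_cells),
              generations = as.integer(generations),
              mtdna_copies = as.integer(mtdna_copies),
              founder_variants = founder_variants,
              mutation_rate = mutation_rate,
              genome_length = as.integer(genome_length),
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              fragment_bias_sd = fragment_bias_sd,
              condition_fractions = condition_fractions,
              n_low_depth_cells = as.integer(n_low_depth_cells),
              low_depth_factor = low_depth_factor,
              n_imbalanced_cells = as.integer(n_imbalanced_cells),
              rna = rna)
  .validateConfig(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$mtdna_copies >= 1L, cfg$n_cells >= 1L,
            cfg$generations >= 0L, cfg$genome_length >= 1L,
            cfg$mean_depth >= 0, cfg$depth_dispersion >= 0)
  probs <- c(cfg$mutation_rate, cfg$error_rate, cfg$condition_fractions,
             cfg$rna$polyA_rate)
  fv <- cfg$founder_variants
  if (nrow(fv)) probs <- c(probs, fv$af)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities in the simulation config must lie in [0, 1]")
  }
  if (abs(sum(cfg$condition_fractions) - 1) > 1e-8) {
    stop("condition_fractions must sum to 1")
  }
  if (nrow(fv) && any(fv$pos < 1L | fv$pos > cfg$genome_length)) {
    stop("founder variant positions must lie within the genome")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: ", x$n_cells, " DNA cells / ",
      x$rna$n_cells, " RNA cells, g = ", x$generations,
      ", N = ", x$mtdna_copies, ", L = ", x$genome_length,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Default founder variant panel
#'
#' Eight heteroplasmic founder variants spread over the synthetic genome:
#' one within 25 bp of the circular origin (to exercise shifted-reference
#' calling), a linked trio sharing one haplotype (mirroring co-segregating
#' mutation sets seen in clonal populations), one high-frequency variant
#' near 0.6, one stop-gain candidate inside a protein gene, and two
#' variants placed outside transcribed features so they surface as
#' DNA-specific in modality comparisons.
#'
#' Reference alleles match [syntheticReference()]; positions echo the
#' field's conventional "pos ref>alt" notation.
#' @return data.frame with columns pos, ref, alt, af, haplotype.
#' @export
defaultFounderVariants <- function() {
  data.frame(
    pos = c(15L, 4793L, 5313L, 9122L, 4958L, 6790L, 13861L, 14876L),
    ref = c("T", "C", "T", "C", "G", "G", "C", "G"),
    alt = c("C", "T", "C", "T", "A", "A", "T", "A"),
    af = c(0.12, 0.08, 0.08, 0.08, 0.55, 0.10, 0.05, 0.05),
    haplotype = c("h_ori", "h_trio", "h_trio", "h_trio", "h_4958",
                  "h_6790", "h_13861", "h_14876"),
    stringsAsFactors = FALSE)
}

#' Generate the packaged synthetic circular mitochondrial reference
#'
#' A 16.3 kb random circular genome with a CHO-mtDNA-like gene layout: a
#' D-loop spanning the origin (stored as two sub-intervals), an rRNA and a
#' tRNA, nine protein-coding genes on the plus strand and one on the minus
#' strand (all protein genes a multiple of 3 bp long). Bases at the default
#' founder-variant sites are planted so that the panel's reference alleles
#' match and selected substitutions create stop-gained codons.
#'
#' @param L genome length in bp.
#' @param seed seed for the random background sequence.
#' @return a [CircularReference-class].
#' @export
syntheticReference <- function(L = 16300L, seed = 99L) {
  set.seed(seed)
  base <- sample(BASES, L, replace = TRUE)
  # plant reference alleles of the default founder panel
  fv <- defaultFounderVariants()
  base[fv$pos] <- fv$ref
  # plant codon contexts: 6790 G>A in cox1 codon TGG -> TAG (stop gained),
  # 9122 C>T in atp6 codon CAA -> TAA, 13861 C>T in nd5 codon CAA -> TAA
  base[6789:6791] <- c("T", "G", "G")
  base[9122:9124] <- c("C", "A", "A")
  base[13861:13863] <- c("C", "A", "A")
  genes <- data.frame(
    gene = c("D-loop", "D-loop", "rrnS", "trnF", "nd1", "nd2", "cox1",
             "nd6", "atp6", "cox3", "nd4", "nd5", "cytb"),
    start = c(15800L, 1L, 200L, 1850L, 2051L, 4200L, 5904L, 7600L,
              8800L, 9800L, 11100L, 13000L, 14100L),
    end = c(16300L, 120L, 1800L, 1919L, 3850L, 5399L, 7442L, 8199L,
            9699L, 10999L, 12899L, 13899L, 15236L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-", "+", "+", "+",
               "+", "+"),
    feature_type = c("noncoding", "noncoding", "rRNA", "tRNA",
                     rep("protein_coding", 9)),
    part = c(1L, 2L, rep(1L, 11)),
    stringsAsFactors = FALSE)
  if (L < 16300L) stop("syntheticReference requires L >= 16300")
  CircularReference("synthetic-mt", paste(base, collapse = ""),
                    genes = genes)
}

## ---- lineage simulation -------------------------------------------------

#' Simulate heteroplasmy segregation through a clonal lineage
#'
#' Starts from a single founder cell whose N mtDNA copies carry the
#' configured founder variants (variants sharing a haplotype label sit on
#' the same copies). At each of `generations` divisions every cell produces
#' two daughters; each daughter's N copies are an independent multinomial
#' resample of the parent's copy pool — the Wright-Fisher bottleneck model,
#' under which one division inflates the across-daughter variance of a
#' variant at frequency p by p(1-p)/N while leaving its expectation at p
#' (the martingale property of neutral drift). De novo mutations arise per
#' copy per generation at `mutation_rate`, each on one existing copy at a
#' uniformly random previously unused position. To keep memory bounded the
#' growing population is uniformly subsampled to a cap each generation
#' (uniform subsampling preserves both moments above), and finally to
#' `n_cells` leaves, which are labelled induced/noninduced at random
#' according to `condition_fractions`.
#'
#' @param config a [simulationConfig()].
#' @param cap maximum population size carried between generations.
#' @return a [CellTruthSet-class].
#' @export
simulateLineage <- function(config, cap = max(4L * config$n_cells, 64L)) {
  set.seed(config$seed)
  N <- config$mtdna_copies
  g <- config$generations
  if (g < 63 && config$n_cells > 2^g) {
    stop("n_cells (", config$n_cells, ") exceeds the 2^g = ", 2^g,
         " leaves of a ", g, "-generation lineage")
  }
  fv <- config$founder_variants
  # classes of identical mtDNA copies; class 1 = wild type
  class_variants <- list(integer(0))
  variants <- data.frame(pos = integer(), ref = character(),
                         alt = character(), haplotype = character(),
                         origin = character(), stringsAsFactors = FALSE)
  founder_counts <- integer(0)
  if (nrow(fv)) {
    if (is.null(fv$haplotype)) fv$haplotype <- paste0("h", seq_len(nrow(fv)))
    variants <- data.frame(pos = as.integer(fv$pos),
                           ref = as.character(fv$ref),
                           alt = as.character(fv$alt),
                           haplotype = as.character(fv$haplotype),
                           origin = "founder", stringsAsFactors = FALSE)
    haps <- split(seq_len(nrow(fv)), fv$haplotype)
    hap_af <- vapply(haps, function(i) fv$af[i][1], numeric(1))
    if (sum(hap_af) > 1) {
      stop("founder haplotype frequencies sum to more than 1; ",
           "haplotype classes are modelled as disjoint")
    }
    founder_counts <- round(hap_af * N)
    class_variants <- c(class_variants, unname(haps))
  }
  counts0 <- c(N - sum(founder_counts), founder_counts)
  if (counts0[1] < 0) stop("founder variant copies exceed N")
  pop <- list(list(id = "F", parent = NA_character_, counts = counts0))
  L <- config$genome_length
  mu <- config$mutation_rate
  used <- logical(L)
  used[variants$pos] <- TRUE
  n_used <- sum(used)
  n_founder <- nrow(variants)
  denovo_pos <- integer(0)
  for (gen in seq_len(g)) {
    nxt <- vector("list", 2L * length(pop))
    k <- 0L
    for (cell in pop) {
      p <- cell$counts / N
      for (d in 1:2) {
        counts <- as.integer(stats::rmultinom(1L, N, p))
        # pad with zeros for classes created after this vector was drawn
        if (length(counts) < length(class_variants)) {
          counts <- c(counts,
                      integer(length(class_variants) - length(counts)))
        }
        n_new <- stats::rbinom(1L, N, mu)
        for (m in seq_len(n_new)) {
          if (n_used >= L) break
          # rejection-sample an unused position (collisions are rare)
          repeat {
            pos_new <- sample.int(L, 1L)
            if (!used[pos_new]) break
          }
          used[pos_new] <- TRUE
          n_used <- n_used + 1L
          denovo_pos <- c(denovo_pos, pos_new)
          donor <- sample.int(length(counts), 1L, prob = counts)
          counts[donor] <- counts[donor] - 1L
          class_variants <- c(class_variants,
                              list(c(class_variants[[donor]],
                                     n_founder + length(denovo_pos))))
          counts <- c(counts, 1L)
        }
        k <- k + 1L
        nxt[[k]] <- list(id = paste0(cell$id, d),
                         parent = cell$id, counts = counts)
      }
    }
    pop <- nxt[seq_len(k)]
    if (length(pop) > cap) pop <- pop[sort(sample.int(length(pop), cap))]
  }
  if (length(pop) < config$n_cells) {
    stop("population smaller than n_cells after subsampling")
  }
  pop <- pop[sort(sample.int(length(pop), config$n_cells))]
  if (length(denovo_pos)) {
    variants <- rbind(variants, data.frame(
      pos = denovo_pos, ref = NA_character_, alt = NA_character_,
      haplotype = NA_character_, origin = "denovo",
      stringsAsFactors = FALSE))
  }
  nv <- nrow(variants)
  af <- matrix(0, nrow = length(pop), ncol = nv)
  for (i in seq_along(pop)) {
    counts <- pop[[i]]$counts
    if (length(counts) < length(class_variants)) {
      counts <- c(counts, integer(length(class_variants) - length(counts)))
    }
    for (cl in seq_along(class_variants)) {
      for (v in class_variants[[cl]]) {
        af[i, v] <- af[i, v] + counts[cl]
      }
    }
  }
  af <- af / N
  cond_names <- names(config$condition_fractions)
  n_per <- round(config$condition_fractions * length(pop))
  n_per[length(n_per)] <- length(pop) - sum(n_per[-length(n_per)])
  condition <- sample(rep(cond_names, times = n_per))
  cell_id <- sprintf("%s%02d",
                     ifelse(condition == "induced", "I", "N"),
                     stats::ave(seq_along(pop), condition, FUN = seq_along))
  cells <- S4Vectors::DataFrame(
    cell_id = cell_id,
    parent_id = vapply(pop, function(x) x$parent, character(1)),
    condition = condition)
  dimnames(af) <- list(cell_id, as.character(variants$pos))
  methods::new("CellTruthSet", cells = cells,
               variants = S4Vectors::DataFrame(variants), af = af)
}

#' Assemble a CellTruthSet directly from known allele frequencies
#'
#' Convenience constructor for tests and calibration experiments where the
#' per-cell truth is specified exactly rather than simulated.
#' @param af numeric matrix cells x variants of true allele frequencies.
#' @param variants data.frame with columns pos, ref, alt (haplotype,
#'   origin optional).
#' @param condition character vector of condition labels per cell.
#' @param cell_id cell identifiers.
#' @return a [CellTruthSet-class].
#' @export
cellTruthSet <- function(af, variants,
                         condition = rep("noninduced", nrow(af)),
                         cell_id = sprintf("C%03d", seq_len(nrow(af)))) {
  variants <- as.data.frame(variants)
  if (is.null(variants$haplotype)) variants$haplotype <- NA_character_
  if (is.null(variants$origin)) variants$origin <- "founder"
  dimnames(af) <- list(cell_id, as.character(variants$pos))
  cells <- S4Vectors::DataFrame(cell_id = cell_id,
                                parent_id = NA_character_,
                                condition = condition)
  methods::new("CellTruthSet", cells = cells,
               variants = S4Vectors::DataFrame(variants), af = af)
}
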