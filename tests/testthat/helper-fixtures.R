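# Fixtures built in code: toy references, planted allele-count matrices
# with exactly known allele frequencies, and small simulation configs.

# random circular reference with no annotation
toyReference <- function(L = 2000L, seed = 7L, name = "toy") {
  set.seed(seed)
  CircularReference(name, paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = ""))
}

# a reference with two ~300 bp protein genes, one per strand, for
# effect-annotation tests
twoGeneReference <- function(seed = 11L) {
  set.seed(seed)
  L <- 900L
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  genes <- data.frame(
    gene = c("fwd300", "rev300"),
    start = c(101L, 501L), end = c(400L, 800L),
    strand = c("+", "-"),
    feature_type = "protein_coding", part = 1L)
  CircularReference("twogene", paste(base, collapse = ""), genes = genes)
}

# brute-force effect oracle: mutate the genome, rebuild and translate the
# whole CDS under the vertebrate mitochondrial code, and classify from the
# full protein comparison (independent of the per-codon annotator)
oracleEffect <- function(ref, gene_start, gene_end, strand, pos, alt) {
  code <- Biostrings::getGeneticCode("2")
  chars <- strsplit(as.character(refSequence(ref)), "")[[1]]
  translate_cds <- function(chars) {
    cds <- paste(chars[gene_start:gene_end], collapse = "")
    if (strand == "-") {
      cds <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       genetic.code = code,
                                       no.init.codon = TRUE))
  }
  prot_ref <- translate_cds(chars)
  mutated <- chars
  mutated[pos] <- alt
  prot_alt <- translate_cds(mutated)
  if (prot_ref == prot_alt) return("synonymous")
  aa_ref <- strsplit(prot_ref, "")[[1]]
  aa_alt <- strsplit(prot_alt, "")[[1]]
  changed <- which(aa_ref != aa_alt)
  if (aa_alt[changed[1]] == "*") "stop_gained" else "missense"
}

# AlleleCountMatrix with exactly specified per-cell alt counts at a
# constant depth; one alt allele per planted variant
plantedAcm <- function(ref, plants, n_cells, depth = 2500L,
                       cells = sprintf("P%03d", seq_len(n_cells))) {
  pos <- vapply(plants, `[[`, integer(1), "pos")
  counts <- lapply(c("A", "C", "G", "T", "DEL", "INS"), function(a) {
    matrix(0L, length(pos), n_cells)
  })
  names(counts) <- c("A", "C", "G", "T", "DEL", "INS")
  ref_base <- refBaseAt(ref, pos)
  for (i in seq_along(plants)) {
    alt_counts <- plants[[i]]$alt_counts  # length n_cells
    stopifnot(length(alt_counts) == n_cells, all(alt_counts <= depth))
    counts[[plants[[i]]$alt]][i, ] <- as.integer(alt_counts)
    counts[[ref_base[i]]][i, ] <- counts[[ref_base[i]]][i, ] +
      as.integer(depth - alt_counts)
  }
  AlleleCountMatrix(counts, positions = pos, cells = cells, ref = ref)
}

# reference whose single forward gene is a run of CTT (Leu) codons with a
# CAA (Gln) codon planted at a known place, so substitution effects are
# known by construction
classifierReference <- function() {
  L <- 1000L
  set.seed(5L)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  gene_start <- 101L; gene_end <- 700L
  base[gene_start:gene_end] <- rep(c("C", "T", "T"), 200L)
  base[200:202] <- c("C", "A", "A")  # codon 34 (positions 200-202): Gln
  base[50] <- "C"  # noncoding test position, known non-A reference
  genes <- data.frame(gene = "toyprot", start = gene_start, end = gene_end,
                      strand = "+", feature_type = "protein_coding",
                      part = 1L)
  CircularReference("classifier", paste(base, collapse = ""), genes = genes)
}

# minimal simulation config for count-level tests (no engineered QC cells)
plainConfig <- function(seed, L, n_cells, mean_depth = 200,
                        depth_dispersion = 0.1, error_rate = 0.001,
                        fragment_bias_sd = 0, ...) {
  simulationConfig(
    seed = seed, n_cells = n_cells, genome_length = L,
    founder_variants = data.frame(pos = integer(), ref = character(),
                                  alt = character(), af = numeric(),
                                  haplotype = character()),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    error_rate = error_rate, fragment_bias_sd = fragment_bias_sd,
    n_low_depth_cells = 0L, n_imbalanced_cells = 0L, ...)
}

# truth with explicit per-cell AFs at explicit sites
truthAt <- function(ref, pos, af_matrix,
                    alt = NULL, condition = NULL) {
  ref_base <- refBaseAt(ref, pos)
  if (is.null(alt)) {
    alt <- vapply(ref_base, function(b) {
      setdiff(c("A", "C", "G", "T"), b)[1]
    }, character(1))
  }
  if (is.null(condition)) condition <- rep("noninduced", nrow(af_matrix))
  cellTruthSet(af_matrix,
               data.frame(pos = pos, ref = ref_base, alt = alt),
               condition = condition)
}

# shared default study, simulated once per test run
sharedStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateStudy(simulationConfig(seed = 1))
    cache
  }
})
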