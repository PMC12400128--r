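test_that("lineage truth is exact without division or mutation", {
  cfg <- simulationConfig(seed = 3, n_cells = 1L, generations = 0L,
                          mtdna_copies = 500L, mutation_rate = 0)
  truth <- simulateLineage(cfg)
  fv <- defaultFounderVariants()
  expect_equal(unname(truthAF(truth)[1, as.character(fv$pos)]),
               fv$af, tolerance = 1e-9)
})

test_that("one-generation segregation matches the bottleneck moments", {
  # small Monte Carlo replica of the closed-form check: Var = p(1-p)/N
  reps <- 2000L
  p0 <- 0.5; N <- 2L
  fv <- data.frame(pos = 10L, ref = "A", alt = "G", af = p0,
                   haplotype = "h")
  afs <- vapply(seq_len(reps), function(r) {
    cfg <- simulationConfig(seed = 100000L + r, n_cells = 1L,
                            generations = 1L, mtdna_copies = N,
                            founder_variants = fv, mutation_rate = 0,
                            genome_length = 50L)
    truthAF(simulateLineage(cfg))[1, "10"]
  }, numeric(1))
  expect_true(all(afs %in% c(0, 0.5, 1)))
  expect_lt(abs(mean(afs) - p0), 3 * sqrt(p0 * (1 - p0) / N / reps))
  expect_lt(abs(var(afs) - 0.125), 0.125 * 0.12)
})

test_that("across-cell AF variance grows with generations", {
  fv <- data.frame(pos = 10L, ref = "A", alt = "G", af = 0.3,
                   haplotype = "h")
  v <- vapply(c(6L, 12L, 24L), function(g) {
    cfg <- simulationConfig(seed = 11L, n_cells = 64L, generations = g,
                            mtdna_copies = 50L, founder_variants = fv,
                            mutation_rate = 0, genome_length = 50L)
    var(truthAF(simulateLineage(cfg))[, "10"])
  }, numeric(1))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("linked founder variants co-segregate within cells", {
  truth <- sharedStudy()$dna$truth
  af <- truthAF(truth)
  trio <- truthVariants(truth)
  trio_cols <- which(trio$haplotype == "h_trio")
  expect_length(trio_cols, 3L)
  expect_equal(af[, trio_cols[1]], af[, trio_cols[2]])
  expect_equal(af[, trio_cols[1]], af[, trio_cols[3]])
})

test_that("lineage requires enough leaves for the requested sample", {
  expect_error(
    simulateLineage(simulationConfig(seed = 1, n_cells = 10L,
                                     generations = 3L)),
    "exceeds")
})

test_that("DNA counts conserve depth and respect degenerate AFs", {
  ref <- toyReference(L = 400L, seed = 2L)
  af <- matrix(c(rep(0, 6), rep(1, 6)), nrow = 6L,
               dimnames = NULL)  # 6 cells x 2 variants
  truth <- truthAt(ref, pos = c(50L, 300L), af_matrix = af)
  cfg <- plainConfig(seed = 5, L = 400L, n_cells = 6L,
                     mean_depth = 100, depth_dispersion = 0,
                     error_rate = 0)
  sim <- simulateDnaCounts(truth, ref, cfg)
  acm <- sim$counts
  d <- alleleDepth(acm)
  expect_true(all(d == 100L))
  v <- truthVariants(sim$truth)
  alt1 <- SummarizedExperiment::assay(acm, v$alt[1])[1, ]
  alt2 <- SummarizedExperiment::assay(acm, v$alt[2])[2, ]
  expect_true(all(alt1 == 0L))    # af = 0, e = 0
  expect_true(all(alt2 == 100L))  # af = 1, e = 0
  # counts conservation against independent recomputation
  total <- Reduce(`+`, lapply(c("A", "C", "G", "T", "DEL", "INS"),
    function(a) SummarizedExperiment::assay(acm, a)))
  expect_identical(total, d)
})

test_that("estimated AF is within binomial sampling error of truth", {
  ref <- toyReference(L = 500L, seed = 8L)
  n <- 500L
  af <- matrix(0.3, nrow = n, ncol = 1L)
  truth <- truthAt(ref, pos = 123L, af_matrix = af)
  cfg <- plainConfig(seed = 21, L = 500L, n_cells = n,
                     mean_depth = 1000, depth_dispersion = 0,
                     error_rate = 0)
  sim <- simulateDnaCounts(truth, ref, cfg)
  v <- truthVariants(sim$truth)
  est <- SummarizedExperiment::assay(sim$counts, v$alt[1])[1, ] / 1000
  expect_lt(abs(mean(est) - 0.3), 3 * sqrt(0.3 * 0.7 / 1000 / n))
})

test_that("fragment bias is reciprocal between the two windows", {
  study <- sharedStudy()
  qc <- fragmentDepthQCMatrix(study$dna$depths)
  imb <- study$dna$engineered
  imb_cell <- imb$cell_id[imb$role == "fragment_imbalance"]
  row <- qc[qc$cell_id == imb_cell, ]
  expect_true(row$fragment_proportion_Y > 0.8)
  expect_true(row$passed)  # imbalance is a flag, not an exclusion
  expect_match(row$flags, "fragment_imbalance")
})

test_that("RNA arm honours engineered QC outliers and polyA settings", {
  study <- sharedStudy()
  rna <- study$rna
  qc <- rnaCellQCMatrix(rna$gene_counts, rna$depths)
  eng <- rna$engineered
  mito_cells <- eng$cell_id[eng$role == "high_mito_fraction"]
  expect_length(mito_cells, 5L)
  rows <- qc[match(mito_cells, qc$cell_id), ]
  expect_true(all(!rows$passed))
  expect_true(all(grepl("high_mito_fraction", rows$fail_reasons)))
  expect_true(all(abs(rows$mito_fraction - 0.30) < 0.02))
  # polyA_rate = 0 leaves every read unaltered by masking
  cfg0 <- simulationConfig(seed = 4, rna = list(n_cells = 20L,
                                                polyA_rate = 0,
                                                n_reads = 300L))
  rna_cfg <- cfg0
  rna_cfg$n_cells <- 20L
  class(rna_cfg) <- class(cfg0)
  truth <- simulateLineage(rna_cfg)
  arm <- simulateRnaArm(truth, study$ref, cfg0)
  expect_identical(maskPolyA(arm$reads$read), arm$reads$read)
  # untranscribed variant positions have zero RNA depth
  d <- alleleDepth(rna$counts)
  pos <- acmPositions(rna$counts)
  tr <- rna$transcribed
  transcribed <- vapply(pos, function(p) {
    any(p >= IRanges::start(tr) & p <= IRanges::end(tr))
  }, logical(1))
  expect_true(all(d[!transcribed, ] == 0L))
  expect_true(any(d[transcribed, ] > 0L))
})

test_that("RNA-specific variants surface only in the RNA modality", {
  study <- sharedStudy()
  rna_cells <- acmCells(study$rna$counts)
  pb_rna <- pseudobulk(study$rna$counts, study$ref)
  pb_dna <- pseudobulk(study$dna$counts, study$ref)
  cmp <- modalityCompare(pb_dna, pb_rna)
  rsv <- study$rna$rna_specific
  for (i in seq_len(nrow(rsv))) {
    row <- cmp[cmp$pos == rsv$pos[i] & cmp$alt == rsv$alt[i], ]
    expect_equal(row$class, "RNA_specific")
  }
  # with no injected RNA-only variants, nothing is RNA-specific above floor
  cfg0 <- simulationConfig(seed = 6, rna = list(
    n_cells = 15L,
    rna_specific_variants = data.frame(pos = integer(), ref = character(),
                                       alt = character(), af = numeric())))
  rna_cfg <- cfg0; rna_cfg$n_cells <- 15L; class(rna_cfg) <- class(cfg0)
  arm <- simulateRnaArm(simulateLineage(rna_cfg), study$ref, cfg0)
  expect_equal(nrow(arm$rna_specific), 0L)
})

test_that("fixtures round-trip and are byte-stable under the same seed", {
  study <- sharedStudy()
  dir1 <- withr::local_tempdir()
  writeFixture(study, dir1)
  back <- readAlleleCounts(file.path(dir1, "dna_allele_counts.tsv"))
  for (a in c("A", "C", "G", "T", "DEL", "INS")) {
    expect_equal(unname(SummarizedExperiment::assay(back, a)),
                 unname(SummarizedExperiment::assay(study$dna$counts, a)))
  }
  expect_equal(acmPositions(back), acmPositions(study$dna$counts))

  # same seed, fresh simulation: byte-identical files
  study2 <- simulateStudy(simulationConfig(seed = 1))
  dir2 <- withr::local_tempdir()
  writeFixture(study2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
  # a different seed changes the counts
  study3 <- simulateStudy(simulationConfig(seed = 2))
  expect_false(identical(
    SummarizedExperiment::assay(study$dna$counts, "A"),
    SummarizedExperiment::assay(study3$dna$counts, "A")))

  # the truth VCF parses as valid VCF with one sample column per cell
  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(file.path(dir1, "truth.vcf"),
                                        verbose = FALSE))
  expect_equal(ncol(v@gt) - 1L, nrow(truthCells(study$dna$truth)))
  expect_equal(nrow(v@fix), nrow(truthVariants(study$dna$truth)))
})
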