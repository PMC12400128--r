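test_that("the heteroplasmy window is inclusive at both bounds", {
  expect_true(isHeteroplasmic(0.5))
  expect_true(isHeteroplasmic(0.04))
  expect_true(isHeteroplasmic(0.96))
  expect_false(isHeteroplasmic(0.039))
  expect_false(isHeteroplasmic(0.97))
  expect_false(isHeteroplasmic(NA_real_))
})

test_that("per-codon annotation agrees with full-CDS re-translation", {
  ref <- twoGeneReference()
  genes <- list(list(start = 101L, end = 400L, strand = "+"),
                list(start = 501L, end = 800L, strand = "-"))
  set.seed(33)
  # sample positions across both genes plus every alt base
  tab <- do.call(rbind, lapply(genes, function(g) {
    pos <- sample(g$start:g$end, 40L)
    expand.grid(pos = pos, alt = c("A", "C", "G", "T"),
                stringsAsFactors = FALSE)
  }))
  tab$ref <- refBaseAt(ref, tab$pos)
  tab <- tab[tab$ref != tab$alt, ]
  eff <- annotateEffect(tab[, c("pos", "alt")], ref)
  for (i in seq_len(nrow(tab))) {
    g <- if (tab$pos[i] <= 400L) genes[[1]] else genes[[2]]
    expected <- oracleEffect(ref, g$start, g$end, g$strand,
                             tab$pos[i], tab$alt[i])
    expect_equal(eff$effect[i], expected,
                 info = sprintf("pos %d %s>%s", tab$pos[i], tab$ref[i],
                                tab$alt[i]))
  }
  # impact follows effect deterministically
  impact_map <- c(stop_gained = "HIGH", frameshift = "HIGH",
                  missense = "MODERATE", synonymous = "LOW",
                  noncoding = "MODIFIER")
  expect_equal(eff$impact, unname(impact_map[eff$effect]))
})

test_that("annotation handles strand, indels, and noncoding positions", {
  ref <- classifierReference()
  # gene body is CTT codons; planted CAA codon at 200-202
  eff <- annotateEffect(data.frame(pos = 200L, alt = "T"), ref)
  expect_equal(eff$effect, "stop_gained")   # CAA -> TAA
  expect_equal(eff$impact, "HIGH")
  expect_equal(eff$codon_change, "CAA>TAA")
  eff2 <- annotateEffect(data.frame(pos = 103L, alt = "C"), ref)
  expect_equal(eff2$effect, "synonymous")   # CTT -> CTC (Leu)
  eff3 <- annotateEffect(data.frame(pos = 101L, alt = "T"), ref)
  expect_equal(eff3$effect, "missense")     # CTT -> TTT (Leu -> Phe)
  eff4 <- annotateEffect(data.frame(pos = 150L, alt = "DEL"), ref)
  expect_equal(eff4$effect, "frameshift")
  expect_equal(eff4$impact, "HIGH")
  eff5 <- annotateEffect(data.frame(pos = 50L, alt = "A"), ref)
  expect_equal(eff5$effect, "noncoding")
  expect_equal(eff5$impact, "MODIFIER")
  # mitochondrial code specifics: ATA = Met, TGA = Trp, AGA = stop
  mref <- CircularReference(
    "mito", paste0(strrep("C", 100), "ATTTGGCGA", strrep("C", 91)),
    genes = data.frame(gene = "m", start = 101L, end = 109L, strand = "+",
                       feature_type = "protein_coding", part = 1L))
  e_ata <- annotateEffect(data.frame(pos = 103L, alt = "A"), mref)
  expect_equal(e_ata$effect, "missense")    # ATT(Ile) -> ATA(Met)
  expect_equal(e_ata$aa_change, "I1M")
  # TGA codes Trp in the vertebrate mitochondrial code, so TGG -> TGA is
  # synonymous here (it would be stop-gained under the standard code)
  e_tga <- annotateEffect(data.frame(pos = 106L, alt = "A"), mref)
  expect_equal(e_tga$effect, "synonymous")
  # AGA is a mitochondrial stop: CGA(Arg) -> AGA is stop-gained
  e_aga <- annotateEffect(data.frame(pos = 107L, alt = "A"), mref)
  expect_equal(e_aga$effect, "stop_gained")
})

test_that("tRNA and rRNA positions are modifiers, bad gene length errors", {
  ref <- syntheticReference()
  eff <- annotateEffect(data.frame(pos = 1870L, alt = "A"), ref)  # trnF
  expect_equal(eff$impact, "MODIFIER")
  expect_equal(eff$effect, "noncoding")
  bad <- CircularReference(
    "bad", strrep("ACGT", 100),
    genes = data.frame(gene = "g", start = 10L, end = 20L, strand = "+",
                       feature_type = "protein_coding", part = 1L))
  expect_error(annotateEffect(data.frame(pos = 12L, alt = "C"), bad),
               "divisible by 3")
})

test_that("most-variable and most-impactful respect their boundaries", {
  ref <- classifierReference()
  n <- 84L
  plant <- function(pos, alt, af, n_het) {
    alt_counts <- rep(0L, n)
    alt_counts[seq_len(n_het)] <- as.integer(round(af * 2500))
    list(pos = pos, alt = alt, alt_counts = alt_counts)
  }
  acm <- plantedAcm(ref, list(
    plant(104L, "T", 0.5, 5L),   # 5/84 = 5.95% -> in most-variable
    plant(107L, "T", 0.5, 4L),   # 4/84 = 4.76% -> out
    plant(110L, "T", 0.5, 84L)), # all cells -> in
    n_cells = n)
  vcs <- callVariants(acm, ref, min_depth = 100L)
  mv <- mostVariable(vcs)
  expect_setequal(variantInfo(mv)$pos, c(104L, 110L))

  # impactful: strict 0.30 bound and impact filter
  acm2 <- plantedAcm(ref, list(
    plant(104L, "T", 750 / 2500, 10L),   # exactly 0.30 -> excluded
    plant(107L, "T", 751 / 2500, 10L),   # just above -> included
    plant(103L, "C", 0.5, 10L),          # synonymous -> excluded
    plant(200L, "T", 0.29, 10L)),        # stop-gained but 0.29 -> excluded
    n_cells = n)
  vcs2 <- callVariants(acm2, ref, min_depth = 100L)
  eff2 <- annotateEffect(vcs2, ref)
  mi <- mostImpactful(vcs2, eff2)
  expect_equal(variantInfo(mi)$pos, 107L)
})

test_that("joint impactful intersects DNA impact with RNA heteroplasmy", {
  ref <- classifierReference()
  plant <- function(pos, alt, af, n_het, n, depth = 2500L) {
    alt_counts <- rep(0L, n)
    alt_counts[seq_len(n_het)] <- as.integer(round(af * depth))
    list(pos = pos, alt = alt, alt_counts = alt_counts)
  }
  dna <- plantedAcm(ref, list(plant(104L, "T", 0.5, 10L, 20L),
                              plant(110L, "T", 0.5, 10L, 20L)),
                    n_cells = 20L)
  vcs_dna <- callVariants(dna, ref, min_depth = 100L)
  mi <- mostImpactful(vcs_dna, annotateEffect(vcs_dna, ref))
  expect_equal(length(mi), 2L)
  # RNA arm sees only position 104 heteroplasmic
  rna <- plantedAcm(ref, list(plant(104L, "T", 0.2, 3L, 5L, depth = 100L)),
                    n_cells = 5L, depth = 100L,
                    cells = sprintf("R%02d", 1:5))
  vcs_rna <- callVariants(rna, ref, min_depth = 50L)
  ji <- jointImpactful(mi, vcs_rna)
  expect_equal(variantInfo(ji)$pos, 104L)
  # empty DNA list stays empty
  expect_equal(length(jointImpactful(mi[integer(0), ], vcs_rna)), 0L)
})

test_that("events per cell counts only in-window AFs", {
  ref <- classifierReference()
  info <- data.frame(pos = c(104L, 107L, 110L),
                     ref = refBaseAt(ref, c(104L, 107L, 110L)),
                     alt = "T", source = "unshifted")
  # 3 variants x 2 cells: cell "a" has AFs {0.5, 0.03, 0.97} -> 1 event
  vcs <- VariantCallSet(info, matrix(c(0.5, 0.03, 0.97,
                                       0.03, 0.5, 0.5), ncol = 2,
                                     dimnames = list(NULL, c("a", "b"))),
                        matrix(1000, 3, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(eventsPerCell(vcs, "a")), 1L)
  expect_equal(unname(eventsPerCell(vcs, "b")), 2L)
  expect_error(eventsPerCell(vcs, "zz"), "unknown cell")
  empty <- vcs[integer(0), ]
  expect_equal(unname(eventsPerCell(empty, "a")), 0L)
})

test_that("linked variants keep near-identical AFs through sequencing", {
  study <- sharedStudy()
  vcs <- callVariants(study$dna$counts, study$ref, min_depth = 100L)
  labs <- variantInfo(vcs)
  i1 <- which(labs$pos == 4793L)
  i2 <- which(labs$pos == 5313L)
  i3 <- which(labs$pos == 9122L)
  expect_true(length(i1) == 1 && length(i2) == 1 && length(i3) == 1)
  af <- afMatrix(vcs)
  expect_gt(stats::cor(af[i1, ], af[i2, ], use = "complete.obs"), 0.95)
  expect_gt(stats::cor(af[i1, ], af[i3, ], use = "complete.obs"), 0.95)
})
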