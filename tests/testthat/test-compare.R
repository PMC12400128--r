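test_that("sub-threshold AFs are zeroed before the single-cell mean", {
  expect_equal(singleCellMeanAF(c(0.02, 0.50)), 0.25)
  expect_equal(singleCellMeanAF(c(0.04, 0.50)), 0.27)  # 0.04 kept
  expect_equal(singleCellMeanAF(c(0.1, NA, 0.3)), 0.2) # NA excluded
  expect_error(singleCellMeanAF(NA_real_), "no cells")
})

test_that("zeroing makes the single-cell mean undershoot pseudobulk", {
  ref <- toyReference(L = 100L, seed = 40L)
  pos <- 50L
  ref_base <- refBaseAt(ref, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    depth <- 1000L
    # at least one cell strictly inside (0, 0.04)
    alt_counts <- c(sample(1:39, 1),
                    sample(0:1000, n - 1, replace = TRUE))
    counts <- list()
    counts[[alt]] <- matrix(as.integer(alt_counts), 1L)
    counts[[ref_base]] <- matrix(as.integer(depth - alt_counts), 1L)
    acm <- AlleleCountMatrix(counts, positions = pos,
                             cells = sprintf("c%02d", seq_len(n)),
                             ref = ref)
    pb <- pseudobulk(acm, ref)
    sc <- singleCellMeanAF(alt_counts / depth)
    expect_lt(sc, pb$af)
  }
})

test_that("condition comparison handles identical and constant groups", {
  info <- data.frame(pos = 10L, ref = "A", alt = "G", source = "merged")
  af <- matrix(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), nrow = 1,
               dimnames = list(NULL, sprintf("c%d", 1:6)))
  vcs <- VariantCallSet(info, af, af * 0 + 1000)
  cond <- stats::setNames(rep(c("induced", "noninduced"), each = 3),
                          colnames(af))
  res <- compareConditions(vcs, cond)
  row <- res[res$mutation == "10 A>G", ]
  expect_equal(row$statistic, 0)
  expect_equal(row$p_value, 1)
  # constant identical groups: still statistic 0, p 1
  af2 <- matrix(rep(0.2, 6), nrow = 1, dimnames = dimnames(af))
  vcs2 <- VariantCallSet(info, af2, af2 * 0 + 1000)
  res2 <- compareConditions(vcs2, cond)
  expect_equal(res2$p_value[1], 1)
  # groups with fewer than 2 defined AFs are skipped with a reason
  af3 <- af
  af3[1, 4:6] <- NA
  vcs3 <- VariantCallSet(info, af3, af * 0 + 1000)
  res3 <- compareConditions(vcs3, cond)
  expect_true(res3$skipped[1])
  expect_match(res3$reason[1], "fewer than 2")
  # events-per-cell row is always present
  expect_true("events_per_cell" %in% res$mutation)
  expect_error(compareConditions(vcs, cond[1:3]), "no condition label")
})

test_that("pooled t-test matches stats::t.test on ordinary data", {
  set.seed(50)
  x <- rnorm(15, 0.3, 0.1); y <- rnorm(20, 0.35, 0.1)
  info <- data.frame(pos = 5L, ref = "C", alt = "T", source = "merged")
  af <- matrix(c(x, y), nrow = 1,
               dimnames = list(NULL, sprintf("c%02d", 1:35)))
  vcs <- VariantCallSet(info, af, af * 0 + 1000)
  cond <- stats::setNames(rep(c("a", "b"), c(15, 20)), colnames(af))
  res <- compareConditions(vcs, cond)
  ref_test <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic[1], unname(ref_test$statistic))
  expect_equal(res$p_value[1], ref_test$p.value)
})

test_that("AF-expression correlation reports r and flags low n", {
  af <- stats::setNames(seq(0, 1, length.out = 20), sprintf("c%02d", 1:20))
  # exact linear relation
  res <- afExpressionCorrelation(af, af * 2)
  expect_equal(res$r, 1)
  expect_equal(res$n, 20L)
  # independence: |r| small for a null draw of decent size
  set.seed(60)
  af2 <- stats::setNames(runif(500), sprintf("x%03d", 1:500))
  y2 <- stats::setNames(rnorm(500), names(af2))
  res2 <- afExpressionCorrelation(af2, y2)
  expect_lt(abs(res2$r), 0.1)
  # strict min_af filter leaving < 3 cells is undefined with a reason
  af3 <- stats::setNames(c(0.7, 0.65, 0.1, 0.2), letters[1:4])
  y3 <- stats::setNames(1:4, letters[1:4])
  res3 <- afExpressionCorrelation(af3, y3, min_af = 0.6)
  expect_true(is.na(res3$r))
  expect_equal(res3$n, 2L)
  expect_equal(res3$reason, "low_n")
})

test_that("quartile test splits at quartiles and detects a planted shift", {
  set.seed(70)
  n <- 200L
  cells <- sprintf("c%03d", seq_len(n))
  af <- stats::setNames(runif(n), cells)
  genes <- 40L
  expr <- matrix(stats::rnbinom(genes * n, size = 5, mu = 20), genes, n,
                 dimnames = list(sprintf("g%02d", seq_len(genes)), cells))
  # plant a 2-fold shift in the top AF quartile for gene 1
  top <- names(af)[af >= stats::quantile(af, 0.75)]
  expr[1, top] <- stats::rnbinom(length(top), size = 5, mu = 40)
  res <- quartileExpressionTest(expr, af)
  expect_false(res$skipped)
  expect_true(res$results$significant[1])
  expect_equal(sum(res$results$significant), 1L)
  # BH adjustment invariants
  p <- res$results$p_value
  padj <- res$results$adjusted_p
  expect_true(all(padj >= p - 1e-12))
  ord <- order(p)
  expect_true(all(diff(padj[ord]) >= -1e-12))
  expect_equal(padj, stats::p.adjust(p, "BH"))
  # degenerate: identical AFs cannot form quartiles
  af_const <- stats::setNames(rep(0.5, n), cells)
  res2 <- quartileExpressionTest(expr, af_const)
  expect_true(res2$skipped)
  expect_equal(res2$reason, "degenerate_quartiles")
  expect_error(quartileExpressionTest(expr, af[1:3]), "at least 4")
})

test_that("bulk time-course summary reports ranges and stability", {
  bulk <- data.frame(
    time = rep(c(1, 14, 38), times = 3),
    site = rep(c("6790 G>A", "4958 G>A", "flat"), each = 3),
    af = c(0.06, 0.10, 0.15, 0.60, 0.65, 0.62, 0.3, 0.3, 0.3))
  s <- bulkTimecourseSummary(bulk)
  r <- function(site) s[s$site == site, ]
  expect_equal(r("6790 G>A")$range_af, 0.09)
  expect_true(r("6790 G>A")$stable)     # range 0.09 <= 0.10
  expect_equal(r("flat")$range_af, 0)
  expect_equal(r("4958 G>A")$min_af, 0.60)
  expect_equal(r("4958 G>A")$max_af, 0.65)
  expect_error(bulkTimecourseSummary(bulk[bulk$time == 1, ]),
               "2 time points")
  # range equals brute-force max - min on a random series
  set.seed(80)
  drift <- data.frame(time = 1:10, site = "x",
                      af = pmin(pmax(cumsum(rnorm(10, 0, 0.05)) + 0.3, 0), 1))
  expect_equal(bulkTimecourseSummary(drift)$range_af,
               max(drift$af) - min(drift$af))
})

test_that("report rendering writes stable tables and expected figures", {
  study <- sharedStudy()
  an <- analyzeStudy(study)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- renderReport(an, d1, config = study$config)
  renderReport(an, d2, config = study$config)
  tsvs <- grep("\\.tsv$|\\.json$", list.files(d1), value = TRUE)
  expect_true(all(c("qc_dna.tsv", "qc_rna.tsv", "classification.tsv",
                    "modality.tsv", "events_per_cell.tsv",
                    "manifest.json") %in% list.files(d1)))
  for (f in tsvs) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  pngs <- grep("\\.png$", f1, value = TRUE)
  expect_true(length(pngs) >= 2L)
  expect_true(all(file.exists(pngs)))
  # empty call set: zero-row tables, no crash
  an_empty <- an
  an_empty$calls_dna <- an$calls_dna[integer(0), ]
  an_empty$most_variable <- an$most_variable[integer(0), ]
  an_empty$most_impactful <- an$most_impactful[integer(0), ]
  an_empty$classification <- an$classification[integer(0), ]
  an_empty$events_per_cell <- an$events_per_cell[integer(0)]
  d3 <- withr::local_tempdir()
  expect_no_error(renderReport(an_empty, d3, plots = FALSE))
})
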