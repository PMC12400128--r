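---
title: "Quantifying single-cell mitochondrial heteroplasmy: models and methods"
author: "scMitoHet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell mitochondrial heteroplasmy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Mitochondria carry many copies of their own genome. When a mutation is
present on only some of a cell's mtDNA copies, the cell is *heteroplasmic*
at that site, and the mutant **allele frequency (AF)** — mutant copies over
total copies, estimated as alt-supporting reads over read depth — becomes
the quantity of interest. Bulk sequencing reports only a population-average
AF; single-cell sequencing reveals that nominally clonal populations (such
as recombinant CHO production cell lines) can hide substantial cell-to-cell
AF variation, with potential phenotypic consequences once a variant crosses
its functional threshold in an individual cell.

scMitoHet implements the computational side of such a study: quality
control for a deep two-fragment long-range-PCR DNA arm and a shallower
scRNA-seq arm, variant calling that respects the circularity of the
mitochondrial genome, per-cell heteroplasmy classification, effect
annotation under the vertebrate mitochondrial genetic code, and
condition/modality comparison statistics. Because the raw data of such
studies are large and external, the package also ships a ground-truthed
synthetic-data generator so that every stage is testable end to end.

```{r, eval = FALSE}
library(scMitoHet)
study <- simulateStudy(simulationConfig(seed = 1))
analysis <- analyzeStudy(study)
```

# Circular-genome-aware calling

Linear aligners lose coverage at the two ends of a linearized circular
reference, exactly where the mitochondrial control region (D-loop) sits.
The standard remedy, implemented here, is to repeat calling against a
*shifted* reference — the same sequence rotated by `s` bp so the origin
falls mid-molecule — and merge the two call sets:

* `rotateReference(ref, s)` builds the rotated reference;
  `shiftedToOriginal()`/`originalToShifted()` are the coordinate
  bijections `((pos - 1 ± s) mod L) + 1`.
* `mergeShiftedCalls()` maps shifted calls back and resolves duplicates by
  zone: within `junction_halfwidth` of the origin the shifted call wins
  (the unshifted mapper could not cover it), elsewhere the unshifted call
  wins. Calls present in only one set are kept.

The rotation amount is not fixed by any convention; the package defaults
to `s = floor(L/2)`, which places the origin junction maximally far from
both linear ends. `junction_halfwidth` defaults to 1000 bp — generous
relative to realistic mapper edge losses (tens of bp) while far smaller
than `L/2`, so the two zones never interact. The merge is exact by
construction: the winning record's counts are the counts of the view that
actually covered the site, and the test suite verifies per-cell AF
equality with direct computation from circularly complete counts on random
genomes (integer arithmetic, no tolerance).

Coordinates are 1-based and inclusive throughout, matching the field's
"6790 G>A" mutation notation. Genes spanning the origin are stored as
ordered sub-intervals rather than wrapped coordinates, which keeps all
interval logic linear.

# Allele frequencies, depth thresholds and the heteroplasmy window

`callVariants()` emits one record per (position, alt allele). A cell's AF
at a site is *defined* only where its depth reaches `min_depth` —
otherwise it is `NA`, not zero — and downstream denominators use cells
with defined AF so that low-coverage sites are not penalized twice. The
DNA arm defaults to `min_depth = 100` (long-range-PCR coverage is deep;
typical per-base depth here is >1000x); the RNA arm uses 50, i.e. a site
is retained in a cell only above 49 reads. A site is emitted when at
least one cell reaches the emission floor of 0.01, deliberately below
the heteroplasmy floor so that sub-threshold AFs remain available to the
"counted as 0" bulk comparison.

A variant is *heteroplasmic* in a cell when its AF lies in
`[0.04, 0.96]`, both bounds inclusive. The derived lists are read
literally from their defining phrases:

* **most variable**: heteroplasmic in at least 5% of cells with defined
  AF (inclusive at 0.05);
* **most impactful**: at least one cell strictly above 0.30 AF *and* a
  HIGH or MODERATE predicted impact;
* **joint**: most-impactful DNA variants that are heteroplasmic in at
  least one RNA-arm cell.

Equality at a strict bound fails, equality at an inclusive bound passes;
the boundary semantics are pinned by tests at exactly 0.04, 0.96, 0.30,
and at heteroplasmic cell counts straddling 5%.

# Effect annotation

`annotateEffect()` is a self-contained annotator for mitochondrial coding
effects. For a substitution inside a protein-coding gene it translates the
affected codon before and after the change under the vertebrate
mitochondrial genetic code (TGA = Trp, AGA/AGG = stop, ATA = Met),
honoring strand by complementing the alt base for minus-strand genes. The
verdict taxonomy is deliberately small — stop_gained/frameshift (HIGH),
missense (MODERATE), synonymous (LOW), noncoding (MODIFIER) — because
that is the decision structure the downstream lists consume. Start/stop
loss collapse into missense/stop-gained; tRNA and rRNA variants are
MODIFIER, a documented divergence risk versus annotators that treat
structural RNAs as functional features. Single-base DEL/INS alleles in
coding sequence are frameshift by construction (the count matrix encodes
indels as length-1 symbolic alleles at their leftmost position). The
annotator is validated against a brute-force oracle that re-translates
the entire mutated CDS for every possible SNV in two toy genes, one per
strand.

# QC rules

**DNA arm.** The genome is amplified as two long-range-PCR fragments
that may amplify unevenly per cell. Depth is averaged over interior
windows of each fragment (defaults 2000–7000 and 10000–15000, inclusive;
interior windows avoid the primer-overlap regions) and a cell is removed
when either window mean is strictly below 1000. A fragment imbalance
above 0.8 in either direction is flagged but *not* fatal — such cells
carry usable calls and are kept.

**RNA arm.** A cell passes only if its mitochondrial read fraction is
strictly below 17%, its expressed-feature count lies strictly inside
(2100, 4000), and its mean mitochondrial per-base depth is at least 50.
Whether the original thresholds were strict or inclusive is not
documented anywhere authoritative; the package adopts the strict reading
of the printed inequalities and records every violated rule per cell.

**PolyA masking.** scRNA-seq mitochondrial reads suffer polyA
contamination. `maskPolyA()` replaces every maximal run of ≥5 A's with
N's rather than clipping, preserving read length and coordinates so that
pileup arithmetic needs no realignment; internal runs are masked as well
as terminal ones. The operation is idempotent and never alters a non-A
base.

# Comparison statistics

* `singleCellMeanAF()` zeroes per-cell AFs strictly below 0.04 before
  averaging. With equal depths this forces the single-cell mean strictly
  below the pseudobulk AF whenever any cell sits in (0, 0.04) — the
  mechanism by which single-cell averages systematically undershoot bulk
  for variants hovering near the floor.
* `compareConditions()` uses the two-sided pooled-variance (Student's)
  t-test per mutation, plus one test on heteroplasmic events per cell. A
  Welch option exists but the pooled test is the default. Mutations with
  fewer than 2 defined AFs in either group are skipped and logged. No
  across-mutation multiple-testing correction is applied to condition
  tests — they are reported mutation-by-mutation, unadjusted, and the
  output says so.
* `quartileExpressionTest()` splits cells at the 25th/75th AF
  percentiles (boundary cells go to the extreme group: deterministic and
  n-maximizing), runs a Wilcoxon rank-sum test per gene, and adjusts with
  Benjamini-Hochberg across genes within the mutation. The choice of the
  rank-sum test is the package's own; it is the assumption-light default
  for count-scale expression comparisons between two cell groups.
* `afExpressionCorrelation()` reports Pearson r together with n, because
  restricting to cells above a high AF (e.g. 0.6) can leave so few points
  that large r values are artifacts of low n; results with n below 3 are
  returned as undefined with reason `low_n`.
* `bulkTimecourseSummary()` reports per-site min/max/range over a bulk
  time course; the 0.10 "stable" range threshold is a reporting
  convenience defined by this package, not a biological constant.

# The synthetic study generator

The generator exists so that the pipeline's behaviour can be measured
against known truth. It has three layers.

**Segregation model.** `simulateLineage()` starts from one founder cell
whose N mtDNA copies carry the configured founder variants; variants
sharing a `haplotype` label sit on the same copies and therefore
co-segregate (mirroring linked mutation sets that stay at near-identical
AFs across cells). At each division every daughter's N copies are an
independent multinomial resample of the parent's copy-class frequencies —
the Wright–Fisher bottleneck, chosen because it yields the classical
one-generation closed form Var(AF) = p(1−p)/N with E[AF] = p (the
martingale property of neutral drift), which the acceptance suite checks
by Monte Carlo. A without-replacement partition of a duplicated 2N pool
was considered and rejected: it gives Var = p(1−p)/(2N−1), not the
closed form used for validation, and the two are empirically almost
indistinguishable at realistic N. De novo mutations arise per copy per
generation at rate `mutation_rate` (default 2e-4 per copy per division —
the order implied by per-base mtDNA mutation rates of ~1e-8 over a 16.3
kb genome), each placed at a uniformly random unused position on one
existing copy. The population is uniformly subsampled to a cap each
generation (uniform subsampling preserves both moments) and finally to
`n_cells`.

The bottleneck size and depth of the lineage are not measurable from the
kind of data the package consumes; the defaults N = 500 and g = 30 are
arbitrary placeholders of plausible magnitude and are stated as such.
Under these defaults drift is modest (total drift variance ≈ p(1−p)·g/N),
so a default study may legitimately produce a small or empty
"most impactful" list — variants rarely drift from a 0.1 founder AF past
the 0.30 threshold in 30 generations with N = 500. That is a property of
the chosen conditions, not a defect; the classification logic itself is
validated on planted fixtures with exact AFs.

**DNA arm.** Each cell draws a lognormal amplification factor b
(`fragment_bias_sd`, default 0.2): fragment-X positions are covered at
`mean_depth · b`, fragment-Y positions at `mean_depth / b` (reciprocal
bias), with negative-binomial per-base noise (`depth_dispersion`, one
overdispersion parameter; 0 gives deterministic depth). Allele counts at
each variant site are multinomial given the cell's true AF and the
sequencing error rate e: alt reads at af(1−e) + (1−af)e/3, each other
base at e/3, remainder reference — so counts always sum to depth exactly.
The default study has 88 cells (44 induced / 44 noninduced), of which 4
(2 per condition) are constructed with fragment-X coverage scaled far
below the 1000x threshold, and one passing cell is given a fixed extreme
imbalance (~83% of depth on fragment Y). Fragment-depth QC therefore
passes exactly 84 of 88 cells by construction — the assertion in the test
suite is about the QC rules and determinism, not a reproduction of any
particular dataset. One founder variant sits within 25 bp of position 1
so the circular merge path is always exercised.

**RNA arm.** An independently drawn lineage (different culture batch, so
different cells) of 300 cells receives: a sparse cell-by-gene matrix with
Beta-distributed mitochondrial fractions (mean ≈ 8%), Gaussian feature
counts (mean 3000, sd 350), engineered QC outliers (5 cells at 30% mito
fraction, 2 below and 2 above the feature bounds, 2 with ~30x mito
depth), and a recombinant-antibody transcript ~9-fold higher in induced
cells; mitochondrial allele counts restricted to transcribed intervals at
~80x depth; configured RNA-only variants injected into RNA counts only
(RNA-editing stand-ins, surfacing as RNA-specific in modality
comparisons); and raw read records of which a configurable fraction carry
runs of ≥5 A's for the masking path. Background reads are scrubbed of
chance 5-A runs so that `polyA_rate = 0` implies literally zero masked
reads.

**What the generator does not emulate.** Alignment artifacts, Numts
(nuclear mitochondrial insertions), strand bias, UMI structure, doublets
and ambient RNA, PCR duplicates, and base-quality variation are all out
of scope. Passing tests therefore demonstrate that the *computational*
pipeline is correct under its stated sampling models — binomial read
sampling, NB depth, Wright–Fisher drift — not that those models capture
every failure mode of real libraries.

# Numerical and degenerate-input choices

* AF·depth reproduces integer alt counts exactly wherever AF is defined;
  the circular-merge equivalence is asserted with `identical()`, no
  tolerance.
* Pooled t-tests on zero-variance data: identical constant groups return
  statistic 0 and p = 1; distinct constant groups return ±Inf and p = 0.
* Quartile splits with all AFs identical are skipped with reason
  `degenerate_quartiles` rather than fabricating empty groups.
* Pseudobulk sites with zero pooled depth have undefined AF.
* Empty call sets flow through classification, comparison and report
  rendering producing zero-row tables, never errors.
* All randomness is governed by one integer seed; each stage derives its
  own stream offset, and rerunning a simulation with the same seed
  reproduces every fixture file byte for byte.

# Problem sizes used in validation

The packaged checks run the default 88-cell / 300-cell study once, 20
random circular genomes of 2–16 kb for merge exactness, all 1800 SNVs of
two 300 bp toy genes for the annotator, 10,000 one-generation replicates
for the segregation moments, 200 cells x 5 sites at 1000x for AF
recovery, 1000 null mutations for t-test calibration, and 20 permuted
expression matrices (100 genes x 120 cells) for the quartile test's
false-positive behaviour. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances while keeping a full run in a
few minutes on one core.

# Known limitations

* The annotator's MODIFIER verdict for tRNA/rRNA variants understates
  impacts a structural-RNA-aware annotator would report.
* Indels are single-base symbolic alleles; multi-base indels and their
  in-frame/frameshift distinction are not modelled.
* The condition comparison pools all cells per mutation; no pairing or
  per-site subsetting is attempted, and no across-mutation correction is
  applied (by design, documented above).
* Bottleneck parameters (N, g) are not identifiable from the package's
  inputs; conclusions about drift magnitude in real populations require
  external estimates.
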