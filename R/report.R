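## Report generation: deterministic TSV tables, standard figures (violin /
## heatmap / scatter of allele-frequency structure) and a run manifest.

#' Write analysis tables, figures and a run manifest
#'
#' Tables (TSV, byte-stable across reruns of the same analysis): cell QC
#' for both arms, the classification table, condition tests and the
#' modality table. Figures (PNG): per-mutation AF violins for the "most
#' variable" list split by condition, a cell-by-mutation AF heatmap of the
#' "most impactful" list, heteroplasmic events per cell by condition, and
#' a DNA-vs-RNA pseudobulk AF scatter. A JSON manifest records the
#' configuration, seed and package version.
#'
#' @param analysis result of [analyzeStudy()].
#' @param out_dir output directory (created if needed).
#' @param config optional [simulationConfig()] echoed into the manifest.
#' @param conditions optional named cell -> condition vector used for the
#'   split figures; defaults to the first letter of the cell id (I/N)
#'   convention used by the simulator.
#' @param plots write figure files (default TRUE).
#' @return invisibly, the vector of files written.
#' @export
renderReport <- function(analysis, out_dir, config = NULL,
                         conditions = NULL, plots = TRUE) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- character()
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wt(analysis$qc_dna, "qc_dna.tsv")
  wt(analysis$qc_rna, "qc_rna.tsv")
  wt(analysis$classification, "classification.tsv")
  if (!is.null(analysis$condition_tests)) {
    wt(analysis$condition_tests, "condition_tests.tsv")
  }
  wt(analysis$modality, "modality.tsv")
  epc <- data.frame(cell_id = names(analysis$events_per_cell),
                    events = as.integer(analysis$events_per_cell))
  wt(epc, "events_per_cell.tsv")

  if (plots) files <- c(files, .reportPlots(analysis, out_dir, conditions))

  manifest <- list(package = "scMitoHet",
                   version = as.character(utils::packageVersion("scMitoHet")),
                   n_cells_dna = length(analysis$dna_cells),
                   n_cells_rna = length(analysis$rna_cells),
                   n_calls_dna = length(analysis$calls_dna),
                   n_most_variable = length(analysis$most_variable),
                   n_most_impactful = length(analysis$most_impactful),
                   n_joint_impactful = length(analysis$joint_impactful))
  if (!is.null(config)) {
    cfg <- config
    class(cfg) <- NULL
    manifest$config <- cfg
    manifest$seed <- config$seed
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

.afLong <- function(vcs, conditions = NULL) {
  af <- afMatrix(vcs)
  if (nrow(af) == 0L) return(NULL)
  d <- data.frame(
    mutation = rep(variantLabels(vcs), times = ncol(af)),
    cell_id = rep(colnames(af), each = nrow(af)),
    af = as.vector(af), stringsAsFactors = FALSE)
  d <- d[!is.na(d$af), , drop = FALSE]
  if (is.null(conditions)) {
    d$condition <- ifelse(startsWith(d$cell_id, "I"), "induced",
                          "noninduced")
  } else {
    d$condition <- conditions[d$cell_id]
  }
  d
}

.reportPlots <- function(analysis, out_dir, conditions) {
  files <- character()
  sv <- function(p, name, width = 7, height = 5) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    files <<- c(files, path)
  }
  long_mv <- .afLong(analysis$most_variable, conditions)
  if (!is.null(long_mv) && nrow(long_mv)) {
    p <- ggplot2::ggplot(long_mv,
           ggplot2::aes(x = .data$mutation, y = .data$af,
                        fill = .data$condition)) +
      ggplot2::geom_violin(scale = "width", adjust = 0.8) +
      ggplot2::labs(x = NULL, y = "allele frequency",
                    title = "Most variable heteroplasmic mutations") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 45, hjust = 1))
    sv(p, "most_variable_violin.png", width = 8)
  }
  long_mi <- .afLong(analysis$most_impactful, conditions)
  if (!is.null(long_mi) && nrow(long_mi)) {
    p <- ggplot2::ggplot(long_mi,
           ggplot2::aes(x = .data$cell_id, y = .data$mutation,
                        fill = .data$af)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = "cell", y = NULL, fill = "AF",
                    title = "Most impactful mutations") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
    sv(p, "most_impactful_heatmap.png", width = 9, height = 4)
  }
  epc <- analysis$events_per_cell
  if (length(epc)) {
    d <- data.frame(cell_id = names(epc), events = as.numeric(epc))
    d$condition <- if (is.null(conditions)) {
      ifelse(startsWith(d$cell_id, "I"), "induced", "noninduced")
    } else conditions[d$cell_id]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$condition,
                                         y = .data$events,
                                         fill = .data$condition)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::labs(y = "heteroplasmic events per cell", x = NULL) +
      ggplot2::theme_bw() + ggplot2::guides(fill = "none")
    sv(p, "events_per_cell_violin.png", width = 5)
  }
  mod <- analysis$modality
  if (!is.null(mod) && nrow(mod)) {
    d <- mod
    d$dna_af[is.na(d$dna_af)] <- 0
    d$rna_af[is.na(d$rna_af)] <- 0
    eps <- 1e-4
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dna_af + eps,
                                         y = .data$rna_af + eps,
                                         colour = .data$class)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "DNA pseudobulk AF", y = "RNA pseudobulk AF") +
      ggplot2::theme_bw()
    sv(p, "modality_scatter.png")
  }
  files
}
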