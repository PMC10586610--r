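# Pipeline layer: assembles the stages into the two reproducible workflows
# and writes their result bundles (TSVs + a JSON run manifest echoing the
# full configuration, so every run is reconstructible).

write_manifest <- function(output_dir, stage, config, extra = list()) {
  # no timestamp: identical inputs + config must yield byte-identical bundles
  manifest <- c(list(stage = stage,
                     package_version = as.character(
                       utils::packageVersion("igora"))),
                list(config = config), extra)
  path <- file.path(output_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full gene-set enrichment pipeline
#'
#' Normalize -> gene filter -> per-identity one-sided rank-sum screen with
#' horizontal BH correction and upregulation calls -> eligibility-gated
#' one-sided Fisher over-representation with Bonferroni control. Inputs may
#' be in-memory objects or file paths (MatrixMarket triplet for counts,
#' CSV/TSV for annotation and gene set). When `output_dir` is given, writes
#' `de_table.tsv`, `enrichment.tsv` and `enrich_manifest.json`.
#'
#' @param counts a [count_matrix()], or a list/vector of three paths
#'   `(matrix, genes, barcodes)` for [read_count_matrix()].
#' @param annotation data.frame (`cell_id`, `identity`) or path.
#' @param gene_set data.frame (`gene`, `origin`) or path.
#' @param output_dir directory for the result bundle, or `NULL` to skip
#'   writing.
#' @param scale_target,log_base passed to [normalize_counts()].
#' @param min_cells passed to [filter_genes()].
#' @param q_max,lfc_min,epsilon,bh_family,exact_limit passed to
#'   [de_screen()].
#' @param eligibility_fraction,fc_genes passed to [run_ora()].
#' @return list with `de` (DETable), `enrichment` (ORA table) and `config`.
#' @export
run_enrichment <- function(counts, annotation, gene_set,
                           output_dir = NULL,
                           scale_target = NULL, log_base = "e",
                           min_cells = 20L,
                           q_max = 0.05, lfc_min = 1.0, epsilon = 1e-9,
                           bh_family = "per_gene", exact_limit = 12L,
                           eligibility_fraction = 0.05, fc_genes = "all") {
  if (!inherits(counts, "count_matrix")) {
    counts <- unlist(counts)
    if (length(counts) != 3L) {
      stop_stage("cli", "counts must be a count_matrix or 3 paths ",
                 "(matrix, genes, barcodes)")
    }
    counts <- read_count_matrix(counts[[1L]], counts[[2L]], counts[[3L]])
  }
  if (is.character(annotation)) annotation <- read_cell_annotation(annotation)
  if (is.character(gene_set)) gene_set <- read_gene_set(gene_set)

  expr <- normalize_counts(counts, scale_target, log_base)
  n_before <- length(expr$gene_ids)
  expr <- filter_genes(expr, min_cells)
  de <- de_screen(expr, annotation, q_max = q_max, lfc_min = lfc_min,
                  epsilon = epsilon, bh_family = bh_family,
                  exact_limit = exact_limit)
  ora <- run_ora(de, gene_set, eligibility_fraction = eligibility_fraction,
                 fc_genes = fc_genes)

  config <- list(scale_target = expr$scale_target, log_base = log_base,
                 min_cells = min_cells, q_max = q_max, lfc_min = lfc_min,
                 epsilon = epsilon, bh_family = bh_family,
                 exact_limit = exact_limit,
                 eligibility_fraction = eligibility_fraction,
                 fc_genes = fc_genes)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(de, file.path(output_dir, "de_table.tsv"))
    write_table(ora, file.path(output_dir, "enrichment.tsv"))
    write_manifest(output_dir, "enrich", config, list(
      n_genes_before_filter = n_before,
      n_genes_after_filter = length(expr$gene_ids),
      n_cells = length(expr$cell_ids),
      n_identities = length(unique(annotation$identity)),
      m_eligible = attr(ora, "params")$m_eligible))
  }
  list(de = de, enrichment = ora, config = config)
}

#' Run the full RNAscope quantification pipeline
#'
#' Derive per-channel thresholds from the no-probe control, resolve every
#' supra-threshold object into molecules, classify cells by the positivity
#' rules, and summarise per animal (positives per 1000 cells, H-scores).
#' When `output_dir` is given, writes `cell_molecules.tsv`,
#' `animal_summary.tsv` and `quantify_manifest.json`.
#'
#' @param signals signal table (data.frame) or path.
#' @param control control intensity table (data.frame) or path.
#' @param calibration named list per channel
#'   (`single_signal_mean_intensity`, `background`), or path to a JSON file
#'   with that structure.
#' @param rules named positivity rules, channel -> minimum molecules.
#' @param cells optional cell roster (see [cell_molecule_counts()]).
#' @param output_dir directory for the result bundle, or `NULL`.
#' @return list with `thresholds`, `counts` (cell x channel molecule table),
#'   `summary` (per-animal) and `config`.
#' @export
run_quantify <- function(signals, control, calibration, rules,
                         cells = NULL, output_dir = NULL) {
  if (is.character(signals)) signals <- read_signal_table(signals)
  if (is.character(control)) control <- read_control_table(control)
  if (is.character(calibration)) {
    if (!file.exists(calibration)) {
      stop_stage("cli", "calibration file not found: ", calibration)
    }
    calibration <- jsonlite::read_json(calibration, simplifyVector = TRUE)
  }
  thresholds <- derive_thresholds(control)
  counts <- cell_molecule_counts(signals, thresholds, calibration, cells)
  summary <- summarize_by_animal(counts, rules)

  config <- list(
    rules = as.list(rules),
    calibration = calibration,
    thresholds = lapply(thresholds, function(t) t$threshold))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(counts, file.path(output_dir, "cell_molecules.tsv"))
    write_table(summary, file.path(output_dir, "animal_summary.tsv"))
    write_manifest(output_dir, "quantify", config, list(
      n_cells = nrow(counts),
      n_objects = nrow(signals),
      n_control_cells = length(unique(control$cell_id))))
  }
  list(thresholds = thresholds, counts = counts, summary = summary,
       config = config)
}
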