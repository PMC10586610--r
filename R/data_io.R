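#' Construct a validated count matrix
#'
#' A `count_matrix` holds a genes x cells matrix of non-negative integer UMI
#' counts together with gene and cell identifiers. Gene identifiers must be
#' unique after case normalization (gene-symbol matching downstream is
#' case-insensitive); cell identifiers must be unique as given.
#'
#' @param values genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative integers.
#' @param gene_ids character vector, one per row.
#' @param cell_ids character vector, one per column.
#' @return An object of class `count_matrix`: a list with elements `values`
#'   (a `dgCMatrix`), `gene_ids` and `cell_ids`.
#' @export
count_matrix <- function(values, gene_ids, cell_ids) {
  if (!methods::is(values, "Matrix")) {
    values <- Matrix::Matrix(values, sparse = TRUE)
  }
  values <- methods::as(methods::as(methods::as(values, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids)) {
    stop_stage("data_io", "gene id count (", length(gene_ids),
               ") does not match matrix rows (", nrow(values), ")")
  }
  if (ncol(values) != length(cell_ids)) {
    stop_stage("data_io", "cell id count (", length(cell_ids),
               ") does not match matrix columns (", ncol(values), ")")
  }
  if (length(values@x) > 0L) {
    if (any(values@x < 0)) {
      stop_stage("data_io", "count matrix contains negative entries")
    }
    if (any(values@x != round(values@x))) {
      stop_stage("data_io", "count matrix contains non-integer entries")
    }
  }
  if (anyDuplicated(tolower(gene_ids))) {
    stop_stage("data_io", "gene ids are not unique (case-insensitive)")
  }
  if (anyDuplicated(cell_ids)) {
    stop_stage("data_io", "cell ids are not unique")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d non-zero entries)\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a CellRanger-style MatrixMarket count triplet
#'
#' Reads a sparse genes x cells count matrix in MatrixMarket coordinate
#' format together with its side files listing gene identifiers (rows) and
#' cell barcodes (columns), one record per line. When the genes file has two
#' or more tab-separated columns (Ensembl id, symbol) the second column is
#' used as the gene identifier; otherwise the first.
#'
#' @param matrix_path path to the `.mtx` file (coordinate, integer).
#' @param genes_path path to the genes/features TSV.
#' @param barcodes_path path to the barcodes TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop_stage("data_io", "input file not found: ", p)
  }
  m <- Matrix::readMM(matrix_path)
  genes <- read.delim(genes_path, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- read.delim(barcodes_path, header = FALSE,
                         stringsAsFactors = FALSE)
  gene_ids <- if (ncol(genes) >= 2L) genes[[2L]] else genes[[1L]]
  cell_ids <- barcodes[[1L]]
  if (length(gene_ids) != nrow(m)) {
    stop_stage("data_io", "genes file has ", length(gene_ids),
               " records but matrix header declares ", nrow(m), " rows")
  }
  if (length(cell_ids) != ncol(m)) {
    stop_stage("data_io", "barcodes file has ", length(cell_ids),
               " records but matrix header declares ", ncol(m), " columns")
  }
  count_matrix(m, gene_ids, cell_ids)
}

#' Read per-cell identity labels
#'
#' @param path CSV/TSV with columns `cell_id` and `identity`.
#' @return data.frame with character columns `cell_id`, `identity`.
#' @export
read_cell_annotation <- function(path) {
  df <- read_delim_checked(path, c("cell_id", "identity"), "data_io")
  if (anyDuplicated(df$cell_id)) {
    stop_stage("data_io", "duplicate cell_id in annotation: ",
               paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  }
  data.frame(cell_id = as.character(df$cell_id),
             identity = as.character(df$identity),
             stringsAsFactors = FALSE)
}

#' Read a gene set (e.g. an imprinted-gene list)
#'
#' @param path CSV/TSV with a `gene` column and optionally an `origin` column
#'   (values `MEG`/`PEG`; anything else becomes `unknown`). Duplicate gene
#'   symbols are collapsed with a warning.
#' @return data.frame with columns `gene`, `origin`.
#' @export
read_gene_set <- function(path) {
  df <- read_delim_checked(path, "gene", "data_io")
  if (nrow(df) == 0L) stop_stage("data_io", "gene set file is empty: ", path)
  origin <- if ("origin" %in% names(df)) as.character(df$origin)
            else rep("unknown", nrow(df))
  origin[!origin %in% c("MEG", "PEG")] <- "unknown"
  gene <- as.character(df$gene)
  dup <- duplicated(tolower(gene))
  if (any(dup)) {
    warning(sprintf("gene set: collapsed %d duplicate symbol(s): %s",
                    sum(dup), paste(unique(gene[dup]), collapse = ", ")),
            call. = FALSE)
  }
  data.frame(gene = gene[!dup], origin = origin[!dup],
             stringsAsFactors = FALSE)
}

#' Read a per-cell RNAscope signal (object) table
#'
#' One row per detected fluorescent object. Required columns: `cell_id`,
#' `channel`, `integral_intensity`; metadata columns `animal_id`,
#' `section_id`, `condition` are carried through when present and filled with
#' `NA` otherwise. Channel names are free strings.
#'
#' @param path CSV/TSV file.
#' @return data.frame with columns `cell_id`, `animal_id`, `section_id`,
#'   `condition`, `channel`, `integral_intensity`.
#' @export
read_signal_table <- function(path) {
  df <- read_delim_checked(path, c("cell_id", "channel", "integral_intensity"),
                           "data_io")
  if (any(df$integral_intensity < 0)) {
    stop_stage("data_io", "negative integral_intensity in ", path)
  }
  for (col in c("animal_id", "section_id", "condition")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  data.frame(cell_id = as.character(df$cell_id),
             animal_id = as.character(df$animal_id),
             section_id = as.character(df$section_id),
             condition = as.character(df$condition),
             channel = as.character(df$channel),
             integral_intensity = as.numeric(df$integral_intensity),
             stringsAsFactors = FALSE)
}

#' Read a no-probe-control per-cell maximum-intensity table
#'
#' @param path CSV/TSV with columns `cell_id`, `channel`, `max_intensity`;
#'   one row per (cell, channel).
#' @return data.frame with those three columns.
#' @export
read_control_table <- function(path) {
  df <- read_delim_checked(path, c("cell_id", "channel", "max_intensity"),
                           "data_io")
  if (any(df$max_intensity < 0)) {
    stop_stage("data_io", "negative max_intensity in ", path)
  }
  key <- paste(df$cell_id, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop_stage("data_io", "duplicate (cell_id, channel) rows in ", path)
  }
  data.frame(cell_id = as.character(df$cell_id),
             channel = as.character(df$channel),
             max_intensity = as.numeric(df$max_intensity),
             stringsAsFactors = FALSE)
}

#' Write a tabular result as TSV
#'
#' Columns are written in the data.frame's order, UTF-8, '.' decimal
#' separator, no row names. Doubles are serialized at 17 significant digits
#' so that write -> read round-trips are exact.
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- format_full_precision(records)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Match gene-set symbols against dataset genes
#'
#' Case-insensitive exact match. Unmatched set genes are reported via a
#' message (not an error): curated lists routinely contain genes absent from
#' any one dataset.
#'
#' @param gene_set data.frame as from [read_gene_set()], or character vector.
#' @param dataset_genes character vector of dataset gene identifiers.
#' @return character vector of dataset gene identifiers matched by the set.
#' @export
match_gene_set <- function(gene_set, dataset_genes) {
  set_genes <- if (is.data.frame(gene_set)) gene_set$gene else gene_set
  hit <- match(tolower(set_genes), tolower(dataset_genes))
  unmatched <- set_genes[is.na(hit)]
  if (length(unmatched) > 0L) {
    message(sprintf("gene set: %d of %d genes not in dataset (%s)",
                    length(unmatched), length(set_genes),
                    paste(utils::head(unmatched, 10L), collapse = ", ")))
  }
  dataset_genes[hit[!is.na(hit)]]
}
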