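#' Simulate a single-cell count matrix with optional planted enrichment
#'
#' Generates a genes x cells UMI matrix with the statistical structure the
#' enrichment pipeline assumes: gene baseline means drawn from a log-normal
#' distribution, per-cell counts from a negative binomial parameterised by
#' (mean, dispersion) with variance `mean + mean^2 / dispersion`, cells
#' partitioned into identity groups of equal size, and a designated gene set
#' (the "imprinted" genes). When `planted_identity` is given, a random
#' `planted_set_fraction` of the set genes have their mean multiplied by
#' `planted_fold` in that identity's cells -- the ground-truth enrichment the
#' pipeline should recover. `planted_identity = NULL` (default) is the pure
#' null: all cells exchangeable.
#'
#' Defaults mirror the scale at which the screen operates: a 74-gene set of
#' which 20 genes are planted at fold 4 in one of 10 identity groups of 200
#' cells each.
#'
#' @param n_genes number of genes (default 1000).
#' @param n_identities number of identity groups (default 10).
#' @param cells_per_identity cells per group (default 200).
#' @param baseline_mean_log_mu,baseline_mean_log_sd log-normal parameters of
#'   the gene baseline means (defaults `log(0.5)`, 1).
#' @param nb_dispersion negative-binomial dispersion (size) parameter
#'   (default 2).
#' @param set_size size of the designated gene set (default 74).
#' @param planted_identity identity label receiving the planted effect, or
#'   `NULL` for a null simulation.
#' @param planted_set_fraction fraction of set genes planted (default 20/74).
#' @param planted_fold mean multiplier for planted genes (default 4).
#' @param seed integer seed; the single source of randomness.
#' @return list with `counts` (a [count_matrix()]), `annotation`
#'   (data.frame `cell_id`, `identity`), `gene_set` (data.frame `gene`,
#'   `origin`) and `ground_truth` (list: `planted_identity`,
#'   `planted_genes`, `set_genes`, `baseline_means`).
#' @export
simulate_counts <- function(n_genes = 1000L,
                            n_identities = 10L,
                            cells_per_identity = 200L,
                            baseline_mean_log_mu = log(0.5),
                            baseline_mean_log_sd = 1,
                            nb_dispersion = 2,
                            set_size = 74L,
                            planted_identity = NULL,
                            planted_set_fraction = 20 / 74,
                            planted_fold = 4,
                            seed = 1L) {
  if (set_size > n_genes) {
    stop_stage("synthetic_data", "set_size (", set_size,
               ") exceeds n_genes (", n_genes, ")")
  }
  if (planted_set_fraction < 0 || planted_set_fraction > 1) {
    stop_stage("synthetic_data", "planted_set_fraction must be in [0, 1]")
  }
  if (planted_fold < 1) {
    stop_stage("synthetic_data", "planted_fold must be >= 1")
  }
  set.seed(as.integer(seed))

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  identities <- sprintf("ident%02d", seq_len(n_identities))
  if (!is.null(planted_identity) && !planted_identity %in% identities) {
    stop_stage("synthetic_data", "planted_identity '", planted_identity,
               "' not among generated identities (",
               identities[1L], "..", identities[n_identities], ")")
  }
  n_cells <- n_identities * cells_per_identity
  cell_ids <- sprintf("cell%06d", seq_len(n_cells))
  labels <- rep(identities, each = cells_per_identity)

  mu <- rlnorm(n_genes, baseline_mean_log_mu, baseline_mean_log_sd)
  set_genes <- sort(sample(gene_ids, set_size))
  n_planted <- round(planted_set_fraction * set_size)
  planted_genes <- if (!is.null(planted_identity) && planted_fold > 1 &&
                         n_planted > 0L) {
    sort(sample(set_genes, n_planted))
  } else {
    character(0)
  }

  values <- matrix(0L, n_genes, n_cells)
  planted_idx <- match(planted_genes, gene_ids)
  for (j in seq_along(identities)) {
    mu_j <- mu
    if (length(planted_idx) > 0L && identities[j] == planted_identity) {
      mu_j[planted_idx] <- mu_j[planted_idx] * planted_fold
    }
    cols <- which(labels == identities[j])
    values[, cols] <- rnbinom(n_genes * length(cols), size = nb_dispersion,
                              mu = mu_j)
  }

  origin <- sample(c("MEG", "PEG"), set_size, replace = TRUE)
  list(
    counts = count_matrix(values, gene_ids, cell_ids),
    annotation = data.frame(cell_id = cell_ids, identity = labels,
                            stringsAsFactors = FALSE),
    gene_set = data.frame(gene = set_genes, origin = origin,
                          stringsAsFactors = FALSE),
    ground_truth = list(planted_identity = planted_identity,
                        planted_genes = planted_genes,
                        set_genes = set_genes,
                        baseline_means = setNames(mu, gene_ids))
  )
}

#' Simulate RNAscope per-cell signal and control tables
#'
#' Emulates the per-cell object tables the quantification stage consumes.
#' Each cell is assigned a type with the configured proportions; per channel
#' its true molecule count is Poisson with the type's mean. Each molecule is
#' emitted as a single object (integral intensity
#' `Normal(single_intensity_mean, single_intensity_sd)` plus background) or,
#' with probability `cluster_prob`, pooled into the cell's cluster, whose
#' object intensity is the sum of its members' single intensities plus one
#' background term. No-probe-control cells have per-channel maximum
#' intensities `|Normal(0, control_noise_sd)| + background`.
#'
#' @param cell_types list of cell-type specs, each a list with `label`,
#'   `proportion`, and `means` (named vector, channel -> mean molecule
#'   count). Proportions must sum to 1 (tolerance 1e-9). The default sketches
#'   a preoptic-area-like mix: a small Gal/Calcr-high population against a
#'   large low-expression background.
#' @param n_cells number of probe-section cells (default 2000).
#' @param single_intensity_mean,single_intensity_sd single-signal integral
#'   intensity distribution (a.u.; defaults 300, 30).
#' @param background average background integral intensity added to every
#'   object (default 50).
#' @param cluster_prob probability a molecule joins the cell's cluster
#'   (default 0.3).
#' @param n_control_cells number of no-probe-control cells (default 200).
#' @param control_noise_sd control max-intensity noise SD (default 20).
#' @param animal_id,section_id,condition metadata stamped on every cell.
#' @param seed integer seed; the single source of randomness.
#' @return list with `signals` (signal table), `control` (control intensity
#'   table), `cells` (cell roster with metadata) and `ground_truth` (a
#'   cell x channel molecule-count data.frame in [cell_molecule_counts()]
#'   layout).
#' @export
simulate_spots <- function(cell_types = list(
                             list(label = "gal_calcr", proportion = 0.05,
                                  means = c(Gal = 8, Calcr = 6, Fos = 5)),
                             list(label = "gal_only", proportion = 0.07,
                                  means = c(Gal = 6, Calcr = 0.2, Fos = 2)),
                             list(label = "other", proportion = 0.88,
                                  means = c(Gal = 0.2, Calcr = 0.3, Fos = 1))
                           ),
                           n_cells = 2000L,
                           single_intensity_mean = 300,
                           single_intensity_sd = 30,
                           background = 50,
                           cluster_prob = 0.3,
                           n_control_cells = 200L,
                           control_noise_sd = 20,
                           animal_id = "animal1",
                           section_id = "section1",
                           condition = "control",
                           seed = 1L) {
  props <- vapply(cell_types, function(ct) ct$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop_stage("synthetic_data", "cell type proportions must sum to 1 (got ",
               format(sum(props)), ")")
  }
  if (single_intensity_mean <= 0) {
    stop_stage("synthetic_data", "single_intensity_mean must be > 0")
  }
  set.seed(as.integer(seed))

  channels <- names(cell_types[[1L]]$means)
  labels <- vapply(cell_types, function(ct) ct$label, character(1))
  cell_ids <- sprintf("cell%06d", seq_len(n_cells))
  type_of <- sample(labels, n_cells, replace = TRUE, prob = props)
  mean_table <- do.call(rbind, lapply(cell_types, function(ct)
    ct$means[channels]))
  rownames(mean_table) <- labels

  cells <- data.frame(cell_id = cell_ids, animal_id = animal_id,
                      section_id = section_id, condition = condition,
                      cell_type = type_of, stringsAsFactors = FALSE)
  truth <- cells[, c("cell_id", "animal_id", "section_id", "condition")]

  acc_cell <- list(); acc_channel <- list(); acc_intensity <- list()
  for (ch in channels) {
    k <- rpois(n_cells, mean_table[type_of, ch])
    truth[[ch]] <- as.integer(k)
    for (i in which(k > 0L)) {
      singles <- pmax(rnorm(k[i], single_intensity_mean, single_intensity_sd), 0)
      in_cluster <- rbinom(k[i], 1L, cluster_prob) == 1L
      intensities <- c(
        if (any(!in_cluster)) singles[!in_cluster] + background,
        if (any(in_cluster)) sum(singles[in_cluster]) + background
      )
      j <- length(acc_cell) + 1L
      acc_cell[[j]] <- rep(cell_ids[i], length(intensities))
      acc_channel[[j]] <- rep(ch, length(intensities))
      acc_intensity[[j]] <- intensities
    }
  }
  sig_cell <- unlist(acc_cell) %||% character(0)
  sig_channel <- unlist(acc_channel) %||% character(0)
  sig_intensity <- unlist(acc_intensity) %||% numeric(0)
  idx <- match(sig_cell, cell_ids)
  signals <- data.frame(cell_id = sig_cell,
                        animal_id = cells$animal_id[idx],
                        section_id = cells$section_id[idx],
                        condition = cells$condition[idx],
                        channel = sig_channel,
                        integral_intensity = sig_intensity,
                        stringsAsFactors = FALSE)

  control <- expand.grid(cell_id = sprintf("ctrl%05d", seq_len(n_control_cells)),
                         channel = channels, stringsAsFactors = FALSE)
  control$max_intensity <- abs(rnorm(nrow(control), 0, control_noise_sd)) +
    background
  control <- control[order(control$cell_id, control$channel), ]
  rownames(control) <- NULL

  list(signals = signals, control = control,
       cells = cells[, c("cell_id", "animal_id", "section_id", "condition")],
       ground_truth = truth,
       cell_types = cells$cell_type)
}
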