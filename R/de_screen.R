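#' Normalize a count matrix
#'
#' Each cell's counts are scaled to a common total (`scale_target`, default
#' the median cell total) and then log-transformed as `log(1 + x)` in the
#' requested base. Cells with a zero total cannot be scaled and are rejected.
#'
#' @param counts a [count_matrix()].
#' @param scale_target positive scalar; per-cell total after scaling.
#'   `NULL` (default) uses the median of the observed cell totals.
#' @param log_base `"e"` (natural log, default) or `"2"`.
#' @return An object of class `normalized_expression`: list with `values`
#'   (dense genes x cells matrix), `gene_ids`, `cell_ids`, `scale_target`,
#'   `log_base`.
#' @export
normalize_counts <- function(counts, scale_target = NULL, log_base = c("e", "2")) {
  stopifnot(inherits(counts, "count_matrix"))
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  totals <- Matrix::colSums(counts$values)
  zero <- which(totals == 0)
  if (length(zero) > 0L) {
    stop_stage("de_screen", "cell(s) with zero total count: ",
               paste(counts$cell_ids[zero], collapse = ", "))
  }
  if (is.null(scale_target)) scale_target <- median(totals)
  if (!is.numeric(scale_target) || scale_target <= 0) {
    stop_stage("de_screen", "scale_target must be a positive number")
  }
  scaled <- counts$values %*% Matrix::Diagonal(x = scale_target / totals)
  vals <- log1p(as.matrix(scaled))
  if (log_base == "2") vals <- vals / log(2)
  dimnames(vals) <- list(counts$gene_ids, counts$cell_ids)
  structure(list(values = vals,
                 gene_ids = counts$gene_ids,
                 cell_ids = counts$cell_ids,
                 scale_target = scale_target,
                 log_base = log_base),
            class = "normalized_expression")
}

#' @exportS3Method base::print
print.normalized_expression <- function(x, ...) {
  cat(sprintf("normalized_expression: %d genes x %d cells (scale %g, log %s)\n",
              nrow(x$values), ncol(x$values), x$scale_target, x$log_base))
  invisible(x)
}

#' Filter genes by detection breadth
#'
#' Retains genes detected (normalized value > 0) in at least `min_cells`
#' cells across the whole dataset; the default of 20 is the conventional
#' whole-dataset detection filter for this screen.
#'
#' @param expr `normalized_expression`.
#' @param min_cells integer >= 1.
#' @return `normalized_expression` with the reduced gene list.
#' @export
filter_genes <- function(expr, min_cells = 20L) {
  stopifnot(inherits(expr, "normalized_expression"))
  if (min_cells < 1L) stop_stage("de_screen", "min_cells must be >= 1")
  keep <- rowSums(expr$values > 0) >= min_cells
  if (!any(keep)) {
    stop_stage("de_screen", "gene filter removed all genes (min_cells = ",
               min_cells, ")")
  }
  expr$values <- expr$values[keep, , drop = FALSE]
  expr$gene_ids <- expr$gene_ids[keep]
  expr
}

# Align a cell annotation to an expression object: returns the identity label
# per expression column. Cells missing from the annotation are an error.
align_identities <- function(expr, ann) {
  idx <- match(expr$cell_ids, ann$cell_id)
  if (anyNA(idx)) {
    stop_stage("de_screen", "cells missing from annotation: ",
               paste(utils::head(expr$cell_ids[is.na(idx)], 5L), collapse = ", "))
  }
  ann$identity[idx]
}

# One-sided (greater) Wilcoxon rank-sum p-value for x_in vs x_out.
# Midranks throughout. Exact null by enumeration of all C(N, n_in) group
# assignments when N <= exact_limit; otherwise normal approximation with
# tie-corrected variance and 0.5 continuity correction.
rank_sum_greater_p <- function(x_in, x_out, exact_limit = 12L) {
  n1 <- length(x_in); n2 <- length(x_out); n <- n1 + n2
  r <- rank(c(x_in, x_out))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_limit) {
    combos <- combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    return(mean(sums >= w - 1e-9))
  }
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - 0.5) / sqrt(sigma2)
  min(1, max(pnorm(z, lower.tail = FALSE), .Machine$double.xmin))
}

#' Per-gene one-sided rank-sum upregulation p-values for one identity group
#'
#' For every gene, tests whether expression in the cells of `identity` is
#' stochastically greater than in all other cells (one-sided Wilcoxon
#' rank-sum, midranks). The exact permutation null is enumerated when the
#' total number of cells is at most `exact_limit`; above that a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param expr `normalized_expression`.
#' @param ann annotation data.frame (`cell_id`, `identity`).
#' @param identity group label to test.
#' @param exact_limit maximum combined sample size for exact enumeration.
#' @return named numeric vector of p-values, one per gene.
#' @export
rank_sum_upregulation <- function(expr, ann, identity, exact_limit = 12L) {
  labels <- align_identities(expr, ann)
  if (!identity %in% labels) {
    stop_stage("de_screen", "unknown identity group: ", identity)
  }
  in_group <- labels == identity
  if (all(in_group)) {
    stop_stage("de_screen", "identity group '", identity,
               "' contains every cell; no out-group to compare against")
  }
  p <- apply(expr$values, 1L, function(v) {
    rank_sum_greater_p(v[in_group], v[!in_group], exact_limit)
  })
  setNames(p, expr$gene_ids)
}

#' Horizontal Benjamini-Hochberg correction
#'
#' Applies BH step-up within each correction family of a genes x identities
#' p-value matrix. The default family is `"per_gene"` (the "horizontal"
#' reading: each gene's p-values across identity groups form one family,
#' i.e. the correction runs along the row). `"per_group"` corrects within
#' each column, `"global"` over the whole matrix.
#'
#' @param p numeric matrix (genes x identities) of raw p-values in (0, 1].
#' @param family `"per_gene"`, `"per_group"` or `"global"`.
#' @return matrix of q-values with the same dimnames.
#' @export
horizontal_bh <- function(p, family = c("per_gene", "per_group", "global")) {
  family <- match.arg(family)
  p <- as.matrix(p)
  if (any(p <= 0 | p > 1 | is.na(p))) {
    stop_stage("de_screen", "p-values must lie in (0, 1]")
  }
  q <- switch(family,
    per_gene  = t(apply(p, 1L, p.adjust, method = "BH")),
    per_group = apply(p, 2L, p.adjust, method = "BH"),
    global    = matrix(p.adjust(p, method = "BH"), nrow = nrow(p))
  )
  if (ncol(p) == 1L && family == "per_gene") q <- t(q)  # apply() drops dims
  dimnames(q) <- dimnames(p)
  q
}

#' Fold change and detection percentages for one identity group
#'
#' Linear fold change is `(mean_in + epsilon) / (mean_out + epsilon)` on the
#' normalized values; `pct_in`/`pct_out` are the percentages of cells with a
#' detected (> 0) value inside and outside the group.
#'
#' @param expr `normalized_expression`.
#' @param ann annotation data.frame.
#' @param identity group label.
#' @param epsilon pseudocount guarding against division by zero.
#' @return data.frame with columns `gene`, `fc`, `log2fc`, `pct_in`, `pct_out`.
#' @export
compute_fc <- function(expr, ann, identity, epsilon = 1e-9) {
  labels <- align_identities(expr, ann)
  if (!identity %in% labels) {
    stop_stage("de_screen", "unknown identity group: ", identity)
  }
  in_group <- labels == identity
  mean_in <- rowMeans(expr$values[, in_group, drop = FALSE])
  mean_out <- rowMeans(expr$values[, !in_group, drop = FALSE])
  fc <- (mean_in + epsilon) / (mean_out + epsilon)
  data.frame(
    gene = expr$gene_ids,
    fc = fc,
    log2fc = log2(fc),
    pct_in = 100 * rowMeans(expr$values[, in_group, drop = FALSE] > 0),
    pct_out = 100 * rowMeans(expr$values[, !in_group, drop = FALSE] > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Upregulation call
#'
#' A gene is called upregulated in a group iff `q <= q_max` (inclusive) and
#' `log2fc > lfc_min` (strict).
#'
#' @param q q-value(s).
#' @param log2fc log2 fold change(s).
#' @param q_max q-value ceiling (default 0.05).
#' @param lfc_min log2 fold-change floor, exclusive (default 1).
#' @return logical vector.
#' @export
call_upregulated <- function(q, log2fc, q_max = 0.05, lfc_min = 1.0) {
  q <= q_max & log2fc > lfc_min
}

#' Full differential-upregulation screen across all identity groups
#'
#' Runs [rank_sum_upregulation()] and [compute_fc()] for every identity
#' group, applies [horizontal_bh()], and calls upregulated genes. The
#' rank-sum stage is vectorised: per-gene midranks over all cells are
#' computed once and reused across groups (normal-approximation regime;
#' datasets small enough for the exact branch go through
#' [rank_sum_upregulation()] per group).
#'
#' @param expr `normalized_expression` (already gene-filtered).
#' @param ann annotation data.frame (`cell_id`, `identity`).
#' @param q_max,lfc_min thresholds for [call_upregulated()].
#' @param epsilon pseudocount for [compute_fc()].
#' @param bh_family correction family for [horizontal_bh()].
#' @param exact_limit exact-enumeration size limit for the rank-sum test.
#' @return data.frame (one row per gene x identity) with columns `gene`,
#'   `identity`, `p_raw`, `q`, `fc`, `log2fc`, `pct_in`, `pct_out`,
#'   `upregulated`.
#' @export
de_screen <- function(expr, ann, q_max = 0.05, lfc_min = 1.0,
                      epsilon = 1e-9, bh_family = "per_gene",
                      exact_limit = 12L) {
  stopifnot(inherits(expr, "normalized_expression"))
  labels <- align_identities(expr, ann)
  identities <- unique(labels)
  if (length(identities) < 2L) {
    stop_stage("de_screen", "need at least two identity groups")
  }
  n_cells <- ncol(expr$values)
  n_genes <- nrow(expr$values)

  if (n_cells <= exact_limit) {
    pmat <- vapply(identities, function(id) {
      rank_sum_upregulation(expr, ann, id, exact_limit)
    }, numeric(n_genes))
  } else {
    # midranks per gene across all cells, computed once
    ranks <- t(apply(expr$values, 1L, rank))
    tie_sum <- apply(expr$values, 1L, function(v) {
      tt <- rle(sort(v))$lengths
      sum(tt^3 - tt)
    })
    ind <- vapply(identities, function(id) as.numeric(labels == id),
                  numeric(n_cells))
    w <- ranks %*% ind                       # genes x identities rank sums
    n1 <- colSums(ind)
    pmat <- matrix(NA_real_, n_genes, length(identities))
    for (j in seq_along(identities)) {
      mu <- n1[j] * (n_cells + 1) / 2
      sigma2 <- n1[j] * (n_cells - n1[j]) / 12 *
        ((n_cells + 1) - tie_sum / (n_cells * (n_cells - 1)))
      z <- (w[, j] - mu - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
      pj <- pnorm(z, lower.tail = FALSE)
      pj[sigma2 <= 0] <- 1
      pmat[, j] <- pmin(1, pmax(pj, .Machine$double.xmin))
    }
  }
  dimnames(pmat) <- list(expr$gene_ids, identities)
  qmat <- horizontal_bh(pmat, family = bh_family)

  res <- lapply(seq_along(identities), function(j) {
    fc <- compute_fc(expr, ann, identities[j], epsilon)
    data.frame(gene = expr$gene_ids,
               identity = identities[j],
               p_raw = pmat[, j],
               q = qmat[, j],
               fc = fc$fc, log2fc = fc$log2fc,
               pct_in = fc$pct_in, pct_out = fc$pct_out,
               upregulated = call_upregulated(qmat[, j], fc$log2fc,
                                              q_max, lfc_min),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "params") <- list(q_max = q_max, lfc_min = lfc_min,
                              epsilon = epsilon, bh_family = bh_family,
                              exact_limit = exact_limit)
  out
}
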