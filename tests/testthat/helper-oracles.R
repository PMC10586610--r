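# Independent oracles and fixture builders shared across the test files.
# Each oracle is a from-first-principles route that never touches the code
# path it checks.

# Upper-tail hypergeometric probability P[X >= a] by direct summation of
# binomial-coefficient ratios (X ~ Hypergeom(N, K = a+b, n = a+c)).
oracle_hyper_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  ks <- seq(from = a, to = min(K, n), length.out = max(0, min(K, n) - a + 1))
  if (length(ks) == 0) return(1)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Exact one-sided (first sample greater) rank-sum p by enumerating every
# group assignment and scoring it with the Mann-Whitney U statistic computed
# by pair counting (not via ranks).
oracle_rank_sum_greater <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  ustat <- function(ix) {
    a <- pooled[ix]
    b <- pooled[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  combos <- combn(n, n1)
  u_all <- apply(combos, 2L, ustat)
  mean(u_all >= u_obs - 1e-9)
}

# BH step-up by the textbook formula: q(i) = min_{j >= i} p(j) * m / j on the
# sorted p-values, mapped back to input order and clamped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Build a normalized_expression object directly from a plain matrix
# (for unit tests that exercise the screen without the normalization stage).
as_norm_expr <- function(values) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  structure(list(values = values,
                 gene_ids = rownames(values),
                 cell_ids = colnames(values),
                 scale_target = NA_real_,
                 log_base = "e"),
            class = "normalized_expression")
}

simple_annotation <- function(expr, labels) {
  data.frame(cell_id = expr$cell_ids, identity = labels,
             stringsAsFactors = FALSE)
}

# Write a MatrixMarket coordinate integer file plus side files.
write_mtx_fixture <- function(dir, nrow, ncol, triplets = NULL,
                              n_genes_file = nrow, n_cells_file = ncol) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  body <- if (is.null(triplets) || nrow(triplets) == 0) character(0) else
    apply(triplets, 1L, paste, collapse = " ")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow, ncol, length(body)), body), mtx)
  genes <- file.path(dir, "genes.tsv")
  writeLines(sprintf("ENSMUSG%07d\tGene%d", seq_len(n_genes_file),
                     seq_len(n_genes_file)), genes)
  barcodes <- file.path(dir, "barcodes.tsv")
  writeLines(sprintf("BC%04d-1", seq_len(n_cells_file)), barcodes)
  list(matrix = mtx, genes = genes, barcodes = barcodes)
}

# Integer molecule-count vector of length n with exact mean m (m given to
# two decimals, n a multiple of 100): floor(m) everywhere plus one extra
# molecule in just enough cells.
counts_with_mean <- function(m, n = 100L) {
  base <- floor(m)
  extra <- round((m - base) * n)
  v <- rep.int(base, n)
  if (extra > 0) v[seq_len(extra)] <- base + 1
  stopifnot(abs(mean(v) - m) < 1e-12)
  as.integer(v)
}

default_calibration <- function(channels = c("Gal", "Calcr", "Fos"),
                                single = 300, background = 50) {
  setNames(lapply(channels, function(ch)
    list(single_signal_mean_intensity = single, background = background)),
    channels)
}
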