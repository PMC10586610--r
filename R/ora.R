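#' Contingency table for gene-set over-representation in one identity group
#'
#' Splits the dataset gene universe (genes passing the detection filter) by
#' set membership and upregulation status. The gene set is first intersected
#' with the universe (case-insensitive symbol match); a set disjoint from the
#' dataset yields a degenerate table with a warning.
#'
#' @param upregulated_genes character vector of genes called upregulated in
#'   the group; must be a subset of `dataset_genes`.
#' @param dataset_genes character vector: the gene universe.
#' @param gene_set data.frame from [read_gene_set()] or character vector.
#' @return named integer vector `c(a, b, c, d)`: set & up, set & not up,
#'   non-set & up, non-set & not up.
#' @export
contingency <- function(upregulated_genes, dataset_genes, gene_set) {
  up <- unique(tolower(upregulated_genes))
  universe <- unique(tolower(dataset_genes))
  if (!all(up %in% universe)) {
    stop_stage("ig_ora", "upregulated gene(s) absent from dataset universe: ",
               paste(utils::head(setdiff(up, universe), 5L), collapse = ", "))
  }
  set_genes <- if (is.data.frame(gene_set)) gene_set$gene else gene_set
  set_in <- intersect(unique(tolower(set_genes)), universe)
  if (length(set_in) == 0L) {
    warning("gene set is disjoint from the dataset universe", call. = FALSE)
  }
  a <- length(intersect(set_in, up))
  b <- length(set_in) - a
  cc <- length(up) - a
  d <- length(universe) - length(set_in) - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher exact test for over-representation
#'
#' Upper-tail hypergeometric probability `P[X >= a]` with
#' `X ~ Hypergeom(N = a+b+c+d, K = a+b, n = a+c)`, i.e. the probability of
#' drawing at least `a` set genes among the upregulated genes when drawing
#' without replacement from the universe. The odds ratio is the sample odds
#' ratio `(a d)/(b c)` (`Inf` when `b c = 0` and `a d > 0`).
#'
#' @param a,b,c,d non-negative integers (see [contingency()]).
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop_stage("ig_ora", "negative contingency cell")
  if (any(cells != round(cells))) {
    stop_stage("ig_ora", "contingency cells must be integers")
  }
  p <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  p <- min(1, max(p, .Machine$double.xmin))
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Eligibility gate for over-representation testing
#'
#' An identity group enters the ORA only if at least `min_fraction` of the
#' dataset-intersected gene set is upregulated in it. The comparison is on
#' the exact real-valued product (e.g. with a 74-gene set at 5%, `a >= 3.7`,
#' so 4 upregulated set genes qualify and 3 do not).
#'
#' @param a number of set genes upregulated in the group.
#' @param set_size_in_dataset size of the set intersected with the universe.
#' @param min_fraction eligibility floor (default 0.05).
#' @return logical.
#' @export
eligibility <- function(a, set_size_in_dataset, min_fraction = 0.05) {
  if (set_size_in_dataset < 1L) {
    stop_stage("ig_ora", "set_size_in_dataset must be >= 1")
  }
  a >= min_fraction * set_size_in_dataset
}

#' Bonferroni correction
#'
#' @param p raw p-value(s) in (0, 1].
#' @param m_eligible family size (number of eligible identity groups).
#' @return `min(1, p * m_eligible)`.
#' @export
bonferroni <- function(p, m_eligible) {
  if (m_eligible < 1L) stop_stage("ig_ora", "m_eligible must be >= 1")
  pmin(1, p * m_eligible)
}

#' Mean fold-change contrast between set and non-set genes in one group
#'
#' Arithmetic mean of the linear fold changes over set genes versus over all
#' other filter-passing genes within the identity group (`genes = "all"`,
#' default), or restricted to upregulated genes (`genes = "upregulated"`).
#'
#' @param de DETable from [de_screen()].
#' @param identity group label.
#' @param gene_set data.frame or character vector.
#' @param genes which genes enter the means.
#' @return list with `mean_fc_set`, `mean_fc_rest`.
#' @export
mean_fc_contrast <- function(de, identity, gene_set,
                             genes = c("all", "upregulated")) {
  genes <- match.arg(genes)
  rows <- de[de$identity == identity, , drop = FALSE]
  if (nrow(rows) == 0L) stop_stage("ig_ora", "unknown identity: ", identity)
  if (genes == "upregulated") rows <- rows[rows$upregulated, , drop = FALSE]
  set_genes <- if (is.data.frame(gene_set)) gene_set$gene else gene_set
  in_set <- tolower(rows$gene) %in% tolower(set_genes)
  if (!any(in_set)) {
    stop_stage("ig_ora", "gene set has no genes in the DE table for ",
               identity)
  }
  list(mean_fc_set = mean(rows$fc[in_set]),
       mean_fc_rest = mean(rows$fc[!in_set]))
}

#' Eligibility-gated one-sided Fisher over-representation analysis
#'
#' For every identity group in a DETable: build the 2x2 table of gene-set
#' membership against upregulation over the filtered gene universe, run the
#' one-sided Fisher exact test, gate on the eligibility rule, and apply a
#' Bonferroni correction whose family is the set of *eligible* groups only
#' (ineligible groups keep their raw Fisher p but `p_bonferroni = NA`).
#'
#' @param de DETable from [de_screen()].
#' @param gene_set data.frame from [read_gene_set()] or character vector.
#' @param eligibility_fraction eligibility floor (default 0.05).
#' @param fc_genes passed to [mean_fc_contrast()] (`"all"` or
#'   `"upregulated"`).
#' @return data.frame, one row per identity group, columns `identity`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p_fisher`, `eligible`, `p_bonferroni`,
#'   `mean_fc_set`, `mean_fc_rest`.
#' @export
run_ora <- function(de, gene_set, eligibility_fraction = 0.05,
                    fc_genes = "all") {
  universe <- unique(de$gene)
  identities <- unique(de$identity)
  rows <- lapply(identities, function(id) {
    sub <- de[de$identity == id, , drop = FALSE]
    up <- sub$gene[sub$upregulated]
    tab <- contingency(up, universe, gene_set)
    fish <- fisher_one_sided(tab["a"], tab["b"], tab["c"], tab["d"])
    set_size <- tab["a"] + tab["b"]
    elig <- set_size >= 1L && eligibility(tab["a"], set_size,
                                          eligibility_fraction)
    mfc <- mean_fc_contrast(de, id, gene_set, genes = fc_genes)
    data.frame(identity = id,
               a = unname(tab["a"]), b = unname(tab["b"]),
               c = unname(tab["c"]), d = unname(tab["d"]),
               odds_ratio = fish$odds_ratio,
               p_fisher = fish$p,
               eligible = unname(elig),
               p_bonferroni = NA_real_,
               mean_fc_set = mfc$mean_fc_set,
               mean_fc_rest = mfc$mean_fc_rest,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(out$eligible)
  if (m > 0L) {
    out$p_bonferroni[out$eligible] <- bonferroni(out$p_fisher[out$eligible], m)
  }
  attr(out, "params") <- list(eligibility_fraction = eligibility_fraction,
                              fc_genes = fc_genes,
                              m_eligible = m,
                              universe_size = length(universe))
  out
}

#' Top over-represented identity groups
#'
#' Orders eligible groups by Fisher p (ascending), breaking ties by larger
#' `a`, then lexicographic identity name, so output order is deterministic.
#'
#' @param ora result of [run_ora()].
#' @return the eligible rows of `ora`, ranked.
#' @export
top_hits <- function(ora) {
  el <- ora[ora$eligible, , drop = FALSE]
  el[order(el$p_fisher, -el$a, el$identity), , drop = FALSE]
}
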