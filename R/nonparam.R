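#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Midranks throughout. When the combined sample size is at most
#' `exact_limit` the null distribution is enumerated over all group
#' assignments (valid under ties); otherwise a tie-corrected normal
#' approximation with 0.5 continuity correction is used. The two-sided exact
#' p is twice the smaller one-sided tail, clamped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_limit maximum combined n for exact enumeration (default 12).
#' @return list of class `igora_test`: `statistic` (U for x), `p`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_per_group`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop_stage("nonparam_stats", "both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2

  if (n <= exact_limit) {
    combos <- combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    pg <- mean(sums >= w - 1e-9)
    pl <- mean(sums <= w + 1e-9)
    p <- switch(alternative,
                greater = pg,
                less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
    method <- "exact"
  } else {
    ties <- table(r)
    tie_sum <- sum(ties^3 - ties)
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_sum / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sdv <- sqrt(sigma2)
      pg <- pnorm((w - mu - 0.5) / sdv, lower.tail = FALSE)
      pl <- pnorm((w - mu + 0.5) / sdv)
      p <- switch(alternative,
                  greater = pg,
                  less = pl,
                  two.sided = min(1, 2 * min(pg, pl)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u, p = min(1, max(p, .Machine$double.xmin)),
                 method = method, n_per_group = c(n1, n2),
                 alternative = alternative),
            class = "igora_test")
}

#' @exportS3Method base::print
print.igora_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s, n = %s, %s)\n",
              x$statistic, x$p, x$method,
              paste(x$n_per_group, collapse = "/"), x$alternative))
  invisible(x)
}

# Midrank bookkeeping shared by Kruskal-Wallis and Dunn.
pooled_ranks <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  ties <- table(r)
  list(r = r, idx = idx, sizes = sizes, n = n,
       tie_sum = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank test
#'
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)` with midranks,
#' divided by the tie-correction factor `1 - sum(t^3 - t) / (N^3 - N)`;
#' p from the chi-square distribution with k - 1 degrees of freedom. When
#' all observations are identical the statistic is 0 and p is 1.
#'
#' @param groups list of >= 2 non-empty numeric samples.
#' @return list of class `igora_test` with `statistic` (H), `df`, `p`,
#'   `method`, `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_stage("nonparam_stats", "need a list of >= 2 groups")
  }
  if (any(lengths(groups) == 0L)) {
    stop_stage("nonparam_stats", "all groups must be non-empty")
  }
  pr <- pooled_ranks(groups)
  n <- pr$n
  rank_sums <- tapply(pr$r, pr$idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / pr$sizes) - 3 * (n + 1)
  correction <- 1 - pr$tie_sum / (n^3 - n)
  if (correction <= 0) {        # every observation identical
    h <- 0
    p <- 1
  } else {
    h <- h / correction
    p <- pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(statistic = h, df = length(groups) - 1L,
                 p = min(1, max(p, .Machine$double.xmin)),
                 method = "chi-square approximation",
                 n_per_group = unname(pr$sizes)),
            class = "igora_test")
}

#' Dunn post-hoc pairwise comparisons
#'
#' For each pair of groups,
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - sum(t^3 - t) /
#' (12 (N - 1))) * (1 / n_i + 1 / n_j))` with midranks; two-sided normal
#' p-values, Bonferroni-corrected over all pairs performed.
#'
#' @param groups named (or unnamed) list of >= 2 non-empty numeric samples;
#'   a family of >= 3 groups is the intended use.
#' @param correction only `"bonferroni"` is implemented.
#' @return data.frame, one row per pair: `group_i`, `group_j`, `z`, `p_raw`,
#'   `p_corrected`, `n_i`, `n_j`.
#' @export
dunn_posthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  if (!is.list(groups) || length(groups) < 2L) {
    stop_stage("nonparam_stats", "need a list of >= 2 groups")
  }
  if (any(lengths(groups) == 0L)) {
    stop_stage("nonparam_stats", "all groups must be non-empty")
  }
  labels <- names(groups) %||% as.character(seq_along(groups))
  pr <- pooled_ranks(groups)
  n <- pr$n
  mean_ranks <- tapply(pr$r, pr$idx, mean)
  var_term <- n * (n + 1) / 12 - pr$tie_sum / (12 * (n - 1))
  pairs <- combn(length(groups), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(var_term * (1 / pr$sizes[i] + 1 / pr$sizes[j]))
    z <- if (se > 0) (mean_ranks[i] - mean_ranks[j]) / se else 0
    p_raw <- 2 * pnorm(-abs(z))
    data.frame(group_i = labels[i], group_j = labels[j],
               z = unname(z), p_raw = unname(p_raw),
               p_corrected = unname(min(1, p_raw * n_pairs)),
               n_i = unname(pr$sizes[i]), n_j = unname(pr$sizes[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric comparison report
#'
#' Runs a Kruskal-Wallis test over the groups and, when there are three or
#' more, Dunn post-hoc pairwise tests; with exactly two groups a two-sided
#' Mann-Whitney test is reported instead. Returns a tidy table suitable for
#' [write_table()].
#'
#' @param groups named list of numeric samples.
#' @param label comparison label recorded in the output.
#' @return data.frame with columns `comparison`, `groups`, `n`, `statistic`,
#'   `p_raw`, `p_corrected`, `method`.
#' @export
compare_groups <- function(groups, label = "comparison") {
  if (length(groups) == 2L) {
    mw <- mann_whitney(groups[[1L]], groups[[2L]], "two.sided")
    return(data.frame(comparison = label,
                      groups = paste(names(groups), collapse = " vs "),
                      n = paste(mw$n_per_group, collapse = "/"),
                      statistic = mw$statistic, p_raw = mw$p,
                      p_corrected = mw$p, method = mw$method,
                      stringsAsFactors = FALSE))
  }
  kw <- kruskal_wallis(groups)
  omnibus <- data.frame(comparison = label,
                        groups = paste(names(groups), collapse = ", "),
                        n = paste(kw$n_per_group, collapse = "/"),
                        statistic = kw$statistic, p_raw = kw$p,
                        p_corrected = kw$p, method = "kruskal_wallis",
                        stringsAsFactors = FALSE)
  dunn <- dunn_posthoc(groups)
  posthoc <- data.frame(comparison = label,
                        groups = paste(dunn$group_i, "vs", dunn$group_j),
                        n = paste(dunn$n_i, dunn$n_j, sep = "/"),
                        statistic = dunn$z, p_raw = dunn$p_raw,
                        p_corrected = dunn$p_corrected,
                        method = "dunn_bonferroni",
                        stringsAsFactors = FALSE)
  rbind(omnibus, posthoc)
}
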