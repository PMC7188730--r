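#' Two-sided Wilcoxon rank-sum test
#'
#' Policy wrapper around [stats::wilcox.test()]: exact enumeration of the
#' rank-sum distribution when the combined sample size is at most 20 and the
#' pooled data are untied; otherwise the normal approximation with tie and
#' continuity correction. `mode` overrides the automatic choice.
#'
#' @param a,b nonempty numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"approximate"`.
#' @param labels length-2 character, group names for reporting.
#' @param alpha significance level for the reported flag (default 0.05).
#' @return object of class `group_comparison`: list with `labels`, `n`,
#'   `medians`, `statistic` (rank-sum W), `p_value`, `significant`, `method`.
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "approximate"),
                          labels = c("a", "b"), alpha = 0.05) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("rank_sum_test: both samples must be nonempty", call. = FALSE)
  if (any(!is.finite(c(a, b))))
    stop("rank_sum_test: samples must be finite", call. = FALSE)
  tied <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    approximate = FALSE,
    auto = (length(a) + length(b)) <= 20L && !tied)
  if (use_exact && tied) {
    warning("rank_sum_test: ties present, falling back to the corrected ",
            "normal approximation", call. = FALSE)
    use_exact <- FALSE
  }
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = use_exact, correct = TRUE)
  p <- min(wt$p.value, 1)
  # fully tied pooled data: zero rank variance makes the z statistic 0/0,
  # but every rank assignment is equivalent, so the two-sided p is 1
  if (!is.finite(p)) p <- 1
  structure(list(labels = labels,
                 n = c(length(a), length(b)),
                 medians = c(stats::median(a), stats::median(b)),
                 statistic = unname(wt$statistic),
                 p_value = p,
                 significant = p < alpha,
                 method = if (use_exact) "exact" else "normal_approx"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "rank-sum (%s): %s (n=%d, median %.4g) vs %s (n=%d, median %.4g), p = %.4g%s\n",
    x$method, x$labels[1], x$n[1], x$medians[1],
    x$labels[2], x$n[2], x$medians[2], x$p_value,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Spearman rank correlation with midrank ties
#'
#' rho is the Pearson correlation of midranks. The two-sided p-value comes
#' from exact permutation enumeration for n < 10 and from the large-sample
#' t approximation (`t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df) otherwise.
#' Zero rank variance in either variable leaves rho undefined (`NA`).
#'
#' @param x,y numeric vectors, equal length n >= 3, finite.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("spearman_cor: lengths differ", call. = FALSE)
  if (n < 3L) stop("spearman_cor: need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spearman_cor: values must be finite", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  rho <- stats::cor(rx, ry)
  if (n < 10L) {
    p <- spearman_perm_p(rx, ry)
    method <- "exact_permutation"
  } else {
    r <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approx"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# Exact two-sided permutation p for Spearman rho at small n: enumerate all n!
# permutations of one rank vector. rho is monotone in sum(rx * ry_perm) only
# for untied ranks, so the correlation itself is recomputed per permutation
# (midranks kept fixed; permuting pairs off y).
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  perms <- all_permutations(n)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  stat <- abs(as.vector((matrix(ryc[perms], nrow = nrow(perms)) %*% rxc)) / denom)
  obs <- abs(sum(rxc * ryc) / denom)
  mean(stat >= obs - 1e-12)
}

# All permutations of 1..n as a (n! x n) integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, setdiff(seq_len(n), pos)] <- sub
  }
  out
}
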