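## Statistical toolkit for sweep output: Tukey-Kramer comparisons against a
## baseline and the high-persistence sub-group analysis.

#' Tukey-Kramer pairwise comparisons against a baseline group
#'
#' Compares every group's mean to a designated baseline group using the
#' studentized-range criterion with the Tukey-Kramer adjustment for unequal
#' group sizes: the difference between group `i` and the baseline `b` is
#' significant when
#' \deqn{|\bar y_i - \bar y_b| > q_{\alpha,k,N-k}
#'   \sqrt{\tfrac{MSE}{2}\left(\tfrac 1{n_i} + \tfrac 1{n_b}\right)}}
#' where `MSE` is the pooled within-group variance and `k` the number of
#' groups. Used to decide whether a parameter perturbation changed mean
#' chain persistence relative to an unperturbed baseline.
#'
#' @param groups Named list of numeric vectors (one per group), e.g. the
#'   `runs$persistence` columns of several [run_replicates()] results. Every
#'   group needs at least two observations, and the observations must not
#'   be globally constant (the pooled variance would be zero).
#' @param baseline Name or index of the baseline group.
#' @param alpha Significance level (default 0.05, i.e. 95 per cent).
#' @return Data frame with one row per non-baseline group: `group`, `n`,
#'   `mean`, `diff` (group minus baseline), `se`, `q` (studentized-range
#'   statistic), `p_value`, `significant`.
#' @examples
#' set.seed(1)
#' g <- list(base = rnorm(50, 5), same = rnorm(50, 5), far = rnorm(50, 50))
#' tukey_kramer(g, baseline = "base")
#' @export
tukey_kramer <- function(groups, baseline = 1, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups")
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least two observations")
  b <- if (is.character(baseline)) match(baseline, names(groups)) else as.integer(baseline)
  if (is.na(b) || b < 1 || b > length(groups)) stop("unknown baseline group")

  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  mse <- sum((sizes - 1) * vars) / (N - k)
  if (mse <= 0) stop("degenerate groups: pooled within-group variance is zero")
  df <- N - k
  qcrit <- stats::qtukey(1 - alpha, k, df)

  others <- setdiff(seq_len(k), b)
  se <- sqrt(mse / 2 * (1 / sizes[others] + 1 / sizes[b]))
  diff <- means[others] - means[b]
  q <- abs(diff) / se
  data.frame(
    group = names(groups)[others],
    n = as.integer(sizes[others]),
    mean = means[others],
    diff = diff,
    se = se,
    q = q,
    p_value = stats::ptukey(q, k, df, lower.tail = FALSE),
    significant = q > qcrit,
    row.names = NULL
  )
}

#' High-persistence sub-group analysis of a parameter sweep
#'
#' Splits the swept parameter sets at a mean-persistence threshold (20 time
#' steps by default) and characterizes the high-persistence sub-group: for
#' every parameter, its mean and s.e.m. in both groups with a Welch
#' two-sample p-value; its value-frequency table within the high group; and
#' the Pearson product-moment correlation (with the p-value for the null
#' r = 0) between every pair of parameters within the high group. Logical
#' parameters (SID/SIP) are coded 0/1.
#'
#' @param summaries Per-set sweep summaries: the data frame returned by
#'   [run_sweep()], or a bare numeric vector of mean persistences aligned
#'   with `sets`.
#' @param sets The parameter-set data frame that produced `summaries`.
#' @param threshold Mean persistence (time steps) defining the
#'   high-persistence sub-group (`mean >= threshold`).
#' @return A `subgroup_report`: list with `threshold`, `n_high`, `n_low`,
#'   `empty_high`, `parameters` (per-parameter two-group table),
#'   `frequencies` (named list of tables over the high group), and
#'   `correlation` / `correlation_p` (matrices over the high group; `NULL`
#'   when the high group has fewer than 3 sets).
#' @export
subgroup_analysis <- function(summaries, sets, threshold = 20) {
  mean_per <- if (is.numeric(summaries)) summaries else summaries$mean_persistence
  if (length(mean_per) != nrow(sets)) {
    stop("summaries and parameter sets are not aligned")
  }
  vals <- as.data.frame(lapply(sets, function(col) {
    if (is.logical(col)) as.numeric(col) else as.numeric(col)
  }))
  high <- mean_per >= threshold
  n_high <- sum(high)
  n_low <- sum(!high)

  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  params <- data.frame(
    parameter = names(vals),
    mean_high = NA_real_, sem_high = NA_real_,
    mean_low = NA_real_, sem_low = NA_real_,
    p_value = NA_real_,
    row.names = NULL
  )
  for (j in seq_along(vals)) {
    hv <- vals[high, j]
    lv <- vals[!high, j]
    params$mean_high[j] <- if (n_high) mean(hv) else NA_real_
    params$sem_high[j] <- if (n_high) sem(hv) else NA_real_
    params$mean_low[j] <- if (n_low) mean(lv) else NA_real_
    params$sem_low[j] <- if (n_low) sem(lv) else NA_real_
    if (n_high > 1 && n_low > 1 &&
        (stats::sd(hv) > 0 || stats::sd(lv) > 0)) {
      params$p_value[j] <- stats::t.test(hv, lv)$p.value
    }
  }

  frequencies <- if (n_high) {
    lapply(stats::setNames(names(vals), names(vals)), function(nm) {
      table(vals[high, nm])
    })
  } else {
    NULL
  }

  correlation <- correlation_p <- NULL
  if (n_high >= 3) {
    p <- ncol(vals)
    correlation <- diag(1, p)
    correlation_p <- matrix(NA_real_, p, p)
    dimnames(correlation) <- dimnames(correlation_p) <- list(names(vals), names(vals))
    for (i in seq_len(p - 1)) {
      for (j in seq.int(i + 1, p)) {
        xi <- vals[high, i]
        xj <- vals[high, j]
        if (stats::sd(xi) > 0 && stats::sd(xj) > 0) {
          ct <- stats::cor.test(xi, xj, method = "pearson")
          correlation[i, j] <- correlation[j, i] <- unname(ct$estimate)
          correlation_p[i, j] <- correlation_p[j, i] <- ct$p.value
        }
      }
    }
  }

  structure(
    list(
      threshold = threshold,
      n_high = n_high,
      n_low = n_low,
      empty_high = n_high == 0,
      parameters = params,
      frequencies = frequencies,
      correlation = correlation,
      correlation_p = correlation_p
    ),
    class = "subgroup_report"
  )
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf(
    "<subgroup_report> %d of %d parameter sets reach mean persistence >= %s (%.2f%%)\n",
    x$n_high, x$n_high + x$n_low, format(x$threshold),
    100 * x$n_high / (x$n_high + x$n_low)
  ))
  if (x$empty_high) {
    cat("  high-persistence sub-group is empty\n")
  } else {
    print(x$parameters, digits = 3)
  }
  invisible(x)
}
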