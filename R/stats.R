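check_measurement_table <- function(table, value, group) {
  table <- as_tibble(table)
  v <- eval_tidy(value, table)
  g <- eval_tidy(group, table)
  if (is.null(v) || is.null(g)) {
    eq_abort("measurement table needs the value and group columns.",
             "eq_stats_error")
  }
  if (any(!is.finite(v))) {
    eq_abort("measurement values must be finite.", "eq_stats_error")
  }
  list(value = v, group = as.character(g))
}

#' Per-group Shapiro-Wilk normality screen
#'
#' Normality is screened per group before committing to the nonparametric
#' tests; groups with fewer than 3 observations, or with all observations
#' equal, are reported as not testable rather than dropped.
#'
#' @param table Data frame of per-embryo measurements.
#' @param value,group Columns holding the measurement and the group label
#'   (tidy-eval; defaults `relative_activity` and `group`).
#' @return A tibble with `group`, `n`, `statistic`, `p_value`, `testable`,
#'   `note`.
#' @export
normality_screen <- function(table, value = relative_activity, group = group) {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  split(d$value, d$group) %>%
    imap(function(v, g) {
      if (length(v) < 3) {
        tibble(group = g, n = length(v), statistic = NA_real_,
               p_value = NA_real_, testable = FALSE, note = "n < 3")
      } else if (length(unique(v)) == 1) {
        tibble(group = g, n = length(v), statistic = NA_real_,
               p_value = NA_real_, testable = FALSE, note = "degenerate (all values equal)")
      } else {
        sw <- shapiro.test(v)
        tibble(group = g, n = length(v), statistic = unname(sw$statistic),
               p_value = sw$p.value, testable = TRUE, note = NA_character_)
      }
    }) %>%
    bind_rows()
}

#' Interquartile-range outlier flags
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]` (k = 1.5 by
#' default; quartiles by linear interpolation, quantile type 7). Flagged
#' values are never removed — downstream tests keep them — the flags are
#' bookkeeping only.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Logical vector of flags; all `NA` (with a warning) when
#'   `length(values) < 4`, where the rule is not applicable.
#' @export
iqr_outlier_flags <- function(values, k = 1.5, type = 7) {
  if (length(values) < 4) {
    warn("IQR outlier rule not applicable for n < 4; returning NA flags.")
    return(rep(NA, length(values)))
  }
  q <- quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Flag outliers per group in a measurement table
#'
#' @inheritParams normality_screen
#' @param k Fence multiplier of [iqr_outlier_flags()].
#' @return The table with a logical `.outlier` column added.
#' @export
flag_outliers <- function(table, value = relative_activity, group = group,
                          k = 1.5) {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  out <- as_tibble(table)
  flags <- logical(length(d$value))
  for (g in unique(d$group)) {
    i <- which(d$group == g)
    flags[i] <- if (length(i) < 4) {
      NA
    } else {
      iqr_outlier_flags(d$value[i], k = k)
    }
  }
  out$.outlier <- flags
  out
}

new_group_comparison <- function(test_name, statistic, df, p_value, method,
                                 pairwise = NULL, group_n = NULL,
                                 degenerate = FALSE, scheme = "methods") {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, method = method, pairwise = pairwise,
         group_n = group_n, degenerate = degenerate,
         stars = star_annotation(p_value, scheme = scheme), scheme = scheme),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (%s)%s\n",
              x$test_name, x$statistic, x$p_value, x$stars,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$pairwise)) {
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    return(x$pairwise)
  }
  tibble(test = x$test_name, statistic = x$statistic, df = x$df,
         p_value = x$p_value, stars = x$stars)
}

#' @rdname kruskal_wallis
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test = x$test_name, statistic = x$statistic, df = x$df,
         p_value = x$p_value, method = x$method,
         n_groups = if (is.null(x$group_n)) NA_integer_ else nrow(x$group_n),
         n_total = if (is.null(x$group_n)) NA_integer_ else sum(x$group_n$n))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared approximation on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). A table in
#' which every observation is identical is degenerate: H is 0 and p is 1,
#' with the `degenerate` flag set. Use [dunn_bonferroni()] for the post
#' hoc pairwise comparisons and [mann_whitney()] when only two groups are
#' compared.
#'
#' @inheritParams normality_screen
#' @param scheme Star scheme, see [star_annotation()].
#' @return A `group_comparison` object; [tidy()] and [glance()] methods
#'   return tibbles.
#' @export
kruskal_wallis <- function(table, value = relative_activity, group = group,
                           scheme = "methods") {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  groups <- unique(d$group)
  if (length(groups) < 3) {
    eq_abort("Kruskal-Wallis needs >= 3 groups; use mann_whitney() for two.",
             "eq_stats_error")
  }
  group_n <- tibble(group = groups,
                    n = vapply(groups, function(g) sum(d$group == g), integer(1)))
  if (length(unique(d$value)) == 1) {
    return(new_group_comparison("Kruskal-Wallis", 0, length(groups) - 1, 1,
                                "chi-squared approximation", group_n = group_n,
                                degenerate = TRUE, scheme = scheme))
  }
  kt <- kruskal.test(d$value, factor(d$group))
  new_group_comparison("Kruskal-Wallis", unname(kt$statistic),
                       unname(kt$parameter), kt$p.value,
                       "chi-squared approximation", group_n = group_n,
                       scheme = scheme)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Rank-based pairwise z comparisons following a Kruskal-Wallis test, with
#' the usual tie correction; raw two-sided p-values are multiplied by the
#' number of comparisons performed (Bonferroni) and clamped at 1. The
#' family size is the number of comparisons actually made, so restricting
#' `comparisons` to the pairs a figure annotates changes the correction
#' accordingly.
#'
#' @inheritParams kruskal_wallis
#' @param comparisons `"all"` for all pairs, or a two-column data frame of
#'   group pairs.
#' @return A tibble with `group1`, `group2`, `z`, `p_raw`, `p_adj`,
#'   `stars`.
#' @export
dunn_bonferroni <- function(table, value = relative_activity, group = group,
                            comparisons = "all", scheme = "methods") {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  groups <- unique(d$group)
  if (length(groups) < 2) {
    eq_abort("every compared group needs n >= 1.", "eq_stats_error")
  }
  r <- rank(d$value)
  N <- length(r)
  mean_ranks <- vapply(groups, function(g) mean(r[d$group == g]), numeric(1))
  ns <- vapply(groups, function(g) sum(d$group == g), numeric(1))
  ties <- base::table(d$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term

  if (identical(comparisons, "all")) {
    pairs <- t(combn(groups, 2))
  } else {
    pairs <- as.matrix(as.data.frame(comparisons)[, 1:2])
    if (!all(pairs %in% groups)) {
      eq_abort("`comparisons` mentions unknown groups.", "eq_stats_error")
    }
  }
  m <- nrow(pairs)
  res <- map(seq_len(m), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    se <- sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- if (se == 0) 0 else (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble(group1 = g1, group2 = g2, z = z, p_raw = p_raw,
           p_adj = min(1, m * p_raw))
  }) %>% bind_rows()
  res$stars <- star_annotation(res$p_adj, scheme = scheme)
  res
}

# U statistic of the first group from pooled ranks
u_statistic <- function(ranks, n1) {
  sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

mw_exact_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- u_statistic(r, n1)
  idx <- combn(n1 + n2, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  lo <- min(u_obs, n1 * n2 - u_obs)
  hi <- max(u_obs, n1 * n2 - u_obs)
  min(1, (sum(us <= lo) + sum(us >= hi)) / length(us))
}

mw_approx_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y))
  u <- u_statistic(r, n1)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  vu <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (vu == 0) {
    return(list(u = u, p = 1))
  }
  z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(vu)
  list(u = u, p = min(1, 2 * pnorm(-abs(z))))
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided rank-sum comparison. For small samples
#' (`max(n1, n2) <= exact_max`) the p-value is computed by full
#' enumeration of all group reassignments of the pooled observations,
#' which handles ties exactly; larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric observation vectors of the two groups.
#' @param exact `TRUE`/`FALSE` to force a branch; default chooses
#'   enumeration when `max(n1, n2) <= exact_max`.
#' @param exact_max Size cutoff for the enumeration branch (default 8).
#' @param scheme Star scheme, see [star_annotation()].
#' @return A `group_comparison` object with the U statistic of the first
#'   group.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # exact two-sided 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_max = 8, scheme = "methods") {
  if (length(x) == 0 || length(y) == 0) {
    eq_abort("both groups need at least one observation.", "eq_stats_error")
  }
  exact <- exact %||% (max(length(x), length(y)) <= exact_max)
  r <- rank(c(x, y))
  u <- u_statistic(r, length(x))
  if (exact) {
    p <- mw_exact_p(x, y)
    method <- "exact enumeration"
  } else {
    p <- mw_approx_p(x, y)$p
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  new_group_comparison(
    "Mann-Whitney U", u, NA_real_, p, method,
    group_n = tibble(group = c("x", "y"), n = c(length(x), length(y))),
    scheme = scheme
  )
}

#' Compare groups of a measurement table
#'
#' Routes to the appropriate test: [mann_whitney()] for exactly two
#' groups, otherwise [kruskal_wallis()] followed by [dunn_bonferroni()]
#' (whose pairwise table is attached to the result).
#'
#' @inheritParams kruskal_wallis
#' @param comparisons Passed to [dunn_bonferroni()] when applicable.
#' @return A `group_comparison` object.
#' @export
compare_groups <- function(table, value = relative_activity, group = group,
                           comparisons = "all", scheme = "methods") {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  tab <- tibble(relative_activity = d$value, group = d$group)
  if (length(unique(d$group)) == 2) {
    gs <- unique(d$group)
    return(mann_whitney(d$value[d$group == gs[1]], d$value[d$group == gs[2]],
                        scheme = scheme))
  }
  res <- kruskal_wallis(tab, scheme = scheme)
  res$pairwise <- dunn_bonferroni(tab, comparisons = comparisons,
                                  scheme = scheme)
  res
}

#' Significance star annotation
#'
#' Maps p-values to star labels. The default `"methods"` scheme uses the
#' strict thresholds `* p < 0.05`, `** p < 0.005`, `*** p < 0.0005`,
#' `**** p < 0.0001`; the `"figure"` preset uses the more common
#' `0.05 / 0.01 / 0.001 / 0.0001` ladder seen in figure legends. `p`
#' equal to a threshold maps to the weaker label (strict inequality), and
#' `p >= 0.05` is `"ns"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param scheme `"methods"` (default) or `"figure"`, or a decreasing
#'   numeric vector of four thresholds for `*` to `****`.
#' @return Character vector of `ns`/`*`/`**`/`***`/`****`.
#' @examples
#' star_annotation(c(0.017, 0.0004, 0.05))
#' @export
star_annotation <- function(p, scheme = "methods") {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    eq_abort("p-values must lie in [0, 1].", "eq_stats_error")
  }
  thr <- if (is.numeric(scheme)) {
    sort(scheme, decreasing = TRUE)
  } else {
    switch(scheme,
           methods = c(0.05, 0.005, 0.0005, 0.0001),
           figure = c(0.05, 0.01, 0.001, 0.0001),
           eq_abort("unknown star scheme.", "eq_stats_error"))
  }
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- "ns"
  out[ok & p < thr[1]] <- "*"
  out[ok & p < thr[2]] <- "**"
  out[ok & p < thr[3]] <- "***"
  out[ok & p < thr[4]] <- "****"
  out
}
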