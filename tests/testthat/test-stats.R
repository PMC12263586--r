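test_that("normality screen reports per-group Shapiro-Wilk and flags degenerate groups", {
  tab <- tibble::tibble(
    group = rep(c("a", "b", "c"), times = c(5, 5, 2)),
    relative_activity = c(rnorm(5), rep(1, 5), 1:2)
  )
  scr <- normality_screen(tab)
  expect_equal(nrow(scr), 3)
  expect_true(scr$testable[scr$group == "a"])
  expect_false(scr$testable[scr$group == "b"]) # all equal
  expect_false(scr$testable[scr$group == "c"]) # n < 3
  sw <- shapiro.test(tab$relative_activity[tab$group == "a"])
  expect_equal(scr$p_value[scr$group == "a"], sw$p.value)
})

test_that("normality screen calibrates: normal samples pass, skewed samples fail", {
  set.seed(5)
  p_norm <- vapply(1:30, function(i) {
    shp <- normality_screen(tibble::tibble(
      group = "g", relative_activity = rnorm(300)))
    shp$p_value
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_skew <- vapply(1:30, function(i) {
    shp <- normality_screen(tibble::tibble(
      group = "g", relative_activity = rexp(300)))
    shp$p_value
  }, numeric(1))
  expect_gte(mean(p_skew < 0.05), 0.9)
})

test_that("IQR outlier flags follow the fence rule without dropping values", {
  flags <- iqr_outlier_flags(c(1, 2, 3, 100))
  expect_equal(flags, c(FALSE, FALSE, FALSE, TRUE))
  # hand check: type-7 quartiles of (1,2,3,100)
  q <- quantile(c(1, 2, 3, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(100 > q[2] + 1.5 * diff(q))
  expect_equal(iqr_outlier_flags(rep(7, 6)), rep(FALSE, 6))
  v <- c(3, 5, 8, 13, 50)
  expect_equal(iqr_outlier_flags(v), iqr_outlier_flags(v + 1000))
  expect_warning(f <- iqr_outlier_flags(1:3), "n < 4")
  expect_true(all(is.na(f)))
  tabbed <- flag_outliers(tibble::tibble(
    group = rep("g", 4), relative_activity = c(1, 2, 3, 100)))
  expect_equal(tabbed$.outlier, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  tab <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 3),
    relative_activity = c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  )
  res <- kruskal_wallis(tab)
  # no ties: H = 12/(N(N+1)) * sum(R_g^2 / n_g) - 3(N+1)
  H <- 12 / (9 * 10) * (6^2 / 3 + 15^2 / 3 + 24^2 / 3) - 3 * 10
  expect_equal(res$statistic, H)
  expect_equal(res$df, 2)
  expect_lt(res$p_value, 0.05)

  # label permutation leaves H unchanged
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(kruskal_wallis(perm)$statistic, H)

  degen <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                          relative_activity = rep(1, 9))
  dres <- kruskal_wallis(degen)
  expect_equal(dres$statistic, 0)
  expect_equal(dres$p_value, 1)
  expect_true(dres$degenerate)
  expect_error(kruskal_wallis(tab[tab$group != "c", ]), "mann_whitney")
})

test_that("rank tests are invariant under strictly monotone transformations", {
  set.seed(11)
  tab <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 8),
    relative_activity = c(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  )
  res1 <- kruskal_wallis(tab)
  tab2 <- dplyr::mutate(tab, relative_activity = exp(relative_activity))
  res2 <- kruskal_wallis(tab2)
  expect_equal(res1$statistic, res2$statistic)
  expect_equal(res1$p_value, res2$p_value)

  x <- rnorm(10); y <- rnorm(10, 0.5)
  expect_equal(mann_whitney(x, y)$p_value,
               mann_whitney(exp(x), exp(y))$p_value)
})

test_that("Dunn-Bonferroni corrects by the number of comparisons and clamps at 1", {
  # with n = 10 per group, complete separation drives every pair below 0.05
  # (rank statistics bound the adjacent-pair z at smaller n)
  tab <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 10),
    relative_activity = c(1:10, 101:110, 201:210)
  )
  pw <- dunn_bonferroni(tab)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, pmin(1, 3 * pw$p_raw))
  expect_true(all(pw$p_adj < 0.05))
  expect_true(all(pw$p_adj >= pw$p_raw))

  # z for a pair recomputed from the rank formula (no ties)
  r <- rank(tab$relative_activity)
  mr <- tapply(r, tab$group, mean)
  sigma2 <- 30 * 31 / 12
  z_ab <- (mr[["a"]] - mr[["b"]]) / sqrt(sigma2 * (1 / 10 + 1 / 10))
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"], unname(z_ab))

  # identical groups inside a 3-group table: corrected p clamps to 1
  tab2 <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 5),
    relative_activity = c(1:5, 1:5, 201:205)
  )
  pw2 <- dunn_bonferroni(tab2)
  expect_equal(pw2$p_adj[pw2$group1 == "a" & pw2$group2 == "b"], 1)

  # restricting the comparisons shrinks the family
  pw3 <- dunn_bonferroni(tab, comparisons = data.frame(g1 = "a", g2 = "c"))
  expect_equal(nrow(pw3), 1)
  expect_equal(pw3$p_adj, pmin(1, pw3$p_raw))
})

test_that("exact Mann-Whitney matches enumeration and handles complete ties", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)

  tie <- mann_whitney(5, 5)
  expect_equal(tie$statistic, 0.5)
  expect_equal(tie$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), class = "eq_stats_error")
})

test_that("exact Mann-Whitney agrees with wilcox.test enumeration for n <= 6", {
  set.seed(29)
  for (i in 1:30) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, 0.8)
    ours <- mann_whitney(x, y, exact = TRUE)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("exact and approximate Mann-Whitney branches agree closely at n = 9", {
  set.seed(33)
  diffs <- vapply(1:50, function(i) {
    x <- rnorm(9)
    y <- rnorm(9, runif(1, 0, 1))
    abs(mann_whitney(x, y, exact = TRUE)$p_value -
          mann_whitney(x, y, exact = FALSE)$p_value)
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("type-I error of both tests is calibrated at the 5% level", {
  set.seed(101)
  n_sim <- 1000
  kw_rej <- mw_rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    tab <- tibble::tibble(group = rep(c("a", "b", "c"), each = 10),
                          relative_activity = rnorm(30))
    kw_rej[i] <- kruskal_wallis(tab)$p_value < 0.05
    mw_rej[i] <- mann_whitney(rnorm(10), rnorm(10), exact = FALSE)$p_value < 0.05
  }
  expect_gte(mean(kw_rej), 0.03); expect_lte(mean(kw_rej), 0.07)
  expect_gte(mean(mw_rej), 0.03); expect_lte(mean(mw_rej), 0.07)
})

test_that("star annotation reproduces the reporting thresholds exactly", {
  expect_equal(star_annotation(0.017), "*")
  expect_equal(star_annotation(0.0004), "***")
  expect_equal(star_annotation(0.05), "ns") # strict inequality at the boundary
  expect_equal(star_annotation(c(0.2, 0.049, 0.004, 0.0004, 5e-5)),
               c("ns", "*", "**", "***", "****"))
  # figure-legend preset: ** at p < 0.01
  expect_equal(star_annotation(0.008, scheme = "figure"), "**")
  expect_equal(star_annotation(0.008, scheme = "methods"), "*")
  expect_error(star_annotation(1.2), class = "eq_stats_error")
})

test_that("two-group tables route to Mann-Whitney and tidy/glance are well-formed", {
  tab <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                        relative_activity = c(1:5, 6:10))
  res <- compare_groups(tab)
  expect_equal(res$test_name, "Mann-Whitney U")
  g <- glance(res)
  expect_equal(g$n_total, 10)
  tab3 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 5),
                         relative_activity = c(1:5, 11:15, 21:25))
  res3 <- compare_groups(tab3)
  expect_equal(res3$test_name, "Kruskal-Wallis")
  td <- tidy(res3)
  expect_true(all(c("group1", "group2", "p_adj", "stars") %in% names(td)))
  expect_true(all(td$p_adj >= td$p_raw))
})

test_that("swarm report writes the figure and a summary with correct medians", {
  set.seed(2)
  tab <- tibble::tibble(group = rep(c("WT", "mut"), each = 12),
                        relative_activity = c(rnorm(12, 0.8, 0.1),
                                              rnorm(12, 0.3, 0.1)))
  prefix <- file.path(tempdir(), "swarmtest")
  res <- compare_groups(tab)
  out <- swarm_report(tab, comparison = NULL, path_prefix = prefix)
  expect_true(file.exists(paste0(prefix, "_swarm.png")))
  expect_true(file.exists(paste0(prefix, "_summary.csv")))
  expect_equal(out$summary$n, c(12, 12))
  for (g in c("WT", "mut")) {
    expect_equal(out$summary$median[out$summary$group == g],
                 median(tab$relative_activity[tab$group == g]))
  }
})
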