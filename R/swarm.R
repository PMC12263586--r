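# deterministic "beeswarm-lite" offsets: points are binned along the value
# axis and spread symmetrically within each bin, densest bin at full width
swarm_offsets <- function(v, width = 0.35, nbins = 25) {
  if (length(v) == 1) {
    return(0)
  }
  bins <- cut(rank(v, ties.method = "first"),
              breaks = min(nbins, length(v)), labels = FALSE)
  off <- numeric(length(v))
  maxcount <- max(tabulate(bins))
  for (b in unique(bins)) {
    i <- which(bins == b)
    k <- length(i)
    pos <- (seq_len(k) - (k + 1) / 2)
    off[i[order(v[i])]] <- pos / max(maxcount - 1, 1) * 2 * width
  }
  off
}

#' Swarm plot of per-embryo activity with medians and significance stars
#'
#' Each point is one embryo's relative activity; the red bar marks the
#' group median and group sizes are printed in the axis labels. When a
#' comparison result with pairwise p-values is supplied, significant pairs
#' are annotated with star brackets.
#'
#' @inheritParams normality_screen
#' @param comparison Optional `group_comparison` (e.g. from
#'   [compare_groups()]) whose pairwise stars are drawn.
#' @param group_order Optional character vector fixing the group order.
#' @return A ggplot object.
#' @export
plot_activity_swarm <- function(table, comparison = NULL,
                                value = relative_activity, group = group,
                                group_order = NULL) {
  d <- check_measurement_table(table, enquo(value), enquo(group))
  groups <- group_order %||% unique(d$group)
  df <- tibble(value = d$value, group = factor(d$group, levels = groups))
  df <- df %>%
    group_by(.data$group) %>%
    mutate(xoff = swarm_offsets(.data$value)) %>%
    ungroup() %>%
    mutate(x = as.numeric(.data$group) + .data$xoff)

  med <- df %>%
    group_by(.data$group) %>%
    summarise(median = median(.data$value), n = dplyr::n(), .groups = "drop") %>%
    mutate(gx = as.numeric(.data$group))
  labels <- sprintf("%s\nN=%d", med$group, med$n)

  p <- ggplot(df, aes(x = .data$x, y = .data$value)) +
    geom_point(size = 1.6, alpha = 0.8) +
    geom_segment(data = med,
                 aes(x = .data$gx - 0.3, xend = .data$gx + 0.3,
                     y = .data$median, yend = .data$median),
                 colour = "red", linewidth = 1) +
    ggplot2::scale_x_continuous(breaks = med$gx, labels = labels) +
    labs(x = NULL, y = "relative activity (GFP/RFP)") +
    theme_minimal()

  if (!is.null(comparison) && !is.null(comparison$pairwise)) {
    sig <- filter(comparison$pairwise, .data$stars != "ns")
    if (nrow(sig) > 0) {
      ymax <- max(df$value)
      step <- 0.08 * max(diff(range(df$value)), 1e-9)
      for (i in seq_len(nrow(sig))) {
        x1 <- match(sig$group1[i], groups)
        x2 <- match(sig$group2[i], groups)
        y <- ymax + i * step
        p <- p +
          annotate("segment", x = x1, xend = x2, y = y, yend = y,
                   linewidth = 0.4) +
          annotate("text", x = (x1 + x2) / 2, y = y + 0.3 * step,
                   label = sig$stars[i], size = 3)
      }
    }
  }
  p
}

#' Write the swarm figure and group summary for a measurement table
#'
#' @inheritParams plot_activity_swarm
#' @param path_prefix Output prefix; writes `<prefix>_swarm.png` and
#'   `<prefix>_summary.csv`.
#' @param width,height,dpi Figure geometry for [ggplot2::ggsave()].
#' @return Invisibly, a list with the ggplot object and the summary tibble
#'   (`group`, `n`, `median`, `q1`, `q3`, `iqr`, `n_outliers`).
#' @export
swarm_report <- function(table, comparison = NULL, path_prefix = "activity",
                         value = relative_activity, group = group,
                         group_order = NULL, width = 6, height = 4, dpi = 150) {
  vq <- enquo(value)
  gq <- enquo(group)
  d <- check_measurement_table(table, vq, gq)
  groups <- group_order %||% unique(d$group)
  summary <- map(groups, function(g) {
    v <- d$value[d$group == g]
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    n_out <- if (length(v) >= 4) sum(iqr_outlier_flags(v)) else NA_integer_
    tibble(group = g, n = length(v), median = median(v),
           q1 = q[1], q3 = q[2], iqr = q[2] - q[1], n_outliers = n_out)
  }) %>% bind_rows()

  p <- plot_activity_swarm(tibble(value = d$value, group = d$group),
                           comparison = comparison,
                           value = .data$value, group = .data$group,
                           group_order = groups)
  ggsave(paste0(path_prefix, "_swarm.png"), p,
         width = width, height = height, dpi = dpi)
  readr::write_csv(summary, paste0(path_prefix, "_summary.csv"),
                   progress = FALSE)
  invisible(list(plot = p, summary = summary))
}
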