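#' Protein binding microarray intensity table
#'
#' A `pbm_table` is a tibble with columns `kmer` (uppercase 8-mer) and
#' `intensity` (median signal, >= 0), one transcription factor per table.
#' 8-mers are stored reverse-complement expanded: an 8-mer and its reverse
#' complement share one intensity, the UniProbe convention for
#' double-stranded probes.
#'
#' @param x A data frame with columns `kmer` and `intensity`.
#' @param factor_name Transcription factor the table belongs to.
#' @param expand If `TRUE` (default), add the reverse complement of every
#'   8-mer with the same intensity (collapsed tables are normalized to the
#'   expanded form). Conflicting duplicate intensities are an error.
#' @return A tibble of class `pbm_table`, sorted lexicographically, with the
#'   factor name in attribute `factor_name`.
#' @export
pbm_table <- function(x, factor_name = "TF", expand = TRUE) {
  x <- as_tibble(x)
  if (!all(c("kmer", "intensity") %in% names(x))) {
    eq_abort("a PBM table needs columns `kmer` and `intensity`.",
             "eq_pbm_parse_error")
  }
  x$kmer <- str_to_upper(x$kmer)
  bad <- which(!grepl("^[ACGT]{8}$", x$kmer))
  if (length(bad) > 0) {
    eq_abort(sprintf("invalid 8-mer '%s' at row %d.", x$kmer[bad[1]], bad[1]),
             "eq_pbm_parse_error")
  }
  if (!is.numeric(x$intensity) || any(!is.finite(x$intensity)) ||
      any(x$intensity < 0)) {
    eq_abort("PBM intensities must be finite, non-negative numbers.",
             "eq_pbm_parse_error")
  }
  if (expand) {
    rc <- tibble(kmer = reverse_complement(x$kmer), intensity = x$intensity)
    x <- bind_rows(x, rc)
  }
  x <- distinct(x, .data$kmer, .data$intensity)
  if (anyDuplicated(x$kmer)) {
    dup <- x$kmer[duplicated(x$kmer)][1]
    eq_abort(sprintf("conflicting intensities for 8-mer '%s' (or its reverse complement).", dup),
             "eq_pbm_parse_error")
  }
  x <- arrange(x, .data$kmer)
  attr(x, "factor_name") <- factor_name
  class(x) <- c("pbm_table", class(x))
  x
}

#' Read a UniProbe-style 8-mer intensity TSV
#'
#' Expects a two-column tab-separated file: 8-mer, median intensity. The
#' header's second column conventionally names the factor. Collapsed tables
#' (one row per reverse-complement pair) are expanded on read.
#'
#' @param path Path to the TSV.
#' @param factor_name Factor name; defaults to the second header column.
#' @return A [pbm_table()].
#' @export
load_pbm_table <- function(path, factor_name = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), readr::col_character()
  ), col_names = TRUE, progress = FALSE)
  if (ncol(raw) < 2) {
    eq_abort(sprintf("'%s': expected 2 tab-separated columns.", path),
             "eq_pbm_parse_error")
  }
  factor_name <- factor_name %||% names(raw)[2]
  kmer <- raw[[1]]
  intensity <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(intensity) | !grepl("^[ACGTacgt]{8}$", kmer))
  if (length(bad) > 0) {
    # +1 for the header line
    eq_abort(sprintf("'%s': malformed entry at line %d ('%s').",
                     path, bad[1] + 1, kmer[bad[1]]),
             "eq_pbm_parse_error")
  }
  pbm_table(tibble(kmer = kmer, intensity = intensity),
            factor_name = factor_name)
}

#' Write a PBM table as a two-column TSV
#'
#' @param table A [pbm_table()].
#' @param path Output path. The header names the factor in the second
#'   column.
#' @param collapse Write one row per reverse-complement pair (the compact
#'   UniProbe layout) instead of the fully expanded table.
#' @export
write_pbm_table <- function(table, path, collapse = FALSE) {
  stopifnot(inherits(table, "pbm_table"))
  out <- table
  if (collapse) {
    out <- out[out$kmer <= reverse_complement(out$kmer), ]
  }
  names(out) <- c("8mer", attr(table, "factor_name") %||% "intensity")
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Optimal 8-mer of a PBM table
#'
#' The optimal 8-mer is the maximum-intensity word over all 8-mers; its
#' intensity is the denominator of every relative affinity for that factor.
#' Ties are broken lexicographically and flagged.
#'
#' @param table A [pbm_table()].
#' @return A list with `intensity`, `kmer`, and logical `tie`.
#' @export
optimal_intensity <- function(table) {
  stopifnot(inherits(table, "pbm_table"))
  if (nrow(table) == 0) {
    eq_abort("empty PBM table.", "eq_pbm_parse_error")
  }
  mx <- max(table$intensity)
  winners <- sort(table$kmer[table$intensity == mx])
  list(intensity = mx, kmer = winners[1], tie = length(winners) > 2 ||
         (length(winners) == 2 && winners[2] != reverse_complement(winners[1])))
}

#' Relative affinity of an 8-mer
#'
#' The ratio of the 8-mer's median intensity to the factor's optimal
#' (maximum) 8-mer intensity, on a 0-1 scale. An 8-mer absent in the
#' forward orientation is looked up as its reverse complement.
#'
#' @param table A [pbm_table()].
#' @param kmer An 8-mer (or vector of 8-mers) over A/C/G/T.
#' @return Relative affinity in `[0, 1]` (vectorized over `kmer`).
#' @examples
#' tab <- simulate_pbm_table("TAATAAAA", noise_cv = 0, seed = 1)
#' relative_affinity(tab, "TAATAAAA")
#' @export
relative_affinity <- function(table, kmer) {
  stopifnot(inherits(table, "pbm_table"))
  kmer <- str_to_upper(kmer)
  opt <- optimal_intensity(table)
  i <- match(kmer, table$kmer)
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(reverse_complement(kmer[miss]), table$kmer)
  }
  if (any(is.na(i))) {
    eq_abort(sprintf("8-mer '%s' not present in the PBM table.",
                     kmer[is.na(i)][1]),
             "eq_missing_kmer_error")
  }
  val <- table$intensity[i] / opt$intensity
  if (any(val > 1)) {
    warn("relative affinity above 1 clamped; the table's maximum should dominate.")
    val <- pmin(val, 1)
  }
  val
}

#' Relative affinity of a binding site
#'
#' Scores a candidate binding site as the maximum relative affinity over
#' the 8-base windows that represent it. The default policy admits every
#' 8-mer window overlapping the site interval by at least 6 bases, which
#' covers the 6-9 bp homeobox and E-box sites scored in this kind of assay;
#' `"contained"` restricts to windows fully inside the interval, and
#' `"any_overlap"` admits any window touching it.
#'
#' @param table A [pbm_table()].
#' @param sequence Query DNA sequence (string over A/C/G/T).
#' @param site A list or one-row data frame with `name`, `start`, `end`
#'   (1-based, inclusive, within the sequence).
#' @param window_policy One of `"overlap6"`, `"contained"`, `"any_overlap"`.
#' @return A list: `value` (relative affinity in `[0, 1]`), `kmer` (the
#'   maximizing window, forward-strand sequence), `strand` (orientation
#'   under which the table stores that word), `window_start`.
#' @export
site_relative_affinity <- function(table, sequence, site,
                                   window_policy = c("overlap6", "contained",
                                                     "any_overlap")) {
  window_policy <- match.arg(window_policy)
  stopifnot(inherits(table, "pbm_table"))
  sequence <- str_to_upper(sequence)
  L <- nchar(sequence)
  start <- as.integer(site$start)
  end <- as.integer(site$end)
  if (is.na(start) || is.na(end) || start < 1 || end > L || start > end) {
    eq_abort(sprintf("site '%s': interval [%s, %s] outside the %d bp sequence.",
                     site$name %||% "?", site$start, site$end, L),
             "eq_site_error")
  }
  min_overlap <- switch(window_policy,
                        overlap6 = 6L, contained = 8L, any_overlap = 1L)
  starts <- seq_len(max(L - 7, 0))
  if (window_policy == "contained") {
    starts <- starts[starts >= start & starts + 7 <= end]
  } else {
    ov <- pmin(starts + 7, end) - pmax(starts, start) + 1
    starts <- starts[ov >= min_overlap]
  }
  if (length(starts) == 0) {
    eq_abort(sprintf("site '%s' admits no 8-mer window under policy '%s'.",
                     site$name %||% "?", window_policy),
             "eq_site_error")
  }
  words <- str_sub(sequence, starts, starts + 7)
  valid <- grepl("^[ACGT]{8}$", words)
  if (any(!valid)) {
    warn(sprintf("site '%s': %d window(s) with non-ACGT bases skipped.",
                 site$name %||% "?", sum(!valid)))
  }
  if (!any(valid)) {
    eq_abort(sprintf("site '%s': all windows contain non-ACGT bases.",
                     site$name %||% "?"),
             "eq_site_error")
  }
  starts <- starts[valid]
  words <- words[valid]

  opt <- optimal_intensity(table)
  i <- match(words, table$kmer)
  strand <- rep("+", length(words))
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(reverse_complement(words[miss]), table$kmer)
    strand[miss] <- "-"
  }
  known <- !is.na(i)
  if (!any(known)) {
    eq_abort(sprintf("site '%s': no window present in the PBM table.",
                     site$name %||% "?"),
             "eq_missing_kmer_error")
  }
  vals <- table$intensity[i[known]] / opt$intensity
  best <- which.max(vals)
  list(value = min(vals[best], 1),
       kmer = words[known][best],
       strand = strand[known][best],
       window_start = starts[known][best])
}

#' Assemble the transcription factor x binding site affinity matrix
#'
#' Scores every factor against every site with [site_relative_affinity()].
#' A factor supplied as `NULL` (no PBM data available, as happens for some
#' bHLH factors) yields an explicit `NA` row rather than being dropped; a
#' cell whose scoring fails records `NA` plus the reason.
#'
#' @param tables Named list of [pbm_table()] objects (or `NULL` entries).
#' @param sequence Query DNA sequence.
#' @param sites Data frame of sites with columns `name`, `start`, `end`.
#' @param window_policy Passed to [site_relative_affinity()].
#' @return An object of class `affinity_matrix`: the tidy per-cell tibble is
#'   available via [tidy()] and the numeric factor x site matrix via
#'   `as.matrix()`.
#' @export
build_affinity_matrix <- function(tables, sequence, sites,
                                  window_policy = "overlap6") {
  sites <- as_tibble(sites)
  if (length(tables) < 1 || nrow(sites) < 1) {
    eq_abort("need at least one PBM table and one site.", "eq_config_error")
  }
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) {
      attr(t, "factor_name") %||% "TF"
    }, character(1))
  }
  cells <- list()
  k <- 0L
  for (f in names(tables)) {
    for (s in seq_len(nrow(sites))) {
      k <- k + 1L
      site <- sites[s, ]
      if (is.null(tables[[f]])) {
        cells[[k]] <- tibble(factor = f, site = site$name, affinity = NA_real_,
                             kmer = NA_character_, strand = NA_character_,
                             window_start = NA_integer_,
                             note = "no PBM data")
        next
      }
      res <- tryCatch(
        site_relative_affinity(tables[[f]], sequence, site, window_policy),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        cells[[k]] <- tibble(factor = f, site = site$name, affinity = NA_real_,
                             kmer = NA_character_, strand = NA_character_,
                             window_start = NA_integer_,
                             note = conditionMessage(res))
      } else {
        cells[[k]] <- tibble(factor = f, site = site$name,
                             affinity = res$value, kmer = res$kmer,
                             strand = res$strand,
                             window_start = res$window_start,
                             note = NA_character_)
      }
    }
  }
  structure(
    list(cells = bind_rows(cells),
         factors = names(tables),
         sites = sites$name,
         window_policy = window_policy),
    class = "affinity_matrix"
  )
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d factors x %d sites (policy %s)\n",
              length(x$factors), length(x$sites), x$window_policy))
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.affinity_matrix <- function(x, ...) {
  m <- matrix(NA_real_, length(x$factors), length(x$sites),
              dimnames = list(x$factors, x$sites))
  m[cbind(match(x$cells$factor, x$factors),
          match(x$cells$site, x$sites))] <- x$cells$affinity
  m
}

#' @rdname build_affinity_matrix
#' @param x An `affinity_matrix`.
#' @param ... Unused.
#' @export
tidy.affinity_matrix <- function(x, ...) {
  x$cells
}

#' Heatmap of an affinity matrix
#'
#' Renders the factor x site relative-affinity matrix on the conventional
#' white (0) to dark blue (1) scale; `NA` cells (no PBM data or failed
#' scoring) are grey and crossed out.
#'
#' @param object An `affinity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.affinity_matrix <- function(object, ...) {
  cells <- object$cells %>%
    mutate(factor = factor(.data$factor, levels = rev(object$factors)),
           site = factor(.data$site, levels = object$sites))
  p <- ggplot(cells, aes(x = .data$site, y = .data$factor)) +
    geom_tile(aes(fill = .data$affinity), colour = "grey60") +
    scale_fill_gradient(low = "white", high = "darkblue",
                        limits = c(0, 1), na.value = "grey85",
                        name = "relative\naffinity") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(panel.grid = element_blank())
  na_cells <- filter(cells, is.na(.data$affinity))
  if (nrow(na_cells) > 0) {
    p <- p + geom_point(data = na_cells, shape = 4, size = 3, colour = "grey40")
  }
  p
}

#' @rdname autoplot.affinity_matrix
#' @param matrix An `affinity_matrix`.
#' @param path Output image path (png/pdf/svg by extension).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @export
render_heatmap <- function(matrix, path, width = 7, height = 4, dpi = 150) {
  stopifnot(inherits(matrix, "affinity_matrix"))
  p <- autoplot(matrix)
  ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
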