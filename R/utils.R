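# internal helpers shared across modules

eq_abort <- function(message, class, ...) {
  abort(message, class = c(class, "enhancerquant_error"), ...)
}

# clip intensities to the representable range of a bit depth
clip_to_depth <- function(x, bit_depth) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

check_number <- function(x, field, min = -Inf, max = Inf, len = 1L,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != len || any(!is.finite(x))) {
    eq_abort(sprintf("`%s` must be a finite numeric of length %d.", field, len),
             "eq_config_error")
  }
  if (any(x < min) || any(x > max)) {
    eq_abort(sprintf("`%s` must be in [%s, %s] (got %s).", field,
                     format(min), format(max), paste(format(x), collapse = ", ")),
             "eq_config_error")
  }
  if (integerish && any(x != round(x))) {
    eq_abort(sprintf("`%s` must be a whole number.", field), "eq_config_error")
  }
  invisible(x)
}

# anatomical axes: which image edge is anterior, which is distal.
# The two must lie on perpendicular axes (anterior/posterior on one,
# proximal/distal on the other).
check_orientation <- function(orientation) {
  ok_ap <- orientation[["anterior"]] %in% c("top", "bottom")
  ok_pd <- orientation[["distal"]] %in% c("left", "right")
  ok_ap2 <- orientation[["anterior"]] %in% c("left", "right")
  ok_pd2 <- orientation[["distal"]] %in% c("top", "bottom")
  if (!((ok_ap && ok_pd) || (ok_ap2 && ok_pd2))) {
    eq_abort("`orientation` must place anterior and distal on perpendicular image edges.",
             "eq_config_error")
  }
  orientation
}

# 4-connected rasterization of a polyline given as a 2-column (x, y) matrix
# in pixel coordinates. A 4-connected curve separates 8-connected regions,
# so the rasterized boundary can be used as a cut line.
rasterize_polyline <- function(polyline, nrow, ncol) {
  if (!is.matrix(polyline) || ncol(polyline) != 2 || nrow(polyline) < 2) {
    eq_abort("`boundary` must be a matrix of (x, y) vertices with >= 2 rows.",
             "eq_annotation_error")
  }
  px <- integer(0)
  py <- integer(0)
  for (i in seq_len(nrow(polyline) - 1)) {
    x0 <- round(polyline[i, 1]); y0 <- round(polyline[i, 2])
    x1 <- round(polyline[i + 1, 1]); y1 <- round(polyline[i + 1, 2])
    nstep <- max(abs(x1 - x0), abs(y1 - y0), 1)
    xs <- round(seq(x0, x1, length.out = nstep + 1))
    ys <- round(seq(y0, y1, length.out = nstep + 1))
    # insert orthogonal in-between pixels where both coordinates step
    for (j in seq_len(nstep)) {
      px <- c(px, xs[j])
      py <- c(py, ys[j])
      if (xs[j + 1] != xs[j] && ys[j + 1] != ys[j]) {
        px <- c(px, xs[j + 1])
        py <- c(py, ys[j])
      }
    }
    px <- c(px, xs[nstep + 1])
    py <- c(py, ys[nstep + 1])
  }
  keep <- px >= 1 & px <= ncol & py >= 1 & py <= nrow
  mask <- matrix(FALSE, nrow, ncol)
  mask[cbind(py[keep], px[keep])] <- TRUE
  mask
}

# bounding box of a logical mask as row/col ranges
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) {
    eq_abort("mask is empty.", "eq_empty_mask_error")
  }
  list(row = range(rows), col = range(cols))
}

DNA_BASES <- c("A", "C", "G", "T")

# vectorized reverse complement (IUPAC-aware); the equal-width fast path
# matters because PBM tables carry 65,536 8-mers
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  widths <- unique(nchar(comp))
  if (length(widths) == 1 && length(comp) > 0) {
    k <- widths
    do.call(paste0, lapply(k:1, function(p) substr(comp, p, p)))
  } else {
    vapply(comp, function(s) {
      paste(rev(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
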