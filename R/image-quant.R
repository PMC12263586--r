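#' Convert an image to grayscale
#'
#' Single-channel input passes through unchanged; 3-channel arrays are
#' combined with the standard luminance weights (0.2125, 0.7154, 0.0721).
#'
#' @param image A numeric matrix or an `H x W x 3` array.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    return(image)
  }
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3) {
    w <- c(0.2125, 0.7154, 0.0721)
    return(image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3])
  }
  eq_abort("`image` must be a matrix or an H x W x 3 array.", "eq_image_error")
}

#' Edge-preserving bilateral denoising
#'
#' Classic bilateral filter: each pixel is replaced by a weighted mean of
#' its neighbourhood, with weights that decay with both spatial distance
#' (`sigma_spatial`) and intensity difference (`sigma_range`). Smooth
#' regions are averaged while steps larger than a few `sigma_range` are
#' preserved, which keeps the limb/background edge sharp for thresholding.
#' Borders are handled by edge replication.
#'
#' @param image Numeric matrix.
#' @param sigma_spatial Spatial kernel sigma in pixels (> 0).
#' @param sigma_range Intensity kernel sigma, in intensity units (> 0); a
#'   common choice is ~10% of the dynamic range.
#' @return Denoised matrix of the same dimensions.
#' @export
bilateral_denoise <- function(image, sigma_spatial = 3, sigma_range = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    eq_abort("`image` must be a numeric matrix.", "eq_image_error")
  }
  sigma_range <- sigma_range %||% (0.1 * max(diff(range(image)), 1))
  if (sigma_spatial <= 0 || sigma_range <= 0) {
    eq_abort("`sigma_spatial` and `sigma_range` must be positive.",
             "eq_image_error")
  }
  H <- nrow(image)
  W <- ncol(image)
  r <- max(1L, ceiling(2 * sigma_spatial))
  acc <- matrix(0, H, W)
  wacc <- matrix(0, H, W)
  rows <- seq_len(H)
  cols <- seq_len(W)
  for (dy in -r:r) {
    ri <- pmin(pmax(rows + dy, 1L), H)
    for (dx in -r:r) {
      ci <- pmin(pmax(cols + dx, 1L), W)
      shifted <- image[ri, ci, drop = FALSE]
      w <- exp(-(dx^2 + dy^2) / (2 * sigma_spatial^2)) *
        exp(-(shifted - image)^2 / (2 * sigma_range^2))
      acc <- acc + w * shifted
      wacc <- wacc + w
    }
  }
  acc / wacc
}

#' Otsu's threshold
#'
#' Exhaustively maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over every candidate cut, where the foreground
#' class is the pixels strictly greater than the threshold (ties go to the
#' background, a deterministic tie-break). The returned threshold is the
#' smallest maximizer, itself one of the observed values.
#'
#' @param values Numeric vector of intensities with at least two distinct
#'   values.
#' @return The threshold; foreground is `values > threshold`.
#' @examples
#' otsu_threshold(c(rep(0, 10), rep(255, 10)))
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  u <- sort(unique(values))
  if (length(u) < 2) {
    eq_abort("Otsu thresholding needs >= 2 distinct values.",
             "eq_degenerate_error")
  }
  cnt <- tabulate(match(values, u), nbins = length(u))
  n <- length(values)
  csum <- cumsum(cnt)
  cint <- cumsum(cnt * u)
  total <- cint[length(u)]
  # candidate thresholds: all but the largest distinct value
  k <- seq_len(length(u) - 1)
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cint[k] / csum[k]
  mu1 <- (total - cint[k]) / (n - csum[k])
  between <- w0 * w1 * (mu0 - mu1)^2
  # exact ties (e.g. symmetric histograms) resolve to the smallest
  # threshold; the tolerance keeps fp round-off from flipping a tie
  best <- max(between)
  u[min(k[between >= best - 1e-9 * max(best, 1)])]
}

# Otsu-based region finding within a mask, with an optional bimodality gate.
#
# Plain Otsu mis-handles unimodal masked images: with all pixels background
# it promotes the upper noise tail to foreground, and with all pixels active
# it splits the noise in half. When `background` (a list with `level` and
# `sd`, estimated outside the limb) is supplied, the Otsu split is accepted
# only if it is genuinely bimodal: the class-mean separation must exceed
# `min_separation_sd` pooled within-class standard deviations (a d-prime
# statistic; an Otsu cut through unimodal noise gives ~2.7 regardless of
# the noise level). Otherwise the masked region is treated as unimodal and
# called entirely foreground (mean above `level + guard_sd * sd`) or
# empty. A fixed `threshold` bypasses Otsu.
masked_otsu_region <- function(image, mask, background = NULL,
                               min_separation_sd = 4, guard_sd = 3,
                               threshold = NULL) {
  if (!all(dim(image) == dim(mask))) {
    eq_abort("image and mask dimensions differ.", "eq_image_error")
  }
  if (!any(mask)) {
    eq_abort("analysis mask is empty.", "eq_empty_mask_error")
  }
  vals <- image[mask]
  if (!is.null(threshold)) {
    return(list(region = mask & image > threshold, threshold = threshold,
                degenerate = FALSE))
  }
  guard <- function() {
    if (is.null(background)) {
      return(NULL)
    }
    background$level + guard_sd * background$sd
  }
  u <- unique(vals)
  if (length(u) < 2) {
    g <- guard()
    if (!is.null(g) && u[1] > g) {
      return(list(region = mask, threshold = NA_real_, degenerate = TRUE,
                  uniform = "foreground"))
    }
    return(list(region = mask & FALSE, threshold = NA_real_, degenerate = TRUE,
                uniform = "background"))
  }
  t <- otsu_threshold(vals)
  lo <- vals[vals <= t]
  hi <- vals[vals > t]
  mu0 <- mean(lo)
  mu1 <- mean(hi)
  if (!is.null(background)) {
    s0 <- if (length(lo) > 1) sd(lo) else 0
    s1 <- if (length(hi) > 1) sd(hi) else 0
    pooled <- sqrt((s0^2 + s1^2) / 2)
    dprime <- if (pooled > 0) (mu1 - mu0) / pooled else Inf
    # absolute floor: numerical jitter on an effectively constant region
    # must never read as bimodal
    jitter_floor <- 1e-6 * max(abs(mu0), abs(mu1), 1)
    if (dprime <= min_separation_sd || (mu1 - mu0) <= jitter_floor) {
      # unimodal: all-or-nothing by comparison with the background
      g <- guard()
      if (mean(vals) > g) {
        return(list(region = mask, threshold = NA_real_, degenerate = TRUE,
                    uniform = "foreground"))
      }
      return(list(region = mask & FALSE, threshold = NA_real_,
                  degenerate = TRUE, uniform = "background"))
    }
    if (mu1 <= guard()) {
      return(list(region = mask & FALSE, threshold = t, degenerate = TRUE,
                  uniform = "background"))
    }
  }
  list(region = mask & image > t, threshold = t, degenerate = FALSE)
}

#' Segment the limb on the light image
#'
#' Otsu thresholding of the light image finds the tissue foreground (limb
#' plus body wall); the manually annotated boundary polyline is rasterized
#' as a cut line separating the two, and the limb is the connected
#' component on the annotated limb side.
#'
#' @param light Light-channel matrix (grayscale).
#' @param boundary Polyline as a 2-column `(x, y)` matrix in pixel
#'   coordinates.
#' @param limb_side_point `(x, y)` point inside the limb, from the
#'   annotation.
#' @return Logical limb mask.
#' @export
segment_limb <- function(light, boundary, limb_side_point) {
  t <- otsu_threshold(as.vector(light))
  fg <- light > t
  cut <- rasterize_polyline(boundary, nrow(light), ncol(light))
  pieces <- fg & !cut
  labels <- bwlabel(pieces)
  ncomp <- max(labels)
  if (ncomp < 2) {
    eq_abort("boundary does not split the tissue foreground into >= 2 components.",
             "eq_annotation_error")
  }
  px <- round(limb_side_point[[1]])
  py <- round(limb_side_point[[2]])
  if (px < 1 || px > ncol(light) || py < 1 || py > nrow(light) ||
      labels[py, px] == 0) {
    eq_abort("`limb_side_point` does not fall on a foreground component.",
             "eq_annotation_error")
  }
  labels == labels[py, px]
}

# posterior-most / distal-most index sets of a mask's bounding box
axis_fraction_keep <- function(mask, fraction, axis = c("row", "col"),
                               from_end = TRUE) {
  axis <- match.arg(axis)
  bb <- mask_bbox(mask)
  rng <- if (axis == "row") bb$row else bb$col
  extent <- rng[2] - rng[1] + 1
  n_keep <- max(1L, ceiling(fraction * extent))
  if (from_end) {
    keep <- (rng[2] - n_keep + 1):rng[2]
  } else {
    keep <- rng[1]:(rng[1] + n_keep - 1)
  }
  sel <- matrix(FALSE, nrow(mask), ncol(mask))
  if (axis == "row") {
    sel[keep, ] <- TRUE
  } else {
    sel[, keep] <- TRUE
  }
  sel
}

ap_selector <- function(mask, fraction, orientation) {
  side <- orientation[["anterior"]]
  axis <- if (side %in% c("top", "bottom")) "row" else "col"
  # posterior is the edge opposite the anterior one
  from_end <- side %in% c("top", "left")
  axis_fraction_keep(mask, fraction, axis, from_end)
}

pd_selector <- function(mask, fraction, orientation) {
  side <- orientation[["distal"]]
  axis <- if (side %in% c("top", "bottom")) "row" else "col"
  from_end <- side %in% c("bottom", "right")
  axis_fraction_keep(mask, fraction, axis, from_end)
}

#' Posterior analysis mask
#'
#' Retains the posterior-most `ap_fraction` of the limb along the
#' anterior-posterior axis (an axis-aligned fractional crop of the limb
#' bounding box), excluding anterior tissue that may be transfected but
#' would not express wild-type enhancer activity.
#'
#' @param limb Logical limb mask.
#' @param ap_fraction Fraction of the anterior-posterior extent retained,
#'   in `(0, 1]`; default 0.5 (the posterior half).
#' @param orientation Named vector mapping `anterior` and `distal` to image
#'   edges; see [default_orientation()].
#' @return Logical mask, a subset of `limb`.
#' @export
build_posterior_mask <- function(limb, ap_fraction = 0.5,
                                 orientation = default_orientation()) {
  check_orientation(orientation)
  check_number(ap_fraction, "ap_fraction", min = 1e-9, max = 1)
  limb & ap_selector(limb, ap_fraction, orientation)
}

#' ZPA analysis mask
#'
#' Approximates the zone of polarizing activity — the posterior-distal
#' region of active Shh transcription — as the intersection of the
#' distal-most `pd_fraction` and posterior-most `ap_fraction` of the limb
#' bounding box, further restricted to the posterior mask.
#'
#' @param limb,posterior Logical masks, `posterior` a subset of `limb`.
#' @param pd_fraction Distal fraction retained, default 0.4.
#' @param ap_fraction Posterior fraction retained, default 0.35.
#' @param orientation See [build_posterior_mask()].
#' @return Logical mask, a subset of `posterior`.
#' @export
build_zpa_mask <- function(limb, posterior, pd_fraction = 0.4,
                           ap_fraction = 0.35,
                           orientation = default_orientation()) {
  check_orientation(orientation)
  check_number(pd_fraction, "pd_fraction", min = 1e-9, max = 1)
  check_number(ap_fraction, "ap_fraction", min = 1e-9, max = 1)
  if (!any(posterior)) {
    eq_abort("posterior mask is empty.", "eq_empty_mask_error")
  }
  limb & posterior &
    ap_selector(limb, ap_fraction, orientation) &
    pd_selector(limb, pd_fraction, orientation)
}

#' Default anatomical orientation
#'
#' Dorsal-view limb images are conventionally displayed with the anterior
#' edge at the top and the distal edge to the right.
#'
#' @return A named character vector with entries `anterior` and `distal`.
#' @export
default_orientation <- function() {
  c(anterior = "top", distal = "right")
}

#' Transfection region within an analysis mask
#'
#' Otsu-thresholds the (denoised) RFP channel using only the pixels inside
#' the analysis mask, so the threshold reflects the masked intensity
#' distribution rather than the whole frame. With a `background` reference
#' the bimodality gate described in [quantify_bundle()] is applied; a
#' masked RFP image that is constant, or indistinguishable from background,
#' raises a "no transfection detected" condition.
#'
#' @param rfp RFP-channel matrix.
#' @param analysis_mask Logical mask (limb, posterior or ZPA).
#' @param background Optional list with `level` and `sd` of the background,
#'   estimated outside the limb.
#' @param threshold Optional fixed threshold bypassing Otsu.
#' @return Logical transfection mask (subset of `analysis_mask`) with the
#'   threshold in attribute `threshold`.
#' @export
transfection_region <- function(rfp, analysis_mask, background = NULL,
                                threshold = NULL) {
  res <- tryCatch(
    masked_otsu_region(rfp, analysis_mask, background, threshold = threshold),
    eq_degenerate_error = function(e) {
      eq_abort("no transfection detected (constant RFP within the mask).",
               "eq_no_transfection_error")
    }
  )
  if (isTRUE(res$degenerate) && identical(res$uniform, "background")) {
    eq_abort("no transfection detected (masked RFP indistinguishable from background).",
             "eq_no_transfection_error")
  }
  structure(res$region, threshold = res$threshold)
}

#' Enhancer activity region within the transfection region
#'
#' Otsu-thresholds the (denoised) GFP channel on the transfected pixels
#' only. A silent enhancer is a valid outcome: masked GFP that is constant
#' at, or indistinguishable from, background yields an empty region with a
#' warning rather than an error; masked GFP that is uniformly above
#' background (a fully active region, where no threshold can be placed) is
#' returned whole.
#'
#' @param gfp GFP-channel matrix.
#' @param transfection_mask Logical mask from [transfection_region()].
#' @param background Optional background reference, as in
#'   [transfection_region()].
#' @param threshold Optional fixed threshold.
#' @return Logical activity mask (subset of `transfection_mask`) with the
#'   threshold in attribute `threshold`.
#' @export
activity_region <- function(gfp, transfection_mask, background = NULL,
                            threshold = NULL) {
  if (!any(transfection_mask)) {
    eq_abort("transfection mask is empty.", "eq_empty_mask_error")
  }
  res <- tryCatch(
    masked_otsu_region(gfp, transfection_mask, background,
                       threshold = threshold),
    eq_degenerate_error = function(e) {
      warn("constant GFP within the transfection region: silent enhancer, empty activity region.")
      list(region = transfection_mask & FALSE, threshold = NA_real_,
           degenerate = TRUE, uniform = "background")
    }
  )
  if (isTRUE(res$degenerate) && identical(res$uniform, "background") &&
      !is.null(background)) {
    warn("masked GFP indistinguishable from background: empty activity region.")
  }
  structure(res$region, threshold = res$threshold)
}

#' Measure pixel count and total intensity within a region
#'
#' @param image Numeric matrix.
#' @param region Logical mask of the same dimensions.
#' @return A one-row tibble with `pixel_count` and `total_intensity`.
#' @export
measure_region <- function(image, region) {
  if (!all(dim(image) == dim(region))) {
    eq_abort("image and region dimensions differ.", "eq_image_error")
  }
  tibble(pixel_count = sum(region),
         total_intensity = sum(image[region]))
}

#' Relative enhancer activity
#'
#' Total GFP intensity normalized to total RFP intensity; the
#' normalization accounts for differences in transfection between embryos.
#' Invariant under joint rescaling of both channels.
#'
#' @param gfp_total,rfp_total Non-negative totals.
#' @return `gfp_total / rfp_total`.
#' @export
relative_activity <- function(gfp_total, rfp_total) {
  if (any(gfp_total < 0) || any(rfp_total < 0)) {
    eq_abort("intensity totals must be non-negative.", "eq_image_error")
  }
  if (any(rfp_total == 0)) {
    eq_abort("undefined relative activity: RFP total is zero.",
             "eq_undefined_activity_error")
  }
  gfp_total / rfp_total
}
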