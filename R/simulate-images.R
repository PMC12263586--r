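#' Simulation settings for synthetic limb reporter images
#'
#' Builds the configuration for [simulate_limb_bundle()]. The simulated scene
#' emulates a transfected embryonic limb imaged in three channels: a light
#' (brightfield) channel showing the limb and the adjacent body wall, an RFP
#' channel marking the mosaic of transfected cells (the transfection control),
#' and a GFP channel reporting enhancer activity within a posterior focus of
#' the limb. The limb is an ellipse, the body wall a strip along the proximal
#' edge touching the limb, so that separating the two requires the manual
#' boundary annotation, as it does in real embryo images.
#'
#' In active, transfected cells the clean GFP signal is
#' `background_level + activity_level * (RFP - background_level)`, i.e. GFP
#' scales with the local transfection dose and `activity_level` is the true
#' GFP/RFP ratio above background. Additive Gaussian noise (`noise_sd`) is
#' applied per channel and intensities are clipped to the bit depth.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param bit_depth Camera bit depth, 8 or 16.
#' @param limb_center Ellipse centre `(x, y)` in pixels; default scales with
#'   the frame and touches the body-wall strip.
#' @param limb_semiaxes Ellipse semi-axes `(a, b)` in pixels.
#' @param limb_rotation Ellipse rotation in radians.
#' @param body_wall_fraction Fraction of the frame width occupied by the
#'   body-wall strip along the proximal (left) edge.
#' @param transfection_fraction Fraction of limb pixels transfected, in
#'   `[0, 1]`.
#' @param transfection_patchiness Spatial correlation length (Gaussian blur
#'   sigma, pixels) of the mosaic transfection field.
#' @param activity_level True enhancer activity: expected GFP:RFP intensity
#'   ratio (above background) in active cells. Dimensionless, `>= 0`.
#' @param activity_center Centre of the activity focus in limb-normalized
#'   coordinates (fractions of the limb bounding box; `(0.5, 0.8)` is
#'   mid-way along the limb and well into the posterior half).
#' @param activity_radius Radius of the activity focus in limb-normalized
#'   units. The default covers the entire posterior half of the limb so that
#'   a posterior-mask measurement sees uniform activity.
#' @param background_level Fluorescence background, intensity units.
#' @param rfp_level Transfection dose: clean RFP signal above background on
#'   transfected pixels.
#' @param light_levels Named vector with `background`, `body_wall` and `limb`
#'   intensities for the light channel.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units), applied to every channel.
#' @param seed Integer seed; identical configurations produce identical
#'   bundles.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_limb_bundle()], [simulate_cohort()]
#' @export
sim_config <- function(image_width = 160,
                       image_height = 120,
                       bit_depth = 8,
                       limb_center = NULL,
                       limb_semiaxes = NULL,
                       limb_rotation = 0,
                       body_wall_fraction = 0.18,
                       transfection_fraction = 0.4,
                       transfection_patchiness = 6,
                       activity_level = 0.5,
                       activity_center = c(0.5, 0.8),
                       activity_radius = 0.6,
                       background_level = 2,
                       rfp_level = 150,
                       light_levels = c(background = 20, body_wall = 120, limb = 170),
                       noise_sd = 0,
                       seed = 1L) {
  check_number(image_width, "image_width", min = 16, integerish = TRUE)
  check_number(image_height, "image_height", min = 16, integerish = TRUE)
  if (!bit_depth %in% c(8, 16)) {
    eq_abort("`bit_depth` must be 8 or 16.", "eq_config_error")
  }
  limb_center <- limb_center %||% c(0.47 * image_width, 0.5 * image_height)
  limb_semiaxes <- limb_semiaxes %||% c(0.30 * image_width, 0.36 * image_height)
  check_number(limb_center, "limb_center", len = 2L)
  check_number(limb_semiaxes, "limb_semiaxes", min = 1, len = 2L)
  check_number(limb_rotation, "limb_rotation")
  check_number(body_wall_fraction, "body_wall_fraction", min = 0, max = 0.5)
  check_number(transfection_fraction, "transfection_fraction", min = 0, max = 1)
  check_number(transfection_patchiness, "transfection_patchiness", min = 0)
  check_number(activity_level, "activity_level", min = 0)
  check_number(activity_center, "activity_center", len = 2L)
  check_number(activity_radius, "activity_radius", min = 0)
  check_number(background_level, "background_level", min = 0)
  check_number(rfp_level, "rfp_level", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed", integerish = TRUE)
  if (!all(c("background", "body_wall", "limb") %in% names(light_levels))) {
    eq_abort("`light_levels` must name background, body_wall and limb.",
             "eq_config_error")
  }

  # rotated-ellipse bounding half-extents; the limb must fit in the frame
  th <- limb_rotation
  hw <- sqrt((limb_semiaxes[1] * cos(th))^2 + (limb_semiaxes[2] * sin(th))^2)
  hh <- sqrt((limb_semiaxes[1] * sin(th))^2 + (limb_semiaxes[2] * cos(th))^2)
  if (limb_center[1] - hw < 1 || limb_center[1] + hw > image_width ||
      limb_center[2] - hh < 1 || limb_center[2] + hh > image_height) {
    eq_abort("`limb_semiaxes`/`limb_center`: limb ellipse does not fit within the frame.",
             "eq_config_error")
  }

  structure(
    list(
      image_width = as.integer(image_width),
      image_height = as.integer(image_height),
      bit_depth = as.integer(bit_depth),
      limb_center = limb_center,
      limb_semiaxes = limb_semiaxes,
      limb_rotation = limb_rotation,
      body_wall_fraction = body_wall_fraction,
      transfection_fraction = transfection_fraction,
      transfection_patchiness = transfection_patchiness,
      activity_level = activity_level,
      activity_center = activity_center,
      activity_radius = activity_radius,
      background_level = background_level,
      rfp_level = rfp_level,
      light_levels = light_levels,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

new_limb_bundle <- function(light, rfp, gfp, embryo_id, group, bit_depth,
                            annotation) {
  stopifnot(all(dim(light) == dim(rfp)), all(dim(light) == dim(gfp)))
  structure(
    list(light = light, rfp = rfp, gfp = gfp,
         embryo_id = embryo_id, group = group,
         bit_depth = bit_depth, annotation = annotation),
    class = "limb_bundle"
  )
}

#' @export
print.limb_bundle <- function(x, ...) {
  cat(sprintf("<limb_bundle> %s (group %s): %d x %d px, %d-bit\n",
              x$embryo_id, x$group, ncol(x$light), nrow(x$light), x$bit_depth))
  invisible(x)
}

#' Simulate one limb reporter image bundle with ground truth
#'
#' Generates the light/RFP/GFP channels described in [sim_config()] together
#' with the ground truth needed to benchmark the quantification pipeline:
#' the limb mask, the mosaic of transfected pixels, the subset of active
#' pixels, the true activity level, and the manual limb/body-wall boundary
#' polyline that a human annotator would supply.
#'
#' The transfection mosaic is white noise smoothed with a Gaussian of sigma
#' `transfection_patchiness` and thresholded at the
#' `1 - transfection_fraction` quantile within the limb, which reproduces
#' patchy electroporation without modelling cells. Active pixels are the
#' transfected pixels inside the activity focus.
#'
#' @param config A [sim_config()] object.
#' @param embryo_id,group Labels stored in the bundle.
#' @return A list with elements `bundle` (class `limb_bundle`, carrying the
#'   boundary annotation as its sidecar) and `truth` (class `limb_truth` with
#'   `limb_mask`, `transfected_mask`, `active_mask`, `true_activity`,
#'   `boundary_polyline`).
#' @examples
#' sim <- simulate_limb_bundle(sim_config(noise_sd = 0, seed = 7))
#' range(sim$bundle$rfp)
#' @export
simulate_limb_bundle <- function(config, embryo_id = "embryo_1", group = "group_1") {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  W <- config$image_width
  H <- config$image_height
  maxval <- 2^config$bit_depth - 1

  xs <- matrix(rep(seq_len(W), each = H), nrow = H)
  ys <- matrix(rep(seq_len(H), times = W), nrow = H)

  # rotated ellipse
  th <- config$limb_rotation
  dx <- xs - config$limb_center[1]
  dy <- ys - config$limb_center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ellipse <- (u / config$limb_semiaxes[1])^2 + (v / config$limb_semiaxes[2])^2 <= 1

  wall_cols <- floor(config$body_wall_fraction * W)
  body_wall <- xs <= wall_cols & !ellipse

  # the manual boundary runs just distal to the body-wall strip; the limb is
  # everything on its distal side
  cut_col <- wall_cols + 1L
  limb <- ellipse & xs > cut_col
  if (!any(limb)) {
    eq_abort("`body_wall_fraction`: body wall swallows the limb ellipse.",
             "eq_config_error")
  }
  boundary <- cbind(x = c(cut_col, cut_col), y = c(0, H + 1))

  set.seed(config$seed)

  # mosaic transfection field
  field <- matrix(rnorm(H * W), nrow = H)
  if (config$transfection_patchiness >= 0.5) {
    field <- gblur(field, sigma = config$transfection_patchiness)
  }
  if (config$transfection_fraction <= 0) {
    transfected <- limb & FALSE
  } else if (config$transfection_fraction >= 1) {
    transfected <- limb
  } else {
    thr <- quantile(field[limb], 1 - config$transfection_fraction, names = FALSE)
    transfected <- limb & field > thr
  }

  # activity focus in limb-normalized coordinates
  bb <- mask_bbox(limb)
  nx <- (xs - bb$col[1]) / max(bb$col[2] - bb$col[1], 1)
  ny <- (ys - bb$row[1]) / max(bb$row[2] - bb$row[1], 1)
  focus <- sqrt((nx - config$activity_center[1])^2 +
                  (ny - config$activity_center[2])^2) <= config$activity_radius
  active <- transfected & focus
  if (config$activity_level == 0) {
    active <- active & FALSE
  }

  bg <- config$background_level
  light_clean <- matrix(config$light_levels[["background"]], H, W)
  light_clean[body_wall] <- config$light_levels[["body_wall"]]
  light_clean[ellipse] <- config$light_levels[["limb"]]

  rfp_clean <- matrix(bg, H, W)
  rfp_clean[transfected] <- bg + config$rfp_level

  gfp_clean <- matrix(bg, H, W)
  gfp_clean[active] <- bg + config$activity_level * config$rfp_level

  noisy <- function(img) {
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, sd = config$noise_sd), H, W)
    }
    clip_to_depth(img, config$bit_depth)
  }
  light <- noisy(light_clean)
  rfp <- noisy(rfp_clean)
  gfp <- noisy(gfp_clean)

  annotation <- list(
    embryo_id = embryo_id,
    group = group,
    boundary_polyline = boundary,
    limb_side_point = c(x = config$limb_center[1], y = config$limb_center[2]),
    orientation = default_orientation()
  )
  bundle <- new_limb_bundle(light, rfp, gfp, embryo_id, group,
                            config$bit_depth, annotation)
  truth <- structure(
    list(limb_mask = limb,
         transfected_mask = transfected,
         active_mask = active,
         true_activity = config$activity_level,
         boundary_polyline = boundary),
    class = "limb_truth"
  )
  list(bundle = bundle, truth = truth)
}

#' Simulate a cohort of limb bundles across experimental groups
#'
#' @param group_specs A data frame (or tibble) with one row per group:
#'   columns `label`, `n` (embryos per group) and either a `config` list
#'   column of [sim_config()] objects / argument lists, or extra columns
#'   (e.g. `activity_level`, `noise_sd`) passed to [sim_config()].
#' @param seed Master seed. Per-bundle seeds are `seed + bundle index`, so a
#'   cohort is reproducible from the master seed alone.
#' @return A tibble with one row per embryo: `embryo_id`, `group`, `bundle`
#'   (list of `limb_bundle`), `truth` (list of `limb_truth`),
#'   `true_activity`.
#' @examples
#' specs <- tibble::tibble(label = c("WT", "mutant"), n = 2,
#'                         activity_level = c(0.8, 0.2))
#' cohort <- simulate_cohort(specs, seed = 42)
#' cohort$embryo_id
#' @export
simulate_cohort <- function(group_specs, seed = 1L) {
  group_specs <- as_tibble(group_specs)
  if (!all(c("label", "n") %in% names(group_specs))) {
    eq_abort("`group_specs` needs columns `label` and `n`.", "eq_config_error")
  }
  if (anyDuplicated(group_specs$label)) {
    eq_abort("duplicate group labels in `group_specs`.", "eq_config_error")
  }
  if (any(group_specs$n < 1)) {
    eq_abort("each group needs `n` >= 1.", "eq_config_error")
  }
  check_number(seed, "seed", integerish = TRUE)

  extra_cols <- setdiff(names(group_specs), c("label", "n", "config"))
  idx <- 0L
  rows <- list()
  for (g in seq_len(nrow(group_specs))) {
    label <- group_specs$label[g]
    base <- if ("config" %in% names(group_specs)) {
      cfg <- group_specs$config[[g]]
      if (inherits(cfg, "sim_config")) unclass(cfg) else cfg
    } else {
      as.list(group_specs[g, extra_cols, drop = FALSE])
    }
    base$light_levels <- base$light_levels %||% NULL
    for (i in seq_len(group_specs$n[g])) {
      idx <- idx + 1L
      args <- base
      args$seed <- as.integer(seed + idx)
      cfg <- do.call(sim_config, args[!vapply(args, is.null, logical(1))])
      id <- sprintf("%s_%02d", label, i)
      sim <- simulate_limb_bundle(cfg, embryo_id = id, group = label)
      rows[[idx]] <- tibble(
        embryo_id = id, group = label,
        bundle = list(sim$bundle), truth = list(sim$truth),
        true_activity = cfg$activity_level
      )
    }
  }
  bind_rows(rows)
}
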