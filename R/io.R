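#' Write an image bundle to disk
#'
#' The three channels are written as one multi-page TIFF (page order:
#' light, RFP, GFP) scaled to the bundle's bit depth, with the annotation
#' sidecar as JSON (`embryo_id`, `group`, `boundary_polyline`,
#' `orientation`, `limb_side_point`, `bit_depth`).
#'
#' @param bundle A `limb_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "limb_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^bundle$bit_depth - 1
  tif <- file.path(dir, paste0(bundle$embryo_id, ".tif"))
  pages <- lapply(list(bundle$light, bundle$rfp, bundle$gfp),
                  function(m) m / maxval)
  tiff::writeTIFF(pages, tif, bits.per.sample = bundle$bit_depth)
  ann <- bundle$annotation
  js <- file.path(dir, paste0(bundle$embryo_id, ".json"))
  jsonlite::write_json(
    list(embryo_id = bundle$embryo_id,
         group = bundle$group,
         bit_depth = bundle$bit_depth,
         boundary_polyline = unname(as.matrix(ann$boundary_polyline)),
         limb_side_point = unname(as.numeric(ann$limb_side_point)),
         orientation = as.list(ann$orientation)),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tif, js))
}

#' Read an image bundle written by [write_bundle()]
#'
#' @param tif Path to the multi-page TIFF; the JSON sidecar is expected
#'   next to it with the same stem.
#' @return A `limb_bundle`.
#' @export
read_bundle <- function(tif) {
  js <- sub("\\.tiff?$", ".json", tif)
  if (!file.exists(js)) {
    eq_abort(sprintf("annotation sidecar '%s' not found.", js),
             "eq_annotation_error")
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != 3) {
    eq_abort(sprintf("'%s': expected 3 pages (light, RFP, GFP), found %d.",
                     tif, length(pages)),
             "eq_image_error")
  }
  maxval <- 2^meta$bit_depth - 1
  ann <- list(
    embryo_id = meta$embryo_id, group = meta$group,
    boundary_polyline = matrix(as.numeric(meta$boundary_polyline), ncol = 2),
    limb_side_point = as.numeric(meta$limb_side_point),
    orientation = unlist(meta$orientation)
  )
  new_limb_bundle(pages[[1]] * maxval, pages[[2]] * maxval, pages[[3]] * maxval,
                  meta$embryo_id, meta$group, meta$bit_depth, ann)
}

#' Read every bundle in a directory into a cohort tibble
#'
#' @param dir Directory of TIFF + JSON pairs from [write_bundle()].
#' @return A tibble with `embryo_id`, `group` and a `bundle` list-column.
#' @export
read_cohort <- function(dir) {
  tifs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  tifs <- tifs[!grepl("_truth\\.tiff?$", tifs)]
  tifs <- tifs[file.exists(sub("\\.tiff?$", ".json", tifs))]
  if (length(tifs) == 0) {
    eq_abort(sprintf("no TIFF bundles found in '%s'.", dir), "eq_image_error")
  }
  bundles <- map(tifs, read_bundle)
  tibble(
    embryo_id = map_chr(bundles, "embryo_id"),
    group = map_chr(bundles, "group"),
    bundle = bundles
  )
}

#' Write ground truth alongside a bundle
#'
#' Masks go into a multi-page TIFF (limb, transfected, active) and the
#' scalar truth (true activity, boundary polyline) into JSON. Fully
#' synthetic data: these files exist so that pipeline benchmarks can be
#' re-read without re-simulation.
#'
#' @param truth A `limb_truth`.
#' @param dir Output directory.
#' @param stem File stem.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir, stem) {
  stopifnot(inherits(truth, "limb_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(stem, "_truth.tif"))
  tiff::writeTIFF(lapply(list(truth$limb_mask, truth$transfected_mask,
                              truth$active_mask),
                         function(m) m * 1),
                  tif, bits.per.sample = 8)
  js <- file.path(dir, paste0(stem, "_truth.json"))
  jsonlite::write_json(
    list(true_activity = truth$true_activity,
         boundary_polyline = unname(as.matrix(truth$boundary_polyline))),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tif, js))
}

#' Write / read per-embryo activity records
#'
#' @param records Activity record tibble from [quantify_cohort()].
#' @param path CSV path.
#' @return `write_activity_csv()` returns the path invisibly;
#'   `read_activity_csv()` returns the tibble.
#' @export
write_activity_csv <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @export
read_activity_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read binding-site intervals
#'
#' BED input (0-based, half-open) is converted to the package's 1-based
#' inclusive convention via `rtracklayer`; TSV input is expected 1-based
#' with columns `name`, `start`, `end`.
#'
#' @param path Path to a `.bed` or `.tsv` file.
#' @param format `"bed"` or `"tsv"`; guessed from the extension by
#'   default.
#' @return A tibble with `name`, `start`, `end`.
#' @export
read_sites <- function(path, format = NULL) {
  format <- format %||% ifelse(grepl("\\.bed$", path, ignore.case = TRUE),
                               "bed", "tsv")
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- as.data.frame(gr)
    tibble(name = as.character(df$name %||% seq_len(nrow(df))),
           start = df$start, end = df$end)
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("name", "start", "end") %in% names(df))) {
      eq_abort("site TSV needs columns name, start, end.", "eq_site_error")
    }
    tibble(name = as.character(df$name), start = df$start, end = df$end)
  }
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA path.
#' @return The sequence as an uppercase string.
#' @export
read_query_fasta <- function(path) {
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0) {
    eq_abort(sprintf("'%s' contains no sequences.", path), "eq_site_error")
  }
  str_to_upper(as.character(seqs[[1]]))
}
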