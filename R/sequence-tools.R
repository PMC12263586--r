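#' Genomic intervals (1-based, inclusive)
#'
#' All coordinates in this package are 1-based and inclusive, the convention
#' under which the published enhancer coordinates reproduce the published
#' fragment lengths (e.g. a 1,373 bp chicken ZRS at Chr2:8,553,160-8,554,532).
#' BED input is converted from 0-based half-open on read.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param name Optional interval name(s).
#' @return A tibble with columns `name`, `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+", name = NA_character_) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 1)) {
    eq_abort("interval `start`/`end` must be finite and >= 1.", "eq_interval_error")
  }
  if (any(start > end)) {
    eq_abort("interval `start` must be <= `end`.", "eq_interval_error")
  }
  if (!all(strand %in% c("+", "-"))) {
    eq_abort("`strand` must be '+' or '-'.", "eq_interval_error")
  }
  tibble(name = name, chrom = chrom, start = start, end = end, strand = strand)
}

#' Length of 1-based inclusive intervals
#'
#' @param interval A data frame with `start` and `end` columns (e.g. from
#'   [genomic_interval()]), or a numeric `start` if `end` is given.
#' @param end Optional numeric end coordinate(s) when `interval` is numeric.
#' @return Interval length(s) in bp: `end - start + 1`.
#' @examples
#' interval_length(8553160, 8554532) # the 1,373 bp chicken ZRS
#' @export
interval_length <- function(interval, end = NULL) {
  if (is.numeric(interval) && !is.null(end)) {
    interval <- genomic_interval("chr", interval, end)
  }
  if (any(interval$start > interval$end)) {
    eq_abort("interval `start` must be <= `end`.", "eq_interval_error")
  }
  interval$end - interval$start + 1
}

#' Published ZRS coordinates
#'
#' The chicken (galGal6) and human (hg38) ZRS enhancer intervals as
#' published, for coordinate arithmetic checks.
#'
#' @return A [genomic_interval()] tibble with rows `cZRS` and `hZRS`.
#' @export
zrs_intervals <- function() {
  genomic_interval(
    name = c("cZRS", "hZRS"),
    chrom = c("chr2", "chr7"),
    start = c(8553160, 156791072),
    end = c(8554532, 156792269)
  )
}

#' Enhancer fragment specifications
#'
#' A fragment spec lists the ordered components of a deletion construct,
#' either as bare lengths (for a length audit) or as `start`/`end`
#' subsequence intervals of a source sequence (for assembly).
#'
#' @param name Construct name.
#' @param components A data frame with a `label` column and either a
#'   `length` column (bp) or `start`/`end` columns.
#' @param printed_total Optional published total length, kept alongside the
#'   computed total so discrepancies can be audited rather than silently
#'   resolved.
#' @return An object of class `fragment_spec`.
#' @export
fragment_spec <- function(name, components, printed_total = NA_real_) {
  components <- as_tibble(components)
  if (!"label" %in% names(components)) {
    eq_abort("fragment components need a `label` column.", "eq_fragment_error")
  }
  if (!("length" %in% names(components)) &&
      !all(c("start", "end") %in% names(components))) {
    eq_abort("fragment components need `length` or `start`/`end` columns.",
             "eq_fragment_error")
  }
  structure(list(name = name, components = components,
                 printed_total = printed_total),
            class = "fragment_spec")
}

#' Assemble (or length-audit) a fragment construct
#'
#' Concatenates the spec's components in order. With a source sequence and
#' `start`/`end` components the actual subsequence is returned; with
#' lengths-only components (or no source) only the total length audit is
#' performed.
#'
#' @param spec A [fragment_spec()].
#' @param source Optional source DNA string the `start`/`end` components
#'   refer to.
#' @return A list with `name`, `sequence` (or `NULL` in lengths-only mode)
#'   and `length` (the computed total in bp).
#' @examples
#' f3 <- fragment_spec("F3", tibble::tibble(
#'   label = c("3prime_subdomain", "adjacent_3prime"), length = c(236, 66)))
#' assemble_fragment(f3)$length # 302
#' @export
assemble_fragment <- function(spec, source = NULL) {
  stopifnot(inherits(spec, "fragment_spec"))
  comp <- spec$components
  if (nrow(comp) == 0) {
    return(list(name = spec$name, sequence = "", length = 0))
  }
  has_coords <- all(c("start", "end") %in% names(comp))
  if (has_coords) {
    if (any(comp$start < 1) || any(comp$start > comp$end)) {
      eq_abort(sprintf("fragment '%s': invalid component coordinates.", spec$name),
               "eq_fragment_error")
    }
    lens <- comp$end - comp$start + 1
  } else {
    lens <- comp$length
    if (any(!is.finite(lens)) || any(lens < 0)) {
      eq_abort(sprintf("fragment '%s': invalid component lengths.", spec$name),
               "eq_fragment_error")
    }
  }
  sequence <- NULL
  if (!is.null(source) && has_coords) {
    source <- str_to_upper(source)
    if (any(comp$end > nchar(source))) {
      eq_abort(sprintf("fragment '%s': component beyond the %d bp source.",
                       spec$name, nchar(source)),
               "eq_fragment_error")
    }
    sequence <- paste(str_sub(source, comp$start, comp$end), collapse = "")
  }
  list(name = spec$name, sequence = sequence, length = sum(lens))
}

#' Published construct catalogue for the ZRS fragment series
#'
#' The six deletion/recombination constructs (F1, F2, F3, F1F2, F2F3, F1F3)
#' with their published component lengths and published totals. Two entries
#' are internally inconsistent as published: F2's printed total
#' (309 bp) exceeds its printed components (236 + 60 + 11 = 307 bp; an
#' alternative published figure of 13 bp for the last piece would reconcile),
#' and F1F2's printed total (1065 bp) does not match 749 + 236 + 11 = 996 bp.
#' [fragment_audit()] reports both numbers rather than choosing.
#'
#' @return A named list of [fragment_spec()] objects.
#' @export
zrs_fragments <- function() {
  fr <- function(name, labels, lengths, printed) {
    fragment_spec(name, tibble(label = labels, length = lengths),
                  printed_total = printed)
  }
  list(
    F1 = fr("F1", c("5prime_subdomain", "upstream_DNA"), c(168, 581), 749),
    F2 = fr("F2", c("central_subdomain", "adjacent_5prime", "adjacent_3prime"),
            c(236, 60, 11), 309),
    F3 = fr("F3", c("3prime_subdomain", "adjacent_3prime_DNA"), c(236, 66), 302),
    F1F2 = fr("F1F2", c("F1", "central_subdomain", "adjacent_3prime"),
              c(749, 236, 11), 1065),
    F2F3 = fr("F2F3",
              c("central_subdomain", "3prime_subdomain",
                "adjacent_5prime", "adjacent_3prime_DNA"),
              c(236, 253, 60, 66), 615),
    F1F3 = fr("F1F3", c("5prime_subdomain", "upstream_DNA", "F3"),
              c(175, 581, 302), 1058)
  )
}

#' Audit fragment lengths against published totals
#'
#' @param specs A list of [fragment_spec()] objects; defaults to the ZRS
#'   construct catalogue of [zrs_fragments()].
#' @return A tibble with `name`, `printed_total`, `computed_total`,
#'   `consistent` and `discrepancy_bp` (printed minus computed).
#' @export
fragment_audit <- function(specs = zrs_fragments()) {
  rows <- map(specs, function(sp) {
    total <- assemble_fragment(sp)$length
    tibble(name = sp$name,
           printed_total = sp$printed_total,
           computed_total = total,
           consistent = isTRUE(sp$printed_total == total),
           discrepancy_bp = sp$printed_total - total)
  })
  bind_rows(rows)
}
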