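#' Scan a sequence for an IUPAC motif
#'
#' Reports every (possibly overlapping) match of an IUPAC degenerate motif,
#' such as the E-box `CANNTG` or the Hox core `YAATAAAA`, on one or both
#' strands. Minus-strand hits are reported in plus-strand coordinates
#' (1-based start of the occupied interval); `matched` is the strand-local
#' sequence, i.e. the reverse complement of the plus-strand window for
#' minus-strand hits, so it always satisfies the motif.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param motif IUPAC pattern string.
#' @param motif_name Name recorded with each hit; defaults to the pattern.
#' @param both_strands Scan the minus strand as well (default `TRUE`).
#' @return A tibble with columns `position`, `strand`, `matched`,
#'   `motif_name`, sorted by position.
#' @examples
#' scan_motif("CAGATGA", "CANNTG")
#' @export
scan_motif <- function(sequence, motif, motif_name = motif, both_strands = TRUE) {
  sequence <- str_to_upper(sequence)
  motif <- str_to_upper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    eq_abort(sprintf("invalid IUPAC character '%s' in motif.", bad[1]),
             "eq_motif_error")
  }
  if (!grepl("^[ACGTN]*$", sequence)) {
    eq_abort("`sequence` must be over A/C/G/T/N.", "eq_motif_error")
  }
  subj <- DNAString(sequence)
  pat <- DNAString(motif)
  k <- nchar(motif)

  collect <- function(pattern, strand) {
    hits <- matchPattern(pattern, subj, fixed = "subject")
    if (length(hits) == 0) {
      return(NULL)
    }
    pos <- Biostrings::start(hits)
    matched <- str_sub(sequence, pos, pos + k - 1)
    if (strand == "-") {
      matched <- reverse_complement(matched)
    }
    tibble(position = pos, strand = strand, matched = matched,
           motif_name = motif_name)
  }
  out <- collect(pat, "+")
  if (both_strands) {
    out <- bind_rows(out, collect(reverseComplement(pat), "-"))
  }
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(position = integer(0), strand = character(0),
                  matched = character(0), motif_name = character(0)))
  }
  arrange(out, .data$position, .data$strand)
}

#' Site-directed mutation specification
#'
#' Describes an in-silico substitution that disrupts a binding site: the
#' replacement has the same length as the target interval (no indels), and
#' the mutagenesis strategy modelled here alters 3-4 core bases while
#' introducing a restriction site for colony screening.
#'
#' @param name Mutation name (e.g. `"Ebox2_mut"`).
#' @param start,end 1-based inclusive target interval in the construct.
#' @param replacement Replacement sequence of length `end - start + 1`.
#' @param restriction_site Recognition sequence introduced for screening
#'   (e.g. `"GAATTC"` for EcoRI); optional.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(name, start, end, replacement, restriction_site = NULL) {
  check_number(start, "start", min = 1, integerish = TRUE)
  check_number(end, "end", min = start, integerish = TRUE)
  replacement <- str_to_upper(replacement)
  if (nchar(replacement) != end - start + 1) {
    eq_abort(sprintf("mutation '%s': replacement length %d != interval length %d (substitution only, no indels).",
                     name, nchar(replacement), end - start + 1),
             "eq_mutation_error")
  }
  if (!grepl("^[ACGT]+$", replacement)) {
    eq_abort(sprintf("mutation '%s': replacement must be over A/C/G/T.", name),
             "eq_mutation_error")
  }
  structure(list(name = name, start = as.integer(start), end = as.integer(end),
                 replacement = replacement,
                 restriction_site = restriction_site),
            class = "mutation_spec")
}

#' Apply a substitution mutation to a sequence
#'
#' @param sequence DNA string.
#' @param spec A [mutation_spec()].
#' @param check_core If `TRUE`, require the substitution to alter 3-4 bases
#'   (the core-base rule used for binding-site knockouts); default `FALSE`.
#' @return The mutated sequence (uppercase). Its Hamming distance to the
#'   input equals the number of bases the spec actually alters; a
#'   replacement identical to the original is a no-op error.
#' @examples
#' m <- mutation_spec("Ebox_ko", 1, 6, "CTTCAG", "GAATTC")
#' apply_mutation("CAGATGAAA", m)
#' @export
apply_mutation <- function(sequence, spec, check_core = FALSE) {
  stopifnot(inherits(spec, "mutation_spec"))
  sequence <- str_to_upper(sequence)
  if (spec$end > nchar(sequence)) {
    eq_abort(sprintf("mutation '%s': interval [%d, %d] outside the %d bp sequence.",
                     spec$name, spec$start, spec$end, nchar(sequence)),
             "eq_mutation_error")
  }
  original <- str_sub(sequence, spec$start, spec$end)
  altered <- sum(strsplit(original, "")[[1]] != strsplit(spec$replacement, "")[[1]])
  if (altered == 0) {
    eq_abort(sprintf("mutation '%s' is a no-op: replacement equals the original.",
                     spec$name),
             "eq_mutation_error")
  }
  if (check_core && (altered < 3 || altered > 4)) {
    eq_abort(sprintf("mutation '%s' alters %d bases; the core-base rule requires 3-4.",
                     spec$name, altered),
             "eq_mutation_error")
  }
  out <- sequence
  str_sub(out, spec$start, spec$end) <- spec$replacement
  out
}

#' Verify an in-silico binding-site mutation
#'
#' Checks the three acceptance rules of a site-directed binding-site
#' knockout: (a) no match of any destroyed motif remains overlapping the
#' mutated positions, (b) the screening restriction site is present in the
#' mutant but absent from the original, and (c) no new match of any
#' forbidden motif (sites relevant to the system under study) appears
#' anywhere in the mutant that is absent from the original.
#'
#' @param original,mutated Same-length DNA strings.
#' @param destroyed_motifs Character vector of IUPAC patterns the mutation
#'   must destroy at the mutated site.
#' @param forbidden_new_motifs IUPAC patterns that must not gain new
#'   occurrences anywhere.
#' @param restriction_site Screening recognition sequence; scanned on both
#'   strands.
#' @return A list of class `mutation_check`: `pass` plus per-rule logicals
#'   (`site_destroyed`, `restriction_added`, `no_new_sites`) and a
#'   `violations` tibble (`rule`, `motif`, `position`, `strand`).
#' @export
verify_mutation <- function(original, mutated,
                            destroyed_motifs,
                            forbidden_new_motifs = character(0),
                            restriction_site = NULL) {
  original <- str_to_upper(original)
  mutated <- str_to_upper(mutated)
  if (nchar(original) != nchar(mutated)) {
    eq_abort("`original` and `mutated` must have equal length.",
             "eq_mutation_error")
  }
  changed <- which(strsplit(original, "")[[1]] != strsplit(mutated, "")[[1]])
  violations <- list()

  # (a) destroyed motifs must not survive across the mutated positions
  site_destroyed <- TRUE
  for (m in destroyed_motifs) {
    hits <- scan_motif(mutated, m)
    if (nrow(hits) > 0) {
      k <- nchar(m)
      overlaps <- vapply(hits$position, function(p) {
        any(changed >= p & changed <= p + k - 1)
      }, logical(1))
      if (any(overlaps)) {
        site_destroyed <- FALSE
        violations[[length(violations) + 1]] <-
          hits[overlaps, ] %>%
          mutate(rule = "site_destroyed") %>%
          select("rule", motif = "motif_name", "position", "strand")
      }
    }
  }

  # (b) the screening site must be gained by the mutation
  restriction_added <- TRUE
  if (!is.null(restriction_site)) {
    in_mut <- nrow(scan_motif(mutated, restriction_site)) > 0
    in_orig <- nrow(scan_motif(original, restriction_site)) > 0
    restriction_added <- in_mut && !in_orig
    if (!restriction_added) {
      violations[[length(violations) + 1]] <-
        tibble(rule = "restriction_added", motif = restriction_site,
               position = NA_integer_,
               strand = NA_character_)
    }
  }

  # (c) no forbidden motif may gain an occurrence
  no_new_sites <- TRUE
  for (m in forbidden_new_motifs) {
    before <- scan_motif(original, m)
    after <- scan_motif(mutated, m)
    new_hits <- dplyr::anti_join(after, before,
                                 by = c("position", "strand", "motif_name"))
    if (nrow(new_hits) > 0) {
      no_new_sites <- FALSE
      violations[[length(violations) + 1]] <-
        new_hits %>%
        mutate(rule = "no_new_sites") %>%
        select("rule", motif = "motif_name", "position", "strand")
    }
  }

  violations <- if (length(violations) > 0) {
    bind_rows(violations)
  } else {
    tibble(rule = character(0), motif = character(0),
           position = integer(0), strand = character(0))
  }
  structure(
    list(pass = site_destroyed && restriction_added && no_new_sites,
         site_destroyed = site_destroyed,
         restriction_added = restriction_added,
         no_new_sites = no_new_sites,
         n_changed = length(changed),
         violations = violations),
    class = "mutation_check"
  )
}

#' @export
print.mutation_check <- function(x, ...) {
  cat(sprintf("<mutation_check> %s (site_destroyed=%s, restriction_added=%s, no_new_sites=%s, %d bases changed)\n",
              if (x$pass) "PASS" else "FAIL",
              x$site_destroyed, x$restriction_added, x$no_new_sites, x$n_changed))
  if (nrow(x$violations) > 0) print(x$violations)
  invisible(x)
}
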