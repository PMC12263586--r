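# small default frames keep image tests fast
tiny_config <- function(...) {
  sim_config(image_width = 100, image_height = 76, ...)
}

# independent Otsu oracle: brute-force between-class variance over explicit
# subsets (no cumulative-histogram shortcuts); ties broken toward the
# smallest threshold, with a tolerance so fp noise cannot flip a tie
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  cand <- u[-length(u)]
  between <- vapply(cand, function(t) {
    lo <- values[values <= t]
    hi <- values[values > t]
    w0 <- length(lo) / length(values)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  best <- max(between)
  min(cand[between >= best - 1e-9 * max(best, 1)])
}

# position-by-position IUPAC matcher
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_scan <- function(sequence, motif, both_strands = TRUE) {
  seq_chars <- strsplit(sequence, "")[[1]]
  scan_one <- function(pat_chars) {
    k <- length(pat_chars)
    hits <- integer(0)
    for (p in seq_len(length(seq_chars) - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!seq_chars[p + j - 1] %in% IUPAC_SETS[[pat_chars[j]]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, p)
    }
    hits
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  pat <- strsplit(toupper(motif), "")[[1]]
  hit_df <- function(pos, strand) {
    data.frame(position = pos, strand = rep(strand, length(pos)))
  }
  out <- hit_df(scan_one(pat), "+")
  if (both_strands) {
    rc_pat <- rev(unname(comp[pat]))
    out <- rbind(out, hit_df(scan_one(rc_pat), "-"))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

rc_str <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}
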