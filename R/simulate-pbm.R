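#' Simulate a protein binding microarray 8-mer intensity table
#'
#' Generates a complete UniProbe-style intensity landscape over all 65,536
#' DNA 8-mers with a known optimum: the expected intensity of an 8-mer with
#' `m` mismatches to the consensus (counting the fewer of the mismatches to
#' the consensus or to its reverse complement, since PBM signal is
#' double-stranded) is `optimal_intensity * decay_per_mismatch^m`.
#' Multiplicative lognormal noise with coefficient of variation `noise_cv`
#' is shared between each 8-mer and its reverse complement, so the table is
#' exactly reverse-complement symmetric, as UniProbe tables are.
#'
#' @param consensus The optimal 8-mer, a string over A/C/G/T.
#' @param optimal_intensity Median signal intensity of the consensus
#'   (arbitrary fluorescence units, > 0).
#' @param decay_per_mismatch Multiplicative intensity decay per mismatch,
#'   in (0, 1).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the noise-free closed-form landscape).
#' @param seed Integer seed.
#' @param factor_name Name of the simulated transcription factor.
#' @return A [pbm_table()] with 65,536 rows.
#' @examples
#' tab <- simulate_pbm_table("TAATAAAA", noise_cv = 0, seed = 1)
#' optimal_intensity(tab)
#' @export
simulate_pbm_table <- function(consensus,
                               optimal_intensity = 5000,
                               decay_per_mismatch = 0.45,
                               noise_cv = 0.15,
                               seed = 1L,
                               factor_name = "synthetic_tf") {
  consensus <- str_to_upper(consensus)
  if (nchar(consensus) != 8 || !grepl("^[ACGT]{8}$", consensus)) {
    eq_abort("`consensus` must be an 8-mer over A/C/G/T.", "eq_config_error")
  }
  check_number(optimal_intensity, "optimal_intensity", min = .Machine$double.eps)
  check_number(decay_per_mismatch, "decay_per_mismatch",
               min = 1e-12, max = 1 - 1e-12)
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(seed, "seed", integerish = TRUE)

  digits <- kmer_digit_matrix(8)
  cons_d <- kmer_to_digits(consensus)
  rc_cons_d <- rev(3L - cons_d)
  mm_fwd <- rowSums(digits != matrix(cons_d, nrow(digits), 8, byrow = TRUE))
  mm_rev <- rowSums(digits != matrix(rc_cons_d, nrow(digits), 8, byrow = TRUE))
  m <- pmin(mm_fwd, mm_rev)

  intensity <- optimal_intensity * decay_per_mismatch^m
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    set.seed(seed)
    z <- rlnorm(nrow(digits), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    # one draw per reverse-complement pair keeps the table RC-symmetric
    canonical <- pmin(seq_len(nrow(digits)) - 1, rc_index(digits))
    intensity <- intensity * z[canonical + 1]
  }

  # the enumeration already covers every 8-mer and is RC-symmetric by
  # construction, so no reverse-complement expansion is needed
  pbm_table(tibble(kmer = kmers_from_digits(digits), intensity = intensity),
            factor_name = factor_name, expand = FALSE)
}
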