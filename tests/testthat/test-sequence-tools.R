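test_that("interval lengths reproduce the published enhancer sizes", {
  zrs <- zrs_intervals()
  lens <- interval_length(zrs)
  expect_equal(lens[zrs$name == "cZRS"], 1373)
  expect_equal(lens[zrs$name == "hZRS"], 1198)
  expect_equal(interval_length(5, 5), 1)
  expect_error(genomic_interval("chr1", 10, 5), class = "eq_interval_error")
})

test_that("fragment assembly sums component lengths and concatenates subsequences", {
  audit <- fragment_audit()
  get <- function(n, col) audit[[col]][audit$name == n]
  expect_equal(get("F3", "computed_total"), 302)
  expect_true(get("F3", "consistent"))
  expect_equal(get("F1F3", "computed_total"), 1058)
  expect_true(get("F1F3", "consistent"))
  expect_equal(get("F2F3", "computed_total"), 615)
  expect_true(get("F2F3", "consistent"))
  expect_equal(get("F1", "computed_total"), 749)
  # the published F2 and F1F2 totals disagree with their published
  # components; the audit reports the discrepancy instead of resolving it
  expect_false(get("F2", "consistent"))
  expect_equal(get("F2", "printed_total"), 309)
  expect_equal(get("F2", "computed_total"), 307)
  expect_false(get("F1F2", "consistent"))
  expect_equal(get("F1F2", "discrepancy_bp"), 1065 - 996)

  # sequence mode concatenates in listed order
  spec <- fragment_spec("toy", tibble::tibble(label = c("a", "b"),
                                              start = c(1, 7), end = c(3, 9)))
  out <- assemble_fragment(spec, source = "AAACCCGGGTTT")
  expect_equal(out$sequence, "AAAGGG")
  expect_equal(out$length, 6)
  empty <- assemble_fragment(fragment_spec("none", tibble::tibble(
    label = character(0), length = numeric(0))))
  expect_equal(empty$length, 0)
  bad <- fragment_spec("bad", tibble::tibble(label = "a", start = 10, end = 20))
  expect_error(assemble_fragment(bad, source = "ACGT"), class = "eq_fragment_error")
})

test_that("k-mer enumeration counts 4^k and lists each word once", {
  expect_equal(kmer_count(8), 65536)
  expect_equal(length(enumerate_kmers(8)), 65536)
  expect_equal(enumerate_kmers(1), c("A", "C", "G", "T"))
  two <- enumerate_kmers(2)
  brute <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             paste0)))
  expect_equal(two, brute)
  expect_false(anyDuplicated(two) > 0)
  expect_error(enumerate_kmers(0), "k")
})

test_that("motif scanning finds E-box and Hox motifs with strand bookkeeping", {
  hits <- scan_motif("CAGATG", "CANNTG", motif_name = "Ebox")
  expect_equal(hits$position[hits$strand == "+"], 1)
  expect_equal(hits$matched[hits$strand == "+"], "CAGATG")
  expect_equal(nrow(scan_motif("AAAAAAAA", "CANNTG")), 0)
  # the Hox core: both C and T allowed at the first position
  expect_equal(nrow(scan_motif("GCAATAAAAG", "YAATAAAA",
                               both_strands = FALSE)), 1)
  expect_equal(nrow(scan_motif("GTAATAAAAG", "YAATAAAA",
                               both_strands = FALSE)), 1)
  expect_error(scan_motif("ACGT", "CAXXTG"), class = "eq_motif_error")
})

test_that("motif scanning matches a brute-force oracle on random sequences", {
  set.seed(19)
  for (i in 1:15) {
    seqq <- random_dna(200)
    motif <- sample(c("CANNTG", "YAATAAAA", "GAATTC", "TGANTCA"), 1)
    hits <- scan_motif(seqq, motif)
    oracle <- oracle_scan(seqq, motif)
    expect_equal(hits$position, oracle$position)
    expect_equal(hits$strand, oracle$strand)
    expect_true(all(vapply(seq_len(nrow(hits)), function(j) {
      w <- if (hits$strand[j] == "+") {
        substr(seqq, hits$position[j], hits$position[j] + nchar(motif) - 1)
      } else {
        rc_str(substr(seqq, hits$position[j], hits$position[j] + nchar(motif) - 1))
      }
      w == hits$matched[j]
    }, logical(1))))
  }
})

test_that("minus-strand hits map bijectively to hits on the reverse complement", {
  set.seed(23)
  for (i in 1:10) {
    seqq <- random_dna(150)
    hits <- scan_motif(seqq, "CANNTG")
    rc_hits <- scan_motif(rc_str(seqq), "CANNTG")
    minus <- hits$position[hits$strand == "-"]
    plus_on_rc <- rc_hits$position[rc_hits$strand == "+"]
    expect_setequal(150 - (minus + 6 - 1) + 1, plus_on_rc)
  }
})

test_that("mutations substitute in place with the declared Hamming distance", {
  m <- mutation_spec("ebox_ko", 1, 6, "CTTCAG", "GAATTC")
  out <- apply_mutation("CAGATGAAA", m)
  expect_equal(out, "CTTCAGAAA")
  expect_equal(nchar(out), 9)
  expect_equal(hamming("CAGATG", "CTTCAG"), 4)

  noop <- mutation_spec("noop", 1, 3, "CAG")
  expect_error(apply_mutation("CAGATG", noop), class = "eq_mutation_error")
  far <- mutation_spec("far", 8, 10, "AAA")
  expect_error(apply_mutation("CAGATG", far), class = "eq_mutation_error")
  expect_error(mutation_spec("indel", 1, 3, "AAAA"), class = "eq_mutation_error")
  # the mutagenesis rule: 3-4 core bases altered
  one_base <- mutation_spec("weak", 1, 3, "AAG")
  expect_error(apply_mutation("AAAATG", one_base, check_core = TRUE),
               "3-4")
})

test_that("disjoint mutations commute", {
  m1 <- mutation_spec("a", 1, 4, "TTTT")
  m2 <- mutation_spec("b", 9, 12, "CCCC")
  s <- "AAAAGGGGAAAAGGGG"
  expect_equal(apply_mutation(apply_mutation(s, m1), m2),
               apply_mutation(apply_mutation(s, m2), m1))
})

test_that("mutation verification enforces destruction, screening site and no new sites", {
  original <- "GGGCAGATGGGGAAA"
  spec <- mutation_spec("ebox_ko", 4, 9, "GAATTC", "GAATTC")
  mutated <- apply_mutation(original, spec)
  rep <- verify_mutation(original, mutated,
                         destroyed_motifs = "CANNTG",
                         forbidden_new_motifs = "CANNTG",
                         restriction_site = "GAATTC")
  expect_true(rep$pass)
  expect_true(rep$site_destroyed && rep$restriction_added && rep$no_new_sites)

  # a mutation that creates a forbidden E-box elsewhere fails with position
  orig2 <- "GGGCAGATGGGGTAA"
  mut2 <- "GGGGAATTCCATTTG" # gains GAATTC but also a new CATTTG E-box
  rep2 <- verify_mutation(orig2, mut2,
                          destroyed_motifs = "CANNTG",
                          forbidden_new_motifs = "CANNTG",
                          restriction_site = "GAATTC")
  expect_false(rep2$pass)
  expect_false(rep2$no_new_sites)
  expect_true(any(rep2$violations$rule == "no_new_sites" &
                    !is.na(rep2$violations$position)))

  # an unchanged sequence cannot pass: the screening site is not gained
  rep3 <- verify_mutation(original, original, destroyed_motifs = character(0),
                          restriction_site = "GAATTC")
  expect_false(rep3$pass)
  expect_false(rep3$restriction_added)
  expect_error(verify_mutation("AAA", "AAAA", "CANNTG"),
               class = "eq_mutation_error")
})
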