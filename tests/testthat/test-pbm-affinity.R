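test_that("table loading expands reverse complements and reports parse errors by line", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("8mer\tHoxd13", "AAAAAAAC\t10", "CCCCCCCC\t4"), f)
  tab <- load_pbm_table(f)
  expect_equal(attr(tab, "factor_name"), "Hoxd13")
  expect_equal(nrow(tab), 4) # both entries gain their reverse complement
  expect_equal(tab$intensity[tab$kmer == "GTTTTTTT"], 10)

  # a collapsed pair sharing one intensity is accepted
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("8mer\tTF", "AAAAAAAA\t10", "TTTTTTTT\t10"), f2)
  tab2 <- load_pbm_table(f2)
  expect_equal(unique(tab2$intensity), 10)
  expect_setequal(tab2$kmer, c("AAAAAAAA", "TTTTTTTT"))

  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("8mer\tTF", "AAAAAAAA\t10", "AAAAAAAN\t3"), f3)
  expect_error(load_pbm_table(f3), "line 3")

  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("8mer\tTF", "AAAAAAAA\t10", "TTTTTTTT\t11"), f4)
  expect_error(load_pbm_table(f4), class = "eq_pbm_parse_error")
})

test_that("the optimal 8-mer is the maximum with lexicographic tie-breaking", {
  tab <- pbm_table(tibble::tibble(kmer = c("AAAAAAAA", "CAAAAAAA", "GGGGGGGG"),
                                  intensity = c(1, 5, 2)))
  opt <- optimal_intensity(tab)
  expect_equal(opt$intensity, 5)
  expect_equal(opt$kmer, "CAAAAAAA")
  expect_false(opt$tie)

  flat <- pbm_table(tibble::tibble(kmer = c("AAAAAAAA", "CCCCCCCC", "GGAATTCC"),
                                   intensity = c(3, 3, 3)))
  optf <- optimal_intensity(flat)
  expect_equal(optf$kmer, "AAAAAAAA")
  expect_true(optf$tie)
})

test_that("relative affinity is the intensity ratio to the optimum", {
  tab <- simulate_pbm_table("TAATAAAA", decay_per_mismatch = 0.5,
                            noise_cv = 0, seed = 1)
  expect_equal(relative_affinity(tab, "TAATAAAA"), 1)
  expect_equal(relative_affinity(tab, "TAATAATT"), 0.25) # two mismatches
  expect_error(relative_affinity(tab[1:10, ], "TAATAAAA"),
               class = "eq_missing_kmer_error")
})

test_that("relative affinity matches a brute-force re-read of the raw file", {
  tab <- simulate_pbm_table("CTAATAAA", noise_cv = 0.2, seed = 3,
                            factor_name = "Hoxd13")
  f <- tempfile(fileext = ".tsv")
  write_pbm_table(tab, f, collapse = TRUE)
  reloaded <- load_pbm_table(f)
  raw <- read.delim(f, stringsAsFactors = FALSE)
  names(raw) <- c("kmer", "intensity")
  opt <- max(raw$intensity)
  set.seed(12)
  for (k in sample(raw$kmer, 20)) {
    expect_equal(relative_affinity(reloaded, k), raw$intensity[raw$kmer == k] / opt)
  }
})

test_that("site affinity maximizes over admitted windows and honours the policy", {
  tab <- simulate_pbm_table("TAATAAAA", decay_per_mismatch = 0.5,
                            noise_cv = 0, seed = 1)
  seqq <- paste0("GGCGGCGG", "TAATAAAA", "GGCGGCGG")
  # an exactly-8-bp site under full containment has one window
  res <- site_relative_affinity(tab, seqq, list(name = "s", start = 9, end = 16),
                                window_policy = "contained")
  expect_equal(res$value, 1)
  expect_equal(res$kmer, "TAATAAAA")
  expect_equal(res$window_start, 9)
  # a planted consensus always scores 1 under the default policy
  res2 <- site_relative_affinity(tab, seqq, list(name = "s", start = 9, end = 16))
  expect_equal(res2$value, 1)
  expect_error(site_relative_affinity(tab, seqq, list(name = "s", start = 30, end = 35)),
               class = "eq_site_error")
})

test_that("site affinity equals a brute-force window enumeration oracle", {
  tab <- simulate_pbm_table("TAATAAAA", noise_cv = 0.25, seed = 7)
  lookup <- setNames(tab$intensity, tab$kmer)
  opt <- max(tab$intensity)
  set.seed(9)
  for (i in 1:20) {
    seqq <- random_dna(60)
    s <- sample(5:50, 1)
    e <- min(60, s + sample(5:8, 1))
    res <- site_relative_affinity(tab, seqq, list(name = "r", start = s, end = e))
    # oracle: enumerate every window overlapping [s, e] by >= 6 bases
    best <- 0
    for (w in 1:(60 - 7)) {
      ov <- min(w + 7, e) - max(w, s) + 1
      if (ov < 6) next
      word <- substr(seqq, w, w + 7)
      v <- lookup[word]
      if (is.na(v)) v <- lookup[rc_str(word)]
      best <- max(best, v / opt)
    }
    expect_equal(res$value, unname(best))
  }
})

test_that("site affinity is reverse-complement symmetric", {
  tab <- simulate_pbm_table("TAATAAAA", noise_cv = 0.2, seed = 11)
  set.seed(14)
  for (i in 1:10) {
    seqq <- random_dna(50)
    s <- sample(5:40, 1); e <- s + 7
    fwd <- site_relative_affinity(tab, seqq, list(name = "f", start = s, end = e))
    rc_seq <- rc_str(seqq)
    rc_start <- 50 - e + 1
    rev <- site_relative_affinity(tab, rc_seq,
                                  list(name = "r", start = rc_start,
                                       end = rc_start + 7))
    expect_equal(fwd$value, rev$value)
  }
})

test_that("noise-free site affinity decreases strictly with planted mismatches", {
  tab <- simulate_pbm_table("TAATAAAA", decay_per_mismatch = 0.45,
                            noise_cv = 0, seed = 1)
  planted <- c("TAATAAAA", "TACTAAAA", "TACTGAAA", "TACTGCAA")
  pad <- "GGCGGCGGCC"
  vals <- vapply(planted, function(p) {
    seqq <- paste0(pad, p, pad)
    site_relative_affinity(tab, seqq,
                           list(name = p, start = 11, end = 18))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(unname(vals[1]), 1)
})

test_that("the affinity matrix keeps ordering, NA rows and permutation equivariance", {
  tab1 <- simulate_pbm_table("TAATAAAA", noise_cv = 0, seed = 1,
                             factor_name = "Hoxd13")
  tab2 <- simulate_pbm_table("CACCTGCC", noise_cv = 0, seed = 2,
                             factor_name = "Snai1")
  seqq <- paste0("GGCGGCGG", "TAATAAAA", "GGCGGCGGCC", "CACCTGCC", "GGCGGCGG")
  sites <- tibble::tibble(name = c("hox_site", "ebox_site"),
                          start = c(9, 27), end = c(16, 34))
  am <- build_affinity_matrix(list(Hoxd13 = tab1, Snai1 = tab2, Hand2 = NULL),
                              seqq, sites)
  m <- as.matrix(am)
  expect_equal(dim(m), c(3, 2))
  expect_equal(m["Hoxd13", "hox_site"], 1)
  expect_equal(m["Snai1", "ebox_site"], 1)
  expect_true(all(is.na(m["Hand2", ])))
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  expect_equal(tidy(am)$note[tidy(am)$factor == "Hand2"],
               rep("no PBM data", 2))

  am_perm <- build_affinity_matrix(list(Hoxd13 = tab1, Snai1 = tab2, Hand2 = NULL),
                                   seqq, sites[2:1, ])
  expect_equal(as.matrix(am_perm), m[, 2:1])

  # single factor x single site equals the scalar call
  am1 <- build_affinity_matrix(list(Hoxd13 = tab1), seqq, sites[1, ])
  expect_equal(as.matrix(am1)[1, 1],
               site_relative_affinity(tab1, seqq, sites[1, ])$value)
})

test_that("heatmap rendering writes a decodable image", {
  tab1 <- simulate_pbm_table("TAATAAAA", noise_cv = 0, seed = 1,
                             factor_name = "Hoxd13")
  sites <- tibble::tibble(name = "s1", start = 3, end = 10)
  am <- build_affinity_matrix(list(Hoxd13 = tab1, Hand2 = NULL),
                              paste0("GG", "TAATAAAA", "GG"), sites)
  f <- tempfile(fileext = ".png")
  render_heatmap(am, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  img <- png::readPNG(f)
  expect_gte(length(dim(img)), 2)
})
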