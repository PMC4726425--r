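test_that("window centering uses floor placement and flags clipping", {
  w <- build_window_a("c1", 300L, 600L, 10000L)
  expect_equal(c(w$start, w$end), c(0L, 600L))
  expect_false(w$clipped)

  w2 <- build_window_a("c1", 100L, 600L, 10000L)
  expect_equal(c(w2$start, w2$end), c(0L, 400L))
  expect_true(w2$clipped)

  w3 <- build_window_a("c1", 5000L, 500L, 10000L)
  expect_equal(c(w3$start, w3$end), c(4750L, 5250L))

  expect_error(build_window_a("c1", 20000L, 500L, 10000L), "outside")
})

test_that("scheme-1 window-B collection applies the distance exclusion", {
  clens <- c(c1 = 100000L)
  cfg <- neighborhood_config(window_size = 600L)
  lib <- contact_library(toy_contacts(c("c1", 9800L, "c1", 50000L)))
  wa <- list(chrom = "c1", start = 9700L, end = 10300L, clipped = FALSE)
  wbs <- collect_window_bs_b1("c1", 10000L, wa, lib, cfg, clens)
  expect_equal(nrow(wbs), 1L)
  expect_equal(c(wbs$start, wbs$end), c(49700L, 50300L))

  # other end too close: nearest edge 600 nt from the site -> excluded
  lib2 <- contact_library(toy_contacts(c("c1", 9800L, "c1", 10900L)))
  expect_equal(nrow(collect_window_bs_b1("c1", 10000L, wa, lib2, cfg, clens)), 0L)

  # no contact end in window-A -> empty
  lib3 <- contact_library(toy_contacts(c("c1", 60000L, "c1", 80000L)))
  expect_equal(nrow(collect_window_bs_b1("c1", 10000L, wa, lib3, cfg, clens)), 0L)

  # inter-chromosomal partner is retained regardless of position
  clens2 <- c(c1 = 100000L, c2 = 100000L)
  lib4 <- contact_library(toy_contacts(c("c1", 9800L, "c2", 10000L)))
  expect_equal(collect_window_bs_b1("c1", 10000L, wa, lib4, cfg, clens2)$chrom,
               "c2")
})

test_that("scheme-2 collection keeps only long-range contacts through the range", {
  clens <- c(c1 = 1000000L)
  cfg <- neighborhood_config(window_size = 600L, hic_range = 10000L)
  lib <- contact_library(toy_contacts(
    c("c1", 98000L, "c1", 150000L),   # sep 52000 > 10000 -> in
    c("c1", 98000L, "c1", 104000L),   # sep 6000 <= 10000 -> out
    c("c1", 300000L, "c1", 400000L))) # neither end in range -> out
  wbs <- collect_window_bs_b2("c1", 100000L, lib, cfg, clens)
  expect_equal(nrow(wbs), 1L)
  expect_equal(c(wbs$start, wbs$end), c(149700L, 150300L))
})

test_that("indexed contact queries equal a brute-force linear scan", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(50:400, 1L)
    con <- data.frame(
      chrom_a = sample(c("c1", "c2"), n, replace = TRUE),
      pos_a = sample.int(5000L, n, replace = TRUE) - 1L,
      chrom_b = sample(c("c1", "c2"), n, replace = TRUE),
      pos_b = sample.int(5000L, n, replace = TRUE) - 1L,
      stringsAsFactors = FALSE)
    lib <- contact_library(con)
    for (q in 1:10) {
      s <- sample.int(4500L, 1L) - 1L
      e <- s + sample.int(500L, 1L)
      chrom <- sample(c("c1", "c2"), 1L)
      cc <- lib$contacts
      brute <- which((cc$chrom_a == chrom & cc$pos_a >= s & cc$pos_a < e) |
                     (cc$chrom_b == chrom & cc$pos_b >= s & cc$pos_b < e))
      expect_identical(query_contacts(lib, chrom, s, e), brute)
    }
  }
})

test_that("random control windows avoid the Hi-C range and its contacts", {
  clens <- c(c1 = 200000L)
  cfg <- neighborhood_config(window_size = 500L, hic_range = 10000L)
  # contacts anchored in the range with partners scattered on c1
  set.seed(5)
  anchors <- sample(95000:105000, 30L)
  partners <- sample(c(1:80000, 120000:199000), 30L)
  lib <- contact_library(data.frame(chrom_a = "c1", pos_a = anchors,
                                    chrom_b = "c1", pos_b = partners))
  expect_equal(nrow(sample_random_windows("c1", 100000L, lib, cfg, clens, 0L)),
               0L)
  set.seed(7)
  w <- sample_random_windows("c1", 100000L, lib, cfg, clens, 40L)
  expect_equal(nrow(w), 40L)
  # exhaustive post-hoc checks
  expect_true(all(w$end <= 95000L | w$start >= 105000L))
  for (i in seq_len(nrow(w)))
    expect_false(any(partners >= w$start[i] & partners < w$end[i]))
  # determinism under a fixed seed
  set.seed(7)
  expect_identical(sample_random_windows("c1", 100000L, lib, cfg, clens, 40L), w)
  # zero-contact library: every window passes the contact check
  set.seed(8)
  no_contacts <- contact_library(data.frame(
    chrom_a = character(0), pos_a = integer(0),
    chrom_b = character(0), pos_b = integer(0)))
  w2 <- sample_random_windows("c1", 100000L, no_contacts, cfg, clens, 5L)
  expect_equal(nrow(w2), 5L)
})

test_that("Hi-C coverage is reads x length / genome and monotone", {
  expect_equal(hic_coverage(10, 100, 1000), 1.0)
  expect_equal(hic_coverage(1, 36, 3e9), 1.2e-8)
  expect_true(hic_coverage(20, 36, 3e9) > hic_coverage(10, 36, 3e9))
  expect_error(hic_coverage(10, 100, 0), "positive")
})
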