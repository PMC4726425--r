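test_that("island boost enriches CG dinucleotides in hypo domains", {
  cfg0 <- synth_config(genome_length = 100000L, n_chroms = 1L,
                       island_gc_boost = 1, seed = 81L)
  cfg3 <- synth_config(genome_length = 100000L, n_chroms = 1L,
                       island_gc_boost = 3, seed = 81L)
  cg_freq_by_type <- function(cfg) {
    set.seed(cfg$seed)
    g <- simulate_genome(cfg)
    expect_equal(sum(g$domains$end - g$domains$start),
                 unname(sum(Biostrings::width(g$genome))))
    s <- g$genome[[1L]]
    vapply(c("hypo", "hyper"), function(ty) {
      d <- g$domains[g$domains$type == ty, , drop = FALSE]
      hits <- 0L; len <- 0L
      for (i in seq_len(nrow(d))) {
        sub <- Biostrings::subseq(s, d$start[i] + 1L, d$end[i])
        hits <- hits + Biostrings::countPattern("CG", sub)
        len <- len + length(sub)
      }
      hits / len
    }, numeric(1L))
  }
  f0 <- cg_freq_by_type(cfg0)
  f3 <- cg_freq_by_type(cfg3)
  # no boost: frequencies statistically equal (binomial z-test, alpha 0.001)
  p <- mean(f0)
  z <- abs(f0[["hypo"]] - f0[["hyper"]]) / sqrt(2 * p * (1 - p) / 40000)
  expect_lt(z, 3.3)
  # boost 3: hypo CG frequency at least doubled
  expect_gte(f3[["hypo"]], 2 * f3[["hyper"]])
})

test_that("simulated methylation sits at CG sites with a bimodal histogram", {
  ds <- small_synth()
  g <- ds$genome
  for (i in seq_len(nrow(ds$track))) {
    p <- ds$track$pos[i]
    expect_equal(as.character(Biostrings::subseq(g[[ds$track$chrom[i]]],
                                                 p + 1L, p + 2L)), "CG")
    if (i >= 50L) break   # spot-check; construction is identical for all
  }
  pm <- ds$track$percent_meth
  expect_lt(mean(pm > 0.1 & pm < 0.9), 0.4)
  # hypo domains without noise stay low
  set.seed(91)
  cfg <- synth_config(genome_length = 50000L, n_chroms = 1L, p_hypo = 1,
                      noise_sd = 0, read_depth = 0L, seed = 91L)
  g2 <- simulate_genome(cfg)
  tr2 <- simulate_methylation(g2$genome, g2$domains, cfg)
  expect_true(all(tr2$percent_meth < 0.3))
})

test_that("contacts decay with distance and respect the domain boost", {
  ds <- small_synth()
  d <- abs(ds$contacts$pos_b - ds$contacts$pos_a)
  expect_true(all(d > 1000))
  within_frac <- function(boost, seed) {
    cfg <- synth_config(genome_length = 400000L, n_chroms = 1L,
                        domain_length_mean = 5000L, n_contacts = 1000L,
                        within_domain_contact_boost = boost, seed = seed)
    set.seed(cfg$seed)
    g <- simulate_genome(cfg)
    con <- simulate_contacts(g$genome, g$domains, cfg)
    dom <- methtopo:::domain_of
    same <- mapply(function(c1, p1, p2)
      dom(g$domains, c1, p1) == dom(g$domains, c1, p2),
      con$chrom_a, con$pos_a, con$pos_b)
    mean(same)
  }
  f1 <- within_frac(1, 101L)
  f10 <- within_frac(10, 101L)
  expect_gte(f10, 2 * f1)
})

test_that("a dataset written twice with one seed is byte-identical", {
  cfg <- synth_config(genome_length = 60000L, n_chroms = 2L, cpg_rate = 2,
                      n_contacts = 300L, seed = 77L)
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("genome.fa", "methylation.tsv", "contacts.tsv", "domains.bed",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # every output is readable by the package's own parsers
  g <- read_fasta(file.path(d1, "genome.fa"))
  expect_equal(length(g), 2L)
  tr <- read_methylation_track(file.path(d1, "methylation.tsv"), "simple")
  expect_gt(nrow(tr), 0L)
  con <- read_contacts(file.path(d1, "contacts.tsv"))
  expect_equal(nrow(con), 300L)
  expect_gt(nrow(read_bed(file.path(d1, "domains.bed"))), 0L)
})

test_that("spatial neighbours carry methylation correlated with the target", {
  ds <- small_synth()
  lib <- contact_library(ds$contacts)
  cfg <- neighborhood_config(window_size = 500L, hic_range = 10000L)
  clens <- chrom_lengths(ds$genome)
  midx <- meth_index(ds$track)
  set.seed(111)
  idx <- sample(nrow(ds$track), 150L)
  pairs <- t(vapply(idx, function(i) {
    wbs <- collect_window_bs_b2(ds$track$chrom[i], ds$track$pos[i], lib, cfg,
                                clens)
    if (nrow(wbs) == 0L) return(c(NA_real_, NA_real_))
    avg <- mean(vapply(seq_len(nrow(wbs)), function(k)
      mean_methylation(wbs$chrom[k], wbs$start[k], wbs$end[k], midx)$value,
      numeric(1L)))
    c(ds$track$percent_meth[i], avg)
  }, numeric(2L)))
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  expect_gt(nrow(pairs), 50L)
  expect_gt(stats::cor(pairs[, 1L], pairs[, 2L]), 0.3)
})
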