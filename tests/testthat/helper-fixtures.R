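# Shared fixtures, all built in code.

# Write a tiny FASTA and return its path.
write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  lines <- unlist(lapply(names(records), function(n) c(paste0(">", n),
                                                       records[[n]])))
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(rows, ...) {
  path <- tempfile(fileext = ".tsv")
  writeLines(rows, path)
  path
}

# Deterministic toy genome: one 10 kb chromosome.
toy_genome <- function(len = 10000L, seed = 42L) {
  set.seed(seed)
  s <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- "c1"
  g
}

toy_track <- function(chrom = "c1", pos = c(10L, 20L, 5000L),
                      pm = c(0.2, 0.8, 0.5)) {
  methylation_track(data.frame(chrom = chrom, pos = pos, percent_meth = pm))
}

toy_contacts <- function(...) {
  df <- as.data.frame(rbind(...))
  names(df) <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  df$pos_a <- as.integer(df$pos_a); df$pos_b <- as.integer(df$pos_b)
  df$chrom_a <- as.character(df$chrom_a); df$chrom_b <- as.character(df$chrom_b)
  canonicalize_contacts(df)
}

# Small simulated dataset cached across tests in one session.
.fixture_env <- new.env(parent = emptyenv())
small_synth <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synth_config(genome_length = 300000L, n_chroms = 1L,
                        cpg_rate = 2, n_contacts = 2000L, seed = 123L)
    .fixture_env$small <- simulate_dataset(cfg)
  }
  .fixture_env$small
}
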