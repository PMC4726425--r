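#' Configuration for the synthetic genome / methylation / Hi-C simulator
#'
#' The simulator plants the structure the predictor is meant to exploit:
#' the genome is tiled with methylation domains (hypo- or
#' hyper-methylated), CpG sites inside a domain share its methylation
#' propensity (giving the characteristic bimodal percent-methylation
#' histogram), Hi-C contact distances decay as a power law, and contacts
#' are enriched within domains so that the spatial neighbours of a CpG
#' site carry methylation levels correlated with it. Setting
#' `within_domain_contact_boost = 1` and `island_gc_boost = 1` removes
#' every planted signal and serves as the negative control.
#'
#' @param genome_length Total genome length in nt.
#' @param n_chroms Number of equally sized chromosomes.
#' @param domain_length_mean Mean methylation-domain length in nt
#'   (exponential lengths, 2 kb minimum).
#' @param p_hypo Probability a domain is hypo-methylated.
#' @param cpg_rate Expected retained CpG sites per kb.
#' @param n_contacts Number of Hi-C contact pairs.
#' @param contact_decay_exponent Power-law exponent of the contact
#'   distance distribution (`P(d) ~ d^-gamma`, d > 1 kb).
#' @param within_domain_contact_boost Relative enrichment of contacts
#'   whose two ends fall in the same domain (1 = no enrichment).
#' @param island_gc_boost CG-dinucleotide enrichment factor in
#'   hypo-methylated domains (CpG-island-like sequence; 1 = none).
#' @param noise_sd SD of truncated Gaussian noise added to the domain
#'   methylation propensity.
#' @param read_depth Simulated bisulfite read count per CpG site;
#'   percent-methylation is reported as a binomial fraction of this
#'   depth (0 disables read sampling). Read sampling yields the exact-0
#'   and near-1 values real RRBS tracks contain.
#' @param seed Master seed for the whole dataset.
#' @return List of class `SynthConfig`.
#' @export
synth_config <- function(genome_length = 3000000L, n_chroms = 1L,
                         domain_length_mean = 20000L, p_hypo = 0.5,
                         cpg_rate = 0.4, n_contacts = 20000L,
                         contact_decay_exponent = 1.0,
                         within_domain_contact_boost = 8,
                         island_gc_boost = 3, noise_sd = 0.05,
                         read_depth = 20L, seed = 1L) {
  stopifnot(genome_length > 0, n_chroms >= 1L, domain_length_mean > 0,
            p_hypo >= 0, p_hypo <= 1, cpg_rate > 0, n_contacts >= 0,
            within_domain_contact_boost >= 1, island_gc_boost >= 1,
            noise_sd >= 0, read_depth >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms),
                 domain_length_mean = as.integer(domain_length_mean),
                 p_hypo = p_hypo, cpg_rate = cpg_rate,
                 n_contacts = as.integer(n_contacts),
                 contact_decay_exponent = contact_decay_exponent,
                 within_domain_contact_boost = within_domain_contact_boost,
                 island_gc_boost = island_gc_boost,
                 noise_sd = noise_sd, read_depth = as.integer(read_depth),
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Simulate a domain-structured genome
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. Chromosomes are
#' tiled with exponential-length domains; hypo-methylated domains receive
#' planted CG dinucleotides raising their CG frequency by roughly
#' `island_gc_boost`-fold (CpG-island-like enrichment). Uses the current
#' RNG state; seed with [set.seed()] or call through
#' [simulate_dataset()].
#'
#' @param cfg A `SynthConfig`.
#' @return List with `genome` (named [Biostrings::DNAStringSet]) and
#'   `domains` (data frame chrom, start, end, type).
#' @export
simulate_genome <- function(cfg) {
  clen <- cfg$genome_length %/% cfg$n_chroms
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  dom_rows <- list()
  seqs <- character(cfg$n_chroms)
  for (ci in seq_along(chroms)) {
    # tile domains with exponential lengths (2 kb minimum); the last
    # domain absorbs the chromosome end
    starts <- 0L
    repeat {
      len <- max(2000L, as.integer(stats::rexp(1L, 1 / cfg$domain_length_mean)))
      nxt <- starts[length(starts)] + len
      if (nxt >= clen - 2000L) break
      starts <- c(starts, nxt)
    }
    ends <- c(starts[-1L], clen)
    type <- ifelse(stats::runif(length(starts)) < cfg$p_hypo, "hypo", "hyper")
    s <- sample(c("A", "C", "G", "T"), clen, replace = TRUE)
    if (cfg$island_gc_boost > 1) {
      for (d in which(type == "hypo")) {
        L <- ends[d] - starts[d]
        n_plant <- round((cfg$island_gc_boost - 1) * L / 16)
        if (n_plant > 0L) {
          at <- sample(seq_len(L - 1L), min(n_plant, L %/% 2L))
          s[starts[d] + at] <- "C"
          s[starts[d] + at + 1L] <- "G"
        }
      }
    }
    seqs[ci] <- paste0(s, collapse = "")
    dom_rows[[ci]] <- data.frame(chrom = chroms[ci], start = starts,
                                 end = ends, type = type,
                                 stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  list(genome = genome, domains = do.call(rbind, dom_rows))
}

# global domain row index for positions on one chromosome (domain rows
# are grouped by chromosome in genomic order)
domain_of <- function(domains, chrom, pos) {
  sel <- which(domains$chrom == chrom)
  sel[findInterval(pos, domains$start[sel])]
}

#' Simulate a percent-methylation track over the genome's CpG sites
#'
#' CpG sites are the genome's actual CG dinucleotides, subsampled to
#' `cpg_rate` per kb. Each site draws a propensity from its domain
#' (hypo: Beta(1,20); hyper: Beta(20,1)), adds truncated Gaussian noise,
#' and -- when `read_depth > 0` -- is observed as a binomial read
#' fraction, which produces the exact-0 and exact-1 values the
#' fixed-threshold labeling rule relies on.
#'
#' @param genome,domains Output of [simulate_genome()].
#' @param cfg A `SynthConfig`.
#' @return A `MethylationTrack` with the generating propensity attached
#'   as attribute `"propensity"`.
#' @export
simulate_methylation <- function(genome, domains, cfg) {
  rows <- list()
  for (chrom in names(genome)) {
    hits <- Biostrings::start(Biostrings::matchPattern("CG", genome[[chrom]]))
    pos0 <- hits - 1L                       # 0-based position of the C
    want <- round(cfg$cpg_rate * length(genome[[chrom]]) / 1000)
    if (length(pos0) > want) pos0 <- sort(sample(pos0, want))
    di <- domain_of(domains, chrom, pos0)
    hypo <- domains$type[di] == "hypo"
    prop <- ifelse(hypo, stats::rbeta(length(pos0), 1, 20),
                   stats::rbeta(length(pos0), 20, 1))
    prop <- pmin(pmax(prop + stats::rnorm(length(pos0), 0, cfg$noise_sd), 0), 1)
    pm <- if (cfg$read_depth > 0L) {
      stats::rbinom(length(pos0), cfg$read_depth, prop) / cfg$read_depth
    } else {
      prop
    }
    rows[[chrom]] <- data.frame(chrom = chrom, pos = pos0, percent_meth = pm,
                                read_count = if (cfg$read_depth > 0L)
                                  cfg$read_depth else NA_integer_,
                                propensity = prop,
                                stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  prop <- df$propensity
  df$propensity <- NULL
  track <- methylation_track(df)
  attr(track, "propensity") <- prop
  track
}

#' Simulate Hi-C contacts with distance decay and domain enrichment
#'
#' Anchors are uniform over the genome; the partner lies at a distance
#' drawn from `P(d) ~ d^-gamma` for d > 1 kb (cis). Candidate pairs
#' whose two ends share a methylation domain are accepted preferentially
#' (by factor `within_domain_contact_boost`), planting the correlation
#' between the methylation of a site and of its spatial neighbours.
#'
#' @param genome,domains Output of [simulate_genome()].
#' @param cfg A `SynthConfig`.
#' @return Canonically ordered contact data frame.
#' @export
simulate_contacts <- function(genome, domains, cfg) {
  clens <- chrom_lengths(genome)
  chroms <- names(clens)
  gam <- cfg$contact_decay_exponent
  dmin <- 1000; boost <- cfg$within_domain_contact_boost
  rpow <- function() {
    u <- stats::runif(1L)
    dmax <- max(clens)
    if (abs(gam - 1) < 1e-9) {
      dmin * (dmax / dmin)^u
    } else {
      (dmin^(1 - gam) + u * (dmax^(1 - gam) - dmin^(1 - gam)))^(1 / (1 - gam))
    }
  }
  ca <- character(cfg$n_contacts); cb <- character(cfg$n_contacts)
  pa <- integer(cfg$n_contacts); pb <- integer(cfg$n_contacts)
  for (i in seq_len(cfg$n_contacts)) {
    repeat {
      chrom <- sample(chroms, 1L, prob = clens)
      a <- as.integer(floor(stats::runif(1L, 0, clens[[chrom]])))
      d <- max(1001, ceiling(rpow()))
      b <- if (stats::runif(1L) < 0.5) a - d else a + d
      if (b < 0 || b >= clens[[chrom]]) next
      b <- as.integer(b)
      same <- domain_of(domains, chrom, a) == domain_of(domains, chrom, b)
      if (same || stats::runif(1L) < 1 / boost) {
        ca[i] <- chrom; pa[i] <- a; cb[i] <- chrom; pb[i] <- b
        break
      }
    }
  }
  canonicalize_contacts(data.frame(chrom_a = ca, pos_a = pa,
                                   chrom_b = cb, pos_b = pb,
                                   stringsAsFactors = FALSE))
}

#' Simulate a complete dataset and write it to disk
#'
#' Seeds the RNG from `cfg$seed`, simulates genome, methylation track and
#' contact library, and writes them in the package's standard formats:
#' `genome.fa`, `methylation.tsv` (simple 3-column dialect plus read
#' count), `contacts.tsv` (4-column), `domains.bed` and a
#' `manifest.json` recording the full configuration. The same seed
#' produces byte-identical files.
#'
#' @param cfg A `SynthConfig`.
#' @param dir Output directory (created if missing). `NULL` skips
#'   writing and returns the in-memory objects only.
#' @return Invisibly, a list with `genome`, `domains`, `track`,
#'   `contacts` and the output `paths`.
#' @export
simulate_dataset <- function(cfg = synth_config(), dir = NULL) {
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  track <- simulate_methylation(g$genome, g$domains, cfg)
  contacts <- simulate_contacts(g$genome, g$domains, cfg)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  methylation = file.path(dir, "methylation.tsv"),
                  contacts = file.path(dir, "contacts.tsv"),
                  domains = file.path(dir, "domains.bed"),
                  manifest = file.path(dir, "manifest.json"))
    Biostrings::writeXStringSet(g$genome, paths$genome)
    utils::write.table(
      data.frame(track$chrom, track$pos,
                 format(track$percent_meth, digits = 15L, trim = TRUE)),
      paths$methylation, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(contacts, paths$contacts, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(g$domains, paths$domains, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(unclass(cfg), paths$manifest, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(genome = g$genome, domains = g$domains, track = track,
                 contacts = contacts, paths = paths))
}
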