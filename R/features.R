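# Fixed per-scheme feature orders. Scheme 1 (23 features) carries the
# window-A methylation average; scheme 2 (109 features) drops it and adds
# the 74 PseTNC components plus extra window-B composition features.

B1_MOTIFS_A <- c("AAWGGR", "TGRAAT", "AAT", "ATGVAA", "ACG", "GC", "CG", "TG")
B1_MOTIFS_B <- c("AAWGGR", "TGRAAT", "AAT", "ATGVAA", "ACG")
B2_MOTIFS_A <- c("AAWGGR", "TGRAAT", "AAT", "ATGVAA", "ACG", "GC", "CG", "TG",
                 "CCGC", "CCCC", "CGCC", "AAAG", "CTCC")
B2_MOTIFS_B <- c("AAWGGR", "TGRAAT", "AAT", "ATGVAA", "ACG",
                 "CCGC", "CCCC", "CGCC", "AAAG", "CTCC", "GC", "CG", "TG")
RATIO_NAMES <- c("Ra_A", "Ra_B", "Ra_C", "Ra_D")

#' Feature names of a scheme, in fixed order
#'
#' @param scheme `"b1"` (23 features) or `"b2"` (109 features).
#' @param lambda PseTNC tier count for scheme 2 (default 10).
#' @return Character vector of feature names.
#' @export
feature_names <- function(scheme = c("b1", "b2"), lambda = 10L) {
  scheme <- match.arg(scheme)
  if (scheme == "b1") {
    c(RATIO_NAMES, paste0("Pa_", B1_MOTIFS_A), "Ave_meth",
      "Ave_meth_Hi_C", paste0("Ave_", RATIO_NAMES, "_Hi_C"),
      paste0("Ave_Pa_", B1_MOTIFS_B, "_Hi_C"))
  } else {
    tri <- all_trinucleotides()
    c(RATIO_NAMES, paste0("Pa_", B2_MOTIFS_A),
      paste0("PseTNC_", tri), paste0("PseTNC_lam", seq_len(lambda)),
      "Ave_meth_Hi_C", paste0("Ave_", RATIO_NAMES, "_Hi_C"),
      paste0("Ave_Pa_", B2_MOTIFS_B, "_Hi_C"))
  }
}

# Extract window sequences from the genome as a DNAStringSet (windows may
# span several chromosomes; order of the input rows is preserved).
extract_window_seqs <- function(windows, genome) {
  n <- nrow(windows)
  out <- character(n)
  for (chr in unique(windows$chrom)) {
    sel <- windows$chrom == chr
    v <- Biostrings::Views(genome[[chr]],
                           start = windows$start[sel] + 1L,
                           end = windows$end[sel])
    out[sel] <- as.character(v)
  }
  Biostrings::DNAStringSet(out)
}

# Composition block for a set of windows: ratios + pattern frequencies
# (+ methylation average), averaged across windows.
window_b_block <- function(windows, genome, midx, motifs) {
  if (nrow(windows) == 0L) {
    out <- numeric(1L + 4L + length(motifs))
  } else {
    seqs <- extract_window_seqs(windows, genome)
    ratios <- nucleotide_ratios_batch(seqs)
    pat <- vapply(motifs, function(m) mean(pattern_frequency_batch(seqs, m)),
                  numeric(1L))
    meth <- vapply(seq_len(nrow(windows)), function(i) {
      mean_methylation(windows$chrom[i], windows$start[i], windows$end[i],
                       midx)$value
    }, numeric(1L))
    out <- c(mean(meth), colMeans(ratios), pat)
  }
  names(out) <- c("Ave_meth_Hi_C", paste0("Ave_", RATIO_NAMES, "_Hi_C"),
                  paste0("Ave_Pa_", motifs, "_Hi_C"))
  out
}

window_a_block <- function(seq_a, motifs) {
  c(nucleotide_ratios(seq_a),
    stats::setNames(vapply(motifs, function(m) pattern_frequency(seq_a, m),
                           numeric(1L)), paste0("Pa_", motifs)))
}

#' Build the scheme-1 (23-dimensional) feature vector for one CpG site
#'
#' Window-A contributes 4 nucleotide ratios, 8 pattern frequencies and the
#' averaged percent-methylation of its CpG sites; the window-Bs (Hi-C
#' spatial neighbours) contribute 4 ratios, 5 pattern frequencies and a
#' methylation average, each averaged over all window-Bs. Sites with no
#' qualifying window-B are skipped (return `NULL`), as only CpG sites with
#' at least one Hi-C contact enter this scheme.
#'
#' @param chrom,pos Target CpG site (0-based position of the C).
#' @param genome Named [Biostrings::DNAStringSet] from [read_fasta()].
#' @param track A `MethylationTrack` (or a [meth_index()] of one).
#' @param lib A `ContactLibrary`.
#' @param cfg A `NeighborhoodConfig`.
#' @param mask_target Exclude the target site's own percent-methylation
#'   from the window-A average (default `FALSE`: it is included).
#' @return List with `names`, `values`, `n_window_b`, `chrom`, `pos`, or
#'   `NULL` when the site has no window-B.
#' @export
build_vector_b1 <- function(chrom, pos, genome, track, lib, cfg,
                            mask_target = FALSE) {
  clens <- chrom_lengths(genome)
  midx <- if (inherits(track, "MethylationTrack")) meth_index(track) else track
  wa <- build_window_a(chrom, pos, cfg$window_size, clens[[chrom]])
  wbs <- collect_window_bs_b1(chrom, pos, wa, lib, cfg, clens)
  if (nrow(wbs) == 0L) return(NULL)
  seq_a <- as.character(Biostrings::subseq(genome[[chrom]],
                                           wa$start + 1L, wa$end))
  mm <- mean_methylation(chrom, wa$start, wa$end, midx)
  ave_meth <- mm$value
  if (mask_target && mm$n_sites > 0L) {
    own <- mean_methylation(chrom, pos, pos + 1L, midx)
    if (own$n_sites == 1L) {
      ave_meth <- if (mm$n_sites == 1L) 0 else
        (mm$value * mm$n_sites - own$value) / (mm$n_sites - 1L)
    }
  }
  vals <- c(window_a_block(seq_a, B1_MOTIFS_A),
            Ave_meth = ave_meth,
            window_b_block(wbs, genome, midx, B1_MOTIFS_B))
  list(names = feature_names("b1"), values = unname(vals),
       n_window_b = nrow(wbs), chrom = chrom, pos = pos)
}

#' Build the scheme-2 (109-dimensional) feature vector for one CpG site
#'
#' Window-A contributes 4 nucleotide ratios, 13 pattern frequencies and
#' 74 PseTNC components (91 features); the window-A methylation average is
#' deliberately excluded so the model never sees the methylation of the
#' sequential neighbourhood. The window-B block (18 features) carries the
#' averaged methylation and composition of the Hi-C spatial neighbours
#' collected through the Hi-C range; with zero window-Bs the block is
#' all zeros and `n_window_b` is 0.
#'
#' @inheritParams build_vector_b1
#' @param windows_override Optional data frame of windows (e.g. from
#'   [sample_random_windows()]) replacing the Hi-C window-B collection.
#' @param psetnc A `PseTNCConfig` (default [pse_tnc_config()]).
#' @return List with `names`, `values`, `n_window_b`, `chrom`, `pos`.
#' @export
build_vector_b2 <- function(chrom, pos, genome, track, lib, cfg,
                            windows_override = NULL,
                            psetnc = pse_tnc_config()) {
  clens <- chrom_lengths(genome)
  midx <- if (inherits(track, "MethylationTrack")) meth_index(track) else track
  wa <- build_window_a(chrom, pos, cfg$window_size, clens[[chrom]])
  wbs <- if (is.null(windows_override)) {
    collect_window_bs_b2(chrom, pos, lib, cfg, clens)
  } else {
    windows_override
  }
  seq_a <- as.character(Biostrings::subseq(genome[[chrom]],
                                           wa$start + 1L, wa$end))
  vals <- c(window_a_block(seq_a, B2_MOTIFS_A),
            pse_tnc(seq_a, psetnc),
            window_b_block(wbs, genome, midx, B2_MOTIFS_B))
  list(names = feature_names("b2", psetnc$lambda), values = unname(vals),
       n_window_b = nrow(wbs), chrom = chrom, pos = pos)
}

#' Chromosome lengths of a genome
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Assemble the feature matrix for a set of CpG sites
#'
#' Runs [build_vector_b1()] or [build_vector_b2()] over the given sites
#' and binds the results into a labeled feature table. For scheme 1,
#' sites with no window-B are dropped. `windows = "random"` replaces each
#' site's Hi-C window-Bs with the same number of random control windows
#' (scheme 2); `windows = "none"` zero-fills the window-B block.
#'
#' @param sites Data frame with columns `chrom`, `pos` and optionally
#'   `label` / `percent_meth` carried through to the output.
#' @param genome,track,lib,cfg As in [build_vector_b1()].
#' @param scheme `"b1"` or `"b2"`.
#' @param windows Window-B source: `"hic"`, `"random"` or `"none"`.
#' @param psetnc A `PseTNCConfig` for scheme 2.
#' @return Data frame: metadata columns (`chrom`, `pos`, plus any carried
#'   from `sites`, plus `n_window_b`) followed by the feature columns.
#' @export
build_feature_matrix <- function(sites, genome, track, lib, cfg,
                                 scheme = c("b1", "b2"),
                                 windows = c("hic", "random", "none"),
                                 psetnc = pse_tnc_config()) {
  scheme <- match.arg(scheme)
  windows <- match.arg(windows)
  if (scheme == "b1" && windows != "hic")
    stop("random/none window sources apply to scheme b2 only")
  midx <- meth_index(track)
  clens <- chrom_lengths(genome)
  rows <- vector("list", nrow(sites))
  nwb <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    if (scheme == "b1") {
      v <- build_vector_b1(ch, p, genome, midx, lib, cfg)
    } else {
      ov <- NULL
      if (windows == "random") {
        n_real <- nrow(collect_window_bs_b2(ch, p, lib, cfg, clens))
        ov <- sample_random_windows(ch, p, lib, cfg, clens, n_real)
      } else if (windows == "none") {
        ov <- empty_windows()
      }
      v <- build_vector_b2(ch, p, genome, midx, lib, cfg,
                           windows_override = ov, psetnc = psetnc)
    }
    if (!is.null(v)) {
      rows[[i]] <- v$values
      nwb[i] <- v$n_window_b
    }
  }
  keep <- !vapply(rows, is.null, logical(1L))
  fn <- feature_names(scheme, psetnc$lambda)
  X <- do.call(rbind, rows[keep])
  colnames(X) <- fn
  meta <- sites[keep, , drop = FALSE]
  meta$n_window_b <- nwb[keep]
  out <- cbind(meta, as.data.frame(X, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "feature_names") <- fn
  out
}

#' Fit / apply per-feature min-max scaling
#'
#' Min and max are learned on training rows only; the transform maps
#' training values into `[0,1]`, clips out-of-range test values, and maps
#' constant features to 0. The reconstruction cross-entropy of the
#' denoising autoencoder requires inputs in `[0,1]`, which this
#' guarantees.
#'
#' @param X Numeric training matrix (rows = samples).
#' @return `fit_scaler` returns a `FeatureScaler`; `apply_scaler` the
#'   scaled matrix.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training matrix")
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max)),
            class = "FeatureScaler")
}

#' @rdname fit_scaler
#' @param scaler A `FeatureScaler`.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1          # constant features map to 0
  out <- sweep(sweep(X, 2L, scaler$min), 2L, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
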