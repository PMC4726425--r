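#' Nucleotide composition ratios of a window
#'
#' Ratios of A, T, G and C over the non-N bases of the window; N is
#' excluded from numerator and denominator, and an all-N window yields
#' zeros. The feature labels follow the fixed scheme order `Ra_A` (A),
#' `Ra_B` (T), `Ra_C` (G), `Ra_D` (C).
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return Named numeric 4-vector `(Ra_A, Ra_B, Ra_C, Ra_D)`.
#' @export
nucleotide_ratios <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  m <- nucleotide_ratios_batch(Biostrings::DNAStringSet(seq))
  stats::setNames(as.numeric(m[1L, ]), colnames(m))
}

nucleotide_ratios_batch <- function(seqs) {
  cnt <- Biostrings::letterFrequency(seqs, letters = c("A", "T", "G", "C"))
  tot <- rowSums(cnt)
  out <- cnt / ifelse(tot == 0, 1, tot)
  colnames(out) <- c("Ra_A", "Ra_B", "Ra_C", "Ra_D")
  out
}

# Supported IUPAC ambiguity codes for motif features
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   W = c("A", "T"), R = c("A", "G"), V = c("A", "C", "G"))

#' Expand an IUPAC motif into its concrete DNA variants
#'
#' @param motif IUPAC string over A/C/G/T/W/R/V.
#' @return Character vector of all concrete ACGT motifs it denotes.
#' @export
expand_iupac <- function(motif) {
  letters <- strsplit(motif, "")[[1L]]
  if (!all(letters %in% names(IUPAC_SETS)))
    stop("unsupported IUPAC code in motif ", motif)
  sets <- IUPAC_SETS[letters]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[rev(seq_along(sets))], 1L, paste0, collapse = "")
}

#' Overlapping IUPAC pattern frequency in a window
#'
#' Number of overlapping matches of the motif (ambiguity codes expanded;
#' N in the sequence never matches) divided by the number of possible
#' alignment positions, `L - k + 1`. A window shorter than the motif has
#' frequency 0 (a warning is raised for the degenerate window).
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param motif IUPAC motif (length >= 2) over A/C/G/T/W/R/V.
#' @return Frequency in `[0,1]`.
#' @export
pattern_frequency <- function(seq, motif) {
  k <- nchar(motif)
  stopifnot(k >= 2L)
  L <- nchar(seq)
  if (L < k) {
    warning("window shorter than motif ", motif, "; frequency set to 0")
    return(0)
  }
  as.numeric(pattern_frequency_batch(Biostrings::DNAStringSet(seq), motif))
}

pattern_frequency_batch <- function(seqs, motif) {
  k <- nchar(motif)
  L <- Biostrings::width(seqs)
  counts <- rep(0L, length(seqs))
  for (v in expand_iupac(motif))
    counts <- counts + Biostrings::vcountPattern(v, seqs)
  denom <- pmax(L - k + 1L, 1L)
  ifelse(L < k, 0, counts / denom)
}

#' Configuration for pseudo trinucleotide composition
#'
#' @param lambda Number of global-correlation tiers (default 10, giving
#'   the standard 64 + 10 = 74 components).
#' @param w Weight of the correlation block in `(0,1]` (default 0.05).
#' @param properties 64 x K numeric matrix of per-trinucleotide
#'   physicochemical properties, rows named by trinucleotide; each column
#'   is standardised to zero mean and unit variance over the 64
#'   trinucleotides. Defaults to [default_tnc_properties()].
#' @return List of class `PseTNCConfig`.
#' @export
pse_tnc_config <- function(lambda = 10L, w = 0.05,
                           properties = default_tnc_properties()) {
  stopifnot(lambda >= 1L, w > 0, w <= 1)
  properties <- as.matrix(properties)
  tri <- all_trinucleotides()
  if (!setequal(rownames(properties), tri))
    stop("property table must cover all 64 trinucleotides")
  properties <- properties[tri, , drop = FALSE]
  properties <- scale(properties)
  attr(properties, "scaled:center") <- NULL
  attr(properties, "scaled:scale") <- NULL
  structure(list(lambda = as.integer(lambda), w = w, properties = properties),
            class = "PseTNCConfig")
}

all_trinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Default trinucleotide physicochemical property table
#'
#' Six properties per trinucleotide, built programmatically: unified
#' nearest-neighbour duplex thermodynamics (SantaLucia 1998) summed over
#' the trinucleotide's two dinucleotide steps (enthalpy dH in kcal/mol,
#' entropy dS in cal/mol/K, free energy dG37 in kcal/mol), plus GC
#' fraction, purine fraction and CpG-step count. Columns are standardised
#' by [pse_tnc_config()]; the table is a plain matrix so users can
#' substitute any other property set.
#'
#' @return 64 x 6 numeric matrix with trinucleotide row names.
#' @export
default_tnc_properties <- function() {
  # unique nearest-neighbour parameters; a dinucleotide shares its values
  # with its reverse complement
  nn <- rbind(
    AA = c(-7.9, -22.2, -1.00), AT = c(-7.2, -20.4, -0.88),
    TA = c(-7.2, -21.3, -0.58), CA = c(-8.5, -22.7, -1.45),
    GT = c(-8.4, -22.4, -1.44), CT = c(-7.8, -21.0, -1.28),
    GA = c(-8.2, -22.2, -1.30), CG = c(-10.6, -27.2, -2.17),
    GC = c(-9.8, -24.4, -2.24), GG = c(-8.0, -19.9, -1.84))
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
  full <- matrix(NA_real_, 16L, 3L)
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  rownames(full) <- dinucs
  for (d in dinucs)
    full[d, ] <- if (d %in% rownames(nn)) nn[d, ] else nn[rc(d), ]
  tri <- all_trinucleotides()
  steps1 <- substr(tri, 1L, 2L)
  steps2 <- substr(tri, 2L, 3L)
  thermo <- full[steps1, ] + full[steps2, ]
  gc <- (nchar(gsub("[AT]", "", tri))) / 3
  pur <- (nchar(gsub("[CT]", "", tri))) / 3
  cpg <- as.integer(steps1 == "CG") + as.integer(steps2 == "CG")
  out <- cbind(thermo, gc, pur, cpg)
  dimnames(out) <- list(tri, c("dH", "dS", "dG37", "gc_frac",
                               "purine_frac", "cpg_steps"))
  out
}

#' Pseudo trinucleotide composition of a window
#'
#' The first 64 components are the normalised trinucleotide occurrence
#' frequencies; the next `lambda` components carry the sequence-order
#' correlation: tier j is the mean over window positions i of
#' `Theta(R_i, R_(i+j))`, the mean squared difference of standardised
#' property values between the trinucleotides starting at i and i + j.
#' Both blocks share the denominator `1 + w * sum(theta)`, so the full
#' vector sums to 1. Trinucleotides containing N are skipped in both
#' blocks.
#'
#' @param seq DNA string over A/C/G/T/N; must satisfy
#'   `nchar(seq) >= lambda + 3`.
#' @param cfg A `PseTNCConfig`.
#' @return Named numeric vector of length `64 + lambda` summing to 1.
#' @export
pse_tnc <- function(seq, cfg = pse_tnc_config()) {
  lam <- cfg$lambda
  L <- nchar(seq)
  if (L < lam + 3L)
    stop("sequence too short for PseTNC: need at least ", lam + 3L, " nt")
  tri_names <- all_trinucleotides()
  m <- L - 2L                    # trinucleotide start positions
  tris <- substring(seq, seq_len(m), seq_len(m) + 2L)
  valid <- !grepl("N", tris, fixed = TRUE)
  if (!any(valid)) stop("no N-free trinucleotide in sequence")
  counts <- table(factor(tris[valid], levels = tri_names))
  f <- as.numeric(counts) / sum(counts)
  P <- cfg$properties
  # property profile per position (rows: positions; invalid rows NA)
  prop <- matrix(NA_real_, m, ncol(P))
  prop[valid, ] <- P[tris[valid], , drop = FALSE]
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    i <- seq_len(m - j)
    d2 <- (prop[i, , drop = FALSE] - prop[i + j, , drop = FALSE])^2
    corr <- rowMeans(d2)         # Theta per position pair
    theta[j] <- mean(corr, na.rm = TRUE)
    if (is.nan(theta[j])) theta[j] <- 0
  }
  denom <- 1 + cfg$w * sum(theta)
  out <- c(f, cfg$w * theta) / denom
  names(out) <- c(paste0("PseTNC_", tri_names),
                  paste0("PseTNC_lam", seq_len(lam)))
  out
}

#' Build a fast lookup index over a methylation track
#'
#' @param track A `MethylationTrack`.
#' @return Per-chromosome sorted positions with cumulative sums, for O(log n)
#'   window averaging.
#' @export
meth_index <- function(track) {
  lapply(split(track[c("pos", "percent_meth")], track$chrom), function(d) {
    o <- order(d$pos)
    list(pos = d$pos[o], cum = cumsum(d$percent_meth[o]))
  })
}

#' Average percent-methylation over a genomic window
#'
#' Unweighted mean of `percent_meth` over CpG sites falling in the
#' 0-based half-open window; a window with no sites reports value 0 with
#' `n_sites` 0 so downstream models can condition on missingness.
#'
#' @param chrom,start,end Window coordinates.
#' @param index Index from [meth_index()] (or a `MethylationTrack`, which
#'   is indexed on the fly).
#' @return List with `value` and `n_sites`.
#' @export
mean_methylation <- function(chrom, start, end, index) {
  if (inherits(index, "MethylationTrack")) index <- meth_index(index)
  ix <- index[[chrom]]
  if (is.null(ix)) return(list(value = 0, n_sites = 0L))
  lo <- findInterval(start - 0.5, ix$pos)
  hi <- findInterval(end - 0.5, ix$pos)
  n <- hi - lo
  if (n == 0L) return(list(value = 0, n_sites = 0L))
  s <- ix$cum[hi] - if (lo == 0L) 0 else ix$cum[lo]
  list(value = s / n, n_sites = n)
}
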