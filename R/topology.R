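#' Build an interval-queryable Hi-C contact library
#'
#' Indexes both ends of every contact per chromosome in sorted position
#' order, so that "contacts with at least one end inside a window" is a
#' pair of binary searches rather than a scan.
#'
#' @param contacts Contact data frame from [read_contacts()].
#' @param dedup Drop exact duplicate pairs (PCR duplicates) before
#'   indexing. Default `FALSE`: duplicate contacts are retained and later
#'   produce duplicate window-Bs, weighting features by contact
#'   multiplicity.
#' @return An object of class `ContactLibrary`.
#' @export
contact_library <- function(contacts, dedup = FALSE) {
  stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b") %in% names(contacts)))
  contacts <- canonicalize_contacts(contacts)
  if (dedup)
    contacts <- contacts[!duplicated(contacts), , drop = FALSE]
  rownames(contacts) <- NULL
  n <- nrow(contacts)
  ends <- data.frame(
    chrom = c(contacts$chrom_a, contacts$chrom_b),
    pos = c(contacts$pos_a, contacts$pos_b),
    id = rep.int(seq_len(n), 2L),
    end = rep(c(1L, 2L), each = n),
    stringsAsFactors = FALSE)
  idx <- lapply(split(ends[c("pos", "id", "end")], ends$chrom), function(d) {
    o <- order(d$pos)
    list(pos = d$pos[o], id = d$id[o], end = d$end[o])
  })
  structure(list(contacts = contacts, index = idx, n = n),
            class = "ContactLibrary")
}

#' @export
print.ContactLibrary <- function(x, ...) {
  cat("ContactLibrary:", x$n, "contacts on",
      length(x$index), "chromosome(s)\n")
  invisible(x)
}

#' Query contacts with at least one end in a window
#'
#' @param lib A `ContactLibrary`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @return Integer vector of row indices into `lib$contacts` (unique,
#'   sorted); a contact with both ends inside the window appears once.
#' @export
query_contacts <- function(lib, chrom, start, end) {
  stopifnot(inherits(lib, "ContactLibrary"), start < end)
  ix <- lib$index[[chrom]]
  if (is.null(ix)) return(integer(0))
  lo <- findInterval(start - 0.5, ix$pos) + 1L
  hi <- findInterval(end - 0.5, ix$pos)
  if (lo > hi) return(integer(0))
  sort(unique(ix$id[lo:hi]))
}

#' Neighborhood configuration for window construction
#'
#' @param window_size Length in nt of window-A and every window-B
#'   (typically 500--1000).
#' @param hic_range Hi-C range in nt (scheme-2 collection interval and
#'   minimum sequential separation of retained contacts, e.g. 10000--50000);
#'   `NULL` for scheme-1 use.
#' @param min_seq_distance Scheme-1 exclusion radius: a window-B must have
#'   its nearest edge more than this many nt from the target CpG
#'   (default 1000).
#' @param cis_only Restrict window-B sources to same-chromosome contacts.
#' @param random_window_attempts Rejection-sampling cap per random window.
#' @return A list of class `NeighborhoodConfig`.
#' @export
neighborhood_config <- function(window_size = 600L, hic_range = NULL,
                                min_seq_distance = 1000L, cis_only = FALSE,
                                random_window_attempts = 10000L) {
  stopifnot(window_size >= 2L)
  if (!is.null(hic_range) && hic_range <= window_size)
    stop("hic_range must exceed window_size")
  structure(list(window_size = as.integer(window_size),
                 hic_range = if (is.null(hic_range)) NULL else as.integer(hic_range),
                 min_seq_distance = as.integer(min_seq_distance),
                 cis_only = isTRUE(cis_only),
                 random_window_attempts = as.integer(random_window_attempts)),
            class = "NeighborhoodConfig")
}

#' Center a fixed-size window on a genomic position
#'
#' The window start is `pos - window_size/2` (floor placement for even
#' sizes), clipped to the chromosome; clipping is flagged.
#'
#' @param chrom Chromosome name.
#' @param pos 0-based target position.
#' @param window_size Window length in nt.
#' @param chrom_length Chromosome length in nt.
#' @return List with `chrom`, `start`, `end`, `clipped`.
#' @export
build_window_a <- function(chrom, pos, window_size, chrom_length) {
  start <- pos - window_size %/% 2L
  end <- start + window_size
  if (end <= 0L || start >= chrom_length)
    stop("window entirely outside chromosome ", chrom)
  clipped <- start < 0L || end > chrom_length
  list(chrom = chrom, start = max(0L, start),
       end = min(as.integer(chrom_length), end), clipped = clipped)
}

window_from_centers <- function(chroms, centers, window_size, chrom_lengths) {
  start <- centers - window_size %/% 2L
  end <- start + window_size
  len <- as.integer(chrom_lengths[chroms])
  data.frame(chrom = chroms,
             start = pmax(0L, start),
             end = pmin(len, end),
             clipped = start < 0L | end > len,
             stringsAsFactors = FALSE)
}

# other-end extraction: given contact rows and the anchor window/interval,
# return (chrom, pos) of the end NOT used as anchor; a contact with both
# ends qualifying as anchors contributes its canonical "b" end.
other_ends <- function(contacts, anchor_chrom, anchor_start, anchor_end) {
  a_in <- contacts$chrom_a == anchor_chrom &
    contacts$pos_a >= anchor_start & contacts$pos_a < anchor_end
  chrom <- ifelse(a_in, contacts$chrom_b, contacts$chrom_a)
  pos <- ifelse(a_in, contacts$pos_b, contacts$pos_a)
  data.frame(chrom = chrom, pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' Collect window-Bs under the scheme-1 (window-A anchored) rule
#'
#' Every contact with one end inside window-A contributes a window-B of the
#' same size centred on its other end. A window-B is retained only if it
#' lies on a different chromosome or its nearest edge is more than
#' `cfg$min_seq_distance` nt from the target CpG position, so the
#' topological neighbourhood never restates the sequential one.
#'
#' @param chrom,pos Target CpG location.
#' @param window_a Window from [build_window_a()].
#' @param lib `ContactLibrary`.
#' @param cfg `NeighborhoodConfig`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return Data frame of windows (`chrom`, `start`, `end`, `clipped`); one
#'   row per qualifying contact, duplicates retained.
#' @export
collect_window_bs_b1 <- function(chrom, pos, window_a, lib, cfg, chrom_lengths) {
  ids <- query_contacts(lib, window_a$chrom, window_a$start, window_a$end)
  if (length(ids) == 0L) return(empty_windows())
  ends <- other_ends(lib$contacts[ids, , drop = FALSE],
                     window_a$chrom, window_a$start, window_a$end)
  if (cfg$cis_only) ends <- ends[ends$chrom == chrom, , drop = FALSE]
  if (nrow(ends) == 0L) return(empty_windows())
  ends <- ends[ends$chrom %in% names(chrom_lengths), , drop = FALSE]
  w <- window_from_centers(ends$chrom, ends$pos, cfg$window_size, chrom_lengths)
  # nearest-edge distance from the target CpG to the window-B interval
  edge <- pmax(w$start - pos, pos - (w$end - 1L), 0L)
  keep <- w$chrom != chrom | edge > cfg$min_seq_distance
  w[keep, , drop = FALSE]
}

#' Collect window-Bs under the scheme-2 (Hi-C range) rule
#'
#' Contacts are anchored anywhere inside the Hi-C range (an interval of
#' length `cfg$hic_range` centred on the target CpG) and retained only when
#' long range: both ends on the same chromosome separated by more than
#' `cfg$hic_range` nt, or on different chromosomes.
#'
#' @inheritParams collect_window_bs_b1
#' @return Data frame of windows; duplicates retained.
#' @export
collect_window_bs_b2 <- function(chrom, pos, lib, cfg, chrom_lengths) {
  if (is.null(cfg$hic_range)) stop("cfg$hic_range must be set for scheme 2")
  rng <- build_window_a(chrom, pos, cfg$hic_range, chrom_lengths[[chrom]])
  ids <- query_contacts(lib, rng$chrom, rng$start, rng$end)
  if (length(ids) == 0L) return(empty_windows())
  con <- lib$contacts[ids, , drop = FALSE]
  trans <- con$chrom_a != con$chrom_b
  sep <- abs(con$pos_b - con$pos_a)
  keep <- trans | sep > cfg$hic_range
  if (cfg$cis_only) keep <- keep & !trans
  con <- con[keep, , drop = FALSE]
  if (nrow(con) == 0L) return(empty_windows())
  ends <- other_ends(con, rng$chrom, rng$start, rng$end)
  ends <- ends[ends$chrom %in% names(chrom_lengths), , drop = FALSE]
  if (nrow(ends) == 0L) return(empty_windows())
  window_from_centers(ends$chrom, ends$pos, cfg$window_size, chrom_lengths)
}

empty_windows <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             clipped = logical(0), stringsAsFactors = FALSE)
}

#' Sample random control windows with no Hi-C link to the target
#'
#' Draws uniform windows on the target chromosome, rejecting any window
#' that (a) overlaps the target's Hi-C range, or (b) shares a Hi-C contact
#' with it -- i.e. some contact has one end in the window and the other in
#' the range. The surviving windows carry no topological relation to the
#' target CpG and serve as the negative control for the window-B features.
#'
#' @inheritParams collect_window_bs_b2
#' @param count Number of windows to return.
#' @return Data frame of windows (`chrom`, `start`, `end`, `clipped`).
#' @export
sample_random_windows <- function(chrom, pos, lib, cfg, chrom_lengths, count) {
  stopifnot(count >= 0L)
  if (count == 0L) return(empty_windows())
  if (is.null(cfg$hic_range)) stop("cfg$hic_range must be set")
  clen <- chrom_lengths[[chrom]]
  rng <- build_window_a(chrom, pos, cfg$hic_range, clen)
  # partner positions of every contact anchored in the Hi-C range, per chrom
  ids <- query_contacts(lib, rng$chrom, rng$start, rng$end)
  partners <- if (length(ids)) {
    other_ends(lib$contacts[ids, , drop = FALSE], rng$chrom, rng$start, rng$end)
  } else {
    data.frame(chrom = character(0), pos = integer(0))
  }
  ppos <- sort(partners$pos[partners$chrom == chrom])
  got <- 0L
  starts <- integer(count)
  attempts <- 0L
  max_start <- clen - cfg$window_size
  if (max_start < 0L) stop("chromosome shorter than window_size")
  while (got < count) {
    attempts <- attempts + 1L
    if (attempts > cfg$random_window_attempts)
      stop("random-window sampling failed after ",
           cfg$random_window_attempts, " attempts")
    s <- as.integer(floor(stats::runif(1L, 0, max_start + 1)))
    e <- s + cfg$window_size
    if (s < rng$end && e > rng$start) next            # overlaps the range
    if (length(ppos)) {
      k <- findInterval(e - 0.5, ppos) - findInterval(s - 0.5, ppos)
      if (k > 0L) next                                # shares a contact
    }
    got <- got + 1L
    starts[got] <- s
  }
  data.frame(chrom = rep(chrom, count), start = starts,
             end = starts + cfg$window_size,
             clipped = rep(FALSE, count), stringsAsFactors = FALSE)
}

#' Hi-C sequencing coverage
#'
#' Mean number of Hi-C read bases per genome position:
#' `n_reads * read_length / genome_length`.
#'
#' @param n_reads Number of mapped Hi-C reads.
#' @param read_length Read length in nt.
#' @param genome_length Total reference length in nt.
#' @return Coverage (reads x read length / genome length).
#' @export
hic_coverage <- function(n_reads, read_length, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  n_reads * read_length / genome_length
}
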