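#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and any character outside A/C/G/T/N is mapped to
#' N, so downstream feature code only ever sees the five-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop("malformed FASTA at line 1: expected '>' header in ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record: ", paste(names(x)[Biostrings::width(x) == 0L],
                                       collapse = ", "))
  chars <- toupper(as.character(x))
  chars <- gsub("[^ACGTN]", "N", chars)
  out <- Biostrings::DNAStringSet(chars)
  # keep only the first word of each header, as genome FASTA headers carry
  # free-text descriptions
  names(out) <- sub("\\s.*$", "", names(x))
  if (any(names(out) == "")) stop("malformed FASTA: empty record name")
  out
}

#' Read a CpG percent-methylation track
#'
#' Two dialects are supported. `"simple"` is a headerless 3-column TSV
#' (chrom, 0-based position of the C, percent-methylation in `[0,1]`).
#' `"bedmethyl"` is the ENCODE-style BED9+2 layout with read coverage in
#' column 10 and percent-methylation on a 0--100 scale in column 11.
#'
#' @param path Path to the track file.
#' @param dialect `"simple"` or `"bedmethyl"`.
#' @return A `MethylationTrack`: a data frame with columns `chrom`, `pos`,
#'   `percent_meth` (in `[0,1]`) and `read_count`, sorted by (chrom, pos)
#'   and free of duplicate positions.
#' @export
read_methylation_track <- function(path, dialect = c("simple", "bedmethyl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("methylation track not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (dialect == "simple") {
    if (ncol(raw) < 3L) stop("simple methylation dialect needs 3 columns")
    df <- data.frame(chrom = as.character(raw[[1L]]),
                     pos = as.integer(raw[[2L]]),
                     percent_meth = as.numeric(raw[[3L]]),
                     read_count = NA_integer_,
                     stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 11L) stop("bedMethyl dialect needs 11 columns (BED9+2)")
    df <- data.frame(chrom = as.character(raw[[1L]]),
                     pos = as.integer(raw[[2L]]),
                     percent_meth = as.numeric(raw[[11L]]) / 100,
                     read_count = as.integer(raw[[10L]]),
                     stringsAsFactors = FALSE)
  }
  methylation_track(df)
}

#' Construct and validate a MethylationTrack
#'
#' @param df Data frame with columns `chrom`, `pos`, `percent_meth` and
#'   optionally `read_count`.
#' @return The validated, sorted track (class `MethylationTrack`).
#' @export
methylation_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "percent_meth") %in% names(df)))
  if (is.null(df$read_count)) df$read_count <- NA_integer_
  if (anyNA(df$pos) || any(df$pos < 0L))
    stop("invalid CpG position (negative or non-integer)")
  bad <- df$percent_meth < 0 | df$percent_meth > 1 | is.na(df$percent_meth)
  if (any(bad))
    stop("percent_meth outside [0,1] at row(s) ", paste(utils::head(which(bad), 5L), collapse = ","))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  dup <- duplicated(df[c("chrom", "pos")])
  if (any(dup))
    stop("duplicate CpG site(s), e.g. ", df$chrom[dup][1L], ":", df$pos[dup][1L])
  rownames(df) <- NULL
  class(df) <- c("MethylationTrack", "data.frame")
  df
}

#' Read a Hi-C contact library
#'
#' The canonical contact format is a headerless 4-column TSV: chrom_a,
#' pos_a, chrom_b, pos_b, one mapped read-pair per row. Pairs are
#' canonically ordered so that (chrom_a, pos_a) <= (chrom_b, pos_b).
#'
#' @param path Path to the contact TSV.
#' @return Data frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("contact file not found: ", path)
  info <- file.info(path)
  if (info$size == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(chrom_a = character(0), pos_a = integer(0),
                      chrom_b = character(0), pos_b = integer(0),
                      stringsAsFactors = FALSE))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#",
                           colClasses = c("character", "character",
                                          "character", "character"))
  if (ncol(raw) < 4L) stop("contact file needs 4 columns")
  pa <- suppressWarnings(as.numeric(raw[[2L]]))
  pb <- suppressWarnings(as.numeric(raw[[4L]]))
  if (anyNA(pa) || anyNA(pb) || any(pa != floor(pa)) || any(pb != floor(pb)))
    stop("non-integer contact position at row ",
         which(is.na(pa) | is.na(pb) | pa != floor(pa) | pb != floor(pb))[1L])
  df <- data.frame(chrom_a = raw[[1L]], pos_a = as.integer(pa),
                   chrom_b = raw[[3L]], pos_b = as.integer(pb),
                   stringsAsFactors = FALSE)
  if (any(df$pos_a < 0L | df$pos_b < 0L)) stop("negative contact position")
  canonicalize_contacts(df)
}

#' Put contact pairs in canonical end order
#'
#' Swaps ends so that (chrom_a, pos_a) <= (chrom_b, pos_b) lexicographically.
#' @param df Contact data frame.
#' @return The reordered data frame.
#' @export
canonicalize_contacts <- function(df) {
  swap <- df$chrom_a > df$chrom_b |
    (df$chrom_a == df$chrom_b & df$pos_a > df$pos_b)
  if (any(swap)) {
    tmp_c <- df$chrom_a[swap]; tmp_p <- df$pos_a[swap]
    df$chrom_a[swap] <- df$chrom_b[swap]; df$pos_a[swap] <- df$pos_b[swap]
    df$chrom_b[swap] <- tmp_c; df$pos_b[swap] <- tmp_p
  }
  rownames(df) <- NULL
  df
}

#' Read a BED3 interval file
#'
#' @param path Path to a BED file (>= 3 columns, 0-based half-open).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(raw) < 3L) stop("BED file needs >= 3 columns")
  df <- data.frame(chrom = as.character(raw[[1L]]),
                   start = as.integer(raw[[2L]]),
                   end = as.integer(raw[[3L]]),
                   stringsAsFactors = FALSE)
  bad <- df$start >= df$end
  if (any(bad)) stop("BED interval with start >= end at row ", which(bad)[1L])
  df
}

#' Write / read a labeled feature table
#'
#' Feature tables are TSV with a header line. Metadata columns (`chrom`,
#' `pos`, `label`, `n_window_b`) precede the feature columns, whose names
#' follow the fixed per-scheme feature order. Numeric values are written
#' with 15 significant digits so a round-trip is an identity to within
#' float formatting.
#'
#' @param tab Feature table (data frame) as produced by
#'   [build_feature_matrix()].
#' @param path Output path.
#' @export
write_feature_table <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  out <- tab
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15L,
                                                  scientific = TRUE,
                                                  trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param expected_features Optional character vector of feature names the
#'   table must contain, in order; a mismatch is a schema error.
#' @return `read_feature_table` returns the data frame.
#' @export
read_feature_table <- function(path, expected_features = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  if (!is.null(expected_features)) {
    have <- setdiff(names(tab), c("chrom", "pos", "label", "n_window_b"))
    if (!identical(have, expected_features))
      stop("feature table header does not match expected schema")
  }
  tab
}
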