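#' Read a multi-record FASTA file as a genome
#'
#' Sequences are case-normalized to upper case and the alphabet is restricted
#' to A, C, G, T, N. Record descriptions are truncated at the first
#' whitespace, following the usual chromosome-naming convention.
#'
#' @param path Path to a FASTA file (wrapped lines supported).
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# Shared plain-text table writer: tab-separated, no quoting, no row names.
write_tsv0 <- function(df, path, col.names = FALSE) {
  df2 <- df
  for (j in seq_along(df2)) if (is.numeric(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

#' Read a BED file (BED3/BED6, extra columns preserved)
#'
#' Coordinates are kept in the file's native 0-based half-open convention.
#' Columns beyond the sixth are read as character and named `extra1`,
#' `extra2`, ...
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`, `extra*`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#",
                         quote = "")
  if (ncol(x) < 3L) stop("BED needs at least 3 columns: ", path)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  n <- ncol(x)
  names(x) <- c(nm[seq_len(min(n, 6L))],
                if (n > 6L) paste0("extra", seq_len(n - 6L)))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if ("score" %in% names(x)) x$score <- as.numeric(x$score)
  x
}

#' Write a BED file
#'
#' Writes `chrom`, `start`, `end` and any of `name`, `score`, `strand`,
#' `extra*` columns present, in BED column order.
#'
#' @param df Interval data.frame (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand",
                      grep("^extra", names(df), value = TRUE)), names(df))
  write_tsv0(df[, cols, drop = FALSE], path)
}

#' Read a BEDPE file of read pairs or generic paired intervals
#'
#' Standard 10-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2`); shorter files down to 6 columns are accepted.
#'
#' @param path Path to a BEDPE file.
#' @return A data.frame with paired-interval columns.
#' @export
read_bedpe <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#",
                         quote = "")
  if (ncol(x) < 6L) stop("BEDPE needs at least 6 columns: ", path)
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
          "name", "score", "strand1", "strand2")
  names(x) <- nm[seq_len(min(ncol(x), 10L))]
  for (k in c("start1", "end1", "start2", "end2"))
    x[[k]] <- as.integer(x[[k]])
  if ("score" %in% names(x)) x$score <- as.numeric(x$score)
  x
}

#' Write a BEDPE file
#'
#' @param df Paired-interval data.frame.
#' @param path Output path.
#' @export
write_bedpe <- function(df, path) {
  cols <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score", "strand1", "strand2"), names(df))
  write_tsv0(df[, cols, drop = FALSE], path)
}

#' Read a bedGraph track
#'
#' @param path Path to a bedGraph file.
#' @return A data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "numeric"),
                         comment.char = "#", quote = "")
  names(x) <- c("chrom", "start", "end", "value")
  x
}

#' Write a track as bedGraph
#'
#' @param track A data.frame with `chrom`, `start`, `end`, `value` (e.g. a
#'   window track from [window_counts()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  write_tsv0(track[, c("chrom", "start", "end", "value")], path)
}

#' Read a fragment-level count table
#'
#' Five tab-separated columns: chrom, start, end, fragment id, count.
#'
#' @param path Path to the TSV.
#' @return A fragment-count data.frame (`chrom`, `start`, `end`, `frag_id`,
#'   `count`).
#' @export
read_fragment_counts <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer"),
                         quote = "")
  names(x) <- c("chrom", "start", "end", "frag_id", "count")
  x
}

#' Write a fragment-level count table
#'
#' @param counts Fragment-count data.frame.
#' @param path Output path.
#' @export
write_fragment_counts <- function(counts, path) {
  write_tsv0(counts[, c("chrom", "start", "end", "frag_id", "count")], path)
}
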