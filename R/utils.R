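# Internal helpers shared across modules.
#
# All user-facing coordinates are 0-based, half-open (BED convention).
# GenomicRanges (1-based, closed) is used internally for overlap machinery;
# conversion happens only inside these helpers.

# 0-based half-open data.frame -> GRanges
gr0 <- function(df, use_strand = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if (use_strand && "strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# midpoint of a 0-based half-open interval
midpoint0 <- function(start, end) (start + end) %/% 2L

#' @importFrom utils head tail
NULL

# Normalize a genome to an uppercase DNAStringSet over {A,C,G,T,N}
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
      stop("genome sequences must be named by chromosome")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named character vector or a DNAStringSet")
  if (length(genome) == 0L) stop("empty genome")
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names")
  if (any(BiocGenerics::width(genome) == 0L)) stop("empty chromosome sequence")
  af <- Biostrings::alphabetFrequency(genome, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  if (any(rowSums(af[, setdiff(colnames(af), allowed), drop = FALSE]) > 0))
    stop("genome alphabet restricted to A, C, G, T, N")
  genome
}

chrom_sizes_of <- function(genome) {
  genome <- as_genome(genome)
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

# Hamming distance between two equal-length strings (N never matches ACGT)
str_mismatches <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)
  vb <- strsplit(b, "", fixed = TRUE)
  mapply(function(x, y) sum(x != y), va, vb, USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / n
}

# Melting-temperature estimate: Wallace rule for short oligos, the
# GC-fraction/length formula otherwise. Deterministic design surrogate.
tm_estimate <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  at <- nchar(gsub("[^ATat]", "", x))
  ifelse(n <= 14, 2 * at + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
}

# Expand 0-based intervals by a symmetric flank and clip to chromosome bounds
expand_clip <- function(df, flank, chrom_sizes = NULL) {
  out <- df
  out$start <- pmax(0L, df$start - as.integer(flank))
  out$end <- df$end + as.integer(flank)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[as.character(out$chrom)]
    if (anyNA(len)) stop("interval chromosome missing from chrom_sizes")
    out$end <- pmin(out$end, unname(len))
  }
  out
}

# format a numeric column for text output without scientific notation
fmt_num <- function(x) {
  if (is.integer(x)) return(as.character(x))
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}
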