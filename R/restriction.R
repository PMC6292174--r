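#' Define a restriction enzyme
#'
#' Enzymes are data, not code: a recognition site and the offset (bases from
#' the site start) at which the fragment boundary falls. DpnII is GATC with a
#' blunt cut 5' of the site (offset 0); Csp6I is GTAC cutting after the G.
#'
#' @param name Enzyme name.
#' @param site Recognition site (A/C/G/T only, length >= 4).
#' @param cut_offset Bases from site start to the fragment boundary
#'   (0 <= cut_offset <= site length).
#' @return An object of class `restriction_enzyme`.
#' @examples
#' dpnii <- restriction_enzyme("DpnII", "GATC", 0)
#' @export
restriction_enzyme <- function(name, site, cut_offset = 0L) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site must be at least 4 bases")
  if (grepl("[^ACGT]", site))
    stop("recognition site must contain only A, C, G, T (no ambiguity codes)")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within the site")
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<%s> site %s, cut at +%d\n", x$name, x$site, x$cut_offset))
  invisible(x)
}

#' Find all occurrences of a recognition site in one sequence
#'
#' Exact forward-strand scan (palindromic sites such as GATC need no reverse
#' scan). Sites spanning an N never match.
#'
#' @param seq A DNA string.
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted 0-based start offsets of every occurrence.
#' @export
scan_restriction_sites <- function(seq, enzyme) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (length(seq) == 0L) stop("empty sequence")
  m <- Biostrings::matchPattern(enzyme$site, seq, fixed = TRUE)
  sort(BiocGenerics::start(m)) - 1L
}

#' Digest a genome into a restriction-fragment map
#'
#' Fragments tile each chromosome exactly: boundaries fall at
#' `site start + cut_offset` for every site occurrence; the first fragment
#' starts at 0 and the last ends at the chromosome length. Empty fragments
#' produced by a boundary at either chromosome end are suppressed.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param enzyme A [restriction_enzyme()].
#' @return A data.frame of class `restriction_map` with columns `chrom`,
#'   `start`, `end`, `index` (1-based per-chromosome fragment rank) and
#'   attributes `enzyme` and `chrom_sizes`.
#' @export
digest_genome <- function(genome, enzyme) {
  genome <- as_genome(genome)
  if (!inherits(enzyme, "restriction_enzyme"))
    stop("enzyme must be a restriction_enzyme")
  sizes <- chrom_sizes_of(genome)
  frags <- lapply(names(genome), function(cn) {
    len <- sizes[[cn]]
    sites <- scan_restriction_sites(genome[[cn]], enzyme)
    b <- sites + enzyme$cut_offset
    b <- b[b > 0L & b < len]
    starts <- c(0L, b)
    ends <- c(b, len)
    data.frame(chrom = cn, start = starts, end = ends,
               index = seq_along(starts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frags)
  rownames(out) <- NULL
  structure(out, enzyme = enzyme, chrom_sizes = sizes,
            class = c("restriction_map", "data.frame"))
}

#' Build the reduced genome of cut-site flanks
#'
#' For every internal cut boundary, the fixed-length sequence on each side is
#' emitted when at least `flank` bases exist on that side. A flank is flagged
#' `unique` iff its exact sequence occurs exactly once in the whole genome,
#' counting both strands (reverse-complement occurrences included); flanks
#' containing N are never unique. The unique flanks form the mappable target
#' space for 4C-style reads.
#'
#' @param rmap A `restriction_map` from [digest_genome()].
#' @param genome The genome the map was built from.
#' @param flank Flank length in bases (default 25, minimum 10).
#' @return A data.frame of class `reduced_genome`: `chrom`, `start`, `end`,
#'   `side` ("up"/"down"), `frag_index` (parent fragment rank), `frag_id`,
#'   `seq`, `unique`.
#' @export
build_reduced_genome <- function(rmap, genome, flank = 25L) {
  flank <- as.integer(flank)
  if (flank < 10L) stop("flank must be >= 10")
  genome <- as_genome(genome)
  sizes <- attr(rmap, "chrom_sizes")
  rows <- lapply(split(rmap, rmap$chrom), function(fr) {
    cn <- fr$chrom[1L]
    len <- sizes[[cn]]
    b <- fr$end[fr$end < len]  # internal boundaries
    if (length(b) == 0L) return(NULL)
    # upstream flank belongs to the fragment ending at b, downstream to the
    # fragment starting at b
    up <- data.frame(chrom = cn, start = b - flank, end = b, side = "up",
                     frag_index = fr$index[match(b, fr$end)],
                     stringsAsFactors = FALSE)
    dn <- data.frame(chrom = cn, start = b, end = b + flank, side = "down",
                     frag_index = fr$index[match(b, fr$start)],
                     stringsAsFactors = FALSE)
    out <- rbind(up[up$start >= 0L, ], dn[dn$end <= len, ])
    out[order(out$start, out$side), ]
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), side = character(),
                      frag_index = integer(), frag_id = character(),
                      seq = character(), unique = logical())
    return(structure(out, flank = flank, chrom_sizes = sizes,
                     class = c("reduced_genome", "data.frame")))
  }
  rownames(out) <- NULL
  out$frag_id <- sprintf("%s_%d_%s", out$chrom, out$frag_index, out$side)
  out$seq <- NA_character_
  for (cn in unique(out$chrom)) {
    idx <- out$chrom == cn
    out$seq[idx] <- as.character(Biostrings::extractAt(
      genome[[cn]], IRanges::IRanges(out$start[idx] + 1L, out$end[idx])))
  }
  has_n <- grepl("N", out$seq, fixed = TRUE)
  uniq_seqs <- unique(out$seq[!has_n])
  counts <- stats::setNames(integer(length(uniq_seqs)), uniq_seqs)
  if (length(uniq_seqs) > 0L) {
    pd <- Biostrings::PDict(uniq_seqs)
    for (cn in names(genome)) {
      counts <- counts + Biostrings::countPDict(pd, genome[[cn]])
      counts <- counts + Biostrings::countPDict(
        pd, Biostrings::reverseComplement(genome[[cn]]))
    }
  }
  out$unique <- !has_n & counts[out$seq] == 1L
  out$unique[is.na(out$unique)] <- FALSE
  structure(out, flank = flank, chrom_sizes = sizes,
            class = c("reduced_genome", "data.frame"))
}

#' Export a restriction map as BED
#'
#' Fragment index goes in the BED name column.
#'
#' @param rmap A `restriction_map`.
#' @param path Output path.
#' @export
write_restriction_map <- function(rmap, path) {
  df <- data.frame(chrom = rmap$chrom, start = rmap$start, end = rmap$end,
                   name = as.character(rmap$index))
  write_bed(df, path)
}

#' Export reduced-genome flanks as BED6
#'
#' Only the unique (mappable) flanks are written by default.
#'
#' @param reduced A `reduced_genome`.
#' @param path Output path.
#' @param unique_only Write only flanks with `unique == TRUE`.
#' @export
write_reduced_genome <- function(reduced, path, unique_only = TRUE) {
  df <- if (unique_only) reduced[reduced$unique, ] else reduced
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$frag_id, score = as.integer(df$unique),
                    strand = ifelse(df$side == "down", "+", "-"))
  write_bed(out, path)
}
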