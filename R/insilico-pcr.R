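#' Find primer binding sites genome-wide (in-silico PCR matching)
#'
#' A primer matches a locus when its 3'-terminal `min_perfect_3prime` bases
#' match the genome exactly and the remaining 5' bases carry at most
#' `max_mismatch_5prime` mismatches (an N in the genome counts as a
#' mismatch). Both strands are searched; the protected block is always the
#' primer's own 3' end, which for a minus-strand match faces leftward on the
#' forward genome.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param primer Primer sequence (character).
#' @param min_perfect_3prime Length of the protected, perfectly matching 3'
#'   block (default 15, the lowest-stringency setting).
#' @param max_mismatch_5prime Mismatches tolerated outside the protected
#'   block (default 2).
#' @param primer_id Identifier recorded in the output.
#' @return A data.frame sorted by coordinate: `chrom`, `start`, `end`
#'   (0-based half-open span of the full primer), `strand`, `mismatches`,
#'   `primer_id`.
#' @export
find_primer_sites <- function(genome, primer, min_perfect_3prime = 15L,
                              max_mismatch_5prime = 2L,
                              primer_id = "primer") {
  genome <- as_genome(genome)
  primer <- toupper(primer)
  L <- nchar(primer)
  b <- as.integer(min_perfect_3prime)
  if (L < b) stop("primer shorter than the protected 3' block")
  rp <- revcomp(primer)
  out <- list()
  for (cn in names(genome)) {
    seq <- genome[[cn]]
    len <- length(seq)
    chr_str <- NULL  # lazily decoded
    # plus strand: protected block is the primer's 3'-terminal b bases
    blk <- substr(primer, L - b + 1L, L)
    hits <- BiocGenerics::start(Biostrings::matchPattern(blk, seq,
                                                         fixed = TRUE)) - 1L
    starts <- hits - (L - b)
    starts <- starts[starts >= 0L]
    if (length(starts) > 0L) {
      if (is.null(chr_str)) chr_str <- as.character(seq)
      pre <- substring(chr_str, starts + 1L, starts + (L - b))
      mm <- if (L == b) integer(length(starts))
            else str_mismatches(pre, substr(primer, 1L, L - b))
      keep <- mm <= max_mismatch_5prime
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = starts[keep], end = starts[keep] + L,
          strand = "+", mismatches = mm[keep], primer_id = primer_id,
          stringsAsFactors = FALSE)
    }
    # minus strand: the genome segment reads as revcomp(primer); the
    # protected 3' block of the primer is the first b bases of that segment
    blk_m <- substr(rp, 1L, b)
    hits_m <- BiocGenerics::start(Biostrings::matchPattern(blk_m, seq,
                                                           fixed = TRUE)) - 1L
    starts_m <- hits_m[hits_m + L <= len]
    if (length(starts_m) > 0L) {
      if (is.null(chr_str)) chr_str <- as.character(seq)
      suf <- substring(chr_str, starts_m + b + 1L, starts_m + L)
      mm <- if (L == b) integer(length(starts_m))
            else str_mismatches(suf, substr(rp, b + 1L, L))
      keep <- mm <= max_mismatch_5prime
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = starts_m[keep], end = starts_m[keep] + L,
          strand = "-", mismatches = mm[keep], primer_id = primer_id,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), primer_id = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Predict amplified bait regions from primer match lists
#'
#' Pairs every plus-strand match of one primer with every minus-strand match
#' of the other on the same chromosome, facing inward (the minus match starts
#' at or after the plus match start), with a product no longer than
#' `max_product`. When a TE annotation is supplied, each amplicon is flagged
#' `on_target` iff it overlaps an annotation of `target_family` and of no
#' other family.
#'
#' @param fwd,rev Match tables from [find_primer_sites()] for the two
#'   primers (both cross-orientations are paired).
#' @param max_product Maximum product size in bases (default 4000).
#' @param te Optional TE annotation data.frame (`chrom`, `start`, `end`,
#'   `family`).
#' @param target_family Family the bait is designed against.
#' @return A data.frame of predicted baits: amplicon `chrom`, `start`,
#'   `end`, `product_size`, primer ids and match coordinates, and (with
#'   annotation) `on_target` plus comma-joined `families`.
#' @export
predict_baits <- function(fwd, rev, max_product = 4000L, te = NULL,
                          target_family = NULL) {
  pair_one <- function(plus, minus) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return(NULL)
    idx <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    p <- plus[idx$i, ]; m <- minus[idx$j, ]
    size <- m$end - p$start
    ok <- p$chrom == m$chrom & m$start >= p$start & size <= max_product
    if (!any(ok)) return(NULL)
    data.frame(chrom = p$chrom[ok], start = p$start[ok], end = m$end[ok],
               product_size = size[ok],
               fwd_primer = p$primer_id[ok], rev_primer = m$primer_id[ok],
               fwd_start = p$start[ok], rev_start = m$start[ok],
               stringsAsFactors = FALSE)
  }
  res <- rbind(
    pair_one(fwd[fwd$strand == "+", ], rev[rev$strand == "-", ]),
    pair_one(rev[rev$strand == "+", ], fwd[fwd$strand == "-", ])
  )
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), product_size = integer(),
                      fwd_primer = character(), rev_primer = character(),
                      fwd_start = integer(), rev_start = integer())
  }
  res <- unique(res)
  res <- res[order(res$chrom, res$start, res$end), ]
  rownames(res) <- NULL
  if (!is.null(te)) {
    fams <- character(nrow(res))
    on_target <- logical(nrow(res))
    if (nrow(res) > 0L) {
      ov <- GenomicRanges::findOverlaps(gr0(res), gr0(te))
      fam_by_bait <- split(te$family[S4Vectors::subjectHits(ov)],
                           S4Vectors::queryHits(ov))
      for (k in names(fam_by_bait)) {
        f <- sort(unique(fam_by_bait[[k]]))
        i <- as.integer(k)
        fams[i] <- paste(f, collapse = ",")
        on_target[i] <- !is.null(target_family) &&
          identical(f, target_family)
      }
    }
    res$on_target <- on_target
    res$families <- fams
  }
  res
}

#' Write predicted baits as BED6+
#'
#' Product size and on-target flag go in extra columns.
#'
#' @param baits Output of [predict_baits()].
#' @param path Output path.
#' @export
write_predicted_baits <- function(baits, path) {
  df <- data.frame(chrom = baits$chrom, start = baits$start,
                   end = baits$end,
                   name = sprintf("bait_%d", seq_len(nrow(baits))),
                   score = 0L, strand = ".",
                   extra1 = as.character(baits$product_size),
                   extra2 = if ("on_target" %in% names(baits))
                     as.character(as.integer(baits$on_target)) else ".")
  write_bed(df, path)
}
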