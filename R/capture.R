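#' Predict probe hybridization targets by local alignment
#'
#' Seeds exact `seed_k`-mer matches of the probe (both strands), extends each
#' candidate window with a Smith-Waterman local alignment (match +1,
#' mismatch -1, gap open -2, gap extend -1), and reports the aligned genomic
#' spans that reach at least `min_identity` over at least `min_aligned`
#' aligned columns. Overlapping hits are merged; hits closer than a probe
#' length therefore coalesce.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param probe Probe sequence (~120 nt).
#' @param min_identity Minimum fraction of identical columns (default 0.80).
#' @param min_aligned Minimum aligned columns (default 60).
#' @param seed_k Exact seed length used to locate candidate windows
#'   (default 12).
#' @return Sorted, merged interval data.frame (`chrom`, `start`, `end`).
#' @export
predict_probe_targets <- function(genome, probe, min_identity = 0.80,
                                  min_aligned = 60L, seed_k = 12L) {
  genome <- as_genome(genome)
  probe <- toupper(probe)
  L <- nchar(probe)
  if (L < min_aligned) stop("probe shorter than min_aligned")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  hits <- list()
  for (strand_probe in c(probe, revcomp(probe))) {
    kmers <- unique(substring(strand_probe, seq_len(L - seed_k + 1L),
                              seq_len(L - seed_k + 1L) + seed_k - 1L))
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (length(kmers) == 0L) next
    pd <- Biostrings::PDict(kmers)
    for (cn in names(genome)) {
      seq <- genome[[cn]]
      len <- length(seq)
      m <- Biostrings::matchPDict(pd, seq)
      starts <- BiocGenerics::start(unlist(m)) - 1L
      if (length(starts) == 0L) next
      cand <- IRanges::reduce(IRanges::IRanges(
        pmax(1L, starts - L + 1L), pmin(len, starts + 2L * L)))
      for (j in seq_along(cand)) {
        ws <- BiocGenerics::start(cand)[j]
        we <- BiocGenerics::end(cand)[j]
        win <- Biostrings::subseq(seq, ws, we)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(strand_probe), win, type = "local",
          substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
        ncol_aln <- Biostrings::nchar(aln)
        if (ncol_aln >= min_aligned &&
            Biostrings::nmatch(aln) / ncol_aln >= min_identity) {
          sub <- Biostrings::subject(aln)
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = cn,
            start = ws - 1L + BiocGenerics::start(sub) - 1L,
            end = ws - 1L + BiocGenerics::end(sub),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, hits)
  gr <- GenomicRanges::reduce(gr0(res))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Assign read-pair ends to restriction fragments and filter
#'
#' Each end's 5' position is assigned the per-chromosome index of the
#' fragment containing it. Same-chromosome pairs closer than
#' `min_fragment_separation` fragments (strict, on the index difference) are
#' removed as self-ligation / undigested products; trans pairs are always
#' retained. Ends are put in canonical (lexicographic) order and exact
#' duplicates are collapsed to one, mirroring unique-read counting.
#'
#' @param pairs Read-pair data.frame: `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (5' positions, 0-based). See
#'   [bedpe_to_pairs()] for conversion from BEDPE intervals.
#' @param rmap A `restriction_map` from [digest_genome()].
#' @param min_fragment_separation Minimum same-chromosome index separation
#'   (default 100).
#' @return Filtered, deduplicated pairs with `frag1`, `frag2` columns added.
#' @export
pairs_to_fragments <- function(pairs, rmap, min_fragment_separation = 100L) {
  sizes <- attr(rmap, "chrom_sizes")
  starts_by_chrom <- split(rmap$start, rmap$chrom)
  index_by_chrom <- split(rmap$index, rmap$chrom)
  assign_frag <- function(chrom, pos) {
    out <- integer(length(pos))
    for (cn in unique(chrom)) {
      i <- chrom == cn
      st <- starts_by_chrom[[cn]]
      if (is.null(st)) stop("chromosome absent from restriction map: ", cn)
      bad <- pos[i] < 0L | pos[i] >= sizes[[cn]]
      if (any(bad)) stop("read position outside any fragment on ", cn)
      out[i] <- index_by_chrom[[cn]][findInterval(pos[i], st)]
    }
    out
  }
  p <- pairs
  p$frag1 <- assign_frag(p$chrom1, p$pos1)
  p$frag2 <- assign_frag(p$chrom2, p$pos2)
  # canonical end order so the duplicate key is orientation-invariant
  k1 <- paste(p$chrom1, formatC(p$pos1, width = 12, flag = "0"), p$strand1)
  k2 <- paste(p$chrom2, formatC(p$pos2, width = 12, flag = "0"), p$strand2)
  swap <- k2 < k1
  if (any(swap)) {
    tmp <- p[swap, c("chrom1", "pos1", "strand1", "frag1")]
    p[swap, c("chrom1", "pos1", "strand1", "frag1")] <-
      p[swap, c("chrom2", "pos2", "strand2", "frag2")]
    p[swap, c("chrom2", "pos2", "strand2", "frag2")] <- tmp
  }
  cis_close <- p$chrom1 == p$chrom2 &
    abs(p$frag1 - p$frag2) < min_fragment_separation
  p <- p[!cis_close, ]
  key <- paste(p$chrom1, p$pos1, p$strand1, p$chrom2, p$pos2, p$strand2)
  p <- p[!duplicated(key), ]
  rownames(p) <- NULL
  p
}

#' Convert BEDPE intervals to 5'-position read pairs
#'
#' The 5' position of each end is its interval start on the plus strand and
#' `end - 1` on the minus strand.
#'
#' @param bedpe Data.frame from [read_bedpe()].
#' @return Read-pair data.frame (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`).
#' @export
bedpe_to_pairs <- function(bedpe) {
  s1 <- if ("strand1" %in% names(bedpe)) bedpe$strand1 else "+"
  s2 <- if ("strand2" %in% names(bedpe)) bedpe$strand2 else "+"
  data.frame(
    chrom1 = bedpe$chrom1,
    pos1 = ifelse(s1 == "-", bedpe$end1 - 1L, bedpe$start1),
    strand1 = s1,
    chrom2 = bedpe$chrom2,
    pos2 = ifelse(s2 == "-", bedpe$end2 - 1L, bedpe$start2),
    strand2 = s2,
    stringsAsFactors = FALSE)
}

#' Select capture anchor fragments from filtered read pairs
#'
#' Unique-read counts are accumulated per fragment (each retained pair
#' contributes one to each of its two end fragments). The empirical
#' `(1 - top_quantile)` quantile of the observed per-fragment counts sets
#' the threshold and fragments strictly above it are selected, so a flat
#' count vector yields no anchors. Selected fragments are flagged
#' `predicted` when they overlap a probe-target interval; with a TE
#' annotation, anchors not overlapping `target_family` are removed and the
#' removed count is recorded in the `n_removed_off_target` attribute.
#'
#' @param pairs Filtered pairs from [pairs_to_fragments()].
#' @param rmap The `restriction_map` used for assignment.
#' @param top_quantile Upper tail mass selecting anchors (default 0.0005).
#' @param predicted Optional probe-target intervals from
#'   [predict_probe_targets()].
#' @param te Optional TE annotation (`chrom`, `start`, `end`, `family`).
#' @param target_family Family anchors must overlap when `te` is given.
#' @return Anchor data.frame: `chrom`, `start`, `end`, `frag_index`,
#'   `unique_read_count`, `predicted`, `te_families`.
#' @export
select_anchors <- function(pairs, rmap, top_quantile = 0.0005,
                           predicted = NULL, te = NULL,
                           target_family = NULL) {
  empty <- structure(
    data.frame(chrom = character(), start = integer(), end = integer(),
               frag_index = integer(), unique_read_count = integer(),
               predicted = logical(), te_families = character()),
    n_removed_off_target = 0L)
  if (nrow(pairs) == 0L) return(empty)
  if (top_quantile <= 0 || top_quantile >= 0.5)
    stop("top_quantile must be in (0, 0.5)")
  keys <- c(paste(pairs$chrom1, pairs$frag1),
            paste(pairs$chrom2, pairs$frag2))
  tab <- table(keys)
  cnt <- as.integer(tab)
  thr <- stats::quantile(cnt, 1 - top_quantile, names = FALSE)
  sel <- cnt > thr
  if (!any(sel)) return(empty)
  sel_keys <- names(tab)[sel]
  parts <- strsplit(sel_keys, " ", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[`, character(1), 2L))
  rkey <- paste(rmap$chrom, rmap$index)
  row <- match(paste(chrom, idx), rkey)
  out <- data.frame(chrom = chrom, start = rmap$start[row],
                    end = rmap$end[row], frag_index = idx,
                    unique_read_count = cnt[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out$predicted <- FALSE
  if (!is.null(predicted) && nrow(predicted) > 0L && nrow(out) > 0L) {
    ov <- GenomicRanges::findOverlaps(gr0(out), gr0(predicted))
    out$predicted[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  out$te_families <- ""
  n_removed <- 0L
  if (!is.null(te) && nrow(out) > 0L) {
    ov <- GenomicRanges::findOverlaps(gr0(out), gr0(te))
    fam_by_anchor <- split(te$family[S4Vectors::subjectHits(ov)],
                           S4Vectors::queryHits(ov))
    for (k in names(fam_by_anchor))
      out$te_families[as.integer(k)] <-
        paste(sort(unique(fam_by_anchor[[k]])), collapse = ",")
    if (!is.null(target_family)) {
      on <- vapply(strsplit(out$te_families, ",", fixed = TRUE),
                   function(f) target_family %in% f, logical(1))
      n_removed <- sum(!on)
      out <- out[on, ]
      rownames(out) <- NULL
    }
  }
  structure(out, n_removed_off_target = n_removed)
}

#' Load scored interactions (BEDPE or CHiCAGO ibed)
#'
#' Interactions with `score < score_cutoff` are dropped (a score exactly at
#' the cutoff is kept). The ibed dialect is detected by its `bait_chr`
#' header; otherwise 8+-column BEDPE with the score in column 8 is assumed.
#'
#' @param path Path to the interaction file.
#' @param score_cutoff Minimum retained score (default 7.5).
#' @param format `"auto"`, `"bedpe"` or `"ibed"`.
#' @return An interaction data.frame: `anchor_chrom`, `anchor_start`,
#'   `anchor_end`, `anchor_name`, `other_chrom`, `other_start`,
#'   `other_end`, `other_name`, `n_reads`, `score`.
#' @export
load_interactions <- function(path, score_cutoff = 7.5, format = "auto") {
  lines <- readLines(path)
  if (length(lines) == 0L || all(lines == ""))
    return(data.frame(anchor_chrom = character(), anchor_start = integer(),
                      anchor_end = integer(), anchor_name = character(),
                      other_chrom = character(), other_start = integer(),
                      other_end = integer(), other_name = character(),
                      n_reads = integer(), score = numeric()))
  if (format == "auto")
    format <- if (grepl("^bait_chr", lines[1L])) "ibed" else "bedpe"
  parse_fail <- function(i, why)
    stop(sprintf("malformed %s line %d: %s", format, i, why))
  header <- format == "ibed" && grepl("^bait_chr", lines[1L])
  body <- if (header) lines[-1L] else lines
  offset <- if (header) 1L else 0L
  body_idx <- which(body != "")
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (format == "ibed") {
      if (length(f) < 10L) parse_fail(i + offset, "expected 10 columns")
      score <- suppressWarnings(as.numeric(f[10L]))
      nread <- suppressWarnings(as.integer(f[9L]))
      if (is.na(score)) parse_fail(i + offset, "non-numeric score")
      co <- suppressWarnings(as.integer(f[c(2, 3, 6, 7)]))
      if (anyNA(co)) parse_fail(i + offset, "non-integer coordinate")
      rows[[k]] <- data.frame(
        anchor_chrom = f[1L], anchor_start = co[1L], anchor_end = co[2L],
        anchor_name = f[4L], other_chrom = f[5L], other_start = co[3L],
        other_end = co[4L], other_name = f[8L], n_reads = nread,
        score = score, stringsAsFactors = FALSE)
    } else {
      if (length(f) < 8L) parse_fail(i + offset, "expected >= 8 columns")
      score <- suppressWarnings(as.numeric(f[8L]))
      if (is.na(score)) parse_fail(i + offset, "non-numeric score")
      co <- suppressWarnings(as.integer(f[c(2, 3, 5, 6)]))
      if (anyNA(co)) parse_fail(i + offset, "non-integer coordinate")
      nm <- strsplit(f[7L], "|", fixed = TRUE)[[1L]]
      rows[[k]] <- data.frame(
        anchor_chrom = f[1L], anchor_start = co[1L], anchor_end = co[2L],
        anchor_name = if (length(nm) >= 1L) nm[1L] else ".",
        other_chrom = f[4L], other_start = co[3L], other_end = co[4L],
        other_name = if (length(nm) >= 2L) nm[2L] else ".",
        n_reads = NA_integer_, score = score, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$score >= score_cutoff, ]
  rownames(out) <- NULL
  out
}

#' Write interactions in CHiCAGO ibed dialect
#'
#' @param ints Interaction data.frame (see [load_interactions()]).
#' @param path Output path.
#' @export
write_ibed <- function(ints, path) {
  hdr <- paste("bait_chr", "bait_start", "bait_end", "bait_name",
               "otherEnd_chr", "otherEnd_start", "otherEnd_end",
               "otherEnd_name", "N_reads", "score", sep = "\t")
  body <- sprintf("%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%d\t%s",
                  ints$anchor_chrom, ints$anchor_start, ints$anchor_end,
                  ints$anchor_name, ints$other_chrom, ints$other_start,
                  ints$other_end, ints$other_name, ints$n_reads,
                  fmt_num(ints$score))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write interactions as BEDPE with the score in column 8
#'
#' @param ints Interaction data.frame.
#' @param path Output path.
#' @export
write_interactions_bedpe <- function(ints, path) {
  body <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s\t.\t.",
                  ints$anchor_chrom, ints$anchor_start, ints$anchor_end,
                  ints$other_chrom, ints$other_start, ints$other_end,
                  paste(ints$anchor_name, ints$other_name, sep = "|"),
                  fmt_num(ints$score))
  writeLines(body, path)
  invisible(path)
}

#' Binned read-pair signal around one anchor fragment
#'
#' Counts, in sliding bins across the region centered on the anchor
#' fragment's midpoint, the retained pairs that have one end inside the
#' anchor fragment and the other end's 5' position inside the bin. A 1 Mb
#' region with 1 kb bins stepping 500 bp yields 1999 bins.
#'
#' @param pairs Filtered pairs from [pairs_to_fragments()].
#' @param anchor One anchor row (`chrom`, `start`, `end`).
#' @param region_half_width Half-width of the profiled region (default
#'   500 kb).
#' @param bin Bin size (default 1 kb).
#' @param step Step between bin starts (default 500 bp).
#' @return A `window_track` data.frame (`chrom`, `start`, `end`, `value`).
#' @export
anchor_signal_track <- function(pairs, anchor, region_half_width = 500000L,
                                bin = 1000L, step = 500L) {
  mid <- midpoint0(anchor$start[1L], anchor$end[1L])
  cn <- anchor$chrom[1L]
  r0 <- mid - as.integer(region_half_width)
  r1 <- mid + as.integer(region_half_width)
  starts <- seq.int(r0, r1 - bin, by = step)
  in1 <- pairs$chrom1 == cn & pairs$pos1 >= anchor$start[1L] &
    pairs$pos1 < anchor$end[1L]
  in2 <- pairs$chrom2 == cn & pairs$pos2 >= anchor$start[1L] &
    pairs$pos2 < anchor$end[1L]
  other <- c(
    pairs$pos2[in1 & pairs$chrom2 == cn],
    pairs$pos1[in2 & pairs$chrom1 == cn])
  val <- vapply(starts, function(s)
    sum(other >= s & other < s + bin), numeric(1))
  structure(
    data.frame(chrom = cn, start = starts, end = starts + as.integer(bin),
               value = val, stringsAsFactors = FALSE),
    window_size = as.integer(bin), step = as.integer(step),
    class = c("window_track", "data.frame"))
}

#' Median-of-ratios size factors across per-sample tracks
#'
#' Computes median-of-ratios size factors over bins with nonzero value in
#' every sample (the geometric-mean reference construction) and divides each
#' track by its factor.
#'
#' @param tracks Named list of `window_track` data.frames with identical
#'   binning.
#' @return A list with `factors` (named numeric) and `tracks` (normalized).
#' @export
size_factor_normalize <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least 2 samples")
  ref <- tracks[[1L]]
  for (t in tracks[-1L])
    if (!identical(t$start, ref$start) || !identical(t$chrom, ref$chrom))
      stop("tracks must share identical binning")
  mat <- vapply(tracks, function(t) t$value, numeric(nrow(ref)))
  common <- rowSums(mat > 0) == ncol(mat)
  if (!any(common)) stop("no bin with nonzero value in all samples")
  lg <- log(mat[common, , drop = FALSE])
  geo <- rowMeans(lg)
  factors <- exp(apply(lg - geo, 2, stats::median))
  names(factors) <- names(tracks)
  norm <- Map(function(t, f) { t$value <- t$value / f; t },
              tracks, as.list(factors))
  list(factors = factors, tracks = norm)
}

#' Export a per-interaction read-count matrix
#'
#' Writes one row per interaction with per-sample read counts, for external
#' differential testing (negative-binomial tools expect raw counts with an
#' adjusted-p cutoff of 0.01 and |log2 fold change| >= 2 in the workflow
#' this package accompanies; those thresholds are metadata here, not
#' computation).
#'
#' @param ints Interaction data.frame.
#' @param counts Matrix or data.frame of per-sample counts, rows parallel to
#'   `ints`.
#' @param path Output path.
#' @export
export_interaction_counts <- function(ints, counts, path) {
  counts <- as.data.frame(counts)
  if (nrow(counts) != nrow(ints))
    stop("counts rows must parallel interactions")
  df <- cbind(ints[, c("anchor_chrom", "anchor_start", "anchor_end",
                       "other_chrom", "other_start", "other_end")],
              counts)
  write_tsv0(df, path, col.names = TRUE)
}
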