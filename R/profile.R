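#' Filter fragment counts by blacklist and self-ligation quantile
#'
#' Fragments overlapping a blacklist interval are dropped regardless of
#' count. Fragments whose count exceeds the `upper_quantile` empirical
#' quantile of the nonzero-count distribution are then dropped; ties at the
#' threshold are retained. The quantile rule removes the self-ligation /
#' incomplete-digestion pile-ups next to the viewpoint.
#'
#' @param counts Fragment-count data.frame (`chrom`, `start`, `end`,
#'   `frag_id`, `count`).
#' @param blacklist Optional interval data.frame (`chrom`, `start`, `end`).
#' @param upper_quantile Quantile of the nonzero counts above which
#'   fragments are removed (default 0.999).
#' @return The filtered fragment-count data.frame.
#' @export
preprocess_counts <- function(counts, blacklist = NULL,
                              upper_quantile = 0.999) {
  if (upper_quantile <= 0 || upper_quantile >= 1)
    stop("upper_quantile must be in (0, 1)")
  out <- counts
  if (!is.null(blacklist) && nrow(blacklist) > 0L && nrow(out) > 0L) {
    ov <- GenomicRanges::findOverlaps(gr0(out), gr0(blacklist))
    hit <- unique(S4Vectors::queryHits(ov))
    if (length(hit) > 0L) out <- out[-hit, ]
  }
  nz <- out$count[out$count > 0]
  if (length(nz) > 0L) {
    thr <- stats::quantile(nz, upper_quantile, names = FALSE)
    out <- out[out$count <= thr, ]
  }
  rownames(out) <- NULL
  out
}

#' Bin fragment counts into sliding windows
#'
#' Each window's value is the sum of counts of fragments whose midpoint
#' falls inside it; `n_frag` records how many fragment midpoints fall in the
#' window (mappability). When `cap_quantile` is given, window values above
#' that empirical quantile of all window values are reduced to it (the PCR
#' artifact cap used for visualization tracks).
#'
#' @param counts Fragment-count data.frame.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_size Window size in bases (default 100 kb).
#' @param step Step between window starts (default `window_size`, i.e.
#'   non-overlapping; use 25 kb for visualization tracks).
#' @param cap_quantile Optional cap quantile (e.g. 0.75).
#' @return A data.frame of class `window_track`: `chrom`, `start`, `end`,
#'   `value`, `n_frag`, with `window_size` and `step` attributes. The last
#'   window on each chromosome is truncated at the chromosome end.
#' @export
window_counts <- function(counts, chrom_sizes, window_size = 100000L,
                          step = window_size, cap_quantile = NULL) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (step <= 0L) stop("step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  wins <- lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  wins <- do.call(rbind, wins)
  wins$value <- 0
  wins$n_frag <- 0L
  if (nrow(counts) > 0L) {
    mids <- midpoint0(counts$start, counts$end)
    pts <- GenomicRanges::GRanges(counts$chrom,
                                  IRanges::IRanges(mids + 1L, mids + 1L))
    ov <- GenomicRanges::findOverlaps(gr0(wins), pts)
    if (length(ov) > 0L) {
      q <- S4Vectors::queryHits(ov)
      v <- tapply(counts$count[S4Vectors::subjectHits(ov)], q, sum)
      n <- tapply(rep(1L, length(q)), q, sum)
      idx <- as.integer(names(v))
      wins$value[idx] <- as.numeric(v)
      wins$n_frag[idx] <- as.integer(n)
    }
  }
  if (!is.null(cap_quantile)) {
    thr <- stats::quantile(wins$value, cap_quantile, names = FALSE)
    wins$value[wins$value > thr] <- thr
  }
  rownames(wins) <- NULL
  structure(wins, window_size = window_size, step = step,
            chrom_sizes = chrom_sizes,
            class = c("window_track", "data.frame"))
}

#' Per-window enrichment statistics
#'
#' For the mappable windows of a track (at least one fragment midpoint), the
#' z-score against the genome-wide mean and standard deviation, the
#' one-sided upper-tail normal p-value, and the Benjamini-Hochberg adjusted
#' q-value.
#'
#' @param track A `window_track` from [window_counts()].
#' @return The mappable windows with `z`, `p`, `q` columns appended, or
#'   `NULL` when the genome is flat (zero standard deviation).
#' @export
window_zscores <- function(track) {
  inf <- track$n_frag >= 1L
  v <- track$value[inf]
  if (length(v) == 0L) return(NULL)
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (!is.finite(sdv) || sdv == 0) return(NULL)
  out <- track[inf, c("chrom", "start", "end", "value")]
  out$z <- (v - mu) / sdv
  out$p <- stats::pnorm(out$z, lower.tail = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Call observed baits from replicate window tracks
#'
#' Per replicate, a z-score is computed for each mappable window (at least
#' one fragment midpoint) against the genome-wide mean and standard
#' deviation; a one-sided upper-tail normal p-value is converted to a
#' Benjamini-Hochberg q-value and windows with `q < alpha` are kept. Kept
#' windows separated by at most `merge_gap` are merged into regions, and
#' only regions supported by an overlapping region in every replicate are
#' reported; each reported region is the union of its supporting regions.
#'
#' @param tracks List of `window_track` objects (one per replicate, built
#'   with identical non-overlapping windows).
#' @param alpha FDR threshold on the adjusted p-values (default 0.05).
#' @param merge_gap Maximum gap merged between enriched windows (default
#'   100 kb).
#' @return A data.frame of observed baits: `chrom`, `start`, `end`,
#'   `peak_z`, `p_value`, `q_value`, `replicate_support`.
#' @export
detect_observed_baits <- function(tracks, alpha = 0.05,
                                  merge_gap = 100000L) {
  if (!is.list(tracks) || length(tracks) == 0L)
    stop("tracks must be a non-empty list of window tracks")
  if (inherits(tracks, "data.frame")) tracks <- list(tracks)
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) {
    if (!identical(t$chrom, ref$chrom) || !identical(t$start, ref$start) ||
        !identical(t$end, ref$end))
      stop("replicate tracks must share identical windowing")
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_z = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      replicate_support = integer())
  per_rep <- vector("list", length(tracks))
  stats_rep <- vector("list", length(tracks))
  for (r in seq_along(tracks)) {
    win <- window_zscores(tracks[[r]])
    if (is.null(win)) {
      warning("flat genome: window standard deviation is zero; no calls")
      return(empty)
    }
    stats_rep[[r]] <- win
    kept <- win[win$q < alpha, ]
    if (nrow(kept) == 0L) return(empty)
    gr <- GenomicRanges::reduce(gr0(kept),
                                min.gapwidth = as.integer(merge_gap) + 1L)
    per_rep[[r]] <- gr
  }
  all_regions <- do.call(c, per_rep)
  rep_id <- rep(seq_along(per_rep),
                vapply(per_rep, length, integer(1)))
  supported <- logical(length(all_regions))
  for (i in seq_along(all_regions)) {
    ok <- TRUE
    for (r in seq_along(per_rep)) {
      if (r == rep_id[i]) next
      if (IRanges::countOverlaps(all_regions[i], per_rep[[r]]) == 0L) {
        ok <- FALSE; break
      }
    }
    supported[i] <- ok
  }
  if (!any(supported)) return(empty)
  final <- GenomicRanges::reduce(all_regions[supported])
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(final)),
    start = BiocGenerics::start(final) - 1L,
    end = BiocGenerics::end(final),
    peak_z = NA_real_, p_value = NA_real_, q_value = NA_real_,
    replicate_support = length(tracks),
    stringsAsFactors = FALSE)
  # peak statistics: best window (max z) inside each region over replicates
  for (i in seq_len(nrow(out))) {
    best_z <- -Inf; best_p <- NA_real_; best_q <- NA_real_
    for (r in seq_along(stats_rep)) {
      w <- stats_rep[[r]]
      inside <- w$chrom == out$chrom[i] & w$start < out$end[i] &
        w$end > out$start[i]
      if (any(inside)) {
        j <- which(inside)[which.max(w$z[inside])]
        if (w$z[j] > best_z) {
          best_z <- w$z[j]; best_p <- w$p[j]; best_q <- w$q[j]
        }
      }
    }
    out$peak_z[i] <- best_z; out$p_value[i] <- best_p
    out$q_value[i] <- best_q
  }
  out
}

#' Compare two bait/region sets by any-overlap (Venn partition)
#'
#' Partitions two region sets (observed vs predicted baits, or two strains)
#' by any-overlap. Counts are per side: `n_shared_a` counts regions of `a`
#' overlapping at least one region of `b`, and symmetrically; with one-to-one
#' overlaps the two shared counts agree and give the Venn intersection.
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`).
#' @return A list with counts (`n_shared_a`, `n_shared_b`, `n_a_only`,
#'   `n_b_only`) and the corresponding region subsets (`shared_a`,
#'   `shared_b`, `a_only`, `b_only`).
#' @export
compare_bait_sets <- function(a, b) {
  ga <- gr0(a); gb <- gr0(b)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  ia <- unique(S4Vectors::queryHits(ov))
  ib <- unique(S4Vectors::subjectHits(ov))
  list(
    n_shared_a = length(ia),
    n_shared_b = length(ib),
    n_a_only = nrow(a) - length(ia),
    n_b_only = nrow(b) - length(ib),
    shared_a = a[ia, , drop = FALSE],
    shared_b = b[ib, , drop = FALSE],
    a_only = if (length(ia)) a[-ia, , drop = FALSE] else a,
    b_only = if (length(ib)) b[-ib, , drop = FALSE] else b
  )
}

#' Write observed baits as BED6+
#'
#' z, p, q and replicate support go in extra columns.
#'
#' @param baits Output of [detect_observed_baits()].
#' @param path Output path.
#' @export
write_observed_baits <- function(baits, path) {
  df <- data.frame(chrom = baits$chrom, start = baits$start,
                   end = baits$end,
                   name = sprintf("obs_bait_%d", seq_len(nrow(baits))),
                   score = 0L, strand = ".",
                   extra1 = fmt_num(baits$peak_z),
                   extra2 = fmt_num(baits$p_value),
                   extra3 = fmt_num(baits$q_value),
                   extra4 = as.character(baits$replicate_support))
  write_bed(df, path)
}
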