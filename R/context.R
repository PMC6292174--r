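#' Construct a binned contact matrix
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bases.
#' @param matrix Square, symmetric, nonnegative numeric matrix.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("contact matrix must be square")
  if (any(matrix < 0)) stop("contact matrix must be nonnegative")
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("contact matrix must be symmetric within 1e-9")
  dimnames(matrix) <- NULL
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 matrix = matrix),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %d bp\n",
              x$chrom, nrow(x$matrix), x$bin_size))
  invisible(x)
}

#' Read a contact matrix from dense TSV or COO triplets
#'
#' Dense: an n x n tab-separated table. COO: three columns
#' `bin_i`, `bin_j`, `value` (0-based bins); symmetry is completed from the
#' given triangle.
#'
#' @param path Path to the file.
#' @param chrom Chromosome name to attach.
#' @param bin_size Bin size in bases.
#' @param format `"dense"` or `"coo"`.
#' @param n_bins Number of bins (required for COO).
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, chrom, bin_size, format = "dense",
                                n_bins = NULL) {
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  } else if (format == "coo") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("i", "j", "value"))
    if (is.null(n_bins)) n_bins <- max(x$i, x$j) + 1L
    m <- matrix(0, n_bins, n_bins)
    m[cbind(x$i + 1L, x$j + 1L)] <- x$value
    m[cbind(x$j + 1L, x$i + 1L)] <- x$value
  } else stop("unknown contact-matrix format: ", format)
  contact_matrix(chrom, bin_size, m)
}

#' A/B compartment scores from a contact matrix
#'
#' The standard compartment construction: the matrix is distance-normalized
#' (observed / expected, where the expected value of each diagonal is its
#' mean over informative bin pairs), the Pearson correlation matrix of the
#' normalized columns is formed, and the first principal component
#' (leading eigenvector of the correlation matrix) gives one score per bin.
#' The component's sign is flipped, if needed, so that it correlates
#' positively with `reference_track` (e.g. gene density). Bins with zero
#' coverage are masked: score `NA`, excluded from labeling.
#'
#' @param m A `contact_matrix`.
#' @param reference_track Numeric vector, one value per bin, fixing the sign
#'   convention.
#' @return A data.frame of class `compartment_track`: `chrom`, `start`,
#'   `end`, `pc_score`, `label` ("A" iff score > 0, "B" otherwise, `NA`
#'   when masked).
#' @export
compartment_scores <- function(m, reference_track) {
  mat <- m$matrix
  n <- nrow(mat)
  if (length(reference_track) != n)
    stop("reference_track must cover the bins")
  if (all(mat == 0)) stop("all-zero contact matrix")
  informative <- rowSums(mat) > 0
  if (sum(informative) < 10L)
    stop("need at least 10 informative bins")
  sub <- mat[informative, informative, drop = FALSE]
  k <- nrow(sub)
  pos <- which(informative)
  # observed / expected per diagonal of the informative submatrix, using
  # genomic (original-bin) distance
  d <- abs(outer(pos, pos, "-"))
  oe <- sub
  for (dist in unique(as.vector(d))) {
    sel <- d == dist
    ex <- mean(sub[sel])
    oe[sel] <- if (ex > 0) sub[sel] / ex else 0
  }
  cc <- suppressWarnings(stats::cor(oe))
  degenerate <- apply(cc, 2, function(col) all(is.na(col)))
  keep <- !degenerate
  if (sum(keep) < 10L) stop("too few non-degenerate bins")
  cc2 <- cc[keep, keep, drop = FALSE]
  cc2[is.na(cc2)] <- 0
  eig <- eigen(cc2, symmetric = TRUE)
  pc <- eig$vectors[, 1L]
  ref <- reference_track[pos][keep]
  r <- suppressWarnings(stats::cor(pc, ref))
  if (is.finite(r) && r < 0) pc <- -pc
  score <- rep(NA_real_, n)
  score[pos[keep]] <- pc
  starts <- (seq_len(n) - 1L) * m$bin_size
  label <- ifelse(is.na(score), NA_character_,
                  ifelse(score > 0, "A", "B"))
  structure(
    data.frame(chrom = m$chrom, start = starts,
               end = starts + m$bin_size, pc_score = score, label = label,
               stringsAsFactors = FALSE),
    bin_size = m$bin_size,
    class = c("compartment_track", "data.frame"))
}

#' Mean compartment score of regions
#'
#' Per-region coverage-weighted mean of the PC score over overlapped
#' informative bins. Regions overlapping no informative bin get `NA` and are
#' excluded from the positive-fraction denominator.
#'
#' @param regions Interval data.frame on the track's chromosome.
#' @param track A `compartment_track`.
#' @return A list: `scores` (per region) and `fraction_positive`.
#' @export
pc_of_regions <- function(regions, track) {
  if (nrow(regions) == 0L)
    return(list(scores = numeric(0), fraction_positive = NA_real_))
  inf_bins <- track[!is.na(track$pc_score), ]
  scores <- rep(NA_real_, nrow(regions))
  if (nrow(inf_bins) > 0L) {
    ov <- GenomicRanges::findOverlaps(gr0(regions), gr0(inf_bins))
    if (length(ov) > 0L) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- pmin(regions$end[q], inf_bins$end[s]) -
        pmax(regions$start[q], inf_bins$start[s])
      num <- tapply(w * inf_bins$pc_score[s], q, sum)
      den <- tapply(w, q, sum)
      scores[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
    }
  }
  defined <- !is.na(scores)
  list(scores = scores,
       fraction_positive = if (any(defined))
         mean(scores[defined] > 0) else NA_real_)
}

#' Classify interactions by chromosome and TAD membership
#'
#' An interaction is trans when its ends are on different chromosomes. Cis
#' interactions are same-TAD iff both end midpoints fall inside one TAD
#' interval (membership by midpoint, so border-straddling ends classify
#' deterministically).
#'
#' @param ints Interaction data.frame (see [load_interactions()]).
#' @param tads Non-overlapping TAD intervals (`chrom`, `start`, `end`).
#' @return A list: `trans`, `cis_same_tad`, `cis_diff_tad`,
#'   `same_tad_fraction_of_cis`.
#' @export
classify_interactions_by_tad <- function(ints, tads) {
  n <- nrow(ints)
  if (n == 0L)
    return(list(trans = 0L, cis_same_tad = 0L, cis_diff_tad = 0L,
                same_tad_fraction_of_cis = NA_real_))
  tad_of <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (cn in unique(chrom)) {
      i <- which(chrom == cn)
      tt <- which(tads$chrom == cn)
      if (length(tt) == 0L) next
      hit <- outer(pos[i], tads$start[tt], ">=") &
        outer(pos[i], tads$end[tt], "<")
      j <- apply(hit, 1L, function(h) if (any(h)) tt[which(h)[1L]]
                 else NA_integer_)
      out[i] <- j
    }
    out
  }
  amid <- midpoint0(ints$anchor_start, ints$anchor_end)
  omid <- midpoint0(ints$other_start, ints$other_end)
  trans <- ints$anchor_chrom != ints$other_chrom
  ta <- tad_of(ints$anchor_chrom, amid)
  to <- tad_of(ints$other_chrom, omid)
  same <- !trans & !is.na(ta) & !is.na(to) & ta == to
  n_trans <- sum(trans)
  n_same <- sum(same)
  n_diff <- n - n_trans - n_same
  list(trans = n_trans, cis_same_tad = n_same, cis_diff_tad = n_diff,
       same_tad_fraction_of_cis = if (n_trans < n)
         n_same / (n - n_trans) else NA_real_)
}

#' Distances between anchors and their cis interactions
#'
#' Midpoint-to-midpoint distance for cis interactions only; trans
#' interactions are excluded.
#'
#' @param ints Interaction data.frame.
#' @return A list: `distances` (cis only) and `median` (`NA` when no cis
#'   interaction exists).
#' @export
interaction_distance_stats <- function(ints) {
  cis <- ints$anchor_chrom == ints$other_chrom
  d <- abs(midpoint0(ints$anchor_start[cis], ints$anchor_end[cis]) -
             midpoint0(ints$other_start[cis], ints$other_end[cis]))
  list(distances = as.numeric(d),
       median = if (length(d)) stats::median(d) else NA_real_)
}

#' Write a compartment track as bedGraph
#'
#' Masked bins are skipped.
#'
#' @param track A `compartment_track`.
#' @param path Output path.
#' @export
write_compartment_track <- function(track, path) {
  df <- track[!is.na(track$pc_score),
              c("chrom", "start", "end", "pc_score")]
  names(df)[4L] <- "value"
  write_bedgraph(df, path)
}
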