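#' Feature-overlap enrichment with a chromosome-preserving shuffle
#'
#' The observed statistic is the number of interaction other-ends (expanded
#' by `interaction_flank` on both sides) overlapping at least one feature
#' interval (features expanded by `feature_flank`, clipped to chromosome
#' bounds). Each background iteration independently redraws every
#' other-end's start uniformly on its own chromosome (length preserved,
#' shuffled intervals may overlap each other) and recomputes the statistic.
#' The empirical p-value is the fraction of iterations whose background
#' overlap strictly exceeds the observed one — zero is reportable, no
#' pseudocount.
#'
#' @param ints Interaction data.frame (see [load_interactions()]); only the
#'   other-ends are shuffled, the anchors being the fixed viewpoints.
#' @param features Feature intervals (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of chromosome lengths covering every
#'   chromosome that carries an other-end.
#' @param feature_flank Symmetric flank added to features (e.g. 3000 for
#'   gene bodies +/- 3 kb; default 0).
#' @param iterations Number of shuffles (default 1000).
#' @param interaction_flank Symmetric flank added to other-ends (default
#'   1000).
#' @param seed Mandatory RNG seed.
#' @param feature_name Label recorded in the result.
#' @return A list: `feature_name`, `observed`, `background` (length
#'   `iterations`), `background_median`, `empirical_p`.
#' @export
overlap_enrichment <- function(ints, features, chrom_sizes,
                               feature_flank = 0L, iterations = 1000L,
                               interaction_flank = 1000L, seed,
                               feature_name = "feature") {
  if (missing(seed)) stop("seed is required")
  if (iterations < 1L) stop("iterations must be >= 1")
  other <- data.frame(chrom = ints$other_chrom, start = ints$other_start,
                      end = ints$other_end, stringsAsFactors = FALSE)
  if (!all(unique(other$chrom) %in% names(chrom_sizes)))
    stop("interaction chromosome absent from chrom_sizes")
  featx <- expand_clip(features, feature_flank, chrom_sizes)
  fgr <- gr0(featx)
  obs_int <- expand_clip(other, interaction_flank, chrom_sizes)
  observed <- sum(GenomicRanges::countOverlaps(gr0(obs_int), fgr) > 0)
  n <- nrow(other)
  w <- other$end - other$start
  len <- unname(chrom_sizes[other$chrom])
  maxstart <- pmax(0L, len - w)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  draws <- floor(stats::runif(n * iterations) *
                   rep(maxstart + 1L, iterations))
  sh <- data.frame(chrom = rep(other$chrom, iterations),
                   start = as.integer(draws),
                   end = as.integer(draws) + rep(w, iterations),
                   stringsAsFactors = FALSE)
  shx <- expand_clip(sh, interaction_flank, chrom_sizes)
  hit <- GenomicRanges::countOverlaps(gr0(shx), fgr) > 0
  background <- as.integer(rowsum(as.integer(hit),
                                  rep(seq_len(iterations), each = n)))
  list(feature_name = feature_name,
       observed = observed,
       background = background,
       background_median = stats::median(background),
       empirical_p = mean(background > observed))
}

#' Map interactions to gene promoters
#'
#' Keeps interactions with `score > min_score`, in cis, with
#' midpoint-to-midpoint distance strictly below `max_distance`, whose
#' other-end (expanded by `interaction_flank`) overlaps a TSS window
#' (TSS +/- `tss_flank`). Returns the per-anchor number of distinct
#' contacted promoters and the per-promoter number of distinct contacting
#' anchors.
#'
#' @param ints Interaction data.frame.
#' @param tss TSS intervals (`chrom`, `start`, `end`, optional `name`).
#' @param tss_flank Symmetric promoter window half-width (default 2000).
#' @param min_score Strict score threshold (default 10).
#' @param max_distance Strict distance threshold (default 5 Mb).
#' @param interaction_flank Symmetric flank on other-ends (default 1000).
#' @return A list: `per_anchor` (named counts), `per_promoter` (named
#'   counts), `interactions` (qualifying rows with a `promoter` column).
#' @export
promoter_contact_map <- function(ints, tss, tss_flank = 2000L,
                                 min_score = 10, max_distance = 5000000L,
                                 interaction_flank = 1000L) {
  amid <- midpoint0(ints$anchor_start, ints$anchor_end)
  omid <- midpoint0(ints$other_start, ints$other_end)
  cis <- ints$anchor_chrom == ints$other_chrom
  keep <- ints$score > min_score & cis & abs(amid - omid) < max_distance
  cand <- ints[keep, , drop = FALSE]
  empty <- list(per_anchor = integer(0), per_promoter = integer(0),
                interactions = cbind(cand[0, , drop = FALSE],
                                     promoter = character(0)))
  if (nrow(cand) == 0L) return(empty)
  tssx <- expand_clip(tss, tss_flank)
  tss_name <- if ("name" %in% names(tss)) tss$name
              else sprintf("%s:%d-%d", tss$chrom, tss$start, tss$end)
  otherx <- expand_clip(
    data.frame(chrom = cand$other_chrom, start = cand$other_start,
               end = cand$other_end, stringsAsFactors = FALSE),
    interaction_flank)
  ov <- GenomicRanges::findOverlaps(gr0(otherx), gr0(tssx))
  if (length(ov) == 0L) return(empty)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  hits <- cand[q, , drop = FALSE]
  hits$promoter <- tss_name[s]
  anchor_id <- sprintf("%s:%d-%d", hits$anchor_chrom, hits$anchor_start,
                       hits$anchor_end)
  per_anchor <- vapply(split(hits$promoter, anchor_id),
                       function(x) length(unique(x)), integer(1))
  per_promoter <- vapply(split(anchor_id, hits$promoter),
                         function(x) length(unique(x)), integer(1))
  rownames(hits) <- NULL
  list(per_anchor = per_anchor, per_promoter = per_promoter,
       interactions = hits)
}

#' Feature overlap partitioned by genomic context
#'
#' Each interaction other-end is assigned to exactly one partition — TSS
#' window (TSS +/- `tss_flank`), gene body, or intergenic — with TSS taking
#' precedence over gene body. Per-partition counts of other-ends (expanded
#' by `interaction_flank`) overlapping each feature set are returned.
#'
#' @param ints Interaction data.frame.
#' @param tss TSS intervals.
#' @param genes Gene-body intervals.
#' @param features Named list of feature interval data.frames.
#' @param tss_flank Promoter window half-width for partitioning (default
#'   3000).
#' @param interaction_flank Flank on other-ends for feature overlap
#'   (default 1000).
#' @return A data.frame: one row per partition with `n` interactions and
#'   one overlap-count column per feature set.
#' @export
partitioned_overlap <- function(ints, tss, genes, features,
                                tss_flank = 3000L,
                                interaction_flank = 1000L) {
  other <- data.frame(chrom = ints$other_chrom, start = ints$other_start,
                      end = ints$other_end, stringsAsFactors = FALSE)
  ogr <- gr0(other)
  in_tss <- GenomicRanges::countOverlaps(
    ogr, gr0(expand_clip(tss, tss_flank))) > 0
  in_gene <- GenomicRanges::countOverlaps(ogr, gr0(genes)) > 0
  partition <- ifelse(in_tss, "TSS",
                      ifelse(in_gene, "gene_body", "intergenic"))
  partition <- factor(partition,
                      levels = c("TSS", "gene_body", "intergenic"))
  otherx <- gr0(expand_clip(other, interaction_flank))
  out <- data.frame(partition = levels(partition),
                    n = as.integer(table(partition)),
                    stringsAsFactors = FALSE)
  for (fn in names(features)) {
    hit <- GenomicRanges::countOverlaps(otherx, gr0(features[[fn]])) > 0
    out[[fn]] <- as.integer(tapply(hit, partition, sum, default = 0L))
  }
  out
}
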