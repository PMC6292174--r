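#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator: genome geometry,
#' planted-insertion structure (truncation-class fractions, divergence,
#' strain sharing), the contact distance-decay law and background rate, and
#' read/pair depths. The decay law for a read landing at genomic distance d
#' from its viewpoint is proportional to `(1 + d/decay_scale)^-decay_exponent`,
#' cis only. The seed is mandatory: every generator draw flows from it.
#'
#' @param chrom_count Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param n_insertions Number of planted insertions in strain A.
#' @param fraction_full_length,fraction_solo_ltr,fraction_5prime_truncated
#'   Truncation-class fractions (must sum to 1). Truncations are
#'   5'-anchored: the 3' end of the consensus is retained.
#' @param mutation_rate Per-base substitution rate applied to each inserted
#'   copy (divergence from consensus).
#' @param strain_shared_fraction Probability that a strain-A insertion is
#'   also present in strain B.
#' @param decay_exponent,decay_scale Contact decay parameters (defaults 1.5
#'   and 20 kb).
#' @param background_rate Fraction of reads/pairs drawn uniformly rather
#'   than from a viewpoint.
#' @param loop_fraction Fraction of capture pairs from planted loops.
#' @param n_reads 4C reads per replicate.
#' @param n_pairs Capture read pairs.
#' @param insertion_spacing Minimum distance between planted insertions
#'   (default 200 kb, keeping them resolvable by 100 kb windows).
#' @param ltr_length Length of the terminal span retained by a solo-LTR
#'   copy (default 350).
#' @param min_retained Minimum consensus length retained by a 5'-truncated
#'   copy (default 200).
#' @param seed RNG seed (required).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_count = 2L, chrom_length = 10000000L,
                       n_insertions = 15L, fraction_full_length = 0.6,
                       fraction_solo_ltr = 0.2,
                       fraction_5prime_truncated = 0.2,
                       mutation_rate = 0, strain_shared_fraction = 0.7,
                       decay_exponent = 1.5, decay_scale = 20000,
                       background_rate = 0.1, loop_fraction = 0.2,
                       n_reads = 200000L, n_pairs = 10000L,
                       insertion_spacing = 200000L, ltr_length = 350L,
                       min_retained = 200L, seed) {
  if (missing(seed)) stop("seed is required")
  fr <- c(fraction_full_length, fraction_solo_ltr,
          fraction_5prime_truncated)
  if (abs(sum(fr) - 1) > 1e-9) stop("class fractions must sum to 1")
  rates <- c(mutation_rate, strain_shared_fraction, background_rate,
             loop_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(
    chrom_count = as.integer(chrom_count),
    chrom_length = as.integer(chrom_length),
    n_insertions = as.integer(n_insertions),
    fraction_full_length = fraction_full_length,
    fraction_solo_ltr = fraction_solo_ltr,
    fraction_5prime_truncated = fraction_5prime_truncated,
    mutation_rate = mutation_rate,
    strain_shared_fraction = strain_shared_fraction,
    decay_exponent = decay_exponent, decay_scale = decay_scale,
    background_rate = background_rate, loop_fraction = loop_fraction,
    n_reads = as.integer(n_reads), n_pairs = as.integer(n_pairs),
    insertion_spacing = as.integer(insertion_spacing),
    ltr_length = as.integer(ltr_length),
    min_retained = as.integer(min_retained),
    seed = as.integer(seed)), class = "sim_config")
}

random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit)
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

#' Simulate two strain genomes with planted TE insertions
#'
#' Generates a random background genome shared by both strains and plants
#' `n_insertions` copies of the consensus at positions at least
#' `insertion_spacing` apart. Each copy retains a consensus span drawn by
#' truncation class (full length; solo LTR = 3'-terminal `ltr_length`;
#' 5'-truncated = uniform truncation point retaining at least
#' `min_retained`), diverged by per-base substitutions at `mutation_rate`.
#' Insertions overwrite the background segment of equal length, so both
#' strains share one coordinate frame. Strain B carries each strain-A
#' insertion with probability `strain_shared_fraction` and additionally
#' `round(n_insertions * (1 - strain_shared_fraction))` strain-private
#' insertions.
#'
#' @param cfg A [sim_config()].
#' @param consensus Consensus sequence (character).
#' @param primer_sites Optional list of two 0-based consensus spans
#'   (`c(start, end)`) occupied by the primer pair; used to record whether
#'   each planted copy structurally retains both primer segments.
#' @return A list: `genomes` (named list `A`, `B` of `DNAStringSet`) and
#'   `truth` (data.frame: `copy_id`, `chrom`, `start`, `end`, `span_lo`,
#'   `span_hi`, `class`, `retains_primers`, `strain_A`, `strain_B`).
#' @export
simulate_te_genome <- function(cfg, consensus, primer_sites = NULL) {
  set.seed(cfg$seed)
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  if (cfg$chrom_length <= 4L * (cfg$insertion_spacing + L))
    stop("chromosomes too short for the requested insertion spacing")
  chroms <- stats::setNames(
    vapply(seq_len(cfg$chrom_count), function(i)
      random_chrom(cfg$chrom_length), character(1)),
    sprintf("chr%d", seq_len(cfg$chrom_count)))
  n_private_b <- round(cfg$n_insertions * (1 - cfg$strain_shared_fraction))
  n_total <- cfg$n_insertions + n_private_b
  pitch <- cfg$insertion_spacing + L
  slots <- do.call(rbind, lapply(names(chroms), function(cn) {
    pos <- seq.int(cfg$insertion_spacing,
                   cfg$chrom_length - L - cfg$insertion_spacing,
                   by = pitch)
    data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_total)
    stop("cannot place insertions with the required spacing")
  slots <- slots[sample.int(nrow(slots), n_total), ]
  cls <- sample(c("full_length", "solo_ltr", "truncated"), n_total,
                replace = TRUE,
                prob = c(cfg$fraction_full_length, cfg$fraction_solo_ltr,
                         cfg$fraction_5prime_truncated))
  span_lo <- integer(n_total)
  for (i in seq_len(n_total)) {
    span_lo[i] <- switch(cls[i],
      full_length = 0L,
      solo_ltr = max(0L, L - cfg$ltr_length),
      truncated = sample.int(max(1L, L - cfg$min_retained), 1L))
  }
  span_hi <- rep(L, n_total)
  in_b <- c(stats::runif(cfg$n_insertions) < cfg$strain_shared_fraction,
            rep(TRUE, n_private_b))
  in_a <- c(rep(TRUE, cfg$n_insertions), rep(FALSE, n_private_b))
  seqs <- vapply(seq_len(n_total), function(i)
    mutate_seq(substr(consensus, span_lo[i] + 1L, span_hi[i]),
               cfg$mutation_rate), character(1))
  retains <- if (is.null(primer_sites)) rep(NA, n_total) else
    vapply(seq_len(n_total), function(i)
      all(vapply(primer_sites, function(ps)
        ps[1L] >= span_lo[i] && ps[2L] <= span_hi[i], logical(1))),
      logical(1))
  truth <- data.frame(
    copy_id = sprintf("ins_%02d", seq_len(n_total)),
    chrom = slots$chrom, start = slots$pos,
    end = slots$pos + nchar(seqs),
    span_lo = span_lo, span_hi = span_hi, class = cls,
    retains_primers = retains, strain_A = in_a, strain_B = in_b,
    stringsAsFactors = FALSE)
  ord <- order(truth$chrom, truth$start)
  truth <- truth[ord, ]
  seqs <- seqs[ord]
  rownames(truth) <- NULL
  build <- function(strain_mask) {
    g <- chroms
    for (i in which(strain_mask)) {
      cn <- truth$chrom[i]
      substr(g[[cn]], truth$start[i] + 1L, truth$end[i]) <- seqs[i]
    }
    Biostrings::DNAStringSet(g)
  }
  list(genomes = list(A = build(truth$strain_A), B = build(truth$strain_B)),
       truth = truth)
}

#' Simulate fragment-level 4C counts around planted viewpoints
#'
#' Each read is either background (probability `background_rate`, landing
#' uniformly on any mappable reduced-genome flank) or a viewpoint read: a
#' bait insertion is chosen uniformly and the read lands on a flank of the
#' bait's chromosome with probability proportional to
#' `(1 + d/decay_scale)^-decay_exponent`, where d is the distance between
#' flank midpoint and insertion midpoint. Replicates differ only by their
#' position in the seed stream.
#'
#' @param reduced A `reduced_genome` from [build_reduced_genome()]; only
#'   flanks with `unique == TRUE` receive reads.
#' @param truth Truth table rows to use as baits (subset by strain first).
#' @param cfg A [sim_config()].
#' @param replicates Number of replicates (default 2).
#' @return A list of fragment-count data.frames (`chrom`, `start`, `end`,
#'   `frag_id`, `count`), one per replicate.
#' @export
simulate_4c_reads <- function(reduced, truth, cfg, replicates = 2L) {
  frags <- reduced[reduced$unique, , drop = FALSE]
  if (nrow(frags) == 0L) stop("no mappable reduced fragments")
  if (nrow(truth) == 0L) stop("no bait insertions supplied")
  set.seed(cfg$seed)
  mids <- midpoint0(frags$start, frags$end)
  idx_by_chrom <- split(seq_len(nrow(frags)), frags$chrom)
  weights <- lapply(seq_len(nrow(truth)), function(b) {
    idx <- idx_by_chrom[[truth$chrom[b]]]
    if (is.null(idx)) return(NULL)
    bmid <- midpoint0(truth$start[b], truth$end[b])
    d <- abs(mids[idx] - bmid)
    list(idx = idx,
         w = (1 + d / cfg$decay_scale)^(-cfg$decay_exponent))
  })
  lapply(seq_len(replicates), function(r) {
    is_bg <- stats::runif(cfg$n_reads) < cfg$background_rate
    n_bg <- sum(is_bg)
    hits <- integer(0)
    if (n_bg > 0L)
      hits <- sample.int(nrow(frags), n_bg, replace = TRUE)
    n_bait <- cfg$n_reads - n_bg
    if (n_bait > 0L) {
      bait_of <- sample.int(nrow(truth), n_bait, replace = TRUE)
      nb <- tabulate(bait_of, nbins = nrow(truth))
      for (b in seq_len(nrow(truth))) {
        if (nb[b] == 0L || is.null(weights[[b]])) next
        wb <- weights[[b]]
        hits <- c(hits, sample(wb$idx, nb[b], replace = TRUE, prob = wb$w))
      }
    }
    out <- frags[, c("chrom", "start", "end", "frag_id")]
    out$count <- tabulate(hits, nbins = nrow(frags))
    rownames(out) <- NULL
    out
  })
}

#' Build a synthetic uniform restriction map
#'
#' Tiles each chromosome with fixed-size fragments (the last fragment is
#' truncated). A stand-in for a sequence-derived map in simulations that
#' need only fragment geometry.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param fragment_size Fragment size in bases.
#' @return A `restriction_map` data.frame.
#' @export
tile_restriction_map <- function(chrom_sizes, fragment_size = 250L) {
  fragment_size <- as.integer(fragment_size)
  out <- do.call(rbind, lapply(names(chrom_sizes), function(cn) {
    len <- chrom_sizes[[cn]]
    starts <- seq.int(0L, len - 1L, by = fragment_size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + fragment_size, len),
               index = seq_along(starts), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, enzyme = NULL, chrom_sizes = chrom_sizes,
            class = c("restriction_map", "data.frame"))
}

#' Simulate capture read pairs with planted anchors and loops
#'
#' Pairs are a seeded mixture of: anchor-decay pairs (one end uniform inside
#' a planted anchor fragment, the other end on a same-chromosome fragment
#' drawn by the decay law), planted-loop pairs (ends uniform inside the
#' loop's anchor and target fragments, loop chosen with probability
#' proportional to `strength`), and uniform background (both ends uniform
#' over the genome). Natural duplicates are preserved; deduplication is the
#' analysis pipeline's job.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param anchors Anchor intervals (`chrom`, `start`, `end`); each is
#'   assigned the fragment containing its midpoint.
#' @param loops Optional data.frame of planted loops: `anchor_chrom`,
#'   `anchor_pos`, `target_chrom`, `target_pos`, `strength`.
#' @param rmap A `restriction_map` (sequence-derived or
#'   [tile_restriction_map()]).
#' @param cfg A [sim_config()]; uses `n_pairs`, `background_rate`,
#'   `loop_fraction`, decay parameters and `seed`.
#' @return A read-pair data.frame (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`).
#' @export
simulate_capture_experiment <- function(chrom_sizes, anchors, loops = NULL,
                                        rmap, cfg) {
  set.seed(cfg$seed)
  frag_at <- function(chrom, pos) {
    i <- which(rmap$chrom == chrom & rmap$start <= pos & rmap$end > pos)
    if (length(i) == 0L) stop("position outside the restriction map")
    i[1L]
  }
  anchor_rows <- mapply(frag_at, anchors$chrom,
                        midpoint0(anchors$start, anchors$end))
  have_loops <- !is.null(loops) && nrow(loops) > 0L
  n_bg <- round(cfg$n_pairs * cfg$background_rate)
  n_loop <- if (have_loops) round(cfg$n_pairs * cfg$loop_fraction) else 0L
  n_decay <- cfg$n_pairs - n_bg - n_loop
  mids <- midpoint0(rmap$start, rmap$end)
  rows_by_chrom <- split(seq_len(nrow(rmap)), rmap$chrom)
  unif_in <- function(rows)
    rmap$start[rows] +
      floor(stats::runif(length(rows)) * (rmap$end[rows] - rmap$start[rows]))
  p1 <- list(); p2 <- list(); c1 <- list(); c2 <- list()
  if (n_decay > 0L) {
    a <- sample(seq_along(anchor_rows), n_decay, replace = TRUE)
    arow <- anchor_rows[a]
    orow <- integer(n_decay)
    for (ai in unique(a)) {
      sel <- a == ai
      fr <- anchor_rows[ai]
      cis <- rows_by_chrom[[rmap$chrom[fr]]]
      d <- abs(mids[cis] - mids[fr])
      w <- (1 + d / cfg$decay_scale)^(-cfg$decay_exponent)
      orow[sel] <- sample(cis, sum(sel), replace = TRUE, prob = w)
    }
    c1[[1L]] <- rmap$chrom[arow]; p1[[1L]] <- unif_in(arow)
    c2[[1L]] <- rmap$chrom[orow]; p2[[1L]] <- unif_in(orow)
  }
  if (n_loop > 0L) {
    li <- sample(seq_len(nrow(loops)), n_loop, replace = TRUE,
                 prob = loops$strength)
    arow <- mapply(frag_at, loops$anchor_chrom[li], loops$anchor_pos[li])
    trow <- mapply(frag_at, loops$target_chrom[li], loops$target_pos[li])
    k <- length(p1) + 1L
    c1[[k]] <- rmap$chrom[arow]; p1[[k]] <- unif_in(arow)
    c2[[k]] <- rmap$chrom[trow]; p2[[k]] <- unif_in(trow)
  }
  if (n_bg > 0L) {
    draw_unif <- function(n) {
      cn <- sample(names(chrom_sizes), n, replace = TRUE,
                   prob = as.numeric(chrom_sizes))
      list(chrom = cn,
           pos = floor(stats::runif(n) * unname(chrom_sizes[cn])))
    }
    e1 <- draw_unif(n_bg); e2 <- draw_unif(n_bg)
    k <- length(p1) + 1L
    c1[[k]] <- e1$chrom; p1[[k]] <- e1$pos
    c2[[k]] <- e2$chrom; p2[[k]] <- e2$pos
  }
  n_all <- cfg$n_pairs
  data.frame(
    chrom1 = unlist(c1), pos1 = as.integer(unlist(p1)),
    strand1 = sample(c("+", "-"), n_all, replace = TRUE),
    chrom2 = unlist(c2), pos2 = as.integer(unlist(p2)),
    strand2 = sample(c("+", "-"), n_all, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Write simulated read pairs as BEDPE
#'
#' Each end is written as a 1-bp interval at its 5' position.
#'
#' @param pairs Read-pair data.frame.
#' @param path Output path.
#' @export
write_pairs_bedpe <- function(pairs, path) {
  df <- data.frame(chrom1 = pairs$chrom1, start1 = pairs$pos1,
                   end1 = pairs$pos1 + 1L, chrom2 = pairs$chrom2,
                   start2 = pairs$pos2, end2 = pairs$pos2 + 1L,
                   name = sprintf("pair_%d", seq_len(nrow(pairs))),
                   score = 0L, strand1 = pairs$strand1,
                   strand2 = pairs$strand2)
  write_bedpe(df, path)
}
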