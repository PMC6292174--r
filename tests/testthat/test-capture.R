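mk_pairs <- function(c1, p1, c2, p2, s1 = "+", s2 = "+") {
  data.frame(chrom1 = c1, pos1 = as.integer(p1), strand1 = s1,
             chrom2 = c2, pos2 = as.integer(p2), strand2 = s2,
             stringsAsFactors = FALSE)
}

test_that("fragment assignment and the 100-fragment proximity filter", {
  cs <- c(c1 = 100000L, c2 = 100000L)
  rmap <- tile_restriction_map(cs, 250L)
  # fragments 10 and 60: separation 50 < 100 -> removed
  # fragments 10 and 200: separation 190 -> retained
  # trans pair: retained regardless of indices
  pairs <- rbind(
    mk_pairs("c1", 9L * 250L + 10L, "c1", 59L * 250L + 10L),
    mk_pairs("c1", 9L * 250L + 10L, "c1", 199L * 250L + 10L),
    mk_pairs("c1", 9L * 250L + 10L, "c2", 9L * 250L + 10L))
  out <- pairs_to_fragments(pairs, rmap)
  expect_equal(nrow(out), 2L)
  expect_equal(out$frag1, c(10L, 10L))
  expect_equal(out$frag2, c(200L, 10L))
  expect_equal(out$chrom2, c("c1", "c2"))

  # boundary: separation exactly 100 is retained (strict <)
  p100 <- mk_pairs("c1", 0L, "c1", 100L * 250L + 5L)
  expect_equal(nrow(pairs_to_fragments(p100, rmap)), 1L)
  p99 <- mk_pairs("c1", 0L, "c1", 99L * 250L + 5L)
  expect_equal(nrow(pairs_to_fragments(p99, rmap)), 0L)

  # byte-identical duplicates collapse to one, orientation-invariantly
  dup <- rbind(
    mk_pairs("c1", 500L, "c2", 700L),
    mk_pairs("c2", 700L, "c1", 500L))
  outd <- pairs_to_fragments(dup, rmap)
  expect_equal(nrow(outd), 1L)

  # position outside any fragment errors
  bad <- mk_pairs("c1", 100001L, "c1", 50L)
  expect_error(pairs_to_fragments(bad, rmap), "outside")
})

test_that("pairs_to_fragments is idempotent and never grows", {
  set.seed(501)
  cs <- c(c1 = 100000L, c2 = 50000L)
  rmap <- tile_restriction_map(cs, 250L)
  n <- 500
  cn1 <- sample(names(cs), n, TRUE)
  cn2 <- sample(names(cs), n, TRUE)
  pairs <- mk_pairs(cn1, floor(runif(n) * (cs[cn1] - 1)),
                    cn2, floor(runif(n) * (cs[cn2] - 1)),
                    sample(c("+", "-"), n, TRUE),
                    sample(c("+", "-"), n, TRUE))
  once <- pairs_to_fragments(pairs, rmap)
  twice <- pairs_to_fragments(once, rmap)
  expect_identical(once, twice)
  expect_lte(nrow(once), nrow(pairs))
})

test_that("anchor selection equals a full-sort oracle with strict threshold", {
  set.seed(502)
  cs <- c(c1 = 2500000L, c2 = 2500000L)
  rmap <- tile_restriction_map(cs, 250L)  # 10,000 fragments per chrom
  # background counts ~ Poisson(2) on c1; 5 fragments at 400; the partner
  # ends are spread across c2 so they cannot concentrate anywhere
  hot <- c(100L, 2000L, 4000L, 6000L, 9000L)
  bg_frag <- rep(seq_len(10000L), rpois(10000L, 2))
  hot_frag <- rep(hot, each = 400L)
  ends <- c(bg_frag, hot_frag)
  partner <- (seq_along(ends) %% 9000L) + 500L
  pairs <- mk_pairs("c1", (ends - 1L) * 250L + 3L,
                    "c2", (partner - 1L) * 250L + 7L)
  pairs$frag1 <- ends
  pairs$frag2 <- partner
  anc <- select_anchors(pairs, rmap, top_quantile = 0.0005)
  # oracle: aggregate counts, manual type-7 quantile, strictly above
  keys <- c(paste(pairs$chrom1, pairs$frag1),
            paste(pairs$chrom2, pairs$frag2))
  tab <- table(keys)
  thr <- oracle_quantile7(as.numeric(tab), 1 - 0.0005)
  sel <- names(tab)[as.numeric(tab) > thr]
  expect_setequal(paste(anc$chrom, anc$frag_index), sel)
  expect_true(all(hot %in% anc$frag_index))
  # flat counts: nothing strictly above the quantile
  flat <- mk_pairs("c1", (seq_len(1000L) - 1L) * 250L + 3L,
                   "c1", (seq_len(1000L) + 4999L) * 250L + 3L)
  flat2 <- pairs_to_fragments(flat, rmap)
  expect_equal(nrow(select_anchors(flat2, rmap, 0.0005)), 0L)
})

test_that("off-target anchors are removed and tallied", {
  cs <- c(c1 = 1000000L)
  rmap <- tile_restriction_map(cs, 250L)  # 4000 fragments
  # a flat cycle of pairs (every fragment count 2) plus 25 extra pairs on
  # each of fragments 10 and 500, with spread-out partners
  i <- seq_len(4000L)
  cyc <- mk_pairs("c1", (i - 1L) * 250L + 3L,
                  "c1", ((i + 1999L) %% 4000L) * 250L + 3L)
  hot <- mk_pairs("c1", rep(c(10L, 500L) - 1L, each = 25L) * 250L + 7L,
                  "c1", (2999L + seq_len(50L)) * 250L + 7L)
  pairs <- pairs_to_fragments(rbind(cyc, hot), rmap)
  te <- data.frame(chrom = "c1", start = 9L * 250L, end = 10L * 250L,
                   family = "MER41B")
  anc <- select_anchors(pairs, rmap, 0.0005, te = te,
                        target_family = "MER41B")
  expect_equal(anc$frag_index, 10L)
  expect_equal(attr(anc, "n_removed_off_target"), 1L)
})

test_that("probe-target hits agree with a Smith-Waterman oracle", {
  set.seed(503)
  chr <- rand_dna(30000)
  probe <- rand_dna(120)
  substr(chr, 5001, 5120) <- probe
  pm <- strsplit(probe, "")[[1]]
  mut <- sample(120, 15)
  for (i in mut) pm[i] <- sample(setdiff(c("A", "C", "G", "T"), pm[i]), 1)
  diverged <- paste(pm, collapse = "")
  substr(chr, 20001, 20120) <- diverged
  hits <- predict_probe_targets(c(c1 = chr), probe)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start[1], 5000L)
  # the diverged hit may trim terminal mismatches, so allow a few bases
  expect_lte(abs(hits$start[2] - 20000L), 5L)
  # oracle alignment on the diverged window: at least the no-gap score of
  # 105 matches minus 15 mismatches (trimming terminal mismatches can only
  # raise it)
  ora <- oracle_sw(probe, diverged)
  expect_gte(ora$score, 105 - 15)
  expect_lte(ora$score, 105)
  # reverse-complement insertion is found
  chr2 <- rand_dna(10000)
  substr(chr2, 3001, 3120) <- oracle_revcomp(probe)
  h2 <- predict_probe_targets(c(c1 = chr2), probe)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$start, 3000L)
  # shuffled probe against a fresh genome: no hits
  sp <- paste(sample(strsplit(probe, "")[[1]]), collapse = "")
  expect_equal(nrow(predict_probe_targets(c(c1 = rand_dna(50000)), sp)),
               0L)
})

test_that("local alignment identities match the DP oracle on variants", {
  set.seed(504)
  probe <- rand_dna(100)
  for (nmut in c(0, 5, 10, 20)) {
    pm <- strsplit(probe, "")[[1]]
    if (nmut > 0) {
      mut <- sample(100, nmut)
      for (i in mut) pm[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                             pm[i]), 1)
    }
    target <- paste(pm, collapse = "")
    chr <- paste0(rand_dna(500), target, rand_dna(500))
    # short exact seeds so divergence cannot defeat candidate discovery
    # and the alignment itself decides
    hits <- predict_probe_targets(c(c1 = chr), probe,
                                  min_identity = 0.75, seed_k = 6L)
    ora <- oracle_sw(probe, target)
    expect_equal(nrow(hits), 1L, info = paste("nmut", nmut))
    # the no-gap alignment is a lower bound on the oracle optimum
    expect_gte(ora$score, 100 - 2 * nmut)
    expect_lte(ora$score, 100)
  }
})

test_that("interaction loading applies the score cutoff at the boundary", {
  ints <- data.frame(
    anchor_chrom = "c1", anchor_start = c(100L, 200L, 300L),
    anchor_end = c(150L, 250L, 350L), anchor_name = c("a", "b", "c"),
    other_chrom = "c2", other_start = 1000L, other_end = 1100L,
    other_name = "o", n_reads = 4L, score = c(7.4, 7.5, 9.9),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".ibed")
  write_ibed(ints, f)
  got <- load_interactions(f)
  expect_equal(got$score, c(7.5, 9.9))

  # empty file
  fe <- tempfile(); writeLines(character(0), fe)
  expect_equal(nrow(load_interactions(fe)), 0L)

  # BEDPE and ibed encodings parse to the same interactions
  fb <- tempfile(fileext = ".bedpe")
  write_interactions_bedpe(ints, fb)
  gb <- load_interactions(fb, score_cutoff = 0)
  gi <- load_interactions(f, score_cutoff = 0)
  expect_equal(gb[, c("anchor_chrom", "anchor_start", "anchor_end",
                      "other_chrom", "other_start", "other_end",
                      "score")],
               gi[, c("anchor_chrom", "anchor_start", "anchor_end",
                      "other_chrom", "other_start", "other_end",
                      "score")])

  # malformed line reports its line number
  fm <- tempfile()
  writeLines(c("c1\t1\t2\tc2\t3\t4\tn\t5.0\t.\t.",
               "c1\t1\t2\tc2\t3\t4\tn\tNOTANUMBER\t.\t."), fm)
  expect_error(load_interactions(fm), "line 2")
})

test_that("anchor signal bins slide correctly around the viewpoint", {
  anchor <- data.frame(chrom = "c1", start = 5000000L, end = 5000250L)
  pairs <- mk_pairs("c1", c(5000100L, 5000100L, 5000200L),
                    "c1", c(5100000L, 5100400L, 4600000L))
  tr <- anchor_signal_track(pairs, anchor)
  expect_equal(nrow(tr), 1999L)
  # an other-end in the overlap of two bins is counted in both
  # ([5099500,5100500) holds one end; [5100000,5101000) holds two)
  hit_bins <- tr$value[tr$start <= 5100000L & tr$end > 5100000L]
  expect_equal(hit_bins, c(1, 2))
  # a pair with its other end outside the region is ignored
  far <- mk_pairs("c1", 5000100L, "c1", 9000000L)
  expect_equal(sum(anchor_signal_track(far, anchor)$value), 0)
})

test_that("size factors recover scale differences by median of ratios", {
  base <- structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 500L,
                                             length.out = 100L),
               end = seq.int(1000L, by = 500L, length.out = 100L),
               value = c(rep(2, 50), rep(6, 50))),
    window_size = 1000L, step = 500L,
    class = c("window_track", "data.frame"))
  t2 <- base; t2$value <- base$value * 2
  sf <- size_factor_normalize(list(a = base, b = t2))
  expect_equal(unname(sf$factors["b"] / sf$factors["a"]), 2,
               tolerance = 1e-12)
  expect_equal(sf$tracks$a$value, sf$tracks$b$value, tolerance = 1e-9)

  # identical samples get identical factors
  sfi <- size_factor_normalize(list(a = base, b = base))
  expect_equal(unname(sfi$factors), c(1, 1), tolerance = 1e-12)

  # bins zero in one sample are excluded from the median
  t3 <- base; t3$value[1:10] <- 0
  sf3 <- size_factor_normalize(list(a = base, b = t3))
  expect_equal(unname(sf3$factors), c(1, 1), tolerance = 1e-12)

  # no common nonzero bin errors
  t4 <- base; t4$value <- 0
  expect_error(size_factor_normalize(list(a = base, b = t4)),
               "no bin")
})
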