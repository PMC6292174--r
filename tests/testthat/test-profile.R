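make_counts <- function(counts, spacing = 1000L, chrom = "c1") {
  n <- length(counts)
  starts <- seq.int(0L, by = spacing, length.out = n)
  data.frame(chrom = chrom, start = starts, end = starts + 25L,
             frag_id = sprintf("f%d", seq_len(n)), count = counts,
             stringsAsFactors = FALSE)
}

test_that("count filtering drops the upper-quantile tail and blacklist", {
  fc <- make_counts(c(1:1000, 1e6))
  out <- preprocess_counts(fc)
  thr <- oracle_quantile7(fc$count[fc$count > 0], 0.999)
  expect_equal(out$count, fc$count[fc$count <= thr])
  expect_false(1e6 %in% out$count)

  # blacklist removal is unconditional
  fc2 <- make_counts(c(5, 5, 5, 5))
  bl <- data.frame(chrom = "c1", start = 1990L, end = 2100L)
  out2 <- preprocess_counts(fc2, blacklist = bl)
  expect_equal(out2$frag_id, c("f1", "f2", "f4"))

  # all counts equal: ties at the threshold are retained
  fc3 <- make_counts(rep(7L, 50))
  expect_equal(nrow(preprocess_counts(fc3)), 50L)
  expect_error(preprocess_counts(fc3, upper_quantile = 1), "in \\(0, 1\\)")
})

test_that("window counting sums fragment midpoints with optional cap", {
  cs <- c(c1 = 200000L)
  fc <- data.frame(chrom = "c1", start = c(10000L, 30000L),
                   end = c(10025L, 30025L), frag_id = c("a", "b"),
                   count = c(1L, 1L))
  tr <- window_counts(fc, cs, 100000L, 25000L)
  expect_equal(tr$value[1], 2)          # both midpoints in [0, 100k)
  expect_equal(attr(tr, "step"), 25000L)
  # truncated final windows still tile to the chromosome end
  expect_equal(max(tr$end), 200000L)

  # cap reduces values above the track quantile to the quantile
  fc4 <- make_counts(c(1, 1, 1, 100), spacing = 50000L)
  cs4 <- c(c1 = 200000L)
  tr4 <- window_counts(fc4, cs4, 50000L, 50000L, cap_quantile = 0.75)
  expect_equal(max(tr4$value), oracle_quantile7(c(1, 1, 1, 100), 0.75))

  # empty counts give an all-zero track
  tr5 <- window_counts(fc[0, ], cs, 100000L, 100000L)
  expect_true(all(tr5$value == 0))
  expect_true(all(tr5$n_frag == 0L))
})

test_that("uncapped non-overlapping windows conserve total counts", {
  set.seed(401)
  cs <- c(c1 = 1000000L, c2 = 500000L)
  n <- 300
  chrom <- sample(names(cs), n, replace = TRUE)
  pos <- floor(runif(n) * (cs[chrom] - 25))
  fc <- data.frame(chrom = chrom, start = as.integer(pos),
                   end = as.integer(pos) + 25L,
                   frag_id = sprintf("f%d", 1:n),
                   count = rpois(n, 4))
  tr <- window_counts(fc, cs, 100000L, 100000L)
  expect_equal(sum(tr$value), sum(fc$count))
  for (cn in names(cs))
    expect_equal(sum(tr$value[tr$chrom == cn]),
                 sum(fc$count[fc$chrom == cn]))
})

test_that("window z, p and BH q match direct computation", {
  set.seed(402)
  n <- 2000
  vals <- rpois(n, 5)
  track <- structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 100000L,
                                             length.out = n),
               end = seq.int(100000L, by = 100000L, length.out = n),
               value = as.numeric(vals), n_frag = 1L),
    window_size = 1e5L, step = 1e5L,
    class = c("window_track", "data.frame"))
  zs <- window_zscores(track)
  mu <- mean(vals); sdv <- sqrt(sum((vals - mu)^2) / (n - 1))
  z_ora <- (vals - mu) / sdv
  p_ora <- 1 - pnorm(z_ora)
  expect_lt(max(abs(zs$z - z_ora) / pmax(abs(z_ora), 1e-12)), 1e-9)
  expect_lt(max(abs(zs$p - p_ora) / pmax(p_ora, 1e-300)), 1e-6)
  expect_lt(max(abs(zs$q - oracle_bh(zs$p))), 1e-12)
})

test_that("BH adjustment equals the manual reference on random vectors", {
  set.seed(403)
  for (n in c(10, 1000, 20000)) {
    p <- runif(n)^2
    expect_lt(max(abs(p.adjust(p, "BH") - oracle_bh(p))), 1e-12)
  }
})

test_that("a single enriched window is called with oracle statistics", {
  set.seed(404)
  n <- 1000
  vals <- rpois(n, 5)
  vals[500] <- 500
  mk <- function(v) structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 100000L,
                                             length.out = n),
               end = seq.int(100000L, by = 100000L, length.out = n),
               value = as.numeric(v), n_frag = 1L),
    window_size = 1e5L, step = 1e5L,
    class = c("window_track", "data.frame"))
  ob <- detect_observed_baits(list(mk(vals), mk(vals)))
  expect_equal(nrow(ob), 1L)
  expect_equal(ob$start, 499L * 100000L)
  mu <- mean(vals); sdv <- sd(vals)
  z_ora <- (500 - mu) / sdv
  expect_lt(abs(ob$peak_z - z_ora) / z_ora, 1e-9)
  p_ora <- 1 - pnorm(z_ora)
  q_ora <- oracle_bh(1 - pnorm((vals - mu) / sdv))[500]
  expect_equal(ob$p_value, p_ora, tolerance = 1e-9)
  expect_equal(ob$q_value, q_ora, tolerance = 1e-9)
  expect_equal(ob$replicate_support, 2L)
})

test_that("flat genomes and gap merging behave as specified", {
  n <- 50
  mk <- function(v) structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 100000L,
                                             length.out = n),
               end = seq.int(100000L, by = 100000L, length.out = n),
               value = as.numeric(v), n_frag = 1L),
    window_size = 1e5L, step = 1e5L,
    class = c("window_track", "data.frame"))
  # all windows equal: no calls, warning
  expect_warning(ob0 <- detect_observed_baits(list(mk(rep(5, n)))),
                 "flat")
  expect_equal(nrow(ob0), 0L)

  # two significant windows separated by one window are merged
  v <- rpois(n, 5)
  v[c(20, 22)] <- 400
  set.seed(405)
  ob <- detect_observed_baits(list(mk(v)))
  expect_equal(nrow(ob), 1L)
  expect_equal(c(ob$start, ob$end), c(19L * 100000L, 22L * 100000L))

  # a gap wider than merge_gap keeps regions separate
  v2 <- rpois(n, 5)
  v2[c(20, 24)] <- 400
  ob2 <- detect_observed_baits(list(mk(v2)))
  expect_equal(nrow(ob2), 2L)
})

test_that("replicate intersection requires support in every replicate", {
  n <- 60
  mk <- function(v) structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 100000L,
                                             length.out = n),
               end = seq.int(100000L, by = 100000L, length.out = n),
               value = as.numeric(v), n_frag = 1L),
    window_size = 1e5L, step = 1e5L,
    class = c("window_track", "data.frame"))
  set.seed(406)
  v1 <- rpois(n, 5); v2 <- rpois(n, 5)
  v1[c(10, 40)] <- 400   # windows 10 and 40 enriched in rep 1
  v2[10] <- 400          # only window 10 enriched in rep 2
  ob <- detect_observed_baits(list(mk(v1), mk(v2)))
  expect_equal(nrow(ob), 1L)
  expect_equal(ob$start, 9L * 100000L)
})

test_that("raising a called window's count never removes it", {
  set.seed(407)
  n <- 500
  v <- rpois(n, 5)
  v[c(100, 200, 300)] <- c(120, 200, 400)
  mk <- function(x) structure(
    data.frame(chrom = "c1", start = seq.int(0L, by = 100000L,
                                             length.out = n),
               end = seq.int(100000L, by = 100000L, length.out = n),
               value = as.numeric(x), n_frag = 1L),
    window_size = 1e5L, step = 1e5L,
    class = c("window_track", "data.frame"))
  called <- function(x) {
    ob <- detect_observed_baits(list(mk(x)))
    sort(ob$start)
  }
  base_calls <- called(v)
  for (w in c(100, 200, 300)) {
    s <- (w - 1L) * 100000L
    if (!s %in% base_calls) next
    for (mult in c(2, 10)) {
      v2 <- v; v2[w] <- v[w] * mult
      expect_true(s %in% called(v2),
                  info = sprintf("window %d at x%g", w, mult))
    }
  }
})

test_that("bait-set comparison partitions by any-overlap", {
  a <- data.frame(chrom = "c1", start = c(0L, 1000L, 2000L, 3000L, 4000L),
                  end = c(100L, 1100L, 2100L, 3100L, 4100L))
  cmpi <- compare_bait_sets(a, a)
  expect_equal(cmpi$n_shared_a, 5L)
  expect_equal(cmpi$n_a_only, 0L)
  expect_equal(cmpi$n_b_only, 0L)

  b <- data.frame(chrom = "c1", start = c(10000L, 11000L, 12000L, 13000L),
                  end = c(10100L, 11100L, 12100L, 13100L))
  cmpd <- compare_bait_sets(a[1:3, ], b)
  expect_equal(cmpd$n_shared_a, 0L)
  expect_equal(cmpd$n_a_only, 3L)
  expect_equal(cmpd$n_b_only, 4L)
  expect_equal(cmpd$n_shared_a + cmpd$n_a_only, 3L)
  expect_equal(cmpd$n_shared_b + cmpd$n_b_only, 4L)
})
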