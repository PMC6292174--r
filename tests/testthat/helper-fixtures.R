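# Shared fixtures and independent oracles, all built in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Consensus with a controlled site layout: DpnII (GATC) at 0-based offsets
# 100 and 900, Csp6I (GTAC) at 300, and no other occurrence of either site.
make_consensus <- function(len = 1500, seed = 42) {
  set.seed(seed)
  cons <- rand_dna(len)
  cons <- gsub("GATC", "AATC", cons)
  cons <- gsub("GTAC", "ATAC", cons)
  substr(cons, 101, 104) <- "GATC"
  substr(cons, 901, 904) <- "GATC"
  substr(cons, 301, 304) <- "GTAC"
  cons
}

dpnii <- restriction_enzyme("DpnII", "GATC", 0)
csp6i <- restriction_enzyme("Csp6I", "GTAC", 1)

# --- independent oracles -------------------------------------------------

# brute-force forward-strand site scan by explicit substring comparison
oracle_site_scan <- function(seq, site) {
  L <- nchar(site)
  n <- nchar(seq)
  if (n < L) return(integer(0))
  starts <- 0:(n - L)
  hits <- vapply(starts, function(s)
    substr(seq, s + 1, s + L) == site, logical(1))
  starts[hits]
}

# count exact occurrences of a pattern in a sequence at every offset
oracle_substring_count <- function(seq, pat) {
  L <- nchar(pat)
  n <- nchar(seq)
  if (n < L) return(0L)
  sum(vapply(0:(n - L), function(s)
    substr(seq, s + 1, s + L) == pat, logical(1)))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force in-silico PCR primer scan: every offset of the genome is
# examined on both strands (vectorized substring comparisons, no seeding)
oracle_primer_scan <- function(seq, primer, block = 15, max_mm = 2) {
  L <- nchar(primer)
  n <- nchar(seq)
  if (n < L) return(data.frame(start = integer(), strand = character()))
  starts <- 0:(n - L)
  rp <- oracle_revcomp(primer)
  mism_vec <- function(wins, ref) {
    if (nchar(ref) == 0L) return(rep(0L, length(wins)))
    refv <- strsplit(ref, "")[[1]]
    vapply(strsplit(wins, ""), function(w) sum(w != refv), integer(1))
  }
  out <- list()
  # plus strand: 3' block is the last `block` bases of the primer
  blk_p <- substr(primer, L - block + 1, L)
  cand <- starts[substring(seq, starts + (L - block) + 1,
                           starts + L) == blk_p]
  if (length(cand)) {
    mm <- mism_vec(substring(seq, cand + 1, cand + (L - block)),
                   substr(primer, 1, L - block))
    keep <- cand[mm <= max_mm]
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(start = keep, strand = "+")
  }
  # minus strand: segment reads as revcomp(primer); 3' block comes first
  blk_m <- substr(rp, 1, block)
  cand <- starts[substring(seq, starts + 1, starts + block) == blk_m]
  if (length(cand)) {
    mm <- mism_vec(substring(seq, cand + block + 1, cand + L),
                   substr(rp, block + 1, L))
    keep <- cand[mm <= max_mm]
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(start = keep, strand = "-")
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), strand = character()))
  do.call(rbind, out)
}

# manual Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# manual type-7 empirical quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# Smith-Waterman local alignment score/identity oracle
# match +1 / mismatch -1 / gap open -2 / gap extend -1 (affine)
oracle_sw <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (deletion)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (insertion)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (va[i - 1] == vb[j - 1]) 1 else -1
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - 3, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 3, Y[i, j - 1] - 1)
      h <- max(M[i, j], X[i, j], Y[i, j])
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  list(score = best, end_a = bi - 1, end_b = bj - 1)
}

# power-iteration leading eigenvector (independent of eigen())
oracle_pc1 <- function(mat, iters = 2000) {
  v <- rep(1, nrow(mat)) + seq_len(nrow(mat)) / nrow(mat)
  for (i in seq_len(iters)) {
    v2 <- mat %*% v
    v <- as.numeric(v2) / sqrt(sum(v2^2))
  }
  v
}

# The hand-enumerated 8-interaction toy set with TADs and TSS windows.
# Anchor 1 = cA:[1000,1200) (mid 1100, TAD1); anchor 2 = cA:[25000,25200)
# (mid 25100, TAD2). TADs on cA: [0,20000), [20000,60000), [60000,100000).
toy_interactions <- function() {
  ints <- data.frame(
    anchor_chrom = c("cA", "cA", "cA", "cA", "cA", "cA", "cA", "cA"),
    anchor_start = c(1000L, 1000L, 1000L, 1000L, 25000L, 25000L, 25000L,
                     1000L),
    anchor_end = c(1200L, 1200L, 1200L, 1200L, 25200L, 25200L, 25200L,
                   1200L),
    anchor_name = c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "a1"),
    other_chrom = c("cA", "cA", "cA", "cB", "cA", "cA", "cB", "cA"),
    other_start = c(5000L, 30000L, 61000L, 1000L, 45000L, 90000L, 50000L,
                    15000L),
    other_end = c(5200L, 30200L, 61200L, 1200L, 45200L, 90200L, 50200L,
                  15200L),
    other_name = sprintf("o%d", 1:8),
    n_reads = 1L,
    score = c(12, 8, 11, 9, 15, 10, 20, 10.5),
    stringsAsFactors = FALSE)
  tads <- data.frame(chrom = "cA", start = c(0L, 20000L, 60000L),
                     end = c(20000L, 60000L, 100000L))
  tss <- data.frame(chrom = c("cA", "cA", "cA", "cB"),
                    start = c(15600L, 45500L, 90100L, 50100L),
                    end = c(15601L, 45501L, 90101L, 50101L),
                    name = c("t1", "t2", "t3", "t4"))
  list(ints = ints, tads = tads, tss = tss)
}
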