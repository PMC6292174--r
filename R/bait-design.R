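#' Enumerate bait candidates on a TE family consensus
#'
#' A 4C bait fragment on the consensus is delimited by two adjacent primary
#' enzyme sites at least `min_primary` bases apart and must contain a
#' secondary enzyme site at least `min_secondary` bases downstream of the
#' left (reading-side) primary site. Candidates read left-to-right: the
#' reading primer sits on the left primary site and the nearest qualifying
#' secondary site is recorded.
#'
#' @param consensus Consensus sequence (character) of the TE family.
#' @param primary,secondary [restriction_enzyme()] objects (must differ).
#' @param min_primary Minimum spacing between adjacent primary sites
#'   (default 300 bp).
#' @param min_secondary Minimum distance from the reading primary site to the
#'   secondary site (default 150 bp).
#' @return A data.frame with one row per candidate: `primary_site_pos`,
#'   `partner_primary_site_pos`, `secondary_site_pos`, `primary_spacing`,
#'   `primary_to_secondary` (all 0-based consensus offsets).
#' @export
enumerate_bait_candidates <- function(consensus, primary, secondary,
                                      min_primary = 300L,
                                      min_secondary = 150L) {
  if (identical(primary$site, secondary$site))
    stop("primary and secondary enzymes must be distinct")
  consensus <- toupper(consensus)
  p <- scan_restriction_sites(consensus, primary)
  s <- scan_restriction_sites(consensus, secondary)
  empty <- data.frame(primary_site_pos = integer(),
                      partner_primary_site_pos = integer(),
                      secondary_site_pos = integer(),
                      primary_spacing = integer(),
                      primary_to_secondary = integer())
  if (length(p) < 2L) return(empty)
  s_len <- nchar(secondary$site)
  rows <- lapply(seq_len(length(p) - 1L), function(i) {
    p1 <- p[i]; p2 <- p[i + 1L]
    if (p2 - p1 < min_primary) return(NULL)
    ok <- s[s - p1 >= min_secondary & s + s_len <= p2]
    if (length(ok) == 0L) return(NULL)
    s1 <- min(ok)
    data.frame(primary_site_pos = p1, partner_primary_site_pos = p2,
               secondary_site_pos = s1, primary_spacing = p2 - p1,
               primary_to_secondary = s1 - p1)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design the primer pair for one bait candidate
#'
#' The reading primer is the 20-mer ending at the 3' end of the primary site
#' (site included), reading into the bait fragment. The second primer is
#' chosen by exhaustive scoring over every window of length 18-27 between the
#' primary and secondary sites: windows containing N or with GC outside
#' `[0.20, 0.80]` are disqualified; among the rest the melting-temperature
#' estimate closest to `target_tm` wins, ties broken by shorter length, then
#' leftmost position. The second primer is reported as the reverse complement
#' of the winning window (it anneals to the opposite strand, facing the
#' reading primer).
#'
#' @param candidate One row of [enumerate_bait_candidates()] output.
#' @param consensus The consensus sequence the candidate was enumerated on.
#' @param primary The primary [restriction_enzyme()].
#' @param target_tm Target melting temperature (degrees C, default 60).
#' @return A one-row data.frame: primer sequences, 0-based positions,
#'   orientations, GC fractions and Tm estimates.
#' @export
design_primer_pair <- function(candidate, consensus, primary,
                               target_tm = 60) {
  consensus <- toupper(consensus)
  p1 <- candidate$primary_site_pos[1L]
  s1 <- candidate$secondary_site_pos[1L]
  site_len <- nchar(primary$site)
  r_start <- p1 + site_len - 20L
  if (r_start < 0L)
    stop(sprintf("candidate at %d: too close to consensus start for a 20-nt reading primer", p1))
  reading <- substr(consensus, r_start + 1L, p1 + site_len)
  region_start <- p1 + site_len
  region_end <- s1
  if (region_end - region_start < 18L)
    stop(sprintf("candidate at %d: fragment too short to place both primers", p1))
  best <- NULL
  for (len in 18:27) {
    if (region_end - len < region_start) next
    starts <- region_start:(region_end - len)
    wins <- substring(consensus, starts + 1L, starts + len)
    gc <- gc_fraction(wins)
    ok <- !grepl("N", wins, fixed = TRUE) & gc >= 0.20 & gc <= 0.80
    if (!any(ok)) next
    dt <- abs(tm_estimate(wins) - target_tm)
    dt[!ok] <- Inf
    i <- which.min(dt)  # leftmost among Tm ties within a length
    cand <- list(start = starts[i], len = len, seq = wins[i],
                 dtm = dt[i], gc = gc[i])
    if (is.finite(cand$dtm) &&
        (is.null(best) || cand$dtm < best$dtm - 1e-12 ||
         (abs(cand$dtm - best$dtm) <= 1e-12 && cand$len < best$len)))
      best <- cand
  }
  if (is.null(best))
    stop(sprintf("candidate at %d: no qualifying second-primer window", p1))
  data.frame(
    reading_primer = reading, reading_pos = r_start,
    reading_strand = "+",
    second_primer = revcomp(best$seq), second_pos = best$start,
    second_len = best$len, second_strand = "-",
    reading_gc = gc_fraction(reading), reading_tm = tm_estimate(reading),
    second_gc = best$gc, second_tm = tm_estimate(best$seq),
    stringsAsFactors = FALSE
  )
}

#' Design all primer pairs for a TE family consensus
#'
#' Convenience wrapper: enumerate bait candidates, design a primer pair for
#' each, and return a combined report. Candidates where primer placement
#' fails are dropped with a message.
#'
#' @inheritParams enumerate_bait_candidates
#' @inheritParams design_primer_pair
#' @param family Family name recorded in the report.
#' @return Data.frame combining candidate coordinates with primer designs.
#' @export
design_baits <- function(consensus, primary, secondary, family = "TE",
                         min_primary = 300L, min_secondary = 150L,
                         target_tm = 60) {
  cands <- enumerate_bait_candidates(consensus, primary, secondary,
                                     min_primary, min_secondary)
  if (nrow(cands) == 0L) {
    return(cbind(data.frame(family = character()), cands))
  }
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    pp <- tryCatch(design_primer_pair(cands[i, ], consensus, primary,
                                      target_tm),
                   error = function(e) {
                     message("dropping candidate: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(pp)) return(NULL)
    cbind(data.frame(family = family), cands[i, ], pp, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(cbind(data.frame(family = character()), cands[0, ]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write designed primers to FASTA
#'
#' @param baits Output of [design_baits()].
#' @param path Output path.
#' @export
write_primer_fasta <- function(baits, path) {
  seqs <- c(rbind(baits$reading_primer, baits$second_primer))
  names(seqs) <- c(rbind(
    sprintf("%s_bait%d_reading", baits$family, seq_len(nrow(baits))),
    sprintf("%s_bait%d_second", baits$family, seq_len(nrow(baits)))))
  write_fasta(seqs, path)
}
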