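# fourTran

Chromosome-conformation profiling from repetitive transposable-element (TE)
viewpoints.

Viewpoint assays such as 4C-seq profile all chromatin contacts of one
genomic locus, but endogenous retroviruses (ERVs) and other TEs exist in
hundreds of near-identical copies, so a "single viewpoint" does not exist
for them. fourTran implements the computational workflow for two
family-level variants of the assay:

* **PCR-based TE profiling** — primers designed against the family
  *consensus* amplify circularized ligation products from every genomic
  copy that retains the primer sequences. Reads map only to unique
  sequence, so each amplifiable insertion produces a local pile-up
  ("bait-like profile") around its own integration site. The package
  designs the primers, predicts amplifiable copies genome-wide by
  in-silico PCR, calls observed bait profiles statistically from
  fragment-level counts, and compares observed/predicted sets and strains.
* **Capture-based TE profiling** — a consensus-matching oligo captures
  Hi-C ligation junctions touching any copy, so both interaction ends are
  sequenced. The package predicts probe targets by local alignment,
  assigns read pairs to restriction fragments, detects anchor fragments by
  an upper-quantile rule, imports scored interactions (BEDPE / CHiCAGO
  ibed), and builds size-factor-normalized signal tracks.

Around both assays it provides A/B-compartment scoring from binned contact
matrices (observed/expected → correlation → first principal component,
sign-oriented by a reference track), TAD-context classification,
distance statistics, promoter-contact mapping, permutation-based feature
enrichment with a chromosome-preserving shuffle, and a fully seeded
simulator (planted insertions with 5'-truncation/solo-LTR structure,
strain polymorphism, distance-decay 4C reads, capture pairs with planted
loops) that serves as the ground-truth substrate for every statistical
component.

## The statistics at the core

For fragment counts aggregated in genome-wide windows `x_1..x_N`, a window
is an **observed bait** when its z-score `z_i = (x_i - mean(x)) / sd(x)`
has a one-sided upper-tail normal p-value whose Benjamini–Hochberg
adjustment is below 0.05, in *every* replicate; significant windows
separated by ≤ 100 kb are merged. Upstream, fragments overlapping a
blacklist or above the 99.9% quantile of nonzero counts (self-ligation
products) are removed. For capture data, read pairs within 100 fragments
are discarded, unique reads are counted per fragment, and **anchors** are
the fragments strictly above the `1 - 0.0005` empirical quantile of the
observed counts. Feature enrichment of interactions is tested against
`n = 1000` chromosome-preserving shuffles of the non-anchor ends, with
`p = #(background > observed) / n`.

## Worked example

Design a primer pair on a TE consensus, simulate a genome with 15 planted
insertions plus replicate 4C counts, and recover the insertions as
observed baits:

```r
library(fourTran)

dpnii <- restriction_enzyme("DpnII", "GATC", 0)
csp6i <- restriction_enzyme("Csp6I", "GTAC", 1)

## a 1.5 kb consensus with DpnII sites at 100/900 and a Csp6I site at 300
set.seed(42)
consensus <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
consensus <- gsub("GATC", "AATC", consensus)
consensus <- gsub("GTAC", "ATAC", consensus)
substr(consensus, 101, 104) <- "GATC"
substr(consensus, 901, 904) <- "GATC"
substr(consensus, 301, 304) <- "GTAC"

baits <- design_baits(consensus, dpnii, csp6i, family = "IAPEz")
baits[, c("family", "primary_spacing", "primary_to_secondary",
          "reading_primer", "second_primer")]
#>   family primary_spacing primary_to_secondary       reading_primer        second_primer
#> 1  IAPEz             800                  200 ATTAGGATATTCATCCGATC CGGCAAGCGGGAGGCGTGAT

cfg <- sim_config(chrom_count = 2, chrom_length = 10e6, n_insertions = 15,
                  fraction_full_length = 1, fraction_solo_ltr = 0,
                  fraction_5prime_truncated = 0, insertion_spacing = 1e6,
                  n_reads = 2e5, strain_shared_fraction = 1, seed = 7)
sim <- simulate_te_genome(cfg, consensus)

rmap <- digest_genome(sim$genomes$A, dpnii)
reduced <- build_reduced_genome(rmap, sim$genomes$A, flank = 25)
#> 77942 fragments, 155819 unique 25 bp flanks

reps <- simulate_4c_reads(reduced, sim$truth, cfg, replicates = 2)
chrom_sizes <- setNames(rep(10000000L, 2), c("chr1", "chr2"))
tracks <- lapply(reps, function(x)
  window_counts(preprocess_counts(x), chrom_sizes, 25000, 25000))
observed <- detect_observed_baits(tracks)
head(observed, 3)
#>   chrom   start     end   peak_z      p_value      q_value replicate_support
#> 1  chr1  975000 1025000 4.948966 3.730433e-07 3.177901e-05                 2
#> 2  chr1 1975000 2025000 4.551018 2.669350e-06 1.334675e-04                 2
#> 3  chr1 2975000 3025000 5.452778 2.479453e-08 4.958906e-06                 2
nrow(observed)
#> [1] 15
```

All 15 planted insertions are recovered (`peak_z` is the most enriched
window's z-score inside each merged region; `q_value` its BH-adjusted
p-value; `replicate_support` the number of replicates confirming the
region). The in-silico PCR route (`find_primer_sites()` +
`predict_baits()`) predicts the same sites from sequence alone, and
`compare_bait_sets()` intersects observed, predicted, or per-strain sets.

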