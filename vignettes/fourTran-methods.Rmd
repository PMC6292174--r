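---
title: "Profiling chromatin contacts from transposable-element viewpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling chromatin contacts from transposable-element viewpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourTran)
```

## The problem

Endogenous retroviruses (ERVs) and other transposable elements (TEs) are
present in hundreds to thousands of near-identical copies, so conventional
viewpoint-based chromosome-conformation assays (4C-seq), which assume a
single bait locus, cannot be applied to them directly. fourTran implements
the computational side of a family of TE-viewpoint assays:

* **PCR-based profiling**: a primer pair designed against the *family
  consensus* amplifies circularized ligation products from *every* copy that
  retains the primer sequences. Reads are mapped only to unique genomic
  sequence, so each copy produces a local pile-up ("bait-like profile")
  around its own integration site. Detecting those pile-ups recovers the
  set of amplifiable insertions — including polymorphic, strain-specific
  ones — and the contact profile of individual copies.
* **Capture-based profiling**: a biotinylated oligo matching the consensus
  pulls down Hi-C ligation products touching any copy. Because both sides
  of each ligation junction are sequenced, interactions can be assigned to
  individual anchor copies even though the probe is family-wide.

The package also places the resulting interactions in nuclear-organization
context (A/B compartments, TADs), tests feature enrichment with a
chromosome-preserving permutation null, and ships a seeded simulator that
generates the full synthetic test substrate: genomes with planted
insertions, 4C counts, and capture read pairs.

## Coordinates and containers

All user-facing tables are plain data.frames with 0-based, half-open
coordinates (BED convention); 1-based formats exist only inside the
GenomicRanges/Biostrings machinery used for overlaps and sequence work.
Genomes are `DNAStringSet`s (or named character vectors) over
`{A,C,G,T,N}`.

## Restriction geometry and the reduced genome

`digest_genome()` tiles each chromosome into fragments at every occurrence
of the primary enzyme's site (DpnII: `GATC`, blunt cut at the site start;
enzymes are data via `restriction_enzyme()`, not code). Sites spanning an
`N` never match — a conservative choice for assembly gaps.
`build_reduced_genome()` then emits the 25 bp flank on each side of every
internal cut and flags a flank `unique` iff its exact sequence occurs
exactly once in the genome counting both strands. Only unique flanks are
mappable for single-end 4C reads; exact-sequence uniqueness stands in for
unique alignability, which is what short-read mappers enforce in practice.

## Bait design on a consensus

`enumerate_bait_candidates()` scans the consensus for pairs of adjacent
primary sites at least 300 bp apart that contain a secondary enzyme site at
least 150 bp downstream of the reading-side primary site. Both distances
are treated as *minima*, the classical 4C design constraint (too-short
fragments circularize poorly); the reading direction is left-to-right, with
the nearest qualifying secondary site recorded. `design_primer_pair()`
places a 20-nt reading primer ending exactly at the primary site (site
included, reading into the fragment) and chooses the second primer by
exhaustive scoring of every 18–27-nt window between the sites: windows
containing `N` or with GC outside [0.20, 0.80] are disqualified, the
melting-temperature estimate closest to 60 °C wins, and ties go to the
shorter, then leftmost window, making the design fully deterministic. The
Tm estimate is the Wallace rule below 15 nt and the standard GC-fraction /
length formula above — a deliberate, reproducible surrogate for interactive
primer-design software, adequate because only the *relative* ranking of
windows matters here. No thermodynamic nearest-neighbor model, hairpin or
dimer screening is attempted.

## In-silico PCR

`find_primer_sites()` reports every locus, on either strand, where a
primer's 3'-terminal 15 bases match exactly and the remaining 5' bases
carry at most 2 mismatches. The protected-3'-block reading of the
"lowest stringency (15 nucleotides)" convention is adopted because primer
extension is abolished by 3' mismatches but tolerates 5' ones; both the
block length and the mismatch allowance are arguments.
`predict_baits()` pairs inward-facing plus/minus matches on one chromosome
into amplicons of at most 4000 bp (the conventional in-silico PCR product
cap) and, given a TE annotation, flags an amplicon `on_target` iff it
overlaps the target family and no other. Overlapping amplicons from
clustered matches are all reported; deduplication is the caller's choice.

## From fragment counts to observed baits

`preprocess_counts()` removes blacklist-overlapping fragments and then
drops fragments whose count exceeds the 99.9% empirical quantile of the
nonzero counts — the self-ligation / undigested-product pile-ups
immediately at viewpoints. Ties at the threshold are retained, so a flat
count vector loses nothing. `window_counts()` sums counts by fragment
midpoint into sliding windows (100 kb / 25 kb step for visualization
tracks, with an optional 75%-quantile cap against PCR artifacts;
non-overlapping windows for detection). `detect_observed_baits()` computes
per-window z-scores against the genome-wide mean and standard deviation
over mappable windows (windows containing no reduced-genome fragment are
excluded from both fitting and calling), converts them to one-sided
upper-tail normal p-values — enrichment is the only signal of interest —
adjusts by Benjamini–Hochberg, keeps windows with q < 0.05, merges kept
windows separated by at most 100 kb, and reports only regions supported by
an overlapping region in *every* replicate (the reported region is the
union of its supports). Raw counts are used for the normal fit.

**Window size and genome scale.** The detection window defaults to 100 kb
(non-overlapping). The z-score is computed against a genome-wide spread, so
what matters statistically is the *fraction* of windows carrying bait
signal: with B baits among N windows the attainable z is capped near
sqrt(N/B), because the bait windows themselves inflate the standard
deviation. On a full mammalian genome (N ≈ 27,000 for 100 kb windows) this
cap is irrelevant; on the 20 Mb simulated genomes used in the tests and
acceptance runs, 100 kb windows give N = 200 for 15 baits and the cap
(~3.6) sits below the Benjamini–Hochberg threshold. The package's test and
acceptance scenarios therefore use 25 kb windows, which restores the
signal-window fraction to the regime the method was designed for. This is
a resolution-scaling choice, not a tuning of the statistics: the calling
rule itself is identical at every window size.

`compare_bait_sets()` partitions two region sets by any-overlap (observed
vs predicted baits; two strains) and returns per-side shared counts, which
coincide for the one-to-one overlaps produced by well-separated
insertions.

## Capture anchors and interactions

`pairs_to_fragments()` assigns each read-pair end to the restriction
fragment containing its 5' position, removes same-chromosome pairs closer
than 100 fragments (strict, per-chromosome index difference; trans pairs
are never proximity-filtered because the self-ligation artifacts the rule
models are cis by construction), and collapses exact duplicates after
putting ends in canonical order. `select_anchors()` accumulates unique-read
counts per observed fragment and selects those strictly above the
(1 − 0.0005) empirical quantile of the observed-count vector; the
strictly-greater rule means a flat vector yields no anchors. The quantile
is taken over fragments with at least one read — counts only exist for
observed fragments — which also keeps the threshold in the regime where
the 0.05% tail is meant to match the expected fraction of probe-enriched
fragments. Anchors are flagged against `predict_probe_targets()` output
(seeded local alignment, match +1 / mismatch −1 / gap open −2 / gap extend
−1, ≥ 80% identity over ≥ 60 aligned bases; the exact-seed length is a
sensitivity knob — shorter seeds find more diverged copies at more
alignment cost) and optionally restricted to fragments overlapping the
target TE family, with the removed count reported.

Scored interactions (CHiCAGO-style) are an *import*: `load_interactions()`
reads BEDPE or ibed dialects and applies the 7.5 score cut-off (scores
exactly at the cut-off are kept). Interaction calling itself and
negative-binomial differential testing are out of scope;
`export_interaction_counts()` writes the per-interaction count matrix for
external tools. `anchor_signal_track()` bins pairs touching one anchor into
1 kb / 500 bp sliding bins across the 1 Mb region centered on the anchor
fragment midpoint (1999 bins), and `size_factor_normalize()` applies
median-of-ratios size factors over bins nonzero in every sample.

## Compartments and TADs

`compartment_scores()` uses the standard construction: per-diagonal
observed/expected normalization (the expected value of a diagonal is its
plain mean — no smoothing, since nothing downstream needs it), Pearson
correlation of the normalized columns, and the leading eigenvector of that
correlation matrix as the per-bin score. Zero-coverage bins are masked and
excluded from labeling. The eigenvector sign is arbitrary, so orientation
requires a user-supplied reference track (gene density is the usual
choice); the component is flipped to correlate positively with it, and A =
positive score, B otherwise. PC extraction is per chromosome and the bin
size is an argument — both 50 kb and 200 kb are sensible on real data.
`pc_of_regions()` reports coverage-weighted mean scores per region and the
fraction positive. `classify_interactions_by_tad()` assigns same-TAD status
iff both end *midpoints* fall in one TAD interval, which classifies
border-straddling fragments deterministically, and
`interaction_distance_stats()` reports midpoint distances for cis
interactions only.

## Permutation enrichment

`overlap_enrichment()` counts interaction other-ends (± 1 kb) overlapping a
feature set (optionally flanked, e.g. gene bodies ± 3 kb), then redraws
every other-end's start uniformly on its own chromosome (length preserved,
overlaps permitted, no exclusion zones) `iterations` times and reports the
empirical p as the fraction of iterations whose overlap strictly exceeds
the observed one. Only the non-anchor end is shuffled — the anchor is the
fixed viewpoint. The strictly-greater rule makes p = 0 reportable with no
pseudocount and ties favor significance; with very discrete overlap counts
this is measurably anti-conservative, so calibration claims should be
evaluated (as the test suite does) at scales where the overlap statistic
has a standard deviation of at least a few counts. The seed is a required
argument and the caller's RNG state is restored afterwards.
`promoter_contact_map()` keeps cis interactions with score > 10 and
distance < 5 Mb (both strict) whose other-end ± 1 kb overlaps a TSS ± 2 kb
window, and returns contacts per anchor and anchors per promoter.
`partitioned_overlap()` assigns each other-end to exactly one of TSS
(± 3 kb), gene body, or intergenic — TSS takes precedence so
promoter-proximal signal is not double-counted — and tabulates feature
overlaps per partition.

## The simulator

`simulate_te_genome()` plants TE copies in a random background genome:
truncation classes are full-length, solo-LTR (the 3'-terminal 350 bp,
modeling the LTR left by recombination), and 5'-truncated (uniform
truncation point, ≥ 200 bp retained) — truncations are 5'-anchored because
reverse transcription failure clips the 5' end, which is also why copies
sorted by 5' consensus position form the characteristic staircase.
Insertions *overwrite* the background rather than inserting, so both
simulated strains share one coordinate frame; strain B carries each
strain-A insertion with probability `strain_shared_fraction` (default 0.7)
plus a matching number of private insertions. Per-base substitution at
`mutation_rate` models family divergence. Placement uses a shuffled grid
with 200 kb default spacing so planted baits stay resolvable by the
detection windows.

`simulate_4c_reads()` draws each read as background (probability 0.1,
uniform over mappable flanks) or as a viewpoint read landing at genomic
distance d with probability ∝ `(1 + d/s)^-alpha`, cis only, with defaults
α = 1.5 and s = 20 kb — a standard contact-decay surrogate of the right
shape and scale for mammalian 4C profiles. `simulate_capture_experiment()`
mixes anchor-decay pairs, planted-loop pairs (mass ∝ loop strength), and
uniform background; duplicates arise naturally and are left for the
pipeline to remove. Everything is deterministic under the configuration
seed, and replicates differ only by their position in the seed stream.

What the simulator does **not** model: sequencing errors and base
qualities, PCR amplification bias beyond natural duplicates, chromatin
compartment structure in the background contact field, GC/mappability
biases, and trans-contact structure beyond uniform background. Passing
tests therefore demonstrate correctness of the algorithms under a clean
generative model, not robustness to every artifact of real libraries.

## Problem sizes used in tests and acceptance runs

The bait-recovery scenario uses a 2 × 10 Mb genome, 15 full-length
insertions ≥ 1 Mb apart, and 2 replicates × 200,000 reads with 25 kb
detection windows. The anchor-recovery scenario uses 10^5 fragments of
250 bp, 25,000 background pairs (mean 0.5 reads per fragment) and 20
anchors at 50× that per-fragment mass — chosen so the 0.0005 quantile tail
(~20 of ~39,000 observed fragments) matches the planted anchor count, the
same matching logic used to pick the quantile on real data. Permutation
calibration uses 200 null runs of 1000 iterations with 600 interactions
against 2000 × 3 kb features on 2 × 10 Mb, where the overlap statistic has
a standard deviation near 12 counts and tie-induced anti-conservatism is
below two percentage points.

## Known limitations

* Exact-seed probe-target prediction can miss copies whose divergence
  leaves no intact seed (k = 12 by default); this mirrors the behavior of
  word-seeded alignment tools rather than a full DP scan.
* The normal fit for observed-bait detection is a pragmatic choice
  inherited from the field's practice; counts are not variance-stabilized,
  and on very small genomes the signal-window fraction must be kept low
  (see the window-size note above).
* `compare_bait_sets()` reports per-side shared counts; many-to-many
  overlap structures have no single Venn "shared" number.
* The empirical permutation p is anti-conservative under heavy ties by
  construction (strictly-greater rule, the field's convention).
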