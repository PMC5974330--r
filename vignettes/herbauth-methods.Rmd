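---
title: "Methods: ITS2 metabarcoding QC for herbal preparations"
author: "herbauth developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS2 metabarcoding QC for herbal preparations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-ingredient herbal preparations are mixtures of plant material in
which individual species can be substituted, adulterated or lost during
manufacture. High-throughput amplicon sequencing of the nuclear
ribosomal ITS2 spacer — a standard plant barcode flanked by the highly
conserved 5.8S and 28S rRNA genes — can qualitatively enumerate the
species present in such a mixture. The catch is exactly those
conserved flanks: amplicons read through ITS2 into 28S, and any
reference sequence that retains a piece of 5.8S or 28S attracts reads
from *unrelated* species whose rRNA is nearly identical. In a
published ITS2 survey of a reference herbal mixture this mechanism
manufactured hundreds of false-positive reads for a sugarcane relative
out of *Coix* material, which disappeared only after the reference
database was stripped of rRNA flanks. `herbauth` implements that
complete pipeline — read QC, profile-HMM flank trimming, curated
reference database, identity-threshold species assignment — together
with the companion assays used for confirmation: in-silico qPCR primer
specificity, Ct presence calls, and digital-PCR Poisson quantification.

## Pipeline and models

### Read QC (`filter_reads`, `mask_primers`, `run_qc`)

Reads are single-end (Ion-Torrent-like; no pairing logic). A read is
kept iff its quality statistic passes `min_quality` (default Q20) and
its length is within `[min_length, max_length]` (defaults 300 and
500 bp). Two interpretive choices were genuinely open:

* **"QV < Q20" is read as the per-read mean phred.** The usual
  amplicon-pipeline convention, and it keeps the filter a single scalar
  test. A windowed per-base alternative (`method = "window"`) rejects
  a read whose worst `window`-base mean dips below the cutoff, for
  users who want a local criterion.
* **The upper length cutoff.** The source describes a 50–500 bp
  high-quality range alongside a hard 300 bp lower cutoff, without
  stating whether 500 bp was enforced. We default `max_length = 500`
  and make it configurable.

Rejections are counted by the *first failing rule*, quality before
length, so the accounting is deterministic and partitions the input
exactly (`kept + rejected == input`).

Primer masking scans a window of primer length + 3 bases at each read
end (tolerating small terminal artifacts without scanning the whole
read) at Hamming distance ≤ 2. Both orientations are tried, since
fragment-library amplicon inserts are not orientation-fixed; the
matched orientation is recorded and later reused to halve the HMM
scanning work. Reads with no primer at either end are flagged
`unprimed`, not dropped — flank trimming usually rescues them.

Run-level gates mirror sequencing-facility acceptance rules: at least
10,000 reads per sample, and 99% / 97% / 95% of targeted positions
covered at depth 1 / 20 / 100, computed by pooling per-position depth
over all reference positions via a pluggable read-mapping hook.

### Flank models (`build_profile`, `viterbi_locate`, `annotate_its2`)

Each conserved flank (5.8S 3' end, 28S 5' end) is modelled with a small
Plan7-like profile HMM: match/insert/delete states, begin entering only
at the first column, exit only from the last (no internal entry/exit).
Columns of the seed alignment with ≥ 50% residues become match states.
Emissions and transitions are Laplace-smoothed observed counts,
`(count + pc) / (total + k·pc)`; the background is the overall residue
frequency with the same smoothing (an unsmoothed background would make
log-odds infinite for any base absent from the seed). Two topology
corner cases are folded rather than modelled: an observed I→D step
counts as I→M, and residues in insert columns outside the first/last
match column are ignored.

Decoding is **glocal** Viterbi: the full model must align, but to any
substring of the target; flanking positions emit at background and
contribute zero log-odds, so a hit's score is independent of its
context (a tested invariant). Scores are log₂-odds in bits. The
compiled decoder is checked cell-for-cell against an exhaustive
per-entry-boundary dynamic program in R on hundreds of random
sequences.

**Threshold.** The score cutoff is calibrated empirically: shuffle
representative target sequences dinucleotide-wise (destroying the
motif, preserving composition), score the shuffles, and take the 95th
percentile (`calibrate_threshold`). For the *packaged* models we then
raise the cutoff to the midpoint between the null maximum and the
consensus score. The reason is arithmetic, not taste: a threshold
sitting exactly on a null quantile admits ~5% chance hits per scan *by
construction*, so validating a clean database (10 scans for 5 records)
would flag a phantom flank almost half the time. True flank hits score
on the order of +100 bits against a null that tops out near 0, so the
midpoint loses nothing real — a flank with 10–15% divergence or a
dozen missing terminal columns still clears it comfortably.

ITS2 proper is the span between the best 5.8S hit's end and the best
28S hit's start (0-based half-open everywhere). Missing flanks default
to the sequence boundaries; overlapping or crossing hits yield status
`none` and no trim, on the principle that an incoherent annotation
should never delete sequence. Records trimming below 100 nt are
dropped and reported. Reads are trimmed with the same models,
orientation-aware (`hmm_trim_reads`): both orientations are annotated
unless primer masking already fixed one, and the span with the higher
total flank score wins.

### Reference database (`curate`, `validate_db`)

Curation = flank-trim every record, drop sub-100-nt remnants,
deduplicate identical (species, sequence) pairs, and *keep but flag*
identical sequences labelled with different species — the classifier's
tie logic is the honest place to surface that ambiguity, not a silent
drop. Taxonomy is a flat species/genus table: reporting is at species
level with genus as the tie-break fallback, and all sources are
weighted equally. `validate_db` rescans every record with both
models; a clean database yields an empty report, and
`validate_db(curate(X))` is clean by construction (a tested
round-trip).

### Classification (`classify_reads`, `assign_read`)

Candidate references share ≥ 5 8-mers with the read (either strand) —
a cheap stand-in for BLAST seeding whose superset property is tested
against exhaustive alignment. Candidates are aligned semi-globally:
free end gaps on the reference, the read aligned end-to-end, match +1,
mismatch −1, gap open −2, gap extend −1. Identity is BLAST-like —
matches over the columns between the first and last aligned pair — so
a terminal overhang costs score and *coverage* but not identity;
query coverage is the percentage of read bases aligned to reference
bases. This split is what makes the false-positive mechanism
expressible: a read-through read scores ~100% identity to a clean
reference at 60% coverage, and ~97% identity at 100% coverage to a
flank-bearing one.

Assignment: hits qualify at identity ≥ 97% (an OTU-style species
cutoff) *and* coverage ≥ 80%. The coverage floor is our addition —
the source is silent, but its own false-positive example turns on an
80% query-cover BLAST hit, and without a floor short spurious matches
assign freely. No qualifying hit → `UNASSIGNED`; a unique
best-scoring species → that species; a score tie across species →
`AMBIGUOUS`, collapsed to the genus when the tied species are
congeners. Ties are never broken randomly. The sentence in the
source about "reads that had 2 or more identified species" is
ambiguous (a multi-mapped-read report vs. a species-count criterion);
we read it as the former: all computed hits are retained and written
as a BLAST-outfmt-6-like table, so multi-mapped reads are inspectable.

Counts are read counts only; no biomass claim is made (read abundance
does not track compound abundance). Screening against a prescription
partitions detected species (count ≥ 2, so singleton noise never
"detects" a species while a legitimate 2-read trace does) into
prescribed-present, prescribed-absent and non-prescribed extras.

### qPCR and dPCR (`predict_amplification`, `call_presence`, `dpcr_quantify`)

In-silico primer specificity deliberately replaces thermodynamics with
a mismatch-count rule: a primer binds if its best ungapped site has ≤ 2
total mismatches and **0 mismatches in the last 4 bases of its 3'
end**, and a pair amplifies if the forward primer binds the plus
strand, the reverse primer binds the minus strand downstream, and the
product is ≤ 1000 bp. The published congener assays (both forward
primers share the motif `TGGCCCACC` and diverge 3'-wards) are exactly
the case this rule captures; 3'-terminal mismatches block polymerase
extension, which is how such assays are designed. Real templates for
the two medicinal congeners are not published, so the packaged
specificity fixtures are synthetic (labelled as such) and a helper
accepts user FASTA templates.

Ct presence is strict: present ⇔ Ct < 32; a Ct exactly at the
threshold is absent, matching the source's strict phrasing. The
cutoff has no published derivation and is a configurable constant.

Digital PCR: with fraction `p` of positive wells, occupancy is
Poisson, `λ = −ln(1−p)` copies/well, concentration `λ / v × dilution`.
The 95% CI is Clopper–Pearson on `p` pushed through the same
transform. `p = 1` is a saturation error, `p = 0` reports zero with a
zero lower bound; `λ` is strictly increasing in `p` and equals `p`
within 1% below 1% occupancy (tested closed-form properties).

## The simulator: a stated world

`sim_config` defaults *are* the emulated platform, chosen once:

| parameter | default | why |
|---|---|---|
| read length mode | 488 bp | the platform's reported modal read length; reads never exceed their amplicon (~478 bp with the packaged flanks), normal sd 15 |
| substitution rate | 0.005/base | Ion-Torrent-like mismatch error |
| homopolymer ±1 indel | 0.01/run ≥ 3 nt | the platform's dominant error mode; stresses affine gap handling |
| truncation fraction | 0.05 → 50–299 bp | exercises the 300 bp length filter |
| low-quality fraction | 0.05 at flat Q15 (vs flat Q30) | makes the Q20 mean filter exactly predictable |
| minus-strand fraction | 0.5 | fragment-library inserts are unoriented |

Reference sets mutate a common ancestor at *disjoint* position sets, so
pairwise divergence is at least (in fact twice) the requested
percentage — the guarantee is a floor, verified by alignment in tests.
`make_readthrough_experiment` scripts the conserved-flank
false-positive mechanism directly: species A's reference is clean
ITS2, species B's retains a long shared 28S head, and every read is an
A read running through into that same 28S. Against the uncurated
database the reads fail A's coverage floor and clear B's identity
cutoff (assigned to B); after curation and read trimming, zero reads
go to B. All generators are deterministic under a seed (byte-identical
outputs, tested).

What a green simulation does **not** establish: real chimeras, PCR
bias, flowgram-level error structure, copy-number differences between
species, or real 5.8S/28S sequence (the packaged seed alignments are
synthetic motifs — substitute real seeds via `build_profile` /
`flank_hmms` file arguments for production use).

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; minus-strand hits are
  mapped back to input coordinates.
* Alignment tie-breaks are fixed (match layer before gap layers,
  leftmost end) so results are deterministic; binding-site ties prefer
  fewer 3'-window mismatches, then the leftmost position.
* FASTQ is strictly phred+33; phred+64-looking files error loudly.
* Empty inputs return empty outputs throughout; saturated dPCR chips
  and empty seed alignments are errors.
* The identity denominator excludes terminal gap runs; a degenerate
  alignment with no aligned pair has identity 0.
* `filter_reads` is idempotent; `curate` is idempotent on its own
  output (both tested).

## Known limitations

* The aligner is exact DP, not heuristic — fine for curated ITS2
  databases (hundreds of records), not for nucleotide-wide search.
* No E-values, chimera detection, or OTU clustering (out of scope).
* The qPCR rule knows nothing about Tm, ΔG or secondary structure; it
  is a specificity screen, not a design tool.
* Genus collapse assumes the flat two-rank taxonomy is correct;
  synonymy resolution is the user's problem.
* Species-level accuracy is only guaranteed when references are ≥ 3%
  diverged from all other database entries (tested at that margin).
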