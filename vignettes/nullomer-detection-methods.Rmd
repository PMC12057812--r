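---
title: "Methods: nullomer-based neoepitope and fusion detection in cfRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nullomer-based neoepitope and fusion detection in cfRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonull)
```

## Rationale

Cell-free RNA is fragmented and sparse: the reads carrying a tumour
mutation are short, few, and easily discarded by pipelines built around
genome alignment and pileup-based variant calling. `neonull` inverts the
problem. For a *known* catalogue of neoepitope-producing point mutations
and fusion junctions, it precomputes the set of 16-nt words that the
mutation creates and that are absent from the human consensus coding
sequences (CCDS-nullomers). Detection is then exact multi-pattern string
matching over the reads, followed by a targeted alignment step whose only
job is to confirm that the read really comes from the expected locus.

Two properties make this work:

1. a k-mer that is absent from the whole coding sequence set but present
   in a mutated conformation is a sequence-level *witness* of the
   mutation — no genotype or pileup is needed;
2. k = 16 is long enough that random cross-matches are rare, yet short
   enough that a fragmented read still contains several witnesses.

Because nullomers may still occur in non-coding genomic regions whose
transcription would masquerade as a mutation, words occurring more than
`cap = 300` times in the genome are removed at build time.

## Database build

### Neoepitopes

Input records are (wildtype peptide, neoepitope, transcript) rows. The
pair is aligned with Smith–Waterman (BLOSUM62, gap open 10, gap extend 1 —
the alignment is only needed to classify the mutation, and for the
equal-length pairs that dominate these catalogues it reduces to a
column-wise comparison, which the implementation uses as a fast path).
Records with an insertion/deletion or more than two substitutions are
excluded; nothing downstream can represent them. The wildtype peptide is
located on the protein translation of its coding sequence by exact search
(all overlapping offsets are processed; entries carry the offset so
coverage attribution stays unambiguous).

At each substitution site every codon of the new amino acid is
substituted, and the cartesian product over sites gives all DNA
conformations of the neoepitope. Every 16-nt window of the mutated coding
sequence that overlaps ≥ 1 mutated nucleotide is a candidate; windows are
clipped at the sequence boundary (no padding), so a mutation within 15 nt
of an end has fewer candidates. A candidate survives if it is absent from
the CCDS presence index and within the genome occurrence cap. We extend
candidate windows into the full coding-sequence context rather than
clipping at the epitope boundary: any window overlapping a mutated base
can witness the mutation, and windows that do not overlap one cannot, so
this is the minimal faithful window set.

Neoepitopes produced by the same mutation (e.g. nested peptides of
different lengths) are grouped into a single target named by the
transcript and the protein-level change (`TX01:p.33S>F`); positions are
0-based internally and 1-based in reports.

### Strandedness conventions

CCDS presence is **forward-only**: coding sequences are stranded and a
reverse-complement match is not a coding match. Genome occurrence counting
is **double-stranded** (configurable): transcription can originate from
either strand, so a word frequent on either strand is a false-positive
risk. The occurrence counter saturates at `cap + 1` — beyond the cap the
exact value is irrelevant.

### Fusions

For each curated junction the target is 500 nt ending at the 5′
breakpoint plus 500 nt starting at the 3′ breakpoint, each
reverse-complemented for minus-strand partners, joined in transcript
orientation. (The breakpoint convention: `pos5` is the last transcribed
base of the 5′ partner and `pos3` the first of the 3′ partner, 1-based,
matching curated fusion tables; flanks truncate at chromosome ends and the
recorded junction offset is the actual 5′ contribution.) The k − 1 = 15
windows with at least one base on each side of the junction are the only
possible junction witnesses; they pass the same presence/occurrence
filters. Junction neoepitopes are scanned only where both breakpoints are
inside annotated coding sequence, the 5′ junction is past the start codon,
and the 3′ gene keeps its frame (`u ≡ v (mod 3)` for 5′ retained length
`u` and 3′ offset `v`); the fused coding sequence is translated in the 5′
frame and each 9-aa window whose encoding interval strictly contains the
junction is kept if absent from the reference proteome — 8 windows when
the junction falls between codons, 9 when it splits a codon (the hybrid
codon spans the junction too). Windows running into a stop codon are not
peptides and are not counted.

## Detection

### Scanning

Nullomers are matched exactly (a preprocessed dictionary over all
patterns): forward on mate 1, reverse-complement on mate 2. This encodes
the stranded-library assumption that mate 1 carries the sense strand; a
`library_type` switch swaps mates for the opposite chemistry. Reads with
`N` at the pattern site never match. Antisense occurrences (the forward
pattern on mate 2, or vice versa) are deliberately ignored — in a stranded
library they are artefacts.

### Alignment and filters

Each hit mate is aligned locally (match +2, mismatch −4, gap open 5, gap
extend 3) to the target sequences of its own nullomers only, keeping the
best-scoring target; mate 2 is reverse-complemented first. The score is
`2·matches − penalties`, so a 35-nt perfect alignment scores 70 and one
with a single medium-quality mismatch 64. Unaligned read ends count as
soft-clips, and the built-in aligner reports MAPQ 0 so that its records
are judged purely by the score branch below. Records from an external
aligner can be supplied as SAM (`read_sam_records()`); the filter logic is
identical, with AS from the `AS` tag and soft-clips from the CIGAR.

Duplicate fragments — same target, fragment start, fragment end and
orientation — are collapsed to the pair with the highest summed base
quality *before* the read filters (ties keep the first pair in input
order, making the contract deterministic). Then a read is kept when:

* its soft-clipped fraction of the full read length is ≤ 1/3 (the
  threshold is the exact rational, not 0.333; removal is strict `>`);
* MAPQ exceeds 10 (coding targets) or 30 (fused targets, where mapping
  quality against a small target set is uninformative), **or** its
  alignment score reaches `MES(AL) = slope·(AL − 35) + 64`.

The slope is stored as the exact rational 213/115 = (277 − 64)/(150 − 35);
a compatibility flag substitutes the two-decimal 1.85. With the exact
slope both anchor cases (AS 64 at AL 35; AS 277 at AL 150) sit exactly on
the line, and since these mismatch loads are meant to be *allowed*, the
comparison is non-strict (`AS ≥ MES`); a `strict_mes` switch restores the
strict reading. Fusion reads additionally need ≥ 5 aligned bases on each
side of the junction — fewer bases cannot distinguish a junction read from
a read of either partner.

### Coverage

A nullomer's coverage is the number of surviving reads that contain it
*and* whose alignment landed on that nullomer's own target; hits whose
read aligned elsewhere count for nothing. A target's `mapped_reads` is the
coverage of its most covered nullomer (ties broken lexicographically for
determinism), `n_nullomers_detected` the distinct covered nullomers, and
`max_nullomers_per_read` the largest number of the target's nullomers seen
on one read. Pass thresholds: ≥ 3 reads for neoepitopes; ≥ 2 reads *and*
≥ 2 nullomers for fusions. Coverage counts individual mates: each read is
independent evidence, and a fragment whose two mates both contain the
witness contributes two reads.

## Annotation and cohort rules

HLA-binding predictions are retained at %Rank strictly below 2 (per
peptide–allele row; all retained predictions are serialized). Germline
rows are retained when AF > 1e−7, the consequence is `missense_variant`,
the biotype `protein_coding`, and the feature an `ENST` transcript.
Annotation joins are by exact, case-insensitive peptide equality and never
drop entries.

Cohort expression is `log10(1 + 10^6·reads/total)` — counts per million
with a pseudocount so zero maps to zero. The catalogue-wide rules then
are: *generic* — prevalence > 20 % and mean normalized expression > 0.1 in
both groups (these targets are background and excluded from downstream
comparisons); *discriminative* — mean expression ≥ 2-fold higher in one
group and detected in ≥ 3 individuals of that group. The normalization
constant behind the 0.1 threshold is not uniquely determined by the rule's
verbal form; we fix the log10(1 + CPM) definition so the threshold has a
stable meaning, and the configuration object exposes all four constants.
"Present in a sample" means ≥ 1 mapped read after the detection
thresholds. RPKM is computed exactly as
`(reads/(total/10^6))/effective_length`.

## The synthetic reference and what tests do (and do not) show

`make_toy_reference()` embeds random open reading frames (ATG, random
sense codons, stop) in a random background genome at uniform base
composition; translations stand in for the proteome. `plant_epitope_db()`
plants substitution records whose tumour allele differs by **one
nucleotide per site** — the single-nucleotide-variant case the epitope
catalogues describe — resampling until at least one witness nullomer
survives, is absent from the toy genome, and is disjoint from every other
record's witnesses. Negative controls embed a decoy coding record carrying
the mutated context, so every candidate window is coding-present and the
build drops the record. `plant_fusion_db()` alternates between-codon and
mid-codon junctions, always in frame. `simulate_reads()` draws fragments
whose mate 1 fully contains a witness window (and ≥ 5 nt on each junction
side for fusions), at distinct fragment starts so duplicate removal keeps
all planted pairs; qualities are constant Q40 and the default error rate
is zero, so aligned length plus soft-clips equals read length exactly and
round trips are deterministic.

Test and acceptance runs use a 6-gene, 300-nt-CDS reference (~2.4 kb
genome), 10 planted neoepitopes plus one negative control, 3 fusions,
100-nt reads at fragment length 160 and 6 pairs per target — sizes at
which every brute-force oracle (exhaustive k-mer enumeration, per-window
scans, two-strand occurrence counts) is itself cheap to compute.

What passing shows: the combinatorics (windows, conformations, junction
peptides), the filter arithmetic at its boundaries, and exact recovery of
planted targets with zero false passes *when witnesses are unique by
construction*. What it does not show: behaviour under sequencing error,
paralogy and shared k-mers between real transcripts, alignment ambiguity
in repeat regions, or the empirical discriminative power on patient
cohorts — those require the real catalogues and datasets.

## Numerical and degenerate-input choices

* Exact rationals for slope (213/115) and soft-clip threshold (1/3);
  boundary comparisons are therefore exact, not tolerance-based.
* Ties: best nullomer lexicographic; duplicate pairs first-in-input;
  best alignment target first-candidate on equal score.
* Empty inputs (no reads, no hits, empty pattern set) propagate to empty
  reports with success status; mate-count mismatches, malformed FASTA and
  missing columns raise typed errors (`neonull_format_error`,
  `neonull_usage_error`) that the CLI maps to exit codes 3 and 2.
* Windows containing `N` are excluded from presence sets and never match.
* A mutation within 15 nt of a sequence end simply has fewer candidate
  windows; a fused flank truncated at a chromosome end records its actual
  junction offset.

## Known limitations

* The built-in aligner is a plain Smith–Waterman with MAPQ fixed at 0; it
  has no multi-mapping model, so the MAPQ branches of the filters only
  act on externally supplied SAM alignments.
* Indel-derived neoepitopes are excluded by design, as are junctions in
  UTRs/introns (frame prediction there is not well defined).
* Coding annotation for fusions assumes contiguous coding intervals per
  partner; spliced structures must be resolved by the caller.
* Exact matching means a sequencing error inside the only witness window
  of a read hides that witness; sensitivity at realistic error rates is
  governed by the number of witness windows per fragment.
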