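---
title: "Gene-structure forensics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-structure forensics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudocasp)
```

## The problem

A gene stops being a gene in small, legible steps: a single-nucleotide
deletion shifts the reading frame, the shifted frame soon runs into a stop
codon, alternative splicing may or may not rescue the frame, an internal ATG
may still encode a usable fragment, and the residues that carry catalytic
function may or may not survive. `pseudocasp` turns each of those steps into
a computable check, with the caspase-16 locus of primates as its motivating
case: an eleven-exon gene whose N-terminal prodomain arose by internal
duplication of the catalytic domain, and whose human ortholog carries a
1-nt deletion in exon 3 that truncates the product long before the
catalytic His/Cys dyad.

The package has three layers:

1. **Substrate**: sequences, gene models, splicing phases, transcript
   assembly, and from-scratch pairwise alignment with affine gaps.
2. **Forensics**: indel calling against an intact ortholog, premature-stop
   localisation, exon-skip evaluation, rescue-ORF mapping, dyad checks and a
   rule-based verdict.
3. **Synthesis**: a seed-reproducible generator of caspase-16-like loci with
   truth manifests, so every claim above is testable without downloading a
   single accession.

## Coordinates and splicing phases

Internally coordinates are 0-based half-open only where unavoidable; every
user-facing coordinate is 1-based inclusive, matching GenBank and GFF3 and
the field's habit of naming residues like His290. Exon ordinals are 1-based
in transcription order.

The *end phase* of an exon is the cumulative coding length through that exon
mod 3, so phase 0 means "the last nucleotide of the exon is position 3 of a
codon". An exon's *start phase* is the cumulative coding length before it
mod 3. This is deliberately not the GFF3 phase column (which counts
nucleotides to the next codon start); `compute_splice_phases()` reports both
so the two conventions cannot be confused, and the GFF3 reader validates the
file's phase column against the recomputed values.

Exon skipping restores the downstream frame exactly when the end phase of
the upstream exon equals the start phase of the downstream exon, which for a
single skipped exon is equivalent to its coding length being a multiple
of 3. `evaluate_exon_skip()` uses the phase arithmetic *and* conceptual
translation of the skip isoform, and warns when they disagree; the verdict
requires both. Phases are always computed on the pre-lesion exon
architecture (event lengths added back), because the phase labels of a
broken gene are inherited from its intact ancestor; this matches how the
flanking phases of a mutant gene are quoted alongside its intact ortholog's.

One consequence worth stating: when a skip fuses two partial codons into an
incidental stop codon, phase arithmetic alone would say "restored" while
translation says "truncated". The conjunction keeps the stronger guarantee
(`frame_restored` implies the isoform translates through to the terminal
stop). The random-gene generator used by the property tests screens out such
junction stops so that the phase law can be asserted exactly.

## Alignment

Global (Needleman–Wunsch), local (Smith–Waterman) and free-end-gap
("overlap") alignment are implemented in C++ as a three-state Gotoh DP.
The published analyses this toolkit reconstructs used BLASTn, MultAlin and
MUSCLE; those tools name no parameters, so the defaults mirror their
conventions and everything is configurable:

* nucleotide: match +2, mismatch −3, gap open 5, gap extend 2;
* protein: BLOSUM62 (from `Biostrings`), gap open 11, gap extend 1;
* a gap of length L costs `open + (L−1)·extend`;
* tie-breaks are deterministic: diagonal, then gap-in-b, then gap-in-a.

The test suite holds the DP to two independent standards: exhaustive
enumeration of *all* alignments for short sequences (a recursion that never
uses the DP tables), and `Biostrings::pairwiseAlignment` with its gap
convention translated. Exhaustive global checks run over every pair up to
length 6 on a two-letter alphabet; exhaustive local enumeration over all
pairs up to length 8 is combinatorially out of reach, so local runs
exhaustively to length 5 plus a seeded sample of longer pairs.

`call_indels()` condenses maximal gap runs into events and left-aligns each
event within repeat runs (the VCF normalisation), so a deletion inside a
homopolymer has one canonical coordinate. The `percent_identity()`
denominator defaults to alignment columns (gap columns never count as
identical); `shorter_sequence` is available because published "percent
identity" figures rarely state their denominator.

## Premature stops, rescue ORFs, dyads, verdicts

`locate_ptc()` translates the query's full spliced CDS from the annotated
start codon. Counting conventions, since prose claims depend on them:

* *codons downstream to the stop* counts complete triplets strictly after
  the codon disrupted by the lesion, in the shifted frame, with the stop
  triplet included as the terminating ordinal;
* *truncated length* counts from the initiator methionine with Met as
  residue 1.

`find_rescue_orf()` scans the transcript 3′ of the premature stop for the
earliest ATG lying in the ortholog-defined downstream frame (the frame is
carried across indels by the event bookkeeping, not guessed), translates the
ORF to its stop and maps it onto the ortholog protein with a free-end-gap
alignment. `check_catalytic_dyad()` is alignment-anchored rather than
motif-based on purpose: degenerate prodomain copies lack the dyad, and only
an alignment can say which column the reference His and Cys land on.

`classify_gene_status()` applies the paper-shaped rule set: *intact* needs
no premature stop and an intact dyad; *pseudogene* needs a premature stop
that no single-exon skip rescues and whose rescue ORF is absent or starts
inside the catalytic-domain window (so no complete domain can be made), or a
lost dyad; everything else is *truncated_coding*. The catalytic-domain
window is an input parameter — domain boundaries are annotation, not
something this package invents. Multi-exon skip enumeration is out of scope;
single-exon skips are the analysed mode.

## Intragenic duplication

`self_compare()` asks whether the N-terminal part of a protein is a
degenerate copy of its C-terminal part. The statistic is the maximum over
split points *s* of the Smith–Waterman score between `p[1..s]` and
`p[s+1..n]` — this replaces "mask the dot-plot diagonal" with a constraint
on spans, which is the primitive here. Split points run on a grid of about
50 candidates (step 1 for short proteins); local alignment trims into the
gap between true copies, so grid resolution is not a precision limit.
Significance is a residue-shuffling permutation test (composition
preserved, seed required), with the usual conservative `(r+1)/(n+1)`
estimator. For calibration checks, a `randomized` tie-break is available:
with an integer-valued statistic the conservative estimator is biased
upward exactly by the tie mass, and randomized tie-breaking is the standard
device to verify that the permutation machinery is exchangeable. Inference
defaults to the conservative estimator.

The best hit is always reported with its p-value (callers judge it);
`min_len` bounds the split windows and stops the masked search for further
hits once spans fall below it. `map_exon_homology()` intersects a hit's
aligned residue pairs with the per-exon peptide segments from
`split_by_exon()`, where a junction-spanning codon belongs to the exon
contributing at least 2 of its 3 nucleotides — the rule that makes per-exon
peptides tile the protein exactly once.

`phase_signature_compare()` reduces each gene to its ordered junction
end-phases and reports the longest common subsequence per pair — the
splice-phase evidence used to argue that specific exons share an origin.

## The synthetic locus

`generate_caspase16_like_locus()` does not draw a generic gene: its defaults
*are* the caspase-16 architecture, so the pipeline's printed outputs can be
compared against the published ones without any download.

* An ancestral 8-exon caspase gene (UTR exon, two prodomain exons, two
  large-subunit exons, one linker exon, two small-subunit exons; 319
  residues plus stop) is generated codon-aware: codons are drawn uniformly
  from the 60 codons that are neither ATG nor stops, so the coding frame has
  no internal stop and no stray in-frame ATG.
* The duplication plan copies the large- and small-subunit exon blocks
  5′-ward to form the prodomain and duplicates the linker exon in place,
  yielding the derived 11-exon gene: a 470-residue protein whose prodomain
  (residues 1–197, exons 2–5) mirrors the catalytic subunits
  (exons 6–7 and 10–11), with exon coding lengths
  144, 280, 90, 77 | 144, 280 | 114, 114 | 90, 80. Cumulative sums were
  chosen so every junction phase of the copied block equals its source's —
  the positive control for the phase-signature comparison — and so exon 2
  ends in phase 0 while exon 4 begins in phase 1, the pair of phases that
  makes the exon-3 skip a frame-rescue failure by default.
* Planted motifs: the start ATG; a `QAMSH` pentapeptide placing a Met at
  residue 288 (the only internal in-frame ATG, inside exon 7) and the
  catalytic His at 290; the classic caspase `QACRG` motif placing Cys at
  332. The prodomain copy has the copied Met/His/Cys knocked out, so the
  dyad exists only in the C-terminal domain. Forcing the start codon and
  these knockouts means the copy differs from its source at four codons
  even at zero divergence — identity is asserted as ≥ 97% over matched
  residues there, and exactly 100% only on constructed exact repeats.
* A frameshift cassette occupies exon-3 codons 99–107: a fixed non-G codon,
  `GGG`, five `GGC`, `CTA`, `AAA`. Deleting one G of the run (CDS position
  300; canonically left-aligned to position 297) shifts the frame so that
  the sixth downstream triplet reads TAA: stop at CDS codon 106, truncated
  product of 105 residues — for every seed, because the cassette pins the
  whole left-alignment context.
* The prodomain copy diverges at a per-residue substitution rate (default
  0.40, the regime where recovery is still expected but identity is deeply
  degenerate); the linker duplicate diverges at the nucleotide level since
  it starts mid-codon, with a cleanup pass that resamples any in-frame stop
  or ATG it creates.

`diverge_orthologs()` emulates between-species divergence: per-site
substitutions (a substituted site always changes base, so expected identity
is exactly `100·(1−p_sub)`), indels of length 1–3 kept at least 20 nt apart
and away from protected intervals. Substitutions are kept at least a few
bases clear of injected indels: an indel with a substitution in its
immediate neighbourhood admits two equally-optimal alignments, so "recovered
at the exact left-aligned position" would be ill-posed, not hard. The
scenario wrapper protects coding segments and splice dinucleotides and
applies about 1% non-coding divergence — human–chimpanzee scale — so the
locus-level identity lands above 98% while the coding comparison isolates
the single engineered deletion.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: substitution-rate heterogeneity, codon-usage
bias, splice-site mutations, transcription-level evidence (read coverage,
isoform abundances), and polymorphism within species. The verdicts are
statements about gene architecture, not about expression.

## Problem sizes and numerics

The default test suite and the acceptance script run at sizes chosen to
make the statistics meaningful at desk scale: exhaustive alignment-oracle
pairs up to length 6 (global) and sampled to length 8 (local); 300–1000
random gene models for the frame law; 50–100 generator seeds for
duplication recovery; 200–500 permutation-calibration trials at 200
permutations on 100-residue null proteins; 10 kb orthologs at 2%
substitution and 0.2% indel rates. A 10 kb × 10 kb global alignment keeps
full traceback matrices (three byte matrices, ~300 MB) and runs in a few
seconds.

Degenerate inputs are handled as errors where the spec of the operation is
undefined (empty alignment identity, skipping the start-codon exon, models
without coding segments) and as empty-but-warned results where a scan can
legitimately find nothing (too-short proteins, empty FASTA files).

## Known limitations

* `inject_lesions()` supports plus-strand models; strand symmetry is
  guaranteed (and tested) at the transcript level instead.
* Rescue-ORF scanning considers the single annotated frame carried from the
  ortholog; chimeric frames produced by multiple interleaved indels between
  the stop and the rescue ATG would need the event list to be trusted there.
* The linker-exon duplication (exons 8/9) involves a 38-residue segment at
  substantial divergence; its detection by `self_compare()` is best-effort
  and intentionally not a test gate, while its phase signature is.
* `classify_gene_status()` is a rule system, not a probabilistic model: it
  reports which rules fired, and inputs that contradict each other (a
  "truncated" peptide longer than the reference) are errors, not guesses.
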