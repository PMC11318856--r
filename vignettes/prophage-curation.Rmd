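---
title: "Curation and characterization of prophages in poly-lysogenic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and characterization of prophages in poly-lysogenic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophager)
```

## The problem

Prophage finders applied to a bacterial chromosome return candidate
intervals, not prophages: the same element may be reported as several
partial hits, and non-phage gene clusters (defence islands, integrative
elements, ordinary operons) are called as well. Deciding which candidates
are prophages, whether each is likely still viable, what virion it would
build and how its dormancy is controlled is normally manual work over the
annotation. `prophager` encodes that manual procedure as testable rules
operating purely on per-ORF functional annotations (coordinates, strand,
functional category, trait flags, protein length) — never on nucleotide
sequence, which is deliberately out of scope.

## The curation model

**Hit merging.** Candidate hits that overlap, or that are separated by at
most `max_gap` bp, are unioned (`merge_hits`, implemented on
`IRanges::reduce`). `max_gap` defaults to 1000 bp; for chromosomes where
distinct prophages can directly abut — the packaged fixture has two
prophages 8 bp apart, one having integrated at the edge of its neighbour —
the merge must be overlap-only (`max_gap = 0`), which is what the packaged
analyses use. The parameter is exposed everywhere.

**Module conformance.** A merged interval is confirmed as prophage (or
prophage remnant) if it contains a gene cluster conforming to at least one
of the five canonical functional modules. The category families are:
lysogeny control ← {integration/excision, transcription regulation}; DNA
replication ← {replication}; packaging/capsid ← {packaging/capsid,
connector}; tail ← {tail}; lysis ← {lysis}. A cluster is a chain of family
ORFs in which successive members are separated by at most two interspersed
non-family ORFs, containing at least two members on the same strand. Two
deliberate softenings are built in:

- *Interspersed ORFs of any category count toward the gap tolerance*, not
  just unannotated ones. Real lysogeny modules are interrupted by cargo
  (restriction–modification genes), and replication modules by intron
  insertions; a stricter rule fragments modules that a curator reads as
  single.
- *Co-orientation is required of at least one member pair, not all
  members*, because divergently transcribed repressor pairs live inside
  lysogeny modules by construction.

Tail and lysis admit single-gene evidence (single-tail-gene phages occur in
the fixture genome). Both the gap tolerance and the two-ORF minimum are
arguments of `assign_modules`.

## Defects and categorization

Completeness scores are inputs (0–100, from an upstream AAI-based
assessment); this package never recomputes them from sequence. The bands
are: exactly 100 with no defect → `functional`; strictly between 60 and
100 → `unknown`; at or below 60 → `defective`; absent → `unclassified`.
The published bands (">60–<100", "<60") leave the value 60 itself
unassigned; we resolve boundaries low (60 → `defective`) and require an
exact 100 for `functional`, so rounding never promotes a region.

A score of 100 says the gene complement looks complete; it cannot see
architecture. `detect_defects` formalizes the features that justify
demoting a score-100 region to `unknown`:

- `split_integrase` — ≥2 *adjacent, co-oriented* integrase-trait ORFs each
  < 200 aa: the annotation signature of a frameshift that split one
  integrase gene.
- `truncated_integrase` — integrase-trait ORFs present but all < 200 aa,
  without the split signature (e.g. opposite-strand degenerate fragments).
  The 200 aa threshold separates the fixture's defective fragments
  (165/167 aa) from its intact recombinases (282/420 aa); it is the
  `truncation_aa` argument. Full-length recombinases elsewhere in the
  region do not cancel the flag: whether they could complement the broken
  integrase is exactly the open question the `unknown` category expresses.
- `missing_terminase_or_portal` — a packaging/capsid module with neither a
  large-terminase nor a portal trait: the virion cannot package DNA.
- `intron_split_gene` — a group II intron reverse-transcriptase/maturase
  ORF immediately between two co-oriented ORFs sharing a helicase or
  DNA-polymerase trait (one replication gene split by the insertion).
- `misoriented_late_orf` — an ORF inside a tail or lysis cluster running
  against at least two flanking cluster members, breaking the late operon's
  polycistronic transcript.
- `mosaic_region` — at least two disjoint lysogeny-control clusters or two
  disjoint replication clusters: consecutive/overlapping prophage remnants
  from repeated integration.

The split/truncated pair is mutually exclusive by design: the two
annotation signatures describe different lesions of the same gene, and
emitting both for one locus would double-count evidence.

**Mosaic delineation.** `delineate_mosaic` scans the canonical ORF order:
a sub-region opens at a likely phage start (Mu-type transposase, integrase
trait, or a replication-category gene), and closes at the last consecutive
likely end (tail gene or recombinase) seen before the next opener; if no
closer occurred, the boundary falls on the ORF preceding the next opener.
Openers consecutive with the opening run (a transposase followed by its
transposition and replication genes) extend the current sub-region instead
of splitting it. Two caveats are intentional: ORFs between a closer and the
next opener belong to no sub-region, and regulator genes that precede the
first opener of a Mu-type block (the C/Ner pair sits upstream of the
transposase) fall outside the algorithmic boundary even though a curator
would draw the sub-region to include them. The delineation is therefore a
reproducible segmentation — correct in number and order of sub-regions —
while boundary placement around Mu-type starts is conservative; the
packaged fixture carries the curated coordinate-defined sub-regions
alongside for exactly this reason.

## Typing

**Morphology** uses tail-gene content with precedence sheath > tape
measure > baseplate: a contractile-tail sheath implies a myovirus whatever
else is present; a tape measure without sheath a siphovirus; a
baseplate/fiber gene alone a podovirus (short-tailed phages carry little
more); no tail genes, untyped.

**Lysogeny switch** (`call_lysogeny`) matches synteny grammars on the
canonical orientation, in precedence order chosen by marker specificity:

1. *ImmR/ImmA-like*: an ImmA/IrrE-family metallopeptidase adjacent (≤1
   intervening ORF) and co-oriented with an HTH regulator, with the next
   downstream HTH regulator opposed. The metallopeptidase is the most
   specific marker, so this is tested first.
2. *Mu-like C/Ner*: two divergently transcribed HTH regulators whose
   downstream partner is small (≤80 aa; Mu's Ner is 76 aa) with a Mu-type
   transposase within 10 ORFs downstream. The pair window is also 10 ORFs,
   because observed systems carry up to nine hypothetical inserts between
   the C and Ner homologues.
3. *λ-like CI/Cro*: the fallback — two adjacent divergently transcribed
   lysogeny-family ORFs, at least one an HTH regulator. Requiring the
   partner to be lysogeny-family (not any hypothetical neighbour) keeps
   stray divergent junctions from typing as switches.

Promoter calls participate only above a 0.87 score (the high-confidence
band of the upstream predictor's 0–1 score) and only to record the
intergenic pair geometry — divergent, convergent (transcriptional
interference designs), or tandem. Promoters *strengthen* calls; their
absence never vetoes one (`promoter_geometry = "none"`). All windows and
thresholds are exported arguments.

## qPCR release quantification

The DNase-protection design distinguishes encapsidated phage DNA (protected
by the capsid) from free DNA in culture supernatant. Technical replicates
are averaged after imputing non-amplifying wells at the cycle cap (40, the
run length of the protocol); ΔCq = treated mean − untreated mean;
ΔΔCq normalizes by the housekeeper's ΔCq; fold change = 2^−ΔΔCq. Detection
is treated-mean < NTC (margin configurable, default 0 — the design
criterion is simply "detectable relative to its NTC"), and a housekeeper at
or above its NTC is reported fully degraded, the positive control that
unprotected DNA was removed. ΔΔCq is computed on condition means rather
than per-replicate pairings because plate-to-plate replicate pairing is not
part of the input contract. No amplification-efficiency correction or
significance testing is attempted — inputs are Cq tables, and the
published analyses' ANOVA layer is out of scope.

## Synthetic data: what it shows and what it cannot

`generate_chromosome` plants prophages whose lysogeny switches, tail-gene
repertoires, defects and accessory cargo are realized literally as the
grammars above, interleaved with non-phage decoy clusters and
duplicate/overlapping hits, and emits ground truth for every element.
Defaults mirror the study conditions: 15 prophages, 8 non-phage decoys plus
6 duplicate hits (29 candidate hits in all), mostly CI/Cro switches with
ImmR/ImmA and Mu-like minorities, mixed morphotypes, intergenic spacing
around 40 kb. Layout randomness (gene-length jitter, spacing, decoy
content) is driven entirely by the seed; two runs with the same spec and
seed are byte-identical.

Noiseless recovery is exact by construction *and that is the point of the
test*: it verifies that every decoder inverts its generator — that rule
implementations match their definitions, orientations mirror correctly,
and nothing interferes across modules. What it cannot show is robustness to
real annotation noise: mislabelled categories, missing trait flags, wrong
protein lengths, fragmented gene calls. The packaged fixture is the harder
benchmark half-way to reality: its architectures carry the full
idiosyncrasies of a real poly-lysogen (abutting prophages, intron-split
genes inside modules, a 136 kb recombination hotspot), though its ORF
coordinates and Cq replicates are synthetic, constrained by the published
sizes, orderings and NTC relationships.

## Numerical and interface choices

- Coordinates are 1-based inclusive everywhere (`region_length(s, e) =
  e − s + 1`), the GenBank/GFF3 convention; the fixture's coordinate table
  retains one published size that disagrees with its own coordinates, and
  the tests assert the discrepancy rather than silently adopting either
  value.
- ORF order within a region is by start coordinate (ties: end, then id);
  reverse-packaged regions are mirrored (ORF order and strands flipped,
  coordinates preserved) before any grammar matching, and the mirroring is
  idempotent.
- The feature-table dialect carries no explicit region spans, so spans
  reconstruct as ORF envelopes and packaging strands by majority ORF
  orientation; GFF3 and the GenBank writer carry explicit region features
  and round-trip spans exactly.
- Trait vocabulary for the accessory screen ships as an editable TSV;
  edits affect only the screen, never curation or typing. A solitary
  antitoxin (no toxin partner in the region) is classed as
  anti-phage-defence with a degenerate-TA caveat, since either reading is
  defensible.
- Problem sizes in the test suite: the fixture (15 regions, ~450 ORFs) is
  built once per run; property tests use 100 generated chromosomes of up
  to 10 prophages and 1000 random hit lists against a brute-force
  interval-union oracle.

## Limitations

Annotations are trusted as given: no gene calling, no translation, no
sequence-level verification of frameshifts or intron boundaries. The
completeness score is consumed, not computed. Morphology is a genotype
prediction, not microscopy. The accessory screen sees only flagged traits —
hypothetical proteins stay invisible to it. And mosaic boundary placement
is conservative around Mu-type starts, as discussed above.
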