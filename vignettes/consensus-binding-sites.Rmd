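---
title: "Consensus miRNA binding sites: models, parameters and design choices"
author: "mirtrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus miRNA binding sites: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrack)
```

## Scope and rationale

`mirtrack` predicts microRNA binding sites over *full-length mature
transcripts* — not only 3′UTRs, since functional sites occur in coding
sequence and 5′UTRs too — keeps only sites that three independent predictor
engines agree on, and projects the survivors back to genome coordinates
through each transcript's exon structure. Working per transcript rather than
per gene is the point: two isoforms of one gene can differ in exactly the
exon that carries a site, and the package's output makes that visible as
isoform-specific track items.

This vignette explains the models inside each engine, every tunable
parameter with its default and units, what the synthetic-fixture generator
does and does not emulate, the numerical conventions, and the design
decisions taken where more than one reasonable choice existed.

## Coordinate conventions

All internal coordinates are 0-based half-open, on both transcripts and the
genome. GTF input (1-based closed) is converted on read; BED output is
written natively in 0-based half-open form, so `chromStart` in the bedDetail
file is one less than what the UCSC browser displays. Human-facing ranges
(detail pages, the CSV's transcript ranges) are printed 1-based inclusive.
A single internal convention avoids off-by-one drift between the parser, the
aligner, the splice map and the writers.

Minus-strand transcripts read 5′→3′ along descending genomic coordinates:
transcript offset 0 maps to the model's *highest* genomic position, and
projected block lists are re-sorted to genomic ascending order because BED
requires it.

## The three predictor engines

The three engines are deliberately simplified, documented re-creations of
the three classic prediction strategies — seed match, complementarity
alignment, and site accessibility. Bit-parity with the original binaries is
a non-goal; for users who need the original tools' numbers, the native
output adapters (`parse_native_output()`) produce the same candidate-site
tables from TargetScan/miRanda/PITA tabular files, and slot into the same
consensus step.

### Seed classifier

An 8-nt window slides over the transcript; its last base sits opposite
miRNA position 1. With strict Watson–Crick pairing (G:U never counts in the
seed):

* `8mer-1a` — window positions 1–7 reverse-complement miRNA positions 2–8
  and position 8 is A;
* `7mer-m8` — the same 2–8 pairing without the terminal A;
* `7mer-1a` — positions 2–7 pair miRNA 2–7, position 8 is A, and pairing at
  miRNA position 8 fails (otherwise the site would be an 8mer).

The three predicates are mutually exclusive by construction. The reported
span is the matched target span: 8 nt for `8mer-1a`, positions 1–7 of the
window for `7mer-m8`, positions 2–8 for `7mer-1a`. The terminal A is part of
the span: like the original seed taxonomy, the A opposite position 1 is a
feature of the *site*, whether or not it pairs.

### Complementarity aligner

A Smith–Waterman/Gotoh local alignment of the *reversed* miRNA against the
transcript, scoring complementarity instead of identity. Defaults
(`miranda_params()`):

| parameter | default | meaning |
|---|---|---|
| `match` | +5 | Watson–Crick pair reward per column |
| `wobble` | +1 | G:U pair reward |
| `mismatch` | −3 | non-pairing column |
| `gap_open` | −9 | first base of a gap |
| `gap_extend` | −4 | each additional gap base |
| `seed_scale` | ×2 | multiplier on columns pairing miRNA positions 2–8 |
| `report_threshold` | 100 | minimum score to report a site |

A perfect complement of a 22-nt miRNA therefore scores
5 × (22 + 7) = 145: 22 match columns plus 7 seed columns counted twice.
Binding energy is computed over the alignment's paired columns with the
per-pair duplex model below. Multiple sites per (miRNA, transcript) pair are
extracted best-first with overlap masking — masked target bases can be
consumed neither by aligned nor by gapped columns — so reported sites never
share target bases. Ties in the DP traceback resolve deterministically
(local start, then diagonal, then query-gap, then target-gap; best cell ties
resolve to the smallest target, then query, end).

### Per-pair duplex energy

`duplex_energy()` is a stacking-free stand-in for nearest-neighbor
thermodynamics: G:C −3.0, A:U −2.0, G:U −1.0 kcal/mol per pair, unpaired
columns 0, summed. It is monotone in the number and strength of pairs, which
is the property the retention thresholds actually use; absolute Turner-model
accuracy is out of scope and documented as such.

### Accessibility engine

Candidate regions anchor at seed matches and extend to the span the
full-length miRNA would cover, with position 1 opposite the base 3′ of the
seed match (for `7mer-m8` spans, which stop at position 2, the anchor is
extended by one base). The score is

ΔΔG = ΔG_duplex + ΔG_open,

where ΔG_duplex (≤ 0) is the gapless antiparallel duplex energy of the miRNA
over the site and ΔG_open (≥ 0) is the cost of opening local target
structure. The default opening backend scores the strongest antiparallel
stem (contiguous WC/G:U run of ≥ 4 bp, per-pair energies as above) between
the site and up to 35 nt of flank on either side; an unstructured flank
(e.g. poly-A against a site without a U-run) opens for free. The backend is
pluggable — any function `(transcript_seq, t_start, t_end) → ΔG_open` can
replace it, e.g. one backed by a full RNA-folding tool. Full partition-
function folding is intentionally not re-implemented.

## Retention thresholds and consensus

`threshold_config()` holds the high-confidence filter, with inclusive
comparisons throughout:

* miRanda engine: binding energy ≤ −20 kcal/mol **and** score ≥ 140;
* accessibility engine: ΔΔG ≤ −10 kcal/mol;
* seed engine: site type in {`8mer-1a`, `7mer-1a`, `7mer-m8`};
* three-way transcript-space overlap ≥ 6 nt.

"Overlap" is read as the length of the *common intersection* of the three
engines' intervals, computed per (miRNA, transcript) pair over every triple
of one site per engine; the pairwise-overlap reading was rejected as weaker.
The reported interval is that intersection core — the most conservative
choice — while each engine's full range is preserved for the detail page.
When cores from distinct triples overlap, the triple with the lowest (most
negative) miRanda energy wins, ties broken by leftmost core; the rule is
arbitrary but deterministic, which the byte-reproducibility guarantee
requires. Whether the original three-tool pipelines required the overlap
pairwise or jointly is not documented anywhere we could verify, so the
minimum overlap is exposed as configuration (`min_overlap`).

One consequence of anchoring the accessibility engine at seed matches: a
site with a broken seed has neither a seed call nor an accessibility call.
The package's decoy fixtures (below) account for this — a seed-broken decoy
is excluded from consensus with *two* missing engines rather than one, which
does not change what the tests assert (exclusion).

## Genome projection and track output

`transcript_to_genome()` is a self-contained re-implementation of spliced
interval projection (the `transcriptToGenome`-style operation): the
consensus core is cut at every exon junction it crosses, yielding a BED
block list. `genome_to_transcript()` is its exact per-base inverse and
exists chiefly so the round-trip property can be tested mechanically. Sites
spanning more than two exons are supported (with a warning, since ~20-nt
sites rarely cross two junctions) and still serialize as valid BED.

Track items deduplicate by *exact* (chromosome, strand, block tuple): the
same genomic region reached through several transcripts and/or miRNAs is one
item, labelled with the lexicographically first member miRNA plus a trailing
`*` when two or more distinct miRNAs share it (the label choice is not
specified by any convention we know of; lexicographic-first is deterministic).
Identical spans with different block splits stay distinct. Item ids are
`MBS` + 8-digit ordinal in sorted genomic order. The BED score column is
fixed at 0 (unused), the item color at `255,255,0`. Energies print with two
decimals and scores as integers when integral, for byte-stable output.

## The synthetic-fixture generator

`generate_fixture()` builds the complete test bed the rest of the package is
validated against, deterministically per seed. Defaults
(`fixture_spec()`): 2 chromosomes of 5,000 nt with uniform 25% base
composition; 4 genes of 3–4 exons (90–150 nt, introns 60–140 nt), laid
alternately across chromosomes and strands; two isoforms per gene — the full
exon chain and a middle-exon-skipping isoform, so planted sites in shared
exons propagate between isoforms and junction-spanning sites vanish from the
skipping isoform; 3 miRNAs of 23 nt. These sizes keep a full pipeline run in
about a second while still exercising multi-chromosome, multi-isoform, both-
strand and junction-spanning behavior; they are fixture dimensions, not
statistical claims.

miRNAs are drawn with a 5′-terminal U (the canonical bias of mature miRNAs)
and positions 5 and 8 from {G, U}. The terminal U makes the planted A
opposite position 1 a real pair, so a full-length plant aligns end to end;
the {G, U} constraint guarantees a wobble partner exists wherever a plant
needs one (see decoys). At 23 nt, a perfect plant scores
5 × (23 + 7) = 150, leaving headroom: one seed wobble costs 8 → 142, still
above the 140 threshold — which is exactly what the `7mer-1a` plant (whose
definition requires broken pairing at position 8) needs to reach consensus.

The default plant plan is five consensus sites (all three seed classes, one
spanning an exon–exon junction) and three single-engine decoys:

* *seed decoy* — a G:U wobble inside seed positions 2–7 with the terminal A
  kept: no seed class matches, the aligner still scores 142;
* *aligner decoy* — three non-pairing bases in the non-seed region: score
  drops to 126 < 140 while seed and accessibility calls survive;
* *accessibility decoy* — a perfect site whose downstream flank hides the
  reverse complement of the site's first 20 nt: the opening backend finds a
  20-bp stem, ΔG_open cancels most of ΔG_duplex, and ΔΔG lands above −10
  (arithmetically bounded between −8 and −6 for any base composition).

Sites are planted by writing the reverse complement of the miRNA into the
*genome* through the splice map, so isoforms sharing the exon inherit the
site; the ground-truth table enumerates every (plant, carrier transcript)
pair with its expected seed span, site type, consensus flag and projected
block count. Where a skipping isoform would carry only the 5′ fragment of a
junction plant, the generator writes two non-pairing bases just after that
isoform's junction, so a truncated plant cannot be completed by chance by
the next exon's sequence. After all edits, the generator re-runs the actual
engines over every (miRNA, transcript) pair and requires the consensus calls
to match the ground truth exactly — plants recovered uniquely, decoys and
unplanned sites absent — retrying with fresh randomness (bounded at 20
attempts) when the random background interferes.

`shuffle_negative_control()` replaces each planted site by a same-composition
permutation verified (bounded retries) to produce no seed match in its
region, for negative-control scanning.

What the fixtures deliberately do **not** emulate: realistic (GC-skewed,
repeat-containing) sequence composition, evolutionary conservation, miRNA
expression levels, non-canonical site chemistry, and real thermodynamics.
Passing the fixture suite therefore demonstrates that the pipeline's logic —
classification, alignment, thresholding, intersection, projection,
serialization — is correct and deterministic; it does not validate
biological accuracy of the simplified engines on real transcriptomes, for
which the native adapters plus the original tools remain the reference
route.

## Degenerate inputs and numerical corner cases

* Transcripts shorter than 8 nt yield empty scans, not errors.
* Transcripts mixing chromosomes or strands across exons are rejected at
  parse time with a warning naming the transcript.
* The canonical-chromosome filter defaults to chr1–chr22, chrX, chrY, chrM
  (common GRCh38 practice; no authoritative list exists), and is plain
  configuration.
* DP traceback comparisons use an absolute tolerance of 1e-6; all default
  scores are integers, so ties are exact.
* An opening backend returning a negative or non-finite ΔG_open is a
  reported error, not silently clamped.
* `intersect_three()` refuses mixed (miRNA, transcript) identifiers rather
  than guessing a grouping.

## Problem sizes used by the shipped checks

The test suite exercises: 10,000 random model/interval projection
round-trips; 1,000 random three-way intersection instances against a
per-base brute-force oracle; 100 aligner instances (transcripts ≤ 40 nt)
against an independently coded cell-by-cell DP; and 50 seeded fixtures run
end-to-end with their shuffled negative controls, on which planted-site
recall and precision are both required to be 100%. The acceptance script
regenerates a fixture and re-measures the emitted bedDetail/CSV artifacts
from scratch on every run.

## Known limitations

* The built-in engines are simplified by design; their absolute scores are
  not comparable to the original tools' outputs, only their decisions under
  the shipped thresholds are analogous.
* The aligner applies the score threshold per site, not per pair total;
  with multiple sites per pair the per-pair reading would be more permissive.
* GTF is the only supported annotation dialect (no GFF3), and trans-spliced
  or multi-chromosome transcripts are rejected upstream.
* The opening-energy heuristic considers a single best stem; competing or
  pseudoknotted structure is ignored.
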