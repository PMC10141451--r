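# mirtrack

Consensus microRNA binding-site prediction over full-length mature
transcripts, with splice-aware projection onto the genome and UCSC custom
track output.

## The problem

MicroRNAs (miRNAs) repress messenger RNAs by base-pairing with short binding
sites, classically through the *seed* — miRNA nucleotides 2–7. Individual
prediction algorithms disagree wildly, so a common strategy is to keep only
sites that several independent methods agree on. Because different transcripts
of one gene splice different exons, the same genomic binding site can exist in
one isoform and be absent from another — a distinction lost when predictions
are made per gene or per 3′UTR. `mirtrack` therefore works on *whole mature
transcripts* and carries every site back to genome coordinates through each
transcript's exon structure, so isoform-specific sites are visible in a
genome browser.

`mirtrack` is for computational biologists who want a reproducible,
configurable consensus pipeline at small-to-medium scale, and for method
developers who need a fully synthetic, ground-truthed test bed for
binding-site tools.

## What it computes

Three predictor engines score every (miRNA, transcript) pair:

* **seed classifier** (TargetScan-style): slides an 8-nt window and calls
  canonical site types — `8mer-1a` (Watson–Crick pairing to miRNA positions
  2–8 plus an A opposite position 1), `7mer-m8` (pairing 2–8, no A), and
  `7mer-1a` (pairing 2–7 plus the A);
* **complementarity aligner** (miRanda-style): Smith–Waterman/Gotoh local
  alignment of the reversed miRNA against the transcript with match/wobble/
  mismatch/gap scoring, seed positions weighted ×2, plus a per-pair duplex
  binding energy;
* **accessibility scorer** (PITA-style): ΔΔG = ΔG_duplex + ΔG_open, the
  duplex energy gained minus the cost of opening local target structure
  (default backend: strongest complementary stem between the site and ±35 nt
  of flank).

A site is retained only when **all three** engines call it with ≥ 6 nt of
transcript-space overlap and it passes the retention thresholds
(miRanda energy ≤ −20 kcal/mol and score ≥ 140; ΔΔG ≤ −10 kcal/mol; site type
one of the three seed classes; all comparisons inclusive). Consensus cores
are projected through the exon structure (sites crossing an exon–exon
junction become multi-block BED features) and serialized as:

* a 14-column UCSC **bedDetail** track (one item per distinct genomic region;
  a trailing `*` on the label marks regions shared by several miRNAs),
* one **HTML detail page** per item (6-column per-pair evidence table),
* a 14-column semicolon-separated **CSV**.

Adapters for native TargetScan/miRanda/PITA tabular output let you substitute
real tool runs for any built-in engine.

## Worked example

Everything below runs offline on a synthetic fixture: a two-chromosome
genome, four multi-exon genes with two isoforms each (one skips a middle
exon), three miRNAs, and planted binding sites — including one that straddles
an exon–exon junction and three per-engine decoys.

```r
library(mirtrack)

fx <- generate_fixture(fixture_spec(rng_seed = 1))
write_fixture(fx, "fixture")

res <- run_pipeline(
  gtf = "fixture/transcripts.gtf",
  transcripts_fasta = "fixture/transcripts.fa",
  mirnas_fasta = "fixture/mirnas.fa",
  bed = "track.bed", csv = "track.csv", details_dir = "details"
)
res
#> Consensus miRNA binding-site track
#>   transcripts: 8
#>   candidate sites (all engines): 42
#>   consensus sites: 9
#>   track items (deduplicated regions): 5
```

Nine consensus sites collapse into five track items because sites shared by
both isoforms of a gene are annotated once. The first lines of the track:

```
track type=bedDetail name="miRNA binding sites" description="Consensus miRNA binding sites" itemRgb="On"
chr1  151  159  syn-miR-2-5p  0  +  151  159  255,255,0  1  8,    0,     MBS00000001  syn-miR-2-5p
chr1  262  333  syn-miR-1-5p  0  +  262  333  255,255,0  2  2,6,  0,65,  MBS00000002  syn-miR-1-5p
```

`MBS00000002` is the junction-spanning site: `blockCount` 2, with a 2-nt and
a 6-nt block separated by an intron — exactly how a spliced feature renders
in the UCSC browser. The CSV holds one row per (miRNA, transcript) pair with
the per-engine evidence:

```
transcript_id;gene_id;gene_name;mirna_id;t_start;t_end;chrom;strand;g_start;g_end;targetscan_site_type;pita_ddg;miranda_energy;miranda_score
ENSTESTT00000001;ENSTESTG00000001;GENE1;syn-miR-2-5p;32;39;chr1;+;151;159;8mer-1a;-44.00;-57.00;150
ENSTESTT00000002;ENSTESTG00000001;GENE1;syn-miR-2-5p;32;39;chr1;+;151;159;8mer-1a;-44.00;-57.00;150
```

The same genomic site (chr1:151–159) appears through both isoforms of
`GENE1`; the junction site, by contrast, exists only in the isoform that
retains both exons. Downstream, results chain with the usual verbs:

```r
tidy(res)                             # one row per (miRNA, transcript) pair
glance(res)                           # one-row run summary
filter_track(res$items, by_mirna = "syn-miR-1-5p")
ggplot2::autoplot(res)                # track items along each chromosome
```

A thin CLI wraps the same functions
(`inst/cli/mirtrack.R fixture|run|filter ...`).

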