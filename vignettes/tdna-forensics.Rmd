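---
title: "Forensics of T-DNA integration from short-read resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensics of T-DNA integration from short-read resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Agrobacterium-mediated transformation integrates a T-DNA segment — the
region of a binary plasmid between the left border (LB) and right border
(RB) repeats — into the host genome, sometimes together with unintended
vector-backbone sequence, small "filler" nucleotides created during
double-strand-break repair, deletions of host DNA at the integration
site, and occasionally larger rearrangements. Whole-genome resequencing
of primary transformants against a hybrid reference (host chromosomes
plus the plasmid appended as one extra sequence) exposes all of these
events through two read-level signals:

* **broken pairs** — read pairs whose mates align to different
  references (host vs plasmid, or two different host chromosomes);
* **split reads** — single reads that span a junction, aligning partly
  to the host and partly to the plasmid, with the remainder as a soft
  clip.

`tdnascout` turns those signals into locus-level insert calls
(positions, construct segments, orientation, zygosity, site deletion,
filler DNA, class), transformant-unique small variants, and
insert-associated structural variation (large heterozygous deletions,
insert-flanking translocations). A first-class simulator generates
diploid transgenic genomes and paired-end reads with complete ground
truth, so every stage of the pipeline is testable without any external
data.

## The simulator and what it emulates

`realize_scenario()` turns a declarative `scenario_spec` into genomes:

1. a random reference (i.i.d. bases, GC 0.36 by default — a plant-like
   composition), plus any engineered repeated blocks;
2. a synthetic 14,200-bp binary plasmid with an 8,379-bp T-DNA
   (LB at position 1, RB at 8,379) and named features (`bar`, a
   host-derived promoter copied verbatim from the reference, `gfp`
   placed so that its central 50-bp window at 5,841–5,890 lies more
   than 2 kb from both borders, `GUS`, backbone);
3. a diploid parent carrying shared homozygous SNPs (default density
   ~45/Mb, matching the observed divergence of a laboratory stock from
   its published reference genome). Parental variants are SNPs only, so
   parent coordinates remain identical to reference coordinates and
   every engineered event is bp-exact on the reference frame;
4. per-plant diploid genomes: each insert event replaces
   `site_deletion` bases on one haplotype with
   `filler_left + segments + filler_right` (segments
   reverse-complemented on the "−" strand; a referenced translocation
   appends a copy of a donor-chromosome fragment next to the insert).
   The homologous haplotype is untouched — every event is heterozygous
   unless engineered twice.

`simulate_reads()` draws fragments uniformly from both haplotypes
(Normal fragment length, default 625 ± 30 bp truncated at twice the
read length), reads 2 × 101 nt inward (FR), and applies i.i.d.
substitution errors (default 0.001). There are no indel errors, no
quality-score model (qualities are flat), no PCR duplicates, and no
coverage biases — passing tests therefore demonstrate the logic of the
callers under clean Illumina-like data, not robustness to every
real-world artifact.

Two deliberate generator choices matter for interpretation:

* **Junction identifiability.** One-base homology between an insert's
  terminal base and the adjacent deleted host base (or the plasmid base
  just outside a junction-defining segment boundary) makes the true
  breakpoint ambiguous — any caller would report a shifted junction.
  The generator resamples those single reference/plasmid bases so each
  engineered junction has one identifiable breakpoint. Real data offer
  no such guarantee; junction coordinates there are reported up to
  microhomology.
* **Single-sided inserts.** Inserts whose one flank lies in a block
  that also occurs elsewhere in the reference produce junction evidence
  with mapping quality 0 on that side and are therefore called
  single-sided with "at least" size semantics — the same mechanism
  (repetitive flank) hypothesized for one-transition inserts in real
  transformants.

### The bundled five-transformant scenario

`transformant_scenario(scale)` encodes the full event inventory of five
transformants: 12 heterozygous inserts (two full LB–RB inserts, six
partials of which several are single-sided or translocation-flanked,
two inverted repeats of which one includes backbone, one backbone-only
insert, and one 50-bp *gfp*-internal "splinter" with 1-bp and 6-bp
fillers over an 11-bp site deletion in reverse orientation), ten unique
heterozygous small variants (six short deletions, four SNPs, two of
them adjacent to a full insert and only discoverable by the rescue
scan; none in plants 2 and 5), four translocation-flanked inserts, and
two large heterozygous deletions, one starting at the plant-5 insert.
Genomic coordinates are divided by `scale` (default 150: five
chromosomes of 124–203 kb, ~0.8 Mb haploid — desk-scale runtime of
roughly two minutes per cohort on one core), while all within-junction
geometry (segment coordinates, fillers, site deletions of 11/15/34/90/
2,393 bp, insert-adjacent variant offsets) never scales. At
`scale = 1` the coordinates are the published ones, e.g. the plant-5
deletion spans 736,487 bp. `at5_deletion_scenario()` reproduces that
rearrangement at full length on a 1.5-Mb test chromosome (the second,
1.2-Mb chromosome keeps the deleted fraction of the genome small
enough that the genome-wide median depth is an unbiased normalizer).

## The mapper

The built-in mapper is a seed-and-extend aligner over a k-mer index of
the hybrid reference (k = 21 by default; odd, 15–31). Seed hits are
chained by diagonal; candidates are extended ungapped (best-scoring
contiguous segment, clips free at the ends; match +1, mismatch −4).
When seeds disagree by a small offset, or an ungapped extension leaves
a clipped tail, a banded Smith–Waterman with a capped gap length takes
over (one indel of at most 6 bp, cost 5 + length). The cap is the
pivot of the whole design: indels up to 6 bp — the small mutations the
variant caller must see — are absorbed into the alignment, while every
junction with 11 bp or more of site deletion, and every T-DNA border,
surfaces as a soft clip, i.e. as evidence. Mapping quality is 60 for a
unique best hit, 0 for ties, and otherwise interpolated from the score
gap — counting only alternative placements that explain the same read
bases, so the complementary segment of a split read never penalizes
its mate segment. Reads whose aligned window is mostly non-unique
(per a read-length uniqueness mask over the hybrid reference) are
capped at MQ 50, which feeds the "MQ > 50" structural-variant filter.

`local_align()` exposes the exhaustive local aligner used as the
independent oracle in the tests.

## Evidence and insert calling

`collect_evidence()` classifies mated alignments (construct,
inter-chromosomal and long-range pairs) and realigns every soft clip of
at least 12 bp against the hybrid reference with a small-k index,
accepting hits of ≥ 90% identity. Unaligned residue between the two
segments of one read is kept as candidate filler DNA (bounded at 20 bp;
longer residues mark the record unresolved). Evidence whose construct
span lies wholly inside a host-derived construct feature (the promoter
amplified from the host genome) is excluded — such reads cannot
distinguish plasmid from host origin. The 12-bp clip threshold and the
90% identity floor are configuration knobs; they balance specificity
against sensitivity at 101-nt reads and can be lowered to recover
shorter informative clips.

`cluster_evidence()` merges split breakpoints within 5 bp per
chromosome and junction side (cluster position = median) and assigns
broken pairs to the nearest split cluster within
`frag_mean + 3·frag_sd`. `call_inserts()` pairs left- and right-side
clusters on one chromosome into both-sided calls (site deletion =
right breakpoint − left breakpoint − 1, bridging up to 3 kb), pairs
leftover single-sided clusters across chromosomes when their construct
boundaries are complementary and orientations agree (translocation
candidates, flanking chromosomes of size 2), and reports the rest as
single-sided calls whose construct extent is a lower bound ("at
least"). Stray single-sided clusters within 800 bp of an accepted
call's breakpoint are absorbed rather than emitted — they are satellite
evidence of the same junction. Zygosity follows from the fraction of
junction-supporting versus reference-spanning reads (heterozygous when
the fraction lies in [0.2, 0.8] and a two-sided binomial test against
0.5 is not rejected at p < 0.01); for translocation candidates the two
junctions are genotyped separately, because the donor locus of a
copied fragment stays fully covered and would dilute a pooled
fraction.

Classification: **full** if segments cover ≥ 95% of the LB–RB span in
one orientation; **inverted_repeat** for opposing-strand segments;
**backbone** if any segment lies outside the T-DNA; **splinter** for a
both-sided call of total construct length ≤ 300 bp with every segment
at least 100 bp from both borders (`splinter_max` and `border_margin`
operationalize "a small fragment not coming from a border region");
otherwise **partial**. `reconstruct_junction()` rebuilds the full
inserted sequence of short inserts from the consensus of
junction-spanning reads and places the construct segment inside it to
derive the fillers; the reconstruction is checked base-for-base
against the engineered haplotype in the tests.

## The two-tier small-variant scheme

`pileup_host()` counts, per host position, reads that are not linked to
the construct (a read is construct-linked when its mate maps to the
plasmid or its clip realigns there); excluded reads are tallied
separately. Short soft clips (2–11 bp) that exactly match the reference
after skipping 1–8 bases are counted as split-read support for the
corresponding small deletion — reads whose deletion-side tail is too
short for a gapped alignment would otherwise silently vanish from the
variant fraction. `call_stringent()` emits alleles with coverage
strictly above 10× and variant fraction ≥ 40%, skipping masked
positions; `call_lenient()` records every allele at ≥ 10% in the
control pool and the other transformants. `filter_unique()` keeps
candidates that are lenient-unsupported everywhere else and
heterozygous — the deterministic replacement for by-eye re-inspection.
`rescue_insert_proximal()` re-piles within 500 bp of each insert
breakpoint without construct-linked exclusion, additionally projecting
the host-aligned clip segments of plasmid-primary junction reads back
onto the host, and applies the same stringent thresholds; new unique
heterozygous variants enter with status "rescued".

A power caveat that the tests quantify: a true heterozygous variant at
~25× has allele fraction ~Binomial(n≈25, 0.5)/n, and
P(fraction ≥ 0.40) = 0.885 (closed form at n = 25). Recovery of any
fixed inventory of ~10 variants is therefore expected to fall 1–3
short in a typical cohort at these thresholds — an inherent property
of the 40%-fraction rule at this depth, not of the implementation,
which the tests verify captures every informative read.

## Structural variation

`build_depth_track()` bins coverage (500 bp at desk scale, 5 kb for
full-length chromosomes — at least ten fragments per bin at the
simulated depths) and normalizes plant/control, each scaled by its
genome-wide median bin. Runs of ≥ 3 bins with normalized ratio in
[0.3, 0.7] seed heterozygous-deletion candidates (single-bin
excursions inside a long run are closed); boundaries snap to the
nearest split cluster within 2 kb, then to broken pairs. Candidates
pass when they meet the reporting filters: ≥ 10 supporting pairs, mean
MQ > 50, genotype quality > 30 from a transparent binomial genotyper
(alt-read probabilities 0.05/0.5/0.95; GQ = phred difference between
best and second-best likelihood), alt fraction ≥ 0.4, heterozygous in
the plant and homozygous-reference in the control; failures are
retained with the failed filters named. Deletions whose boundaries
coincide with a both-sided insert call's breakpoints are that call's
site deletion and are rejected here with reason
`insert_site_deletion`; deletions below ~300 bp are below the
detection design of this track altogether. `call_translocations()`
emits a breakend-style record for every insert whose two flanks map to
different chromosomes, genotyped per junction at pair level and
annotated with the insert id. Derivative chromosomes are not
reconstructed — with ~625-bp fragments the exact size and type of the
translocated piece is not resolvable, and the record says only where
the two junctions are.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout the package; BED output
  converts to 0-based half-open at the file boundary.
* Ties in the mapper break toward the lowest reference index and
  coordinate; cluster positions are medians; consensus bases are
  per-position majorities.
* Indel alleles use the anchored ref/alt convention; the generator
  avoids homopolymer context for engineered indels so gap placement is
  unambiguous (real indels in homopolymers would be reported
  left-shifted by the aligner's deterministic traceback).
* Reads with no seed hit become unmapped records, never errors; orphan
  mates are flagged and kept; a control bin with zero coverage flags
  its ratio rather than dividing by zero; an empty cohort is an error
  in `summarize()`.
* All randomness flows from one master seed through deterministic
  per-stage derived seeds (kept below 2^31); identical seeds give
  byte-identical FASTQ, truth tables and reports.

## Problem sizes used by the test-suite and reproduction script

The bundled cohort runs five plants plus a control pool at 25×,
2 × 101 nt on an ~0.8-Mb haploid genome (about two minutes per
cohort); the full-length deletion test uses a 2.7-Mb two-chromosome
genome at 10×. The depth-ratio calibration uses 12 heterozygous
deletions of 4–12 kb on one 400-kb chromosome; the variant-power check
uses 30 replicates of a single heterozygous SNP at 25× on a 30-kb
chromosome. These sizes are the package's documented trade-off between
statistical resolution and a turnaround that keeps the whole suite
runnable on a laptop core.

## Known limitations

* The simulator's error model is substitutions only with flat
  qualities; base-quality-aware calling is neither needed nor
  implemented.
* Multi-copy concatemer assembly is out of scope: composite inserts
  are reported through their junction segments and construct-coverage
  extents, not assembled end-to-end.
* The uniqueness mask counts forward-strand window occurrences;
  palindromic duplications are handled through mapping ties rather
  than the mask.
* Gene-annotation overlap (which features an insert interrupts)
  requires an external annotation and is not part of the package.
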