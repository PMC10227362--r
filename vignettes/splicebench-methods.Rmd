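---
title: "Methods: simulation, normalization and benchmark metrics"
author: "splicebench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, normalization and benchmark metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicebench)
```

## The unified event representation

Every alternative-splicing (AS) event is reduced to its *event-defining
coordinates* on the genome, 1-based inclusive (the native convention shared
by GTF and SAM; half-open coordinates appear nowhere in this package):

| type | blocks | meaning |
|------|--------|---------|
| ES   | 1      | the skipped cassette exon |
| MES  | ≥ 2    | the consecutively skipped exons |
| MEE  | ≥ 2    | the mutually exclusive exons |
| IR   | 1      | the retained intron |
| A5 / A3 | 1   | the exonic bases present in exactly one of the two splice-site variants |
| AFE / ALE | 1 | the alternative first / last exon |

A5 and A3 are *strand-relative*: A5 is a donor shift (the 5′ end of an
intron), A3 an acceptor shift. On the genome this means an A5 on the `+`
strand moves an exon's right boundary, while the same genomic change on the
`-` strand is an A3. The "alternative part of an exon" for A5/A3 is defined
as the set difference of the two exon variants, reported as one closed
interval; this is the unique choice that is symmetric under strand
reflection, and it is what the coordinate arithmetic in
`normalize_junctions()` computes from the two competing splice sites
(`[min(d, d_ann)+1, max(d, d_ann)]` for donors given as last exonic bases,
mirrored for acceptors).

Events compare by `event_key()`: chromosome, strand, effective type and
exact blocks. Gene name, event id and source tool are deliberately excluded
(tools disagree on identifiers; coordinates are the comparable signal).
With `collapse_skipping` (default on) MES and MEE count as ES, reflecting
that most tools report any skipping variant as plain exon skipping.

## Dialect normalization

Three reporting conventions are supported. The *skipped-exon* dialect
carries event-defining coordinates directly (with an optional claimed type,
so it can express all eight types). The *flanking-exons* dialect gives the
two neighboring exons of a skipping event; the skipped exons are recovered
as the main-transcript exons strictly between the flanks — adjacent flanks
are rejected (`not-normalizable`), because this dialect cannot express
retention or splice-site shifts. The *junction* dialect gives an anchor
exon plus `donor:acceptor` genomic pairs, or a retained-intron flag.

Junction classification makes a deliberate two-level use of the annotation:

* **site existence** is checked against *all* transcripts of the anchor
  gene — a junction whose donor or acceptor is annotated nowhere is
  rejected as `novel-junction`;
* **block derivation** uses the *main transcript only*: both sites on main
  introns with exons in between → ES/MES; a shared acceptor with a shifted
  donor → A5 (strand-aware), and symmetrically A3; a retained flag over a
  main intron → IR.

This split is what makes the truncated-annotation experiment meaningful:
`truncate_annotation()` removes all alternative isoforms, after which the
shifted splice site of an A5/A3 junction loses its annotation support and
the record is rejected as novel, while ES and IR records — whose sites are
all on the main transcript — survive. The package's tests assert exactly
this degradation pattern (A5/A3 recall drops with novel-junction
rejections; ES/IR recall stays at 1). Retention records remain
normalizable against a main-only annotation by construction, so the
implemented de novo penalty is specific to splice-site shifts.

Anchor genes are resolved by span containment with a deterministic
tie-break (smallest span, then lexicographic gene id). In lenient mode a
record that resolves to no gene is rejected and counted
(`unresolved-gene`), never half-emitted; strict mode turns the first
rejection into an error. A record with an explicit gene hint that matches a
known gene skips containment.

## The synthetic truth generator

`simulate_annotation()` builds `n_genes` non-overlapping genes on one
synthetic chromosome (`simchr1`), alternating strands. Geometry: 4–12 exons
per gene, exon lengths 50–300 bp, intron lengths 100–1000 bp, 5000 bp
intergenic gaps. These values are a package choice: they are small enough
for desk-scale runs yet leave room for every event type (a 4-exon gene
still has two internal exons) and keep splice-site shifts (10–60 bp,
capped below intron/exon size) unambiguous — a shift can never be mistaken
for a retention because shifts are < 100 bp and introns are ≥ 100 bp.

Each gene gets a main transcript (all exons) and one alternative transcript
realizing the configured events:

* ES removes one internal exon; MES removes 2–3 consecutive internal exons;
* MEE replaces an internal exon by a novel exon in the adjacent intron
  (the two exons are mutually exclusive between the isoforms);
* IR merges two adjacent internal exons across their intron;
* A5/A3 move a donor/acceptor by 10–60 bp, extending into the intron or
  retreating into the exon with equal probability, strand-aware;
* AFE/ALE replace the first/last transcribed exon by a novel exon placed
  200–1000 bp into the flanking intergenic region.

The presets encode the six study designs: S0 = {ES, IR, A5, A3} in equal
proportions, one event per transcript, error-free; S1/S2 add
{MES, ALE, AFE} (S2 with a 0.1% per-base substitution error); S3/S4 place
two events per transcript — of *distinct* types, which is how "two types of
events within one transcript" is read here, and which also keeps the
structural validator's diff unambiguous (two adjacent single-exon skips
would otherwise be indistinguishable from one MES); S5 returns to the four
core types with caller-supplied proportions. The biologically derived S5
mixture is a free parameter (`load_preset("S5", proportions = ...)`,
default equal) because no published numeric decomposition is available to
hard-code.

With two events per transcript, `events_per_exon = 1` (S3) forces the two
events onto exon sets separated by at least one untouched exon;
`events_per_exon = 2` (S4/S5) allows anchors to touch and allows the one
well-defined same-exon combination, A5 + A3 on the two boundaries of a
single exon. Two skipping events are always kept non-adjacent, and two
events never claim the same intron — both constraints exist so that the
main-vs-alternative diff re-derives events uniquely. Event types are drawn
from the configured proportions; a draw infeasible on the sampled gene
(e.g. a pair that does not fit a 4-exon gene under the separation rule) is
resampled, so every gene carries exactly the configured number of events.
This resampling can shift realized type frequencies slightly for 2-event
designs on small genes; for 1-event designs every type fits every gene and
the realized counts are exactly multinomial — the χ² recovery check is
therefore run on S0.

An independent validator (`rederive_events()`) reconstructs all events
from the transcript structures alone — exact exon matches are stripped,
merged exons yield IR, single-boundary shifts yield A5/A3 by strand, novel
exons yield AFE/ALE/MEE by position, and remaining missing runs yield
ES/MES — and `truth_recovery()` compares this against the recorded truth.
Recovery is 100% on all six presets in the test suite.

## Read simulation and mapping metrics

Reads are single-end (`read_length` default 76 bp, the common short-read
length): a gene is drawn uniformly among genes with a sufficiently long
isoform, an isoform uniformly within the gene, and a start position
uniformly along the transcript; transcript coordinates are projected
through the exon chain to genomic blocks, giving the per-read truth (blocks
and junctions) and a perfectly aligned SAM (CIGAR `M`/`N` only). Sequences
come from a seeded i.i.d. reference, so an error-free FASTQ equals the
reference projection exactly; the error model is substitution-only at a
flat per-base rate (no indels, no quality-dependence — qualities are
constant `I` and nothing consumes them). There is no fragment-length or
expression model beyond uniform isoform sampling: the mapping metrics are
coordinate-level and gain nothing from one.

`evaluate_mapping()` scores primary alignments only (one vote per read);
reads absent from the SAM count as unmapped because real mappers sometimes
drop reads instead of flagging them, and the denominator of the unmapped
fraction is *all simulated reads*. A read is correct iff chromosome, block
count, every block boundary and the junction set agree with truth within
`tolerance` (default 0 — simulation and truth share one coordinate system,
so exactness is free; the parameter exists for real-world slack). Because
"correctly mapped reads and junctions" pools two granularities, the package
reports both: `precision_read` (junction-strict per-read correctness, the
headline number) and `precision_junction` (pooled over all junctions).
`corrupt_alignments(u, m)` uses largest-remainder rounding so the expected
metrics are exact at any read count: `fraction_unmapped = u`,
`precision_read = (1-u-m)/(1-u)`.

## Event matching and consensus

`match_events()` builds candidate pairs (equal chromosome/strand, equal
effective type when `type_strict`, blocks within `tolerance`; with
`partial_mes_credit` a reported single-exon skip may claim one exon of a
truth MES/MEE, consuming it) and assigns them greedily, exact matches
first, then in (chromosome, start, truth id, reported id) order — fully
deterministic, independent of input row order. At tolerance 0 the candidate
relation is essentially a partial matching and greedy assignment is
optimal; the test suite verifies equality with maximum bipartite matching
(igraph) on hundreds of random fixtures. Duplicate reports of a consumed
truth event are false positives; a truth MES counts once however many exons
it has. Precision and recall are `NA`, not 0/0, on empty denominators.

`intersect_toolsets()` computes exclusive UpSet regions over event keys
(regions sum to the union — a conservation law the tests assert), and
`consensus_events()` returns one representative per key with support ≥ k,
taking the representative from the lexicographically smallest tool label
for determinism.

## Problem sizes and limitations

The package's own checks run at desk scale by design: 200-gene simulations
for the end-to-end round trips, 500 genes per preset for the structural
validator, 2000 genes × 10 seeds for the χ² proportion recovery, 100 reads
for the analytic mapping-metric checks. These sizes give the properties
being tested (exact recovery, conservation laws, closed-form expectations)
their full force — they are deterministic or analytic, not
sampling-limited.

What passing these tests shows is internal coherence of format,
normalization and metrics against a generator whose events are *clean*:
real annotations have overlapping genes, nested and many-isoform loci,
fuzzy splice-site usage and coverage-dependent detection noise, none of
which the generator emulates. Results on simulated truth therefore bound
tool-comparison machinery, not biological detection difficulty. Further
out of scope: paired-end reads, PSI/quantification, differential splicing,
native parsers for specific tools' file formats, and execution of external
mappers or detectors.
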