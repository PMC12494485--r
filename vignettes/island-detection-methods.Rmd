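---
title: "Detecting under-recruited genomic islands and profiling virus-host signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting under-recruited genomic islands and profiling virus-host signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustvir)
library(dplyr)
```

## The problem

When environmental short reads are recruited back onto assembled genomes
(MAGs) or viral contigs (vOTUs), most of each replicon is covered at a
roughly uniform depth, but some stretches systematically under-recruit.
These *metagenomic islands* (MGIs, in microbial genomes) and *metaviromic
islands* (MVIs, in viral genomes) mark regions of population-level
hypervariability: in viruses they are implicated in evading host defences,
and in microbes they are enriched for integration, recombination and
mobile-element functions. `crustvir` implements a complete, testable
workflow for this analysis as it is applied to glacier weathering-crust
communities: stringent read recruitment, island detection, island-gene
functional profiling, and the surrounding viral curation stages
(vOTU screening and retention, consensus taxonomy, host-association typing,
auxiliary metabolic gene (AMG) curation, TPM abundance).

## Coverage model and the two-regime island rule

Reads from all samples are pooled and recruited; alignments carrying two or
more mismatches (an NM-style edit count, so indels count as reported
upstream) are discarded, restricting coverage to near-identical population
members. Only primary alignments contribute, avoiding double counting, and
depth is the number of alignment intervals containing a base — only the
aligned reference span counts, never clipped bases. All coordinates are
0-based half-open internally; GFF3 is converted at ingestion and BED is
written natively.

Islands are called per genome against its length-weighted mean depth
$\bar d$ (total aligned bases over genome length):

* **Drop regime** ($\bar d \ge 5\times$): a maximal run of at least 100
  bases in which *every* base satisfies $d_i \le (1 - 0.25)\,\bar d$, i.e.
  coverage dropped by at least 25% relative to the genome mean. The
  boundary is inclusive.
* **Zero regime** ($2\times \le \bar d < 5\times$): a maximal run of at
  least 200 bases of exactly zero coverage.
* Below $2\times$ no calls are made — mean coverage that low cannot support
  a reliable under-recruitment signal.

Three choices here were genuinely open and are fixed as follows. First, the
qualifying predicate is evaluated *per base*, not as a windowed average:
a "continuous stretch" reading is deterministic, has exact maximality
properties (extending any island by one base violates the predicate or the
contig bound), and admits an exhaustive per-base oracle that the test suite
checks against on a thousand random tracks. Second, a mean of exactly
$5\times$ uses the drop rule (the regimes partition as $[5,\infty)$ and
$[2, 5)$). Third, islands separated by short above-threshold gaps are *not*
merged by default; a `merge_gap` parameter exists for users who want
bridging, but merging changes maximality semantics, so it is off.

Islands never span contig boundaries. Stretches touching a contig end are
reported with `at_contig_edge = TRUE` rather than dropped — edge coverage
decay is an assembly artefact the caller cannot distinguish from signal, so
flagging leaves the decision to the analyst (AMG curation, by contrast,
*does* exclude contig ends, see below).

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `max_mismatches` | 1 | edits/alignment | recruitment stringency |
| `drop_fraction` | 0.25 | fraction of mean | required relative coverage drop |
| `min_len_drop` | 100 | bases | minimum island length, drop regime |
| `min_len_zero` | 200 | bases | minimum island length, zero regime |
| `high_cov_threshold` | 5 | mean depth | drop regime applies at/above |
| `low_cov_threshold` | 2 | mean depth | no calls below |
| `merge_gap` | 0 | bases | gap bridging (off) |

## Island-gene profiling

A gene belongs to an island if it overlaps it by at least one base
("fully or partially contained", taken literally; no minimum fraction).
For eggNOG category profiles, a protein annotated with a multi-letter
category string such as `"EGP"` contributes one hit to *each* letter, and a
gene overlapping several islands is counted once (de-duplicated by protein
id). Categories under 2% relative abundance collapse into an `"Others"`
bucket. Whether category S (function unknown) belongs in the denominator is
ambiguous in practice, so both modes are provided (`exclude_S`); the default
keeps S. COG rankings count genes per COG, ties broken lexicographically so
output is deterministic.

## Viral curation rules

All thresholds are applied with literal boundary semantics (`>=` vs `>`
exactly as stated), and an absent tool score means "tool did not run",
never zero:

* **Candidate screening**: length $\ge$ 5,000 b and at least one of
  VirSorter2 $\ge 0.7$, DeepVirFinder $\ge 0.9$ with $P \le 0.05$,
  Seeker $\ge 0.9$, or a VIBRANT call.
* **vOTU retention**: length $\ge$ 5,000 b and (viral genes $\ge 1$, or no
  viral and no host genes, or no viral genes but VirSorter2 $\ge 0.95$ or
  more than two hallmark genes). The hallmark clause is allowed to fire
  even when host genes are present, matching the stated disjunction.
* **MAG tiers**: high = completeness $> 90$ and contamination $< 5$;
  medium = not high, completeness $\ge 50$ and contamination $< 10$; the
  tiers partition every record.
* **Lifestyle**: the larger of the virulent/temperate scores is called only
  at $\ge 0.80$; an exact tie is conservatively left unassigned.

## Consensus taxonomy

Four classifier streams are filtered at their own thresholds (bit-score
$\ge 50$ for protein and profile alignments, identity $> 90\%$ for gene
alignments, virus score $> 0.7$ for the composite classifier). A rank is
named only when every classifier that assigns a name there agrees;
classifiers that leave a rank absent abstain rather than veto. Ranks are
evaluated independently by default. Because an agreeing family under a
disagreeing class is then possible, an optional
`truncate_below_conflict` mode blanks all ranks below the first
disagreement; it is off by default since the plain rule is the literal
reading.

## Host associations and AMGs

Sequence-match evidence is filtered at 80% identity / 80% query coverage
for protein matches and 90/90 for gene and tRNA matches. Multi-hit
vOTU-MAG matches collapse to distinct pairs before counting. Association
specificity is typed per vOTU: `unique` (one MAG),
`multiple_family_consensus` (several MAGs sharing one named family), else
`multiple_class_or_higher`.

AMG calls from the two callers are *combined* — interpreted as a union with
callers recorded per call, since requiring both callers is available as an
explicit `combine = "intersection"` flag. Calls at vOTU ends are removed:
by default the first or last CDS of the contig, where prophage-boundary and
assembly artefacts concentrate; a `bp_buffer` mode (distance from the
terminus in bases) is available when gene coordinates are supplied.

## Abundance

TPM divides each feature's count by its length and scales per sample to
$10^6$, so columns are comparable across sequencing depths; genome-level
values pool member-contig counts over the full genome length rather than
averaging contig TPMs. Displayed abundances use $\log_{10}(\mathrm{TPM}+1)$.
By default counts include all mapped reads (the abundance stage sits
upstream of the island-specific mismatch filter).

## What the simulator emulates — and what it does not

`simulate_recruitment()` draws a genome set, plants non-overlapping
low-coverage islands (separated by at least 200 b from each other and from
contig ends, so maximal-run truth is unambiguous), and emits alignment
records. In `poisson` mode read starts follow a position-dependent Poisson
process whose rate is keyed on the read midpoint, so depth transitions are
centred on island edges and expected depth is uniform elsewhere (starts may
overhang contig ends and are clipped, avoiding artificial edge ramps). In
`tiling` mode alignments are constructed deterministically from the target
depth vector: depths are exact, mismatches zero, so boundary-exact recovery
can be asserted. Defaults encode the reference conditions used throughout
the tests: 20 genomes, 3 islands each at depth fraction 0.2 of a 20x
baseline, islands of 300-1,000 b, 100 b reads, 4 samples, and a mismatch
mass of (0.80, 0.15, 0.04, 0.01) over 0-3 edits so the filter keeps 95% of
reads.

`simulate_tables()` generates the downstream tables. Each classifier
follows the true lineage with probability `classifier_agreement` or else
one of two decoy lineages differing from the truth at every rank; the
choice is made per classifier (not per rank) so each call remains
prefix-consistent, and classifiers are independent — which makes the
probability that a rank is named exactly enumerable, the closed form the
acceptance checks compare against. Host links, AMG prevalence and the
temperate fraction default to proportions typical of a glacier-ice
metavirome (8.5%, 4.4% and 6.5% of vOTUs respectively); AMG tables include
planted end-located decoys so curation can be verified against truth.

The simulator does **not** emulate sequence content (reads are coordinate
intervals, not nucleotides), GC- or mappability-driven coverage bias,
within-classifier rank-specific error, chimeric contigs, or strain mixtures.
Passing the recovery tests therefore demonstrates the correctness of the
detection and decision logic under the stated statistical model — not
robustness to every bias of real recruitment data.

## Numerical and degenerate-input choices

Depth thresholds compare integer depths to the real number
$(1-f)\,\bar d$ with an inclusive boundary; no floating-point tolerance is
needed because depths are integers. Zero-length genomes, negative mismatch
counts, alignments beyond contig ends, unknown score kinds and duplicate
classifier calls raise classed errors rather than producing silent output.
Empty inputs return empty tibbles of the documented shape. All randomness
is seeded; `run_pipeline()` writes a manifest with per-stage record counts
and md5 checksums, and reruns with the same configuration are byte-identical.

## Problem sizes used in the tests

The oracle-equivalence suite uses 1,000 random tracks up to 10 kb across
all three coverage regimes; recovery tests use the default 20-genome
configuration (60 planted islands); consensus recovery uses 1,000 vOTUs;
TPM conservation uses 100 random count tables. These sizes give the
property checks comfortable statistical power while keeping a full test run
under a minute per suite.

## Interface note

The pipeline is orchestrated from R: `run_pipeline(pipeline_config(...))`
executes the stages in dependency order and records the manifest. The
package deliberately ships no shell wrapper — every stage is a data-frame
function, and scripted runs are a few lines of R (see the README's worked
example).

## Known limitations

* Island significance is structural (maximal runs under a threshold), not
  statistical; no smoothing or GC correction is applied.
* Consensus taxonomy does not reconcile conflicting parent/child ranks
  unless `truncate_below_conflict` is enabled.
* Host-predictor confidence filtering is assumed upstream; predictions are
  consumed as given.
* TPM uses all mapped reads; a mismatch-filtered abundance mode would
  require re-running the filter upstream of counting.
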