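# crustvir

Detection of **metagenomic and metaviromic islands** (MGIs/MVIs) and
virus–host profiling for environmental metagenomes, built around glacier
weathering-crust communities — the porous, water-filled surface ice layer
whose microbes and viruses are released downstream as glaciers retreat.

When environmental reads are recruited back onto metagenome-assembled
genomes (MAGs) or viral contigs (vOTUs), stretches that systematically
under-recruit mark population-level hypervariability: viral islands help
phages evade host defences; microbial islands concentrate integration,
recombination and mobile-element genes. `crustvir` implements the full
analysis as composable, pipe-friendly functions over data frames:

- **Recruitment coverage** — `filter_alignments()` (alignments with ≥ 2
  mismatches removed, primary only), `compute_coverage()` (per-base depth,
  bedGraph-style), `genome_mean_coverage()` (length-weighted mean d̄).
- **Island calling** — `detect_islands()` under the two-regime rule: for
  genomes with d̄ ≥ 5×, maximal runs of ≥ 100 bases where every base's
  depth ≤ (1 − 0.25) · d̄; for 2× ≤ d̄ < 5×, maximal zero-coverage runs of
  ≥ 200 bases; no calls below 2×.
- **Island-gene profiling** — `overlap_islands_with_cds()` (≥ 1 bp overlap),
  `summarize_categories()` (one hit per eggNOG category letter per protein,
  < 2% categories collapsed to "Others"), `top_cogs()`.
- **Viral QC** — `screen_candidates()`, `retain_votus()`, `tier_mags()`,
  `call_lifestyle()` with literal threshold boundaries.
- **Consensus taxonomy** — `filter_calls()` per classifier threshold and
  `consensus_taxonomy()`: a rank is named only if all assigning classifiers
  agree, otherwise "unclassified".
- **Virus–host links** — `filter_matches()` (blastp-style 80/80, blastn-style
  90/90), `classify_association()` / `association_spectrum()` (unique /
  family-consensus / class-or-higher), `curate_amgs()` (two-caller union,
  vOTU-end calls removed).
- **Abundance** — `tpm()` (counts normalised by length and depth so each
  sample sums to 10⁶) and `log_tpm()` for log10(TPM + 1).
- **Synthetic data & pipeline** — `simulate_recruitment()` /
  `simulate_tables()` generate seeded inputs with planted ground truth;
  `run_pipeline()` orchestrates all stages with a checksummed manifest.

## Worked example

Simulate recruitment at the package's reference conditions (20 genomes,
20× baseline, three planted islands each at 0.2× depth), then call and
profile islands:

```r
library(crustvir)
library(dplyr)

cfg <- sim_config(seed = 42)
rec <- simulate_recruitment(cfg)

cov <- rec$alignments |>
  filter_alignments(max_mismatches = 1) |>
  compute_coverage(rec$genomes)

genome_mean_coverage(cov, rec$genomes) |> head(3)
#>   genome_id genome_length mean_coverage
#> 1 g001              28752          17.8
#> 2 g002              19289          16.9
#> 3 g003              11251          16.4

islands <- detect_islands(cov, rec$genomes)
head(islands, 3)
#>   genome_id contig_id start   end regime genome_mean island_mean at_contig_edge
#> 1 g001      g001_c01   7614  7727 drop          17.8       11.1  FALSE
#> 2 g001      g001_c01   7982  8588 drop          17.8        5.97 FALSE
#> 3 g001      g001_c01   9361 10339 drop          17.8        3.20 FALSE
```

The genome means sit below the 20× baseline because the ≥ 2-mismatch filter
removes ~5% of reads and the planted islands depress the mean; all genomes
remain in the drop regime (≥ 5×), so islands are maximal runs at ≤ 75% of
each genome's mean. The second and third islands above recover two of the
planted truth intervals, `g001_c01:[7988, 8601)` and `[9373, 10320)`,
within a few tens of bases of read-length smoothing at the edges.

Downstream tables from the same seed feed the rest of the pipeline:

```r
tabs <- simulate_tables(cfg, recruitment = rec)

overlap_islands_with_cds(islands, tabs$tables$cds) |>
  summarize_categories() |> head(5)
#>   category count percent
#> 1 L           57   47.1      # replication, recombination and repair
#> 2 M           21   17.4      # cell wall / membrane / envelope biogenesis
#> 3 P           10    8.26
#> 4 S            9    7.44
#> 5 G            5    4.13

tabs$tables$classifier_calls |>
  filter_calls() |>
  consensus_taxonomy() |>
  classification_rates() |> head(3)
#>   rank    n_classified percent
#> 1 realm             13      65
#> 2 kingdom           13      65
#> 3 phylum            13      65

tpm(tabs$tables$counts) |>
  group_by(sample_id) |> summarise(total_tpm = sum(tpm)) |> head(2)
#>   sample_id total_tpm
#> 1 S1          1000000
#> 2 S2          1000000
```

Category L dominates island genes (the simulator biases island genes toward
integrases and transposases, mirroring the biology the caller targets);
65% of vOTU ranks reach consensus at a 0.9 classifier agreement over four
classifiers; and every sample's TPM column sums to one million. The whole
run end-to-end, with a reproducibility manifest:

```r
res <- run_pipeline(pipeline_config(sim = cfg, outdir = "run42"))
res$manifest
```

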