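# wobblebias

Codon-bias analysis of Elongator-dependent translation: the AA:AG
wobble-codon statistic, ORFeome scanning, transcriptome–proteome
integration, bias/length response profiling, and codon-biased biosensor
design.

## The problem

The Elongator complex (ELP1–6) is required for the mcm⁵s² modification of
the wobble uridine (U₃₄) of the tRNAs that read the A-ending codons for
lysine, glutamine and glutamate — **AAA**, **CAA**, **GAA**. When Elongator
is lost, translation of these *AA-ending* codons is impaired, while their
synonymous *AG-ending* counterparts (**AAG**, **CAG**, **GAG**) are read by
wobble pairing and, if anything, translated slightly faster without the
modification. A transcript's exposure to this defect is summarised by its

```
AA:AG ratio  =  #(AAA, CAA, GAA codons) / #(AAG, CAG, GAG codons)
```

A ratio of 1 is unbiased; mammalian ORFeomes lean AG (mean ratio ≈ 0.67 in
mouse). Protein-level consequences of Elongator loss scale with the
*product* of AA bias and transcript length: long, AA-biased transcripts
lose protein, while short, strongly AG-biased transcripts (e.g. H2A
histones) gain it — all at normal mRNA levels. `wobblebias` implements that
analysis as a reusable, tested pipeline for anyone studying U₃₄-modification
biology, codon-usage-dependent proteostasis, or synonymous-recoding
reporter design:

* **codon core** — CDS validation, frame-0 codon counting (stop included),
  the AA:AG statistic with explicit infinite/undefined sentinels;
* **ORFeome scan** — FASTA ingestion (consensus-CDS pipe headers), per-CDS
  bias tables, ratio histograms, summary means, rule-based prevalence scans
  (`stringent`: ≥ 1,755 codons & ratio > 1.3, or ≤ 150 codons & ratio < 0.3);
* **omics integration** — signed fold-change convention (x ≥ 1 up, −1/x
  down), detection filters in both genotypes and both assays, strict
  normal-transcription bound (|fc| < 1.5), protein classes
  DEPLETED (≤ −2) / NORMAL / UP (≥ 2);
* **bias response** — class percentages over (ratio, length) threshold
  grids, the AA-abundance control curve, and the `large-aa` (≥ 1,755
  codons, ratio > 1.3) and `small-ag` (≤ 150 codons, ratio < 0.2) candidate
  target filters;
* **sensor design** — synonymous recoding of all (or all-but-*k*) K/Q/E
  codons to AA or AG endings, with translation verification; the bundled
  240-codon AA-biased eGFP biosensor ships in `inst/extdata/`;
* **synthetic data** — a generator for ORFeomes and matched omics tables
  with known ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(wobblebias)

# the bundled AA-biased eGFP biosensor: 240 codons, all 44 K/Q/E codons AA-ending
egfp <- egfp_aa_sensor()
count_codons(egfp)
#> <BiasProfile: 240 codons, AA=44, AG=0, AA:AG=inf>

# derive the AG-biased sensor, keeping 2 of the 44 codons AA-ending
sensor <- recode(egfp, target = "AG", keep_opposite = 2)
sensor$report
#> <RecodeReport eGFP_AA -> AG-biased: 42 codon(s) changed; AA:AG inf -> 0.05>
verify_synonymous(egfp, sensor$cds)$synonymous
#> [1] TRUE

# a synthetic 2,000-gene study, integrated and profiled
cfg   <- generator_config(n_genes = 2000, seed = 17)
study <- gen_study(cfg, sequences = FALSE)
rows  <- merge_and_filter(study$rna, study$prot, study$manifest)
grid  <- threshold_grid(rows, ratio_thresholds = c(1.1, 1.5), ratio_dir = ">",
                        length_thresholds = c(505, 1755), length_dir = ">=")
format_bin_summary(grid)
#>   ratio_threshold ratio_dir length_threshold length_dir n_genes pct_depleted
#> 1             1.1         >              505         >=     118         33.1
#> 2             1.5         >              505         >=      76         44.7
#> 3             1.1         >             1755         >=      12         41.7
#> 4             1.5         >             1755         >=       6         83.3
#>   pct_normal pct_up low_count
#> 1       66.1    0.8     FALSE
#> 2       55.3    0.0     FALSE
#> 3       58.3    0.0     FALSE
#> 4       16.7    0.0     FALSE
```

Reading the grid: among normally transcribed genes with AA:AG ratio > 1.5,
the depleted fraction climbs from 44.7% of the 76 genes ≥ 505 codons to
83.3% of the 6 genes ≥ 1,755 codons — depletion intensifies with the
bias × length product, the pipeline's core readout. `low_count` marks cells
built from fewer than five proteins.

File-based runs (`run_pipeline()`, `run_simulation_pipeline()`) write every
table as TSV plus JSON summaries and a provenance `config.json`; a thin
command-line dispatcher over the same functions is at
`inst/cli/wobblebias.R`.

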