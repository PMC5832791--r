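---
title: "Methods: the AA:AG codon-bias pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AA:AG codon-bias pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wobblebias)
```

## The biological model

Lysine, glutamine and glutamate are each encoded by one A-ending codon
(AAA, CAA, GAA) and one G-ending codon (AAG, CAG, GAG). Both members of
each pair are read by a single tRNA with a uridine at position 34, the
wobble position. Efficient reading of the A-ending member requires the
mcm⁵s² modification of that uridine, which the six-subunit Elongator
complex installs. Ablating Elongator therefore slows decoding of AA-ending
codons, and — because the unmodified U₃₄ pairs somewhat better with G —
can mildly speed the AG-ending ones.

Whether a given protein is affected depends on how the transcript spends
its K/Q/E codon budget. The per-transcript statistic is the **AA:AG
ratio**, the count of AA-ending over AG-ending K/Q/E codons. Two regimes
matter:

* **large, AA-biased transcripts** (many codons, ratio well above 1)
  accumulate many slow codons per molecule and lose protein output;
* **small, AG-biased transcripts** (few codons, ratio near 0) benefit from
  the faster unmodified wobble reading and gain protein output.

Both effects are post-transcriptional: the analysis is conditioned
throughout on *normally transcribed* genes.

## The analysis pipeline

1. **Codon counting** (`validate_cds`, `count_codons`, `aa_ag_ratio`).
   Counting is mechanical in frame 0 and includes the stop codon in
   `total_codons`; no internal-stop or start check is made, since consensus
   CDS collections can carry annotation quirks the counter should not
   editorialize about. Codons containing N are excluded from all tallies
   and counted in `n_ambiguous`; a sequence whose ambiguous codons exceed
   10% is flagged rather than dropped, leaving the drop decision to the
   analyst.

2. **Ratio sentinels.** A CDS with AA-ending but no AG-ending codons has an
   *infinite* ratio (`Inf`): it is maximally AA-biased and deliberately
   satisfies every "ratio > t" predicate. A CDS with no K/Q/E codons at all
   has an *undefined* ratio (`NaN`): it carries no information about wobble
   bias, fails every ratio predicate, and is reported in its own overflow
   category. Ratios are kept at full precision internally; only
   presentation helpers (`format_ratio`, `format_bin_summary`) round —
   half-up, to 2 decimals for ratios and 1 for percentages, matching how
   such tables are conventionally printed.

3. **ORFeome scanning** (`read_cds_fasta`, `scan_orfeome`). Each CDS record
   is one analysis unit; `collapse = "longest"` keeps the longest CDS per
   gene symbol when a gene-level join is the goal. Pipe-delimited headers
   are split into id and gene symbol. Invalid records are skipped with a
   logged reason, not fatal: one malformed record should not kill a
   20,000-record scan.

4. **Omics integration** (`merge_and_filter`). Fold changes use the signed
   convention (x ≥ 1 means x-fold up, x ≤ −1 means |x|-fold down), so
   thresholds read the way they are usually quoted ("fold change ≤ −2").
   The filters, applied in order: present in both tables; detected in both
   genotypes in both assays (one-genotype genes are dropped, not imputed);
   signed transcript fold change *strictly* inside (−1.5, 1.5) — a gene at
   exactly 1.5 is excluded; bias profile available by upper-cased gene
   symbol. Duplicate transcript probes are averaged on the signed scale; a
   mean landing in the impossible (−1, 1) gap snaps to the nearest valid
   value (±1, "no change"). Duplicate proteome rows resolve to the entry
   with the most peptides, else the first as read. No alias or ortholog
   resolution is attempted; unmatched symbols are logged and dropped.

5. **Classification and response curves** (`classify_fc`,
   `threshold_grid`, `aa_abundance_curve`, `target_filter`). Protein
   classes are DEPLETED (≤ −2), UP (≥ 2), NORMAL (strictly between);
   boundaries are inclusive toward the extremes. Grid cells report class
   percentages with a `low_count` flag below five proteins (the
   dashed-line convention) and NA percentages for empty cells. Candidate
   filters use raw, unrounded ratios. The AA-abundance curve conditions on
   the raw AA-ending count irrespective of ratio; a flat curve is the
   control showing bias, not abundance, drives depletion.

6. **Sensor recoding** (`recode`, `verify_synonymous`). Only third
   positions of K/Q/E codons are rewritten (standard genetic code; the
   constructs are mammalian expression cassettes). `keep_opposite = k`
   leaves the first *k* K/Q/E codons — counted 5′→3′, a deterministic and
   reviewable choice — at the opposite ending, so exact splits such as
   2-of-44 are expressible. Recoding refuses sequences with an N in any
   codon that could resolve to a K/Q/E codon. `verify_synonymous` reports
   the first mismatch as a 1-based codon index, following R indexing.

## The synthetic-study generator

Real inputs to this analysis are a downloaded ORFeome and two published
differential-expression tables. The generator (`generator_config`,
`gen_orfeome`, `gen_omics`) stands in for them with a transparent
generative law so that every stage has testable ground truth.

Per gene: length L (non-stop codons) ~ lognormal, rounded, floored at 50;
K/Q/E codon count ~ Binomial(L, 0.16); a per-gene AA-ending fraction
p ~ Beta(a, b); AA-ending count ~ Binomial(K/Q/E count, p); codon
identities uniform within their class; remaining codons uniform over the 55
non-stop, non-K/Q/E codons; one terminal stop. Protein log2 fold change is

```
-beta_aa * max(0, log2 r) * min(L/1755, 1)
+ beta_ag * max(0, -log2 r) * min(150/L, 1) + Normal(0, sigma)
```

with r the pseudocount-smoothed ratio (aa + 0.5)/(ag + 0.5) — smoothing
keeps the covariate finite and saturating for genes with zero AA- or
AG-ending codons. Transcript log2 fold change is pure Normal(0, rna_sigma)
noise, matching the conditioning on normal transcription. Truth classes
are recorded from the noise-free effect at ±1 on the log2 scale. All draws
are deterministic under the seed, and every per-gene quantity is drawn
before any sequence is materialized, so manifests are identical with or
without sequence construction.

**Default calibration.** Lognormal meanlog = log(555) − 0.32, sdlog = 0.8:
mean total length ≈ 556 codons with ~3% of genes above 1,755 codons and
~11% below 150. Beta(2, 3.985): mean odds a/(b−1) = 0.67, mode below 1.
These choices pin the distribution's *tails*, not only its means: the
fraction of genes simultaneously long and AA-biased (ratio > 1.3 and
≥ 1,755 codons, ≈ 0.4%) and the stringent prevalence (≈ 3.9%) land close
to what mammalian ORFeome scans report, which matters because the
analysis interrogates exactly those joint-tail cells. The cost is a mean
AA-ending count of ~30 rather than the ~36 of a mouse ORFeome: with a
K/Q/E fraction of 0.16, no Beta can deliver a mean ratio of 0.67 and a
mean AA count of 36 simultaneously (Jensen's inequality forces the mean
odds above E[p]/(1−E[p])), and the ratio and tail anchors take priority.
Couplings beta_aa = beta_ag = 1.2 with sigma = 0.6 give non-degenerate
class proportions at n = 2,000; rna_sigma = 0.2 keeps ~95% of genes inside
the transcription filter; 5% of genes are flagged undetected in one
random assay/genotype to exercise the detection filters.

**What the generator does not emulate.** Genes are independent: no operon-
or family-level correlation (the real AG-biased histone cluster is a
family), no correlation between length and bias beyond the joint tails, no
GC-content or expression-level structure, and no measurement model for
either platform (probe effects, peptide sampling). The effect law is an
invention with the right monotonicities, not an estimate of the real
dose–response. Passing tests on synthetic data therefore demonstrate that
the pipeline's inferences are correct *for data with this structure* —
they do not validate the biological effect sizes.

## Numerical and design choices

* Infinite/undefined ratio handling is explicit (see above); TSV
  serialization writes `inf` and `NA` and round-trips exactly.
* Percentages and ratios are rounded half-up only at the presentation
  layer; all filters compare raw values.
* `threshold_grid` treats ratio bounds strictly (`>` / `<`) and length
  bounds inclusively (`>=` / `<=`), as the anchored cells are quoted.
* Default grids fix only the text-anchored thresholds
  (ratio > {0.5 … 1.5} × length ≥ {505, 1005, 1755}; ratio < {0.5 … 0.1} ×
  length ≤ {150, 300, 505}); both are configurable because the full panel
  of published curves is readable only from figures.
* Duplicate-id ORFeome input is an error rather than silently de-duplicated;
  duplicate gene symbols in the bias table are an error unless collapsed
  deliberately with `collapse = "longest"`.
* Test and example problem sizes — 2,000-gene studies, 20 seeds for the
  reproducibility check, 5,000 genes for coupling recovery, 1,000-case
  property suites — were chosen so the distributional checks have 3-SE
  resolution while the whole suite stays interactive.

## Known limitations

* Gene matching is by upper-cased symbol only; cross-species or alias
  mapping is out of scope and unmatched genes are dropped with a log line.
* The scanner counts CDS records mechanically: it does not detect
  pseudogenes, internal stops, or mis-annotated frames.
* Only the standard genetic code is supported.
* Statistical significance of trend curves is not computed — the response
  curves are descriptive, as is conventional for this analysis.
* The prevalence and target thresholds are biologically motivated
  conventions, not fitted quantities; sensitivity to them can be explored
  by passing custom rule sets.

```{r example}
# a compact end-to-end run on a small synthetic study
cfg <- generator_config(n_genes = 500, seed = 7)
study <- gen_study(cfg, sequences = FALSE)
rows <- merge_and_filter(study$rna, study$prot, study$manifest)
format_bin_summary(
  threshold_grid(rows, c(0.9, 1.3), ">", c(505, 1755), ">="))
```
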