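---
title: "Methods: window-based 5hmC analysis and its synthetic test world"
author: "hmeseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based 5hmC analysis and its synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

hMeDIP-seq recovers DNA fragments containing 5-hydroxymethylcytosine by
antibody capture; the data are fragment alignments, and the signal of
interest is fragment *density*, not base-resolution methylation calls.
`hmeseq` quantifies that density in fixed-width genome windows and builds
three layers of inference on top:

1. **Window tracks.** The genome is tiled into consecutive, disjoint 150 bp
   windows (the last window of a chromosome may be short). Each fragment is
   assigned to exactly one window — the one containing its midpoint
   `floor((start + end) / 2)` in 0-based coordinates — and raw counts are
   normalised to reads per million (rpm), so each sample's track sums to
   10⁶ and tracks are comparable across sequencing depths.
2. **Feature enrichment.** Windows are classified by overlap (≥ 1 bp) with
   gene bodies, promoters (the 1 kb strand-aware region upstream of the
   TSS), a symmetric TSS region (default 300 bp), supplied enhancers, and
   the intergenic complement. Classes are *not* mutually exclusive: real
   genomes overlap, and imposing a precedence hierarchy would be an
   arbitrary choice, so a window straddling a TSS legitimately carries
   promoter, gene-body and TSS labels at once. Enrichment per class is a
   two-sided Wilcoxon rank-sum test of the class's window values against
   intergenic windows.
3. **Gene-level differences.** The gene-body 5hmC score is the arithmetic
   mean rpm over the windows whose midpoint lies in the gene body. The
   group contrast `Δ5hmC = mean(score | HFD) − mean(score | CON)` (units:
   normalised reads per 150 bp window) is regressed on transcriptional
   change by ordinary least squares, and samples are stratified by
   hierarchical clustering of row-wise z-scores (Euclidean distance).

## Interpretation choices the source methods leave open

Several decisions were genuinely open and are therefore configuration
knobs, with the defaults below:

* **"Sliding windows" = disjoint tiles.** Window quantification uses
  non-overlapping consecutive tiles (step = width). Overlapping windows
  would count fragments more than once and break the exact conservation
  property (`sum(counts) + dropped = n reads`) that every run asserts; a
  histogram-bar rendering of per-window scores also implies disjoint bars.
  For this reason no step-smaller-than-width mode is offered: the width
  itself is the sensitivity knob. An any-overlap counting mode
  (`countReads(assign = "overlap")`) exists purely for comparison.
* **Midpoint assignment, not any-overlap.** One fragment, one window makes
  "normalised to total reads" exactly interpretable. The brute-force
  any-overlap alternative is available for comparison in the test oracles.
* **Normalisation scale.** "Normalised to total reads" is realised as reads
  per million, the conventional scale; the denominator is the number of
  fragments assigned to the grid, so the rpm total is exactly 10⁶ even when
  off-grid fragments are dropped (drops are recorded per sample).
* **Input libraries are not subtracted.** Paired 10% input libraries exist
  in this assay, but the window analysis here normalises to total reads
  only; input handling enters only through the qPCR percent-input formula.
* **Clustering linkage.** Only the distance (Euclidean) is stated upstream;
  complete linkage is the default of the standard R heatmap stack and is
  used here, exposed as a parameter.
* **Transcriptional-change axis.** Log2 fold change from the DE stage — the
  native effect size of that stage. Whether the top-10 induced/suppressed
  genes should be ranked by fold change or p-value is likewise unstated;
  `topGenes()` ranks by |log2FC| with adjusted-p and then lexicographic
  tie-breaks, documented and order-stable.
* **Moderated vs ordinary t-statistics.** The original microarray analysis
  used limma's empirical-Bayes moderation; that moderation is limma's
  contribution, not this analysis's. `differentialExpression()` uses the
  ordinary pooled-variance t-test with Benjamini–Hochberg adjustment and
  the stated dual decision rule (adjusted p < 0.05 *and* linear change
  > 10%, i.e. |log2FC| > log2(1.1) — the 10% threshold is read on the
  linear scale, where "percent change" lives).
* **Housekeeper aggregation.** qPCR expression is taken relative to the
  arithmetic mean of the two housekeeper Ct values, which equals the
  geometric mean of their abundances.
* **HOMA-IR units.** Insulin in mU/L and glucose in mmol/L with divisor
  22.5; the reader enforces unit-suffixed headers so a unit mismatch fails
  loudly rather than silently rescaling.

## The synthetic world

The generator's defaults are a desk-scale stand-in for the study design it
emulates, chosen once and not revisited:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 2 Mb | large enough for ~27k windows, small enough for seconds-per-run |
| genes | 300, lengths 1950–10050 bp | ~45% genic fraction, 13–67 windows per gene |
| groups | CON n = 2, HFD n = 4 | the hMeDIP-seq arm of the emulated design |
| reads/sample | 200,000 | scaled stand-in for ~30 M reads/sample |
| fragment length | Normal(275, 80) truncated to [100, 600] | sonication fragments of 100–600 bp, mean 250–300 |
| planted effects | 30 induced + 30 suppressed, &#124;log2FC&#124; ~ U(0.5, 2) | clear effects (≥ 41% change) against a 240-gene null background |
| expression | baseline N(8, 1.5²), noise sd 0.2 log2 units | typical microarray intensity scale and replicate noise |
| coupling slope | 6 rpm/window per unit log2FC | gives per-gene Δ5hmC of ~3–12 rpm against a within-group score SD of ~3 rpm: detectable but not trivial |
| background | 20 rpm/window everywhere; gene enrichment calibrated | gene-body windows average ~57 rpm vs ~20 intergenic (~2.9×), enhancers ~50 |

Key construction details:

* **Exactness by design.** Gene and enhancer coordinates snap to the 150 bp
  grid, and fragments are placed by midpoint then extended symmetrically —
  together these make the expected rpm of every gene-body window an exact
  closed form (background + gene rate), so slope recovery is a sharp test
  rather than an approximate one.
* **Calibration before coupling.** Baseline (CON) intensities are scaled
  once so the genome total is exactly 10⁶ rpm-units; the HFD shift
  (slope × log2FC per planted gene) is added *after* calibration. HFD
  totals then deviate from 10⁶ by ~0.2%, an attenuation far below the
  slope's sampling error.
* **Seeding.** One master seed drives everything; each sample's fragments
  use `seed + sample index`, so adding a sample never changes existing
  ones. Identical seed and configuration give byte-identical output files.
* **Parameter recovery uses the truth table.** The slope-recovery check
  regresses Δ5hmC on the *planted* log2FC. Regressing on the DE-estimated
  log2FC instead attenuates the slope (errors-in-variables) by ~8% at the
  n = 2 vs 4 design — a property of noisy regressors, not of the pipeline —
  which is why the truth file is written alongside every simulated dataset.

What the generator does **not** emulate — and hence what a green test does
not establish: no sequence content (no FASTA, no GC or mappability bias),
no duplicate fragments, no TSS depletion or promoter-specific 5hmC
structure (gene bodies are uniformly enriched, so the metagene profile is a
plateau rather than the 5′-skewed curves of real livers), no input-library
noise, and no inter-animal biological variability beyond sampling noise.
Tests on this world validate the *statistical machinery and its wiring*,
not biological discovery performance on real data.

## Numerical notes

* The rank-sum test enumerates all `choose(n+m, n)` assignments (midranks,
  so ties are handled exactly) when both groups have ≤ 8 values; larger
  groups use the normal approximation with tie correction and a 0.5
  continuity correction. Two-sided p doubles the smaller tail, capped at 1.
* Degenerate inputs fail loudly: empty samples (0 reads), zero-variance
  regressors, all-zero-variance z-score matrices, out-of-range NAS
  components, non-positive HOMA-IR inputs, genes beyond chromosome bounds.
  A one-way ANOVA on completely constant data returns F = 0 and p = 1
  rather than a 0/0 artefact.
* Genes without any window midpoint (shorter than one window and unluckily
  placed) are excluded from gene-body scores with a message; zero-variance
  z-score rows are dropped and recorded in the `ClusterResult`.
* Cluster agreement uses the adjusted Rand index; two identical trivial
  partitions score 1 by convention.
* All tabular output serialises floats at 6 significant digits; reruns
  under the same seed are bit-identical.

## Limitations

Beyond the generator's simplifications above: the pipeline consumes
alignments as BED intervals (duplicate removal and quality filtering are
assumed upstream); enhancers are consumed as a ready interval set, never
called from histone data; window-level differential testing with
genome-wide FDR is deliberately out of scope (the analysis works at gene
level); and the ordinary t-test will be conservative relative to moderated
statistics at very small n.
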