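# hmeseq

Window-based analysis of hepatic 5-hydroxymethylcytosine (5hmC) from
hMeDIP-seq fragment alignments, for studies of diet-induced obesity and
non-alcoholic fatty liver disease (NAFLD) in mouse models — and, more
generally, for any design that compares immunoprecipitation-based 5hmC
profiles between sample groups and asks whether the changes track
transcription.

## What it computes

5hmC is enriched over the bodies of expressed genes and tissue enhancers, so
hMeDIP-seq signal is informative about transcriptional state. The package
implements the full analysis chain:

1. **Window quantification.** The genome is tiled into fixed 150 bp windows;
   each aligned fragment is assigned to the single window containing its
   midpoint `floor((start + end)/2)`, and counts are normalised to total
   reads on a reads-per-million (rpm) scale, so every sample track sums to
   10⁶. Conservation (`sum(counts) + dropped = n reads`) is asserted on
   every run.
2. **Feature enrichment.** Windows are classified by genomic feature
   (gene body; promoter = 1 kb upstream of the TSS, strand-aware; a
   symmetric TSS region; enhancers from a supplied BED; intergenic
   complement) and each class is compared against intergenic windows with a
   two-sided Wilcoxon rank-sum test (exact enumeration for group sizes ≤ 8,
   normal approximation with tie correction otherwise).
3. **Metagene profile.** Mean rpm over all genes with fixed 150 bp flank
   bins and 40 length-scaled gene-body bins, minus-strand genes reversed.
4. **Differential expression.** Pooled-variance t-tests per gene on a log2
   expression matrix with Benjamini–Hochberg adjustment and the dual
   decision rule: adjusted p < 0.05 **and** linear fold change > 10%.
5. **Gene-body Δ5hmC.** Per gene, the score is the mean rpm over the
   windows whose midpoint lies in the gene body;
   `Δ5hmC = mean(score | HFD) − mean(score | CON)` (normalised reads per
   150 bp window). Δ5hmC is regressed on transcriptional change (OLS, slope
   t-test), and samples are stratified by row-wise z-scores with Euclidean /
   complete-linkage hierarchical clustering on all genes and on the top-10
   induced / suppressed genes, scored by adjusted Rand index (ARI) against
   the declared diet groups.
6. **qPCR and phenotypes.** hMeDIP-qPCR percent input
   `100·2^((Ct_input − log2(1/f)) − Ct_IP)` with fold change vs CON and
   one-way ANOVA + Tukey HSD; expression qPCR relative to the mean of two
   housekeepers; HOMA-IR = insulin × glucose / 22.5; the NAFLD activity
   score (steatosis 0–3 + lobular inflammation 0–3 + ballooning 0–2).

A seeded synthetic-data generator (`simConfig()`, `simulateStudy()`) stands
in for deposited sequencing data: it plants induced/suppressed genes with
known log2 fold changes and couples gene-body 5hmC to them with a known
slope (default 6 rpm/window per unit log2FC), recording the ground truth so
recovery can be tested.

## Worked example

```r
library(hmeseq)

cfg <- simConfig(seed = 7)            # CON n=2 vs HFD n=4, 200k reads/sample
st  <- simulateStudy(cfg)             # genes, reads, expression, truth
grid <- buildWindowGrid(st$chromSizes)            # 150 bp tiling
hx   <- countWindows(grid, st$reads, st$samples)  # HmcExperiment
fs   <- deriveFeatures(st$genes, st$enhancers, st$chromSizes)
enr  <- featureEnrichment(hx, annotateWindows(grid, fs))
subset(enr, unit == "CON", select = c(class, mean_rpm, p))
#>        class mean_rpm             p
#>    gene_body 57.02708  0.000000e+00
#>     promoter 20.48348  3.634037e-02
#>          tss 42.58000 3.083880e-167
#>     enhancer 50.81019  0.000000e+00
#>   intergenic 19.92414            NA
```

Gene bodies carry ~2.9× the intergenic 5hmC density (57 vs 20 rpm/window,
rank-sum p below machine precision), enhancers ~2.5× — the expected
enrichment hierarchy. Continuing:

```r
sc  <- geneBodyScores(hx, st$genes)
m   <- merge(delta5hmc(sc, st$samples, "HFD", "CON"), st$truth, by = "gene_id")
fit <- regressDeltaExpression(m, x = "true_log2fc")
c(slope = fit$slope, se = fit$slope_se, r2 = fit$r_squared)
#>     slope        se        r2
#> 6.1235270 0.2534898 0.6619612
top <- m$gene_id[order(-m$true_log2fc)][1:10]
clusterARI(zscoreCluster(sc, st$samples, top, k = 2))
#> [1] 1
```

The fitted Δ5hmC-per-log2FC slope (6.12 ± 0.25) recovers the planted
coupling (6), and clustering the top-10 induced genes separates the diet
groups perfectly (ARI = 1) even though all-genes clustering need not — the
stratification contrast at the heart of the analysis.

`runPipeline(validateConfig("inst/extdata/demo_config.txt"))` runs every
stage end-to-end and writes tracks, tables, dendrograms and a manifest;
`inst/scripts/run_pipeline.R` wraps it for the shell.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch at the default design under the given
seed (simulation, quantification, annotation, profiles, differential
expression, Δ5hmC regression and clustering) and writes the JSON report to
`--out`. The accompanying property-based checks — counting oracle, read
conservation, exact rank-sum enumeration, Benjamini–Hochberg step-up,
enrichment / slope-recovery / stratification Monte-Carlo, DE recall and
type-I error, deterministic formula identities, end-to-end reproducibility —
live in `tests/testthat/test-acceptance.R`.
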