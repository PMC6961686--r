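## Seeded synthetic hMeDIP-seq study generator. Emulates the structure the
## analysis exploits: grouped samples (CON/HFD and reversal arms), 100-600 bp
## sonication fragments enriched over the bodies of expressed genes and over
## enhancers, an expression matrix with planted induced/suppressed genes, and
## 5hmC gain/loss coupled to the planted log2FC in HFD samples. Ground truth
## (which genes, what effects, the coupling slope) is recorded for recovery
## tests.
##
## Rate model, in normalised-reads-per-window (rpm) units:
##   every window:   backgroundRate
##   gene windows:  + kappa * max(eps, geneRateBase
##                                + geneRateExprCoef * (baseline - mean))
##   enhancers:     + enhancerRate
## kappa is calibrated once so the CON genome total is exactly 1e6; the HFD
## coupling shift (hmcCouplingSlope * log2FC) is added AFTER calibration, so
## the planted slope is exact in rpm units. Fragments are placed by midpoint
## (uniform within their component) and extended symmetrically, matching the
## midpoint counting rule, so expected window counts are analytic.

#' Simulate a toy genome: gene models and enhancers
#'
#' Genes are placed non-overlapping with both strands represented, separated
#' by intergenic gaps; enhancers sit intergenically between genes. With the
#' default `snapBp = 150`, gene and enhancer coordinates are multiples of
#' the window width, so gene bodies tile exactly onto windows.
#'
#' @param config a [SimConfig-class].
#' @return list with `genes` (stranded `GRanges`, `gene_id` column),
#'   `enhancers` (`GRanges`) and `chromSizes`.
#' @export
simulateGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  snap <- max(1L, config@snapBp)
  chromSizes <- setNames(rep(config@chromLength, config@nChroms),
                         sprintf("chr%d", seq_len(config@nChroms)))
  perChrom <- diff(round(seq(0, config@nGenes,
                             length.out = config@nChroms + 1)))
  # gaps leave room for promoters and an intergenic enhancer with margins
  minGap <- max(6L * snap, config@enhancerWidth + 4L * snap)
  glr <- config@geneLengthRange

  genesL <- list()
  enhL <- list()
  nEnh <- round(config@enhancerFraction * config@nGenes)
  enhPerChrom <- diff(round(seq(0, nEnh, length.out = config@nChroms + 1)))
  for (ci in seq_len(config@nChroms)) {
    nG <- perChrom[ci]
    if (nG == 0) next
    len <- round(runif(nG, glr[1], glr[2]) / snap) * snap
    len <- pmax(snap, len)
    slack <- chromSizes[ci] - sum(len) - (nG + 1) * minGap
    if (slack < 0)
      stop("infeasible gene packing on ", names(chromSizes)[ci],
           ": increase chromLength (need >= ",
           sum(len) + (nG + 1) * minGap, " bp)")
    cuts <- runif(nG + 1); cuts <- cuts / sum(cuts)
    extra <- floor(cuts * slack / snap) * snap
    gaps <- minGap + extra                    # gap i precedes gene i
    starts0 <- cumsum(gaps[seq_len(nG)]) +
      cumsum(c(0, len[-nG]))                  # 0-based, snap multiples
    strandV <- rep_len(c("+", "-"), nG)[sample.int(nG)]
    genesL[[ci]] <- GRanges(names(chromSizes)[ci],
                            IRanges(start = starts0 + 1, width = len),
                            strand = strandV)
    if (enhPerChrom[ci] > 0) {
      gapIdx <- sort(sample.int(nG - 1, min(enhPerChrom[ci], nG - 1)))
      gapLo0 <- starts0[gapIdx] + len[gapIdx]          # end of gene i
      gapHi0 <- starts0[gapIdx + 1]                    # start of gene i+1
      eStart0 <- floor(((gapLo0 + gapHi0) / 2 -
                          config@enhancerWidth / 2) / snap) * snap
      eStart0 <- pmax(eStart0, gapLo0 + snap)
      eStart0 <- pmin(eStart0, gapHi0 - config@enhancerWidth - snap)
      enhL[[ci]] <- GRanges(names(chromSizes)[ci],
                            IRanges(start = eStart0 + 1,
                                    width = config@enhancerWidth))
    }
  }
  genes <- sort(suppressWarnings(do.call(c, genesL)), ignore.strand = TRUE)
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
  names(genes) <- genes$gene_id
  enhancers <- if (length(enhL)) sort(suppressWarnings(do.call(c, enhL)))
               else GRanges()
  stopifnot(!any(countOverlaps(genes, genes, ignore.strand = TRUE) > 1))
  list(genes = genes, enhancers = enhancers, chromSizes = chromSizes)
}

#' Simulate a log2 expression matrix with planted effects
#'
#' Baseline log2 intensities are Normal(`exprBaselineMean`,
#' `exprBaselineSd`^2) per gene. In HFD samples, planted induced genes gain
#' and suppressed genes lose their |log2FC| (drawn uniformly from
#' `exprLog2fcRange`); reversal groups revert to baseline. Per-sample noise
#' is Normal(0, `exprNoiseSd`^2).
#'
#' @param config a [SimConfig-class].
#' @param genes gene `GRanges` from [simulateGenome()].
#' @param groups optional named group sizes overriding `config@groups`
#'   (e.g. the microarray arm CON = 4, HFD = 8).
#' @return list with `matrix` (genes x samples, log2), `samples`
#'   (data.frame sample_id, group) and `truth` (data.frame gene_id, status,
#'   true_log2fc, true_delta_5hmc, plus `coupling_slope` attribute).
#' @export
simulateExpression <- function(config, genes, groups = config@groups) {
  validObject(config)
  if (!"CON" %in% names(groups) || !"HFD" %in% names(groups))
    stop("groups must include CON (reference) and HFD (perturbed)")
  nG <- length(genes)
  if (config@nInduced + config@nSuppressed > nG)
    stop("more planted genes than genes")
  set.seed(config@seed + 500003L)
  baseline <- rnorm(nG, config@exprBaselineMean, config@exprBaselineSd)
  pick <- sample.int(nG, config@nInduced + config@nSuppressed)
  induced <- sort(pick[seq_len(config@nInduced)])
  suppressed <- sort(pick[config@nInduced + seq_len(config@nSuppressed)])
  fc <- numeric(nG)
  fc[induced] <- runif(config@nInduced, config@exprLog2fcRange[1],
                       config@exprLog2fcRange[2])
  fc[suppressed] <- -runif(config@nSuppressed, config@exprLog2fcRange[1],
                           config@exprLog2fcRange[2])
  sampleIds <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%d", g, seq_len(groups[[g]]))), use.names = FALSE)
  groupOf <- rep(names(groups), unname(groups))
  mat <- matrix(baseline, nrow = nG, ncol = length(sampleIds),
                dimnames = list(genes$gene_id, sampleIds))
  hfd <- groupOf == "HFD"  # reversal arms revert to baseline
  mat[, hfd] <- mat[, hfd] + fc
  mat <- mat + matrix(rnorm(length(mat), 0, config@exprNoiseSd),
                      nrow = nG)
  status <- rep("null", nG)
  status[induced] <- "induced"; status[suppressed] <- "suppressed"
  truth <- data.frame(gene_id = genes$gene_id, status = status,
                      true_log2fc = fc,
                      true_delta_5hmc = config@hmcCouplingSlope * fc,
                      baseline_log2_expr = baseline)
  attr(truth, "coupling_slope") <- config@hmcCouplingSlope
  list(matrix = mat,
       samples = data.frame(sample_id = sampleIds, group = groupOf),
       truth = truth)
}

## Per-window-equivalent rate components for one sample (rpm units).
## Returns weights per component and the component geometry.
sample_rate_components <- function(config, genes, enhancers, chromSizes,
                                   truth, group) {
  w <- 150  # rpm units are per 150 bp window-equivalent
  nWinTotal <- sum(ceiling(chromSizes / w))
  eps <- 0.5
  geneBase <- pmax(eps, config@geneRateBase + config@geneRateExprCoef *
                     (truth$baseline_log2_expr - config@exprBaselineMean))
  geneWinEq <- width(genes) / w
  enhWinEq <- if (length(enhancers)) width(enhancers) / w else numeric()
  bgMass <- config@backgroundRate * nWinTotal
  enhMass <- config@enhancerRate * sum(enhWinEq)
  geneMassTarget <- 1e6 - bgMass - enhMass
  if (geneMassTarget <= 0)
    stop("backgroundRate/enhancerRate leave no budget for gene enrichment")
  kappa <- geneMassTarget / sum(geneBase * geneWinEq)
  geneRate <- kappa * geneBase
  if (group %in% c("HFD")) {
    geneRate <- geneRate + config@hmcCouplingSlope * truth$true_log2fc
    if (any(geneRate < 0)) {
      warning(sum(geneRate < 0), " gene rate(s) clipped at 0")
      geneRate <- pmax(0, geneRate)
    }
  }
  list(bgMass = bgMass,
       geneMass = geneRate * geneWinEq,
       enhMass = if (length(enhancers)) config@enhancerRate * enhWinEq
                 else numeric(),
       geneRate = geneRate)
}

#' Simulate hMeDIP fragment alignments for one sample
#'
#' Fragment midpoints are drawn from a mixture of a genome-wide uniform
#' background plus per-gene-body rates increasing with baseline expression;
#' in HFD samples the gene rate additionally shifts by
#' `hmcCouplingSlope * log2FC` (gain at induced, loss at suppressed genes).
#' Fragment lengths are Normal(`fragMean`, `fragSd`) truncated to
#' `fragBounds`; fragments are extended symmetrically around their midpoint
#' and shifted inside chromosome bounds if needed.
#'
#' @param config a [SimConfig-class].
#' @param genes,enhancers,chromSizes from [simulateGenome()].
#' @param truth truth table from [simulateExpression()].
#' @param group diet group of the sample ("CON", "HFD", or a reversal arm;
#'   only HFD carries the coupling shift).
#' @param sampleIndex integer; the sample's seed is `config@seed + sampleIndex`,
#'   so adding a sample never perturbs existing ones.
#' @return `GRanges` of exactly `readsPerSample` fragments.
#' @export
simulateHmedipReads <- function(config, genes, enhancers, chromSizes, truth,
                                group, sampleIndex) {
  validObject(config)
  set.seed(config@seed + as.integer(sampleIndex))
  comp <- sample_rate_components(config, genes, enhancers, chromSizes,
                                 truth, group)
  masses <- c(comp$bgMass, comp$geneMass, comp$enhMass)
  nComp <- length(masses)
  nReads <- config@readsPerSample
  counts <- as.vector(rmultinom(1, nReads, masses / sum(masses)))

  chromNames <- names(chromSizes)
  cumLen <- c(0, cumsum(chromSizes))
  genomeLen <- cumLen[length(cumLen)]

  mid0 <- numeric(nReads)
  chromV <- character(nReads)
  pos <- 1L
  ## background: uniform over the concatenated genome
  if (counts[1] > 0) {
    g <- floor(runif(counts[1], 0, genomeLen))
    ci <- findInterval(g, cumLen, rightmost.closed = TRUE)
    mid0[pos:(pos + counts[1] - 1)] <- g - cumLen[ci]
    chromV[pos:(pos + counts[1] - 1)] <- chromNames[ci]
    pos <- pos + counts[1]
  }
  ## genic + enhancer: uniform within the owning region
  regions <- c(granges(genes), granges(enhancers))
  regionCounts <- counts[-1]
  if (sum(regionCounts) > 0) {
    ri <- rep.int(seq_along(regionCounts), regionCounts)
    off <- floor(runif(length(ri)) * width(regions)[ri])
    mid0[pos:nReads] <- (start(regions)[ri] - 1) + off
    chromV[pos:nReads] <- as.character(seqnames(regions))[ri]
  }
  len <- round(rnorm_trunc(nReads, config@fragMean, config@fragSd,
                           config@fragBounds[1], config@fragBounds[2]))
  start0 <- mid0 - floor(len / 2)
  end0 <- start0 + len
  ## shift fragments overhanging a chromosome edge back inside
  maxEnd <- chromSizes[chromV]
  shift <- pmax(0, -start0) - pmax(0, end0 - maxEnd)
  start0 <- start0 + shift
  end0 <- end0 + shift
  ord <- sample.int(nReads)  # shuffle so file order carries no signal
  bed0_to_granges(chromV[ord], start0[ord], end0[ord])
}

#' Simulate a phenotype table
#'
#' HFD animals show fasting hyperglycaemia, hyperinsulinaemia and steatosis
#' scores in \{2, 3\}; CON (and reversal) animals score \{0, 1\}. Lobular
#' inflammation and hepatocyte ballooning are always 0 (no steatohepatitis
#' features), so total NAS equals the steatosis score; fibrosis stage is 0.
#'
#' @param config a [SimConfig-class].
#' @param samples data.frame with `sample_id`, `group`.
#' @return data.frame with glucose (mmol/L), insulin (mU/L), HOMA-IR and NAS
#'   components.
#' @export
simulatePhenotypes <- function(config, samples) {
  set.seed(config@seed + 600007L)
  n <- nrow(samples)
  hfd <- samples$group == "HFD"
  glucose <- ifelse(hfd, rnorm(n, 12.5, 1.2), rnorm(n, 8.5, 0.8))
  glucose <- pmax(3, glucose)
  insulin <- ifelse(hfd, rnorm(n, 18, 3), rnorm(n, 6, 1.5))
  insulin <- pmax(1, insulin)
  steatosis <- ifelse(hfd, 2L + rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))
  df <- data.frame(animal_id = samples$sample_id, group = samples$group,
                   glucose_mmol_l = glucose, insulin_mu_l = insulin,
                   steatosis = steatosis, lobular_inflammation = 0L,
                   ballooning = 0L, fibrosis_stage = 0L)
  df$homa_ir <- homaIr(df$insulin_mu_l, df$glucose_mmol_l)
  df$nas_total <- nasTotal(df$steatosis, df$lobular_inflammation,
                           df$ballooning)
  df
}

#' Simulate a complete study (and optionally write it to disk)
#'
#' Runs [simulateGenome()], [simulateExpression()],
#' [simulateHmedipReads()] per sample and [simulatePhenotypes()] under a
#' single master seed. With `dir` set, writes reads as per-sample BED3,
#' genes as BED6, enhancers as BED3, expression/phenotypes/truth/sample
#' sheet as TSV and a `config.txt` echo, and records every file in the
#' returned manifest. Identical seed + config reproduce byte-identical
#' outputs.
#'
#' @param config a [SimConfig-class].
#' @param dir optional output directory.
#' @return list: `genes`, `enhancers`, `chromSizes`, `expression`,
#'   `samples`, `truth`, `reads` (named list of `GRanges`), `phenotypes`,
#'   and `files` (manifest, when `dir` given).
#' @export
simulateStudy <- function(config, dir = NULL) {
  validObject(config)
  gen <- simulateGenome(config)
  expr <- simulateExpression(config, gen$genes)
  reads <- lapply(seq_len(nrow(expr$samples)), function(i)
    simulateHmedipReads(config, gen$genes, gen$enhancers, gen$chromSizes,
                        expr$truth, expr$samples$group[i], i))
  names(reads) <- expr$samples$sample_id
  pheno <- simulatePhenotypes(config, expr$samples)
  out <- list(genes = gen$genes, enhancers = gen$enhancers,
              chromSizes = gen$chromSizes, expression = expr$matrix,
              samples = expr$samples, truth = expr$truth, reads = reads,
              phenotypes = pheno)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(genes = file.path(dir, "genes.bed"),
               enhancers = file.path(dir, "enhancers.bed"),
               expression = file.path(dir, "expression.tsv"),
               truth = file.path(dir, "truth.tsv"),
               samples = file.path(dir, "samples.tsv"),
               phenotypes = file.path(dir, "phenotypes.tsv"),
               config = file.path(dir, "config.txt"))
    writeBed(gen$genes, files["genes"], strandCol = TRUE)
    writeBed(gen$enhancers, files["enhancers"])
    writeTable(data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                          check.names = FALSE), files["expression"])
    writeTable(expr$truth, files["truth"])
    samp <- expr$samples
    samp$reads_path <- paste0(samp$sample_id, ".bed")  # relative to sheet
    writeTable(samp, files["samples"])
    writeTable(pheno, files["phenotypes"])
    for (i in seq_len(nrow(samp)))
      writeBed(reads[[samp$sample_id[i]]],
               file.path(dir, samp$reads_path[i]))
    samp$reads_path <- file.path(dir, samp$reads_path)
    writeLines(configEcho(config), files["config"])
    out$files <- c(files, setNames(samp$reads_path,
                                   paste0("reads_", samp$sample_id)))
    out$samples <- samp
  }
  out
}

## key: value echo of a SimConfig (round-trippable documentation of the run)
configEcho <- function(config) {
  sl <- slotNames(config)
  vapply(sl, function(s) {
    v <- slot(config, s)
    paste0(s, ": ", paste(if (!is.null(names(v)))
      paste(names(v), v, sep = "=") else v, collapse = ","))
  }, character(1))
}
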