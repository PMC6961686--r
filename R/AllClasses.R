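#' @include hmeseq-package.R
NULL

VALID_GROUPS <- c("CON", "HFD", "HFD-reversal", "CON-reversal")
FEATURE_CLASSES <- c("gene_body", "promoter", "tss", "enhancer", "intergenic")

#' Simulation configuration for a synthetic hMeDIP-seq study
#'
#' Holds every parameter of the synthetic-data generator: toy genome
#' geometry, diet-group design, fragment model, planted expression effects
#' and the 5hmC/expression coupling. Defaults are a desk-scale stand-in for
#' the original study design (hMeDIP-seq in CON n = 2 vs HFD n = 4 mice,
#' ~30 M reads scaled down to 200,000 per sample, sonication fragments of
#' 100-600 bp with mean 250-300 bp).
#'
#' @slot seed integer master seed; per-sample read seeds are `seed + index`.
#' @slot nChroms,chromLength genome geometry (chromosomes x bp each).
#' @slot nGenes number of non-overlapping genes to place.
#' @slot geneLengthRange min/max gene length in bp.
#' @slot snapBp gene and enhancer coordinates are snapped to multiples of
#'   this (default 150, the window width) so expected per-window rates are
#'   analytically exact.
#' @slot groups named integer vector of group sizes; names from
#'   CON, HFD, HFD-reversal, CON-reversal.
#' @slot readsPerSample fragments simulated per sample.
#' @slot fragMean,fragSd,fragBounds fragment-length model: Normal truncated
#'   to `fragBounds` (default mean 275, sd 80, bounds 100-600 bp).
#' @slot nInduced,nSuppressed number of genes planted with expression gain /
#'   loss in HFD.
#' @slot exprLog2fcRange planted |log2 fold change| drawn uniformly from
#'   this range.
#' @slot exprBaselineMean,exprBaselineSd baseline log2 intensity
#'   distribution across genes.
#' @slot exprNoiseSd per-sample log2 measurement noise sd.
#' @slot hmcCouplingSlope change in normalised reads per 150 bp window per
#'   unit log2FC, applied to HFD samples at planted genes.
#' @slot backgroundRate genome-wide background, normalised reads (rpm) per
#'   150 bp window.
#' @slot geneRateBase,geneRateExprCoef baseline gene-body enrichment (rpm per
#'   window, before calibration) and its dependence on baseline expression.
#' @slot enhancerFraction number of enhancers as a fraction of `nGenes`.
#' @slot enhancerWidth,enhancerRate enhancer geometry (bp) and enrichment
#'   (rpm per window).
#' @export
setClass("SimConfig",
  representation(
    seed = "integer", nChroms = "integer", chromLength = "numeric",
    nGenes = "integer", geneLengthRange = "numeric", snapBp = "integer",
    groups = "integer", readsPerSample = "integer",
    fragMean = "numeric", fragSd = "numeric", fragBounds = "numeric",
    nInduced = "integer", nSuppressed = "integer",
    exprLog2fcRange = "numeric", exprBaselineMean = "numeric",
    exprBaselineSd = "numeric", exprNoiseSd = "numeric",
    hmcCouplingSlope = "numeric", backgroundRate = "numeric",
    geneRateBase = "numeric", geneRateExprCoef = "numeric",
    enhancerFraction = "numeric", enhancerWidth = "integer",
    enhancerRate = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@groups) < 1 || is.null(names(object@groups)))
    msg <- c(msg, "groups must be a named integer vector")
  bad <- setdiff(names(object@groups), VALID_GROUPS)
  if (length(bad))
    msg <- c(msg, paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  if (any(object@groups < 2))
    msg <- c(msg, "every group needs >= 2 samples")
  if (object@nInduced + object@nSuppressed >= object@nGenes)
    msg <- c(msg, "nInduced + nSuppressed must be < nGenes")
  fb <- object@fragBounds
  if (length(fb) != 2 || fb[1] >= fb[2] || fb[1] <= 0)
    msg <- c(msg, "fragBounds must be an increasing positive pair")
  if (object@fragMean < fb[1] || object@fragMean > fb[2])
    msg <- c(msg, "fragMean must lie within fragBounds")
  glr <- object@geneLengthRange
  if (length(glr) != 2 || glr[1] > glr[2] || glr[1] < 1)
    msg <- c(msg, "geneLengthRange must be a non-decreasing positive pair")
  if (object@seed >= 2^31 - object@readsPerSample)
    msg <- c(msg, "seed too large for 32-bit derived seeds")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param seed integer master seed.
#' @param nChroms,chromLength,nGenes,geneLengthRange,snapBp genome geometry.
#' @param groups named integer vector of samples per diet group.
#' @param readsPerSample,fragMean,fragSd,fragBounds fragment model.
#' @param nInduced,nSuppressed,exprLog2fcRange planted expression effects.
#' @param exprBaselineMean,exprBaselineSd,exprNoiseSd expression model.
#' @param hmcCouplingSlope rpm-per-window change per unit log2FC in HFD.
#' @param backgroundRate,geneRateBase,geneRateExprCoef 5hmC rate model
#'   (rpm per 150 bp window).
#' @param enhancerFraction,enhancerWidth,enhancerRate enhancer model.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 50L, chromLength = 5e5)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L, chromLength = 2e6,
                      nGenes = 300L, geneLengthRange = c(1950, 10050),
                      snapBp = 150L,
                      groups = c(CON = 2L, HFD = 4L),
                      readsPerSample = 200000L,
                      fragMean = 275, fragSd = 80, fragBounds = c(100, 600),
                      nInduced = 30L, nSuppressed = 30L,
                      exprLog2fcRange = c(0.5, 2),
                      exprBaselineMean = 8, exprBaselineSd = 1.5,
                      exprNoiseSd = 0.2,
                      hmcCouplingSlope = 6,
                      backgroundRate = 20,
                      geneRateBase = 30, geneRateExprCoef = 6,
                      enhancerFraction = 0.3, enhancerWidth = 900L,
                      enhancerRate = 30) {
  grp <- setNames(as.integer(groups), names(groups))
  new("SimConfig",
    seed = as.integer(seed), nChroms = as.integer(nChroms),
    chromLength = as.numeric(chromLength), nGenes = as.integer(nGenes),
    geneLengthRange = as.numeric(geneLengthRange), snapBp = as.integer(snapBp),
    groups = grp, readsPerSample = as.integer(readsPerSample),
    fragMean = fragMean, fragSd = fragSd, fragBounds = as.numeric(fragBounds),
    nInduced = as.integer(nInduced), nSuppressed = as.integer(nSuppressed),
    exprLog2fcRange = as.numeric(exprLog2fcRange),
    exprBaselineMean = exprBaselineMean, exprBaselineSd = exprBaselineSd,
    exprNoiseSd = exprNoiseSd, hmcCouplingSlope = hmcCouplingSlope,
    backgroundRate = backgroundRate, geneRateBase = geneRateBase,
    geneRateExprCoef = geneRateExprCoef,
    enhancerFraction = enhancerFraction,
    enhancerWidth = as.integer(enhancerWidth), enhancerRate = enhancerRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nChroms, " chrom x ",
      format(object@chromLength, big.mark = ","), " bp, ",
      object@nGenes, " genes\n", sep = "")
  cat("  groups: ",
      paste(names(object@groups), object@groups, sep = "=", collapse = ", "),
      "; ", format(object@readsPerSample, big.mark = ","),
      " reads/sample\n", sep = "")
  cat("  planted: ", object@nInduced, " induced + ", object@nSuppressed,
      " suppressed, |log2FC| in [",
      paste(object@exprLog2fcRange, collapse = ", "),
      "], coupling ", object@hmcCouplingSlope, " rpm/window per log2FC\n",
      sep = "")
  cat("  seed: ", object@seed, "\n", sep = "")
})

#' Genomic feature classes derived from gene models and enhancers
#'
#' Container for the five feature classes used throughout the package:
#' gene bodies, promoters (the 1 kb strand-aware region upstream of the TSS),
#' TSS regions (a symmetric window around the TSS), enhancers (supplied, not
#' called), and the intergenic complement. Classes may overlap; there is no
#' precedence hierarchy.
#'
#' @slot features a [GenomicRanges::GRangesList] with one element per class.
#' @slot chromSizes named numeric vector of chromosome lengths.
#' @export
setClass("FeatureSet",
  representation(features = "GRangesList", chromSizes = "numeric"))

setValidity("FeatureSet", function(object) {
  missing <- setdiff(FEATURE_CLASSES, names(object@features))
  if (length(missing))
    return(paste0("missing feature class(es): ", paste(missing, collapse = ", ")))
  if (is.null(names(object@chromSizes)) || any(object@chromSizes < 1))
    return("chromSizes must be a named vector of positive lengths")
  TRUE
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet over", length(object@chromSizes), "chromosome(s)\n")
  n <- vapply(object@features, length, integer(1))
  for (cl in names(n)) cat(sprintf("  %-10s %6d region(s)\n", cl, n[cl]))
})

#' Feature classes of a FeatureSet
#' @param x a [FeatureSet-class]
#' @return character vector of class names.
#' @export
featureClasses <- function(x) names(x@features)

#' Regions of one feature class
#' @param x a [FeatureSet-class]
#' @param class one of `featureClasses(x)`.
#' @return a `GRanges`.
#' @export
featureRegions <- function(x, class) {
  class <- match.arg(class, featureClasses(x))
  x@features[[class]]
}

#' Windowed hMeDIP-seq experiment
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' fixed-width genome windows and whose columns are samples. Assay `counts`
#' holds raw fragment counts (midpoint assignment: each fragment falls in
#' exactly one window); assay `rpm` holds counts normalised to total assigned
#' reads on a reads-per-million scale, so each sample column of `rpm` sums
#' to 1e6. `colData` records `group`, `total_reads` (assigned) and
#' `dropped_reads` (fragments on chromosomes absent from the grid).
#'
#' @export
setClass("HmcExperiment", contains = "RangedSummarizedExperiment")

setValidity("HmcExperiment", function(object) {
  an <- names(assays(object))
  if (!all(c("counts", "rpm") %in% an))
    return("assays must include 'counts' and 'rpm'")
  need <- c("group", "total_reads", "dropped_reads")
  if (!all(need %in% colnames(colData(object))))
    return(paste0("colData must have columns: ", paste(need, collapse = ", ")))
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) return("negative counts")
  tot <- colData(object)$total_reads
  if (!isTRUE(all.equal(unname(colSums(cnt)), as.numeric(tot))))
    return("sum(counts) per sample must equal total_reads")
  r <- assay(object, "rpm")
  pos <- tot > 0
  if (any(pos) && any(abs(colSums(r[, pos, drop = FALSE]) - 1e6) > 1e-3))
    return("rpm columns must sum to 1e6")
  TRUE
})

#' Raw window counts
#' @param x an [HmcExperiment-class]
#' @return integer matrix, windows x samples.
#' @export
windowCounts <- function(x) assay(x, "counts")

#' Normalised window values (reads per million)
#' @param x an [HmcExperiment-class]
#' @return numeric matrix, windows x samples; columns sum to 1e6.
#' @export
rpm <- function(x) assay(x, "rpm")

#' Total assigned reads per sample
#' @param x an [HmcExperiment-class]
#' @return named integer vector.
#' @export
totalReads <- function(x) setNames(colData(x)$total_reads, colnames(x))

#' Reads dropped for lying on chromosomes absent from the grid
#' @param x an [HmcExperiment-class]
#' @return named integer vector.
#' @export
droppedReads <- function(x) setNames(colData(x)$dropped_reads, colnames(x))

#' Diet group per sample
#' @param x an [HmcExperiment-class]
#' @return named character vector.
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group), colnames(x))

#' Result of z-score hierarchical clustering
#'
#' @slot zscores genes x samples matrix of row-wise z-scores (each row mean
#'   0, sd 1; zero-variance rows dropped).
#' @slot dendrogram the sample `hclust` object (Euclidean distance).
#' @slot linkage agglomeration method used.
#' @slot k number of clusters at the cut.
#' @slot clusters named integer cluster assignment per sample.
#' @slot groups declared group labels per sample.
#' @slot ari adjusted Rand index between `clusters` and `groups`.
#' @slot droppedGenes ids of zero-variance rows removed before clustering.
#' @export
setClass("ClusterResult",
  representation(zscores = "matrix", dendrogram = "ANY", linkage = "character",
                 k = "integer", clusters = "integer", groups = "character",
                 ari = "numeric", droppedGenes = "character"))

setValidity("ClusterResult", function(object) {
  z <- object@zscores
  if (nrow(z)) {
    m <- rowMeans(z)
    s <- apply(z, 1, sd)
    if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-8)
      return("z-score rows must have mean 0 and sd 1")
  }
  if (length(object@clusters) != ncol(z))
    return("one cluster assignment per sample required")
  TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", nrow(object@zscores), "gene(s) x",
      ncol(object@zscores), "sample(s); Euclidean distance,",
      object@linkage, "linkage\n")
  cat("  cut at k =", object@k, "-> ARI vs declared groups:",
      format(object@ari, digits = 4), "\n")
  print(table(cluster = object@clusters, group = object@groups))
})

#' Adjusted Rand index of a ClusterResult
#' @param x a [ClusterResult-class]
#' @return numeric scalar in [-1, 1]; 1 is perfect agreement.
#' @export
clusterARI <- function(x) x@ari

#' Cluster assignments of a ClusterResult
#' @param x a [ClusterResult-class]
#' @return named integer vector.
#' @export
clusterAssignments <- function(x) x@clusters

#' Z-score matrix of a ClusterResult
#' @param x a [ClusterResult-class]
#' @return numeric matrix (genes x samples).
#' @export
zscoreMatrix <- function(x) x@zscores
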