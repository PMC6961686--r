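## Feature-class enrichment versus the intergenic background and the
## all-genes metagene profile (fixed-width flanks, length-scaled body bins).

## average rpm tracks within each group -> matrix windows x groups
group_mean_tracks <- function(hx) {
  g <- sampleGroups(hx)
  vapply(unique(g), function(lab)
    rowMeans(rpm(hx)[, g == lab, drop = FALSE]),
    numeric(nrow(hx)))
}

#' Feature-class enrichment relative to intergenic windows
#'
#' For each feature class, compares the normalised values of that class's
#' windows against intergenic windows with a two-sided Wilcoxon rank-sum
#' test (exact enumeration when both sides have <= 8 windows, normal
#' approximation with tie correction otherwise; see [rankSumTest()]). By
#' default samples are pooled within diet group by averaging their rpm
#' tracks; `by = "sample"` tests each sample separately.
#'
#' @param hx an [HmcExperiment-class].
#' @param annotation window annotation from [annotateWindows()]. Ignored
#'   when `level = "region"`, where `features` supplies the geometry.
#' @param by `"group"` (default) or `"sample"`.
#' @param level `"window"` (default: test window values) or `"region"`
#'   (test per-region mean values; requires `features`).
#' @param features a [FeatureSet-class]; required for `level = "region"`.
#' @return data.frame: unit (group or sample), class, n_windows (or
#'   regions), mean_rpm, intergenic mean, rank-sum statistic and p value
#'   (NA for the intergenic row: no self-comparison).
#' @export
featureEnrichment <- function(hx, annotation, by = c("group", "sample"),
                              level = c("window", "region"),
                              features = NULL) {
  by <- match.arg(by)
  level <- match.arg(level)
  tracks <- if (by == "group") group_mean_tracks(hx) else rpm(hx)
  if (level == "region") {
    if (is.null(features)) stop("level = 'region' needs a FeatureSet")
    values <- lapply(setNames(nm = featureClasses(features)), function(cl)
      region_mean_values(tracks, rowRanges(hx), featureRegions(features, cl)))
  } else {
    classes <- intersect(FEATURE_CLASSES, colnames(annotation))
    values <- lapply(setNames(nm = classes), function(cl)
      tracks[annotation[[cl]], , drop = FALSE])
  }
  if (is.null(values$intergenic) || nrow(values$intergenic) < 2)
    stop("need >= 2 intergenic ", level, "s")
  out <- list()
  for (u in colnames(tracks)) {
    vInter <- values$intergenic[, u]
    for (cl in names(values)) {
      v <- values[[cl]][, u]
      if (length(v) == 0) {
        warning("empty feature class omitted: ", cl)
        next
      }
      if (cl == "intergenic") {
        out[[length(out) + 1]] <- data.frame(
          unit = u, class = cl, n_windows = length(v),
          mean_rpm = mean(vInter), intergenic_mean_rpm = mean(vInter),
          rank_sum = NA_real_, p = NA_real_)
        next
      }
      if (length(v) < 2) {
        warning("fewer than 2 ", level, "s in class ", cl, "; omitted")
        next
      }
      rs <- rankSumTest(v, vInter)
      out[[length(out) + 1]] <- data.frame(
        unit = u, class = cl, n_windows = length(v),
        mean_rpm = mean(v), intergenic_mean_rpm = mean(vInter),
        rank_sum = rs$rank_sum, p = rs$p)
    }
  }
  do.call(rbind, out)
}

## per-region mean rpm (bp-overlap weighted) for every track column
region_mean_values <- function(tracks, grid, regions) {
  if (length(regions) == 0)
    return(matrix(numeric(0), 0, ncol(tracks),
                  dimnames = list(NULL, colnames(tracks))))
  hits <- findOverlaps(regions, grid, ignore.strand = TRUE)
  w <- width(pintersect(regions[queryHits(hits)], grid[subjectHits(hits)],
                        ignore.strand = TRUE))
  fac <- factor(queryHits(hits), levels = seq_along(regions))
  wSum <- rowsum(w, fac)  # empty levels drop identically in both rowsums
  sums <- rowsum(tracks[subjectHits(hits), , drop = FALSE] * w, fac)
  out <- sums / as.vector(wSum)
  colnames(out) <- colnames(tracks)
  out
}

## bins for one flank/body layout; returns GRanges of bins with bin index
## and gene index, minus-strand genes reversed so bins run TSS -> TES
metagene_bins <- function(genes, chromSizes, flankBp, bodyBins, flankBinBp) {
  nFlank <- as.integer(flankBp / flankBinBp)
  nBins <- 2L * nFlank + bodyBins
  binsL <- vector("list", length(genes))
  chrom <- as.character(seqnames(genes))
  s0 <- start(genes) - 1; e0 <- end(genes)
  neg <- as.character(strand(genes)) == "-"
  for (i in seq_along(genes)) {
    ## coordinates in gene-forward orientation
    bodyEdges <- round(seq(s0[i], e0[i], length.out = bodyBins + 1))
    upEdges <- seq(s0[i] - nFlank * flankBinBp, s0[i], by = flankBinBp)
    dnEdges <- seq(e0[i], e0[i] + nFlank * flankBinBp, by = flankBinBp)
    edges <- c(upEdges, bodyEdges[-1], dnEdges[-1])
    st <- edges[-length(edges)]; en <- edges[-1]
    binIdx <- seq_len(nBins)
    if (neg[i]) binIdx <- rev(binIdx)
    keep <- st >= 0 & en <= chromSizes[chrom[i]] & en > st
    binsL[[i]] <- GRanges(chrom[i],
                          IRanges(start = st[keep] + 1, end = en[keep]),
                          bin = binIdx[keep], gene = i)
  }
  list(bins = do.call(c, binsL), nBins = nBins, nFlank = nFlank)
}

#' Metagene 5hmC profile over all genes
#'
#' Each gene body is divided into `bodyBins` equal sub-intervals; flanks are
#' tiled in fixed `flankBinBp` steps out to `flankBp`. Window values are
#' averaged into bins weighted by bp overlap; minus-strand genes are
#' reversed so every profile runs TSS to TES; the final profile is the
#' unweighted mean over genes (each gene counts once regardless of length).
#' Genes shorter than `bodyBins` bp are excluded (count reported via
#' message).
#'
#' @param hx an [HmcExperiment-class].
#' @param genes stranded gene `GRanges`.
#' @param flankBp flank extent (default 3000).
#' @param bodyBins body sub-intervals (default 40).
#' @param flankBinBp flank bin width (default 150).
#' @param by `"group"` (average rpm within diet group) or `"sample"`.
#' @return data.frame: bin, bin_class (upstream/body/downstream), one column
#'   per group or sample.
#' @export
metageneProfile <- function(hx, genes, flankBp = 3000L, bodyBins = 40L,
                            flankBinBp = 150L, by = c("group", "sample")) {
  by <- match.arg(by)
  eligible <- width(genes) >= bodyBins
  if (!any(eligible)) stop("no genes longer than bodyBins bp")
  if (any(!eligible))
    message(sum(!eligible), " gene(s) shorter than ", bodyBins,
            " bp excluded from metagene")
  genes <- genes[eligible]
  grid <- rowRanges(hx)
  chromSizes <- setNames(as.numeric(seqlengths(grid)), seqlevels(grid))
  mb <- metagene_bins(genes, chromSizes, flankBp, bodyBins, flankBinBp)
  hits <- findOverlaps(mb$bins, grid, ignore.strand = TRUE)
  wts <- width(pintersect(mb$bins[queryHits(hits)],
                          grid[subjectHits(hits)], ignore.strand = TRUE))
  tracks <- if (by == "group") group_mean_tracks(hx) else rpm(hx)
  key <- (mb$bins$gene[queryHits(hits)] - 1L) * mb$nBins +
    mb$bins$bin[queryHits(hits)]
  keyFac <- factor(key)
  wSum <- rowsum(wts, keyFac)
  prof <- matrix(NA_real_, nrow = mb$nBins, ncol = ncol(tracks),
                 dimnames = list(NULL, colnames(tracks)))
  binOf <- (as.integer(levels(keyFac)) - 1L) %% mb$nBins + 1L
  nGenesPerBin <- tabulate(binOf, nbins = mb$nBins)
  for (j in seq_len(ncol(tracks))) {
    v <- tracks[subjectHits(hits), j] * wts
    geneBin <- rowsum(v, keyFac) / wSum          # per gene x bin mean
    sums <- rowsum(geneBin, binOf)               # sorted by bin index
    idx <- as.integer(rownames(sums))
    prof[idx, j] <- sums[, 1] / nGenesPerBin[idx]
  }
  binClass <- rep(c("upstream", "body", "downstream"),
                  c(mb$nFlank, bodyBins, mb$nFlank))
  data.frame(bin = seq_len(mb$nBins), bin_class = binClass, prof,
             check.names = FALSE)
}
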