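## The core statistic: per-gene gene-body 5hmC scores (mean normalised reads
## per 150 bp window), delta-5hmC between diet groups, OLS regression of
## delta-5hmC on transcriptional change, z-score hierarchical clustering for
## sample stratification, top-N gene selection and hMeDIP-qPCR
## percent-input analysis.

#' Per-gene gene-body 5hmC scores
#'
#' Score = arithmetic mean of normalised (rpm) values over the windows whose
#' midpoint lies inside the gene body. Genes containing no window midpoint
#' are excluded (count reported via message).
#'
#' @param hx an [HmcExperiment-class].
#' @param regions `GRanges` of scoring regions with a `gene_id` metadata
#'   column or names (typically gene bodies; pass promoters/TSS/enhancer
#'   regions for per-class regressions).
#' @return numeric matrix, regions x samples, rownames = gene ids.
#' @export
geneBodyScores <- function(hx, regions) {
  ids <- if (!is.null(regions$gene_id)) regions$gene_id else names(regions)
  if (is.null(ids)) stop("regions need gene_id metadata or names")
  grid <- rowRanges(hx)
  mid0 <- floor((start(grid) - 1 + end(grid)) / 2)
  midGr <- GRanges(seqnames(grid), IRanges(start = mid0 + 1, width = 1))
  hits <- findOverlaps(midGr, regions, ignore.strand = TRUE)
  if (length(hits) == 0) stop("no window midpoint falls in any region")
  fac <- factor(subjectHits(hits), levels = seq_along(regions))
  nWin <- tabulate(fac, nbins = length(regions))
  scored <- nWin > 0
  if (any(!scored))
    message(sum(!scored), " region(s) without a window midpoint excluded")
  sums <- rowsum(rpm(hx)[queryHits(hits), , drop = FALSE], fac)
  present <- as.integer(rownames(sums))  # rowsum drops empty levels
  scores <- sums / nWin[present]
  rownames(scores) <- ids[present]
  colnames(scores) <- colnames(hx)
  scores
}

#' Delta-5hmC between two groups
#'
#' Per gene, the difference in group means of the gene-body score:
#' `mean(score | groupA) - mean(score | groupB)`, in normalised reads per
#' 150 bp window. Antisymmetric under group exchange.
#'
#' @param scores genes x samples matrix from [geneBodyScores()].
#' @param samples data.frame with `sample_id`, `group`.
#' @param groupA,groupB group labels (delta = A - B; the study contrast is
#'   HFD - CON).
#' @param de optional DE table from [differentialExpression()]; when given,
#'   `expr_log2fc` and `expr_adj_p` are merged in by gene_id.
#' @return data.frame: gene_id, delta_5hmc, and the DE columns when merged.
#' @export
delta5hmc <- function(scores, samples, groupA = "HFD", groupB = "CON",
                      de = NULL) {
  for (g in c(groupA, groupB))
    if (!g %in% samples$group) stop("unknown group label: ", g)
  sA <- samples$sample_id[samples$group == groupA]
  sB <- samples$sample_id[samples$group == groupB]
  sA <- intersect(sA, colnames(scores)); sB <- intersect(sB, colnames(scores))
  if (length(sA) < 1 || length(sB) < 1)
    stop("both groups need >= 1 sample with scores")
  keep <- complete.cases(scores[, c(sA, sB), drop = FALSE])
  d <- rowMeans(scores[keep, sA, drop = FALSE]) -
    rowMeans(scores[keep, sB, drop = FALSE])
  out <- data.frame(gene_id = rownames(scores)[keep], delta_5hmc = unname(d))
  if (!is.null(de)) {
    m <- match(out$gene_id, de$gene_id)
    out$expr_log2fc <- de$log2fc[m]
    out$expr_adj_p <- de$adj_p[m]
  }
  out
}

#' Regress delta-5hmC on transcriptional change
#'
#' Ordinary least squares of `delta_5hmc` on the transcriptional-change
#' column, with a two-sided t-test on the slope. Run it on gene-body scores
#' for the primary result and on promoter/TSS/enhancer (or intergenic
#' control) scores for the feature-specificity contrast.
#'
#' @param deltas data.frame with `delta_5hmc` and the `x` column.
#' @param x name of the transcriptional-change column (default
#'   `expr_log2fc`).
#' @param featureClass label stored in the result (default "gene_body").
#' @return list: slope, intercept, r_squared, p_value, slope_se, n,
#'   feature_class.
#' @export
regressDeltaExpression <- function(deltas, x = "expr_log2fc",
                                   featureClass = "gene_body") {
  if (!x %in% names(deltas)) stop("no column '", x, "' in deltas")
  fit <- ols_fit(deltas[[x]], deltas$delta_5hmc)
  fit$feature_class <- featureClass
  fit
}

#' Z-score hierarchical clustering of samples
#'
#' Rows (genes) are z-scored to mean 0, sd 1 (zero-variance rows dropped);
#' samples are clustered on Euclidean distance with the stated linkage
#' (default complete), cut at `k`, and scored against the declared diet
#' groups by adjusted Rand index.
#'
#' @param scores genes x samples matrix (gene-body 5hmC scores or
#'   expression).
#' @param samples data.frame with `sample_id`, `group`.
#' @param geneSubset `"all"` or a character vector of gene ids.
#' @param k number of clusters at the cut (default 2).
#' @param linkage agglomeration method (default "complete").
#' @return a [ClusterResult-class].
#' @export
zscoreCluster <- function(scores, samples, geneSubset = "all", k = 2L,
                          linkage = "complete") {
  if (ncol(scores) < 2) stop("need >= 2 samples")
  if (!identical(geneSubset, "all")) {
    missing <- setdiff(geneSubset, rownames(scores))
    if (length(missing))
      warning("gene(s) absent from score matrix: ",
              paste(head(missing, 5), collapse = ", "))
    scores <- scores[intersect(geneSubset, rownames(scores)), , drop = FALSE]
  }
  if (nrow(scores) == 0) stop("empty gene subset")
  sds <- apply(scores, 1, sd)
  dropped <- rownames(scores)[sds == 0]
  if (length(dropped) == nrow(scores)) stop("all rows have zero variance")
  scores <- scores[sds > 0, , drop = FALSE]
  z <- t(scale(t(scores)))
  hc <- hclust(dist(t(z), method = "euclidean"), method = linkage)
  cl <- cutree(hc, k = min(k, ncol(z)))
  grp <- setNames(as.character(samples$group),
                  samples$sample_id)[colnames(z)]
  new("ClusterResult", zscores = z, dendrogram = hc, linkage = linkage,
      k = as.integer(k), clusters = cl, groups = unname(grp),
      ari = adjustedRandIndex(cl, grp),
      droppedGenes = as.character(dropped))
}

#' Top-N induced or suppressed genes from a DE table
#'
#' Genes with adjusted p below `alpha` and the requested sign, ranked by
#' |log2FC| descending; ties broken by adjusted p ascending, then gene_id.
#' Returns all (with a warning) when fewer than `n` qualify.
#'
#' @param de DE table from [differentialExpression()].
#' @param direction `"induced"` or `"suppressed"`.
#' @param n how many genes (default 10).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of gene ids.
#' @export
topGenes <- function(de, direction = c("induced", "suppressed"), n = 10L,
                     alpha = 0.05) {
  direction <- match.arg(direction)
  sel <- de[!is.na(de$adj_p) & de$adj_p < alpha &
              (if (direction == "induced") de$log2fc > 0 else de$log2fc < 0), ]
  if (nrow(sel) < n)
    warning("only ", nrow(sel), " significant ", direction,
            " gene(s); returning all")
  ord <- order(-abs(sel$log2fc), sel$adj_p, sel$gene_id)
  head(sel$gene_id[ord], n)
}

#' Percent input from IP and input Ct values
#'
#' `100 * 2^((Ct_input - log2(1/inputFraction)) - Ct_IP)`: the input Ct is
#' first adjusted for the fraction of material it represents (10% input adds
#' log2(10) cycles), then compared with the IP Ct. When `Ct_input == Ct_IP`
#' at 10% input the result is exactly 10%.
#'
#' @param ctIp,ctInput numeric Ct values.
#' @param inputFraction fraction of material removed as input (default 0.10).
#' @return percent of input recovered in the IP.
#' @export
percentInput <- function(ctIp, ctInput, inputFraction = 0.10) {
  if (inputFraction <= 0 || inputFraction >= 1)
    stop("inputFraction must be in (0, 1)")
  100 * 2^((ctInput - log2(1 / inputFraction)) - ctIp)
}

#' hMeDIP-qPCR fold-change analysis
#'
#' Converts IP/input Ct pairs to percent input, expresses each animal as
#' fold change versus the CON group mean per locus, and compares groups per
#' locus by one-way ANOVA with Tukey HSD. Rows missing an input or IP Ct are
#' dropped (count reported via message).
#'
#' @param ctTable data.frame: animal_id, group, locus, ct_ip, ct_input.
#' @param inputFraction input fraction (default 0.10).
#' @return list: `table` (per animal x locus: percent_input, fold_vs_con)
#'   and `tests` (per locus: ANOVA F/p and Tukey pairwise rows).
#' @export
hmedipQpcr <- function(ctTable, inputFraction = 0.10) {
  need <- c("animal_id", "group", "locus", "ct_ip", "ct_input")
  miss <- setdiff(need, names(ctTable))
  if (length(miss)) stop("ctTable missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- is.finite(ctTable$ct_ip) & is.finite(ctTable$ct_input)
  if (any(!ok)) message(sum(!ok), " locus-animal row(s) without both Ct values dropped")
  tab <- ctTable[ok, ]
  tab$percent_input <- percentInput(tab$ct_ip, tab$ct_input, inputFraction)
  tests <- list()
  tab$fold_vs_con <- NA_real_
  for (loc in unique(tab$locus)) {
    i <- tab$locus == loc
    conMean <- mean(tab$percent_input[i & tab$group == "CON"])
    if (!is.finite(conMean) || conMean <= 0)
      stop("no usable CON reference for locus ", loc)
    tab$fold_vs_con[i] <- tab$percent_input[i] / conMean
    if (length(unique(tab$group[i])) >= 2 && sum(i) > length(unique(tab$group[i]))) {
      at <- groupAnovaTukey(tab$fold_vs_con[i], tab$group[i])
      tests[[loc]] <- cbind(locus = loc, at$anova)
      tests[[paste0(loc, "_tukey")]] <- cbind(locus = loc, at$tukey)
    }
  }
  anovaRows <- do.call(rbind, tests[!grepl("_tukey$", names(tests))])
  tukeyRows <- do.call(rbind, tests[grepl("_tukey$", names(tests))])
  list(table = tab,
       tests = list(anova = anovaRows, tukey = tukeyRows))
}

#' Intergenic control regions size-matched to genes
#'
#' For each gene, samples one interval of the same length fully inside the
#' intergenic complement (for the regression specificity control: gene-body
#' delta-5hmC tracks expression, size-matched intergenic intervals should
#' not). Deterministic under `seed`.
#'
#' @param features a [FeatureSet-class].
#' @param genes gene `GRanges` with `gene_id`.
#' @param seed integer seed.
#' @return `GRanges` named/annotated with the paired `gene_id`; genes whose
#'   length exceeds every intergenic gap are matched to the largest gap
#'   (width-truncated).
#' @export
intergenicControlRegions <- function(features, genes, seed = 1L) {
  set.seed(seed)
  inter <- featureRegions(features, "intergenic")
  if (length(inter) == 0) stop("no intergenic space")
  wI <- width(inter)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    L <- width(genes)[i]
    fits <- which(wI >= L)
    if (length(fits) == 0) {
      j <- which.max(wI); L <- wI[j]
    } else {
      j <- fits[sample.int(length(fits), 1)]
    }
    off <- floor(runif(1) * (wI[j] - L + 1))
    out[[i]] <- GRanges(seqnames(inter)[j],
                        IRanges(start = start(inter)[j] + off, width = L))
  }
  ctrl <- do.call(c, out)
  mcols(ctrl)$gene_id <- genes$gene_id
  names(ctrl) <- genes$gene_id
  ctrl
}

#' Write a sample dendrogram as Newick text
#'
#' @param result a [ClusterResult-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeNewick <- function(result, path) {
  hc <- result@dendrogram
  lab <- hc$labels
  node <- function(i) {
    if (i < 0) return(lab[-i])
    m <- hc$merge[i, ]
    sprintf("(%s,%s):%g", node(m[1]), node(m[2]), hc$height[i])
  }
  writeLines(paste0(node(nrow(hc$merge)), ";"), path)
  invisible(path)
}
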