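## Differential expression on a log2 matrix (pooled-variance t-test +
## Benjamini-Hochberg, with the study's dual decision rule: adjusted p below
## alpha AND linear fold change beyond 10%), top-variance sample clustering,
## and qPCR relative quantification against two housekeepers.
##
## Note: the original microarray analysis used limma's moderated statistics;
## this package deliberately substitutes the ordinary pooled-variance t-test
## and keeps the stated decision rule (see the methods vignette).

#' Differential expression between two groups
#'
#' Per gene: two-sample pooled-variance t-test on log2 values,
#' Benjamini-Hochberg adjustment across all tested genes, and status from
#' the dual threshold: `up` iff `adj_p < alpha` and linear fold change
#' `> 1 + delta`; `down` iff `adj_p < alpha` and fold change
#' `< 1/(1 + delta)`; otherwise `unchanged`.
#'
#' @param mat genes x samples log2 matrix (rownames = gene ids).
#' @param samples data.frame with `sample_id`, `group`.
#' @param groupA,groupB contrast (log2fc = mean A - mean B; the study
#'   contrast is HFD - CON).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param delta minimum linear change (default 0.10 = 10%).
#' @return data.frame: gene_id, log2fc, raw_p, adj_p, status.
#' @export
differentialExpression <- function(mat, samples, groupA = "HFD",
                                   groupB = "CON", alpha = 0.05,
                                   delta = 0.10) {
  sA <- intersect(samples$sample_id[samples$group == groupA], colnames(mat))
  sB <- intersect(samples$sample_id[samples$group == groupB], colnames(mat))
  if (length(sA) < 2 || length(sB) < 2)
    stop("both groups need >= 2 samples (got ", length(sA), " and ",
         length(sB), ")")
  a <- mat[, sA, drop = FALSE]; b <- mat[, sB, drop = FALSE]
  nA <- length(sA); nB <- length(sB)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- rowSums((a - mA)^2) / (nA - 1)
  vB <- rowSums((b - mB)^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  log2fc <- mA - mB
  tstat <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf))
  rawP <- 2 * pt(-abs(tstat), df = nA + nB - 2)
  adjP <- p.adjust(rawP, method = "BH")
  fc <- 2^log2fc
  status <- rep("unchanged", nrow(mat))
  status[adjP < alpha & fc > 1 + delta] <- "up"
  status[adjP < alpha & fc < 1 / (1 + delta)] <- "down"
  data.frame(gene_id = rownames(mat), log2fc = unname(log2fc),
             raw_p = unname(rawP), adj_p = unname(adjP), status = status)
}

#' Volcano-plot data from a DE table
#' @param de DE table from [differentialExpression()].
#' @return data.frame: gene_id, log2fc, neg_log10_adj_p, status.
#' @export
volcanoData <- function(de) {
  data.frame(gene_id = de$gene_id, log2fc = de$log2fc,
             neg_log10_adj_p = -log10(de$adj_p), status = de$status)
}

#' Cluster samples on the top-variance genes
#'
#' Selects the `nTop` genes with highest variance across samples and
#' delegates to [zscoreCluster()] (Euclidean distance). With the study's
#' design, the top 200 varying transcripts suffice to separate diet groups.
#'
#' @param mat genes x samples matrix.
#' @param samples data.frame with `sample_id`, `group`.
#' @param nTop number of genes (default 200); capped at the gene count with
#'   a warning.
#' @param k,linkage passed to [zscoreCluster()].
#' @return a [ClusterResult-class].
#' @export
topVarianceClustering <- function(mat, samples, nTop = 200L, k = 2L,
                                  linkage = "complete") {
  if (ncol(mat) < 2) stop("need >= 2 samples")
  if (nTop > nrow(mat)) {
    warning("nTop > gene count; using all ", nrow(mat), " genes")
    nTop <- nrow(mat)
  }
  v <- apply(mat, 1, var)
  top <- rownames(mat)[order(-v)[seq_len(nTop)]]
  zscoreCluster(mat, samples, geneSubset = top, k = k, linkage = linkage)
}

#' qPCR relative expression against two housekeepers
#'
#' `delta_ct = Ct_target - mean(Ct_hk1, Ct_hk2)`; relative expression
#' `2^(-delta_ct)`; fold change versus the CON group mean per target. Group
#' comparison per target by one-way ANOVA with Tukey HSD (shared with
#' [hmedipQpcr()]). Rows with missing or non-positive Ct are dropped.
#'
#' @param ctTable data.frame: animal_id, group, target, ct_target, ct_hk1,
#'   ct_hk2.
#' @return list: `table` (delta_ct, rel_expr, fold_vs_con per row) and
#'   `tests` (per-target ANOVA and Tukey rows).
#' @export
qpcrRelativeExpression <- function(ctTable) {
  need <- c("animal_id", "group", "target", "ct_target", "ct_hk1", "ct_hk2")
  miss <- setdiff(need, names(ctTable))
  if (length(miss)) stop("ctTable missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- with(ctTable, is.finite(ct_target) & is.finite(ct_hk1) &
               is.finite(ct_hk2) & ct_target > 0 & ct_hk1 > 0 & ct_hk2 > 0)
  if (any(!ok)) message(sum(!ok), " row(s) with missing/non-positive Ct dropped")
  tab <- ctTable[ok, ]
  tab$delta_ct <- tab$ct_target - (tab$ct_hk1 + tab$ct_hk2) / 2
  tab$rel_expr <- 2^(-tab$delta_ct)
  tab$fold_vs_con <- NA_real_
  tests <- list(anova = list(), tukey = list())
  for (tg in unique(tab$target)) {
    i <- tab$target == tg
    conMean <- mean(tab$rel_expr[i & tab$group == "CON"])
    if (!is.finite(conMean) || conMean <= 0)
      stop("no usable CON reference for target ", tg)
    tab$fold_vs_con[i] <- tab$rel_expr[i] / conMean
    if (length(unique(tab$group[i])) >= 2 &&
        sum(i) > length(unique(tab$group[i]))) {
      at <- groupAnovaTukey(tab$fold_vs_con[i], tab$group[i])
      tests$anova[[tg]] <- cbind(target = tg, at$anova)
      tests$tukey[[tg]] <- cbind(target = tg, at$tukey)
    }
  }
  list(table = tab,
       tests = list(anova = do.call(rbind, tests$anova),
                    tukey = do.call(rbind, tests$tukey)))
}
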