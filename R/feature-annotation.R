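## Feature derivation from gene models and window classification.
## Promoter = the 1 kb region immediately upstream of the TSS, strand-aware,
## truncated at chromosome edges. TSS region = symmetric window around the
## TSS (default 300 bp). Intergenic = genome minus (bodies u promoters u
## enhancers). Classes may overlap; no precedence hierarchy.

#' Derive genomic feature classes from gene models and enhancers
#'
#' @param genes stranded `GRanges` of gene bodies with a `gene_id` metadata
#'   column (see [readGeneModels()]).
#' @param enhancers `GRanges` of enhancer regions (H3K4me1+/H3K4me3-,
#'   supplied as a ready interval set); may be empty.
#' @param chromSizes named vector of chromosome lengths.
#' @param promoterBp promoter extent upstream of the TSS (default 1000).
#' @param tssBp total width of the symmetric TSS region (default 300).
#' @return a [FeatureSet-class].
#' @examples
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 9000),
#'                                 strand = "+", gene_id = "GeneA")
#' names(genes) <- "GeneA"
#' fs <- deriveFeatures(genes, GenomicRanges::GRanges(), c(chr1 = 20000))
#' featureRegions(fs, "promoter")  # chr1 [4001,5000] = BED [4000,5000)
#' @export
deriveFeatures <- function(genes, enhancers = GRanges(), chromSizes,
                           promoterBp = 1000L, tssBp = 300L) {
  if (any(as.character(strand(genes)) == "*"))
    stop("gene models must be stranded")
  if (is.null(genes$gene_id)) {
    if (is.null(names(genes))) stop("genes need a gene_id column or names")
    mcols(genes)$gene_id <- names(genes)
  }
  bad <- !(as.character(seqnames(genes)) %in% names(chromSizes)) |
    end(genes) > chromSizes[as.character(seqnames(genes))] |
    start(genes) < 1
  if (any(bad))
    stop("gene(s) beyond chromosome bounds: ",
         paste(head(genes$gene_id[bad], 10), collapse = ", "))

  si <- Seqinfo(seqnames = names(chromSizes),
                seqlengths = as.integer(chromSizes))
  fix_si <- function(gr) {
    gr <- GRanges(as.character(seqnames(gr)), ranges(gr),
                  strand = strand(gr), seqinfo = si)
    gr
  }
  body <- fix_si(genes)
  mcols(body) <- DataFrame(gene_id = genes$gene_id)

  prom <- trim(suppressWarnings(
    promoters(body, upstream = as.integer(promoterBp), downstream = 0L)))
  prom <- prom[width(prom) > 0]

  tssPt <- resize(body, width = 1L, fix = "start")
  tss <- trim(suppressWarnings(
    resize(tssPt, width = as.integer(tssBp), fix = "center")))
  tss <- tss[width(tss) > 0]

  enh <- fix_si(granges(enhancers))
  mcols(enh) <- DataFrame(gene_id = rep(NA_character_, length(enh)))

  genic <- reduce(c(granges(body), granges(prom), granges(enh)),
                  ignore.strand = TRUE)
  intergenic <- gaps(genic)
  intergenic <- intergenic[as.character(strand(intergenic)) == "*"]
  mcols(intergenic) <- DataFrame(gene_id = rep(NA_character_,
                                               length(intergenic)))
  strand(body) <- "*"; strand(prom) <- "*"; strand(tss) <- "*"
  fl <- GRangesList(gene_body = body, promoter = prom, tss = tss,
                    enhancer = enh, intergenic = intergenic)
  new("FeatureSet", features = fl,
      chromSizes = setNames(as.numeric(chromSizes), names(chromSizes)))
}

#' Classify windows by feature class
#'
#' A window carries class `C` iff it overlaps >= 1 bp of a `C` region.
#' Windows overlapping no gene body, promoter, TSS region or enhancer are
#' intergenic (the fallback), so every window has at least one class.
#'
#' @param grid window `GRanges` from [buildWindowGrid()].
#' @param features a [FeatureSet-class].
#' @return `DataFrame` along `grid` with one logical column per class and a
#'   `gene_id` `CharacterList` of owning genes (gene-body overlap).
#' @export
annotateWindows <- function(grid, features) {
  cls <- setdiff(featureClasses(features), "intergenic")
  cols <- lapply(cls, function(cl)
    overlapsAny(grid, features@features[[cl]], ignore.strand = TRUE))
  names(cols) <- cls
  ann <- DataFrame(cols)
  ann$intergenic <- !Reduce(`|`, cols)
  body <- features@features$gene_body
  hits <- findOverlaps(grid, body, ignore.strand = TRUE)
  ann$gene_id <- extractList(body$gene_id, as(hits, "List"))
  ann
}

#' Export a FeatureSet as BED6 files (one per class)
#'
#' Names take the form `class:gene_id` (or `class` for unowned regions).
#'
#' @param features a [FeatureSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
exportFeatures <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cl in featureClasses(features)) {
    gr <- features@features[[cl]]
    nm <- if (!is.null(gr$gene_id)) ifelse(is.na(gr$gene_id), cl,
                                           paste0(cl, ":", gr$gene_id)) else cl
    if (length(gr)) names(gr) <- nm
    p <- file.path(dir, paste0(cl, ".bed"))
    writeBed(gr, p, strandCol = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
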