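## Readers/writers for BED intervals, gene models and tabular files.
## All internal coordinates are 0-based half-open (BED convention); GRanges
## objects are built at the boundary with the usual 1-based shift. Chromosome
## names are matched by exact string equality -- no "chr" aliasing.

bed0_to_granges <- function(chrom, start0, end0, strand = NULL, names = NULL) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0),
                strand = if (is.null(strand)) "*" else strand)
  if (!is.null(names)) names(gr) <- names
  gr
}

granges_to_bed0 <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Carrier for aligned hMeDIP fragments and enhancer regions. BED
#' coordinates are 0-based half-open; the returned `GRanges` uses the usual
#' 1-based closed representation, so `start(gr) - 1` recovers the BED start.
#' Malformed records are reported with their 1-based line numbers.
#'
#' @param path BED file (>= 3 tab-separated columns, no header).
#' @param expectStrand if `TRUE`, a strand column with values `+`/`-` is
#'   required and attached.
#' @return a `GRanges` in file order; column 4, when present, becomes names.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t250", f)
#' readBed(f)
#' @export
readBed <- function(path, expectStrand = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 3) stop("BED needs >= 3 columns: ", path)
  start0 <- suppressWarnings(as.numeric(df[[2]]))
  end0 <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | df[[1]] == "" |
                 start0 < 0 | start0 >= end0)
  if (length(bad))
    stop("malformed BED record(s) at line(s) ",
         paste(head(bad, 10), collapse = ", "), " in ", path,
         " (need chrom non-empty and 0 <= start < end)")
  strand <- NULL
  if (expectStrand) {
    if (ncol(df) < 6) stop("strand column required but absent: ", path)
    s <- df[[6]]
    badS <- which(!s %in% c("+", "-"))
    if (length(badS))
      stop("invalid strand at line(s) ", paste(head(badS, 10), collapse = ", "),
           " in ", path)
    strand <- s
  } else if (ncol(df) >= 6) {
    s <- df[[6]]
    strand <- ifelse(s %in% c("+", "-"), s, "*")
  }
  nm <- if (ncol(df) >= 4) df[[4]] else NULL
  bed0_to_granges(df[[1]], start0, end0, strand, nm)
}

#' Write intervals as BED
#'
#' @param gr a `GRanges`; names become column 4 when present.
#' @param path output file.
#' @param strandCol write BED6 (name, score 0, strand) instead of BED3.
#' @return invisibly, `path`.
#' @export
writeBed <- function(gr, path, strandCol = FALSE) {
  df <- granges_to_bed0(gr)
  if (strandCol || !is.null(names(gr))) {
    df$name <- if (is.null(names(gr))) "." else names(gr)
    if (strandCol) {
      df$score <- 0L
      df$strand <- as.character(strand(gr))
    }
  }
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6 file
#'
#' One gene per line with mandatory name and strand columns. The TSS of a
#' `+` strand gene is its BED start; of a `-` strand gene, its BED end.
#'
#' @param path BED6 file (chrom, start, end, gene_id, score, strand).
#' @return a `GRanges` named by `gene_id`, with a `gene_id` metadata column.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t5000\t9000\tGeneA\t0\t+", f)
#' genes <- readGeneModels(f)
#' tssPositions(genes)  # 5000 (0-based)
#' @export
readGeneModels <- function(path) {
  gr <- readBed(path, expectStrand = TRUE)
  if (is.null(names(gr))) stop("gene models need a name column: ", path)
  dup <- unique(names(gr)[duplicated(names(gr))])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(head(dup, 10), collapse = ", "))
  mcols(gr)$gene_id <- names(gr)
  gr
}

#' TSS positions of gene models (0-based)
#'
#' Strand-dependent: the transcription start site of a `+` gene is its
#' 0-based start, of a `-` gene its exclusive end.
#'
#' @param genes a stranded `GRanges` of gene bodies.
#' @return numeric vector of 0-based TSS coordinates.
#' @export
tssPositions <- function(genes) {
  s <- as.character(strand(genes))
  if (any(s == "*")) stop("gene models must be stranded")
  ifelse(s == "+", start(genes) - 1L, end(genes))
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `group` and optionally
#' `reads_path`. Groups must come from CON, HFD, HFD-reversal, CON-reversal.
#'
#' @param path TSV file.
#' @return data.frame with validated columns.
#' @export
readSampleSheet <- function(path) {
  df <- readTsv(path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in sample sheet")
  bad <- setdiff(unique(df$group), VALID_GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(VALID_GROUPS, collapse = ", "), ")")
  if ("reads_path" %in% names(df)) {
    # relative read paths resolve against the sheet's own directory
    rel <- !grepl("^(/|[A-Za-z]:)", df$reads_path)
    df$reads_path[rel] <- file.path(dirname(path), df$reads_path[rel])
  }
  df
}

#' Write a table as TSV
#'
#' Tab-separated UTF-8 with one header line; numeric columns serialised at 6
#' significant digits.
#'
#' @param records a data.frame with unique column names.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records)
  if (anyDuplicated(names(records))) stop("duplicate header names")
  out <- records
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [writeTable()]
#' @param path TSV file with a header line.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "")
}

#' Read a log2 expression matrix
#'
#' First column `gene_id`, one column per sample.
#' @param path TSV file.
#' @return numeric matrix, genes x samples, rownames = gene ids.
#' @export
readExpressionMatrix <- function(path) {
  df <- readTsv(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}
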