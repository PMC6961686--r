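## Fixed-width genome tiling, midpoint fragment counting, reads-per-million
## normalisation. "Sliding windows" are realised as non-overlapping
## consecutive tiles (step = width): each histogram bar covers one 150 bp
## window, and disjoint tiles make the per-sample total exactly conserved.

#' Tile a genome into fixed-width windows
#'
#' Consecutive disjoint windows `[k*w, (k+1)*w)` per chromosome; the last
#' window of a chromosome may be shorter. Ordering is deterministic:
#' chromosome name lexicographic, then position.
#'
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param width window width in bp (default 150).
#' @return a `GRanges` of windows with `metadata()$width` set.
#' @examples
#' buildWindowGrid(c(chr1 = 400), width = 150)  # [0,150) [150,300) [300,400)
#' @export
buildWindowGrid <- function(chromSizes, width = 150L) {
  if (width < 1) stop("width must be >= 1")
  if (is.null(names(chromSizes)) || any(chromSizes < 1))
    stop("chromSizes must be a named vector of sizes >= 1")
  chromSizes <- chromSizes[order(names(chromSizes))]
  grid <- tileGenome(setNames(as.integer(chromSizes), names(chromSizes)),
                     tilewidth = as.integer(width),
                     cut.last.tile.in.chrom = TRUE)
  metadata(grid)$width <- as.integer(width)
  grid
}

grid_width <- function(grid) {
  w <- metadata(grid)$width
  if (is.null(w)) stop("grid lacks metadata()$width; build it with buildWindowGrid()")
  w
}

## 0-based fragment midpoints: floor((start0 + end0) / 2).
fragment_midpoints0 <- function(reads) {
  floor((start(reads) - 1 + end(reads)) / 2)
}

#' Count fragments per window
#'
#' With the default midpoint rule each fragment is assigned to exactly one
#' window — the one containing its midpoint `floor((start + end) / 2)` in
#' 0-based coordinates — so `sum(counts) + dropped == length(reads)`.
#' `assign = "overlap"` instead counts a fragment in every window it
#' overlaps by >= 1 bp (a comparison mode: it multi-counts fragments and
#' breaks total-read conservation, so the pipeline itself never uses it).
#' Fragments on chromosomes absent from the grid are dropped (counted, not
#' fatal).
#'
#' @param grid window `GRanges` from [buildWindowGrid()].
#' @param reads `GRanges` of aligned fragments.
#' @param assign `"midpoint"` (default) or `"overlap"`.
#' @return list with `counts` (integer vector along `grid`) and `dropped`.
#' @export
countReads <- function(grid, reads, assign = c("midpoint", "overlap")) {
  assign <- match.arg(assign)
  if (assign == "overlap") {
    onGrid <- as.character(seqnames(reads)) %in% levels(seqnames(grid))
    hits <- findOverlaps(reads[onGrid], grid, ignore.strand = TRUE)
    return(list(counts = tabulate(subjectHits(hits), nbins = length(grid)),
                dropped = sum(!onGrid)))
  }
  w <- grid_width(grid)
  lv <- levels(seqnames(grid))
  nPerChrom <- as.integer(table(seqnames(grid))[lv])
  offset <- setNames(c(0L, cumsum(nPerChrom))[seq_along(lv)], lv)
  chrom <- as.character(seqnames(reads))
  onGrid <- chrom %in% lv
  dropped <- sum(!onGrid)
  counts <- integer(length(grid))
  if (any(onGrid)) {
    mid0 <- fragment_midpoints0(reads[onGrid])
    idx <- offset[chrom[onGrid]] + mid0 %/% w + 1L
    maxIdx <- offset[chrom[onGrid]] + nPerChrom[match(chrom[onGrid], lv)]
    bad <- idx > maxIdx | mid0 < 0
    if (any(bad)) {
      dropped <- dropped + sum(bad)
      idx <- idx[!bad]
    }
    counts <- tabulate(idx, nbins = length(grid))
  }
  list(counts = counts, dropped = dropped)
}

#' Normalise raw window counts to reads per million
#'
#' `rpm_k = raw_k / total * 1e6` with `total = sum(raw)`, so each sample
#' column sums to exactly 1e6. Re-deriving from the same raw counts always
#' gives the same vector.
#'
#' @param counts integer vector or matrix (windows, or windows x samples).
#' @return numeric of the same shape.
#' @export
rpmNormalize <- function(counts) {
  if (is.matrix(counts)) {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("empty sample (total reads = 0)")
    return(sweep(counts, 2, tot, "/") * 1e6)
  }
  tot <- sum(counts)
  if (tot == 0) stop("empty sample (total reads = 0)")
  counts / tot * 1e6
}

#' Quantify hMeDIP fragments over a window grid
#'
#' Builds an [HmcExperiment-class]: counts every sample's fragments into the
#' grid by midpoint assignment and attaches the reads-per-million
#' normalisation. Conservation (`sum(counts) + dropped == n reads` and
#' `sum(rpm) == 1e6`) is asserted by the class validity.
#'
#' @param grid window `GRanges` from [buildWindowGrid()].
#' @param reads named list of fragment `GRanges`, one per sample.
#' @param samples data.frame with `sample_id` and `group` (see
#'   [readSampleSheet()]); defaults to all-CON if omitted.
#' @return an [HmcExperiment-class] (windows x samples).
#' @export
countWindows <- function(grid, reads, samples = NULL) {
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must be a uniquely named list of GRanges")
  if (is.null(samples))
    samples <- data.frame(sample_id = names(reads), group = "CON")
  idx <- match(names(reads), samples$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from sample sheet: ",
                       paste(names(reads)[is.na(idx)], collapse = ", "))
  res <- lapply(reads, function(r) countReads(grid, r))
  cnt <- vapply(res, `[[`, integer(length(grid)), "counts")
  dropped <- vapply(res, `[[`, numeric(1), "dropped")
  tot <- colSums(cnt)
  if (any(tot == 0)) stop("empty sample(s): ",
                          paste(names(reads)[tot == 0], collapse = ", "))
  se <- SummarizedExperiment(
    assays = list(counts = cnt, rpm = rpmNormalize(cnt)),
    rowRanges = grid,
    colData = DataFrame(group = samples$group[idx],
                        total_reads = as.integer(tot),
                        dropped_reads = as.integer(dropped),
                        row.names = names(reads)))
  as(se, "HmcExperiment")
}

#' Input-corrected normalised tracks
#'
#' Optional comparison mode: subtracts an input (pre-capture) library's rpm
#' track from each immunoprecipitation track, clamping at zero. The default
#' pipeline normalises to total reads only and does not subtract input; the
#' result here is a plain matrix, not an [HmcExperiment-class], because a
#' difference of rpm tracks no longer sums to 1e6.
#'
#' @param hx IP samples, an [HmcExperiment-class].
#' @param input matching input samples, an [HmcExperiment-class] on the same
#'   grid; a single input column is recycled across all IP samples,
#'   otherwise columns are matched by position.
#' @return numeric matrix, windows x IP samples.
#' @export
rpmMinusInput <- function(hx, input) {
  if (nrow(hx) != nrow(input))
    stop("IP and input experiments must share the window grid")
  ri <- rpm(input)
  if (ncol(ri) == 1) ri <- ri[, rep(1L, ncol(hx)), drop = FALSE]
  if (ncol(ri) != ncol(hx))
    stop("need one input sample, or one per IP sample")
  out <- pmax(rpm(hx) - ri, 0)
  dimnames(out) <- dimnames(rpm(hx))
  out
}

#' Export one sample's normalised track as bedGraph-style TSV
#'
#' Columns: chrom, start (0-based), end, rpm. Values are normalised reads
#' per million per 150 bp window.
#'
#' @param hx an [HmcExperiment-class].
#' @param sample sample name.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeBedGraph <- function(hx, sample, path) {
  if (!sample %in% colnames(hx)) stop("unknown sample: ", sample)
  grid <- rowRanges(hx)
  df <- data.frame(chrom = as.character(seqnames(grid)),
                   start = start(grid) - 1L, end = end(grid),
                   value = signif(rpm(hx)[, sample], 6))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
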