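#' @include AllClasses.R
#' @importFrom rtracklayer import
NULL

#' Read gene models from a GTF/GFF file
#'
#' Imports the annotation with `rtracklayer`, keeps records of the given
#' feature type and returns one gene per unique `gene_id` as a named,
#' sorted `GRanges`.  Records sharing a `gene_id` with identical
#' coordinates are deduplicated; conflicting coordinates raise an error.
#' Strands must be `+` or `-` (a gene's TSS is strand-dependent).
#'
#' @param path GTF or GFF3 file.
#' @param featureType feature type to keep (default `"gene"`).
#' @param attribute name of the attribute holding the gene identifier
#'   (default `"gene_id"`).
#' @return `GRanges` named by gene id, with a `gene_id` metadata column.
#' @seealso [tssPositions()], [assignProximal()]
#' @export
readGeneModels <- function(path, featureType = "gene",
                           attribute = "gene_id") {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  gff <- rtracklayer::import(path)
  if (!is.null(mcols(gff)$type))
    gff <- gff[as.character(mcols(gff)$type) == featureType]
  if (!length(gff))
    stop("no '", featureType, "' records in ", path)
  ids <- mcols(gff)[[attribute]]
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("parse error: missing ", attribute, " attribute on some ",
         featureType, " records")
  ids <- as.character(ids)
  str <- as.character(strand(gff))
  if (any(!str %in% c("+", "-")))
    stop("unknown strand character for gene(s): ",
         paste(unique(ids[!str %in% c("+", "-")]), collapse = ", "))
  key <- paste(ids, as.character(seqnames(gff)), start(gff), end(gff), str)
  gff <- gff[!duplicated(key)]
  ids <- ids[!duplicated(key)]
  if (anyDuplicated(ids))
    stop("duplicate gene_id with conflicting coordinates: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- granges(gff)
  GenomeInfoDb::seqlevels(out) <- sort(GenomeInfoDb::seqlevels(out))
  mcols(out)$gene_id <- ids
  names(out) <- ids
  out[order(as.integer(seqnames(out)), start(out), end(out))]
}

#' Strand-aware transcription start sites
#'
#' The TSS of a plus-strand gene is its leftmost base, of a minus-strand
#' gene its rightmost base.  Positions are returned in 0-based coordinates
#' so that a plus-strand gene occupying `[s, e)` (half-open) has TSS `s`
#' and its minus-strand counterpart TSS `e - 1`.
#'
#' @param genes `GRanges` of gene models (strand `+`/`-`), as returned by
#'   [readGeneModels()].
#' @return named numeric vector of 0-based TSS positions.
#' @export
tssPositions <- function(genes) {
  stopifnot(is(genes, "GRanges"))
  str <- as.character(strand(genes))
  if (any(!str %in% c("+", "-")))
    stop("gene strands must be '+' or '-'")
  tss <- ifelse(str == "+", start(genes) - 1L, end(genes) - 1L)
  names(tss) <- if (!is.null(names(genes))) names(genes)
                else mcols(genes)$gene_id
  tss
}

.peak_midpoints <- function(gr) {
  ## 0-based midpoint of a half-open interval: floor((start0 + end0)/2)
  floor((start(gr) - 1 + end(gr)) / 2)
}

#' Assign peaks to genes with a TSS within a window
#'
#' A (gene, peak) pair is emitted when the peak interval intersects the
#' closed window `[tss - window, tss + window]` around the gene's TSS
#' (at least 1 bp intersection).  The relation is many-to-many.  The
#' signed distance stored per pair is from TSS to peak midpoint, oriented
#' by gene strand (negative = upstream of the gene).  With
#' `mode = "midpoint"` only the peak midpoint is tested against the
#' window, a stricter variant useful for sensitivity analysis.
#'
#' @param peaks a [PeakSet-class].
#' @param genes `GRanges` from [readGeneModels()].
#' @param window bp half-width (> 0); default 10000.
#' @param mode `"interval"` (default) or `"midpoint"`.
#' @return a [ProximalAssignment-class].
#' @examples
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 55000),
#'                                 strand = "+")
#' names(genes) <- "g1"
#' pk <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(45001, 46000)))
#' assignmentPairs(assignProximal(pk, genes, 10000))
#' @export
assignProximal <- function(peaks, genes, window = 10000,
                           mode = c("interval", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(is(peaks, "PeakSet"), window > 0)
  if (!is(genes, "GRanges") || !length(genes))
    stop("cannot assign: empty gene collection")
  tss <- tssPositions(genes)
  ## closed window [tss - w, tss + w] in 0-based positions is the 1-based
  ## closed range [tss - w + 1, tss + w + 1]
  win <- GRanges(seqnames = seqnames(genes),
                 ranges = IRanges(start = tss - window + 1, end = tss + window + 1))
  gr <- peaks@ranges
  query <- if (mode == "interval") granges(gr) else {
    mid0 <- .peak_midpoints(gr)
    GRanges(seqnames = seqnames(gr), ranges = IRanges(mid0 + 1, mid0 + 1))
  }
  hits <- findOverlaps(query, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  mid0 <- .peak_midpoints(gr)[qi]
  sign <- ifelse(as.character(strand(genes))[si] == "+", 1, -1)
  dist <- (mid0 - tss[si]) * sign
  pairs <- data.frame(gene_id = names(genes)[si],
                      peak_id = mcols(gr)$id[qi],
                      distance = as.numeric(dist),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_id, pairs$peak_id), , drop = FALSE]
  rownames(pairs) <- NULL
  new("ProximalAssignment", pairs = pairs, window = window, mode = mode,
      geneIds = names(genes), factorName = factorName(peaks))
}

#' Histogram of peak distances to the nearest TSS
#'
#' Each peak contributes once, at the signed strand-oriented distance from
#' its nearest TSS (ties between equidistant genes broken by lexicographic
#' gene id) to its midpoint.  Distances beyond `[-span, span]` are
#' excluded.  Bins are right-open `[lo, hi)` except the last, which also
#' includes `+span`.
#'
#' @param peaks a [PeakSet-class].
#' @param genes `GRanges` of gene models.
#' @param span bp half-range of the histogram (multiple of `bin`).
#' @param bin bin width in bp.
#' @return list with `breaks` (bin edges), `counts` (per bin), `mids`,
#'   `distances` (named per counted peak), `n_counted`, `n_total`.
#' @export
tssDistanceProfile <- function(peaks, genes, span = 10000, bin = 1000) {
  stopifnot(is(peaks, "PeakSet"))
  if (!is(genes, "GRanges") || !length(genes))
    stop("cannot profile: empty gene collection")
  stopifnot(span > 0, bin > 0, span %% bin == 0)
  tss <- tssPositions(genes)
  gchrom <- as.character(seqnames(genes))
  gstr <- as.character(strand(genes))
  gr <- peaks@ranges
  mids <- .peak_midpoints(gr)
  pchrom <- as.character(seqnames(gr))
  dist <- rep(NA_real_, length(gr))
  for (chrom in unique(pchrom)) {
    gi <- which(gchrom == chrom)
    if (!length(gi)) next
    pi <- which(pchrom == chrom)
    for (k in pi) {
      d <- abs(mids[k] - tss[gi])
      best <- gi[d == min(d)]
      if (length(best) > 1L)
        best <- best[order(names(genes)[best])][1L]
      sign <- if (gstr[best] == "+") 1 else -1
      dist[k] <- (mids[k] - tss[best]) * sign
    }
  }
  names(dist) <- mcols(gr)$id
  counted <- dist[!is.na(dist) & dist >= -span & dist <= span]
  breaks <- seq(-span, span, by = bin)
  idx <- findInterval(counted, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  list(breaks = breaks,
       counts = counts,
       mids = (breaks[-length(breaks)] + breaks[-1L]) / 2,
       distances = counted,
       n_counted = length(counted),
       n_total = length(gr))
}
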