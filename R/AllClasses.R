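#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
NULL

.PEAK_FACTORS <- c("Smad2", "Eomesa")

#' A set of ChIP-seq peaks for one factor
#'
#' `PeakSet` holds the replicate-consensus (or raw) peak calls of one
#' transcription factor on one genome build.  Peaks live in a
#' [GenomicRanges::GRanges] with metadata columns `id` (unique, stable
#' identifiers) and `height` (peak height in reads per million; `NA` when
#' unknown).  Intervals are kept sorted by (chromosome, start, end).
#'
#' @slot ranges a `GRanges` with mcols `id` (character) and `height`
#'   (numeric RPM, `NA` allowed).
#' @slot factorName label of the immunoprecipitated factor, e.g. `"Smad2"`.
#' @slot genomeBuild genome assembly label, e.g. `"Zv9"`.
#'
#' @seealso [readPeaks()], [replicateConsensus()], [sharePeaks()]
#' @export
setClass("PeakSet",
  representation(ranges = "GRanges",
                 factorName = "character",
                 genomeBuild = "character"))

setValidity("PeakSet", function(object) {
  gr <- object@ranges
  msg <- character()
  if (is.null(mcols(gr)$id))
    msg <- c(msg, "peak ranges must carry an 'id' metadata column")
  else if (anyDuplicated(mcols(gr)$id))
    msg <- c(msg, "peak ids must be unique within a PeakSet")
  if (is.null(mcols(gr)$height))
    msg <- c(msg, "peak ranges must carry a 'height' metadata column")
  else {
    h <- mcols(gr)$height
    if (any(!is.na(h) & h < 0))
      msg <- c(msg, "peak heights must be nonnegative")
  }
  if (length(gr) > 1L && is.unsorted(order(as.integer(seqnames(gr)),
                                           start(gr), end(gr))))
    msg <- c(msg, "peaks must be sorted by (chrom, start, end)")
  if (length(object@factorName) != 1L)
    msg <- c(msg, "factorName must be a single string")
  if (length(object@genomeBuild) != 1L)
    msg <- c(msg, "genomeBuild must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param ranges a `GRanges`; metadata columns `id` and `height` are added
#'   (ids auto-assigned as `<factorName>_<rank>`, heights `NA`) when absent.
#' @param factorName factor label.
#' @param genomeBuild genome assembly label.
#' @return a [PeakSet-class] object, sorted.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' PeakSet(gr, factorName = "Smad2", genomeBuild = "Zv9")
#' @export
PeakSet <- function(ranges, factorName = "factorA", genomeBuild = "unknown") {
  if (!is(ranges, "GRanges"))
    stop("'ranges' must be a GRanges")
  GenomeInfoDb::seqlevels(ranges) <- sort(GenomeInfoDb::seqlevels(ranges))
  o <- order(as.integer(seqnames(ranges)), start(ranges), end(ranges))
  ranges <- ranges[o]
  if (is.null(mcols(ranges)$id))
    mcols(ranges)$id <- if (length(ranges))
      paste0(factorName, "_", seq_along(ranges)) else character()
  if (is.null(mcols(ranges)$height))
    mcols(ranges)$height <- rep(NA_real_, length(ranges))
  new("PeakSet", ranges = ranges, factorName = factorName,
      genomeBuild = genomeBuild)
}

#' Analysis parameters
#'
#' Central container for the tunable parameters of the integrative
#' analysis.  Defaults follow the original study design: peaks are assigned
#' to genes whose transcription start site lies within +/- 10 kb
#' (`proximalWindow`), differential-expression calls use P <= 0.02 for the
#' microarray table and P <= 0.05 for the RNA-seq table, and motif scanning
#' reports windows whose log-odds score reaches 80% of the matrix's score
#' range.
#'
#' @slot proximalWindow bp half-width of the TSS window (default 10000).
#' @slot minOverlap minimum bp overlap for two peaks to count as shared
#'   (default 1).
#' @slot dePThresholdArray P cutoff for microarray DE tables (default 0.02).
#' @slot dePThresholdRnaseq P cutoff for RNA-seq DE tables (default 0.05).
#' @slot motifRelThreshold relative PWM score threshold in \[0,1\]
#'   (default 0.80).
#' @slot pseudocount PWM pseudocount, distributed by background frequency
#'   (default 0.8).
#' @slot background length-4 base frequencies (A,C,G,T) summing to 1.
#' @export
setClass("AnalysisConfig",
  representation(proximalWindow = "numeric",
                 minOverlap = "numeric",
                 dePThresholdArray = "numeric",
                 dePThresholdRnaseq = "numeric",
                 motifRelThreshold = "numeric",
                 pseudocount = "numeric",
                 background = "numeric"),
  prototype(proximalWindow = 10000,
            minOverlap = 1,
            dePThresholdArray = 0.02,
            dePThresholdRnaseq = 0.05,
            motifRelThreshold = 0.80,
            pseudocount = 0.8,
            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@proximalWindow <= 0) msg <- c(msg, "proximalWindow must be > 0")
  if (object@minOverlap < 1) msg <- c(msg, "minOverlap must be >= 1")
  for (s in c("dePThresholdArray", "dePThresholdRnaseq")) {
    v <- slot(object, s)
    if (v <= 0 || v >= 1) msg <- c(msg, paste(s, "must be in (0,1)"))
  }
  if (object@motifRelThreshold < 0 || object@motifRelThreshold > 1)
    msg <- c(msg, "motifRelThreshold must be in [0,1]")
  if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be positive")
  if (length(object@background) != 4L)
    msg <- c(msg, "background must have 4 entries (A,C,G,T)")
  else if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background frequencies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param ... named slots overriding the defaults (see slots above).
#' @return an `AnalysisConfig` object.
#' @examples
#' AnalysisConfig(proximalWindow = 5000)
#' @export
AnalysisConfig <- function(...) new("AnalysisConfig", ...)

#' Peak-to-gene proximal assignment
#'
#' Many-to-many relation between peaks and the genes whose TSS window they
#' intersect; see [assignProximal()].  The `pairs` slot is a data.frame with
#' columns `gene_id`, `peak_id` and `distance` (signed, strand-oriented bp
#' from TSS to peak midpoint; negative = upstream of the gene).
#'
#' @slot pairs data.frame of (gene_id, peak_id, distance).
#' @slot window bp half-width of the window used.
#' @slot mode `"interval"` (whole peak vs window) or `"midpoint"`.
#' @slot geneIds the full gene universe the assignment was built against.
#' @slot factorName factor label inherited from the peak set.
#' @export
setClass("ProximalAssignment",
  representation(pairs = "data.frame",
                 window = "numeric",
                 mode = "character",
                 geneIds = "character",
                 factorName = "character"))

setValidity("ProximalAssignment", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("gene_id", "peak_id", "distance") %in% names(p)))
    msg <- c(msg, "pairs must have columns gene_id, peak_id, distance")
  else {
    ## the signed distance is TSS -> peak midpoint; in interval mode a wide
    ## peak can intersect the window while its midpoint lies slightly
    ## outside, so the bound is not enforced as a hard invariant here
    if (nrow(p) && !all(p$gene_id %in% object@geneIds))
      msg <- c(msg, "pairs reference genes outside the gene universe")
  }
  if (length(msg)) msg else TRUE
})

#' Peak sharing between two factors
#'
#' Result of [sharePeaks()]: identifiers of factor-A peaks overlapping at
#' least one factor-B peak (`sharedA`), the complement (`onlyA`), the
#' reverse classification for B, and the full list of overlapping (A,B)
#' id pairs.
#'
#' @slot sharedA,onlyA,sharedB,onlyB character vectors of peak ids.
#' @slot pairList data.frame with columns `a_id`, `b_id`.
#' @slot factorA,factorB factor labels.
#' @slot minOverlap the bp overlap threshold used.
#' @export
setClass("PeakSharing",
  representation(sharedA = "character", onlyA = "character",
                 sharedB = "character", onlyB = "character",
                 pairList = "data.frame",
                 factorA = "character", factorB = "character",
                 minOverlap = "numeric"))

setValidity("PeakSharing", function(object) {
  msg <- character()
  if (length(intersect(object@sharedA, object@onlyA)))
    msg <- c(msg, "sharedA and onlyA must be disjoint")
  if (length(intersect(object@sharedB, object@onlyB)))
    msg <- c(msg, "sharedB and onlyB must be disjoint")
  if (!all(c("a_id", "b_id") %in% names(object@pairList)))
    msg <- c(msg, "pairList must have columns a_id, b_id")
  if (length(msg)) msg else TRUE
})

#' Per-gene binding class for two factors
#'
#' Gene-level classification produced by [geneBindingClasses()].  Every
#' gene in the universe gets exactly one label: `A_only` (proximal peaks of
#' factor A only), `common` (proximal peaks of both factors that overlap
#' each other), `uncommon` (proximal peaks of both factors, none
#' overlapping), `B_only`, or `none`.
#'
#' @slot classes named factor over the gene universe with levels
#'   A_only, common, uncommon, B_only, none.
#' @slot factorA,factorB factor labels substituting for A and B.
#' @export
setClass("BindingClassMap",
  representation(classes = "factor",
                 factorA = "character", factorB = "character"))

.BINDING_CLASS_LEVELS <- c("A_only", "common", "uncommon", "B_only", "none")

setValidity("BindingClassMap", function(object) {
  msg <- character()
  if (!identical(levels(object@classes), .BINDING_CLASS_LEVELS))
    msg <- c(msg, paste("class levels must be",
                        paste(.BINDING_CLASS_LEVELS, collapse = ", ")))
  if (is.null(names(object@classes)) || anyDuplicated(names(object@classes)))
    msg <- c(msg, "classes must be named by unique gene ids")
  if (anyNA(object@classes))
    msg <- c(msg, "every gene must be classified (no NA labels)")
  if (length(msg)) msg else TRUE
})

#' Position frequency matrix with log-odds scoring parameters
#'
#' A JASPAR-style position frequency matrix (base counts per motif column)
#' together with the background model and pseudocount used to derive its
#' log-odds (position weight) matrix.  The log-odds score of base b at
#' column j is
#' `log2((counts[b,j] + pseudocount * background[b]) / (colTotal_j + pseudocount) / background[b])`
#' and window scores are rescaled to a relative score in \[0,1\] between
#' the matrix's minimum and maximum attainable scores.
#'
#' @slot motifID motif identifier, e.g. `"MA0479.1"`.
#' @slot name motif name, e.g. `"FOXH1"`.
#' @slot counts 4 x L nonnegative matrix, rows A, C, G, T.
#' @slot background named length-4 base frequencies.
#' @slot pseudocount positive real, distributed by background frequency.
#' @seealso [readJaspar()], [scanSequence()]
#' @export
setClass("PFMotif",
  representation(motifID = "character", name = "character",
                 counts = "matrix", background = "numeric",
                 pseudocount = "numeric"))

setValidity("PFMotif", function(object) {
  msg <- character()
  cts <- object@counts
  if (!identical(rownames(cts), c("A", "C", "G", "T")))
    msg <- c(msg, "counts rows must be named A, C, G, T")
  if (ncol(cts) < 4L)
    msg <- c(msg, "motif length must be >= 4 columns")
  if (any(cts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (ncol(cts) && any(colSums(cts) <= 0))
    msg <- c(msg, "every column total must be > 0")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname PFMotif-class
#' @param counts 4 x L matrix (rows A,C,G,T or set by `rownames`).
#' @param motifID,name identifier and name labels.
#' @param background base frequencies (default uniform).
#' @param pseudocount positive pseudocount (default 0.8).
#' @return a `PFMotif`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0), 4, 6, dimnames = list(c("A","C","G","T"), NULL))
#' PFMotif(m, motifID = "toy")
#' @export
PFMotif <- function(counts, motifID = "motif", name = motifID,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) == 4L)
    rownames(counts) <- c("A", "C", "G", "T")
  storage.mode(counts) <- "double"
  if (is.null(names(background)) && length(background) == 4L)
    names(background) <- c("A", "C", "G", "T")
  new("PFMotif", motifID = motifID, name = name, counts = counts,
      background = background[c("A", "C", "G", "T")],
      pseudocount = pseudocount)
}

#' Chi-square contingency-table result
#'
#' Result of a Pearson chi-square test on a 2 x 2 table, as used for
#' binding-class / responsiveness association and between-peak-set motif
#' enrichment.  `foldEnrichment` is observed/expected for the focal
#' (top-left) cell, except for motif-set enrichment where it is the ratio
#' of hit rates (documented in `method`).  `oddsRatio` is the sample odds
#' ratio of the table.
#'
#' @slot observed,expected 2 x 2 matrices.
#' @slot statistic Pearson chi-square statistic (no continuity correction).
#' @slot df degrees of freedom (1).
#' @slot pValue upper-tail chi-square P value.
#' @slot foldEnrichment focal-cell fold enrichment.
#' @slot oddsRatio sample odds ratio (O11 O22)/(O12 O21).
#' @slot method short description of how the table was formed.
#' @export
setClass("ContingencyResult",
  representation(observed = "matrix", expected = "matrix",
                 statistic = "numeric", df = "numeric", pValue = "numeric",
                 foldEnrichment = "numeric", oddsRatio = "numeric",
                 method = "character"))

#' Cross-species conservation table
#'
#' Per reference-gene membership flags for each species' (projected)
#' proximal-bound gene set, with the derived conservation class = number of
#' non-reference species in which the gene is bound.
#'
#' @slot membership data.frame with column `gene_id`, one logical column
#'   per species, and integer `class`.
#' @slot referenceName name of the reference species/set.
#' @slot speciesNames names of the non-reference species columns.
#' @export
setClass("ConservationTable",
  representation(membership = "data.frame",
                 referenceName = "character",
                 speciesNames = "character"))

setValidity("ConservationTable", function(object) {
  m <- object@membership
  msg <- character()
  need <- c("gene_id", object@speciesNames, "class")
  if (!all(need %in% names(m)))
    msg <- c(msg, "membership must have gene_id, one column per species, class")
  else {
    flags <- as.matrix(m[, object@speciesNames, drop = FALSE])
    if (nrow(m) && !identical(as.integer(rowSums(flags)), as.integer(m$class)))
      msg <- c(msg, "class must equal the number of species flags set")
  }
  if (length(msg)) msg else TRUE
})
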