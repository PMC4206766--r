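#' @include AllClasses.R peaks.R
NULL

#' Classify peaks of two factors into shared and factor-specific sets
#'
#' A factor-A peak is *shared* when it overlaps at least one factor-B peak
#' by `minOverlap` bp or more (strand ignored), and vice versa; the
#' remaining peaks are factor-specific.  All overlapping (A, B) id pairs
#' are recorded.
#'
#' @param setA,setB [PeakSet-class] objects on the same genome build.
#' @param minOverlap minimum bp overlap (default 1).
#' @return a [PeakSharing-class].
#' @examples
#' a <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)),
#'              factorName = "Smad2")
#' b <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)),
#'              factorName = "Eomesa")
#' sharingCounts(sharePeaks(a, b))
#' @export
sharePeaks <- function(setA, setB, minOverlap = 1L) {
  stopifnot(is(setA, "PeakSet"), is(setB, "PeakSet"), minOverlap >= 1)
  if (!identical(genomeBuild(setA), genomeBuild(setB)))
    stop("configuration error: peak-set genome builds differ (",
         genomeBuild(setA), " vs ", genomeBuild(setB), ")")
  hits <- findOverlaps(setA@ranges, setB@ranges,
                       minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  aIds <- peakIds(setA)
  bIds <- peakIds(setB)
  pairList <- data.frame(
    a_id = aIds[S4Vectors::queryHits(hits)],
    b_id = bIds[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  sharedA <- unique(pairList$a_id)
  sharedB <- unique(pairList$b_id)
  new("PeakSharing",
      sharedA = sharedA, onlyA = setdiff(aIds, sharedA),
      sharedB = sharedB, onlyB = setdiff(bIds, sharedB),
      pairList = pairList,
      factorA = factorName(setA), factorB = factorName(setB),
      minOverlap = as.numeric(minOverlap))
}

#' Gene-level binding classes for two factors
#'
#' Combines the proximal assignments of two factors with their peak
#' sharing into one label per gene of the universe:
#' \describe{
#'   \item{common}{the gene has at least one proximal A-peak and one
#'     proximal B-peak that overlap each other (binding at the same
#'     coordinates).  A gene with any such overlapping pair is common even
#'     if it also has non-overlapping pairs.}
#'   \item{uncommon}{proximal peaks of both factors, but no overlapping
#'     (A, B) pair.}
#'   \item{A_only / B_only}{proximal peaks of one factor only.}
#'   \item{none}{no proximal peak of either factor.}
#' }
#'
#' @param assignA,assignB [ProximalAssignment-class] objects built against
#'   the same gene set.
#' @param sharing a [PeakSharing-class] built from the same peak sets
#'   (A first).
#' @param universe character vector of gene ids to classify; every gene in
#'   the assignments must belong to it.
#' @return a [BindingClassMap-class].
#' @export
geneBindingClasses <- function(assignA, assignB, sharing, universe) {
  stopifnot(is(assignA, "ProximalAssignment"),
            is(assignB, "ProximalAssignment"),
            is(sharing, "PeakSharing"))
  universe <- unique(as.character(universe))
  pa <- assignmentPairs(assignA)
  pb <- assignmentPairs(assignB)
  out <- setdiff(unique(c(pa$gene_id, pb$gene_id)), universe)
  if (length(out))
    stop("gene(s) in assignment absent from universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  genesA <- unique(pa$gene_id)
  genesB <- unique(pb$gene_id)
  both <- intersect(genesA, genesB)

  ## a gene is common when one of its A-peaks and one of its B-peaks form
  ## an overlapping pair: join A pairs -> sharing pairs -> B pairs
  pl <- sharingPairs(sharing)
  ab <- merge(pa[c("gene_id", "peak_id")], pl,
              by.x = "peak_id", by.y = "a_id")
  abg <- merge(ab[c("gene_id", "b_id")], pb[c("gene_id", "peak_id")],
               by.x = c("gene_id", "b_id"), by.y = c("gene_id", "peak_id"))
  commonGenes <- intersect(unique(abg$gene_id), both)

  cls <- rep("none", length(universe))
  names(cls) <- universe
  cls[intersect(genesA, universe)] <- "A_only"
  cls[intersect(genesB, universe)] <- "B_only"
  cls[both] <- "uncommon"
  cls[commonGenes] <- "common"
  new("BindingClassMap",
      classes = factor(cls, levels = .BINDING_CLASS_LEVELS),
      factorA = assignA@factorName, factorB = assignB@factorName)
}
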