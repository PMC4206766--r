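#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname PeakSet-class
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)

#' @rdname PeakSet-class
#' @export
setMethod("factorName", "PeakSet", function(x) x@factorName)

#' @rdname PeakSet-class
#' @export
setMethod("genomeBuild", "PeakSet", function(x) x@genomeBuild)

#' @rdname PeakSet-class
#' @export
setMethod("peakIds", "PeakSet", function(x) mcols(x@ranges)$id)

#' @rdname PeakSet-class
#' @export
setMethod("peakHeights", "PeakSet", function(x) {
  h <- mcols(x@ranges)$height
  names(h) <- mcols(x@ranges)$id
  h
})

#' @rdname PeakSet-class
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", object@factorName, "on", object@genomeBuild, "\n")
  cat(" ", length(object), "peaks on",
      length(unique(as.character(seqnames(object@ranges)))), "chromosome(s)\n")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  proximalWindow:     ", object@proximalWindow, "bp\n")
  cat("  minOverlap:         ", object@minOverlap, "bp\n")
  cat("  dePThresholdArray:  ", object@dePThresholdArray, "\n")
  cat("  dePThresholdRnaseq: ", object@dePThresholdRnaseq, "\n")
  cat("  motifRelThreshold:  ", object@motifRelThreshold, "\n")
  cat("  pseudocount:        ", object@pseudocount, "\n")
  cat("  background:         ",
      paste(sprintf("%s=%.3g", names(object@background), object@background),
            collapse = " "), "\n")
})

#' @rdname ProximalAssignment-class
#' @export
setMethod("assignmentPairs", "ProximalAssignment", function(x) x@pairs)

#' @rdname ProximalAssignment-class
#' @export
setMethod("boundGenes", "ProximalAssignment",
          function(x) sort(unique(x@pairs$gene_id)))

setMethod("show", "ProximalAssignment", function(object) {
  cat("ProximalAssignment:", object@factorName,
      sprintf("(window +/- %d bp, %s mode)\n",
              as.integer(object@window), object@mode))
  cat(" ", nrow(object@pairs), "gene-peak pairs;",
      length(unique(object@pairs$gene_id)), "of", length(object@geneIds),
      "genes proximally bound\n")
})

#' @rdname PeakSharing-class
#' @export
setMethod("sharingCounts", "PeakSharing", function(x) {
  data.frame(
    factor = c(x@factorA, x@factorB),
    n_total = c(length(x@sharedA) + length(x@onlyA),
                length(x@sharedB) + length(x@onlyB)),
    n_shared = c(length(x@sharedA), length(x@sharedB)),
    n_only = c(length(x@onlyA), length(x@onlyB)),
    stringsAsFactors = FALSE)
})

#' @rdname PeakSharing-class
#' @export
setMethod("sharingPairs", "PeakSharing", function(x) x@pairList)

setMethod("show", "PeakSharing", function(object) {
  cat("PeakSharing:", object@factorA, "vs", object@factorB,
      sprintf("(min overlap %d bp)\n", as.integer(object@minOverlap)))
  print(sharingCounts(object), row.names = FALSE)
})

#' @rdname BindingClassMap-class
#' @export
setMethod("bindingClasses", "BindingClassMap", function(x) x@classes)

#' @rdname BindingClassMap-class
#' @export
setMethod("classCounts", "BindingClassMap", function(x) table(x@classes))

#' @rdname BindingClassMap-class
#' @export
setMethod("length", "BindingClassMap", function(x) length(x@classes))

setMethod("show", "BindingClassMap", function(object) {
  cat("BindingClassMap (A = ", object@factorA, ", B = ", object@factorB,
      ")\n", sep = "")
  print(classCounts(object))
})

#' @rdname PFMotif-class
#' @export
setMethod("motifLength", "PFMotif", function(x) ncol(x@counts))

#' @rdname PFMotif-class
#' @export
setMethod("logOddsMatrix", "PFMotif", function(x) {
  cts <- x@counts
  bg <- x@background
  tot <- colSums(cts)
  p <- sweep(cts + x@pseudocount * bg, 2, tot + x@pseudocount, "/")
  log2(p / bg)
})

#' @rdname PFMotif-class
#' @export
setMethod("motifConsensus", "PFMotif", function(x) {
  paste(rownames(x@counts)[apply(x@counts, 2, which.max)], collapse = "")
})

setMethod("show", "PFMotif", function(object) {
  cat("PFMotif", object@motifID,
      if (nzchar(object@name) && object@name != object@motifID) object@name
      else "", "\n")
  cat("  length", motifLength(object), "bp; consensus",
      motifConsensus(object), "\n")
  cat("  pseudocount", object@pseudocount, "; background",
      paste(sprintf("%.2f", object@background), collapse = "/"), "\n")
})

setMethod("show", "ContingencyResult", function(object) {
  cat("ContingencyResult (", object@method, ")\n", sep = "")
  print(object@observed)
  cat(sprintf("  chi2 = %.4g on %d df, P = %.3g\n",
              object@statistic, as.integer(object@df), object@pValue))
  cat(sprintf("  fold enrichment = %.3g, odds ratio = %.3g\n",
              object@foldEnrichment, object@oddsRatio))
})

#' @rdname ConservationTable-class
#' @export
setMethod("conservationSummary", "ConservationTable", function(x) {
  cls <- factor(x@membership$class, levels = 0:length(x@speciesNames))
  as.data.frame(table(class = cls), responseName = "n_genes")
})

setMethod("show", "ConservationTable", function(object) {
  cat("ConservationTable: reference", object@referenceName, "vs",
      paste(object@speciesNames, collapse = ", "), "\n")
  print(conservationSummary(object), row.names = FALSE)
})
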