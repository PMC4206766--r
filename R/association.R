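#' @include AllClasses.R
NULL

#' Read a differential-expression table
#'
#' Tab-separated table with a header naming `gene_id`, `log2fc` and
#' `pvalue`.  Gene ids must be unique and P values lie in \[0, 1\].
#'
#' @param path TSV file.
#' @param provenance `"array"` or `"rnaseq"`, recorded as an attribute.
#' @return data.frame with columns gene_id, log2fc, pvalue and attribute
#'   `provenance`.
#' @export
readDETable <- function(path, provenance = c("array", "rnaseq")) {
  provenance <- match.arg(provenance)
  if (!file.exists(path))
    stop("DE table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id rows in DE table")
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    stop("P values must lie in [0, 1]")
  attr(df, "provenance") <- provenance
  df
}

#' Responsive gene sets from a DE table
#'
#' Up-regulated genes have `pvalue <= pThreshold` (inclusive) and
#' `log2fc > 0`; down-regulated the same with `log2fc < 0`.  Genes with
#' zero fold change belong to neither set.
#'
#' @param table data.frame with columns gene_id, log2fc, pvalue.
#' @param pThreshold P cutoff in (0, 1).
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @examples
#' de <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.2, -0.5),
#'                  pvalue = c(0.01, 0.02))
#' responsiveSets(de, 0.02, "up")
#' @export
responsiveSets <- function(table, pThreshold, direction = c("up", "down")) {
  direction <- match.arg(direction)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(table)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  stopifnot(pThreshold > 0, pThreshold < 1)
  sel <- table$pvalue <= pThreshold &
    if (direction == "up") table$log2fc > 0 else table$log2fc < 0
  table$gene_id[sel & !is.na(sel)]
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Plain Pearson statistic without continuity correction,
#' `sum((O - E)^2 / E)` with `E = outer(rowSums, colSums) / N`, compared
#' to the upper tail of the chi-square distribution with 1 df.  The focal
#' cell for fold enrichment is the top-left cell (observed/expected).
#'
#' @param counts 2 x 2 matrix of nonnegative counts; all marginals must be
#'   positive.
#' @return a [ContingencyResult-class].
#' @examples
#' chiSquare2x2(matrix(c(10, 90, 30, 70), 2, byrow = TRUE))
#' @export
chiSquare2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L)))
    stop("counts must be a 2 x 2 matrix")
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be nonnegative and non-missing")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("chi-square undefined: a marginal total is zero")
  N <- sum(counts)
  expected <- outer(rs, cs) / N
  stat <- sum((counts - expected)^2 / expected)
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  new("ContingencyResult",
      observed = counts, expected = expected,
      statistic = stat, df = 1,
      pValue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      foldEnrichment = counts[1, 1] / expected[1, 1],
      oddsRatio = or,
      method = "Pearson chi-square, no continuity correction")
}

#' Association between a binding class and a responsive gene set
#'
#' Builds the 2 x 2 table (in/out of the focal binding class) x (in/out of
#' the responsive set) over the gene universe and applies
#' [chiSquare2x2()].  The focal cell (focal class AND responsive) is
#' top-left, so `foldEnrichment` reads as enrichment of responsive genes
#' in the focal class.
#'
#' @param classes a [BindingClassMap-class] (or named factor/character of
#'   class labels).
#' @param responsive character vector of responsive gene ids, a subset of
#'   the universe.
#' @param universe character vector of gene ids to tabulate over.
#' @param focalClass the class label of interest, e.g. `"common"`.
#' @return a [ContingencyResult-class].
#' @export
bindingResponseAssociation <- function(classes, responsive, universe,
                                       focalClass) {
  if (is(classes, "BindingClassMap")) classes <- bindingClasses(classes)
  if (is.null(names(classes)))
    stop("'classes' must be named by gene id")
  universe <- unique(as.character(universe))
  responsive <- unique(as.character(responsive))
  if (length(out <- setdiff(responsive, universe)))
    stop("responsive gene(s) outside universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  if (!focalClass %in% as.character(classes))
    stop("focal class '", focalClass, "' not present in the class map")
  lab <- as.character(classes[universe])
  lab[is.na(lab)] <- "none"
  inFocal <- lab == focalClass
  inResp <- universe %in% responsive
  obs <- matrix(c(sum(inFocal & inResp), sum(inFocal & !inResp),
                  sum(!inFocal & inResp), sum(!inFocal & !inResp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(focalClass, paste0("not_", focalClass)),
                                c("responsive", "not_responsive")))
  res <- chiSquare2x2(obs)
  res@method <- paste0("binding-class association (focal = ", focalClass, ")")
  res
}

#' Fold enrichment of a term set within a gene set
#'
#' `fold = (|gene_set intersect term_set| / |gene_set|) /
#' (|term_set| / |universe|)`, with a two-sided exact hypergeometric
#' (Fisher) P value.
#'
#' @param geneSet,termSet character vectors, subsets of `universe`.
#' @param universe character vector of background gene ids.
#' @return list with `fold`, `pValue`, `overlap`, `nGeneSet`, `nTermSet`,
#'   `nUniverse`.
#' @examples
#' u <- paste0("g", 1:1000)
#' termFoldEnrichment(u[1:50], u[c(1:20, 101:180)], u)
#' @export
termFoldEnrichment <- function(geneSet, termSet, universe) {
  universe <- unique(as.character(universe))
  geneSet <- unique(as.character(geneSet))
  termSet <- unique(as.character(termSet))
  if (!length(geneSet) || !length(termSet))
    stop("geneSet and termSet must be nonempty")
  if (length(setdiff(geneSet, universe)) ||
      length(setdiff(termSet, universe)))
    stop("geneSet and termSet must be subsets of the universe")
  a <- length(intersect(geneSet, termSet))
  fold <- (a / length(geneSet)) / (length(termSet) / length(universe))
  tab <- matrix(c(a, length(geneSet) - a,
                  length(termSet) - a,
                  length(universe) - length(geneSet) - length(termSet) + a),
                nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(fold = fold, pValue = p, overlap = a,
       nGeneSet = length(geneSet), nTermSet = length(termSet),
       nUniverse = length(universe))
}

#' ChIP-qPCR percent input
#'
#' Converts qPCR cycle thresholds to percent of input chromatin:
#' `100 * efficiency^((ct_input - log(dilution, efficiency)) - ct_target)`.
#' The input Ct is first adjusted for its dilution factor.
#'
#' @param ctTarget Ct of the ChIP sample.
#' @param ctInput Ct of the (diluted) input sample.
#' @param dilution input dilution factor (default 1 = undiluted).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return percent input (numeric).
#' @export
percentInput <- function(ctTarget, ctInput, dilution = 1, efficiency = 2) {
  stopifnot(dilution > 0, efficiency > 1)
  100 * efficiency^((ctInput - log(dilution, base = efficiency)) - ctTarget)
}

#' qPCR fold enrichment over a control ChIP
#'
#' Ratio of percent-input values, ChIP over control (e.g. IgG).
#'
#' @param percentInputChip,percentInputControl positive percent-input
#'   values.
#' @return fold enrichment (numeric).
#' @examples
#' qpcrFoldEnrichment(0.8, 0.1)
#' @export
qpcrFoldEnrichment <- function(percentInputChip, percentInputControl) {
  if (any(percentInputChip <= 0) || any(percentInputControl <= 0))
    stop("percent-input values must be positive")
  percentInputChip / percentInputControl
}
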