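#' @include AllClasses.R
NULL

#' Read an ortholog map
#'
#' Three-column tab-separated table (`source_gene`, `target_gene`,
#' `homology_type`), with or without a header; duplicate (source, target)
#' pairs are collapsed.  Homology types are `one2one`, `one2many`,
#' `many2many`.
#'
#' @param path TSV file.
#' @return data.frame with columns source_gene, target_gene, homology_type.
#' @export
readOrthologMap <- function(path) {
  if (!file.exists(path))
    stop("ortholog map not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("source", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = hasHeader,
                          stringsAsFactors = FALSE,
                          col.names = c("source_gene", "target_gene",
                                        "homology_type"))
  bad <- setdiff(unique(df$homology_type),
                 c("one2one", "one2many", "many2many"))
  if (length(bad))
    stop("unknown homology type(s): ", paste(bad, collapse = ", "))
  df[!duplicated(df[c("source_gene", "target_gene")]), , drop = FALSE]
}

#' Project a foreign gene set onto reference gene ids
#'
#' Returns the union of reference (target) genes over all ortholog-map
#' records whose source gene belongs to the input set; input genes with no
#' record are reported as unmapped.  By default all homology types
#' contribute ("orthologues and possible orthologues"); restrict with
#' `homologyTypes` for sensitivity analysis.
#'
#' @param genes character vector of foreign gene ids.
#' @param map ortholog map data.frame from [readOrthologMap()] (or with
#'   the same columns).
#' @param homologyTypes homology types to use (default all three).
#' @return list with `genes` (sorted unique reference ids), `unmapped`
#'   (foreign inputs without a usable record) and `nUnmapped`.
#' @examples
#' map <- data.frame(source_gene = "m1", target_gene = "z1",
#'                   homology_type = "one2one")
#' projectGeneSet("m1", map)$genes
#' @export
projectGeneSet <- function(genes, map,
                          homologyTypes = c("one2one", "one2many",
                                            "many2many")) {
  stopifnot(all(c("source_gene", "target_gene", "homology_type") %in%
                  names(map)))
  genes <- unique(as.character(genes))
  map <- map[map$homology_type %in% homologyTypes, , drop = FALSE]
  used <- map[map$source_gene %in% genes, , drop = FALSE]
  unmapped <- setdiff(genes, used$source_gene)
  list(genes = sort(unique(used$target_gene)),
       unmapped = sort(unmapped),
       nUnmapped = length(unmapped))
}

#' Venn partition of 2-4 gene sets
#'
#' Counts every nonempty membership pattern of the union of the given
#' sets.  Pattern names join the member set names with `&` (e.g.
#' `"zebrafish&human"`); the patterns are disjoint and their counts sum
#' to the size of the union.
#'
#' @param sets named list of 2-4 character vectors; names must be unique.
#' @return named integer vector of pattern counts (all `2^k - 1` patterns,
#'   including zero counts).
#' @examples
#' vennPartition(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
vennPartition <- function(sets) {
  stopifnot(is.list(sets))
  k <- length(sets)
  if (k < 2L || k > 4L)
    stop("vennPartition requires between 2 and 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must have unique nonempty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(p) {
    if (!length(universe)) return(0L)
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  names(counts) <- apply(patterns, 1L, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  counts
}

#' Cross-species conservation classes for a reference gene set
#'
#' For each gene of the reference set, records membership of every
#' projected foreign set, and derives the conservation class as the number
#' of non-reference species in which the gene is also proximally bound.
#'
#' @param referenceSet character vector of reference gene ids.
#' @param otherSets named list of gene-id vectors already projected onto
#'   reference ids (see [projectGeneSet()]).
#' @param referenceName label for the reference set.
#' @return a [ConservationTable-class].
#' @export
conservationClasses <- function(referenceSet, otherSets,
                                referenceName = "reference") {
  stopifnot(is.list(otherSets), length(otherSets) >= 1L)
  if (is.null(names(otherSets)) || anyDuplicated(names(otherSets)))
    stop("otherSets must have unique names")
  referenceSet <- sort(unique(as.character(referenceSet)))
  flags <- vapply(otherSets, function(s) referenceSet %in% s,
                  logical(length(referenceSet)))
  if (length(referenceSet) == 1L)
    flags <- matrix(flags, nrow = 1L,
                    dimnames = list(NULL, names(otherSets)))
  membership <- data.frame(gene_id = referenceSet, flags,
                           class = as.integer(rowSums(flags)),
                           stringsAsFactors = FALSE)
  new("ConservationTable", membership = membership,
      referenceName = referenceName, speciesNames = names(otherSets))
}
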