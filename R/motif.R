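#' @include AllClasses.R
#' @importFrom Biostrings readDNAStringSet DNAStringSet
NULL

#' Read a JASPAR position frequency matrix
#'
#' Parses the JASPAR text format: a header line `>motifID name` followed
#' by four rows (A, C, G, T) of counts, with or without the bracketed
#' row style (`A  [ 1 2 3 ]`).  Files holding several motifs are allowed;
#' `motifID` selects one (default: the first).
#'
#' @param path JASPAR-format file.
#' @param motifID optional motif id to select.
#' @param background,pseudocount scoring parameters stored in the result
#'   (defaults: uniform background, pseudocount 0.8).
#' @return a [PFMotif-class].
#' @export
readJaspar <- function(path, motifID = NULL,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0.8) {
  if (!file.exists(path))
    stop("motif file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads))
    stop("parse error: no JASPAR header line ('>motifID name') in ", path)
  bounds <- c(heads, length(lines) + 1L)
  blocks <- lapply(seq_along(heads), function(i)
    lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)])
  hdr <- sub("^>", "", lines[heads])
  ids <- vapply(strsplit(hdr, "\\s+"), `[[`, character(1), 1L)
  pick <- if (is.null(motifID)) 1L else match(motifID, ids)
  if (is.na(pick))
    stop("motif '", motifID, "' not found in ", path)
  block <- blocks[[pick]]
  if (length(block) != 4L)
    stop("parse error: motif ", ids[pick], " has ", length(block),
         " count rows, expected 4 (A, C, G, T)")
  rows <- lapply(block, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(vals))
      stop("parse error: non-numeric count in motif ", ids[pick])
    vals
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("parse error: count rows of unequal length in motif ", ids[pick])
  counts <- do.call(rbind, rows)
  if (any(counts < 0))
    stop("negative counts in motif ", ids[pick])
  rownames(counts) <- c("A", "C", "G", "T")
  nm <- strsplit(hdr[pick], "\\s+")[[1L]]
  PFMotif(counts, motifID = ids[pick],
          name = if (length(nm) > 1L) nm[2L] else ids[pick],
          background = background, pseudocount = pseudocount)
}

#' Write a PFMotif in JASPAR text format
#'
#' @param x a [PFMotif-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeJaspar <- function(x, path) {
  stopifnot(is(x, "PFMotif"))
  cts <- x@counts
  body <- vapply(rownames(cts), function(b)
    sprintf("%s  [ %s ]", b,
            paste(format(cts[b, ], trim = TRUE, scientific = FALSE),
                  collapse = " ")),
    character(1))
  writeLines(c(paste0(">", x@motifID, " ", x@name), body), path)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.score_windows <- function(M, idx) {
  ## M: 4 x L log-odds; idx: base indices (1..4, NA for N) of the sequence.
  ## Returns the score of every length-L window (NA when it contains N).
  L <- ncol(M)
  n <- length(idx)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  na <- logical(nw)
  for (j in seq_len(L)) {
    v <- M[cbind(idx[j:(nw + j - 1L)], j)]
    na <- na | is.na(v)
    v[is.na(v)] <- 0
    s <- s + v
  }
  s[na] <- NA_real_
  s
}

#' Scan a DNA sequence with a PWM on both strands
#'
#' Scores every length-L window of the sequence with the motif's log-odds
#' matrix on the forward strand, and with its reverse complement for the
#' minus strand, then reports windows whose relative score
#' `(raw - min) / (max - min)` reaches `relThreshold`.  Offsets are
#' 0-based forward-strand window starts regardless of hit strand; windows
#' containing `N` are skipped.  Results are ordered by (offset, strand)
#' with `+` before `-`.
#'
#' @param pfm a [PFMotif-class].
#' @param seq character string or `DNAString` over A, C, G, T, N.
#' @param relThreshold relative score threshold in \[0, 1\].
#' @return data.frame with columns `offset`, `strand`, `raw_score`,
#'   `rel_score`; zero rows when the sequence is shorter than the motif.
#' @examples
#' pfm <- PFMotif(matrix(c(9,0,0,0, 0,9,0,0, 0,0,9,0, 0,0,0,9), 4, 4,
#'                dimnames = list(c("A","C","G","T"), NULL)))
#' scanSequence(pfm, "TTACGTTT", relThreshold = 0.9)
#' @export
scanSequence <- function(pfm, seq, relThreshold = 0.8) {
  stopifnot(is(pfm, "PFMotif"), relThreshold >= 0, relThreshold <= 1)
  seq <- toupper(as.character(seq))
  bases <- strsplit(seq, "")[[1L]]
  if (length(bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N"))))
    stop("sequence contains invalid characters: ",
         paste(bad, collapse = ", "))
  M <- logOddsMatrix(pfm)
  L <- ncol(M)
  idx <- match(bases, c("A", "C", "G", "T"))
  empty <- data.frame(offset = integer(), strand = character(),
                      raw_score = numeric(), rel_score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(idx) < L) return(empty)
  minS <- sum(apply(M, 2, min))
  maxS <- sum(apply(M, 2, max))
  rng <- maxS - minS
  ## minus-strand scores: score the forward sequence with the
  ## reverse-complemented matrix (rows swapped A<->T, C<->G; columns
  ## reversed); min/max score range is strand-invariant
  Mrc <- M[c(4L, 3L, 2L, 1L), rev(seq_len(L)), drop = FALSE]
  rownames(Mrc) <- c("A", "C", "G", "T")
  res <- lapply(c("+", "-"), function(str) {
    mat <- if (str == "+") M else Mrc
    s <- .score_windows(mat, idx)
    rel <- (s - minS) / rng
    keep <- which(!is.na(rel) & rel >= relThreshold)
    data.frame(offset = keep - 1L,
               strand = rep(str, length(keep)),
               raw_score = s[keep], rel_score = rel[keep],
               stringsAsFactors = FALSE)
  })
  out <- rbind(res[[1L]], res[[2L]])
  out <- out[order(out$offset, out$strand), c("offset", "strand",
                                              "raw_score", "rel_score")]
  rownames(out) <- NULL
  out
}

.best_hit <- function(hits) {
  ## maximal rel_score; ties -> smallest offset, then '+' strand
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(-hits$rel_score, hits$offset,
                     factor(hits$strand, levels = c("+", "-"))), ]
  hits[1L, ]
}

.load_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    names(genome) <- sub("\\s.*$", "", names(genome))
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gs <- readDNAStringSet(genome)
    names(gs) <- sub("\\s.*$", "", names(gs))
    return(gs)
  }
  stop("'genome' must be a DNAStringSet or a FASTA file path")
}

#' Per-peak best motif hits and the fraction of peaks with a hit
#'
#' Extracts each peak's sequence from the genome, scans it with
#' [scanSequence()] and keeps the best hit per peak (maximal relative
#' score; ties broken by smallest offset then `+` strand).  The headline
#' statistic is the fraction of peaks carrying at least one hit at the
#' threshold.
#'
#' @param peaks a [PeakSet-class] whose coordinates lie within the genome.
#' @param genome `DNAStringSet` or FASTA path; names must match peak
#'   chromosomes.
#' @param pfm a [PFMotif-class].
#' @param relThreshold relative score threshold (default 0.8).
#' @return list with `perPeak` (data.frame: peak_id, has_hit, offset,
#'   strand, raw_score, rel_score, mid_offset = signed bp from peak
#'   midpoint to motif centre), `fraction`, `nWithHit`, `n`.
#' @export
peakHitStats <- function(peaks, genome, pfm, relThreshold = 0.8) {
  stopifnot(is(peaks, "PeakSet"), is(pfm, "PFMotif"))
  gs <- .load_genome(genome)
  gr <- peaks@ranges
  chroms <- as.character(seqnames(gr))
  if (length(miss <- setdiff(unique(chroms), names(gs))))
    stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
  tooFar <- end(gr) > Biostrings::width(gs)[match(chroms, names(gs))] |
    start(gr) < 1L
  if (any(tooFar))
    stop("peak(s) beyond chromosome end: ",
         paste(utils::head(mcols(gr)$id[tooFar], 5), collapse = ", "))
  L <- motifLength(pfm)
  rows <- lapply(seq_along(gr), function(i) {
    seq <- as.character(Biostrings::subseq(gs[[chroms[i]]],
                                           start(gr)[i], end(gr)[i]))
    best <- .best_hit(scanSequence(pfm, seq, relThreshold))
    if (is.null(best))
      data.frame(peak_id = mcols(gr)$id[i], has_hit = FALSE,
                 offset = NA_integer_, strand = NA_character_,
                 raw_score = NA_real_, rel_score = NA_real_,
                 mid_offset = NA_real_, stringsAsFactors = FALSE)
    else
      data.frame(peak_id = mcols(gr)$id[i], has_hit = TRUE,
                 offset = best$offset, strand = best$strand,
                 raw_score = best$raw_score, rel_score = best$rel_score,
                 mid_offset = (best$offset + floor(L / 2)) -
                   floor(width(gr)[i] / 2),
                 stringsAsFactors = FALSE)
  })
  perPeak <- do.call(rbind, rows)
  list(perPeak = perPeak,
       fraction = if (nrow(perPeak)) mean(perPeak$has_hit) else NA_real_,
       nWithHit = sum(perPeak$has_hit),
       n = nrow(perPeak))
}

#' Positional centrality of best motif hits within peaks
#'
#' Histograms the signed offsets of best hits from their peak midpoints
#' and reports the mean absolute offset, together with the same statistic
#' on offsets re-randomised uniformly within each peak (`nRandom`
#' repetitions), the comparison that distinguishes centrally enriched
#' motifs from uniform placement.
#'
#' @param hits the `perPeak` data.frame from [peakHitStats()] (or a subset).
#' @param peaks the [PeakSet-class] the hits were computed on.
#' @param pfm the [PFMotif-class] used for scanning.
#' @param bin histogram bin width in bp (default 100).
#' @param nRandom number of uniform re-randomisations (default 100).
#' @param seed RNG seed for the re-randomisations.
#' @return list with `histogram` (data.frame lower/upper/count),
#'   `meanAbsOffset`, `nullMeanAbsOffsets` (length `nRandom`),
#'   `nullExpectation` (their mean), `nHits`.
#' @export
motifCentrality <- function(hits, peaks, pfm, bin = 100, nRandom = 100,
                            seed = 1) {
  stopifnot(is(peaks, "PeakSet"), is(pfm, "PFMotif"), bin > 0)
  hits <- hits[hits$has_hit, , drop = FALSE]
  ids <- peakIds(peaks)
  if (length(miss <- setdiff(hits$peak_id, ids)))
    stop("hit peak id(s) not in peak set: ", paste(miss, collapse = ", "))
  widths <- width(peaks@ranges)[match(hits$peak_id, ids)]
  off <- hits$mid_offset
  maxhalf <- if (length(widths)) ceiling(max(widths) / 2 / bin) * bin else bin
  breaks <- seq(-maxhalf, maxhalf, by = bin)
  idx <- findInterval(off, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1 & idx < length(breaks)],
                     nbins = length(breaks) - 1L)
  L <- motifLength(pfm)
  nullMeans <- if (nrow(hits)) withr::with_seed(seed, {
    vapply(seq_len(nRandom), function(r) {
      starts <- floor(stats::runif(length(widths), 0, widths - L + 1))
      mean(abs((starts + floor(L / 2)) - floor(widths / 2)))
    }, numeric(1))
  }) else numeric(0)
  list(histogram = data.frame(lower = breaks[-length(breaks)],
                              upper = breaks[-1L], count = counts),
       meanAbsOffset = if (nrow(hits)) mean(abs(off)) else NA_real_,
       nullMeanAbsOffsets = nullMeans,
       nullExpectation = if (length(nullMeans)) mean(nullMeans) else NA_real_,
       nHits = nrow(hits))
}

#' Motif enrichment between two peak sets
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 table of
#' peaks with/without a motif hit in set A versus set B.  The reported
#' fold is the ratio of hit rates, rate(A) / rate(B).
#'
#' @param nHitA,nA hits and total peaks in set A.
#' @param nHitB,nB hits and total peaks in set B.
#' @return a [ContingencyResult-class] with `foldEnrichment` set to the
#'   hit-rate ratio.
#' @examples
#' motifSetEnrichment(10, 100, 30, 100)
#' @export
motifSetEnrichment <- function(nHitA, nA, nHitB, nB) {
  stopifnot(nHitA <= nA, nHitB <= nB)
  obs <- matrix(c(nHitA, nA - nHitA, nHitB, nB - nHitB), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("setA", "setB"), c("hit", "no_hit")))
  res <- chiSquare2x2(obs)
  res@foldEnrichment <- (nHitA / nA) / (nHitB / nB)
  res@method <- "motif-set enrichment; fold = hit-rate ratio A/B"
  res
}
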