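#' @include AllClasses.R
NULL

## Peak files are small line-oriented tables; they are parsed by hand so
## malformed records can be reported with their line number.  Coordinates in
## files follow the BED convention (0-based half-open); the in-memory
## representation is a GRanges (1-based closed), converted at this boundary.

.parse_peak_fields <- function(fields, lineno) {
  if (length(fields) < 3L)
    stop("parse error at line ", lineno, ": fewer than 3 fields",
         call. = FALSE)
  start <- suppressWarnings(as.numeric(fields[2L]))
  end <- suppressWarnings(as.numeric(fields[3L]))
  if (is.na(start) || is.na(end) ||
      start != floor(start) || end != floor(end))
    stop("parse error at line ", lineno, ": non-integer coordinates '",
         fields[2L], "', '", fields[3L], "'", call. = FALSE)
  if (start < 0)
    stop("parse error at line ", lineno, ": negative start coordinate",
         call. = FALSE)
  if (start >= end)
    stop("parse error at line ", lineno, ": start >= end (", start, " >= ",
         end, ")", call. = FALSE)
  list(chrom = fields[1L], start = start, end = end)
}

#' Read a peak set from a BED or MACS-style TSV file
#'
#' BED files carry columns chrom/start/end and optionally name, score and
#' strand; a numeric score column is interpreted as the peak height in RPM.
#' The `tsv` dialect expects a header line naming at least
#' `chrom`, `start`, `end` and optionally `height` (and `id`).  Both
#' dialects use 0-based half-open coordinates.  Malformed lines
#' (non-integer coordinates, start >= end) raise an error naming the line;
#' an empty file yields an empty `PeakSet`.
#'
#' @param path file path.
#' @param dialect `"auto"` (header line present => tsv), `"bed"` or `"tsv"`.
#' @param factorName,genomeBuild labels stored in the result; peak ids are
#'   auto-assigned `<factorName>_<rank>` when the file provides none.
#' @return a sorted [PeakSet-class].
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t500\t900"), f)
#' readPeaks(f, factorName = "Smad2")
#' @export
readPeaks <- function(path, dialect = c("auto", "bed", "tsv"),
                      factorName = "factorA", genomeBuild = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (dialect == "auto") {
    if (length(lines) &&
        grepl("chrom", strsplit(lines[[1L]], "[\t ]+")[[1L]][1L],
              ignore.case = TRUE))
      dialect <- "tsv" else dialect <- "bed"
  }
  empty <- GRanges(seqnames = character(),
                   ranges = IRanges(integer(), integer()))
  if (!length(lines))
    return(PeakSet(empty, factorName, genomeBuild))

  if (dialect == "tsv") {
    header <- tolower(strsplit(lines[[1L]], "\t")[[1L]])
    need <- c("chrom", "start", "end")
    if (!all(need %in% header))
      stop("tsv peak file must have a header naming chrom, start, end")
    body <- lines[-1L]
    if (!length(body))
      return(PeakSet(empty, factorName, genomeBuild))
    recs <- lapply(seq_along(body), function(i) {
      fields <- strsplit(body[[i]], "\t")[[1L]]
      named <- stats::setNames(as.list(fields), header[seq_along(fields)])
      core <- .parse_peak_fields(c(named$chrom, named$start, named$end), i + 1L)
      core$height <- if (!is.null(named$height))
        suppressWarnings(as.numeric(named$height)) else NA_real_
      core$id <- if (!is.null(named$id)) named$id else NA_character_
      core$strand <- "*"
      core
    })
  } else {
    recs <- lapply(seq_along(lines), function(i) {
      fields <- strsplit(lines[[i]], "[\t ]+")[[1L]]
      core <- .parse_peak_fields(fields, i)
      core$id <- if (length(fields) >= 4L && nzchar(fields[4L]) &&
                     fields[4L] != ".") fields[4L] else NA_character_
      core$height <- if (length(fields) >= 5L)
        suppressWarnings(as.numeric(fields[5L])) else NA_real_
      core$strand <- if (length(fields) >= 6L &&
                         fields[6L] %in% c("+", "-")) fields[6L] else "*"
      core
    })
  }
  df <- do.call(rbind, lapply(recs, as.data.frame))
  gr <- GRanges(seqnames = df$chrom,
                ranges = IRanges(start = df$start + 1L, end = df$end),
                strand = df$strand)
  mcols(gr)$height <- df$height
  if (!anyNA(df$id)) mcols(gr)$id <- df$id
  PeakSet(gr, factorName, genomeBuild)
}

#' Write a peak set as BED
#'
#' Emits tab-separated 6-column BED (chrom, start, end, name, score,
#' strand) in 0-based half-open coordinates; `NA` heights become `0`.
#' A file written by `writePeaks` reads back to an identical `PeakSet`.
#'
#' @param x a [PeakSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(x, path) {
  stopifnot(is(x, "PeakSet"))
  gr <- x@ranges
  h <- mcols(gr)$height
  score <- vapply(h, function(x)
    if (is.na(x)) "0" else format(x, trim = TRUE, scientific = FALSE),
    character(1))
  lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                 mcols(gr)$id, score, as.character(strand(gr)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Do two genomic intervals overlap by at least `minOverlap` bp?
#'
#' Symmetric, strand-blind overlap predicate: TRUE iff both intervals are
#' on the same chromosome and the length of their intersection is at least
#' `minOverlap` bp.  Abutting intervals (end of one equals start of the
#' next in half-open coordinates) do not overlap.  Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param minOverlap minimum intersection length in bp (>= 1).
#' @return logical vector.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' intervalsOverlap(a, b)
#' @export
intervalsOverlap <- function(a, b, minOverlap = 1L) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), minOverlap >= 1)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= minOverlap
}

#' Consensus peaks supported by two replicates
#'
#' Groups the peaks of two replicate experiments into maximal chains of
#' mutually overlapping intervals (overlap of at least `minOverlap` bp,
#' transitively closed) and, for every chain containing at least one peak
#' from each replicate, emits a single consensus interval spanning the
#' union of the chain.  The consensus height is the maximum member height.
#'
#' @param rep1,rep2 [PeakSet-class] objects on the same genome build.
#' @param minOverlap minimum bp overlap (default 1).
#' @return a sorted [PeakSet-class] with ids `consensus_<rank>` and
#'   metadata recording the coordinate policy (`union`).
#' @examples
#' r1 <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)))
#' r2 <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250)))
#' replicateConsensus(r1, r2)
#' @export
replicateConsensus <- function(rep1, rep2, minOverlap = 1L) {
  stopifnot(is(rep1, "PeakSet"), is(rep2, "PeakSet"))
  if (!identical(genomeBuild(rep1), genomeBuild(rep2)))
    stop("configuration error: replicate genome builds differ (",
         genomeBuild(rep1), " vs ", genomeBuild(rep2), ")")
  minOverlap <- as.integer(minOverlap)
  stopifnot(minOverlap >= 1L)
  g1 <- granges(rep1@ranges)
  g2 <- granges(rep2@ranges)
  combined <- c(g1, g2)
  strand(combined) <- "*"
  repl <- rep(1:2, c(length(g1), length(g2)))
  heights <- c(peakHeights(rep1), peakHeights(rep2))
  empty <- PeakSet(GRanges(seqnames = character(),
                           ranges = IRanges(integer(), integer())),
                   factorName = factorName(rep1),
                   genomeBuild = genomeBuild(rep1))
  if (!length(combined)) return(empty)

  ## Two intervals overlap by >= k bp iff, after trimming k-1 bp from each
  ## end, they still overlap by >= 1 bp; reduce() on the trimmed set then
  ## yields exactly the transitive closure of the pairwise predicate.
  trimmed <- combined
  end(trimmed) <- end(trimmed) - (minOverlap - 1L)
  keep <- which(width(combined) >= minOverlap)
  if (!length(keep)) return(empty)
  comp <- reduce(trimmed[keep], min.gapwidth = 0L)
  hit <- findOverlaps(trimmed[keep], comp)
  grp <- integer(length(keep))
  grp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

  spans <- lapply(seq_len(length(comp)), function(g) {
    idx <- keep[grp == g]
    if (length(unique(repl[idx])) < 2L) return(NULL)
    h <- heights[idx]
    list(chrom = as.character(seqnames(combined[idx[1L]])),
         start = min(start(combined[idx])),
         end = max(end(combined[idx])),
         height = if (all(is.na(h))) NA_real_ else max(h, na.rm = TRUE))
  })
  spans <- spans[!vapply(spans, is.null, logical(1))]
  if (!length(spans)) return(empty)
  gr <- GRanges(seqnames = vapply(spans, `[[`, character(1), "chrom"),
                ranges = IRanges(vapply(spans, `[[`, numeric(1), "start"),
                                 vapply(spans, `[[`, numeric(1), "end")))
  mcols(gr)$height <- vapply(spans, `[[`, numeric(1), "height")
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  mcols(gr)$id <- paste0("consensus_", seq_along(gr))
  out <- PeakSet(gr, factorName = factorName(rep1),
                 genomeBuild = genomeBuild(rep1))
  S4Vectors::metadata(out@ranges)$coordinate_policy <- "union"
  out
}

#' Classify peak heights into low / medium / high RPM classes
#'
#' Factor-specific reads-per-million classes: for Smad2 low is <= 1.5 RPM,
#' medium 1.5-3 RPM, high > 3 RPM; for Eomesa low is <= 1 RPM, medium
#' 1-1.5 RPM, high > 1.5 RPM.  Interval endpoints are attached to the
#' lower class (h <= b1 is low; b1 < h <= b2 is medium).  Custom class
#' boundaries can be supplied through `breaks`.
#'
#' @param height numeric vector of nonnegative RPM heights.
#' @param factor `"Smad2"` or `"Eomesa"` (ignored when `breaks` given).
#' @param breaks optional length-2 numeric (low/medium and medium/high
#'   boundaries).
#' @return factor with levels low, medium, high.
#' @examples
#' classifyPeakHeight(c(1.5, 2, 3.5), "Smad2")
#' @export
classifyPeakHeight <- function(height, factor = c("Smad2", "Eomesa"),
                               breaks = NULL) {
  if (is.null(breaks)) {
    factor <- match.arg(factor)
    breaks <- switch(factor, Smad2 = c(1.5, 3), Eomesa = c(1, 1.5))
  }
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  if (any(is.na(height)) || any(height < 0))
    stop("heights must be nonnegative and non-missing")
  cut(height, breaks = c(-Inf, breaks, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}
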