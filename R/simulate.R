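#' @include AllClasses.R peaks.R annotation.R
#' @importFrom withr with_seed
NULL

## Synthetic fixtures with recorded ground truth.  Every generator takes a
## seed and is byte-deterministic given (seed, parameters); a root seed can
## be fanned out to per-stage child seeds with childSeed().

#' Derive a per-stage child seed from a root seed
#'
#' Deterministic fan-out so pipeline stages can be regenerated
#' independently: `childSeed(seed, stream)` mixes the root seed with a
#' stream label hash, staying below 2^31.
#'
#' @param seed integer root seed.
#' @param stream character stage label.
#' @return integer seed.
#' @export
childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate a genome and non-overlapping gene annotation
#'
#' Uniform-random DNA over the four bases, with `nGenes` genes packed
#' without overlap (gaps distributed randomly) on random strands.
#'
#' @param nChroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chromLength length of each chromosome in bp.
#' @param nGenes total number of genes.
#' @param geneWidthRange integer range of gene widths (default 2-8 kb).
#' @param seed RNG seed.
#' @return list with `genome` (`DNAStringSet`), `genes` (named `GRanges`)
#'   and `truth` (parameters echo).
#' @examples
#' sim <- simulateGenomeAnnotation(1, 1e5, 5, seed = 7)
#' length(sim$genes)
#' @export
simulateGenomeAnnotation <- function(nChroms = 1, chromLength = 1e6,
                                     nGenes = 50,
                                     geneWidthRange = c(2000, 8000),
                                     seed = 1) {
  stopifnot(nChroms >= 1, chromLength >= 1000, nGenes >= 0)
  withr::with_seed(seed, {
    chromNames <- paste0("chr", seq_len(nChroms))
    genome <- DNAStringSet(vapply(chromNames, function(cn)
      paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
            collapse = ""), character(1)))
    names(genome) <- chromNames

    if (nGenes == 0) {
      genes <- GRanges(seqnames = character(),
                       ranges = IRanges(integer(), integer()))
      names(genes) <- character()
    } else {
      chromOf <- sort(sample(nChroms, nGenes, replace = TRUE))
      widths <- sample(seq(geneWidthRange[1L], geneWidthRange[2L]),
                       nGenes, replace = TRUE)
      starts0 <- integer(nGenes)
      for (ci in unique(chromOf)) {
        gi <- which(chromOf == ci)
        totalGap <- chromLength - sum(widths[gi])
        if (totalGap < 0)
          stop("infeasible packing: genes do not fit on chr", ci)
        u <- stats::runif(length(gi) + 1L)
        gaps <- floor(totalGap * u / sum(u))
        starts0[gi] <- cumsum(gaps[-length(gaps)]) +
          c(0, cumsum(widths[gi]))[seq_along(gi)]
      }
      genes <- GRanges(seqnames = chromNames[chromOf],
                       ranges = IRanges(start = starts0 + 1L,
                                        end = starts0 + widths),
                       strand = sample(c("+", "-"), nGenes, replace = TRUE))
      ids <- sprintf("gene%04d", seq_len(nGenes))
      mcols(genes)$gene_id <- ids
      names(genes) <- ids
    }
    list(genome = genome, genes = genes,
         truth = list(seed = seed, n_chroms = nChroms,
                      chrom_length = chromLength, n_genes = nGenes,
                      gene_width_range = geneWidthRange))
  })
}

.sample_in_gaps <- function(gaps, widths) {
  ## place intervals of the given widths uniformly inside the allowed gaps
  ## (each interval entirely within one gap); gaps: data.frame
  ## chrom/start1/end1 (1-based closed).  Returns data.frame chrom/start1.
  n <- length(widths)
  chrom <- character(n); start1 <- integer(n)
  for (i in seq_len(n)) {
    room <- pmax(0, (gaps$end1 - gaps$start1 + 1L) - widths[i] + 1L)
    if (sum(room) == 0)
      stop("no gene-free space left for a peak of width ", widths[i])
    g <- sample.int(nrow(gaps), 1L, prob = room)
    start1[i] <- gaps$start1[g] +
      floor(stats::runif(1, 0, room[g]))
    chrom[i] <- gaps$chrom[g]
  }
  data.frame(chrom = chrom, start1 = start1)
}

.gap_frame <- function(chromLengths, exclude) {
  ## complement of 'exclude' (GRanges) within the chromosomes, as a
  ## data.frame of 1-based closed gaps
  all <- GRanges(seqnames = names(chromLengths),
                 ranges = IRanges(1L, as.integer(chromLengths)))
  gaps <- GenomicRanges::setdiff(all, reduce(exclude, ignore.strand = TRUE),
                                 ignore.strand = TRUE)
  data.frame(chrom = as.character(seqnames(gaps)),
             start1 = start(gaps), end1 = end(gaps),
             stringsAsFactors = FALSE)
}

#' Simulate ChIP-seq peaks around TSSs
#'
#' Each peak is proximal with probability `proximalFraction`: proximal
#' peaks are centred on the TSS of a random gene plus Gaussian noise
#' (`proximalSD`, default 3 kb, so essentially all proximal peaks fall
#' within the +/- 10 kb window); the remainder are placed uniformly in
#' space at least `window` bp away from every TSS.  Widths are uniform
#' over `widthRange`; heights are drawn log-normal to mimic RPM peak
#' heights.
#'
#' @param genes named `GRanges` of gene models.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nPeaks number of peaks.
#' @param proximalFraction probability that a peak is TSS-proximal.
#' @param widthRange uniform integer range of peak widths (default
#'   200-800 bp).
#' @param proximalSD Gaussian sd of proximal peak centres around the TSS
#'   (default 3000 bp).
#' @param window bp distance from TSSs kept free of background peaks
#'   (default 10000).
#' @param factorName,genomeBuild labels for the result.
#' @param seed RNG seed.
#' @return list with `peaks` ([PeakSet-class]) and `truth` (per-peak
#'   `proximal` flag, target gene and planted offset, plus parameters).
#' @export
simulatePeaks <- function(genes, chromLengths, nPeaks = 500,
                          proximalFraction = 0.7,
                          widthRange = c(200, 800), proximalSD = 3000,
                          window = 10000, factorName = "factorA",
                          genomeBuild = "sim1", seed = 1) {
  stopifnot(is(genes, "GRanges"), length(genes) >= 1,
            proximalFraction >= 0, proximalFraction <= 1)
  withr::with_seed(seed, {
    tss <- tssPositions(genes)
    gchrom <- as.character(seqnames(genes))
    maxW <- widthRange[2L]
    isProx <- stats::runif(nPeaks) < proximalFraction
    widths <- sample(seq(widthRange[1L], widthRange[2L]), nPeaks,
                     replace = TRUE)
    chrom <- character(nPeaks)
    start0 <- numeric(nPeaks)
    gene <- rep(NA_character_, nPeaks)
    offset <- rep(NA_real_, nPeaks)
    if (any(isProx)) {
      gi <- sample(length(genes), sum(isProx), replace = TRUE)
      off <- round(stats::rnorm(sum(isProx), 0, proximalSD))
      center <- tss[gi] + off
      s0 <- center - floor(widths[isProx] / 2)
      lim <- chromLengths[gchrom[gi]] - widths[isProx]
      s0 <- pmax(0, pmin(s0, lim))
      chrom[isProx] <- gchrom[gi]
      start0[isProx] <- s0
      gene[isProx] <- names(genes)[gi]
      offset[isProx] <- off
    }
    if (any(!isProx)) {
      ## exclusion: the closed TSS window grown by the maximal peak width
      ## upstream, so any peak starting in a gap is fully > window from
      ## every TSS
      excl <- GRanges(seqnames = gchrom,
                      ranges = IRanges(pmax(1, tss - window - maxW + 1),
                                       tss + window + 1))
      gapsF <- .gap_frame(chromLengths, excl)
      bg <- .sample_in_gaps(gapsF, widths[!isProx])
      chrom[!isProx] <- bg$chrom
      start0[!isProx] <- bg$start1 - 1L
    }
    heights <- round(stats::rlnorm(nPeaks, meanlog = log(2), sdlog = 0.6), 3)
    gr <- GRanges(seqnames = chrom,
                  ranges = IRanges(start = start0 + 1, end = start0 + widths))
    ids <- paste0(factorName, "_", seq_len(nPeaks))
    mcols(gr)$id <- ids
    mcols(gr)$height <- heights
    ps <- PeakSet(gr, factorName = factorName, genomeBuild = genomeBuild)
    list(peaks = ps,
         truth = list(seed = seed, n_peaks = nPeaks,
                      proximal_fraction = proximalFraction,
                      proximal_sd = proximalSD, window = window,
                      width_range = widthRange,
                      peaks = data.frame(id = ids, proximal = isProx,
                                         gene = gene, offset = offset,
                                         stringsAsFactors = FALSE)))
  })
}

#' Evenly spaced non-overlapping peaks
#'
#' Deterministic tiling of fixed-width peaks separated by a fixed gap,
#' useful as a base set whose sharing truth is exact: partner peaks of a
#' co-binding factor can only ever overlap their own base peak when base
#' peaks are spaced further apart than the jitter range.
#'
#' @param chromLengths named chromosome lengths.
#' @param n number of peaks (tiled across chromosomes in order).
#' @param width peak width in bp.
#' @param gap bp between consecutive peaks.
#' @param factorName,genomeBuild labels.
#' @return a [PeakSet-class].
#' @export
tilePeaks <- function(chromLengths, n, width = 400, gap = 2000,
                      factorName = "factorA", genomeBuild = "sim1") {
  stopifnot(n >= 1, width >= 1, gap >= 0)
  per <- floor((chromLengths - gap) / (width + gap))
  if (sum(per) < n)
    stop("chromosomes too short to tile ", n, " peaks")
  chrom <- character(n); start0 <- numeric(n)
  left <- n; pos <- 1L
  for (cn in names(chromLengths)) {
    take <- min(left, per[[cn]])
    if (take == 0) next
    k <- seq_len(take) - 1L
    chrom[pos:(pos + take - 1L)] <- cn
    start0[pos:(pos + take - 1L)] <- gap + k * (width + gap)
    pos <- pos + take; left <- left - take
    if (left == 0) break
  }
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = start0 + 1, end = start0 + width))
  mcols(gr)$id <- paste0(factorName, "_", seq_len(n))
  mcols(gr)$height <- rep(NA_real_, n)
  PeakSet(gr, factorName = factorName, genomeBuild = genomeBuild)
}

#' Simulate a co-binding factor's peak set
#'
#' For a Bernoulli(`sharedFraction`) subset of the base peaks, emits a
#' partner peak whose centre is jittered by Gaussian noise but clamped so
#' that at least 1 bp overlap with the base peak is guaranteed; adds
#' `nExtra` independent peaks placed so as to avoid every base peak.
#'
#' The recorded truth labels equal the [sharePeaks()] classification
#' exactly when the base peaks do not overlap one another and are spaced
#' further apart than the jitter range (see [tilePeaks()]); with clustered
#' base peaks a partner can also touch a neighbouring base peak, making
#' the realised shared fraction slightly exceed the planted one.
#'
#' @param base a [PeakSet-class] (e.g. the Smad2 peaks).
#' @param chromLengths named chromosome lengths.
#' @param sharedFraction probability a base peak gets an overlapping
#'   partner (default 0.4, the co-occupancy level observed for
#'   Smad2/Eomesa).
#' @param jitterSD Gaussian sd of the partner-centre jitter (default
#'   100 bp).
#' @param nExtra number of additional independent peaks.
#' @param widthRange partner/extra widths (uniform; default 200-800 bp).
#' @param factorName label for the new set.
#' @param seed RNG seed.
#' @return list with `peaks` ([PeakSet-class]) and `truth` (per base peak
#'   `shared` flag and partner id; extra ids).
#' @export
simulateCofactorPeaks <- function(base, chromLengths, sharedFraction = 0.4,
                                  jitterSD = 100, nExtra = 200,
                                  widthRange = c(200, 800),
                                  factorName = "factorB", seed = 1) {
  stopifnot(is(base, "PeakSet"),
            sharedFraction >= 0, sharedFraction <= 1, nExtra >= 0)
  withr::with_seed(seed, {
    gr <- peakRanges(base)
    n <- length(gr)
    shared <- stats::runif(n) < sharedFraction
    recs <- list()
    partnerIds <- rep(NA_character_, n)
    if (any(shared)) {
      idx <- which(shared)
      w <- sample(seq(widthRange[1L], widthRange[2L]), length(idx),
                  replace = TRUE)
      mid0 <- .peak_midpoints(gr)[idx]
      s0 <- mid0 + round(stats::rnorm(length(idx), 0, jitterSD)) -
        floor(w / 2)
      ## clamp so [s0, s0 + w) overlaps the base peak [bs0, be0) by >= 1 bp
      bs0 <- start(gr)[idx] - 1L
      be0 <- end(gr)[idx]
      s0 <- pmax(bs0 - w + 1, pmin(s0, be0 - 1))
      s0 <- pmax(0, pmin(s0, chromLengths[as.character(seqnames(gr))[idx]] - w))
      partnerIds[idx] <- paste0(factorName, "_p", seq_along(idx))
      recs$partners <- data.frame(chrom = as.character(seqnames(gr))[idx],
                                  start0 = s0, width = w,
                                  id = partnerIds[idx],
                                  stringsAsFactors = FALSE)
    }
    extraIds <- character(0)
    if (nExtra > 0) {
      w <- sample(seq(widthRange[1L], widthRange[2L]), nExtra,
                  replace = TRUE)
      ## extras must not overlap any base peak: exclude base peaks grown by
      ## the maximal extra width upstream
      excl <- GRanges(seqnames = seqnames(gr),
                      ranges = IRanges(pmax(1, start(gr) - widthRange[2L] + 1),
                                       end(gr)))
      gapsF <- .gap_frame(chromLengths, excl)
      bg <- .sample_in_gaps(gapsF, w)
      extraIds <- paste0(factorName, "_x", seq_len(nExtra))
      recs$extras <- data.frame(chrom = bg$chrom, start0 = bg$start1 - 1L,
                                width = w, id = extraIds,
                                stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, recs)
    if (is.null(all))
      all <- data.frame(chrom = character(), start0 = numeric(),
                        width = numeric(), id = character())
    out <- GRanges(seqnames = all$chrom,
                   ranges = IRanges(start = all$start0 + 1,
                                    end = all$start0 + all$width))
    mcols(out)$id <- all$id
    mcols(out)$height <- round(stats::rlnorm(nrow(all), log(1.2), 0.5), 3)
    ps <- PeakSet(out, factorName = factorName,
                  genomeBuild = genomeBuild(base))
    list(peaks = ps,
         truth = list(seed = seed, shared_fraction = sharedFraction,
                      jitter_sd = jitterSD, n_extra = nExtra,
                      base = data.frame(id = peakIds(base), shared = shared,
                                        partner = partnerIds,
                                        stringsAsFactors = FALSE),
                      extra_ids = extraIds))
  })
}

#' Plant motif instances into peak sequences
#'
#' Writes a motif instance (the consensus string by default, maximally
#' detectable; optionally sampled from the PFM column frequencies) into a
#' Bernoulli(`rate`) subset of peaks, at a Gaussian offset from the peak
#' midpoint and on a random strand.
#'
#' @param genome `DNAStringSet`.
#' @param peaks a [PeakSet-class].
#' @param pfm a [PFMotif-class].
#' @param rate planting probability per peak.
#' @param centerSD Gaussian sd of the instance centre around the peak
#'   midpoint (bp).
#' @param samplePFM if TRUE, draw each instance from the PFM frequencies
#'   instead of using the consensus.
#' @param seed RNG seed.
#' @return list with `genome` (modified `DNAStringSet`) and `truth`
#'   (per-peak planted flag, offset from peak start, strand, instance).
#' @export
plantMotifs <- function(genome, peaks, pfm, rate = 0.5, centerSD = 50,
                        samplePFM = FALSE, seed = 1) {
  stopifnot(is(genome, "DNAStringSet"), is(peaks, "PeakSet"),
            is(pfm, "PFMotif"), rate >= 0, rate <= 1)
  withr::with_seed(seed, {
    gr <- peakRanges(peaks)
    L <- motifLength(pfm)
    n <- length(gr)
    planted <- stats::runif(n) < rate
    strandOf <- rep(NA_character_, n)
    startInPeak <- rep(NA_integer_, n)
    instance <- rep(NA_character_, n)
    seqs <- as.list(as.character(genome))
    cons <- motifConsensus(pfm)
    freq <- sweep(pfm@counts, 2, colSums(pfm@counts), "/")
    for (i in which(planted)) {
      w <- width(gr)[i]
      if (w < L) { planted[i] <- FALSE; next }
      mid <- floor(w / 2)
      s <- mid + round(stats::rnorm(1, 0, centerSD)) - floor(L / 2)
      s <- max(0, min(s, w - L))                  # offset from peak start
      inst <- if (samplePFM)
        paste(vapply(seq_len(L), function(j)
          sample(rownames(freq), 1L, prob = freq[, j]), character(1)),
          collapse = "")
      else cons
      str <- sample(c("+", "-"), 1L)
      written <- if (str == "+") inst else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
      chrom <- as.character(seqnames(gr))[i]
      pos1 <- start(gr)[i] + s                    # 1-based genome position
      old <- seqs[[chrom]]
      substr(old, pos1, pos1 + L - 1L) <- written
      seqs[[chrom]] <- old
      strandOf[i] <- str
      startInPeak[i] <- s
      instance[i] <- inst
    }
    newGenome <- DNAStringSet(unlist(seqs))
    names(newGenome) <- names(genome)
    list(genome = newGenome,
         truth = list(seed = seed, rate = rate, center_sd = centerSD,
                      sample_pfm = samplePFM, motif_id = pfm@motifID,
                      peaks = data.frame(id = peakIds(peaks),
                                         planted = planted,
                                         offset = startInPeak,
                                         strand = strandOf,
                                         instance = instance,
                                         stringsAsFactors = FALSE)))
  })
}

#' Simulate ortholog maps and foreign bound gene sets
#'
#' Each reference gene is conserved (proximally bound) in each foreign
#' species with the stated probability.  Every reference gene receives a
#' foreign ortholog per species (one2one, or one2many fan-out to a second
#' conserved reference gene with probability `fanoutProb`); the foreign
#' bound set contains exactly the orthologs of the conserved genes, so
#' projecting it back recovers the planted conservation flags.
#'
#' @param genes character vector (or named `GRanges`) of reference gene
#'   ids.
#' @param conservationFractions named per-species conservation
#'   probabilities (default human 0.30, mouse 0.30, xenopus 0.20, chosen
#'   to emulate the observed cross-species overlap levels).
#' @param fanoutProb probability a conserved gene's ortholog also maps to
#'   a second conserved reference gene (one2many).
#' @param seed RNG seed.
#' @return list with `map` (data.frame source_gene/target_gene/
#'   homology_type), `foreignSets` (named list of foreign bound gene
#'   sets), and `truth` (planted flags matrix and classes).
#' @export
simulateOrthologyAndForeignSets <- function(genes,
                                            conservationFractions =
                                              c(human = 0.30, mouse = 0.30,
                                                xenopus = 0.20),
                                            fanoutProb = 0.1, seed = 1) {
  if (is(genes, "GRanges")) genes <- names(genes)
  genes <- as.character(genes)
  stopifnot(length(genes) >= 1, !is.null(names(conservationFractions)))
  withr::with_seed(seed, {
    species <- names(conservationFractions)
    flags <- matrix(FALSE, length(genes), length(species),
                    dimnames = list(genes, species))
    maps <- list(); fsets <- list()
    for (sp in species) {
      conserved <- stats::runif(length(genes)) < conservationFractions[[sp]]
      flags[, sp] <- conserved
      fid <- paste0(sp, "_g", seq_along(genes))
      map <- data.frame(source_gene = fid, target_gene = genes,
                        homology_type = "one2one",
                        stringsAsFactors = FALSE)
      consIdx <- which(conserved)
      if (length(consIdx) >= 2 && fanoutProb > 0) {
        fan <- consIdx[stats::runif(length(consIdx)) < fanoutProb]
        for (i in fan) {
          j <- sample(setdiff(consIdx, i), 1L)
          map <- rbind(map, data.frame(source_gene = fid[i],
                                       target_gene = genes[j],
                                       homology_type = "one2many",
                                       stringsAsFactors = FALSE))
          map$homology_type[map$source_gene == fid[i]] <- "one2many"
        }
      }
      maps[[sp]] <- map
      fsets[[sp]] <- fid[conserved]
    }
    map <- do.call(rbind, maps)
    rownames(map) <- NULL
    list(map = map, foreignSets = fsets,
         truth = list(seed = seed,
                      conservation_fractions = as.list(conservationFractions),
                      fanout_prob = fanoutProb,
                      flags = as.data.frame(flags),
                      classes = as.integer(rowSums(flags))))
  })
}

#' Simulate a differential-expression table tied to binding classes
#'
#' Each gene is responsive with class-dependent odds: the log-odds of the
#' base responsiveness rate is shifted by `log(oddsRatios[class])`.
#' Responsive genes draw `|log2fc| ~ |N(effectSize, 0.5)|` with the sign
#' set by direction (up with probability `upFraction`) and
#' `p ~ Uniform(0, pThreshold)`; non-responsive genes draw small fold
#' changes and `p ~ Uniform(pThreshold, 1)`.
#'
#' @param classes a [BindingClassMap-class] or named factor/character of
#'   binding classes.
#' @param baseRate baseline responsiveness probability (default 0.1).
#' @param oddsRatios named odds ratios per class; unnamed classes get 1.
#' @param effectSize mean |log2 fold change| of responsive genes.
#' @param pThreshold the DE P cutoff the table is built around.
#' @param upFraction probability a responsive gene is upregulated
#'   (default 0.78, the up/down split observed for Nodal-responsive
#'   genes).
#' @param seed RNG seed.
#' @return list with `table` (data.frame gene_id/log2fc/pvalue) and
#'   `truth` (per-gene responsive flag and direction, planted parameters).
#' @export
simulateDETable <- function(classes, baseRate = 0.1,
                            oddsRatios = c(common = 4), effectSize = 2,
                            pThreshold = 0.05, upFraction = 0.78, seed = 1) {
  if (is(classes, "BindingClassMap")) classes <- bindingClasses(classes)
  stopifnot(!is.null(names(classes)), baseRate > 0, baseRate < 1)
  withr::with_seed(seed, {
    genes <- names(classes)
    lab <- as.character(classes)
    or <- rep(1, length(genes))
    hit <- lab %in% names(oddsRatios)
    or[hit] <- oddsRatios[lab[hit]]
    prob <- stats::plogis(stats::qlogis(baseRate) + log(or))
    responsive <- stats::runif(length(genes)) < prob
    up <- stats::runif(length(genes)) < upFraction
    lfc <- numeric(length(genes))
    pv <- numeric(length(genes))
    nR <- sum(responsive)
    lfc[responsive] <- abs(stats::rnorm(nR, effectSize, 0.5)) *
      ifelse(up[responsive], 1, -1)
    pv[responsive] <- stats::runif(nR, 0, pThreshold)
    lfc[!responsive] <- stats::rnorm(length(genes) - nR, 0, 0.3)
    pv[!responsive] <- stats::runif(length(genes) - nR, pThreshold, 1)
    table <- data.frame(gene_id = genes, log2fc = lfc, pvalue = pv,
                        stringsAsFactors = FALSE)
    list(table = table,
         truth = list(seed = seed, base_rate = baseRate,
                      odds_ratios = as.list(oddsRatios),
                      effect_size = effectSize, p_threshold = pThreshold,
                      up_fraction = upFraction,
                      genes = data.frame(gene_id = genes,
                                         class = lab,
                                         responsive = responsive,
                                         direction = ifelse(up, "up", "down"),
                                         stringsAsFactors = FALSE)))
  })
}

## ---- fixture writers -------------------------------------------------

#' Write simulated fixtures to disk
#'
#' Deterministic plain-text writers for the generator outputs: FASTA
#' (via Biostrings), Ensembl-dialect GTF, ortholog/DE TSV and a JSON
#' truth record.  Re-running a generator with the same seed and writing
#' again reproduces the files byte-identically.
#'
#' @param genome `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @rdname fixture-writers
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @param genes named `GRanges` of gene models.
#' @rdname fixture-writers
#' @export
writeGeneModelsGTF <- function(genes, path) {
  stopifnot(is(genes, "GRanges"))
  ids <- if (!is.null(names(genes))) names(genes) else mcols(genes)$gene_id
  lines <- paste(as.character(seqnames(genes)), "sim", "gene",
                 start(genes), end(genes), ".",
                 as.character(strand(genes)), ".",
                 sprintf('gene_id "%s";', ids), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @param map ortholog map data.frame.
#' @rdname fixture-writers
#' @export
writeOrthologMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @param table DE table data.frame (gene_id, log2fc, pvalue).
#' @rdname fixture-writers
#' @export
writeDETable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @param truth a truth record (list) from any generator.
#' @rdname fixture-writers
#' @export
writeSimulationTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
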