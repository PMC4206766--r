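## Shared fixtures and independent brute-force oracles.  The oracles
## deliberately re-derive every quantity from first principles (quadratic
## scans, per-window rescoring) so they share no code path with the
## package implementations they check.

suppressMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

gr_peaks <- function(chrom, start0, end0, id = NULL, height = NULL,
                     strand = "*") {
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0),
                strand = strand)
  if (!is.null(id)) mcols(gr)$id <- id
  if (!is.null(height)) mcols(gr)$height <- height
  gr
}

## a strongly informative 12-bp test motif (long enough that random
## 400-800 bp backgrounds essentially never reach a 0.8 relative score);
## consensus ACGTATGCCATG
toy_pfm <- function(pseudocount = 0.8) {
  cons <- strsplit("ACGTATGCCATG", "")[[1]]
  m <- vapply(cons, function(b) 9 * (c("A", "C", "G", "T") == b),
              numeric(4))
  rownames(m) <- c("A", "C", "G", "T")
  colnames(m) <- NULL
  PFMotif(m, motifID = "toy01", name = "TOY", pseudocount = pseudocount)
}

## a gene universe on one chromosome
toy_genes <- function(starts0, ends0, strands, ids = NULL,
                      chrom = "chr1") {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_along(starts0))
  gr <- GRanges(chrom, IRanges(starts0 + 1, ends0), strand = strands)
  mcols(gr)$gene_id <- ids
  names(gr) <- ids
  gr
}

random_peakset <- function(n, chromLen = 1e5, chroms = c("chr1", "chr2"),
                           widthRange = c(50, 500),
                           factorName = "factorA") {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample(widthRange[1]:widthRange[2], n, replace = TRUE)
  s0 <- floor(runif(n, 0, chromLen - w))
  PeakSet(gr_peaks(chrom, s0, s0 + w,
                   id = paste0(factorName, "_", seq_len(n)),
                   height = round(runif(n, 0, 5), 2)),
          factorName = factorName, genomeBuild = "sim1")
}

peakset_df <- function(ps) {
  gr <- peakRanges(ps)
  data.frame(chrom = as.character(seqnames(gr)),
             start0 = start(gr) - 1, end0 = end(gr),
             id = peakIds(ps), stringsAsFactors = FALSE)
}

## ---- oracles ----------------------------------------------------------

bf_overlap <- function(c1, s1, e1, c2, s2, e2, k = 1) {
  c1 == c2 && (min(e1, e2) - max(s1, s2)) >= k     # half-open coordinates
}

## quadratic union-find grouping for replicate consensus
bf_consensus <- function(df1, df2, k = 1) {
  all <- rbind(cbind(df1, repl = 1L), cbind(df2, repl = 2L))
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && bf_overlap(all$chrom[i], all$start0[i], all$end0[i],
                            all$chrom[j], all$start0[j], all$end0[j], k)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    if (length(unique(all$repl[idx])) < 2L) return(NULL)
    data.frame(chrom = all$chrom[idx[1]],
               start0 = min(all$start0[idx]), end0 = max(all$end0[idx]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric()))
  out[order(out$chrom, out$start0, out$end0), , drop = FALSE]
}

## exhaustive all-pairs proximal assignment over 0-based coordinates
bf_assign <- function(peaks_df, genes, window) {
  tss <- ifelse(as.character(strand(genes)) == "+",
                start(genes) - 1, end(genes) - 1)
  pairs <- list()
  for (gi in seq_along(genes)) for (pi in seq_len(nrow(peaks_df))) {
    if (as.character(seqnames(genes))[gi] != peaks_df$chrom[pi]) next
    lo <- tss[gi] - window; hi <- tss[gi] + window
    ## peak [s0, e0) intersects the closed position window [lo, hi]
    if (peaks_df$start0[pi] <= hi && (peaks_df$end0[pi] - 1) >= lo)
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene_id = names(genes)[gi], peak_id = peaks_df$id[pi],
                   stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(gene_id = character(), peak_id = character()))
  out <- do.call(rbind, pairs)
  out[order(out$gene_id, out$peak_id), , drop = FALSE]
}

## quadratic sharing oracle
bf_share_pairs <- function(dfA, dfB, k = 1) {
  pairs <- list()
  for (i in seq_len(nrow(dfA))) for (j in seq_len(nrow(dfB))) {
    if (bf_overlap(dfA$chrom[i], dfA$start0[i], dfA$end0[i],
                   dfB$chrom[j], dfB$start0[j], dfB$end0[j], k))
      pairs[[length(pairs) + 1L]] <-
        data.frame(a_id = dfA$id[i], b_id = dfB$id[j],
                   stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(a_id = character(), b_id = character()))
  out <- do.call(rbind, pairs)
  out[order(out$a_id, out$b_id), , drop = FALSE]
}

## per-window rescoring oracle: derives the log-odds matrix from counts
## itself, scores every window, scores the minus strand by explicitly
## reverse-complementing the window string
bf_scan <- function(pfm, seq, relThreshold) {
  cts <- pfm@counts; bg <- pfm@background; pc <- pfm@pseudocount
  M <- log2(sweep(cts + pc * bg, 2, colSums(cts) + pc, "/") / bg)
  L <- ncol(M)
  minS <- sum(apply(M, 2, min)); maxS <- sum(apply(M, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score1 <- function(win) {
    b <- strsplit(win, "")[[1]]
    if (any(b == "N")) return(NA_real_)
    sum(M[cbind(match(b, rownames(M)), seq_len(L))])
  }
  rows <- list()
  for (off in 0:(nchar(seq) - L)) {
    win <- substr(seq, off + 1, off + L)
    for (str in c("+", "-")) {
      w <- if (str == "+") win else
        paste(rev(comp[strsplit(win, "")[[1]]]), collapse = "")
      s <- score1(w)
      if (!is.na(s) && (s - minS) / (maxS - minS) >= relThreshold)
        rows[[length(rows) + 1L]] <-
          data.frame(offset = off, strand = str, raw_score = s,
                     rel_score = (s - minS) / (maxS - minS),
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(),
                      raw_score = numeric(), rel_score = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand), , drop = FALSE]
}

## per-element membership tally for Venn partitions
bf_venn <- function(sets) {
  universe <- unique(unlist(sets))
  out <- integer()
  k <- length(sets)
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  for (r in seq_len(nrow(pat))) {
    p <- as.logical(pat[r, ])
    cnt <- sum(vapply(universe, function(g)
      all(vapply(seq_len(k), function(i)
        (g %in% sets[[i]]) == p[i], logical(1))), logical(1)))
    out[paste(names(sets)[p], collapse = "&")] <- cnt
  }
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## deterministic low-complexity filler that cannot contain the toy motif
random_dna_fixed <- function(n) strrep("T", n)

## full synthetic input bundle + pipeline config for end-to-end tests
make_bundle <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenomeAnnotation(1, 6e5, 12, seed = childSeed(seed, "genome"))
  cl <- c(chr1 = 6e5)
  base <- tilePeaks(cl, 120, width = 400, gap = 2000, factorName = "Smad2")
  pb <- simulateCofactorPeaks(base, cl, sharedFraction = 0.4, nExtra = 60,
                              factorName = "Eomesa",
                              seed = childSeed(seed, "cofactor"))
  pl <- plantMotifs(sim$genome, base, toy_pfm(), rate = 0.6,
                    seed = childSeed(seed, "motifs"))
  orth <- simulateOrthologyAndForeignSets(sim$genes,
                                          seed = childSeed(seed, "orth"))
  lv <- c("A_only", "common", "uncommon", "B_only", "none")
  cls <- stats::setNames(factor(rep("none", 12), levels = lv),
                         names(sim$genes))
  de <- simulateDETable(cls, baseRate = 0.2, oddsRatios = c(),
                        pThreshold = 0.05, seed = childSeed(seed, "de"))

  writeGenomeFasta(pl$genome, file.path(dir, "genome.fa"))
  writeGeneModelsGTF(sim$genes, file.path(dir, "genes.gtf"))
  writePeaks(base, file.path(dir, "smad2.bed"))
  writePeaks(pb$peaks, file.path(dir, "eomesa.bed"))
  writeJaspar(toy_pfm(), file.path(dir, "motif.jaspar"))
  writeOrthologMap(orth$map, file.path(dir, "orthologs.tsv"))
  writeLines(orth$foreignSets$human, file.path(dir, "human_bound.txt"))
  writeDETable(de$table, file.path(dir, "de.tsv"))

  cfg <- list(
    genome_build = "sim1",
    seed = seed,
    peaks = list(
      factorA = list(name = "Smad2", peaks = file.path(dir, "smad2.bed")),
      factorB = list(name = "Eomesa", peaks = file.path(dir, "eomesa.bed"))),
    annotation = file.path(dir, "genes.gtf"),
    genome = file.path(dir, "genome.fa"),
    motif = file.path(dir, "motif.jaspar"),
    orthologs = list(
      human = list(map = file.path(dir, "orthologs.tsv"),
                   bound_genes = file.path(dir, "human_bound.txt"))),
    expression = list(list(path = file.path(dir, "de.tsv"),
                           provenance = "rnaseq")),
    params = list(proximal_window = 10000, min_overlap = 1,
                  motif_rel_threshold = 0.8))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  list(dir = dir, config = file.path(dir, "config.yaml"),
       truth = list(cofactor = pb$truth, motifs = pl$truth))
}

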