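write_gtf <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, start1, end1, strand, id, feature = "gene") {
  paste(chrom, "sim", feature, start1, end1, ".", strand, ".",
        sprintf('gene_id "%s";', id), sep = "\t")
}

test_that("GTF genes convert to half-open spans with strand-aware TSSs", {
  f <- write_gtf(c(gtf_line("chr1", 1001, 2000, "+", "gplus"),
                   gtf_line("chr1", 1001, 2000, "-", "gminus")))
  genes <- readGeneModels(f)
  expect_equal(length(genes), 2L)
  expect_equal(start(genes["gplus"]) - 1, 1000)   # 0-based span start
  expect_equal(end(genes["gplus"]), 2000)         # 0-based span end
  tss <- tssPositions(genes)
  expect_equal(unname(tss["gplus"]), 1000)
  expect_equal(unname(tss["gminus"]), 1999)
})

test_that("duplicate gene records dedup when identical and error when conflicting", {
  f <- write_gtf(c(gtf_line("chr1", 1001, 2000, "+", "g1"),
                   gtf_line("chr1", 1001, 2000, "+", "g1")))
  expect_equal(length(readGeneModels(f)), 1L)
  f2 <- write_gtf(c(gtf_line("chr1", 1001, 2000, "+", "g1"),
                    gtf_line("chr1", 3001, 4000, "+", "g1")))
  expect_error(readGeneModels(f2), "conflicting coordinates")
  f3 <- write_gtf(gtf_line("chr1", 1001, 2000, ".", "g1"))
  expect_error(readGeneModels(f3), "strand")
})

test_that("assignProximal window is closed and interval-based", {
  genes <- toy_genes(50000, 55000, "+", "g1")
  inside <- PeakSet(gr_peaks("chr1", 45000, 46000, id = "p_in"))
  out <- PeakSet(gr_peaks("chr1", 60001, 61000, id = "p_out"))
  edge <- PeakSet(gr_peaks("chr1", 60000, 61000, id = "p_edge"))
  pi <- assignmentPairs(assignProximal(inside, genes, 10000))
  expect_equal(nrow(pi), 1L)
  expect_equal(pi$distance, -4500)           # upstream of a + strand gene
  expect_equal(nrow(assignmentPairs(assignProximal(out, genes, 10000))), 0L)
  ## a peak whose first base sits exactly at tss + window is still inside
  expect_equal(nrow(assignmentPairs(assignProximal(edge, genes, 10000))), 1L)
  expect_error(assignProximal(inside, genes[0], 10000), "empty gene")
})

test_that("assignProximal distances are strand-oriented", {
  genes <- toy_genes(c(10000, 40000), c(15000, 50000), c("+", "-"),
                     c("gp", "gm"))
  ## peak downstream of gm's TSS (at 49999) in genomic terms but the gene
  ## reads leftwards, so a peak left of the TSS is downstream (+)
  pk <- PeakSet(gr_peaks("chr1", 47000, 48000, id = "p1"))
  pr <- assignmentPairs(assignProximal(pk, genes, 10000))
  pm <- pr[pr$gene_id == "gm", ]
  expect_equal(pm$distance, 2499)   # (47500 - 49999) * (-1), oriented
})

test_that("assignProximal matches the exhaustive all-pairs oracle", {
  withr::with_seed(515, {
    for (rep in 1:3) {
      nG <- 30
      starts <- sort(sample(seq(0, 9e4, by = 100), nG))
      genes <- toy_genes(starts, starts + 1500,
                         sample(c("+", "-"), nG, TRUE))
      ps <- random_peakset(100, chromLen = 1e5, chroms = "chr1")
      got <- assignmentPairs(assignProximal(ps, genes, 5000))
      want <- bf_assign(peakset_df(ps), genes, 5000)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[c("gene_id", "peak_id")], want)
    }
  })
})

test_that("widening the window never loses pairs (monotonicity)", {
  withr::with_seed(616, {
    genes <- toy_genes(sort(sample(seq(0, 9e4, by = 50), 20)),
                       sort(sample(seq(0, 9e4, by = 50), 20)) + 2000,
                       sample(c("+", "-"), 20, TRUE))
    ps <- random_peakset(80, chromLen = 1e5, chroms = "chr1")
    key <- function(a) paste(a$gene_id, a$peak_id)
    p1 <- key(assignmentPairs(assignProximal(ps, genes, 2000)))
    p2 <- key(assignmentPairs(assignProximal(ps, genes, 8000)))
    expect_true(all(p1 %in% p2))
  })
})

test_that("TSS distance profile puts planted peaks in the right bins", {
  genes <- toy_genes(c(20000, 60000), c(25000, 70000), c("+", "+"))
  ## peaks exactly at the TSSs -> all mass in the bin containing 0
  at_tss <- PeakSet(gr_peaks("chr1", c(19950, 59950), c(20050, 60050),
                             id = c("p1", "p2")))
  prof <- tssDistanceProfile(at_tss, genes, span = 10000, bin = 1000)
  expect_equal(sum(prof$counts), 2L)
  zero_bin <- which(prof$breaks[-1] > 0)[1]
  expect_equal(prof$counts[zero_bin], 2L)

  ## single peak at a known +7,200 offset lands in the [7000, 8000) bin
  one <- PeakSet(gr_peaks("chr1", 27100, 27300, id = "p1"))
  prof2 <- tssDistanceProfile(one, genes, span = 10000, bin = 1000)
  expect_equal(prof2$counts[which(prof2$breaks == 7000)], 1L)
  expect_equal(unname(prof2$distances["p1"]), 7200)
})

test_that("TSS distance profile matches a nearest-TSS linear scan and drops far peaks", {
  withr::with_seed(717, {
    nG <- 10
    gs <- sort(sample(seq(1e4, 9e4, by = 500), nG))
    genes <- toy_genes(gs, gs + 3000, sample(c("+", "-"), nG, TRUE))
    ps <- random_peakset(120, chromLen = 1e5, chroms = "chr1")
    span <- 5000
    prof <- tssDistanceProfile(ps, genes, span = span, bin = 500)
    tss <- tssPositions(genes)
    str <- as.character(strand(genes))
    df <- peakset_df(ps)
    want <- 0L
    for (i in seq_len(nrow(df))) {
      mid <- floor((df$start0[i] + df$end0[i]) / 2)
      d <- abs(mid - tss)
      j <- which(d == min(d))
      j <- j[order(names(tss)[j])][1]
      signed <- (mid - tss[j]) * (if (str[j] == "+") 1 else -1)
      if (signed >= -span && signed <= span) want <- want + 1L
    }
    expect_equal(prof$n_counted, want)
    expect_equal(sum(prof$counts), want)
    expect_lte(prof$n_counted, length(ps))
  })
})

test_that("profile of peaks planted at N(0, 2kb) offsets is modal at zero", {
  withr::with_seed(818, {
    genes <- toy_genes(seq(2e4, 4.7e5, by = 5e4), seq(2e4, 4.7e5, by = 5e4) + 3000,
                       rep(c("+", "-"), 5), chrom = "chr1")
    tss <- tssPositions(genes)
    n <- 600
    gi <- sample(length(genes), n, replace = TRUE)
    sign <- ifelse(as.character(strand(genes))[gi] == "+", 1, -1)
    off <- round(rnorm(n, 0, 2000))
    mid <- tss[gi] + off * sign          # oriented offset becomes genomic
    ps <- PeakSet(gr_peaks("chr1", mid - 100, mid + 100,
                           id = paste0("p", seq_len(n))))
    prof <- tssDistanceProfile(ps, genes, span = 10000, bin = 1000)
    modal <- which.max(prof$counts)
    expect_true(prof$breaks[modal] == -1000 || prof$breaks[modal] == 0)
    ## the two central bins dominate
    zero_bins <- which(prof$breaks %in% c(-1000, 0))
    expect_gt(sum(prof$counts[zero_bins]) / sum(prof$counts), 0.3)
  })
})
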