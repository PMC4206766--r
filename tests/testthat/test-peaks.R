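test_that("readPeaks parses well-formed BED, keeps sort order, assigns ids", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200", "chr1\t500\t900", "chr1\t50\t120"), f)
  ps <- readPeaks(f, factorName = "Smad2")
  expect_s4_class(ps, "PeakSet")
  expect_equal(length(ps), 3L)
  gr <- peakRanges(ps)
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr1", "chr2"))
  expect_equal(start(gr) - 1, c(50, 500, 100))   # back to 0-based
  expect_equal(peakIds(ps), c("Smad2_1", "Smad2_2", "Smad2_3"))
})

test_that("readPeaks reports malformed lines by number and accepts empties", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1 500 100"), f)
  expect_error(readPeaks(f), "line 2.*start >= end")
  writeLines(c("chr1\tx\t200"), f)
  expect_error(readPeaks(f), "line 1.*non-integer")
  writeLines(character(), f)
  expect_equal(length(readPeaks(f)), 0L)
})

test_that("MACS-style TSV dialect reads header columns including height", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\theight",
               "chr1\t100\t600\t2.5",
               "chr1\t1000\t1400\t0.7"), f)
  ps <- readPeaks(f, dialect = "tsv", factorName = "Eomesa")
  expect_equal(unname(peakHeights(ps)), c(2.5, 0.7))
  ps2 <- readPeaks(f, factorName = "Eomesa")  # auto-detected via header
  expect_equal(peakset_df(ps2), peakset_df(ps))
})

test_that("BED round trip is bit-exact for canonical 6-column files", {
  lines <- c("chr1\t100\t200\tSmad2_1\t2.5\t*",
             "chr1\t500\t900\tSmad2_2\t0.7\t*",
             "chr2\t10\t60\tSmad2_3\t1\t*")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(lines, f)
  ps <- readPeaks(f, factorName = "Smad2")
  g <- withr::local_tempfile(fileext = ".bed")
  writePeaks(ps, g)
  expect_identical(readLines(g), lines)
})

test_that("intervalsOverlap obeys half-open semantics and symmetry", {
  a <- gr_peaks("chr1", 100, 200)
  b <- gr_peaks("chr1", 150, 250)
  c <- gr_peaks("chr1", 200, 300)
  expect_true(intervalsOverlap(a, b))
  expect_false(intervalsOverlap(a, c))        # abutting, no shared base
  expect_true(intervalsOverlap(a, a))         # reflexive
  expect_false(intervalsOverlap(a, gr_peaks("chr2", 100, 200)))
  expect_true(intervalsOverlap(a, b, minOverlap = 50))
  expect_false(intervalsOverlap(a, b, minOverlap = 51))
})

test_that("intervalsOverlap agrees with the quadratic oracle on random pairs", {
  withr::with_seed(101, {
    n <- 50
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    s0 <- sample(0:2000, n, replace = TRUE)
    e0 <- s0 + sample(1:400, n, replace = TRUE)
    gr <- gr_peaks(chrom, s0, e0)
    for (k in c(1, 25)) {
      for (i in seq_len(n)) {
        got <- intervalsOverlap(gr[i], gr, minOverlap = k)
        want <- vapply(seq_len(n), function(j)
          bf_overlap(chrom[i], s0[i], e0[i], chrom[j], s0[j], e0[j], k),
          logical(1))
        expect_identical(got, want)
      }
    }
  })
})

test_that("replicateConsensus spans overlapping groups and drops singletons", {
  r1 <- PeakSet(gr_peaks("chr1", c(100, 300), c(200, 400), height = c(2, 5)),
                factorName = "Smad2")
  r2 <- PeakSet(gr_peaks("chr1", 150, 250, height = 3), factorName = "Smad2")
  cons <- replicateConsensus(r1, r2)
  df <- peakset_df(cons)
  expect_equal(nrow(df), 1L)
  expect_equal(c(df$start0, df$end0), c(100, 250))   # union span
  expect_equal(unname(peakHeights(cons)), 3)          # max of members 2, 3

  r3 <- PeakSet(gr_peaks("chr1", 300, 400), factorName = "Smad2")
  expect_equal(length(replicateConsensus(
    PeakSet(gr_peaks("chr1", 100, 200)), r3)), 0L)
  expect_error(replicateConsensus(
    r1, PeakSet(gr_peaks("chr1", 1, 2), genomeBuild = "other")),
    "configuration error")
})

test_that("replicateConsensus matches the quadratic grouping oracle", {
  withr::with_seed(202, {
    for (rep in 1:5) {
      psA <- random_peakset(200, factorName = "rep1")
      psB <- random_peakset(200, factorName = "rep2")
      for (k in c(1, 40)) {
        got <- peakset_df(replicateConsensus(psA, psB, minOverlap = k))
        want <- bf_consensus(peakset_df(psA), peakset_df(psB), k)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got[c("chrom", "start0", "end0")], want)
      }
    }
  })
})

test_that("replicateConsensus is symmetric and every consensus peak touches both replicates", {
  withr::with_seed(303, {
    psA <- random_peakset(150, factorName = "rep1")
    psB <- random_peakset(150, factorName = "rep2")
    ab <- replicateConsensus(psA, psB)
    ba <- replicateConsensus(psB, psA)
    expect_equal(peakset_df(ab)[c("chrom", "start0", "end0")],
                 peakset_df(ba)[c("chrom", "start0", "end0")])
    grC <- peakRanges(ab)
    expect_true(all(IRanges::overlapsAny(grC, peakRanges(psA))))
    expect_true(all(IRanges::overlapsAny(grC, peakRanges(psB))))
  })
})

test_that("peak height classes match the published RPM boundaries", {
  expect_equal(as.character(classifyPeakHeight(c(0, 1.5, 1.6, 3, 3.5),
                                               "Smad2")),
               c("low", "low", "medium", "medium", "high"))
  expect_equal(as.character(classifyPeakHeight(c(1, 1.2, 1.5, 1.6),
                                               "Eomesa")),
               c("low", "medium", "medium", "high"))
  expect_error(classifyPeakHeight(1, "Foxh1"))
})

test_that("height classification partitions [0, Inf): exactly one label each", {
  withr::with_seed(404, {
    h <- c(0, runif(500, 0, 10), 1.5, 3, 1, 1e6)
    for (f in c("Smad2", "Eomesa")) {
      cls <- classifyPeakHeight(h, f)
      expect_false(anyNA(cls))
      expect_setequal(levels(cls), c("low", "medium", "high"))
    }
  })
})
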