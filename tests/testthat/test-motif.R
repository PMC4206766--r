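jaspar_text <- c(">toy01 TOY",
                 "A  [ 9 0 0 0 9 0 0 0 ]",
                 "C  [ 0 9 0 0 0 0 0 9 ]",
                 "G  [ 0 0 9 0 0 0 9 0 ]",
                 "T  [ 0 0 0 9 0 9 0 0 ]")

test_that("readJaspar parses the 4-row bracketed format and round-trips", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(jaspar_text, f)
  pfm <- readJaspar(f)
  expect_s4_class(pfm, "PFMotif")
  expect_equal(motifLength(pfm), 8L)
  expect_equal(pfm@motifID, "toy01")
  expect_equal(motifConsensus(pfm), "ACGTATGC")
  g <- withr::local_tempfile(fileext = ".jaspar")
  writeJaspar(pfm, g)
  expect_equal(readJaspar(g)@counts, pfm@counts)

  writeLines(jaspar_text[1:4], f)   # only 3 count rows
  expect_error(readJaspar(f), "expected 4")
  writeLines(c(">x y", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), f)
  expect_error(readJaspar(f), "unequal length")
})

test_that("consensus scores maximally and relative score is 1 at the consensus", {
  pfm <- toy_pfm()
  seq <- paste0(random_dna_fixed(10), motifConsensus(pfm),
                random_dna_fixed(12))
  hits <- scanSequence(pfm, seq, relThreshold = 0.99)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$offset, 10)
  expect_equal(plus$rel_score, 1.0)
  ## consensus attains the maximal raw score of the matrix
  M <- logOddsMatrix(pfm)
  expect_equal(plus$raw_score, sum(apply(M, 2, max)))
})

test_that("reverse-complemented sequences score mirror-symmetrically", {
  pfm <- toy_pfm()
  seq <- paste0(random_dna_fixed(15), motifConsensus(pfm),
                random_dna_fixed(7))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scanSequence(pfm, seq, 0.99)
  rev <- scanSequence(pfm, rc, 0.99)
  expect_equal(nrow(fwd), nrow(rev))
  best_f <- fwd[which.max(fwd$rel_score), ]
  best_r <- rev[which.max(rev$rel_score), ]
  expect_equal(best_r$rel_score, best_f$rel_score)
  expect_true(best_f$strand != best_r$strand)
  ## offsets are L-reflected: offset' = nchar - L - offset
  expect_equal(best_r$offset, nchar(seq) - motifLength(pfm) - best_f$offset)
})

test_that("scanSequence equals the brute-force per-window oracle", {
  pfm <- toy_pfm()
  withr::with_seed(121, {
    for (rep in 1:5) {
      seq <- random_dna(300)
      for (thr in c(0.6, 0.8)) {
        got <- scanSequence(pfm, seq, thr)
        want <- bf_scan(pfm, seq, thr)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("N-containing windows are skipped and short sequences yield no hits", {
  pfm <- toy_pfm()
  cons <- motifConsensus(pfm)
  expect_equal(nrow(scanSequence(pfm, "ACGTA", 0)), 0L)   # shorter than L
  ## N at position 4: windows starting at offsets 0-3 cover it and are
  ## skipped; the consensus window at offset 4 survives
  hits <- scanSequence(pfm, paste0("ACGN", cons), 0.95)
  expect_true(all(hits$offset >= 4))
  expect_true(4 %in% hits$offset)
  expect_error(scanSequence(pfm, "ACGTXXXXACGT", 0.5), "invalid characters")
})

test_that("lowering the threshold never removes hits", {
  pfm <- toy_pfm()
  withr::with_seed(232, {
    seq <- random_dna(500)
    key <- function(h) paste(h$offset, h$strand)
    h9 <- key(scanSequence(pfm, seq, 0.9))
    h7 <- key(scanSequence(pfm, seq, 0.7))
    h5 <- key(scanSequence(pfm, seq, 0.5))
    expect_true(all(h9 %in% h7))
    expect_true(all(h7 %in% h5))
  })
})

test_that("peakHitStats finds planted motifs in every peak and none in clean peaks", {
  withr::with_seed(343, {
    pfm <- toy_pfm()
    sim <- simulateGenomeAnnotation(1, 1e5, 0, seed = 5)
    peaks <- tilePeaks(c(chr1 = 1e5), 60, width = 500, gap = 1000)
    planted <- plantMotifs(sim$genome, peaks, pfm, rate = 1,
                           centerSD = 50, seed = 6)
    hs <- peakHitStats(peaks, planted$genome, pfm, 0.8)
    expect_equal(hs$fraction, 1.0)
    expect_equal(hs$nWithHit, 60L)
    ## a genome over {A, C} only cannot contain the consensus (which
    ## needs G and T on either strand), so at threshold 1.0 no peak hits
    ac_genome <- Biostrings::DNAStringSet(c(
      chr1 = paste(sample(c("A", "C"), 1e5, replace = TRUE),
                   collapse = "")))
    clean <- peakHitStats(peaks, ac_genome, pfm, 1.0)
    expect_equal(clean$fraction, 0.0)
  })
})

test_that("peakHitStats rejects peaks outside the genome", {
  pfm <- toy_pfm()
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna_fixed(1000)))
  bad <- PeakSet(gr_peaks("chr1", 900, 1100, id = "p_over"))
  expect_error(peakHitStats(bad, genome, pfm, 0.8), "p_over")
})

test_that("centrally planted motifs give sub-uniform mean |offset|", {
  withr::with_seed(454, {
    pfm <- toy_pfm()
    sim <- simulateGenomeAnnotation(1, 2e5, 0, seed = 8)
    peaks <- tilePeaks(c(chr1 = 2e5), 80, width = 1000, gap = 1000)
    planted <- plantMotifs(sim$genome, peaks, pfm, rate = 1,
                           centerSD = 50, seed = 9)
    hs <- peakHitStats(peaks, planted$genome, pfm, 0.8)
    mc <- motifCentrality(hs$perPeak, peaks, pfm, bin = 100,
                          nRandom = 50, seed = 10)
    expect_lt(mc$meanAbsOffset, mc$nullExpectation)
    ## uniform expectation for |offset| in a width-w peak is ~ w/4
    expect_gt(mc$nullExpectation, 200)
    expect_equal(sum(mc$histogram$count), mc$nHits)
  })
})

test_that("hits placed at peak midpoints give zero mean offset", {
  pfm <- toy_pfm()
  withr::with_seed(565, {
    sim <- simulateGenomeAnnotation(1, 1e5, 0, seed = 11)
    peaks <- tilePeaks(c(chr1 = 1e5), 40, width = 500, gap = 1000)
    planted <- plantMotifs(sim$genome, peaks, pfm, rate = 1,
                           centerSD = 0, seed = 12)
    hs <- peakHitStats(peaks, planted$genome, pfm, 0.8)
    mc <- motifCentrality(hs$perPeak, peaks, pfm, seed = 13)
    expect_equal(mc$meanAbsOffset, 0)
  })
})

test_that("motifSetEnrichment reproduces closed-form cases", {
  eq <- motifSetEnrichment(50, 100, 50, 100)
  expect_equal(eq@statistic, 0)
  expect_equal(eq@foldEnrichment, 1)
  r <- motifSetEnrichment(10, 100, 30, 100)
  expect_equal(r@statistic, 12.5)        # (10,90 / 30,70) Pearson
  expect_equal(r@foldEnrichment, 1 / 3)  # hit-rate ratio A/B
  expect_error(motifSetEnrichment(0, 100, 0, 100), "marginal")
})
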