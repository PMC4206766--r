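test_that("responsive sets split by direction with an inclusive P cutoff", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(1.2, -0.5, 0, 2),
                   pvalue = c(0.01, 0.02, 0.001, 0.5))
  expect_equal(responsiveSets(de, 0.02, "up"), "g1")
  expect_equal(responsiveSets(de, 0.02, "down"), "g2")   # P = cutoff kept
  ## zero fold change lands in neither set; g4 fails the cutoff
  expect_false("g3" %in% c(responsiveSets(de, 0.02, "up"),
                           responsiveSets(de, 0.02, "down")))
  expect_error(responsiveSets(de[1:2], 0.02, "up"), "columns")
})

test_that("planted up/down counts come back exactly from the DE generator", {
  withr::with_seed(147, {
    classes <- stats::setNames(
      factor(rep("none", 500),
             levels = c("A_only", "common", "uncommon", "B_only", "none")),
      paste0("g", 1:500))
    sim <- simulateDETable(classes, baseRate = 0.1, oddsRatios = c(),
                           pThreshold = 0.05, seed = 31)
    up <- responsiveSets(sim$table, 0.05, "up")
    down <- responsiveSets(sim$table, 0.05, "down")
    tr <- sim$truth$genes
    expect_setequal(up, tr$gene_id[tr$responsive & tr$direction == "up"])
    expect_setequal(down, tr$gene_id[tr$responsive & tr$direction == "down"])
  })
})

test_that("chiSquare2x2 reproduces the hand-evaluated Pearson statistic", {
  r <- chiSquare2x2(matrix(c(10, 90, 30, 70), 2, byrow = TRUE))
  expect_equal(r@statistic, 12.5)
  expect_equal(r@df, 1)
  expect_equal(r@pValue, stats::pchisq(12.5, 1, lower.tail = FALSE))
  flat <- chiSquare2x2(matrix(c(25, 75, 25, 75), 2, byrow = TRUE))
  expect_equal(flat@statistic, 0)
  expect_equal(flat@foldEnrichment, 1)
  expect_error(chiSquare2x2(matrix(c(0, 0, 30, 70), 2, byrow = TRUE)),
               "marginal")
})

test_that("chiSquare2x2 agrees with stats::chisq.test without correction", {
  withr::with_seed(258, {
    for (rep in 1:25) {
      m <- matrix(rpois(4, lambda = sample(5:80, 1)) + 1, 2)
      got <- chiSquare2x2(m)
      want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      expect_equal(got@statistic, unname(want$statistic))
      expect_equal(got@pValue, unname(want$p.value))
      expect_equal(got@expected, want$expected,
                   ignore_attr = TRUE)
    }
  })
})

test_that("chiSquare2x2 is invariant under swapping both rows and both columns", {
  m <- matrix(c(12, 34, 56, 78), 2)
  a <- chiSquare2x2(m)
  b <- chiSquare2x2(m[2:1, 2:1])
  expect_equal(a@statistic, b@statistic)
  expect_equal(a@pValue, b@pValue)
  expect_equal(a@oddsRatio, b@oddsRatio)
})

test_that("chi-square power grows with sample size at a fixed odds ratio", {
  tab <- function(n) round(matrix(c(0.2, 0.05, 0.8, 0.95) * n, 2))
  small <- chiSquare2x2(tab(200))@statistic
  big <- chiSquare2x2(tab(2000))@statistic
  expect_gt(big, small)
})

test_that("binding-response association recovers planted odds ratios", {
  withr::with_seed(369, {
    lv <- c("A_only", "common", "uncommon", "B_only", "none")
    cls <- stats::setNames(
      factor(sample(lv, 2000, replace = TRUE,
                    prob = c(0.15, 0.15, 0.05, 0.2, 0.45)), levels = lv),
      paste0("g", 1:2000))
    sim <- simulateDETable(cls, baseRate = 0.1,
                           oddsRatios = c(common = 4), seed = 77)
    resp <- union(responsiveSets(sim$table, 0.05, "up"),
                  responsiveSets(sim$table, 0.05, "down"))
    r <- bindingResponseAssociation(cls, resp, names(cls), "common")
    expect_gt(r@oddsRatio, 2.5)
    expect_lt(r@oddsRatio, 6.5)
    expect_lt(r@pValue, 0.01)
    ## independence for a class with odds ratio 1
    r0 <- bindingResponseAssociation(cls, resp, names(cls), "B_only")
    expect_lt(abs(r0@foldEnrichment - 1), 0.5)
  })
})

test_that("degenerate marginals in the association table raise an error", {
  lv <- c("A_only", "common", "uncommon", "B_only", "none")
  cls <- stats::setNames(factor(c("common", "none"), levels = lv),
                         c("g1", "g2"))
  expect_error(bindingResponseAssociation(cls, c("g1", "g2"),
                                          c("g1", "g2"), "common"),
               "marginal")
  expect_error(bindingResponseAssociation(cls, "g9", c("g1", "g2"),
                                          "common"),
               "outside universe")
})

test_that("term fold enrichment matches the closed form with an exact P", {
  u <- paste0("g", 1:1000)
  gene_set <- u[1:50]
  term_set <- u[c(1:20, 101:180)]         # overlap 20, |term| 100
  r <- termFoldEnrichment(gene_set, term_set, u)
  expect_equal(r$fold, 4.0)               # (20/50) / (100/1000)
  expect_equal(r$overlap, 20L)
  want <- stats::fisher.test(matrix(c(20, 30, 80, 870), 2))$p.value
  expect_equal(r$pValue, want)
  expect_equal(termFoldEnrichment(u, term_set, u)$fold, 1)
  expect_error(termFoldEnrichment(character(), term_set, u), "nonempty")
})

test_that("random gene sets show no term enrichment on average", {
  withr::with_seed(480, {
    u <- paste0("g", 1:500)
    term <- sample(u, 100)
    folds <- replicate(100, termFoldEnrichment(sample(u, 50), term, u)$fold)
    se <- sd(folds) / sqrt(length(folds))
    expect_lt(abs(mean(folds) - 1), 3 * se + 1e-9)
  })
})

test_that("qPCR arithmetic: percent input and fold over control", {
  expect_equal(qpcrFoldEnrichment(0.8, 0.1), 8.0)
  expect_equal(qpcrFoldEnrichment(0.5, 0.5), 1.0)
  expect_error(qpcrFoldEnrichment(0, 0.1), "positive")
  ## ct_target equal to the dilution-adjusted input ct -> 100% input
  expect_equal(percentInput(20, 20 + log2(8), dilution = 8), 100)
  expect_equal(percentInput(22, 20), 100 * 2^-2)
})
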