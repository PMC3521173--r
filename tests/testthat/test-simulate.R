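# The synthetic-data generator: determinism, structure, and the
# substitution process against closed-form expectations.

test_that("configuration validity is enforced", {
  expect_error(simulationConfig(baseFreqs = c(0.5, 0.5, 0.1, 0.1)),
               "sum")
  expect_error(simulationConfig(selectionMultipliers = c(neutral = 0,
                                                         purifying = 0.5,
                                                         positive = 2)),
               "positive")
  expect_error(simulationConfig(branchLengths = c(mouse = -0.1, rat = 0.1,
                                                  human = 0.3)),
               "nonnegative")
  expect_error(simulationConfig(gcFixationBias = -1), ">= 0")
})

test_that("an empty enhancer set still yields valid gene models", {
  cfg <- simulationConfig(seed = 5, nGenes = 6,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0,
                                                  HT = 0),
                          chromLength = 200000L)
  ann <- simulateAnnotation(cfg)
  expect_length(ann$enhancers, 0)
  expect_equal(nrow(ann$truth), 0)
  expect_length(ann$genes@genes, 6)
  expect_true(all(lengths(ann$genes@exonsByTx) >= 1))
})

test_that("the same seed reproduces identical outputs", {
  cfg <- simulationConfig(seed = 99, nGenes = 5,
                          nEnhancersPerTissue = c(FB = 3, MB = 3, LB = 3,
                                                  HT = 3),
                          chromLength = 200000L)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_identical(a$alignment@seqs, b$alignment@seqs)
  expect_identical(a$alignment@ancestor, b$alignment@ancestor)
  expect_identical(as.data.frame(a$genes@covariates),
                   as.data.frame(b$genes@covariates))
})

test_that("every enhancer id in the truth table appears exactly once", {
  sim <- smallStudy()
  expect_equal(sort(sim$truth$enhancer_id), sort(sim$enhancers$enhancer_id))
  expect_false(any(duplicated(sim$truth$enhancer_id)))
})

test_that("gene placement failure names the constraint", {
  cfg <- simulationConfig(seed = 1, nGenes = 50,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0,
                                                  HT = 0),
                          chromLength = 30000L)
  expect_error(simulateAnnotation(cfg), "too crowded|failed to place")
})

test_that("zero branch lengths give three identical sequences", {
  cfg <- simulationConfig(seed = 6, nGenes = 2,
                          nEnhancersPerTissue = c(FB = 1, MB = 0, LB = 0,
                                                  HT = 1),
                          chromLength = 100000L,
                          branchLengths = c(mouse = 0, rat = 0, human = 0))
  sim <- simulateStudy(cfg)
  expect_identical(sim$alignment@seqs[["mouse"]],
                   sim$alignment@seqs[["rat"]])
  expect_identical(sim$alignment@seqs[["mouse"]],
                   sim$alignment@seqs[["human"]])
  expect_identical(sim$alignment@seqs[["mouse"]], sim$alignment@ancestor)
})

test_that("neutral mouse-rat mismatch fraction matches the JC closed form", {
  # equal frequencies and exchangeabilities, single rate category:
  # p(t) = 3/4 (1 - exp(-4 t / 3)) on the mouse+rat path
  t <- 0.2
  cfg <- simulationConfig(seed = 61, nGenes = 0,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0,
                                                  HT = 0),
                          chromLength = 100000L,
                          branchLengths = c(mouse = t / 2, rat = t / 2,
                                            human = 0.1),
                          exchangeabilities = rep(1, 6),
                          baseFreqs = rep(0.25, 4), nCategories = 1L)
  sim <- simulateStudy(cfg)
  sp <- countSitePatterns(sim$alignment, species = c("mouse", "rat"))
  p <- sp$nDiff / sp$nSites
  want <- 0.75 * (1 - exp(-4 * t / 3))
  se <- sqrt(want * (1 - want) / sp$nSites)
  expect_lt(abs(p - want), 3 * se)
})

test_that("enhancer difference rates scale with the class multiplier", {
  # positive class at multiplier 2 versus neutral flanks; compare realized
  # mouse-rat difference fractions with the analytic expectation ratio
  cfg <- simulationConfig(seed = 62, nGenes = 20,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0,
                                                  HT = 25),
                          chromLength = 1200000L,
                          tissueClassProportions = list(
                            HT = c(neutral = 0, purifying = 0, positive = 1)),
                          exchangeabilities = rep(1, 6),
                          baseFreqs = rep(0.25, 4), nCategories = 1L)
  sim <- simulateStudy(cfg)
  sp <- countSitePatterns(sim$alignment, species = c("mouse", "rat"))
  ai <- enhSelScan:::alignIndex(sim$alignment, c("mouse", "rat"))
  enhPos <- unlist(lapply(seq_along(sim$enhancers), function(i)
    GenomicRanges::start(sim$enhancers)[i]:GenomicRanges::end(sim$enhancers)[i]))
  spE <- enhSelScan:::patternsAt(ai, enhPos)
  # neutral flank: everything outside genes and enhancers
  occupied <- IRanges::reduce(c(IRanges::ranges(sim$genes@genes),
                                IRanges::ranges(sim$enhancers)))
  flank <- setdiff(seq_len(1200000L),
                   unlist(lapply(seq_along(occupied), function(i)
                     IRanges::start(occupied)[i]:IRanges::end(occupied)[i])))
  spF <- enhSelScan:::patternsAt(ai, flank)
  expect_gt(spE$nSites, 20000)
  pE <- spE$nDiff / spE$nSites
  pF <- spF$nDiff / spF$nSites
  t <- 0.19
  pExp <- function(tt) 0.75 * (1 - exp(-4 * tt / 3))
  wantRatio <- pExp(2 * t) / pExp(t)
  seRatio <- wantRatio * sqrt(1 / spE$nDiff + 1 / spF$nDiff)
  expect_lt(abs(pE / pF - wantRatio), 3 * seRatio)
})

test_that("forced cross-tissue overlaps consolidate into pleiotropic regions", {
  gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(1000, 1000),
                                                        c(1800, 1800)))
  gr$tissue <- c("HT", "FB")
  gr$enhancer_id <- c("e1", "e2")
  out <- consolidateEnhancers(gr)
  expect_length(out, 1)
  expect_equal(out$pleiotropy, "pleiotropic")
  # and the generator produces some overlapping pairs by construction
  sim <- smallStudy()
  out2 <- consolidateEnhancers(sim$enhancers)
  expect_lt(length(out2), length(sim$enhancers))
})

test_that("gap injection produces gaps only in non-reference rows", {
  cfg <- simulationConfig(seed = 63, nGenes = 2,
                          nEnhancersPerTissue = c(FB = 1, MB = 1, LB = 1,
                                                  HT = 1),
                          chromLength = 100000L)
  ann <- simulateAnnotation(cfg)
  aln <- evolveAlignments(cfg, ann, gapFraction = 0.05)
  expect_false(grepl("-", aln@seqs[["mouse"]], fixed = TRUE))
  gapRat <- lengths(regmatches(aln@seqs[["rat"]],
                               gregexpr("-", aln@seqs[["rat"]])))
  expect_gt(gapRat, 0.02 * 100000)
  # pattern counting excludes the gapped columns
  sp <- countSitePatterns(aln, species = c("mouse", "rat", "human"))
  expect_gt(sp$nExcluded, 0)
  expect_equal(sp$nSites + sp$nExcluded, 100000L)
})

test_that("discrete gamma categories have mean one and recover the JC matrix", {
  for (alpha in c(0.3, 1, 5)) {
    r <- gammaCategoryRates(alpha, 5)
    expect_equal(mean(r), 1, tolerance = 1e-12)
    expect_false(is.unsorted(r))
  }
  expect_equal(gammaCategoryRates(1, 1), 1)
  # transition matrix rows sum to one; detailed balance under GTR
  m <- substitutionModel(c(1, 2, 3, 1, 5, 1), c(0.1, 0.2, 0.3, 0.4))
  P <- transitionMatrix(m, 0.3)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  flux <- outer(m@baseFreqs, rep(1, 4)) * P
  expect_equal(flux, t(flux), tolerance = 1e-10)
  # JC closed form
  jc <- substitutionModel()
  Pjc <- transitionMatrix(jc, 0.3)
  expect_equal(Pjc[1, 2], (1 - exp(-4 * 0.3 / 3)) / 4, tolerance = 1e-10)
})
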