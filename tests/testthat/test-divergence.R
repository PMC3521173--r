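# Pattern counting and the GTR + discrete-gamma ML distance estimator.

# balanced pattern set with mismatch fraction p spread evenly over the 12
# off-diagonal patterns (the Jukes-Cantor limit)
jcPatterns <- function(nSites, p) {
  bases <- c("A", "C", "G", "T")
  nm <- c(); cnt <- c()
  for (b in bases) { nm <- c(nm, paste0(b, b)); cnt <- c(cnt, nSites * (1 - p) / 4) }
  for (b1 in bases) for (b2 in bases) if (b1 != b2) {
    nm <- c(nm, paste0(b1, b2)); cnt <- c(cnt, nSites * p / 12)
  }
  stopifnot(all(abs(cnt - round(cnt)) < 1e-6))  # choose nSites divisible by 48
  cnt <- as.integer(round(cnt))
  out <- list(counts = structure(cnt, names = nm),
              nSites = as.integer(nSites), nDiff = as.integer(round(nSites * p)),
              nExcluded = 0L, nSeq = 2L)
  class(out) <- "sitePatterns"
  out
}

pairSim <- function(seed, t, alpha = 1, nSites = 50000L) {
  cfg <- simulationConfig(seed = seed, nGenes = 0,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0, HT = 0),
                          chromLength = nSites, gammaShape = alpha,
                          branchLengths = c(mouse = t / 2, rat = t / 2,
                                            human = 0.3))
  simulateStudy(cfg)$alignment
}

test_that("pattern counting tallies sites, differences and exclusions", {
  sp <- countSitePatterns(c(mouse = "AAAAAAAAAA", rat = "AAAAAAAAAA"))
  expect_equal(sp$nSites, 10L); expect_equal(sp$nDiff, 0L)
  s1 <- strrep("A", 100); s2 <- paste0(strrep("C", 7), strrep("A", 93))
  sp2 <- countSitePatterns(c(mouse = s1, rat = s2))
  expect_equal(sp2$nSites, 100L); expect_equal(sp2$nDiff, 7L)
  # gaps and ambiguity excluded, oracle by naive per-column scan
  set.seed(1)
  a <- sample(c("A", "C", "G", "T", "-", "N"), 500, replace = TRUE,
              prob = c(rep(0.22, 4), 0.06, 0.06))
  b <- sample(c("A", "C", "G", "T", "-"), 500, replace = TRUE,
              prob = c(rep(0.23, 4), 0.08))
  sp3 <- countSitePatterns(c(mouse = paste(a, collapse = ""),
                             rat = paste(b, collapse = "")))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  expect_equal(sp3$nSites, sum(ok))
  expect_equal(sp3$nDiff, sum(ok & a != b))
  expect_equal(sp3$nExcluded, sum(!ok))
  expect_error(countSitePatterns(c(mouse = "----", rat = "AAAA")) |>
                 fitPairwise(), "no usable sites")
})

test_that("identical sequences give t = 0 without optimization", {
  sp <- countSitePatterns(c(mouse = strrep("ACGT", 30),
                            rat = strrep("ACGT", 30)))
  fit <- fitPairwise(sp)
  expect_equal(substDistance(fit), 0)
  expect_true(isConverged(fit))
})

test_that("the JC-limit distance matches the closed form at p = 0.10", {
  sp <- jcPatterns(12000L, 0.10)
  fit <- fitPairwise(sp, nCategories = 1L)
  expect_equal(substDistance(fit), -0.75 * log(1 - 4 * 0.1 / 3),
               tolerance = 1e-3 / 0.1073)  # absolute 1e-3
  expect_true(isConverged(fit))
})

test_that("distance is invariant to column order (pattern sufficiency)", {
  set.seed(14)
  n <- 2000
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  b <- ifelse(stats::runif(n) < 0.1,
              sample(c("A", "C", "G", "T"), n, replace = TRUE), a)
  perm <- sample.int(n)
  f1 <- fitPairwise(countSitePatterns(c(mouse = paste(a, collapse = ""),
                                        rat = paste(b, collapse = ""))))
  f2 <- fitPairwise(countSitePatterns(c(mouse = paste(a[perm], collapse = ""),
                                        rat = paste(b[perm], collapse = ""))))
  expect_equal(substDistance(f1), substDistance(f2), tolerance = 1e-9)
})

test_that("JC-limit distance increases strictly with the mismatch fraction", {
  ps <- c(0.05, 0.15, 0.30, 0.50, 0.70)
  ts <- vapply(ps, function(p)
    substDistance(fitPairwise(jcPatterns(12000L, p), nCategories = 1L)), 0)
  expect_true(all(diff(ts) > 0))
})

test_that("likelihood at the optimum beats a fixed t = 0.1 start", {
  sp <- jcPatterns(12000L, 0.25)
  fit <- fitPairwise(sp, nCategories = 1L)
  m <- fittedModel(fit)
  llFixed <- -enhSelScan:::pairNLL(0.1, m@exchangeabilities, m@baseFreqs,
                                   m@gammaShape, m@nCategories,
                                   enhSelScan:::decodePatterns(sp))
  expect_gte(logLik(fit), llFixed)
})

test_that("simulated GTR+gamma distances are recovered at 50k sites", {
  aln <- pairSim(seed = 31, t = 0.2, alpha = 1)
  fit <- fitPairwise(countSitePatterns(aln))
  # joint (information-based) SE; recovery within 3 SE, and SE is sane
  se <- max(distanceSE(fit), 0.003)
  expect_lt(abs(substDistance(fit) - 0.2), 3 * se)
  expect_true(isConverged(fit))
})

test_that("pairwise and triple fits agree in the zero-outgroup-branch limit", {
  cfg <- simulationConfig(seed = 37, nGenes = 0,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0, HT = 0),
                          chromLength = 50000L,
                          branchLengths = c(mouse = 0.1, rat = 0.1,
                                            human = 0))
  aln <- simulateStudy(cfg)$alignment
  t3 <- fitTriple(countSitePatterns(aln, species = c("mouse", "rat", "human")))
  t2 <- fitPairwise(countSitePatterns(aln, species = c("mouse", "rat")))
  expect_lt(abs(mouseRatDistance(t3) - substDistance(t2)), 1e-2)
})

test_that("three identical sequences give zero branch lengths", {
  s <- strrep("ACGT", 30)
  t3 <- fitTriple(countSitePatterns(c(mouse = s, rat = s, human = s),
                                    species = c("mouse", "rat", "human")))
  expect_equal(unname(branchLengths(t3)), c(0, 0, 0))
})

test_that("triple branch lengths are recovered on simulated data", {
  cfg <- simulationConfig(seed = 41, nGenes = 0,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0, HT = 0),
                          chromLength = 50000L,
                          branchLengths = c(mouse = 0.1, rat = 0.1,
                                            human = 0.3))
  aln <- simulateStudy(cfg)$alignment
  t3 <- fitTriple(countSitePatterns(aln, species = c("mouse", "rat", "human")))
  bl <- branchLengths(t3)
  # generous bands ~ 3 sampling SEs at 50k sites
  expect_lt(abs(bl[["mouse"]] - 0.1), 0.015)
  expect_lt(abs(bl[["rat"]] - 0.1), 0.015)
  expect_lt(abs(bl[["human"]] - 0.3), 0.03)
})

test_that("the fit agrees with an independent GTR+gamma implementation", {
  skip_if_not_installed("phangorn")
  cfg <- simulationConfig(seed = 53, nGenes = 0,
                          nEnhancersPerTissue = c(FB = 0, MB = 0, LB = 0, HT = 0),
                          chromLength = 20000L,
                          branchLengths = c(mouse = 0.1, rat = 0.1,
                                            human = 0.3))
  aln <- simulateStudy(cfg)$alignment
  myFit <- fitTriple(countSitePatterns(aln,
                                       species = c("mouse", "rat", "human")))
  chars <- rbind(strsplit(aln@seqs[["mouse"]], "")[[1]],
                 strsplit(aln@seqs[["rat"]], "")[[1]],
                 strsplit(aln@seqs[["human"]], "")[[1]])
  rownames(chars) <- c("mouse", "rat", "human")
  pd <- phangorn::phyDat(chars)
  tree <- ape::read.tree(text = "(mouse:0.1,rat:0.1,human:0.3);")
  pml0 <- phangorn::pml(tree, pd, k = 5)
  pmlFit <- suppressWarnings(phangorn::optim.pml(
    pml0, model = "GTR", optGamma = TRUE, optEdge = TRUE,
    control = phangorn::pml.control(trace = 0)))
  tips <- pmlFit$tree$tip.label[pmlFit$tree$edge[, 2]]
  el <- structure(pmlFit$tree$edge.length, names = tips)
  mrPhangorn <- el[["mouse"]] + el[["rat"]]
  expect_equal(mouseRatDistance(myFit), mrPhangorn, tolerance = 0.02)
  expect_equal(unname(branchLengths(myFit)[["human"]]), el[["human"]],
               tolerance = 0.05)
})

test_that("region divergence equals the fit on the concatenated projection", {
  sim <- smallStudy()
  aln <- sim$alignment
  reg <- consolidateEnhancers(sim$enhancers)
  r <- reg[1]
  est <- regionDivergence(r, aln, "pairwise")
  pos <- GenomicRanges::start(r):GenomicRanges::end(r)
  cols <- projectMask(pos, aln, species = c("mouse", "rat"))
  manual <- fitPairwise(countSitePatterns(aln, columns = cols,
                                          species = c("mouse", "rat")))
  expect_equal(substDistance(est), substDistance(manual), tolerance = 1e-9)
  # spanning two disjoint pieces == manual concatenation
  pos2 <- c(pos[1:100], pos[301:400])
  est2 <- regionDivergence(pos2, aln, "pairwise")
  cols2 <- projectMask(pos2, aln, species = c("mouse", "rat"))
  manual2 <- fitPairwise(countSitePatterns(aln, columns = cols2,
                                           species = c("mouse", "rat")))
  expect_equal(substDistance(est2), substDistance(manual2), tolerance = 1e-9)
  # empty projection -> NULL (skipped upstream)
  expect_null(regionDivergence(10^7 + 1:10, aln, "pairwise"))
})

test_that("small units fall back to the pooled model with t-only optimization", {
  sim <- smallStudy()
  aln <- sim$alignment
  sp <- countSitePatterns(aln, columns = 1:150, species = c("mouse", "rat"))
  shared <- substitutionModel(c(1, 4, 1, 1, 4, 1), c(0.29, 0.21, 0.21, 0.29),
                              gammaShape = 1, nCategories = 5L)
  fit <- fitPairwise(sp, fixModel = shared)
  expect_identical(fittedModel(fit)@exchangeabilities,
                   shared@exchangeabilities)
  expect_true(isConverged(fit))
})
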