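test_that("overlapping peaks from two tissues merge into one pleiotropic region", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 151), c(200, 250)))  # 0-based [100,200) + [150,250)
  gr$tissue <- c("HT", "FB")
  out <- consolidateEnhancers(gr)
  expect_length(out, 1)
  expect_equal(GenomicRanges::start(out), 101)
  expect_equal(GenomicRanges::end(out), 250)
  expect_equal(out$tissues, "FB,HT")
  expect_equal(out$pleiotropy, "pleiotropic")
})

test_that("disjoint same-tissue peaks stay separate and specific", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301), c(200, 400)))
  gr$tissue <- c("HT", "HT")
  out <- consolidateEnhancers(gr)
  expect_length(out, 2)
  expect_true(all(out$pleiotropy == "specific"))
})

test_that("bookended intervals are not merged", {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 201), c(200, 300)))  # [100,200) + [200,300)
  gr$tissue <- c("HT", "FB")
  expect_length(consolidateEnhancers(gr), 2)
})

test_that("malformed records are rejected with their index", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), c(20, 49)))
  gr$tissue <- c("HT", "FB")
  expect_error(consolidateEnhancers(gr), "index: 2")
})

test_that("consolidation matches a brute-force transitive-closure oracle", {
  set.seed(42)
  n <- 500
  start <- sample.int(20000, n, replace = TRUE)
  width <- sample(50:400, n, replace = TRUE)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, start + width - 1))
  gr$tissue <- sample(c("FB", "MB", "LB", "HT"), n, replace = TRUE)
  out <- consolidateEnhancers(gr)
  oracle <- oracleMerge(start, start + width - 1)
  expect_equal(GenomicRanges::start(out), oracle$start)
  expect_equal(GenomicRanges::end(out), oracle$end)
  # total covered bp is preserved
  expect_equal(sum(GenomicRanges::width(out)),
               sum(IRanges::width(IRanges::reduce(IRanges::ranges(gr)))))
})

test_that("consolidation is idempotent and order-invariant", {
  set.seed(7)
  n <- 200
  start <- sample.int(5000, n, replace = TRUE)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start, start + sample(20:200, n, replace = TRUE)))
  gr$tissue <- sample(c("FB", "HT"), n, replace = TRUE)
  out1 <- consolidateEnhancers(gr)
  # idempotence (re-feed regions as records)
  again <- out1
  again$tissue <- out1$tissues # single labels not required by the merge
  out2 <- consolidateEnhancers(again)
  expect_equal(GenomicRanges::ranges(out1), GenomicRanges::ranges(out2))
  # order invariance
  out3 <- consolidateEnhancers(gr[sample(seq_along(gr))])
  expect_equal(GenomicRanges::ranges(out1), GenomicRanges::ranges(out3))
  expect_equal(out1$tissues, out3$tissues)
})

test_that("specific and pleiotropic counts partition the regions", {
  sim <- smallStudy()
  out <- consolidateEnhancers(sim$enhancers)
  expect_equal(sum(out$pleiotropy == "specific") +
                 sum(out$pleiotropy == "pleiotropic"), length(out))
  expect_true(all((out$n_tissues == 1) == (out$pleiotropy == "specific")))
})

test_that("pleiotropy classification follows the single-tissue rule", {
  expect_equal(classifyPleiotropy("HT"), "specific")
  expect_equal(classifyPleiotropy(c("HT", "MB")), "pleiotropic")
  expect_equal(classifyPleiotropy("HT,MB"), "pleiotropic")
  expect_error(classifyPleiotropy(character(0)), "nonempty")
})

test_that("nearest-gene assignment handles containment and boundary distance", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  region$region_id <- "r1"
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(301, 501), c(400, 600)))
  genes$gene_id <- c("gA", "gB")
  got <- assignNearestGene(region, genes)
  expect_equal(as.character(got), "gA")
  expect_equal(attr(got, "distance"), 100)
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(320, 340))
  got2 <- assignNearestGene(inside, genes)
  expect_equal(as.character(got2), "gA")
  expect_equal(attr(got2, "distance"), 0)
})

test_that("nearest-gene assignment agrees with the exhaustive-scan oracle", {
  set.seed(11)
  nr <- 200; ng <- 60
  rs <- sample.int(50000, nr); re <- rs + sample(50:500, nr, replace = TRUE)
  gs <- sample.int(50000, ng); ge <- gs + sample(200:3000, ng, replace = TRUE)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs, re))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gs, ge))
  genes$gene_id <- sprintf("g%03d", sample.int(ng))
  got <- as.character(assignNearestGene(regions, genes))
  want <- vapply(seq_len(nr), function(i)
    oracleNearest(rs[i], re[i], gs, ge, genes$gene_id), "")
  expect_equal(got, want)
})

test_that("ortholog restriction can pick a different gene than plain nearest", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 150))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(200, 900), c(300, 1000)))
  genes$gene_id <- c("near_noOrtho", "far_ortho")
  genes$ortholog_rat <- c(FALSE, TRUE)
  expect_equal(as.character(assignNearestGene(region, genes, "none")),
               "near_noOrtho")
  expect_equal(as.character(assignNearestGene(region, genes, "rat")),
               "far_ortho")
  # no ortholog_human flags at all -> empty candidate set -> NA
  expect_true(is.na(assignNearestGene(region, genes, "human")))
})

test_that("recombination rate is looked up by region midpoint", {
  win <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 1001), c(1000, 2000)))
  win$rate <- c(0.5, 2.5)
  # straddles the boundary; midpoint (850+1150)/2 = 1000 -> first window
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(850, 1150))
  expect_equal(attachRecombination(r, win)$recombination_rate, 0.5)
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1050, 1150))
  expect_equal(attachRecombination(r2, win)$recombination_rate, 2.5)
  outside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))
  expect_true(is.na(attachRecombination(outside, win)$recombination_rate))
  overlapping <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 500), c(1000, 1500)))
  overlapping$rate <- c(1, 2)
  expect_error(attachRecombination(r, overlapping), "overlap")
})

test_that("midpoint lookup agrees with a linear-scan oracle on random layouts", {
  set.seed(3)
  edges <- sort(sample.int(100000, 30))
  win <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, edges + 1), c(edges, 110000)))
  win$rate <- stats::runif(length(win), 0, 3)
  rs <- sample.int(109000, 150); re <- rs + sample(10:900, 150, replace = TRUE)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rs, re))
  got <- attachRecombination(regions, win)$recombination_rate
  mid <- (rs + re) %/% 2
  want <- vapply(mid, function(m) {
    hit <- which(GenomicRanges::start(win) <= m & GenomicRanges::end(win) >= m)
    if (length(hit)) win$rate[hit[1]] else NA_real_
  }, 0)
  expect_equal(got, want)
})

test_that("regions annotate end to end on simulated data", {
  sim <- smallStudy()
  regions <- consolidateEnhancers(sim$enhancers)
  regions <- annotateRegions(regions, sim$genes, sim$recomb)
  expect_true(all(!is.na(regions$nearest_gene_id)))
  expect_true(all(c("neutral_reference_gene_id", "recombination_rate") %in%
                    colnames(S4Vectors::mcols(regions))))
})
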