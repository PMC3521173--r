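# Helpers to build a one-gene GeneModels on a given genome string.
makeGene <- function(exonStarts, exonEnds, cdsStarts, cdsEnds, strand = "+",
                     geneId = "g1") {
  exons <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(exonStarts, exonEnds), strand = strand)
  cds <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(cdsStarts, cdsEnds), strand = strand)
  genes <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(min(exonStarts), max(exonEnds)), strand = strand)
  genes$gene_id <- geneId
  genes$ortholog_rat <- TRUE
  genes$ortholog_human <- TRUE
  new("GeneModels", genes = genes,
      exonsByTx = GenomicRanges::GRangesList(structure(list(exons),
                                             names = paste0(geneId, ".t1"))),
      cdsByTx = GenomicRanges::GRangesList(structure(list(cds),
                                           names = paste0(geneId, ".t1"))),
      txGene = S4Vectors::DataFrame(tx_id = paste0(geneId, ".t1"),
                                    gene_id = geneId),
      covariates = S4Vectors::DataFrame(gene_id = geneId, phenotypes = ""))
}

asGenome <- function(s) {
  g <- Biostrings::DNAStringSet(s); names(g) <- "chrT"; g
}

test_that("a hand-built CDS yields exactly the fourfold third positions", {
  # ATG GGA GCT TAA: Met (none), Gly GGN (fourfold), Ala GCN (fourfold),
  # stop excluded from the annotated CDS
  genome <- asGenome("ATGGGAGCTTAA")
  gm <- makeGene(1, 12, 1, 9)   # CDS = ATG GGA GCT (stop outside CDS)
  mask <- fourfoldSites(gm, "g1", genome)
  expect_equal(maskPositions(mask), c(6L, 9L))
})

test_that("a CDS of repeated single-codon amino acids has no fourfold sites", {
  genome <- asGenome(strrep("ATG", 10))
  gm <- makeGene(1, 30, 1, 30)
  expect_length(maskPositions(fourfoldSites(gm, "g1", genome)), 0)
})

test_that("minus-strand genes mirror their plus-strand reverse complement", {
  set.seed(5)
  cds <- randomCds(50)
  n <- nchar(cds)
  genomePlus <- asGenome(cds)
  gmPlus <- makeGene(1, n, 1, n, strand = "+")
  maskPlus <- maskPositions(fourfoldSites(gmPlus, "g1", genomePlus))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genomeMinus <- asGenome(rc)
  gmMinus <- makeGene(1, n, 1, n, strand = "-")
  maskMinus <- maskPositions(fourfoldSites(gmMinus, "g1", genomeMinus))
  expect_length(maskMinus, length(maskPlus))
  expect_equal(sort(n + 1L - maskMinus), maskPlus)  # mirrored coordinates
})

test_that("fourfold calls agree with brute-force codon synonymy on random CDS", {
  set.seed(21)
  for (rep in 1:100) {
    nc <- sample(5:40, 1)
    cds <- randomCds(nc)
    gm <- makeGene(1, nchar(cds), 1, nchar(cds))
    got <- maskPositions(fourfoldSites(gm, "g1", asGenome(cds)))
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    want <- unname(which(vapply(codons, oracleFourfoldCodon, TRUE))) * 3L
    expect_equal(got, want)
    expect_lte(length(got), nchar(cds) / 3)
  }
})

test_that("CDS defects are rejected with a reason", {
  gm <- makeGene(1, 11, 1, 11)  # length 11, not a codon multiple
  expect_error(fourfoldSites(gm, "g1", asGenome(strrep("A", 11))),
               "multiple_of_3")
  gm2 <- makeGene(1, 9, 1, 9)
  expect_error(fourfoldSites(gm2, "g1", asGenome("ATGTAAGGG")),
               "internal_stop")
  # ambiguity codes: codon skipped, not fatal
  gm3 <- makeGene(1, 9, 1, 9)
  mask <- fourfoldSites(gm3, "g1", asGenome("ATGGNAGGA"))
  expect_equal(maskPositions(mask), 9L)  # only the clean GGA counts
})

test_that("intron mask drops the first intron in transcription order", {
  # exons [1,100], [601,700], [1001,1100], [1301,1400] (+): introns 500/300/200
  gm <- makeGene(c(1, 601, 1001, 1301), c(100, 700, 1100, 1400),
                 c(21, 601, 1001, 1301), c(100, 700, 1100, 1320))
  mask <- intronSites(gm, "g1")
  pos <- maskPositions(mask)
  expect_length(pos, 300 + 200)
  expect_true(all(pos >= 701))  # the 500 bp first intron is gone
  expect_equal(attr(mask@positions, "first_intron_removed_bp"), 500L)
  # no overlap with exons
  exonPos <- unlist(lapply(seq_len(4), function(i)
    GenomicRanges::start(gm@exonsByTx[[1]])[i]:GenomicRanges::end(gm@exonsByTx[[1]])[i]))
  expect_length(intersect(pos, exonPos), 0)
})

test_that("minus-strand first intron is the rightmost gap in genome coordinates", {
  gm <- makeGene(c(1, 601, 1001), c(100, 700, 1100),
                 c(1, 601, 1001), c(100, 700, 1080), strand = "-")
  pos <- maskPositions(intronSites(gm, "g1"))
  # introns: [101,600] and [701,1000]; first in tx order is [701,1000]
  expect_true(all(pos >= 101 & pos <= 600))
})

test_that("intronless and single-intron genes yield empty intron masks", {
  gm0 <- makeGene(1, 300, 1, 300)
  expect_length(maskPositions(intronSites(gm0, "g1")), 0)
  gm1 <- makeGene(c(1, 501), c(100, 600), c(1, 501), c(100, 580))
  expect_length(maskPositions(intronSites(gm1, "g1")), 0)
})

test_that("longest isoform is chosen by summed exon length with stable ties", {
  gm <- makeGene(c(1, 601), c(100, 700), c(1, 601), c(100, 700))
  # add a second, shorter isoform
  gm@exonsByTx <- GenomicRanges::GRangesList(
    g1.t1 = gm@exonsByTx[[1]],
    g1.t2 = gm@exonsByTx[[1]][1])
  gm@cdsByTx <- GenomicRanges::GRangesList(
    g1.t1 = gm@cdsByTx[[1]],
    g1.t2 = gm@cdsByTx[[1]][1])
  gm@txGene <- S4Vectors::DataFrame(tx_id = c("g1.t1", "g1.t2"),
                                    gene_id = c("g1", "g1"))
  expect_equal(unname(pickLongestIsoform(gm)["g1"]), "g1.t1")
})

test_that("mask projection matches a per-position linear scan on gapped blocks", {
  set.seed(9)
  aln <- new("TripleAlignment", chrom = "chrT", start = 11L,
             seqs = c(mouse = "ACGT-ACGTAC-GTAC",
                      rat   = "ACGTTAC-TACCGTAC",
                      human = "ACTTTACGTACCGTNC"),
             ancestor = "", siteRate = numeric(0),
             truthMeta = S4Vectors::DataFrame())
  positions <- 8:30
  got <- projectMask(positions, aln)
  # linear scan oracle
  mouse <- strsplit(aln@seqs[["mouse"]], "")[[1]]
  rat <- strsplit(aln@seqs[["rat"]], "")[[1]]
  human <- strsplit(aln@seqs[["human"]], "")[[1]]
  g <- 10L; want <- integer(0)
  for (col in seq_along(mouse)) {
    if (mouse[col] != "-") g <- g + 1L
    if (mouse[col] != "-" && g %in% positions &&
        !"-" %in% c(rat[col], human[col]) &&
        all(c(mouse[col], rat[col], human[col]) %in% c("A", "C", "G", "T")))
      want <- c(want, col)
  }
  expect_equal(as.integer(got), want)
  expect_equal(attr(got, "n_outside"),
               sum(positions > 10 + sum(mouse != "-")) + sum(positions <= 10))
  # disjoint mask -> empty; full clean block -> all columns
  expect_length(projectMask(1000:1010, aln), 0)
  cleanAln <- new("TripleAlignment", chrom = "chrT", start = 1L,
                  seqs = c(mouse = "ACGT", rat = "ACGT", human = "ACGT"),
                  ancestor = "", siteRate = numeric(0),
                  truthMeta = S4Vectors::DataFrame())
  expect_equal(as.integer(projectMask(1:4, cleanAln)), 1:4)
})

test_that("simulated gene masks respect the structural invariants", {
  sim <- smallStudy()
  genome <- referenceGenome(sim$alignment)
  masks <- geneSiteMasks(sim$genes, genome)
  summ <- maskSummary(masks)
  for (g in names(masks$fourfold)) {
    tx <- pickLongestIsoform(sim$genes)[[g]]
    cdsLen <- sum(IRanges::width(sim$genes@cdsByTx[[tx]]))
    expect_lte(length(maskPositions(masks$fourfold[[g]])), cdsLen / 3)
    expect_false(is.unsorted(maskPositions(masks$fourfold[[g]]),
                             strictly = TRUE))
  }
  # intron masks avoid all exons of the longest isoform
  for (g in names(masks$intron)) {
    pos <- maskPositions(masks$intron[[g]])
    if (length(pos) == 0) next
    tx <- pickLongestIsoform(sim$genes)[[g]]
    ex <- sim$genes@exonsByTx[[tx]]
    hits <- IRanges::overlapsAny(IRanges::IRanges(pos, width = 1),
                                 IRanges::ranges(ex))
    expect_false(any(hits))
  }
  # genes recorded intronless/single-intron have empty intron masks
  n0 <- sim$genes@genes$gene_id[sim$genes@genes$n_introns <= 1]
  for (g in n0) expect_length(maskPositions(masks$intron[[g]]), 0)
})
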