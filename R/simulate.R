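## Synthetic-data generator: one chromosome of gene models and
## tissue-labelled enhancers, evolved along ((mouse, rat), human) under
## GTR + discrete gamma with per-region selection multipliers and an optional
## GC-fixation bias.  Every downstream stage of the package can be run
## against the ground truth recorded here.

TISSUES <- c("FB", "MB", "LB", "HT")
SELECTION_CLASSES <- c("neutral", "purifying", "positive")

#' Build a simulation configuration
#'
#' All defaults together define the study conditions the package is tested
#' under: a rodent-like mouse-rat divergence of about 0.19 substitutions per
#' neutral site with a primate outgroup, transition-biased exchangeabilities,
#' moderate rate heterogeneity (alpha = 1, 5 categories), four embryonic
#' tissues, and selection multipliers 1 / 0.5 / 2 for the neutral, purifying
#' and positive classes.
#'
#' @param seed integer seed; the whole simulation is a deterministic function
#'   of the configuration.
#' @param nGenes,nEnhancersPerTissue,chromLength feature counts and
#'   chromosome length (bp).
#' @param branchLengths named numeric, expected substitutions/site for the
#'   mouse, rat and human lineages.
#' @param exchangeabilities,baseFreqs,gammaShape,nCategories GTR + gamma
#'   parameters, see \code{\link{substitutionModel}}.
#' @param selectionMultipliers,classProportions named over classes
#'   \code{neutral}, \code{purifying}, \code{positive}.
#' @param tissueClassProportions optional named list of per-tissue class
#'   proportion vectors overriding \code{classProportions}.
#' @param gcFixationBias nonnegative; rates into G/C are multiplied by
#'   \code{1 + gcFixationBias} (0 = unbiased).
#' @param expressionMeanlog,expressionSdlog log-normal parameters of the
#'   per-gene expression signal (right-skewed positive values spanning the
#'   200/400 binning thresholds).
#' @param essentialFraction,phenotypeUnknownFraction knockout-phenotype
#'   probabilities.
#' @param intronlessFraction,singleIntronFraction gene-structure
#'   probabilities (such genes lack a usable intron reference).
#' @param cdsCodonsRange,intronLengthRange,enhancerLengthRange,utrLength
#'   structural size ranges (codons or bp).
#' @param cdsConstraintMultiplier purifying rate multiplier at codon
#'   positions 1 and 2.
#' @param enhancerOffsetRange bp distance from an enhancer to its anchor
#'   gene.
#' @param crossTissueOverlapFraction fraction of enhancers placed overlapping
#'   an enhancer of another tissue.
#' @param orthologFraction per-species probability of a one-to-one ortholog.
#' @param altIsoformFraction fraction of multi-exon genes with a second,
#'   shorter isoform.
#' @param recombWindow recombination-map window size (bp).
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 5,
#'                         nEnhancersPerTissue = c(FB = 2, MB = 2, LB = 2, HT = 2),
#'                         chromLength = 200000L)
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 60L,
                             nEnhancersPerTissue = c(FB = 50L, MB = 50L,
                                                     LB = 50L, HT = 50L),
                             chromLength = 3000000L,
                             branchLengths = c(mouse = 0.09, rat = 0.10,
                                               human = 0.35),
                             exchangeabilities = c(1, 4, 1, 1, 4, 1),
                             baseFreqs = c(0.29, 0.21, 0.21, 0.29),
                             gammaShape = 1,
                             nCategories = 5L,
                             selectionMultipliers = c(neutral = 1,
                                                      purifying = 0.5,
                                                      positive = 2),
                             classProportions = c(neutral = 0.2,
                                                  purifying = 0.7,
                                                  positive = 0.1),
                             tissueClassProportions = list(),
                             gcFixationBias = 0,
                             expressionMeanlog = log(250),
                             expressionSdlog = 0.8,
                             essentialFraction = 0.3,
                             phenotypeUnknownFraction = 0.1,
                             intronlessFraction = 0.08,
                             singleIntronFraction = 0.08,
                             cdsCodonsRange = c(250L, 600L),
                             intronLengthRange = c(300L, 1200L),
                             enhancerLengthRange = c(700L, 1500L),
                             utrLength = 60L,
                             cdsConstraintMultiplier = 0.1,
                             enhancerOffsetRange = c(500L, 5000L),
                             crossTissueOverlapFraction = 0.08,
                             orthologFraction = 0.9,
                             altIsoformFraction = 0.25,
                             recombWindow = 100000L) {
  cfg <- new("SimulationConfig",
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    nEnhancersPerTissue = structure(as.integer(nEnhancersPerTissue),
                                    names = names(nEnhancersPerTissue)),
    chromLength = as.integer(chromLength),
    branchLengths = branchLengths,
    model = substitutionModel(exchangeabilities, baseFreqs, gammaShape,
                              nCategories),
    selectionMultipliers = selectionMultipliers,
    classProportions = classProportions,
    tissueClassProportions = tissueClassProportions,
    gcFixationBias = as.numeric(gcFixationBias),
    expressionMeanlog = expressionMeanlog, expressionSdlog = expressionSdlog,
    essentialFraction = essentialFraction,
    phenotypeUnknownFraction = phenotypeUnknownFraction,
    intronlessFraction = intronlessFraction,
    singleIntronFraction = singleIntronFraction,
    cdsCodonsRange = as.integer(cdsCodonsRange),
    intronLengthRange = as.integer(intronLengthRange),
    enhancerLengthRange = as.integer(enhancerLengthRange),
    utrLength = as.integer(utrLength),
    cdsConstraintMultiplier = cdsConstraintMultiplier,
    enhancerOffsetRange = as.integer(enhancerOffsetRange),
    crossTissueOverlapFraction = crossTissueOverlapFraction,
    orthologFraction = orthologFraction,
    altIsoformFraction = altIsoformFraction,
    recombWindow = as.integer(recombWindow))
  validObject(cfg)
  cfg
}

## ---- internal structural helpers -----------------------------------------

## k parts each >= minPart summing to total (deterministic fix-up of rounding)
splitLength <- function(total, k, minPart) {
  if (k == 1L) return(total)
  assertThat(total >= k * minPart,
             "cannot split %d bp into %d parts of >= %d bp", total, k, minPart)
  free <- total - k * minPart
  cuts <- sort(stats::runif(k - 1L))
  parts <- minPart + round(diff(c(0, cuts, 1)) * free)
  parts[k] <- total - sum(parts[-k])
  if (parts[k] < minPart) { # rare rounding fix-up
    i <- which.max(parts[-k])
    parts[i] <- parts[i] - (minPart - parts[k])
    parts[k] <- minPart
  }
  parts
}

## One gene's structure in transcription order.
## Returns list(blocks, span): blocks is a data.frame of tx-order segments
## (type exon/intron, cds_start/cds_end offsets inside the exon or NA).
geneStructure <- function(cfg) {
  u <- stats::runif(1)
  nIntrons <- if (u < cfg@intronlessFraction) 0L
    else if (u < cfg@intronlessFraction + cfg@singleIntronFraction) 1L
    else sample(2:6, 1L)
  nExons <- nIntrons + 1L
  codons <- sample(cfg@cdsCodonsRange[1]:cfg@cdsCodonsRange[2], 1L)
  cdsLen <- 3L * codons
  cdsParts <- splitLength(cdsLen, nExons, minPart = 12L)
  intronLens <- if (nIntrons > 0L)
    sample(cfg@intronLengthRange[1]:cfg@intronLengthRange[2], nIntrons,
           replace = TRUE) else integer(0)
  exonLens <- cdsParts
  exonLens[1L] <- exonLens[1L] + cfg@utrLength          # 5' UTR
  exonLens[nExons] <- exonLens[nExons] + cfg@utrLength  # 3' UTR
  cdsOffInExon <- rep(1L, nExons)
  cdsOffInExon[1L] <- cfg@utrLength + 1L
  if (nExons == 1L) cdsOffInExon[1L] <- cfg@utrLength + 1L
  blocks <- data.frame(
    type = rep(c("exon", "intron"), length.out = 2L * nExons - 1L),
    len = as.integer(
      as.vector(rbind(exonLens, c(intronLens, NA)))[seq_len(2L * nExons - 1L)]),
    stringsAsFactors = FALSE)
  exonIdx <- which(blocks$type == "exon")
  blocks$cds_start <- NA_integer_
  blocks$cds_end <- NA_integer_
  blocks$cds_start[exonIdx] <- cdsOffInExon
  blocks$cds_end[exonIdx] <- cdsOffInExon + cdsParts - 1L
  list(blocks = blocks, span = sum(blocks$len), nIntrons = nIntrons,
       cdsLen = cdsLen)
}

## Map transcription-order blocks to genomic GRanges for a gene at
## [geneStart, geneStart+span-1] on `strand`.  Returns list(exons, cds) as
## GRanges in genomic order, plus codon-position annotation for CDS.
layoutGene <- function(struct, chrom, geneStart, strand) {
  blocks <- struct$blocks
  txEnd <- cumsum(blocks$len)
  txStart <- txEnd - blocks$len + 1L
  span <- struct$span
  toGenomic <- function(a, b) { # tx-order offsets (1-based) -> genomic range
    if (strand == "+") c(geneStart + a - 1L, geneStart + b - 1L)
    else c(geneStart + span - b, geneStart + span - a)
  }
  exonIdx <- which(blocks$type == "exon")
  exonRanges <- t(vapply(exonIdx, function(i)
    toGenomic(txStart[i], txEnd[i]), numeric(2)))
  cdsRanges <- t(vapply(exonIdx, function(i)
    toGenomic(txStart[i] + blocks$cds_start[i] - 1L,
              txStart[i] + blocks$cds_end[i] - 1L), numeric(2)))
  ord <- order(exonRanges[, 1])
  exons <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(exonRanges[ord, 1], exonRanges[ord, 2]), strand = strand)
  cds <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(cdsRanges[ord, 1], cdsRanges[ord, 2]), strand = strand)
  list(exons = exons, cds = cds)
}

## any interval [s, e] overlapping the set {[starts_i, ends_i]}?
## plain-vector arithmetic: placement runs this millions of times
anyOverlap <- function(s, e, starts, ends) {
  length(starts) > 0L && any(starts <= e & ends >= s)
}

## Place a feature of `len` bp on [1, chromLength] avoiding occupied
## intervals (plain start/end vectors), uniform rejection sampling with
## bounded retries.
placeFeature <- function(len, chromLength, starts, ends, gap = 0L,
                         maxTries = 500L, what = "feature") {
  for (i in seq_len(maxTries)) {
    s <- sample.int(chromLength - len, 1L)
    if (!anyOverlap(s - gap, s + len - 1L + gap, starts, ends))
      return(c(s, s + len - 1L))
  }
  stop(sprintf(
    "failed to place %s of %d bp after %d tries: chromosome too crowded (chromLength = %d)",
    what, len, maxTries, chromLength), call. = FALSE)
}

## ---- annotation ----------------------------------------------------------

#' Simulate gene models, enhancers and covariates
#'
#' Places non-overlapping genes (with exon/intron/CDS structure, optional
#' second isoform, ortholog flags) and tissue-labelled enhancers near genes
#' on one chromosome, assigns each enhancer a ground-truth selection class,
#' and draws per-gene covariates (knockout phenotypes and 61 per-tissue
#' expression signals).  A deliberate fraction of enhancers overlaps
#' enhancers of other tissues so that interval consolidation is exercised.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{config}, \code{genes}
#'   (\linkS4class{GeneModels}), \code{enhancers} (\code{GRanges} with
#'   metadata \code{enhancer_id}, \code{tissue}, \code{class},
#'   \code{multiplier}, \code{anchor_gene}), \code{truth}
#'   (\code{DataFrame}, one row per enhancer) and \code{recomb}
#'   (\code{GRanges} of recombination windows with a \code{rate} column,
#'   cM/Mb).
#' @examples
#' ann <- simulateAnnotation(simulationConfig(seed = 7, nGenes = 4,
#'   nEnhancersPerTissue = c(FB = 2, MB = 0, LB = 0, HT = 2),
#'   chromLength = 150000L))
#' length(ann$enhancers)
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  chrom <- "chrS"
  chromLength <- config@chromLength

  ## -- gene structures and placement --
  set.seed(subSeed(config@seed, 1L))
  geneIds <- sprintf("gene_%03d", seq_len(config@nGenes))
  occS <- integer(0); occE <- integer(0)
  exonsByTx <- list(); cdsByTx <- list()
  txGeneRows <- list()
  geneStrand <- character(config@nGenes)
  geneNIntrons <- integer(config@nGenes)
  for (i in seq_len(config@nGenes)) {
    struct <- geneStructure(config)
    strand <- sample(c("+", "-"), 1L)
    where <- placeFeature(struct$span, chromLength, occS, occE,
                          gap = 200L, what = geneIds[i])
    occS <- c(occS, where[1]); occE <- c(occE, where[2])
    lay <- layoutGene(struct, chrom, where[1], strand)
    tx1 <- paste0(geneIds[i], ".t1")
    exonsByTx[[tx1]] <- lay$exons
    cdsByTx[[tx1]] <- lay$cds
    txGeneRows[[tx1]] <- geneIds[i]
    geneStrand[i] <- strand
    geneNIntrons[i] <- struct$nIntrons
    ## optional second, shorter isoform: drop the last genomic-order exon in
    ## transcription order (always strictly shorter than tx1)
    if (struct$nIntrons >= 1L &&
        stats::runif(1) < config@altIsoformFraction) {
      tx2 <- paste0(geneIds[i], ".t2")
      ex <- exonsByTx[[tx1]]; cd <- cdsByTx[[tx1]]
      drop <- if (strand == "+") length(ex) else 1L   # last in tx order
      ex2 <- ex[-drop]; cd2 <- cd[-drop]
      ## keep CDS a codon multiple: trim the new terminal CDS range
      w <- sum(IRanges::width(cd2)); trim <- w %% 3L
      if (trim > 0L && length(cd2) > 0L) {
        j <- if (strand == "+") length(cd2) else 1L
        if (strand == "+")
          IRanges::end(cd2)[j] <- IRanges::end(cd2)[j] - trim
        else
          IRanges::start(cd2)[j] <- IRanges::start(cd2)[j] + trim
      }
      exonsByTx[[tx2]] <- ex2
      cdsByTx[[tx2]] <- cd2
      txGeneRows[[tx2]] <- geneIds[i]
    }
  }

  genes <- if (config@nGenes > 0L) {
    g <- GenomicRanges::GRanges(
      rep(chrom, config@nGenes),
      IRanges::IRanges(
        vapply(geneIds, function(id)
          min(GenomicRanges::start(exonsByTx[[paste0(id, ".t1")]])), 0),
        vapply(geneIds, function(id)
          max(GenomicRanges::end(exonsByTx[[paste0(id, ".t1")]])), 0)),
      strand = geneStrand)
    g$gene_id <- geneIds
    g$n_introns <- geneNIntrons
    g
  } else GenomicRanges::GRanges()

  set.seed(subSeed(config@seed, 2L))
  if (config@nGenes > 0L) {
    genes$ortholog_rat <- stats::runif(config@nGenes) < config@orthologFraction
    genes$ortholog_human <- stats::runif(config@nGenes) < config@orthologFraction
  }

  ## -- covariates --
  set.seed(subSeed(config@seed, 3L))
  benign <- c("coat_color", "behavioral", "morphology", "immune", "metabolic")
  phen <- character(config@nGenes)
  for (i in seq_len(config@nGenes)) {
    if (stats::runif(1) < config@phenotypeUnknownFraction) phen[i] <- ""
    else if (stats::runif(1) < config@essentialFraction)
      phen[i] <- sample(c("premature_death", "infertility"), 1L)
    else phen[i] <- paste(sample(benign, sample(1:2, 1L)), collapse = ",")
  }
  exprMat <- matrix(NA_real_, nrow = config@nGenes, ncol = 61L,
                    dimnames = list(NULL, sprintf("expr_%02d", 1:61)))
  for (i in seq_len(config@nGenes)) {
    m <- stats::rlnorm(1, config@expressionMeanlog, config@expressionSdlog)
    exprMat[i, ] <- stats::rlnorm(61L, log(m), 0.4)
  }
  covariates <- S4Vectors::DataFrame(gene_id = geneIds, phenotypes = phen,
                                     as.data.frame(exprMat))

  geneModels <- new("GeneModels",
    genes = genes,
    exonsByTx = GenomicRanges::GRangesList(exonsByTx),
    cdsByTx = GenomicRanges::GRangesList(cdsByTx),
    txGene = S4Vectors::DataFrame(tx_id = names(txGeneRows),
                                  gene_id = unlist(txGeneRows, use.names = FALSE)),
    covariates = covariates)

  ## -- enhancers (plain-vector bookkeeping: this loop is placement-heavy) --
  set.seed(subSeed(config@seed, 4L))
  gS <- if (config@nGenes > 0L) GenomicRanges::start(genes) else integer(0)
  gE <- if (config@nGenes > 0L) GenomicRanges::end(genes) else integer(0)
  eStart <- integer(0); eEnd <- integer(0)
  eTissue <- character(0); eClass <- character(0)
  eAnchor <- character(0); eId <- character(0)
  drawClass <- function(tissue) {
    p <- config@tissueClassProportions[[tissue]] %||% config@classProportions
    sample(SELECTION_CLASSES, 1L, prob = p[SELECTION_CLASSES])
  }
  for (tissue in intersect(TISSUES, names(config@nEnhancersPerTissue))) {
    n <- config@nEnhancersPerTissue[[tissue]]
    for (j in seq_len(n)) {
      len <- sample(config@enhancerLengthRange[1]:config@enhancerLengthRange[2], 1L)
      s <- NA_integer_
      cls <- NA_character_
      anchor <- NA_character_
      sameTissue <- eTissue == tissue
      others <- which(!sameTissue)
      if (length(others) > 0L &&
          stats::runif(1) < config@crossTissueOverlapFraction) {
        ## overlap an existing enhancer of another tissue; inherit its class
        k <- others[sample.int(length(others), 1L)]
        shift <- sample(seq(-len %/% 2L, len %/% 2L), 1L)
        cand <- max(1L, min(config@chromLength - len, eStart[k] + shift))
        ce <- cand + len - 1L
        if (!anyOverlap(cand, ce, gS, gE) &&
            !anyOverlap(cand, ce, eStart[sameTissue], eEnd[sameTissue]) &&
            cand <= eEnd[k] && ce >= eStart[k]) {
          s <- cand; cls <- eClass[k]; anchor <- eAnchor[k]
        }
      }
      if (is.na(s)) {
        cls <- drawClass(tissue)
        if (config@nGenes > 0L) {
          for (try in 1:500) {
            gi <- sample.int(config@nGenes, 1L)
            off <- sample(config@enhancerOffsetRange[1]:config@enhancerOffsetRange[2], 1L)
            cand <- if (stats::runif(1) < 0.5) gS[gi] - off - len else gE[gi] + off
            if (cand < 1L || cand + len - 1L > config@chromLength) next
            ce <- cand + len - 1L
            if (!anyOverlap(cand, ce, gS, gE) &&
                !anyOverlap(cand, ce, eStart[sameTissue], eEnd[sameTissue])) {
              s <- cand; anchor <- geneIds[gi]; break
            }
          }
          if (is.na(s))
            stop(sprintf(
              "failed to place enhancer %d of tissue %s near a gene: relax enhancerOffsetRange or enlarge chromLength",
              j, tissue), call. = FALSE)
        } else {
          where <- placeFeature(len, config@chromLength,
                                eStart[sameTissue], eEnd[sameTissue],
                                what = sprintf("enhancer %s#%d", tissue, j))
          s <- where[1]
        }
      }
      eStart <- c(eStart, s); eEnd <- c(eEnd, s + len - 1L)
      eTissue <- c(eTissue, tissue); eClass <- c(eClass, cls)
      eAnchor <- c(eAnchor, anchor)
      eId <- c(eId, sprintf("enh_%s_%04d", tissue, j))
    }
  }

  if (length(eStart) > 0L) {
    enh <- GenomicRanges::GRanges(chrom, IRanges::IRanges(eStart, eEnd))
    enh$enhancer_id <- eId
    enh$tissue <- eTissue
    enh$class <- eClass
    enh$multiplier <- unname(config@selectionMultipliers[eClass])
    enh$anchor_gene <- eAnchor
  } else {
    enh <- GenomicRanges::GRanges()
  }

  truth <- S4Vectors::DataFrame(
    enhancer_id = if (length(enh)) enh$enhancer_id else character(0),
    tissue = if (length(enh)) enh$tissue else character(0),
    chrom = rep(chrom, length(enh)),
    start0 = if (length(enh)) GenomicRanges::start(enh) - 1L else integer(0),
    end = if (length(enh)) GenomicRanges::end(enh) else integer(0),
    class = if (length(enh)) enh$class else character(0),
    multiplier = if (length(enh)) enh$multiplier else numeric(0),
    anchor_gene = if (length(enh)) enh$anchor_gene else character(0))

  ## -- recombination windows --
  set.seed(subSeed(config@seed, 5L))
  ws <- seq(1L, chromLength, by = config@recombWindow)
  recomb <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(ws, pmin(ws + config@recombWindow - 1L, chromLength)))
  recomb$rate <- stats::rgamma(length(recomb), shape = 2, scale = 0.3)

  list(config = config, genes = geneModels, enhancers = enh, truth = truth,
       recomb = recomb)
}

## ---- evolution -----------------------------------------------------------

## integer-coded random sequence from base frequencies
sampleBases <- function(n, pi) sample.int(4L, n, replace = TRUE, prob = pi)

## evolve integer-coded parent along a branch: per-site total rate `rate`
## (gamma category x regional multiplier), generator Q (possibly GC-biased).
evolveBranch <- function(parent, t, rate, Q, pi, reversible) {
  if (t == 0) return(parent)
  child <- parent
  pf <- transitionFunction(Q, pi, reversible)
  for (u in unique(rate)) {
    P <- pf(t * u)
    sel <- which(rate == u)
    for (b in 1:4) {
      idx <- sel[parent[sel] == b]
      if (length(idx))
        child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
    }
  }
  child
}

## codon-position vector (1,2,3, or 0 outside CDS) along the chromosome for
## the primary isoforms; strand-aware.
codonPositionTrack <- function(geneModels, chromLength) {
  cpos <- integer(chromLength)
  primary <- grep("\\.t1$", names(geneModels@cdsByTx), value = TRUE)
  for (tx in primary) {
    cds <- geneModels@cdsByTx[[tx]]
    if (length(cds) == 0L) next
    strand <- as.character(GenomicRanges::strand(cds))[1]
    ord <- if (strand == "+") order(GenomicRanges::start(cds)) else
      order(-GenomicRanges::start(cds))
    off <- 0L
    for (i in ord) {
      w <- IRanges::width(cds)[i]
      posInCds <- off + seq_len(w)
      gpos <- if (strand == "+")
        GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]
      else GenomicRanges::end(cds)[i]:GenomicRanges::start(cds)[i]
      cpos[gpos] <- ((posInCds - 1L) %% 3L) + 1L
      off <- off + w
    }
  }
  cpos
}

## valid open reading frame of `codons` codons (integer-coded mRNA sense
## strand, stop codons excluded), drawn from the configured base frequencies
sampleOrf <- function(codons, pi) {
  stops <- c("TAA", "TAG", "TGA")
  out <- integer(3L * codons)
  out[1:3] <- c(1L, 4L, 3L) # ATG
  i <- 2L
  while (i <= codons) {
    cand <- sample.int(4L, 3L, replace = TRUE, prob = pi)
    if (!paste(DNA_BASES4[cand], collapse = "") %in% stops) {
      out[(3L * i - 2L):(3L * i)] <- cand
      i <- i + 1L
    }
  }
  out
}

COMPLEMENT4 <- c(4L, 3L, 2L, 1L) # A<->T, C<->G in A,C,G,T coding

## CDS positions (genomic, transcription order) of each primary isoform
primaryCdsPositions <- function(geneModels) {
  primary <- grep("\\.t1$", names(geneModels@cdsByTx), value = TRUE)
  lapply(structure(primary, names = primary), function(tx) {
    cds <- geneModels@cdsByTx[[tx]]
    if (length(cds) == 0L) return(NULL)
    strand <- as.character(GenomicRanges::strand(cds))[1]
    ord <- if (strand == "+") order(GenomicRanges::start(cds)) else
      order(-GenomicRanges::start(cds))
    pos <- unlist(lapply(ord, function(i) {
      if (strand == "+")
        GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]
      else GenomicRanges::end(cds)[i]:GenomicRanges::start(cds)[i]
    }), use.names = FALSE)
    list(pos = pos, strand = strand)
  })
}

## Purifying selection against nonsense mutations: any codon that became a
## stop on a branch is reverted to its (stop-free) ancestral state.  Stops
## can only arise through non-fourfold codons, so fourfold-site evolution is
## untouched.
repairStopCodons <- function(child, parent, cdsIndex) {
  stopCodes <- c("411", "413", "431") # TAA, TAG, TGA in A=1,C=2,G=3,T=4
  for (entry in cdsIndex) {
    if (is.null(entry)) next
    pos <- entry$pos
    txBase <- if (entry$strand == "+") child[pos] else COMPLEMENT4[child[pos]]
    cod <- matrix(txBase, nrow = 3L)
    code <- paste0(cod[1, ], cod[2, ], cod[3, ])
    bad <- which(code %in% stopCodes)
    if (length(bad)) {
      idx <- pos[as.vector(outer(1:3, (bad - 1L) * 3L, `+`))]
      child[idx] <- parent[idx]
    }
  }
  child
}

#' Evolve the three-species alignment of a simulated chromosome
#'
#' Draws the mouse-rat ancestral chromosome (intergenic and intron sequence
#' from the stationary base frequencies; coding sequence as valid open
#' reading frames), then evolves the mouse, rat and human lineages under the
#' configured GTR + discrete-gamma process.  Within enhancer spans the rate
#' is multiplied by the enhancer's true selection-class multiplier; first and
#' second codon positions evolve under purifying constraint; everything else
#' is neutral.  When \code{gcFixationBias > 0} all rates into G/C are
#' multiplied by \code{1 + gcFixationBias} (rescaled to keep the expected
#' total rate at 1), on every lineage.
#'
#' @param config the \linkS4class{SimulationConfig} used for the annotation.
#' @param annotation result of \code{\link{simulateAnnotation}}.
#' @param gapFraction optional fraction of alignment columns in which the rat
#'   or human row is replaced by a gap (independent draws per species;
#'   default 0, i.e. gap-free).
#' @return a \linkS4class{TripleAlignment}.
#' @export
evolveAlignments <- function(config, annotation, gapFraction = 0) {
  validObject(config)
  n <- config@chromLength
  set.seed(subSeed(config@seed, 6L))

  ## root / mouse-rat ancestor
  pi <- config@model@baseFreqs
  anc <- sampleBases(n, pi)
  gm <- annotation$genes
  primary <- grep("\\.t1$", names(gm@cdsByTx), value = TRUE)
  for (tx in primary) {
    cds <- gm@cdsByTx[[tx]]
    if (length(cds) == 0L) next
    strand <- as.character(GenomicRanges::strand(cds))[1]
    w <- sum(IRanges::width(cds))
    orf <- sampleOrf(w %/% 3L, pi)
    ord <- if (strand == "+") order(GenomicRanges::start(cds)) else
      order(-GenomicRanges::start(cds))
    off <- 0L
    for (i in ord) {
      wi <- IRanges::width(cds)[i]
      seg <- orf[off + seq_len(wi)]
      if (strand == "+") {
        anc[GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]] <- seg
      } else {
        anc[GenomicRanges::end(cds)[i]:GenomicRanges::start(cds)[i]] <-
          COMPLEMENT4[seg]
      }
      off <- off + wi
    }
  }

  ## per-site rates: gamma category x regional multiplier
  K <- config@model@nCategories
  cat <- sample.int(K, n, replace = TRUE)
  catRates <- gammaCategoryRates(config@model@gammaShape, K)
  mult <- rep(1, n)
  cpos <- codonPositionTrack(gm, n)
  mult[cpos %in% c(1L, 2L)] <- config@cdsConstraintMultiplier
  enh <- annotation$enhancers
  for (i in seq_along(enh)) {
    mult[GenomicRanges::start(enh)[i]:GenomicRanges::end(enh)[i]] <-
      enh$multiplier[i]
  }
  rate <- catRates[cat] * mult

  Q <- gtrGenerator(config@model@exchangeabilities, pi,
                    gcBias = config@gcFixationBias)
  rev <- config@gcFixationBias == 0
  bl <- config@branchLengths
  cdsIndex <- primaryCdsPositions(gm)
  mouse <- repairStopCodons(evolveBranch(anc, bl[["mouse"]], rate, Q, pi, rev),
                            anc, cdsIndex)
  rat <- repairStopCodons(evolveBranch(anc, bl[["rat"]], rate, Q, pi, rev),
                          anc, cdsIndex)
  human <- repairStopCodons(evolveBranch(anc, bl[["human"]], rate, Q, pi, rev),
                            anc, cdsIndex)

  toChar <- function(x) paste(DNA_BASES4[x], collapse = "")
  seqs <- c(mouse = toChar(mouse), rat = toChar(rat), human = toChar(human))
  if (gapFraction > 0) {
    for (sp in c("rat", "human")) {
      idx <- which(stats::runif(n) < gapFraction)
      if (length(idx)) {
        ch <- strsplit(seqs[[sp]], "", fixed = TRUE)[[1]]
        ch[idx] <- "-"
        seqs[[sp]] <- paste(ch, collapse = "")
      }
    }
  }

  new("TripleAlignment", chrom = "chrS", start = 1L, seqs = seqs,
      ancestor = toChar(anc), siteRate = rate,
      truthMeta = S4Vectors::DataFrame(multiplier = mult, category = cat))
}

#' Ungapped reference (mouse) genome of a simulated alignment
#'
#' @param aln a \linkS4class{TripleAlignment}.
#' @return a \code{DNAStringSet} with one sequence named after the
#'   chromosome.
#' @export
referenceGenome <- function(aln) {
  s <- gsub("-", "", aln@seqs[["mouse"]], fixed = TRUE)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- aln@chrom
  out
}

#' Run annotation and evolution in one call
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param gapFraction see \code{\link{evolveAlignments}}.
#' @return the \code{\link{simulateAnnotation}} list with an extra
#'   \code{alignment} element (\linkS4class{TripleAlignment}).
#' @export
simulateStudy <- function(config, gapFraction = 0) {
  ann <- simulateAnnotation(config)
  ann$alignment <- evolveAlignments(config, ann, gapFraction = gapFraction)
  ann
}
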