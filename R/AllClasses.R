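## Central S4 classes.  Base order everywhere: A, C, G, T.

#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAStringSet GENETIC_CODE
NULL

#' GTR + discrete-gamma substitution model
#'
#' Holds six exchangeabilities (AC, AG, AT, CG, CT, GT), four base
#' frequencies (A, C, G, T), the gamma shape \eqn{\alpha} and the number of
#' equal-probability rate categories (5 by default, as in common
#' maximum-likelihood practice).
#'
#' @slot exchangeabilities numeric(6), nonnegative.
#' @slot baseFreqs numeric(4), summing to 1.
#' @slot gammaShape positive real.
#' @slot nCategories integer >= 1.
#' @seealso \code{\link{substitutionModel}}
#' @export
setClass("SubstitutionModel",
  representation(exchangeabilities = "numeric",
                 baseFreqs = "numeric",
                 gammaShape = "numeric",
                 nCategories = "integer"),
  prototype(exchangeabilities = rep(1, 6), baseFreqs = rep(0.25, 4),
            gammaShape = 1, nCategories = 5L))

setValidity("SubstitutionModel", function(object) {
  msg <- NULL
  if (length(object@exchangeabilities) != 6L || any(object@exchangeabilities < 0))
    msg <- c(msg, "exchangeabilities must be 6 nonnegative values")
  if (length(object@baseFreqs) != 4L ||
      abs(sum(object@baseFreqs) - 1) > 1e-9 || any(object@baseFreqs < 0))
    msg <- c(msg, "baseFreqs must be 4 probabilities summing to 1")
  if (length(object@gammaShape) != 1L || object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be a positive scalar")
  if (object@nCategories < 1L)
    msg <- c(msg, "nCategories must be >= 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel (GTR + discrete gamma)\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(object@exchangeabilities, 4), collapse = " "), "\n")
  cat("  base frequencies  (A C G T):",
      paste(signif(object@baseFreqs, 4), collapse = " "), "\n")
  cat(sprintf("  gamma shape alpha = %.4g, %d categories\n",
              object@gammaShape, object@nCategories))
})

#' Configuration of the synthetic-evolution study
#'
#' Defines a single simulated study: one chromosome carrying protein-coding
#' genes and tissue-labelled enhancers, evolved along the three-taxon tree
#' ((mouse, rat), human) under a GTR + discrete-gamma model.  Enhancer spans
#' evolve at a class-specific rate multiplier (the ground-truth selection
#' regime); an optional GC-fixation bias multiplies all rates into G/C.
#'
#' @slot seed integer RNG seed; the whole run is a deterministic function of
#'   the configuration.
#' @slot nGenes number of genes to place.
#' @slot nEnhancersPerTissue named integer vector over tissues
#'   (FB, MB, LB, HT).
#' @slot chromLength chromosome length in bp.
#' @slot branchLengths named numeric: expected substitutions/site on the
#'   mouse, rat and human lineages (human branch measured from the mouse-rat
#'   ancestor).
#' @slot model a \linkS4class{SubstitutionModel}.
#' @slot selectionMultipliers named numeric over classes neutral, purifying,
#'   positive (rate multipliers inside enhancer spans).
#' @slot classProportions named numeric over the same classes, summing to 1;
#'   prior probability of each selection class for a new enhancer.
#' @slot tissueClassProportions optional list of per-tissue proportion
#'   vectors overriding \code{classProportions} (used for scenarios where,
#'   e.g., one tissue is enriched for positive selection).
#' @slot gcFixationBias nonnegative; 0 disables the bias.
#' @slot expressionMeanlog,expressionSdlog log-normal parameters of the
#'   per-gene mean expression signal (right-skewed, positive).
#' @slot essentialFraction probability that a gene is essential.
#' @slot phenotypeUnknownFraction probability a gene has no documented null
#'   phenotype (essentiality unknown).
#' @slot intronlessFraction,singleIntronFraction probabilities of 0- and
#'   1-intron gene structures (these genes have no usable intron reference).
#' @slot cdsCodonsRange,intronLengthRange,enhancerLengthRange integer ranges
#'   for structure sizes (bp or codons).
#' @slot utrLength length of the untranslated leader/trailer inside terminal
#'   exons, bp.
#' @slot cdsConstraintMultiplier rate multiplier at first and second codon
#'   positions (purifying constraint on coding sequence); third positions
#'   evolve neutrally.
#' @slot enhancerOffsetRange distance range (bp) from an enhancer to its
#'   anchor gene boundary.
#' @slot crossTissueOverlapFraction fraction of enhancers deliberately placed
#'   overlapping an enhancer of another tissue (exercises consolidation).
#' @slot orthologFraction probability a gene has a one-to-one ortholog
#'   (independently for rat and human).
#' @slot altIsoformFraction fraction of genes given a second, shorter isoform
#'   (exercises longest-isoform selection).
#' @slot recombWindow recombination-map window size, bp.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateAnnotation}},
#'   \code{\link{evolveAlignments}}
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nGenes = "integer",
                 nEnhancersPerTissue = "integer", chromLength = "integer",
                 branchLengths = "numeric", model = "SubstitutionModel",
                 selectionMultipliers = "numeric", classProportions = "numeric",
                 tissueClassProportions = "list", gcFixationBias = "numeric",
                 expressionMeanlog = "numeric", expressionSdlog = "numeric",
                 essentialFraction = "numeric",
                 phenotypeUnknownFraction = "numeric",
                 intronlessFraction = "numeric",
                 singleIntronFraction = "numeric",
                 cdsCodonsRange = "integer", intronLengthRange = "integer",
                 enhancerLengthRange = "integer", utrLength = "integer",
                 cdsConstraintMultiplier = "numeric",
                 enhancerOffsetRange = "integer",
                 crossTissueOverlapFraction = "numeric",
                 orthologFraction = "numeric", altIsoformFraction = "numeric",
                 recombWindow = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  cls <- c("neutral", "purifying", "positive")
  if (!all(cls %in% names(object@selectionMultipliers)) ||
      any(object@selectionMultipliers <= 0))
    msg <- c(msg, "selectionMultipliers must be positive and named neutral/purifying/positive")
  if (abs(sum(object@classProportions) - 1) > 1e-9 ||
      !all(cls %in% names(object@classProportions)))
    msg <- c(msg, "classProportions must be named over the 3 classes and sum to 1")
  if (!all(c("mouse", "rat", "human") %in% names(object@branchLengths)) ||
      any(object@branchLengths < 0))
    msg <- c(msg, "branchLengths must be nonnegative and named mouse/rat/human")
  if (any(object@nEnhancersPerTissue < 0) ||
      is.null(names(object@nEnhancersPerTissue)))
    msg <- c(msg, "nEnhancersPerTissue must be a named nonnegative integer vector")
  if (object@gcFixationBias < 0)
    msg <- c(msg, "gcFixationBias must be >= 0")
  v <- validObject(object@model, test = TRUE)
  if (is.character(v)) msg <- c(msg, v)
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed %d | chrom %d bp | %d genes | enhancers: %s\n",
              object@seed, object@chromLength, object@nGenes,
              paste(sprintf("%s=%d", names(object@nEnhancersPerTissue),
                            object@nEnhancersPerTissue), collapse = " ")))
  cat(sprintf("  branches (subst/site): mouse %.3g, rat %.3g, human %.3g\n",
              object@branchLengths["mouse"], object@branchLengths["rat"],
              object@branchLengths["human"]))
  cat(sprintf("  multipliers: %s | gcFixationBias %.3g\n",
              paste(sprintf("%s=%.3g", names(object@selectionMultipliers),
                            object@selectionMultipliers), collapse = " "),
              object@gcFixationBias))
})

#' Simulated gene models with isoform structure and covariates
#'
#' @slot genes \code{GRanges} of gene spans; metadata columns
#'   \code{gene_id}, \code{ortholog_rat}, \code{ortholog_human}.
#' @slot exonsByTx,cdsByTx \code{GRangesList} keyed by transcript id, in
#'   genomic order (CDS excludes the stop codon, Ensembl convention).
#' @slot txGene \code{DataFrame} mapping transcript id to gene id.
#' @slot covariates \code{DataFrame}: \code{gene_id}, \code{phenotypes}
#'   (comma-separated knockout phenotype terms; empty = none documented) and
#'   61 per-tissue expression signal columns \code{expr_1..expr_61}.
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exonsByTx = "GRangesList",
                 cdsByTx = "GRangesList", txGene = "DataFrame",
                 covariates = "DataFrame"))

setValidity("GeneModels", function(object) {
  msg <- NULL
  if (!all(names(object@exonsByTx) == object@txGene$tx_id))
    msg <- c(msg, "exonsByTx must be keyed like txGene$tx_id")
  if (!all(object@txGene$gene_id %in% object@genes$gene_id))
    msg <- c(msg, "txGene$gene_id must appear in genes$gene_id")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes, %d transcripts on %s\n",
              length(object@genes), length(object@exonsByTx),
              paste(unique(as.character(GenomicRanges::seqnames(object@genes))),
                    collapse = ",")))
})

#' Three-species alignment of one simulated chromosome
#'
#' Gap-free by default (columns map one-to-one to mouse coordinates); an
#' optional gap-injection step replaces bases of the non-reference rows with
#' \code{-}.  The mouse-rat ancestral sequence and per-site true rates are
#' retained as simulation ground truth.
#'
#' @slot chrom chromosome name.
#' @slot start 1-based genomic start of the mouse row.
#' @slot seqs named character vector of aligned rows
#'   (\code{mouse}, \code{rat}, \code{human}), equal widths.
#' @slot ancestor mouse-rat ancestral sequence (truth; same width).
#' @slot siteRate numeric per-site total relative rate (gamma category times
#'   regional multiplier; truth).
#' @slot truthMeta \code{DataFrame} of per-site truth used by tests
#'   (columns \code{multiplier}, \code{category}).
#' @export
setClass("TripleAlignment",
  representation(chrom = "character", start = "integer", seqs = "character",
                 ancestor = "character", siteRate = "numeric",
                 truthMeta = "DataFrame"))

setValidity("TripleAlignment", function(object) {
  w <- unique(nchar(object@seqs))
  if (length(w) != 1L) return("aligned rows must have equal width")
  if (!all(c("mouse", "rat", "human") %in% names(object@seqs)))
    return("rows must be named mouse, rat, human")
  TRUE
})

setMethod("show", "TripleAlignment", function(object) {
  cat(sprintf("TripleAlignment %s:%d-%d (%d columns; mouse/rat/human)\n",
              object@chrom, object@start,
              object@start + nchar(object@seqs[[1]]) - 1L,
              nchar(object@seqs[[1]])))
})

#' Genomic positions of one neutral-reference site class for one gene
#'
#' @slot gene_id gene identifier.
#' @slot siteClass \code{"fourfold"} or \code{"intron"}.
#' @slot positions strictly increasing 1-based genomic positions.
#' @export
setClass("SiteMask",
  representation(gene_id = "character", siteClass = "character",
                 positions = "integer"))

setValidity("SiteMask", function(object) {
  if (!object@siteClass %in% c("fourfold", "intron"))
    return("siteClass must be 'fourfold' or 'intron'")
  if (is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  TRUE
})

setMethod("show", "SiteMask", function(object) {
  cat(sprintf("SiteMask %s [%s]: %d sites\n", object@gene_id,
              object@siteClass, length(object@positions)))
})

#' Maximum-likelihood pairwise substitution distance
#'
#' The distance \code{t} is the expected number of substitutions per site on
#' the path between the two sequences (this is D, d4 or di depending on the
#' site set it was fitted on).
#'
#' @slot distance expected substitutions/site.
#' @slot se large-sample standard error of \code{distance}: from the joint
#'   observed-information matrix over all free parameters when the model is
#'   fitted, or the 1-D curvature when only \code{t} is free; \code{NA} when
#'   unavailable.
#' @slot alphaSE standard error of the fitted gamma shape (\code{NA} when
#'   the shape was fixed or not computed).
#' @slot model fitted \linkS4class{SubstitutionModel}.
#' @slot nSites,nDiff counts of usable and mismatching columns.
#' @slot converged optimizer status.
#' @slot logLik maximized log-likelihood.
#' @export
setClass("DivergenceEstimate",
  representation(distance = "numeric", se = "numeric", alphaSE = "numeric",
                 model = "SubstitutionModel", nSites = "integer",
                 nDiff = "integer", converged = "logical",
                 logLik = "numeric"),
  prototype(alphaSE = NA_real_))

setValidity("DivergenceEstimate", function(object) {
  msg <- NULL
  if (object@distance < 0) msg <- c(msg, "distance must be >= 0")
  if (object@nDiff > object@nSites) msg <- c(msg, "nDiff must be <= nSites")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DivergenceEstimate", function(object) {
  cat(sprintf(
    "DivergenceEstimate: t = %.5g (se %.3g), %d/%d sites differ, %sconverged\n",
    object@distance, object@se, object@nDiff, object@nSites,
    if (object@converged) "" else "NOT "))
})

#' Maximum-likelihood branch lengths on the unrooted three-taxon tree
#'
#' @slot branchLengths named numeric (mouse, rat, human) in expected
#'   substitutions/site.
#' @slot model shared fitted \linkS4class{SubstitutionModel}.
#' @slot nSites,nDiff usable columns and non-constant columns.
#' @slot converged optimizer status.
#' @slot logLik maximized log-likelihood.
#' @export
setClass("TripleEstimate",
  representation(branchLengths = "numeric", model = "SubstitutionModel",
                 nSites = "integer", nDiff = "integer", converged = "logical",
                 logLik = "numeric"))

setMethod("show", "TripleEstimate", function(object) {
  cat(sprintf(
    "TripleEstimate: mouse %.5g, rat %.5g, human %.5g (mouse-rat %.5g); %d sites\n",
    object@branchLengths["mouse"], object@branchLengths["rat"],
    object@branchLengths["human"], mouseRatDistance(object), object@nSites))
})
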