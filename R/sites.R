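## Neutral-reference site masks: fourfold-degenerate third codon positions
## and intron positions of the longest isoform with the first intron removed.

## third-position-degenerate codon families of the standard genetic code:
## any third base encodes the same amino acid
FOURFOLD_PREFIXES <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

#' Longest isoform of every gene
#'
#' "Longest" means greatest summed exon length (not genomic span); ties are
#' broken by longest CDS, then lexicographic transcript id.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @return named character vector: transcript id per gene id.
#' @export
pickLongestIsoform <- function(geneModels) {
  tx <- geneModels@txGene$tx_id
  gid <- geneModels@txGene$gene_id
  exonLen <- sum(IRanges::width(geneModels@exonsByTx))[tx]
  cdsLen <- sum(IRanges::width(geneModels@cdsByTx))[tx]
  ord <- order(gid, -exonLen, -cdsLen, tx)
  keep <- !duplicated(gid[ord])
  structure(tx[ord][keep], names = gid[ord][keep])
}

## CDS ranges of a transcript in transcription order (5'->3')
cdsInTxOrder <- function(geneModels, tx) {
  cds <- geneModels@cdsByTx[[tx]]
  if (length(cds) == 0L) return(cds)
  strand <- as.character(GenomicRanges::strand(cds))[1]
  if (strand == "+") cds[order(GenomicRanges::start(cds))]
  else cds[order(-GenomicRanges::start(cds))]
}

## genomic coordinate of each CDS base in transcription order
cdsGenomicPositions <- function(cds) {
  strand <- as.character(GenomicRanges::strand(cds))[1]
  unlist(lapply(seq_along(cds), function(i) {
    if (strand == "+")
      GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]
    else
      GenomicRanges::end(cds)[i]:GenomicRanges::start(cds)[i]
  }), use.names = FALSE)
}

#' Fourfold-degenerate sites of one gene
#'
#' Scans the coding sequence of the longest isoform codon by codon and
#' returns the genomic positions of third codon positions whose first two
#' bases determine the amino acid for all four third-base choices (the eight
#' fourfold families GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN).  Classification
#' uses the mouse codon only.  Codons containing ambiguity codes are
#' skipped.  Genes whose CDS length is not a multiple of 3, or whose CDS
#' contains an internal stop codon, are rejected with an informative
#' condition of class \code{unusableGene}.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param geneId gene identifier.
#' @param genome named \code{DNAStringSet} (chromosome sequences).
#' @param tx transcript to scan; defaults to the longest isoform of
#'   \code{geneId} (precomputed by callers that loop over many genes).
#' @return a \linkS4class{SiteMask} with \code{siteClass = "fourfold"}.
#' @examples
#' ## a 4-codon CDS ATG GGA GCT TAA has fourfold third positions in GGA, GCT
#' @export
fourfoldSites <- function(geneModels, geneId, genome, tx = NULL) {
  if (is.null(tx)) tx <- pickLongestIsoform(geneModels)[[geneId]]
  cds <- cdsInTxOrder(geneModels, tx)
  assertThat(length(cds) > 0L, "gene %s has no CDS", geneId)
  chrom <- as.character(GenomicRanges::seqnames(cds))[1]
  strand <- as.character(GenomicRanges::strand(cds))[1]
  cdsLen <- sum(IRanges::width(cds))
  if (cdsLen %% 3L != 0L)
    stop(unusableGene(geneId, "cds_not_multiple_of_3"))
  seqParts <- Biostrings::extractAt(
    genome[[chrom]],
    IRanges::IRanges(GenomicRanges::start(cds), GenomicRanges::end(cds)))
  if (strand == "-") {
    ## ranges were extracted in transcription order already; complement only
    seqParts <- Biostrings::reverseComplement(seqParts)
  }
  cdsSeq <- as.character(unlist(seqParts))
  codons <- substring(cdsSeq, seq(1L, cdsLen, 3L), seq(3L, cdsLen, 3L))
  if (any(codons %in% c("TAA", "TAG", "TGA")))
    stop(unusableGene(geneId, "internal_stop_codon"))
  clean <- !grepl("[^ACGT]", codons)
  hit <- clean & substring(codons, 1L, 2L) %in% FOURFOLD_PREFIXES
  gpos <- cdsGenomicPositions(cds)
  thirdPos <- gpos[seq(3L, cdsLen, 3L)]
  new("SiteMask", gene_id = geneId, siteClass = "fourfold",
      positions = sort(as.integer(thirdPos[hit])))
}

unusableGene <- function(geneId, reason) {
  structure(class = c("unusableGene", "error", "condition"),
            list(message = sprintf("gene %s unusable: %s", geneId, reason),
                 call = NULL, geneId = geneId, reason = reason))
}

#' Intron sites of one gene, first intron removed
#'
#' Introns are the gaps between consecutive exons of the longest isoform.
#' The 5'-most intron in transcription order (strand-aware: for minus-strand
#' genes the rightmost in genomic coordinates) is removed because first
#' introns often carry regulatory motifs.  Intronless and single-intron
#' genes yield an empty mask — such genes have only the fourfold neutral
#' reference.
#'
#' @inheritParams fourfoldSites
#' @return a \linkS4class{SiteMask} with \code{siteClass = "intron"}; the
#'   removed first-intron length (bp) is in attribute
#'   \code{"first_intron_removed_bp"} of the positions.
#' @export
intronSites <- function(geneModels, geneId, tx = NULL) {
  if (is.null(tx)) tx <- pickLongestIsoform(geneModels)[[geneId]]
  exons <- geneModels@exonsByTx[[tx]]
  strand <- as.character(GenomicRanges::strand(exons))[1]
  exons <- exons[order(GenomicRanges::start(exons))]
  mask <- new("SiteMask", gene_id = geneId, siteClass = "intron",
              positions = integer(0))
  if (length(exons) < 2L) return(mask)
  intronStart <- GenomicRanges::end(exons)[-length(exons)] + 1L
  intronEnd <- GenomicRanges::start(exons)[-1L] - 1L
  keep <- intronEnd >= intronStart
  intronStart <- intronStart[keep]; intronEnd <- intronEnd[keep]
  if (length(intronStart) == 0L) return(mask)
  first <- if (strand == "+") 1L else length(intronStart)
  removedBp <- intronEnd[first] - intronStart[first] + 1L
  intronStart <- intronStart[-first]; intronEnd <- intronEnd[-first]
  if (length(intronStart) == 0L) return(mask)
  pos <- unlist(lapply(seq_along(intronStart),
                       function(i) intronStart[i]:intronEnd[i]),
                use.names = FALSE)
  mask@positions <- sort(as.integer(pos))
  attr(mask@positions, "first_intron_removed_bp") <- removedBp
  mask
}

#' Compute both neutral-reference masks for a set of genes
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param genome named \code{DNAStringSet}.
#' @param geneIds genes to process (default: all).
#' @return list with \code{fourfold} and \code{intron} (lists of
#'   \linkS4class{SiteMask} keyed by gene id) and \code{excluded}
#'   (data.frame of gene id / reason for genes with unusable CDS).
#' @export
geneSiteMasks <- function(geneModels, genome,
                          geneIds = geneModels@genes$gene_id) {
  fourfold <- list(); intron <- list()
  excluded <- list()
  longest <- pickLongestIsoform(geneModels)
  for (g in geneIds) {
    ff <- tryCatch(fourfoldSites(geneModels, g, genome, tx = longest[[g]]),
                   unusableGene = function(e) e)
    if (inherits(ff, "unusableGene")) {
      excluded[[g]] <- ff$reason
    } else {
      fourfold[[g]] <- ff
    }
    intron[[g]] <- intronSites(geneModels, g, tx = longest[[g]])
  }
  list(fourfold = fourfold, intron = intron,
       excluded = data.frame(gene_id = names(excluded) %||% character(0),
                             reason = unlist(excluded, use.names = FALSE) %||%
                               character(0)))
}

#' Project genomic positions onto alignment columns
#'
#' Maps 1-based mouse genomic positions into the columns of an alignment
#' block whose reference (mouse) row may contain gaps, and keeps only the
#' columns in which no aligned species has a gap or ambiguity code.
#'
#' @param positions integer vector of 1-based mouse genomic positions (e.g.
#'   \code{maskPositions} of a \linkS4class{SiteMask}, or an enhancer span).
#' @param aln a \linkS4class{TripleAlignment}.
#' @param species rows that must be gap-free and unambiguous (default: all
#'   rows of the block).
#' @return integer vector of alignment column indices; positions outside the
#'   block are counted in attribute \code{"n_outside"}.
#' @export
projectMask <- function(positions, aln, species = names(aln@seqs)) {
  rows <- lapply(aln@seqs[species], function(s)
    strsplit(toupper(s), "", fixed = TRUE)[[1]])
  ref <- rows[["mouse"]]
  assertThat(!is.null(ref), "alignment block must contain a mouse row")
  notGap <- ref != "-"
  refPos <- aln@start - 1L + cumsum(notGap)   # genomic pos of each column
  refPos[!notGap] <- NA_integer_
  colOf <- match(positions, refPos)
  nOutside <- sum(is.na(colOf))
  cols <- colOf[!is.na(colOf)]
  clean <- Reduce(`&`, lapply(rows, function(r) r %in% DNA_BASES4))
  cols <- cols[clean[cols]]
  out <- sort(cols)
  attr(out, "n_outside") <- nOutside
  out
}

#' Summarize masks as a per-gene table
#'
#' @param masks result of \code{\link{geneSiteMasks}}.
#' @return data.frame with \code{gene_id}, \code{n_fourfold},
#'   \code{n_intron_sites}, \code{first_intron_removed_bp}.
#' @export
maskSummary <- function(masks) {
  ids <- union(names(masks$fourfold), names(masks$intron))
  data.frame(
    gene_id = ids,
    n_fourfold = vapply(ids, function(g)
      if (is.null(masks$fourfold[[g]])) 0L
      else length(maskPositions(masks$fourfold[[g]])), 0L),
    n_intron_sites = vapply(ids, function(g)
      if (is.null(masks$intron[[g]])) 0L
      else length(maskPositions(masks$intron[[g]])), 0L),
    first_intron_removed_bp = vapply(ids, function(g) {
      m <- masks$intron[[g]]
      if (is.null(m)) 0L
      else as.integer(attr(m@positions, "first_intron_removed_bp") %||% 0L)
    }, 0L),
    row.names = NULL)
}
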