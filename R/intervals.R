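## Consolidation of tissue-labelled enhancer peaks into non-overlapping
## regions, pleiotropy classification, nearest-gene assignment and
## recombination-rate lookup.

#' Consolidate overlapping tissue-labelled enhancers into regions
#'
#' Enhancers from different tissues whose coordinates overlap by at least one
#' base pair are merged into a single region (the connected components of the
#' overlap graph, per chromosome).  Bookended intervals (\[100,200) followed
#' by \[200,300) in 0-based terms) are \emph{not} merged.  Each region
#' carries the union of member tissues and a pleiotropy class:
#' \code{specific} when consolidated from a single tissue, else
#' \code{pleiotropic}.
#'
#' @param records \code{GRanges} with a \code{tissue} metadata column
#'   (one of FB, MB, LB, HT); an optional \code{enhancer_id} column is
#'   propagated into a \code{members} column.
#' @return \code{GRanges} sorted by (chromosome, start) with metadata
#'   \code{region_id}, \code{tissues} (comma-collapsed sorted labels),
#'   \code{n_tissues}, \code{pleiotropy} and \code{members}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 151, 301), c(200, 250, 400)))
#' gr$tissue <- c("HT", "FB", "HT")
#' consolidateEnhancers(gr)
#' @export
consolidateEnhancers <- function(records) {
  if (length(records) == 0L) {
    out <- GenomicRanges::GRanges()
    return(out)
  }
  assertThat(!is.null(records$tissue), "records need a 'tissue' metadata column")
  bad <- which(GenomicRanges::width(records) < 1L)
  if (length(bad))
    stop(sprintf("malformed record(s) with end <= start at index: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  GenomicRanges::strand(records) <- "*"
  ## connected components of the >= 1 bp overlap graph == reduce() with
  ## min.gapwidth = 0 (adjacent-but-not-overlapping stays separate)
  merged <- GenomicRanges::reduce(GenomicRanges::sort(records),
                                  min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(records, merged, minoverlap = 1L)
  tiss <- S4Vectors::splitAsList(records$tissue[S4Vectors::queryHits(hits)],
                                 S4Vectors::subjectHits(hits))
  tissues <- vapply(tiss, function(x) paste(sort(unique(x)), collapse = ","), "")
  nTiss <- vapply(tiss, function(x) length(unique(x)), 0L)
  merged$region_id <- sprintf("region_%05d", seq_along(merged))
  merged$tissues <- unname(tissues)
  merged$n_tissues <- unname(nTiss)
  merged$pleiotropy <- ifelse(merged$n_tissues == 1L, "specific", "pleiotropic")
  if (!is.null(records$enhancer_id)) {
    mem <- S4Vectors::splitAsList(
      records$enhancer_id[S4Vectors::queryHits(hits)],
      S4Vectors::subjectHits(hits))
    merged$members <- unname(vapply(mem, paste, "", collapse = ","))
  }
  merged
}

#' Pleiotropy class of a tissue set
#'
#' @param tissues character vector of tissue labels for one region, or a
#'   comma-collapsed string.
#' @return \code{"specific"} when exactly one distinct tissue,
#'   \code{"pleiotropic"} otherwise.
#' @examples
#' classifyPleiotropy("HT")          # "specific"
#' classifyPleiotropy(c("HT", "MB")) # "pleiotropic"
#' @export
classifyPleiotropy <- function(tissues) {
  if (length(tissues) == 1L && grepl(",", tissues))
    tissues <- strsplit(tissues, ",", fixed = TRUE)[[1]]
  assertThat(length(tissues) > 0L, "tissue set must be nonempty")
  if (length(unique(tissues)) == 1L) "specific" else "pleiotropic"
}

#' Assign each region its nearest gene
#'
#' Distance is measured between interval boundaries (0 when overlapping);
#' strand is ignored.  Ties are broken deterministically: smaller distance,
#' then lower gene start, then lexicographic gene id.  With
#' \code{requireOrtholog}, candidates are restricted to genes carrying a
#' one-to-one ortholog in the comparison species — the gene used for the
#' neutral reference may therefore differ from the plain nearest gene.
#'
#' @param regions \code{GRanges} of consolidated regions.
#' @param genes \code{GRanges} with metadata \code{gene_id} and, when
#'   \code{requireOrtholog} is not \code{"none"}, logical columns
#'   \code{ortholog_rat} / \code{ortholog_human}.
#' @param requireOrtholog \code{"none"} (any gene), \code{"rat"} or
#'   \code{"human"}.
#' @return character vector of gene ids (NA when no candidate gene exists),
#'   with the boundary distance in attribute \code{"distance"}.
#' @export
assignNearestGene <- function(regions, genes,
                              requireOrtholog = c("none", "rat", "human")) {
  requireOrtholog <- match.arg(requireOrtholog)
  cand <- genes
  if (requireOrtholog == "rat") cand <- genes[isTRUE2(genes$ortholog_rat)]
  if (requireOrtholog == "human") cand <- genes[isTRUE2(genes$ortholog_human)]
  out <- rep(NA_character_, length(regions))
  dist <- rep(NA_real_, length(regions))
  if (length(cand) == 0L || length(regions) == 0L) {
    attr(out, "distance") <- dist
    return(out)
  }
  hits <- GenomicRanges::distanceToNearest(regions, cand, select = "all",
                                           ignore.strand = TRUE)
  if (length(hits)) {
    df <- data.frame(q = S4Vectors::queryHits(hits),
                     s = S4Vectors::subjectHits(hits),
                     d = S4Vectors::mcols(hits)$distance)
    df$gstart <- GenomicRanges::start(cand)[df$s]
    df$gid <- cand$gene_id[df$s]
    df <- df[order(df$q, df$d, df$gstart, df$gid), ]
    keep <- !duplicated(df$q)
    out[df$q[keep]] <- df$gid[keep]
    dist[df$q[keep]] <- df$d[keep]
  }
  attr(out, "distance") <- dist
  out
}

isTRUE2 <- function(x) !is.na(x) & x

#' Attach recombination rates to regions by window midpoint lookup
#'
#' Each region receives the rate of the window containing its midpoint;
#' regions whose midpoint falls outside every window get \code{NA}.
#'
#' @param regions \code{GRanges}.
#' @param rateWindows \code{GRanges} of non-overlapping windows with a
#'   numeric \code{rate} column (cM/Mb).
#' @return \code{regions} with a \code{recombination_rate} metadata column.
#' @export
attachRecombination <- function(regions, rateWindows) {
  if (length(rateWindows) > 1L) {
    self <- GenomicRanges::findOverlaps(rateWindows, drop.self = TRUE,
                                        minoverlap = 1L)
    assertThat(length(self) == 0L, "rate windows overlap; they must tile disjointly")
  }
  mid <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(regions),
    IRanges::IRanges(
      (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L,
      width = 1L))
  hits <- GenomicRanges::findOverlaps(mid, rateWindows, select = "first")
  regions$recombination_rate <- ifelse(is.na(hits), NA_real_,
                                       rateWindows$rate[hits])
  regions
}

#' Annotate consolidated regions with nearest gene, neutral-reference gene
#' and recombination rate
#'
#' Convenience wrapper used by the pipeline: the plain nearest gene (any
#' candidate) populates \code{nearest_gene_id}; the nearest gene restricted
#' to one-to-one orthologs in \code{orthologSpecies} populates
#' \code{neutral_reference_gene_id}; window midpoint lookup populates
#' \code{recombination_rate}.
#'
#' @param regions consolidated \code{GRanges} from
#'   \code{\link{consolidateEnhancers}}.
#' @param geneModels a \linkS4class{GeneModels}.
#' @param rateWindows optional recombination windows (\code{GRanges} with
#'   \code{rate}).
#' @param orthologSpecies \code{"rat"} or \code{"human"}.
#' @return annotated \code{GRanges}.
#' @export
annotateRegions <- function(regions, geneModels, rateWindows = NULL,
                            orthologSpecies = "rat") {
  g <- geneModels@genes
  regions$nearest_gene_id <- as.character(assignNearestGene(regions, g, "none"))
  nr <- assignNearestGene(regions, g, orthologSpecies)
  regions$neutral_reference_gene_id <- as.character(nr)
  regions$nearest_gene_distance <- attr(nr, "distance")
  if (!is.null(rateWindows)) regions <- attachRecombination(regions, rateWindows)
  regions
}
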