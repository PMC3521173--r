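## Readers and writers.  Internal coordinates are 1-based (GRanges); every
## emitted file uses the 0-based half-open BED convention for interval
## columns.  MAF support is a minimal block-based implementation (no
## installed package parses MAF).

#' Write tissue-labelled enhancers as BED
#'
#' 4-column BED; column 4 (name) carries the tissue label.
#'
#' @param enhancers \code{GRanges} with a \code{tissue} column.
#' @param file output path.
#' @export
writeEnhancerBed <- function(enhancers, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(enhancers)),
                   start = GenomicRanges::start(enhancers) - 1L,
                   end = GenomicRanges::end(enhancers),
                   name = enhancers$tissue)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read tissue-labelled enhancers from BED
#'
#' @param files one or more BED paths; column 4 must be the tissue label
#'   (one file per tissue, or a single mixed file).
#' @return \code{GRanges} with \code{tissue} and \code{enhancer_id} columns.
#' @export
readEnhancerBed <- function(files) {
  parts <- lapply(files, function(f) {
    gr <- rtracklayer::import(f, format = "bed")
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr))
    out$tissue <- gr$name
    out
  })
  gr <- do.call(c, parts)
  gr$enhancer_id <- sprintf("enh_%05d", seq_along(gr))
  gr
}

#' Write gene models as GTF-like text
#'
#' Emits gene, transcript, exon and CDS lines (CDS excludes the stop codon)
#' with \code{gene_id}/\code{transcript_id} attributes; ortholog flags are
#' carried on gene lines.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param file output path.
#' @export
writeGeneModelsGtf <- function(geneModels, file) {
  lines <- character(0)
  g <- geneModels@genes
  for (i in seq_along(g)) {
    attrs <- sprintf('gene_id "%s"; ortholog_rat "%d"; ortholog_human "%d";',
                     g$gene_id[i], as.integer(g$ortholog_rat[i]),
                     as.integer(g$ortholog_human[i]))
    lines <- c(lines, paste(
      as.character(GenomicRanges::seqnames(g))[i], "sim", "gene",
      GenomicRanges::start(g)[i], GenomicRanges::end(g)[i], ".",
      as.character(GenomicRanges::strand(g))[i], ".", attrs, sep = "\t"))
  }
  for (tx in geneModels@txGene$tx_id) {
    gid <- geneModels@txGene$gene_id[geneModels@txGene$tx_id == tx]
    exons <- geneModels@exonsByTx[[tx]]
    cds <- geneModels@cdsByTx[[tx]]
    chrom <- as.character(GenomicRanges::seqnames(exons))[1]
    strand <- as.character(GenomicRanges::strand(exons))[1]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tx)
    lines <- c(lines, paste(chrom, "sim", "transcript",
                            min(GenomicRanges::start(exons)),
                            max(GenomicRanges::end(exons)),
                            ".", strand, ".", attrs, sep = "\t"))
    for (i in seq_along(exons))
      lines <- c(lines, paste(chrom, "sim", "exon",
                              GenomicRanges::start(exons)[i],
                              GenomicRanges::end(exons)[i], ".", strand, ".",
                              attrs, sep = "\t"))
    for (i in seq_along(cds))
      lines <- c(lines, paste(chrom, "sim", "CDS",
                              GenomicRanges::start(cds)[i],
                              GenomicRanges::end(cds)[i], ".", strand, "0",
                              attrs, sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read gene models from GTF
#'
#' @param file GTF path (as written by \code{\link{writeGeneModelsGtf}} or
#'   compatible).
#' @param covariates optional covariate \code{DataFrame} to attach (as from
#'   \code{\link{readCovariatesTsv}}).
#' @return a \linkS4class{GeneModels}.
#' @export
readGeneModelsGtf <- function(file, covariates = NULL) {
  gr <- rtracklayer::import(file, format = "gtf")
  genes <- gr[gr$type == "gene"]
  genes$n_introns <- NA_integer_
  if (!is.null(genes$ortholog_rat))
    genes$ortholog_rat <- genes$ortholog_rat == "1"
  if (!is.null(genes$ortholog_human))
    genes$ortholog_human <- genes$ortholog_human == "1"
  exons <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  exonsByTx <- GenomicRanges::split(exons, exons$transcript_id)
  cdsByTx <- GenomicRanges::split(cds, cds$transcript_id)
  txIds <- names(exonsByTx)
  ## ensure every transcript has a (possibly empty) CDS entry, same order
  cdsByTx <- GenomicRanges::GRangesList(lapply(txIds, function(tx)
    if (tx %in% names(cdsByTx)) cdsByTx[[tx]] else GenomicRanges::GRanges()))
  names(cdsByTx) <- txIds
  gidOfTx <- exons$gene_id[match(txIds, exons$transcript_id)]
  S4Vectors::mcols(genes) <- S4Vectors::mcols(genes)[
    , intersect(c("gene_id", "n_introns", "ortholog_rat", "ortholog_human"),
                colnames(S4Vectors::mcols(genes))), drop = FALSE]
  new("GeneModels", genes = genes,
      exonsByTx = exonsByTx, cdsByTx = cdsByTx,
      txGene = S4Vectors::DataFrame(tx_id = txIds, gene_id = gidOfTx),
      covariates = covariates %||%
        S4Vectors::DataFrame(gene_id = genes$gene_id,
                             phenotypes = NA_character_))
}

#' Write / read the gene covariate table
#'
#' TSV with \code{gene_id}, \code{phenotypes} (comma-separated terms, empty
#' = none documented), \code{essential} (derived 0/1, NA when unknown) and
#' 61 expression signal columns.
#'
#' @param covariates the \code{DataFrame} held by a
#'   \linkS4class{GeneModels}.
#' @param file path.
#' @export
writeCovariatesTsv <- function(covariates, file) {
  df <- as.data.frame(covariates)
  ess <- classifyEssentiality(df$phenotypes)
  df <- cbind(df[, "gene_id", drop = FALSE],
              essential = ifelse(ess == "unknown", NA_integer_,
                                 as.integer(ess == "essential")),
              df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCovariatesTsv
#' @export
readCovariatesTsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  df$phenotypes[is.na(df$phenotypes)] <- ""
  S4Vectors::DataFrame(df[, setdiff(colnames(df), "essential"), drop = FALSE])
}

#' Write a three-species alignment as MAF
#'
#' One block per \code{blockSize} columns; coordinates are 0-based MAF
#' convention on the (ungapped) mouse reference.
#'
#' @param aln a \linkS4class{TripleAlignment}.
#' @param file path.
#' @param blockSize columns per block.
#' @export
writeMaf <- function(aln, file, blockSize = 1000000L) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  width <- alignmentWidth(aln)
  starts <- seq(1L, width, by = blockSize)
  rows <- lapply(aln@seqs, function(s) s)
  for (s in starts) {
    e <- min(s + blockSize - 1L, width)
    writeLines("a score=0", con)
    for (sp in names(aln@seqs)) {
      seg <- substr(aln@seqs[[sp]], s, e)
      ungapped <- nchar(gsub("-", "", seg, fixed = TRUE))
      ## 0-based start of this row within its source sequence
      prior <- substr(aln@seqs[[sp]], 1L, s - 1L)
      off <- nchar(gsub("-", "", prior, fixed = TRUE))
      srcStart <- if (sp == "mouse") aln@start - 1L + off else off
      srcSize <- nchar(gsub("-", "", aln@seqs[[sp]], fixed = TRUE))
      writeLines(sprintf("s %s.%s %d %d + %d %s", sp, aln@chrom, srcStart,
                         ungapped, srcSize, seg), con)
    }
    writeLines("", con)
  }
  invisible(file)
}

#' Read a three-species MAF into a TripleAlignment
#'
#' Blocks must be colinear on the mouse reference (as written by
#' \code{\link{writeMaf}}).  Truth slots (ancestor, per-site rates) are left
#' empty: they exist only for simulated alignments.
#'
#' @param file MAF path.
#' @return a \linkS4class{TripleAlignment}.
#' @export
readMaf <- function(file) {
  lines <- readLines(file)
  sLines <- grep("^s ", lines, value = TRUE)
  parts <- strsplit(sLines, "[[:space:]]+")
  src <- vapply(parts, `[`, "", 2L)
  sp <- sub("\\..*$", "", src)
  chrom <- sub("^[^.]*\\.", "", src[1])
  start0 <- as.integer(vapply(parts, `[`, "", 3L))
  seqs <- vapply(parts, `[`, "", 7L)
  out <- vapply(c("mouse", "rat", "human"), function(s)
    paste(seqs[sp == s], collapse = ""), "")
  mouseStart <- min(start0[sp == "mouse"]) + 1L
  new("TripleAlignment", chrom = chrom, start = as.integer(mouseStart),
      seqs = out, ancestor = "", siteRate = numeric(0),
      truthMeta = S4Vectors::DataFrame())
}

#' Write the aligned slice of one region as FASTA
#'
#' @param aln a \linkS4class{TripleAlignment}.
#' @param region \code{GRanges} of length 1 (mouse coordinates).
#' @param file path.
#' @export
writeRegionFasta <- function(aln, region, file) {
  s <- GenomicRanges::start(region) - aln@start + 1L
  e <- GenomicRanges::end(region) - aln@start + 1L
  assertThat(s >= 1L && e <= alignmentWidth(aln),
             "region outside the alignment block")
  recs <- vapply(names(aln@seqs), function(sp)
    substr(aln@seqs[[sp]], s, e), "")
  out <- Biostrings::DNAStringSet(recs)
  names(out) <- sprintf("%s %s:%d-%d", names(recs), aln@chrom,
                        GenomicRanges::start(region),
                        GenomicRanges::end(region))
  Biostrings::writeXStringSet(out, file)
  invisible(file)
}

#' Write / read recombination windows
#'
#' TSV columns: chrom, start (0-based), end, rate (cM/Mb).
#'
#' @param windows \code{GRanges} with \code{rate}.
#' @param file path.
#' @export
writeRecombTsv <- function(windows, file) {
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
               start = GenomicRanges::start(windows) - 1L,
               end = GenomicRanges::end(windows),
               rate = windows$rate),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeRecombTsv
#' @export
readRecombTsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$rate <- df$rate
  gr
}

#' Write consolidated regions with annotations as TSV
#'
#' BED-style interval columns (0-based start) plus tissue set, pleiotropy,
#' nearest gene, neutral-reference gene and recombination rate.
#'
#' @param regions annotated \code{GRanges}.
#' @param file path.
#' @export
writeRegionsTsv <- function(regions, file) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   region_id = regions$region_id,
                   tissues = regions$tissues,
                   pleiotropy = regions$pleiotropy,
                   nearest_gene_id = regions$nearest_gene_id %||% NA,
                   neutral_reference_gene_id =
                     regions$neutral_reference_gene_id %||% NA,
                   recombination_rate = regions$recombination_rate %||% NA)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeRegionsTsv
#' @export
readRegionsTsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  for (col in setdiff(colnames(df), c("chrom", "start", "end")))
    S4Vectors::mcols(gr)[[col]] <- df[[col]]
  gr
}

#' Write site masks as BED (one interval per run of consecutive sites)
#'
#' @param masks list of \linkS4class{SiteMask}.
#' @param file path.
#' @export
writeMasksBed <- function(masks, file) {
  rows <- lapply(masks, function(m) {
    pos <- maskPositions(m)
    if (length(pos) == 0L) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(pos, width = 1L))
    data.frame(chrom = "chrS", start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               name = sprintf("%s_%s", m@gene_id, m@siteClass))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame()
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
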