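## End-to-end orchestration: simulate -> consolidate -> masks -> divergence
## -> classification -> gBGC -> covariates, with a machine-readable run
## manifest.  All randomness flows from the configuration seed; re-running
## with an identical configuration reproduces byte-identical files.

#' Run the full analysis pipeline on a simulated study
#'
#' Stages run in dependency order; each writes its outputs as TSV/BED/GTF/
#' MAF under \code{outDir} and registers its counts (in / out / excluded
#' with reasons) in \code{manifest.json}.  Data go to files, progress
#' messages to standard error.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir output directory (created if missing).
#' @param alpha per-enhancer significance level.
#' @param smallUnit see \code{\link{divergenceTable}}.
#' @param specificOnly restrict selection scans to tissue-specific regions.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results:
#'   \code{sim}, \code{regions}, \code{masks}, \code{divergence},
#'   \code{scanFourfold}, \code{scanIntron}, \code{gbgc}, \code{covariates},
#'   \code{manifest}.
#' @export
runPipeline <- function(config, outDir, alpha = 0.05, smallUnit = 200L,
                        specificOnly = TRUE, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pth <- function(f) file.path(outDir, f)
  stages <- list()
  exclusions <- list()
  addStage <- function(name, inputs, outputs, nIn, nOut, nExcluded) {
    stages[[length(stages) + 1L]] <<- list(
      name = name, inputs = inputs, outputs = outputs,
      counts = list(`in` = nIn, out = nOut, excluded = nExcluded))
  }
  addExclusions <- function(stage, df) {
    if (!is.null(df) && nrow(df) > 0L) {
      df$stage <- stage
      exclusions[[length(exclusions) + 1L]] <<- df
    }
  }

  ## 1. simulate
  say("simulate: seed %d", config@seed)
  sim <- simulateStudy(config)
  writeEnhancerBed(sim$enhancers, pth("enhancers.bed"))
  writeGeneModelsGtf(sim$genes, pth("genes.gtf"))
  writeCovariatesTsv(sim$genes@covariates, pth("covariates.tsv"))
  utils::write.table(as.data.frame(sim$truth), pth("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeMaf(sim$alignment, pth("alignment.maf"))
  writeRecombTsv(sim$recomb, pth("recomb.tsv"))
  addStage("simulate", character(0),
           c("enhancers.bed", "genes.gtf", "covariates.tsv", "truth.tsv",
             "alignment.maf", "recomb.tsv"),
           nIn = 0L, nOut = length(sim$enhancers), nExcluded = 0L)

  ## 2. consolidate + annotate
  regions <- consolidateEnhancers(sim$enhancers)
  regions <- annotateRegions(regions, sim$genes, sim$recomb,
                             orthologSpecies = "rat")
  writeRegionsTsv(regions, pth("regions.tsv"))
  say("consolidate: %d enhancers -> %d regions", length(sim$enhancers),
      length(regions))
  addStage("consolidate", "enhancers.bed", "regions.tsv",
           nIn = length(sim$enhancers), nOut = length(regions),
           nExcluded = 0L)

  ## 3. site masks
  genome <- referenceGenome(sim$alignment)
  masks <- geneSiteMasks(sim$genes, genome)
  utils::write.table(maskSummary(masks), pth("masks_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeMasksBed(masks$fourfold, pth("masks_fourfold.bed"))
  writeMasksBed(masks$intron, pth("masks_intron.bed"))
  addExclusions("sites", masks$excluded)
  say("sites: %d genes with fourfold mask, %d excluded",
      length(masks$fourfold), nrow(masks$excluded))
  addStage("sites", "genes.gtf",
           c("masks_summary.tsv", "masks_fourfold.bed", "masks_intron.bed"),
           nIn = length(sim$genes@genes), nOut = length(masks$fourfold),
           nExcluded = nrow(masks$excluded))

  ## 4. divergence
  div <- divergenceTable(regions, masks, sim$alignment,
                         nCategories = config@model@nCategories,
                         smallUnit = smallUnit)
  utils::write.table(div$table, pth("divergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  addExclusions("divergence",
                if (nrow(div$skipped))
                  data.frame(region_id = div$skipped$unit_id,
                             reason = div$skipped$reason) else NULL)
  say("divergence: %d units fitted", nrow(div$table))
  addStage("divergence", c("regions.tsv", "alignment.maf"), "divergence.tsv",
           nIn = length(regions), nOut = sum(div$table$kind == "enhancer"),
           nExcluded = sum(div$skipped$kind == "enhancer"))

  ## 5. selection classification, both neutral references
  scans <- list()
  for (ref in c("fourfold", "intron")) {
    scan <- selectionScan(regions, div$table, reference = ref, alpha = alpha,
                          specificOnly = specificOnly)
    utils::write.table(scan$calls, pth(sprintf("calls_%s.tsv", ref)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scan$summary, pth(sprintf("summary_%s.tsv", ref)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addExclusions(paste0("selection_", ref), scan$excluded)
    addStage(paste0("selection_", ref), "divergence.tsv",
             c(sprintf("calls_%s.tsv", ref), sprintf("summary_%s.tsv", ref)),
             nIn = length(regions), nOut = nrow(scan$calls),
             nExcluded = nrow(scan$excluded))
    scans[[ref]] <- scan
  }

  ## 6. gBGC polarization
  gb <- polarityCounts(regions, sim$alignment)
  utils::write.table(gb, pth("gbgc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec1 <- regions$pleiotropy == "specific"
  gbCmp <- NULL
  ratios <- gb$ratio[spec1]
  tiss <- regions$tissues[spec1]
  ok <- is.finite(ratios)
  if (length(unique(tiss[ok])) >= 2L) {
    gbCmp <- compareGroups(ratios[ok], tiss[ok])
    utils::write.table(gbCmp, pth("gbgc_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  say("gbgc: %d regions polarized", nrow(gb))
  addStage("gbgc", c("regions.tsv", "alignment.maf"),
           c("gbgc.tsv", "gbgc_comparison.tsv"),
           nIn = length(regions), nOut = nrow(gb), nExcluded = 0L)

  ## 7. covariate analyses
  covTab <- covariateTable(regions, sim$genes)
  utils::write.table(covTab, pth("covariates_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  enhT <- div$table[div$table$kind == "enhancer", ]
  Dvals <- structure(enhT$t, names = enhT$unit_id)
  ratios4 <- if (nrow(scans$fourfold$calls))
    structure(scans$fourfold$calls$ratio,
              names = scans$fourfold$calls$region_id) else numeric(0)
  ctrl <- list(
    D = controlledComparison(covTab, Dvals, specificOnly = TRUE),
    ratio = if (length(ratios4))
      controlledComparison(covTab, ratios4, specificOnly = TRUE) else NULL)
  utils::write.table(ctrl$D, pth("assoc_controlled_D.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ctrl$ratio))
    utils::write.table(ctrl$ratio, pth("assoc_controlled_ratio.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  addStage("covariates", c("regions.tsv", "divergence.tsv", "covariates.tsv"),
           c("covariates_regions.tsv", "assoc_controlled_D.tsv",
             "assoc_controlled_ratio.tsv"),
           nIn = length(regions), nOut = nrow(covTab), nExcluded = 0L)

  ## 8. manifest + exclusion log
  exdf <- if (length(exclusions)) do.call(rbind, exclusions)
          else data.frame(region_id = character(0), reason = character(0),
                          stage = character(0))
  utils::write.table(exdf, pth("exclusions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    tool = "enhSelScan",
    version = as.character(utils::packageVersion("enhSelScan")),
    seed = config@seed,
    config_hash = configHash(config),
    stages = stages)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, regions = regions, masks = masks,
                 divergence = div, scanFourfold = scans$fourfold,
                 scanIntron = scans$intron, gbgc = gb,
                 gbgcComparison = gbCmp, covariates = covTab,
                 controlled = ctrl, manifest = manifest))
}

#' Fingerprint of a simulation configuration
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return 8-hex-digit hash of the deparsed configuration.
#' @export
configHash <- function(config) {
  slots <- methods::slotNames(config)
  txt <- vapply(slots, function(s)
    paste(s, paste(deparse(methods::slot(config, s)), collapse = ""),
          sep = "="), "")
  textHash(txt)
}

#' Format a selection summary like the published proportion tables
#'
#' Turns counts into the three ratio columns Under selection/Total,
#' Positively selected/Under selection and Positively selected/Total, as
#' percentage strings truncated to two decimals (the convention of the
#' tables this mirrors).  Undefined ratios (zero denominators) print as
#' \code{"-"}.
#'
#' @param summary data.frame from \code{\link{selectionSummary}} (columns
#'   \code{tissue}, \code{total}, \code{under_selection}, \code{positive}).
#' @return data.frame with the counts and formatted percentage columns
#'   \code{under_over_total}, \code{pos_over_under}, \code{pos_over_total}.
#' @examples
#' reportSummary(data.frame(tissue = "HT", total = 2554,
#'                          under_selection = 875, positive = 360))
#' @export
reportSummary <- function(summary) {
  data.frame(
    tissue = summary$tissue,
    total = summary$total,
    under_selection = summary$under_selection,
    positive = summary$positive,
    under_over_total = formatPercent(
      ifelse(summary$total > 0, summary$under_selection / summary$total, NA)),
    pos_over_under = formatPercent(
      ifelse(summary$under_selection > 0,
             summary$positive / summary$under_selection, NA)),
    pos_over_total = formatPercent(
      ifelse(summary$total > 0, summary$positive / summary$total, NA)))
}
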