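## Neutral-reference normalization and Fisher's-exact selection
## classification per enhancer, with per-tissue summary tables.

#' Normalize an enhancer divergence by its neutral reference
#'
#' The ratio D/d4 (or D/di) indexes the relative strength of selection on
#' the enhancer: values below 1 indicate purifying constraint, values above
#' 1 accelerated (possibly positively selected) evolution.  Regions whose
#' neutral reference has zero divergence are undefined and excluded.
#'
#' @param D,d numeric divergences (substitutions/site); \code{d} is the
#'   neutral reference (d4 or di).
#' @param kind \code{"d4"} or \code{"di"} (recorded, not used in the
#'   arithmetic).
#' @return data.frame with \code{D}, \code{d_neutral}, \code{ratio},
#'   \code{reference_kind}; \code{ratio} is \code{NA} where \code{d == 0}.
#' @examples
#' normalizeDivergence(0.10, 0.20, "d4")$ratio  # 0.5
#' @export
normalizeDivergence <- function(D, d, kind = c("d4", "di")) {
  kind <- match.arg(kind)
  ratio <- ifelse(is.finite(d) & d > 0, D / d, NA_real_)
  data.frame(D = D, d_neutral = d, ratio = ratio, reference_kind = kind)
}

## two-sided Fisher's exact p for the 2x2 table
## [diff1, same1; diff2, same2]: sum of hypergeometric point probabilities
## not exceeding the observed one (relative tolerance 1 + 1e-7, the standard
## tie convention).
fisherP2sided <- function(diff1, n1, diff2, n2) {
  m <- diff1 + diff2
  lo <- max(0L, m - n2)
  hi <- min(m, n1)
  k <- lo:hi
  p <- stats::dhyper(k, n1, n2, m)
  pObs <- stats::dhyper(diff1, n1, n2, m)
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

#' Classify the selection regime of one enhancer with Fisher's exact test
#'
#' Builds the 2x2 table (enhancer vs neutral reference) x (substituted vs
#' unsubstituted sites) and computes the exact two-sided hypergeometric
#' p-value (no continuity or large-sample approximation).  At
#' \code{p <= alpha}, an enhancer with a higher substitution proportion than
#' its neutral reference is called \code{positive}, a lower one
#' \code{purifying}; otherwise the neutral model cannot be rejected.
#'
#' @param enhDiff,enhSites substituted and total usable sites of the
#'   enhancer.
#' @param neutDiff,neutSites same for the neutral reference.
#' @param alpha significance level (default 0.05).
#' @return data.frame (vectorized over inputs) with the four counts,
#'   \code{p_value}, \code{direction}
#'   (\code{enhancer_enriched} / \code{enhancer_depleted} / \code{none}) and
#'   \code{call} (\code{positive} / \code{purifying} / \code{neutral}).
#' @examples
#' fisherClassify(10, 100, 10, 100)$call       # "neutral", p = 1
#' fisherClassify(30, 100, 10, 100)$call       # "positive"
#' @export
fisherClassify <- function(enhDiff, enhSites, neutDiff, neutSites,
                           alpha = 0.05) {
  n <- length(enhDiff)
  assertThat(all(c(enhDiff, enhSites, neutDiff, neutSites) >= 0),
             "counts must be nonnegative")
  assertThat(all(enhSites > 0) && all(neutSites > 0),
             "both rows of the table need n_sites > 0")
  assertThat(all(enhDiff <= enhSites) && all(neutDiff <= neutSites),
             "substituted sites cannot exceed total sites")
  p <- vapply(seq_len(n), function(i)
    fisherP2sided(enhDiff[i], enhSites[i], neutDiff[i], neutSites[i]), 0)
  propEnh <- enhDiff / enhSites
  propNeut <- neutDiff / neutSites
  direction <- ifelse(propEnh > propNeut, "enhancer_enriched",
                      ifelse(propEnh < propNeut, "enhancer_depleted", "none"))
  call <- ifelse(p > alpha, "neutral",
                 ifelse(propEnh > propNeut, "positive",
                        ifelse(propEnh < propNeut, "purifying", "neutral")))
  data.frame(enh_diff = enhDiff, enh_same = enhSites - enhDiff,
             neut_diff = neutDiff, neut_same = neutSites - neutDiff,
             p_value = p, direction = direction, call = call)
}

#' Per-enhancer selection scan against a neutral reference
#'
#' Joins each region's divergence row with the d4 (or di) row of its
#' neutral-reference gene, classifies every testable enhancer with
#' \code{\link{fisherClassify}}, attaches the normalized rate D/d, and
#' summarizes per tissue.  Regions are untestable (excluded from Total) when
#' they lack a neutral-reference gene, when the gene has no usable reference
#' sites of the requested kind, or when the neutral divergence is zero (the
#' ratio is undefined).  With \code{specificOnly}, pleiotropic regions are
#' excluded first, mirroring the tissue-specific analysis.
#'
#' @param regions annotated \code{GRanges}
#'   (\code{\link{annotateRegions}}): needs \code{region_id},
#'   \code{tissues}, \code{pleiotropy}, \code{neutral_reference_gene_id}.
#' @param divTable data.frame from \code{\link{divergenceTable}}.
#' @param reference \code{"fourfold"} or \code{"intron"}.
#' @param alpha per-enhancer significance level (no multiple-testing
#'   correction drives the calls; a BH q-value column is emitted for
#'   transparency).
#' @param specificOnly restrict to tissue-specific regions (default TRUE).
#' @return list with \code{calls} (per-enhancer data.frame) and
#'   \code{summary} (see \code{\link{selectionSummary}}), plus
#'   \code{excluded} (region id / reason).
#' @export
selectionScan <- function(regions, divTable, reference = c("fourfold", "intron"),
                          alpha = 0.05, specificOnly = TRUE) {
  reference <- match.arg(reference)
  df <- as.data.frame(S4Vectors::mcols(regions))
  excluded <- list()
  note <- function(id, why)
    excluded[[length(excluded) + 1L]] <<- data.frame(region_id = id,
                                                     reason = why)
  if (specificOnly) {
    drop <- df$pleiotropy != "specific"
    for (id in df$region_id[drop]) note(id, "pleiotropic")
    df <- df[!drop, , drop = FALSE]
  }
  enhRows <- divTable[divTable$kind == "enhancer", , drop = FALSE]
  refRows <- divTable[divTable$kind == reference, , drop = FALSE]
  df$enh_i <- match(df$region_id, enhRows$unit_id)
  df$ref_i <- match(df$neutral_reference_gene_id, refRows$unit_id)
  for (id in df$region_id[is.na(df$neutral_reference_gene_id)])
    note(id, "no_ortholog_gene")
  for (id in df$region_id[!is.na(df$neutral_reference_gene_id) &
                          is.na(df$ref_i)])
    note(id, "no_neutral_reference_sites")
  for (id in df$region_id[is.na(df$enh_i)])
    note(id, "no_enhancer_alignment")
  ok <- !is.na(df$enh_i) & !is.na(df$ref_i)
  df <- df[ok, , drop = FALSE]
  zeroRef <- refRows$t[df$ref_i] <= 0
  for (id in df$region_id[zeroRef]) note(id, "zero_neutral_divergence")
  df <- df[!zeroRef, , drop = FALSE]

  if (nrow(df) == 0L) {
    calls <- data.frame()
  } else {
    cls <- fisherClassify(enhRows$n_diff[df$enh_i], enhRows$n_sites[df$enh_i],
                          refRows$n_diff[df$ref_i], refRows$n_sites[df$ref_i],
                          alpha = alpha)
    norm <- normalizeDivergence(enhRows$t[df$enh_i], refRows$t[df$ref_i],
                                if (reference == "fourfold") "d4" else "di")
    calls <- cbind(
      data.frame(region_id = df$region_id, tissues = df$tissues,
                 pleiotropy = df$pleiotropy,
                 neutral_gene = df$neutral_reference_gene_id,
                 reference = reference),
      cls, norm,
      data.frame(q_bh = stats::p.adjust(cls$p_value, method = "BH")))
  }
  list(calls = calls, summary = selectionSummary(calls),
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(region_id = character(0),
                                  reason = character(0)))
}

#' Per-tissue summary of selection calls
#'
#' Counts, per tissue, the testable enhancers (Total), those with the
#' neutral model rejected (Under selection) and the positively selected
#' subset, with the three ratios Under selection/Total, Positively
#' selected/Under selection and Positively selected/Total.  Regions spanning
#' several tissues contribute to each of their tissues.
#'
#' @param calls data.frame from \code{\link{selectionScan}}.
#' @param tissues tissue labels to report (default FB, MB, LB, HT).
#' @return data.frame with columns \code{tissue}, \code{total},
#'   \code{under_selection}, \code{positive} and the three ratio columns
#'   (proportions; \code{NA} when undefined).
#' @export
selectionSummary <- function(calls, tissues = TISSUES) {
  rows <- lapply(tissues, function(ts) {
    if (nrow(calls) == 0L) sub <- calls
    else sub <- calls[vapply(strsplit(calls$tissues, ",", fixed = TRUE),
                             function(x) ts %in% x, TRUE), , drop = FALSE]
    total <- nrow(sub)
    under <- if (total) sum(sub$call != "neutral") else 0L
    pos <- if (total) sum(sub$call == "positive") else 0L
    data.frame(tissue = ts, total = total, under_selection = under,
               positive = pos,
               under_over_total = if (total > 0) under / total else NA_real_,
               pos_over_under = if (under > 0) pos / under else NA_real_,
               pos_over_total = if (total > 0) pos / total else NA_real_)
  })
  do.call(rbind, rows)
}
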