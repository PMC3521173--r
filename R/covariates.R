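## Gene-level covariates (essentiality, expression) and the grouped /
## controlled comparisons of enhancer evolutionary rates.

ESSENTIAL_TERMS <- c("premature_death", "infertility")
EXPRESSION_BINS <- c("<200", "200-400", ">=400")

#' Classify gene essentiality from knockout phenotype terms
#'
#' A gene is essential when any documented null phenotype is premature death
#' or infertility; non-essential when it has at least one documented null
#' phenotype and none of those; unknown (excluded from essentiality
#' contrasts) when no null phenotype is documented.
#'
#' @param phenotypes character vector, one element per gene: comma-separated
#'   phenotype terms, empty string or NA = none documented.  A list of
#'   character vectors is also accepted.
#' @return factor with levels essential, non_essential, unknown.
#' @examples
#' classifyEssentiality(c("premature_death", "coat_color", ""))
#' @export
classifyEssentiality <- function(phenotypes) {
  if (!is.list(phenotypes))
    phenotypes <- strsplit(ifelse(is.na(phenotypes), "", phenotypes),
                           ",", fixed = TRUE)
  out <- vapply(phenotypes, function(terms) {
    terms <- trimws(terms[nzchar(trimws(terms))])
    if (length(terms) == 0L) "unknown"
    else if (any(terms %in% ESSENTIAL_TERMS)) "essential"
    else "non_essential"
  }, "")
  factor(out, levels = c("essential", "non_essential", "unknown"))
}

#' Summarize a gene's expression signals and bin the summary
#'
#' The summary is the mean (default) or the maximum of the per-tissue
#' signals (61 tissues in the simulated compendium).  Bins partition the
#' axis as \[0, 200), \[200, 400), \[400, Inf): the value 400 falls in the
#' top bin, 200 in the middle bin.
#'
#' @param signals numeric vector (one gene) or matrix (genes x tissues).
#' @param mode \code{"mean"} or \code{"max"}.
#' @return data.frame with \code{value} and \code{bin} (factor
#'   \code{"<200"}, \code{"200-400"}, \code{">=400"}); genes with no
#'   non-missing signal get NA in both.
#' @examples
#' expressionSummary(rep(100, 61))$bin        # "<200"
#' expressionSummary(c(rep(50, 60), 500), mode = "max")$bin  # ">=400"
#' @export
expressionSummary <- function(signals, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  value <- apply(signals, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) NA_real_
    else if (mode == "mean") mean(x) else max(x)
  })
  data.frame(value = value, bin = expressionBin(value))
}

#' @rdname expressionSummary
#' @param value numeric summary values to bin directly.
#' @export
expressionBin <- function(value) {
  cut(value, breaks = c(-Inf, 200, 400, Inf), right = FALSE,
      labels = EXPRESSION_BINS)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient uses average ranks for ties (Pearson correlation of the
#' rank vectors).  For n <= 10 the p-value is an exhaustive two-sided
#' permutation test (all n! pairings); for larger n the usual
#' t-approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{n}, \code{method}.
#' @examples
#' spearmanAssoc(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanAssoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  assertThat(n >= 3L, "need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    perms <- permuteAll(n)
    rhoAll <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

## all permutations of 1..n as a matrix (n! rows); recursive construction
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Composition chi-squared test across groups
#'
#' Generic 2 x k (or m x k) contingency chi-squared, e.g. specific vs
#' pleiotropic composition across tissues.
#'
#' @param counts matrix of counts (rows = categories, columns = groups).
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
compositionChisq <- function(counts) {
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Build the per-region covariate table
#'
#' Joins each region's pleiotropy class with its nearest gene's essentiality
#' and expression summary/bin.
#'
#' @param regions annotated \code{GRanges} (needs \code{region_id},
#'   \code{pleiotropy}, \code{nearest_gene_id}).
#' @param geneModels a \linkS4class{GeneModels} carrying the covariates.
#' @param mode expression summary mode, \code{"mean"} or \code{"max"}.
#' @return data.frame: \code{region_id}, \code{tissues}, \code{pleiotropy},
#'   \code{nearest_gene_id}, \code{essentiality}, \code{expression},
#'   \code{expression_bin}.
#' @export
covariateTable <- function(regions, geneModels, mode = "mean") {
  cov <- geneModels@covariates
  ess <- classifyEssentiality(cov$phenotypes)
  exprCols <- grep("^expr_", colnames(cov), value = TRUE)
  es <- expressionSummary(as.matrix(as.data.frame(cov[, exprCols])),
                          mode = mode)
  i <- match(regions$nearest_gene_id, cov$gene_id)
  data.frame(region_id = regions$region_id,
             tissues = regions$tissues,
             pleiotropy = regions$pleiotropy,
             nearest_gene_id = regions$nearest_gene_id,
             essentiality = as.character(ess)[i],
             expression = es$value[i],
             expression_bin = as.character(es$bin)[i])
}

#' Tissue comparisons of evolutionary rate, controlled for pleiotropy and
#' expression
#'
#' Within every expression bin of the nearest gene (tissue specificity is
#' controlled by restricting to specific regions), compares a rate variable
#' (D or D/d4) between every pair of tissues with two-sided rank-sum tests.
#'
#' @param covTable data.frame from \code{\link{covariateTable}}.
#' @param values named numeric: rate value per \code{region_id} (e.g. D or
#'   D/d4 from the divergence/selection tables).
#' @param specificOnly restrict to specific regions (default TRUE).
#' @param byBin control for expression by comparing within bins (default
#'   TRUE; FALSE reduces to a single uncontrolled comparison).
#' @return data.frame with columns \code{bin}, \code{group1}, \code{group2},
#'   \code{n1}, \code{n2}, \code{median1}, \code{median2}, \code{p_value},
#'   \code{stars}.  Empty bin-tissue cells are skipped.
#' @export
controlledComparison <- function(covTable, values, specificOnly = TRUE,
                                 byBin = TRUE) {
  df <- covTable
  if (specificOnly) df <- df[df$pleiotropy == "specific", , drop = FALSE]
  df$value <- unname(values[df$region_id])
  df <- df[is.finite(df$value), , drop = FALSE]
  ## regions spanning several tissues are excluded upstream by specificOnly;
  ## the remaining tissue set is the single label
  df$tissue <- vapply(strsplit(df$tissues, ",", fixed = TRUE), `[`, "", 1L)
  bins <- if (byBin) EXPRESSION_BINS else "all"
  rows <- list()
  for (b in bins) {
    sub <- if (byBin) df[!is.na(df$expression_bin) & df$expression_bin == b, ]
           else df
    if (length(unique(sub$tissue)) < 2L) next
    cmp <- compareGroups(sub$value, sub$tissue)
    if (is.null(cmp) || nrow(cmp) == 0L) next
    cmp <- cbind(data.frame(bin = b), cmp)
    rows[[length(rows) + 1L]] <- cmp
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(bin = character(0), group1 = character(0),
                  group2 = character(0), n1 = integer(0), n2 = integer(0),
                  median1 = numeric(0), median2 = numeric(0),
                  p_value = numeric(0), stars = character(0))
}
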