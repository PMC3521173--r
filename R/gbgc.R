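## GC-biased gene conversion diagnostics: parsimony polarization of
## mouse-lineage substitutions at ancestrally A/T sites, per-region counts,
## and rank-sum group comparisons.

POLARITY_LEVELS <- c("excluded", "not_ancestral_AT", "no_substitution",
                     "AT_to_GC", "AT_to_AT")

#' Polarize sites with the rat/human outgroup rule
#'
#' A site is ancestrally A/T when rat and human carry the same base and that
#' base is A or T (strict agreement; a rat = A / human = T column leaves the
#' ancestor ambiguous and is classified \code{not_ancestral_AT}).  Given an
#' ancestral A/T, the mouse base decides: equal to the ancestor means
#' \code{no_substitution}; G or C means \code{AT_to_GC}; the other A/T base
#' means \code{AT_to_AT}.  Gaps and ambiguity codes in any species give
#' \code{excluded}.  With \code{loose = TRUE}, rat and human need only both
#' be in \{A, T\} and the rat base is taken as the ancestor.
#'
#' Parsimony (not probabilistic reconstruction) is used, and multiple hits
#' are ignored: a site counts once whatever its true event history.
#'
#' @param mouse,rat,human character vectors of single bases (case
#'   insensitive).
#' @param loose use the looser ancestral rule (default FALSE).
#' @return factor with levels excluded, not_ancestral_AT, no_substitution,
#'   AT_to_GC, AT_to_AT.
#' @examples
#' polarizeSites("G", "A", "A")  # AT_to_GC
#' polarizeSites("T", "A", "A")  # AT_to_AT
#' @export
polarizeSites <- function(mouse, rat, human, loose = FALSE) {
  m <- toupper(mouse); r <- toupper(rat); h <- toupper(human)
  valid <- m %in% DNA_BASES4 & r %in% DNA_BASES4 & h %in% DNA_BASES4
  anc <- rep(NA_character_, length(m))
  if (loose) {
    at <- valid & r %in% c("A", "T") & h %in% c("A", "T")
    anc[at] <- r[at]
  } else {
    at <- valid & r == h & r %in% c("A", "T")
    anc[at] <- r[at]
  }
  out <- rep("not_ancestral_AT", length(m))
  out[!valid] <- "excluded"
  sel <- !is.na(anc)
  out[which(sel & m == anc)] <- "no_substitution"
  out[which(sel & m %in% c("G", "C"))] <- "AT_to_GC"
  out[which(sel & m %in% c("A", "T") & m != anc)] <- "AT_to_AT"
  factor(out, levels = POLARITY_LEVELS)
}

#' Per-region polarity counts for gBGC diagnosis
#'
#' For every region, counts the sites that were ancestrally A/T (rat/human
#' rule) and carry a mouse-lineage substitution (\code{n_substituted_AT}),
#' the subset substituted towards G/C (\code{n_AT_to_GC}), and their ratio
#' (\code{NA} when no A/T site is substituted).  Under GC-biased gene
#' conversion the ratio is elevated.
#'
#' @param regions \code{GRanges} with \code{region_id} (and optionally
#'   \code{tissues}).
#' @param aln a \linkS4class{TripleAlignment}.
#' @param loose passed to \code{\link{polarizeSites}}.
#' @return data.frame: \code{region_id}, \code{tissues},
#'   \code{n_substituted_AT}, \code{n_AT_to_GC}, \code{ratio}.
#' @export
polarityCounts <- function(regions, aln, loose = FALSE) {
  ai <- alignIndex(aln, c("mouse", "rat", "human"))
  cat <- polarizeSites(ai$chars$mouse, ai$chars$rat, ai$chars$human,
                       loose = loose)
  rows <- lapply(seq_along(regions), function(i) {
    pos <- GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]
    pos <- pos[pos >= 1L & pos <= length(ai$posToCol)]
    cols <- ai$posToCol[pos]
    cols <- cols[cols > 0L]
    cc <- cat[cols]
    nSub <- sum(cc %in% c("AT_to_GC", "AT_to_AT"))
    nGC <- sum(cc == "AT_to_GC")
    data.frame(region_id = regions$region_id[i],
               tissues = regions$tissues[i] %||% NA_character_,
               n_substituted_AT = nSub, n_AT_to_GC = nGC,
               ratio = if (nSub > 0) nGC / nSub else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pairwise rank-sum comparison of a value across tissue groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests for every pair of
#' groups: exact enumeration for small samples without ties, normal
#' approximation with tie correction otherwise (the behaviour of
#' \code{\link[stats]{wilcox.test}}).  Stars follow the usual thresholds:
#' \code{***} p <= 0.001, \code{**} p <= 0.01, \code{*} 0.01 < p <= 0.05.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame: \code{group1}, \code{group2}, \code{n1}, \code{n2},
#'   \code{median1}, \code{median2}, \code{p_value}, \code{stars}.  Pairs
#'   with an empty group are skipped.
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
compareGroups <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  gl <- unique(groups)
  assertThat(length(gl) >= 2L, "need at least two nonempty groups")
  rows <- list()
  for (i in seq_along(gl)) for (j in seq_along(gl)) {
    if (j <= i) next
    x <- values[groups == gl[i]]; y <- values[groups == gl[j]]
    if (length(x) == 0L || length(y) == 0L) next
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = gl[i], group2 = gl[j], n1 = length(x), n2 = length(y),
      median1 = stats::median(x), median2 = stats::median(y),
      p_value = p, stars = pStars(p))
  }
  do.call(rbind, rows)
}

pStars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Per-tissue distribution summary (quartile boxes)
#'
#' @param values numeric vector.
#' @param groups labels.
#' @return data.frame with n, lower quartile, median, upper quartile per
#'   group.
#' @export
groupQuartiles <- function(values, groups) {
  keep <- is.finite(values)
  sp <- split(values[keep], groups[keep])
  do.call(rbind, lapply(names(sp), function(g)
    data.frame(group = g, n = length(sp[[g]]),
               q1 = unname(stats::quantile(sp[[g]], 0.25)),
               median = stats::median(sp[[g]]),
               q3 = unname(stats::quantile(sp[[g]], 0.75)))))
}
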