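## Maximum-likelihood substitution distances under GTR + discrete gamma, for
## pairwise alignments (D, d4, di) and for the unrooted three-taxon
## mouse/rat/human tree.

#' Count site patterns of an alignment slice
#'
#' Collapses the selected alignment columns into a multiset of nucleotide
#' patterns (the sufficient statistic of the likelihood).  Columns in which
#' any sequence carries a gap or a non-ACGT symbol are excluded and tallied.
#'
#' @param aln a \linkS4class{TripleAlignment}, or a character vector of
#'   equal-length aligned sequences.
#' @param columns alignment column indices to use (default: all).
#' @param species which rows to use, e.g. \code{c("mouse", "rat")} for a
#'   pairwise analysis.
#' @return object of class \code{sitePatterns}: list with \code{counts}
#'   (named integer vector, names are concatenated bases in row order),
#'   \code{nSites}, \code{nDiff}, \code{nExcluded} and \code{nSeq}.
#' @examples
#' sp <- countSitePatterns(c(mouse = "ACGTAC", rat = "ACGTAT"))
#' sp$nSites; sp$nDiff
#' @export
countSitePatterns <- function(aln, columns = NULL,
                              species = c("mouse", "rat")) {
  seqs <- if (is(aln, "TripleAlignment")) aln@seqs[species] else aln[species]
  rows <- lapply(seqs, function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]])
  len <- unique(lengths(rows))
  assertThat(length(len) == 1L, "sequences must be aligned (equal length)")
  if (!is.null(columns)) rows <- lapply(rows, `[`, columns)
  clean <- Reduce(`&`, lapply(rows, function(r) r %in% DNA_BASES4))
  nExcluded <- sum(!clean)
  rows <- lapply(rows, `[`, clean)
  n <- sum(clean)
  if (n == 0L) {
    out <- list(counts = integer(0), nSites = 0L, nDiff = 0L,
                nExcluded = nExcluded, nSeq = length(rows))
    class(out) <- "sitePatterns"
    return(out)
  }
  pat <- do.call(paste0, rows)
  counts <- table(pat)
  same <- vapply(names(counts), function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    all(ch == ch[1])
  }, TRUE)
  out <- list(counts = structure(as.integer(counts), names = names(counts)),
              nSites = n, nDiff = as.integer(sum(counts[!same])),
              nExcluded = nExcluded, nSeq = length(rows))
  class(out) <- "sitePatterns"
  out
}

## One-off index of an alignment for repeated per-region pattern counting:
## char vectors per row, genomic-position -> column lookup (reference =
## mouse row), and a no-gap/no-ambiguity column mask.
alignIndex <- function(aln, species = c("mouse", "rat")) {
  chars <- lapply(aln@seqs[species], function(s)
    strsplit(toupper(s), "", fixed = TRUE)[[1]])
  notGap <- chars[["mouse"]] != "-"
  colPos <- aln@start - 1L + cumsum(notGap)
  posToCol <- integer(max(colPos))
  posToCol[colPos[notGap]] <- which(notGap)
  clean <- Reduce(`&`, lapply(chars, function(r) r %in% DNA_BASES4))
  list(chars = chars, posToCol = posToCol, clean = clean)
}

## sitePatterns of the given genomic positions, using a prebuilt alignIndex
patternsAt <- function(ai, positions) {
  positions <- positions[positions >= 1L & positions <= length(ai$posToCol)]
  cols <- ai$posToCol[positions]
  cols <- cols[cols > 0L]
  nFound <- length(cols)
  cols <- cols[ai$clean[cols]]
  n <- length(cols)
  if (n == 0L) {
    out <- list(counts = integer(0), nSites = 0L, nDiff = 0L,
                nExcluded = nFound, nSeq = length(ai$chars))
    class(out) <- "sitePatterns"
    return(out)
  }
  pat <- do.call(paste0, lapply(ai$chars, `[`, cols))
  counts <- table(pat)
  same <- vapply(names(counts), function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    all(ch == ch[1])
  }, TRUE)
  out <- list(counts = structure(as.integer(counts), names = names(counts)),
              nSites = n, nDiff = as.integer(sum(counts[!same])),
              nExcluded = nFound - n, nSeq = length(ai$chars))
  class(out) <- "sitePatterns"
  out
}

## empirical base frequencies averaged over all rows of a pattern set
empiricalFreqs <- function(patterns) {
  f <- numeric(4); names(f) <- DNA_BASES4
  for (i in seq_along(patterns$counts)) {
    ch <- strsplit(names(patterns$counts)[i], "", fixed = TRUE)[[1]]
    for (b in ch) f[b] <- f[b] + patterns$counts[i]
  }
  f <- pmax(f / sum(f), 1e-6)
  f / sum(f)
}

## decoded patterns as an integer matrix (nPattern x nSeq) + counts
decodePatterns <- function(patterns) {
  m <- t(vapply(names(patterns$counts), function(p)
    match(strsplit(p, "", fixed = TRUE)[[1]], DNA_BASES4),
    integer(patterns$nSeq)))
  list(idx = m, counts = as.numeric(patterns$counts))
}

## negative log-likelihood of pairwise patterns at distance t
pairNLL <- function(t, exch, pi, alpha, K, dec) {
  r <- gammaCategoryRates(alpha, K)
  Q <- gtrGenerator(exch, pi)
  pf <- transitionFunction(Q, pi)
  lik <- 0
  for (k in seq_len(K)) {
    P <- pf(t * r[k])
    lik <- lik + (pi[dec$idx[, 1]] * P[cbind(dec$idx[, 1], dec$idx[, 2])]) / K
  }
  -sum(dec$counts * log(pmax(lik, 1e-300)))
}

## negative log-likelihood of three-taxon patterns (mouse, rat, human) given
## branch lengths tv = c(tm, tr, th) from the mouse-rat ancestor
tripleNLL <- function(tv, exch, pi, alpha, K, dec) {
  r <- gammaCategoryRates(alpha, K)
  Q <- gtrGenerator(exch, pi)
  pf <- transitionFunction(Q, pi)
  lik <- 0
  for (k in seq_len(K)) {
    Pm <- pf(tv[1] * r[k]); Pr <- pf(tv[2] * r[k]); Ph <- pf(tv[3] * r[k])
    contrib <- 0
    for (a in 1:4) {
      contrib <- contrib + pi[a] * Pm[a, dec$idx[, 1]] *
        Pr[a, dec$idx[, 2]] * Ph[a, dec$idx[, 3]]
    }
    lik <- lik + contrib / K
  }
  -sum(dec$counts * log(pmax(lik, 1e-300)))
}

FIT_STARTS <- c(0.05, 0.2, 1.0)  # fixed multi-start distances

#' Fit a pairwise GTR + discrete-gamma distance by maximum likelihood
#'
#' Maximizes the likelihood of the observed site patterns over the distance
#' \code{t}, five free exchangeabilities (GT fixed at 1) and the gamma shape
#' \eqn{\alpha}, with base frequencies fixed at their empirical means over
#' both sequences.  Optimization is bounded quasi-Newton (L-BFGS-B) on
#' log-transformed parameters, \code{t} in \[0, 10\] and \eqn{\alpha} in
#' \[0.05, 50\], restarted from three fixed starting distances; the result is
#' deterministic given the input.  With \code{fixModel}, exchangeabilities,
#' frequencies and shape are held at the supplied values and only \code{t}
#' is optimized (used for small regions, where the shared model is fitted
#' once on pooled neutral sites).
#'
#' @param patterns a \code{sitePatterns} object from
#'   \code{\link{countSitePatterns}} (two sequences).
#' @param nCategories number of discrete gamma categories (default 5); 1
#'   disables rate heterogeneity (no \eqn{\alpha} is fitted).
#' @param fixModel optional \linkS4class{SubstitutionModel} to hold fixed.
#' @param computeSE whether to compute a curvature-based standard error of
#'   \code{t} (numeric second derivative of the profile log-likelihood).
#' @return a \linkS4class{DivergenceEstimate}.
#' @examples
#' sp <- countSitePatterns(c(mouse = strrep("ACGT", 25),
#'                           rat   = strrep("ACGT", 25)))
#' substDistance(fitPairwise(sp))  # identical sequences: 0
#' @export
fitPairwise <- function(patterns, nCategories = 5L, fixModel = NULL,
                        computeSE = TRUE) {
  if (patterns$nSites == 0L)
    stop("no usable sites: all columns were gapped or ambiguous", call. = FALSE)
  assertThat(patterns$nSeq == 2L, "fitPairwise needs two-sequence patterns")
  dec <- decodePatterns(patterns)
  if (patterns$nDiff == 0L) {
    model <- fixModel %||% substitutionModel(baseFreqs = empiricalFreqs(patterns),
                                             nCategories = as.integer(nCategories))
    return(new("DivergenceEstimate", distance = 0, se = 0, model = model,
               nSites = patterns$nSites, nDiff = 0L, converged = TRUE,
               logLik = -pairNLL(0, model@exchangeabilities, model@baseFreqs,
                                 model@gammaShape, model@nCategories, dec)))
  }
  if (!is.null(fixModel)) {
    K <- fixModel@nCategories
    nll <- function(t) pairNLL(t, fixModel@exchangeabilities,
                               fixModel@baseFreqs, fixModel@gammaShape, K, dec)
    opt <- stats::optimize(nll, c(1e-8, 10), tol = 1e-10)
    t <- opt$minimum
    se <- if (computeSE) curvatureSE(nll, t) else NA_real_
    return(new("DivergenceEstimate", distance = t, se = se, model = fixModel,
               nSites = patterns$nSites, nDiff = patterns$nDiff,
               converged = TRUE, logLik = -opt$objective))
  }
  K <- as.integer(nCategories)
  pi <- empiricalFreqs(patterns)
  useAlpha <- K > 1L
  ## theta = (log t, log exch[1:5], [log alpha])
  nllTheta <- function(theta) {
    t <- exp(theta[1])
    exch <- c(exp(theta[2:6]), 1)
    alpha <- if (useAlpha) exp(theta[7]) else 1
    pairNLL(t, exch, pi, alpha, K, dec)
  }
  lower <- c(log(1e-7), rep(log(1e-3), 5), if (useAlpha) log(0.05))
  upper <- c(log(10), rep(log(1e3), 5), if (useAlpha) log(50))
  best <- NULL
  for (t0 in FIT_STARTS) {
    theta0 <- c(log(t0), rep(0, 5), if (useAlpha) 0)
    fit <- tryCatch(
      stats::optim(theta0, nllTheta, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-12))
      best <- fit
  }
  assertThat(!is.null(best), "pairwise fit failed from all starting points")
  t <- exp(best$par[1])
  model <- substitutionModel(
    exchangeabilities = c(exp(best$par[2:6]), 1),
    baseFreqs = pi,
    gammaShape = if (useAlpha) exp(best$par[7]) else 1,
    nCategories = K)
  se <- NA_real_; alphaSE <- NA_real_
  if (computeSE) {
    ses <- jointSE(nllTheta, best$par,
                   idx = c(1L, if (useAlpha) 7L))
    se <- ses[1]
    if (useAlpha) alphaSE <- ses[2]
    if (!is.finite(se)) { # fall back to profile curvature
      nllT <- function(tt) pairNLL(tt, model@exchangeabilities, pi,
                                   model@gammaShape, K, dec)
      se <- curvatureSE(nllT, t)
    }
  }
  new("DivergenceEstimate", distance = t, se = se, alphaSE = alphaSE,
      model = model, nSites = patterns$nSites, nDiff = patterns$nDiff,
      converged = best$convergence == 0, logLik = -best$value)
}

## standard error from the numeric curvature of a 1-D negative log-likelihood
curvatureSE <- function(nll, t) {
  h <- max(1e-5, 1e-4 * t)
  d2 <- (nll(t + h) - 2 * nll(t) + nll(max(t - h, 1e-9))) / h^2
  if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
}

## central-difference Hessian of f at theta
numericHessian <- function(f, theta) {
  p <- length(theta)
  h <- 1e-4 * (1 + abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) for (j in i:p) {
    ei <- ej <- rep(0, p); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

## joint delta-method SEs (on the natural scale) for log-transformed
## parameters idx of a negative log-likelihood; returns NA on a singular or
## non-positive-definite information matrix.
jointSE <- function(nllTheta, theta, idx) {
  H <- numericHessian(nllTheta, theta)
  V <- tryCatch(solve(H), error = function(e) NULL)
  vapply(idx, function(i) {
    if (is.null(V) || !is.finite(V[i, i]) || V[i, i] <= 0) NA_real_
    else exp(theta[i]) * sqrt(V[i, i])   # d exp(x)/dx = exp(x)
  }, 0)
}

#' Fit branch lengths on the unrooted three-taxon tree
#'
#' Maximum likelihood over the mouse, rat and human branch lengths (measured
#' from the mouse-rat ancestor) and a shared GTR + discrete-gamma model, by
#' summation over the ancestral state (Felsenstein pruning on the 3-taxon
#' star).  \code{mouseRatDistance} of the result is the mouse+rat branch sum
#' used for D/d-style ratios.
#'
#' @param patterns \code{sitePatterns} over rows (mouse, rat, human).
#' @inheritParams fitPairwise
#' @return a \linkS4class{TripleEstimate}.
#' @export
fitTriple <- function(patterns, nCategories = 5L, fixModel = NULL) {
  if (patterns$nSites == 0L)
    stop("no usable sites: all columns were gapped or ambiguous", call. = FALSE)
  assertThat(patterns$nSeq == 3L, "fitTriple needs three-sequence patterns")
  dec <- decodePatterns(patterns)
  if (patterns$nDiff == 0L) {
    model <- fixModel %||% substitutionModel(baseFreqs = empiricalFreqs(patterns),
                                             nCategories = as.integer(nCategories))
    return(new("TripleEstimate",
               branchLengths = c(mouse = 0, rat = 0, human = 0),
               model = model, nSites = patterns$nSites, nDiff = 0L,
               converged = TRUE,
               logLik = -tripleNLL(c(0, 0, 0), model@exchangeabilities,
                                   model@baseFreqs, model@gammaShape,
                                   model@nCategories, dec)))
  }
  fixed <- !is.null(fixModel)
  K <- if (fixed) fixModel@nCategories else as.integer(nCategories)
  pi <- if (fixed) fixModel@baseFreqs else empiricalFreqs(patterns)
  useAlpha <- !fixed && K > 1L
  nFree <- if (fixed) 3L else 3L + 5L + as.integer(useAlpha)
  nllTheta <- function(theta) {
    tv <- exp(theta[1:3])
    exch <- if (fixed) fixModel@exchangeabilities else c(exp(theta[4:8]), 1)
    alpha <- if (fixed) fixModel@gammaShape
             else if (useAlpha) exp(theta[9]) else 1
    tripleNLL(tv, exch, pi, alpha, K, dec)
  }
  lower <- c(rep(log(1e-7), 3), if (!fixed) rep(log(1e-3), 5),
             if (useAlpha) log(0.05))
  upper <- c(rep(log(10), 3), if (!fixed) rep(log(1e3), 5),
             if (useAlpha) log(50))
  best <- NULL
  for (t0 in FIT_STARTS) {
    theta0 <- c(rep(log(t0 / 2), 2), log(t0), if (!fixed) rep(0, 5),
                if (useAlpha) 0)
    fit <- tryCatch(
      stats::optim(theta0, nllTheta, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-12))
      best <- fit
  }
  assertThat(!is.null(best), "triple fit failed from all starting points")
  model <- if (fixed) fixModel else substitutionModel(
    exchangeabilities = c(exp(best$par[4:8]), 1), baseFreqs = pi,
    gammaShape = if (useAlpha) exp(best$par[9]) else 1, nCategories = K)
  new("TripleEstimate",
      branchLengths = structure(exp(best$par[1:3]),
                                names = c("mouse", "rat", "human")),
      model = model, nSites = patterns$nSites, nDiff = patterns$nDiff,
      converged = best$convergence == 0, logLik = -best$value)
}

#' Divergence of one region or site mask
#'
#' Projects the region span (or mask positions) onto the alignment,
#' concatenates all usable columns and fits the distance once.
#'
#' @param positions integer vector of 1-based mouse genomic positions, or a
#'   \code{GRanges} of length 1, or a \linkS4class{SiteMask}.
#' @param aln a \linkS4class{TripleAlignment}.
#' @param mode \code{"pairwise"} (mouse-rat) or \code{"triple"}.
#' @param nCategories,fixModel passed to the fitter.
#' @return a \linkS4class{DivergenceEstimate} or
#'   \linkS4class{TripleEstimate}; \code{NULL} when the region projects to
#'   zero usable columns.
#' @export
regionDivergence <- function(positions, aln, mode = c("pairwise", "triple"),
                             nCategories = 5L, fixModel = NULL) {
  mode <- match.arg(mode)
  if (is(positions, "SiteMask")) positions <- maskPositions(positions)
  if (is(positions, "GRanges"))
    positions <- GenomicRanges::start(positions):GenomicRanges::end(positions)
  species <- if (mode == "pairwise") c("mouse", "rat")
             else c("mouse", "rat", "human")
  cols <- projectMask(positions, aln, species = species)
  if (length(cols) == 0L) return(NULL)
  patterns <- countSitePatterns(aln, columns = cols, species = species)
  if (patterns$nSites == 0L) return(NULL)
  if (mode == "pairwise")
    fitPairwise(patterns, nCategories = nCategories, fixModel = fixModel)
  else fitTriple(patterns, nCategories = nCategories, fixModel = fixModel)
}

#' Per-region divergence table for enhancers and their neutral references
#'
#' Fits D for every region, and d4 / di for every distinct gene appearing as
#' a neutral reference.  A shared substitution model (exchangeabilities,
#' frequencies, gamma shape) is first fitted on the pooled fourfold sites of
#' all reference genes; units with fewer than \code{smallUnit} usable sites
#' re-use that model and optimize only \code{t}.
#'
#' @param regions annotated \code{GRanges} from \code{\link{annotateRegions}}
#'   (needs \code{region_id}, \code{neutral_reference_gene_id}).
#' @param masks result of \code{\link{geneSiteMasks}}.
#' @param aln a \linkS4class{TripleAlignment}.
#' @param nCategories gamma categories (default 5).
#' @param smallUnit units with fewer usable sites than this re-use the
#'   pooled model (default 200; set to \code{Inf} to share the model
#'   everywhere).
#' @return list with \code{table} (data.frame: \code{unit_id}, \code{kind}
#'   (enhancer/fourfold/intron), \code{t}, \code{n_sites}, \code{n_diff},
#'   \code{alpha}, \code{converged}, \code{log_lik}), \code{pooledModel} and
#'   \code{skipped} (data.frame of unit id / reason).
#' @export
divergenceTable <- function(regions, masks, aln, nCategories = 5L,
                            smallUnit = 200L) {
  refGenes <- unique(stats::na.omit(regions$neutral_reference_gene_id))
  ai <- alignIndex(aln, c("mouse", "rat"))
  ## pooled neutral model from all fourfold sites of the reference genes.
  ## The gamma shape is nearly unidentified from a single pairwise
  ## comparison (a flat ridge trades alpha against t), so the shared model
  ## is fitted with the three-taxon likelihood whenever an outgroup row is
  ## present; the outgroup branch resolves the ridge.
  pooledPos <- sort(unique(unlist(lapply(refGenes, function(g) {
    m <- masks$fourfold[[g]]
    if (is.null(m)) integer(0) else maskPositions(m)
  }), use.names = FALSE)))
  assertThat(length(pooledPos) > 0L,
             "no fourfold sites available to fit the pooled neutral model")
  pooledModel <- if ("human" %in% names(aln@seqs)) {
    ai3 <- alignIndex(aln, c("mouse", "rat", "human"))
    fittedModel(fitTriple(patternsAt(ai3, pooledPos),
                          nCategories = nCategories))
  } else {
    fittedModel(fitPairwise(patternsAt(ai, pooledPos),
                            nCategories = nCategories, computeSE = FALSE))
  }

  rows <- list(); skipped <- list()
  fitUnit <- function(id, kind, positions) {
    patterns <- patternsAt(ai, positions)
    if (patterns$nSites == 0L) {
      skipped[[length(skipped) + 1L]] <<- data.frame(unit_id = id, kind = kind,
                                                     reason = "no_usable_sites")
      return(invisible(NULL))
    }
    est <- if (patterns$nSites < smallUnit)
      fitPairwise(patterns, fixModel = pooledModel, computeSE = FALSE)
    else fitPairwise(patterns, nCategories = nCategories, computeSE = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      unit_id = id, kind = kind, t = substDistance(est),
      n_sites = nSites(est), n_diff = nDiff(est),
      alpha = fittedModel(est)@gammaShape, converged = isConverged(est),
      log_lik = logLik(est))
    invisible(NULL)
  }
  for (i in seq_along(regions)) {
    fitUnit(regions$region_id[i], "enhancer",
            GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i])
  }
  for (g in refGenes) {
    if (!is.null(masks$fourfold[[g]]))
      fitUnit(g, "fourfold", maskPositions(masks$fourfold[[g]]))
    m <- masks$intron[[g]]
    if (!is.null(m) && length(maskPositions(m)) > 0L)
      fitUnit(g, "intron", maskPositions(m))
  }
  list(table = do.call(rbind, rows),
       pooledModel = pooledModel,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(unit_id = character(0), kind = character(0),
                                 reason = character(0)))
}
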