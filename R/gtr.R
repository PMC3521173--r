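## GTR + discrete-gamma machinery.
##
## Base order is A, C, G, T throughout; exchangeabilities are ordered
## (AC, AG, AT, CG, CT, GT).  The generator is always scaled so that one unit
## of branch length equals one expected substitution per site at rate 1.

#' Construct a GTR + discrete-gamma substitution model
#'
#' The general time-reversible model is parameterized by six symmetric
#' exchangeabilities (order AC, AG, AT, CG, CT, GT), four stationary base
#' frequencies (order A, C, G, T) and a gamma shape \eqn{\alpha} controlling
#' among-site rate variation, discretized into \code{nCategories}
#' equal-probability categories represented by their means (mean relative
#' rate is 1).  \code{nCategories = 1} disables rate heterogeneity.
#'
#' @param exchangeabilities numeric(6), nonnegative; scale is arbitrary
#'   (GT is conventionally 1).
#' @param baseFreqs numeric(4) summing to 1.
#' @param gammaShape positive shape \eqn{\alpha}; ignored when
#'   \code{nCategories == 1}.
#' @param nCategories integer >= 1, number of discrete gamma categories.
#' @return A \linkS4class{SubstitutionModel} object.
#' @examples
#' m <- substitutionModel()              # Jukes-Cantor-like defaults
#' gammaCategoryRates(m)
#' @export
substitutionModel <- function(exchangeabilities = rep(1, 6),
                              baseFreqs = rep(0.25, 4),
                              gammaShape = 1,
                              nCategories = 5L) {
  new("SubstitutionModel",
      exchangeabilities = as.numeric(exchangeabilities),
      baseFreqs = as.numeric(baseFreqs),
      gammaShape = as.numeric(gammaShape),
      nCategories = as.integer(nCategories))
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Categories are the K equal-probability quantile bins of a Gamma(shape =
#' \eqn{\alpha}, rate = \eqn{\alpha}) distribution (mean 1); each category is
#' represented by its conditional mean, and the rates are renormalized so
#' their average is exactly 1.
#'
#' @param alpha positive gamma shape.
#' @param k number of categories.
#' @return numeric(k) of mean relative rates.
#' @export
gammaCategoryRates <- function(alpha, k = 5L) {
  k <- as.integer(k)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  ## E[X ; a < X <= b] for X ~ Gamma(alpha, alpha) equals
  ## pgamma(b, alpha+1, alpha) - pgamma(a, alpha+1, alpha)  (mean 1)
  up <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(up)
  r / mean(r)
}

## Category rates of a fitted/configured model object.
modelCategoryRates <- function(model) {
  gammaCategoryRates(model@gammaShape, model@nCategories)
}

## Unscaled GTR generator: Q[i,j] = s_ij * pi_j (i != j).
gtrGeneratorRaw <- function(exch, pi) {
  S <- matrix(0, 4, 4, dimnames = list(DNA_BASES4, DNA_BASES4))
  S[1, 2] <- S[2, 1] <- exch[1] # AC
  S[1, 3] <- S[3, 1] <- exch[2] # AG
  S[1, 4] <- S[4, 1] <- exch[3] # AT
  S[2, 3] <- S[3, 2] <- exch[4] # CG
  S[2, 4] <- S[4, 2] <- exch[5] # CT
  S[3, 4] <- S[4, 3] <- exch[6] # GT
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(DNA_BASES4, DNA_BASES4)
  Q
}

#' GTR generator matrix scaled to one substitution per site per unit time
#'
#' @param exch numeric(6) exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param pi numeric(4) base frequencies (A, C, G, T).
#' @param gcBias nonnegative GC-fixation bias: rates into G or C are
#'   multiplied by \code{1 + gcBias} before rescaling (0 = unbiased).  The
#'   matrix is rescaled so the expected rate under \code{pi} is 1.
#' @return 4x4 generator with rows summing to zero.
#' @keywords internal
gtrGenerator <- function(exch, pi, gcBias = 0) {
  Q <- gtrGeneratorRaw(exch, pi)
  if (gcBias > 0) {
    diag(Q) <- 0
    Q[, c("C", "G")] <- Q[, c("C", "G")] * (1 + gcBias)
    diag(Q) <- -rowSums(Q)
  }
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## Eigendecomposition of a reversible generator via symmetrization; returns a
## closure evaluating P(t) cheaply for many t.  Falls back to a dense
## eigen of the (possibly non-reversible, e.g. GC-biased) generator.
transitionFunction <- function(Q, pi = NULL, reversible = TRUE) {
  if (reversible && !is.null(pi) && all(pi > 0)) {
    d <- sqrt(pi)
    B <- diag(d) %*% Q %*% diag(1 / d)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    V <- diag(1 / d) %*% e$vectors
    Vi <- t(e$vectors) %*% diag(d)
  } else {
    e <- eigen(Q)
    V <- e$vectors
    Vi <- solve(V)
  }
  lam <- e$values
  function(t) {
    P <- Re(V %*% (exp(lam * t) * Vi))
    P[P < 0] <- 0
    P <- P / rowSums(P)
    dimnames(P) <- list(DNA_BASES4, DNA_BASES4)
    P
  }
}

#' Transition probability matrix P(t) under a GTR generator
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param t branch length in expected substitutions per site (at relative
#'   rate 1).
#' @param gcBias optional GC-fixation bias passed to \code{\link{gtrGenerator}}.
#' @return 4x4 stochastic matrix over bases A, C, G, T.
#' @export
transitionMatrix <- function(model, t, gcBias = 0) {
  Q <- gtrGenerator(model@exchangeabilities, model@baseFreqs, gcBias)
  transitionFunction(Q, model@baseFreqs, reversible = gcBias == 0)(t)
}

## Closed-form Jukes-Cantor distance from a mismatch proportion.
jcDistance <- function(p) {
  ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
}
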