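# Shared fixtures and independent oracles, built in code.

# small simulated study reused by several test files
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(seed = 101, nGenes = 12,
                              nEnhancersPerTissue = c(FB = 6, MB = 6,
                                                      LB = 6, HT = 6),
                              chromLength = 500000L)
      cache <<- simulateStudy(cfg)
    }
    cache
  }
})

# brute-force transitive-closure merge of intervals (oracle for
# consolidateEnhancers): repeatedly merge any overlapping pair
oracleMerge <- function(start, end) {
  n <- length(start)
  merged <- TRUE
  while (merged && length(start) > 1) {
    merged <- FALSE
    for (i in seq_along(start)) {
      for (j in seq_along(start)) {
        if (i >= j) next
        if (start[i] <= end[j] && start[j] <= end[i]) { # >= 1 bp shared
          start[i] <- min(start[i], start[j])
          end[i] <- max(end[i], end[j])
          start <- start[-j]; end <- end[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  ord <- order(start)
  list(start = start[ord], end = end[ord])
}

# exhaustive-scan nearest gene oracle: boundary (gap) distance with
# deterministic tie-breaking (distance, gene start, gene id)
oracleNearest <- function(rs, re, gs, ge, gid) {
  d <- ifelse(ge < rs, rs - ge - 1, ifelse(re < gs, gs - re - 1, 0))
  ord <- order(d, gs, gid)
  gid[ord][1]
}

# lchoose-based two-sided Fisher p oracle (independent of dhyper)
oracleFisherP <- function(a, b, c, d) {
  # table [a, b; c, d]; margins fixed
  m <- a + c; n1 <- a + b; n2 <- c + d
  lo <- max(0, m - n2); hi <- min(m, n1)
  logp <- function(k) lchoose(n1, k) + lchoose(n2, m - k) - lchoose(n1 + n2, m)
  ps <- exp(vapply(lo:hi, logp, 0))
  pObs <- exp(logp(a))
  min(1, sum(ps[ps <= pObs * (1 + 1e-7)]))
}

# per-codon brute-force fourfold synonymy test over the standard code
oracleFourfoldCodon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (grepl("[^ACGT]", codon)) return(FALSE)
  aa <- gc[[codon]]
  variants <- paste0(substr(codon, 1, 2), c("A", "C", "G", "T"))
  all(vapply(variants, function(v) gc[[v]] == aa, TRUE))
}

# random valid coding sequence (with possible stop-free interior)
randomCds <- function(nCodons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, nCodons - 1, replace = TRUE)), collapse = "")
}
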