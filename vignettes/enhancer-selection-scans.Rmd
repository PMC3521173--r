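---
title: "Testing natural selection on embryonic enhancers with local neutral references"
author: "enhSelScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing natural selection on embryonic enhancers with local neutral references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhSelScan)
```

## The question and the model

Enhancers marked by p300 binding in embryonic mouse tissues (forebrain,
midbrain, limb, heart) evolve at visibly different rates.  A raised
substitution rate can reflect either a locally elevated mutation rate or a
changed regime of natural selection.  The two are separable with a *local
neutral reference*: sites close to the enhancer that experience the same
mutational environment but (to a good approximation) no selective
constraint.  This package uses two such references from the nearest gene
with a one-to-one ortholog in the comparison species:

* **d4** — the substitution rate at fourfold-degenerate third codon
  positions (codon families GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN), and
* **di** — the substitution rate in introns of the same gene, with the
  first intron removed because first introns are enriched for regulatory
  motifs.  Intronless and single-intron genes therefore have only the d4
  reference.

The enhancer divergence **D** and the neutral divergences d4 and di are
maximum-likelihood distances under a general time-reversible (GTR)
substitution model with discrete-gamma rate heterogeneity (5
equal-probability categories represented by their means).  The ratio D/d4
(or D/di) indexes the net selective pressure: values below 1 indicate
purifying constraint, values above 1 accelerated evolution.

Two further analyses mirror the study design this package operationalizes:

* a per-enhancer **Fisher's exact test** on the 2×2 table (enhancer vs
  neutral reference) × (substituted vs unsubstituted sites), classifying
  each enhancer as *positive*, *purifying* or *neutral* at α = 0.05;
* a **GC-biased gene conversion (gBGC) diagnostic** that polarizes
  mouse-lineage substitutions at ancestrally A/T sites (rat and human must
  agree on an A or T) and asks whether A/T→G/C changes are enriched —
  gBGC can mimic positive selection, so the diagnostic guards the
  interpretation.

Covariate analyses (pleiotropy of the enhancer, essentiality and expression
of the adjacent gene, expression-bin-controlled tissue contrasts) use
rank-based statistics throughout: Mann–Whitney U for group contrasts,
Spearman's rank correlation for continuous covariates.

## The estimator

`fitPairwise()` maximizes the likelihood of the observed site-pattern
counts over the distance *t*, five free exchangeabilities (GT fixed at 1)
and the gamma shape α, with base frequencies fixed at their empirical means
over both sequences — fixing frequencies stabilizes fits on small regions
and mirrors common practice of estimating frequencies from the data.
Optimization is bounded L-BFGS-B on log-transformed parameters (*t* ∈ [0,
10], α ∈ [0.05, 50]) restarted from three fixed starting distances (0.05,
0.2, 1.0), so results are deterministic.  Columns containing a gap or an
ambiguity code in any species are excluded (complete-case).  Identical
sequences return *t* = 0 without optimization.  Convergence is flagged,
never silently dropped; the tolerance is the optimizer's `factr = 1e4`
(about 1e-12 relative on the log-likelihood).

`fitTriple()` fits the three branch lengths of the unrooted
mouse/rat/human star by summation over the ancestral state (Felsenstein
pruning), sharing one substitution model; `mouseRatDistance()` is the
mouse+rat branch sum used for D/d ratios with an outgroup.

Two behaviours matter for small regions:

* **Pooled fallback.** Units with fewer than 200 usable sites (the
  `smallUnit` threshold, configurable) re-use exchangeabilities and α
  fitted once on the pooled fourfold sites of all reference genes, and
  optimize only *t*.  Setting `smallUnit = Inf` applies the shared model
  everywhere — the fast batch mode used for large simulated scans, where
  per-region model fits add noise without adding information.
* **Weak identifiability of α in pairwise fits.** A single pairwise
  comparison leaves the likelihood nearly flat along a ridge that trades
  the distance against the gamma shape: on analytically exact expected
  counts generated at (t = 0.2, α = 2), the point (t ≈ 0.209, α ≈ 1.15)
  has an indistinguishable likelihood.  Consequently pairwise α̂ drifts
  along this ridge, and the joint information-based standard error
  reported by `gammaShapeSE()` is honestly large.  The three-taxon fit
  does not have this problem — the outgroup branch resolves the ridge —
  so the pooled shared model is fitted with the triple likelihood
  whenever the alignment carries a human row, and α-sensitive validation
  uses `fitTriple()`.

Uncertainty in the reported distance uses the joint observed-information
matrix over all free parameters (delta method on the log scale), falling
back to the 1-D curvature when the information matrix is singular.

## The Fisher classification

"Substituted sites" are observed mismatching columns (`n_diff` from pattern
counting), not model-inferred substitution counts: the 2×2 construction
with "sites with no substitution" is only coherent with per-site observed
states.  The two-sided p-value is the exact sum of hypergeometric point
probabilities not exceeding the observed one (relative tie tolerance
1 + 1e-7, the standard convention); no continuity or large-sample
approximation is used.  Both test directions are interpreted, hence
two-sided.  No multiple-testing correction drives the calls — matching the
per-enhancer α = 0.05 design — but a Benjamini–Hochberg q-value column is
emitted for transparency.  Enhancers whose neutral reference has zero
usable sites or zero divergence are *untestable* and excluded from the
Total, with machine-readable reasons in the exclusion log.

Summary tables report, per tissue, Total / Under selection / Positively
selected and the three ratios.  Percentages are **truncated** (not rounded)
at the second decimal — the convention under which every printed percentage
of the published proportion tables reproduces exactly (e.g. 875/2554 →
34.25%, 360/2554 → 14.09%).

## The gBGC polarization rule

A site is ancestrally A/T when rat and human carry the *same* base and it
is A or T; a rat = A / human = T column leaves the ancestor ambiguous and
is not counted (`not_ancestral_AT`).  The looser reading — both in {A, T},
ancestor taken from rat — is available behind `loose = TRUE`.  Parsimony
is used rather than probabilistic ancestral reconstruction, matching the
verbal rule being implemented, and multiple hits are ignored (a site
counts once whatever its event history).  Per region, `polarityCounts()`
reports N substituted A/T, N A/T→G/C and their ratio; tissue-level
contrasts use the rank-sum test at the usual significance thresholds.

## The synthetic-data generator

`simulationConfig()` defines a complete study; `simulateStudy()` runs it.
One chromosome carries non-overlapping genes (exon/intron/CDS structure,
optional shorter second isoform, ortholog flags, knockout-phenotype terms,
61 per-tissue expression signals) and tissue-labelled enhancers placed in
gene flanks.  Sequences evolve from a drawn ancestor along the
((mouse, rat), human) tree under GTR + discrete gamma; the simulator and
the estimator share the same equal-probability category-mean
discretization by design, so estimator validation is not confounded by
discretization mismatch.

Ground-truth selection enters as per-region rate multipliers: each
enhancer draws a class (neutral / purifying / positive, default
multipliers 1 / 0.5 / 2) from configurable proportions, optionally
per-tissue.  The default class mix (20% neutral, 70% purifying, 10%
positive) reflects the empirical finding that most tested enhancers are
constrained.  Coding sequence evolves with first and second codon
positions at a purifying multiplier (default 0.1) while third positions
are neutral; codons that nonetheless become stops on a branch are reverted
to their ancestral state, modelling selection against nonsense mutations.
Because stop-gaining changes cannot occur at fourfold-family third
positions, this repair never biases d4.  Genes that still end up with
internal stops are dropped by the fourfold caller with a logged reason, so
the dropout path stays exercised.

The default conditions are rodent-like: mouse and rat branches of 0.09 and
0.10 substitutions/site (≈0.19 on the mouse–rat path, the magnitude of
neutral mouse–rat divergence), a primate-distance outgroup at 0.35,
transition-biased exchangeabilities (AG = CT = 4), mouse-like base
frequencies (A = T = 0.29), α = 1 with 5 categories.  Expression signals
are log-normal around a per-gene mean (meanlog = log 250, sdlog = 0.8),
chosen so the <200 / 200–400 / ≥400 bins are all populated; 30% of genes
with a documented phenotype are essential, and 10% of genes have no
documented null phenotype at all.  A configurable fraction of enhancers is
deliberately placed overlapping an enhancer of another tissue (inheriting
its class) so consolidation is exercised; overlapping placements share one
selection class, keeping region-level truth well defined.

An optional **GC-fixation bias** multiplies all rates into G or C by
1 + `gcFixationBias` (rescaled so the expected total rate stays 1, using
the unbiased stationary frequencies).  This component exists purely as
test scaffolding for the gBGC diagnostics — the study being mirrored
measures gBGC, it does not simulate it — and is off (0) by default.

Randomness: one seed governs the run; each stage (gene structures,
orthologs, covariates, enhancer placement, recombination map, evolution)
draws from a deterministic sub-stream, so adding a later stage never
reshuffles an earlier one.  Identical configurations give byte-identical
outputs.

What the generator does *not* emulate: indels inside alignments (gap
injection is a simple masking overlay, off by default), CpG
context-dependent substitution, chromatin or read-level signal, gene
conversion tracts, and demography.  Passing tests therefore demonstrate
correctness of the inference machinery under the stated model, not
robustness to alignment error or context effects in real genomes.

## Interval, covariate and reporting conventions

* Overlap means ≥ 1 shared bp in half-open terms; bookended intervals are
  not merged — the literal reading of "overlapping coordinates".
* Nearest-gene distance is boundary-to-boundary (0 when overlapping),
  strand-ignored; ties break by distance, then lower gene start, then
  lexicographic id.  The gene providing the neutral reference is assigned
  separately (restricted to one-to-one-ortholog genes) and may differ from
  the plain nearest gene.
* Recombination rates attach by the window containing the region midpoint.
* "Longest isoform" is the isoform with the greatest summed exon length
  (ties: longest CDS, then id).  Fourfold degeneracy is judged on the
  mouse codon only; UTR sequence never enters a mask; the annotated CDS
  excludes the stop codon.
* Expression bins are [0, 200), [200, 400), [400, ∞): the boundary 200
  belongs to the middle bin, 400 to the top bin.
* Spearman p-values are exact (exhaustive permutation, average ranks for
  ties) for n ≤ 10 and t-approximated above; the 11–30 band, unspecified
  in the design, uses the approximation.
* Internally all coordinates are 1-based GRanges; every emitted file uses
  0-based half-open BED convention.  Output percentages truncate to two
  decimals, and undefined ratios print as "-".

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1, nGenes = 30,
                        nEnhancersPerTissue = c(FB = 15, MB = 15,
                                                LB = 15, HT = 15),
                        chromLength = 1500000L)
res <- runPipeline(cfg, "enhscan_out", quiet = TRUE)
reportSummary(res$scanFourfold$summary)
```

The pipeline writes every stage's inputs and outputs (BED, GTF-like, MAF,
TSV) plus `manifest.json` (seed, configuration hash, per-stage counts with
in = out + excluded) and `exclusions.tsv` (one machine-readable reason per
excluded unit) under the output directory.

## Validation strategy and problem sizes

The test suite validates each component against an independent oracle:
brute-force transitive-closure merging for consolidation, exhaustive codon
synonymy over the genetic code for fourfold calling, closed-form
Jukes–Cantor distances and phangorn's GTR+Γ fit for the ML estimator,
exhaustive hypergeometric enumeration for the Fisher p-values, full
permutation enumeration for small-sample Spearman and rank-sum tests, and
the simulator's own event log for polarization.  Calibration experiments
use an all-neutral study of ~1150 consolidated regions on a 13 Mb
chromosome and a three-class study of ~990 regions (about 240–260 testable
per class) with CDS-rich genes (500–900 codons) so each d4 reference has
enough fourfold sites for a stable ratio; estimator recovery uses 50 kb
alignments with three replicates per parameter combination.  These sizes
were chosen to give the comparisons enough statistical resolution while
keeping a full run of the suite practical on a single core.

## Known limitations

* Pairwise α estimates are weakly identified (see above); prefer pooled or
  triple fits when α itself is of interest.
* The parsimony polarization undercounts at sites with multiple hits on
  the outgroup lineages; the strict agreement rule trades a smaller usable
  site set for a cleaner ancestral call.
* The Fisher classification inherits the conservativeness of exact tests
  at small site counts: the realized type-I rate sits below the nominal α.
* Consolidated regions spanning enhancers of different true selection
  classes have no single ground truth; validation restricts to
  single-class regions.
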