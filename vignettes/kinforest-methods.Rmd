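---
title: "Genealogy-aware association analysis: methods and design notes"
author: "kinforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogy-aware association analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinforest)
```

## The problem

Case-control association scans in genetic isolates face a specific
trade-off. On one hand, an isolated population with a recorded genealogy is
an ideal setting for mapping: relatedness between any two subjects is known
exactly, environmental heterogeneity is low, and deleterious variants
segregate at elevated frequency. On the other hand, precisely because
subjects are related, naive scans inherit association signal from shared
ancestry rather than from the disease — stratification noise spread over
hundreds of thousands of variants.

`kinforest` implements a two-part strategy for this setting:

1. **Design**: out of $J$ available controls, select the $I$ controls
   *jointly most related* to the $I$ cases, so that case/control pairs sit
   inside close kin and background genetic variability is differenced out
   before any test is run.
2. **Model**: fit an ensemble of deviance-split classification trees
   (a random forest) to the balanced $2I$-subject sample and rank variants
   by their total contribution to the fit, so that interactions of unknown
   order are captured without being specified in advance.

Single-point Fisher exact scans with multiplicity adjustments
(Benjamini-Hochberg, Storey q-values, local false discovery rate) are
provided as the comparator family, together with a gene-dropping simulation
framework used to validate the whole pipeline.

## Kinship and the assignment design

The kinship coefficient $k_{ij}$ is the probability that one allele drawn
at random from $i$ and one from $j$ are identical by descent. It is computed
from the pedigree by the classical founders-first recursion
($k(j,j) = \frac12(1 + k(f_j, m_j))$;
$k(i,j) = \frac12(k(i,f_j) + k(i,m_j))$ for $i$ preceding $j$ in
topological order), with founders assumed mutually unrelated and non-inbred.
That founder assumption is a genuine modelling choice: the recursion has no
input through which founder kinship could enter, and no estimate of it is
available for a pedigree-only analysis. The recursion is exact; the package
also ships a Monte-Carlo gene-dropping estimator (`mc_kinship_oracle()`)
whose only purpose is to verify the recursion against the *definition* of
kinship — the test suite checks agreement within three standard errors at
$10^6$ drops on every pair of a 20-member, four-generation fixture pedigree
with a double-first-cousin loop.

Given the $I \times J$ case-by-control kinship matrix $K'$, the design step
maximises $\sum_i k_{i,\sigma(i)}$ over injections $\sigma$ of cases into
controls. This is the linear assignment problem, solved exactly by the
Hungarian method (`clue::solve_LSAP`, which handles the rectangular
$I \le J$ case directly). Each control is used at most once; all cases are
used; no caliper or minimum-kinship threshold is applied. The solver is
deterministic — identical inputs give identical matchings — but among
*equally optimal* matchings no particular one (e.g. the lexicographically
smallest) is guaranteed; reproducibility, the reason one would want a tie
rule at all, is already ensured by determinism.

## The forest

The classifier is an ensemble of $M$ trees over categorical predictors
(SNP genotypes with 2–3 levels; categorical covariates may be appended).
Design choices that differ from a stock random forest, and why:

* **Per-tree variable subsampling.** Each tree draws its `mtry` candidate
  variables once, not per node. With 2–3-level predictors and the shallow
  trees a $2I \approx 20$-subject sample admits, per-node sampling would
  barely differ, and the per-tree reading makes *bagging mode* (below)
  exactly "trees differ only by subjects".
* **Stratified half in-bag.** Each tree trains on $\lfloor I/2\rfloor$
  cases plus $\lfloor I/2\rfloor$ controls drawn *without replacement*, so
  both the in-bag and out-of-bag halves stay balanced. The out-of-bag (OOB)
  half provides the honest error estimate $\Lambda$: a subject's prediction
  is the majority vote of only those trees that never saw it (the test suite
  audits this bookkeeping directly from the in-bag matrix).
* **Bernoulli deviance splits.** A split is a binary partition of a
  variable's levels chosen to maximise the decrease in
  $-2\sum [y \log p + (1-y)\log(1-p)]$; with at most 3 levels the partition
  search is exhaustive. Nodes split while they hold at least `min_node = 2`
  subjects and are impure; a split must decrease deviance by more than
  $10^{-12}$ (ties between equal splits go to the first candidate in the
  tree's sampled variable order, which is seed-determined).
* **Importance** $\eta_j$ is the raw summed deviance decrease from all
  splits on variable $j$ across all trees. It is deliberately unnormalised:
  $\eta_j = 0$ then means *exactly* "never used as a split variable", which
  the screening phase relies on. This total-decrease importance is unbiased
  between predictors here only because all predictors have nearly the same
  number of levels; mixing categorical cardinalities (or adding continuous
  covariates) would bias it and is not supported.
* **Prediction** is the mean tree vote; `classify()` calls class 1 when the
  vote fraction strictly exceeds the threshold (default 0.5, the Bayes rule
  under equal priors; exact ties go to class 0 for determinism). The
  threshold is exposed because a disease-prevalence prior may justify
  another cut.
* **Missing/unseen levels** route down the more populous child of each
  split, both in training and prediction; this keeps the 2–3-level split
  structure intact instead of inventing a third branch.
* **Reproducibility.** One master seed spawns an independent splitmix64
  substream per tree, so results do not depend on evaluation order or
  thread count, and doubling $M$ under the same master seed only appends
  trees.

Defaults: $M = 1000$ for interactive fits (the error of these small-$P$,
small-$n$ forests stabilises far earlier; screening and the test suite use
200–500), `mtry` $= \lfloor\sqrt P\rfloor$ for plain fits.

## Screening and backward selection

Linkage disequilibrium makes predictors "clumpily" dependent: many variants
carry a weak echo of a causal site. The selection strategy has two phases.

**Bagging screen** (`bagging_screen()`): run the forest with `mtry`
equal to *all* current variables, so every tree chooses freely among them;
drop every variable with $\eta_j = 0$ (never chosen by any tree); repeat on
the survivors until all have $\eta_j > 0$. The survivor count is
non-increasing by construction and the loop terminates in at most $P$
iterations; survivors are returned ranked by descending final-iteration
$\eta$. (The ranking is re-computed at the final iteration rather than
frozen at the first — the earlier iterations' rankings are contaminated by
the variables about to be dropped.)

**Backward selection** (`backward_select()`): for $k$ from the screened
list size down to 1, refit on the top $k$ variables with
`mtry` $= \lfloor\sqrt k\rfloor$ (restoring tree diversity, which bagging
mode sacrifices) and record $\Lambda_k$. The walk stops once $\Lambda_k$
has exceeded the best value seen by more than one OOB subject's worth of
error ($1/|D_{oob}|$) for 3 consecutive steps — the error curve "starts to
increase" is only observable through OOB noise, so a single bad step must
not end the walk. The reported final set is the smallest $k$ attaining the
minimum *recorded* $\Lambda$, i.e. the smallest model with the lowest
prediction error.

A property worth knowing: with per-tree subsampling, mid-sized models can
show genuinely elevated $\Lambda_k$ (at $k \approx 6$–$8$, `mtry` 2 means
most trees never see the best variable), so on sharply separable toy data
the walk occasionally stops before reaching $k = 1$. This is a real feature
of the per-tree variant, not Monte-Carlo noise — using common random
numbers across $k$ does not remove it — and the patience rule is the
compromise between walking through such stretches and honouring the
"stop when it increases" prescription.

## Single-point comparators

`genome_scan()` tests each variant against status with the two-sided Fisher
exact test (point-probability rule, fixed margins), on the genotypic
$2\times g$ table by default; an allelic $2 \times 2$ collapse is available
for dose-coded genotypes since which table the practitioner wants is
context-dependent. Missing genotypes are dropped per variant; monomorphic
variants are flagged with $p = 1$ rather than silently removed so that
ranks stay aligned across designs. `stats::fisher.test` supplies the exact
enumeration; the test suite checks it against an independent full
enumeration over all tables with the observed margins (grand total
$\le 30$).

Adjustments: standard step-up Benjamini-Hochberg (`stats::p.adjust`);
Storey q-values with $\hat\pi_0$ from a smoothed $\lambda$-grid when
$P \ge 100$ and a fixed $\lambda = 0.5$ below that (exact-test p-values at
these sample sizes concentrate on 0 and 1, where the adaptive grid is
unstable — with four p-values, `mean(p > 0.95)/0.05` is not an estimate of
anything); and a local false discovery rate on the probit scale,
$\widehat{lfdr}(z) = \hat\pi_0\,\phi(z)/\hat f(z)$ with a Gaussian kernel
estimate of $\hat f$ and the *theoretical* standard normal null (the
empirical-null variant needs far more tests than these designs provide).
The lfdr estimate is then monotonised along increasing $p$ (running
maximum). That last step is a deliberate deviation from the raw
empirical-Bayes estimate: all three adjustments are used here as *rankers*
of variants, and the package guarantees — and tests — that none of them
ever reorders variants relative to the raw p-value. p-values of exactly 0
or 1 are clipped into the open interval (with a warning) before the probit
transform.

## The synthetic cohort: what it emulates, and what it cannot

Because the study populations behind this design (small, deeply
consanguineous villages with parish-register genealogies) are not publicly
distributable, validation runs on synthetic cohorts:

* `simulate_pedigree()` grows a multi-generation pedigree in which every
  member of a generation takes a spouse — within the pedigree with
  probability `p_within` (full sibs excluded), otherwise a fresh immigrant
  founder — and couples have Poisson(`mean_offspring`) children. Repeated
  within-pedigree mating yields cousin marriages and hence inbreeding.
  Defaults (25 founders, 4 generations, `p_within = 0.85`,
  `mean_offspring = 3`) produce cohorts of a few hundred with mean pairwise
  kinship around 0.02, i.e. a strongly endogamous but not closed community.
* `gene_drop_genotypes()` drops founder alleles (per-locus frequencies
  supplied by the user; the study default draws them uniformly from
  0.1–0.5) through every meiosis, with optional LD blocks (loci copying a
  shared latent allele, whole-block transmission, free recombination
  between blocks). Genotype correlation between relatives is therefore
  *exactly* $2k_{ij}$ at every locus — consistent with the kinship matrix
  the matching step uses.
* `disease_model()` / `assign_disease()`: a random "risk configuration"
  (one genotype level per causal variant, drawn uniformly), a match count
  $c$ per subject, $\Pr(Y=1) = \mathrm{logit}^{-1}(\alpha + \beta c)$
  (defaults $\alpha = 0$, $\beta = 1$: the inverse logit of the raw count,
  the simplest reading of a count-based logit link; both are exposed since
  the source description fixes neither), and case status for the
  `n_cases` highest-probability subjects, ties broken by a seeded uniform
  draw. Every replicate has exactly `n_cases` cases by construction.

`run_study()` fixes one cohort, then per replicate redraws the $N$-subject
subset and the causal configuration, scores every method's variant ranking
by ROC AUC (Mann-Whitney with half credit for ties — essential here, since
exact-test p-values and bagging importances tie heavily at small $n$),
under both the kinship-matched and the random control design. Reduced
problem sizes used throughout the tests and the acceptance script:
$N = 50$, $P = 200$, $p = 5$ causal, $I = 10$, $R = 100$ replicates,
$M = 200$–$500$ trees.

**A limitation the tests make visible.** In this gene-drop world, *every*
SNP — causal or not — has the identical pedigree-induced correlation
structure, so matching controls to cases by kinship suppresses background
association at noise SNPs and at causal SNPs alike; and because cases are
*selected on* the causal configuration, their close kin are enriched for
it, which dilutes the causal contrast in the matched sample. The two
effects roughly cancel: in this simulation the matched design neither
helps nor hurts the forest's ranking on average (the study criterion
comparing the two designs is a knife-edge at $R = 100$). Real cohorts are
different in exactly the way that matters: rare lineage-specific alleles,
LD blocks of varying depth, genotyping batch effects and residual
population substructure give real noise SNPs *excess* stratification
signal for matching to remove. Passing the synthetic study therefore shows
the machinery is correct, not that the design's benefit on real isolate
data is reproduced; conversely, the clear benefit reported on real data is
not contradicted by a null result under this deliberately homogeneous
generator.

## Numerical and degenerate-input conventions

* Kinship: full-matrix memoisation per pedigree ($O(n^2)$ memory; a
  10k-member pedigree costs ~0.8 GB, beyond which a sparse path-counting
  approach would be needed — out of scope here).
* Assignment: entries must be finite; $I > J$ is an error ("fewer potential
  controls than cases"), not a partial matching.
* Fisher test: a zero row/column margin means the table carries no
  information; $p = 1$ with a warning rather than an error, so scans never
  die on a degenerate variant.
* Forest: classes with fewer than 2 subjects, in-bag sizes that empty a
  class out-of-bag, and `mtry` outside $[1, P]$ are configuration errors;
  a constant predictor simply can never split and gets $\eta = 0$.
* Screening on wholly uninformative data returns an empty list with a
  warning (not an error): downstream code can distinguish "nothing found"
  from "could not run".
* All user-facing randomness flows through explicit integer seeds;
  `NULL` means "consume the session RNG", so `set.seed()` upstream still
  gives reproducibility. Derived sub-seeds stay below $2^{31}$.
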