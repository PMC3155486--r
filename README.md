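# kinforest

Genealogy-aware case-control design and random-forest variant screening for
isolated populations.

## The problem

In a genetic isolate with a recorded genealogy (a village founded by a few
families centuries ago, say), every pair of study subjects has a known
kinship coefficient — and that is both a nuisance and an opportunity.
Nuisance, because related subjects share genome-wide background, so naive
single-point scans pick up ancestry instead of disease. Opportunity,
because one can *design away* the background: for a set of cases, choose
the controls that are jointly their closest relatives, so each case-control
contrast happens inside a family and shared variability cancels.

`kinforest` is for statistical geneticists analysing such cohorts. It
implements:

* **Pedigree kinship** — the classical founders-first recursion for
  k<sub>ij</sub> = P(two random alleles, one from *i*, one from *j*, are
  identical by descent), plus a gene-dropping Monte-Carlo estimator used to
  verify it.
* **Matched design** — selection of the *I* controls maximising
  &Sigma;<sub>i</sub> k<sub>i,&sigma;(i)</sub> over all one-to-one
  assignments &sigma; (the linear assignment problem, solved exactly by the
  Hungarian method), with the usual random-control design as comparator.
* **Forest model** — an ensemble of M Bernoulli-deviance classification
  trees on the balanced 2I sample: stratified half in-bag per tree,
  out-of-bag (OOB) error &Lambda;, and variable importance
  &eta;<sub>j</sub> = total deviance decrease from splits on variant *j*.
  Variant selection runs in two phases: a *bagging screen* (mtry = P;
  iteratively drop every variant with &eta;<sub>j</sub> = 0) and a
  *backward selection* (refit on the top k variants with
  mtry = &lfloor;&radic;k&rfloor;, k decreasing; keep the smallest set at
  the lowest OOB error).
* **Single-point comparators** — Fisher exact genome scan (genotypic 2×g or
  allelic 2×2 tables), p-value ECDF reporting, Benjamini-Hochberg, Storey
  q-values and local false discovery rate.
* **Simulation framework** — consanguineous pedigree generator, Mendelian
  gene-dropped genotypes with optional LD blocks, a configuration-count
  logit disease model, and an ROC/AUC study comparing how well each method
  ranks the truly causal variants under the matched versus the random
  design.

## Worked example

Simulate an endogamous cohort, plant a 5-variant disease configuration,
build the kinship-matched sample, and run both analyses:

```r
library(kinforest)

co <- simulate_cohort(n_founders = 20, n_generations = 4, n_snps = 120,
                      seed = 42)
co
#> Simulated cohort: 182 subjects, 120 SNPs
#>   mean off-diagonal kinship: 0.0259

model  <- disease_model(causal_indices = c(11, 12, 13, 14, 15),
                        configuration  = c(2, 0, 1, 2, 1))
status <- assign_disease(co$genotypes, model, n_cases = 10, seed = 42)
cases  <- names(status)[status == 1]

K   <- kinship_matrix(co$ped, cases, setdiff(co$ids, cases))
asn <- hungarian_select(K)
asn
#> Control assignment (hungarian design): 10 case-control pairs
#> Total matched kinship: 2.625

smp <- matched_sample(asn, co$genotypes)

genome_scan(smp)
#> Single-point scan over 120 variants
#>   p < 0.05: 4   flagged: 4
#> Top 5 variants by p-value:
#>  variant       p     bh      q   lfdr flagged rank
#>    snp13 0.01084 0.6502 0.6502 0.5334   FALSE    1
#>    snp14 0.01084 0.6502 0.6502 0.5334   FALSE    2
#>    snp28 0.01703 0.6811 0.6811 0.6718   FALSE    3
#>    snp23 0.04334 1.0000 1.0000 1.0000   FALSE    4
#>    snp71 0.07657 1.0000 1.0000 1.0000   FALSE    5

scr <- bagging_screen(smp, ntree = 500, seed = 1)
scr
#> Bagging screen: 9 iteration(s), variable sets of size
#>   120 -> 65 -> 57 -> 53 -> 48 -> 47 -> 44 -> 42 -> 40
#> Top survivors: snp13, snp14, snp10, snp28, snp15, snp23, ...

backward_select(smp, ranked = scr, ntree = 500, seed = 2)
#> Backward selection over 40 step(s)
#> Minimum OOB error 0.05 attained with the 6 top variable(s):
#>    snp13, snp14, snp10, snp28, snp15, snp23
```

Reading the output: the single-point scan puts two of the five causal
variants (snp13, snp14) on top but no adjusted p-value survives multiplicity
at n = 20. The forest pipeline screens 120 variants down to 40 informative
ones and backward selection keeps the 6-variant model with the lowest OOB
error (5%) — containing three of the five causal variants (snp13, snp14,
snp15). With 10 cases, recovering 3/5 causal variants in a 6-variant final
model is the kind of yield the method is designed for; which causal variants
are missed depends on how often their risk configuration actually occurred
among the 20 subjects.

The full pipeline (`kinship → match → scan → rf-select`, TSV artifacts with
seed-stamped headers) is available as `run_pipeline()` and as a thin command
line interface:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","kinforest.R",package="kinforest"))')" \
    pipeline --pedigree cohort.fam --genotypes geno.tsv \
    --cases cases.txt --design hungarian --trees 500 --seed 1 --out run1/
```

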