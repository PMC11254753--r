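# excon

Selection and depletion statistics from summary-level population exome
variant tables.

Very large exome cohorts observe so much of the mutational target that the
*absence* of variation becomes measurable.  `excon` implements, as tested
R code, the statistics that turn that absence into inference, for
statistical geneticists working with per-site variant summary tables
(gene, position, ref/alt, consequence class, trinucleotide context,
allele counts, homozygote counts, prediction scores):

* **s_het** — a per-gene heterozygous selection coefficient from the
  cumulative frequency of rare predicted loss-of-function (pLOF) alleles.
  Under mutation–selection balance the cumulative pLOF frequency is
  `q = U/s`, where `U` is the gene's aggregate pLOF mutation rate; the
  package models the rare pLOF allele count as `X ~ Poisson(AN·U/s)`,
  computes a grid posterior under a flat-in-log or empirical-Bayes
  inverse-Gaussian prior, reports 95% highest-posterior-density intervals,
  and flags highly constrained genes (posterior mean > 0.073 and HPD lower
  bound > 0.021).
* **MTR** — the missense tolerance ratio
  `(obs_mis/(obs_mis+obs_syn)) / (exp_mis/(exp_mis+exp_syn))` per codon in
  sliding windows of 21 or 31 codons, with one-sided binomial depletion
  tests under exome-wide Benjamini–Hochberg FDR control, exome-wide
  percentile thresholds, segmentation of constrained regions, and per-gene
  binomial burden tests (π₀ = 0.15).
* **MAPS** — the mutability-adjusted proportion of singletons: singleton
  excess after regressing out mutation-rate effects on synonymous
  variants, plus calibration of splice-prediction score thresholds as the
  minimum score whose MAPS matches the 5/5-missense reference class.
* **Human knockouts** — biallelic pLOF carrier detection (homozygotes and
  phased trans compound heterozygotes), doubleton homozygote-excess and
  background inbreeding estimation, homozygote-deficit tests, and exact
  hypergeometric projection of knockout-gene accrual at hypothetical
  cohort sizes.
* A **mutation model** (trinucleotide contexts, CpG methylation tiers,
  exhaustive possible-variant enumeration, saturation surveys) and a
  **seeded synthetic-exome generator** that produces cohorts with known
  truth for every analysis above.

## Worked example

Doubleton homozygosity on the published cohort tally that ships with the
package (821,979 individuals):

```r
library(excon)

ds <- doubleton_example()
ds
#>        class       D hom_obs   e_hwe      N
#> 1   missense 1580917    5857 0.96165 821979
#> 2 synonymous  679335    2490 0.41323 821979
#> 3       plof  129405     406 0.07872 821979

refcls <- ds[ds$class %in% c("missense", "synonymous"), ]
F <- estimate_inbreeding(refcls)
sprintf("background inbreeding F = %.4f%%", 100 * F)
#> "background inbreeding F = 0.3693%"

homozygote_deficit_test(ds[ds$class == "plof", ], round(F, 4), refcls)
#> expected 479 homozygotes, observed 406: deficit 15.2%, Fisher P = 0.0011
```

Every class carries a Hardy–Weinberg expectation of *under one* homozygous
doubleton (`e_hwe`), yet thousands are observed — the excess calibrates a
background inbreeding coefficient of 0.37%.  pLOF doubletons fall about
15% short of even that inflated expectation: a sizeable share of
homozygous knockouts is missing from the standing population.

Gene constraint on a simulated cohort of 100,000 individuals:

```r
ex <- simulate_exome(sim_config(seed = 1))       # 60 genes, known truth
rates <- vapply(ex$genes, `[[`, 0, "U_plof")     # per-gene pLOF rates
tab <- shet_table(ex$sites, rates)               # empirical-Bayes prior
head(tab[, c("gene_id", "n_plof_variants", "X", "posterior_mean",
             "hpd_low", "hpd_high", "constrained")], 5)
#>   gene_id n_plof_variants  X posterior_mean hpd_low hpd_high constrained
#> 1   G0001              13 28         0.0484  0.0328   0.0665       FALSE
#> 2   G0002              25 44         0.0534  0.0393   0.0693       FALSE
#> 3   G0003              28 55         0.0216  0.0165   0.0274       FALSE
#> 4   G0004              30 50         0.0327  0.0242   0.0416       FALSE
#> 5   G0005              34 59         0.0352  0.0267   0.0439       FALSE
sum(tab$constrained)
#> 7
```

`X` is the cumulative rare pLOF allele count; genes with fewer copies than
their mutation rate predicts get large `posterior_mean` (strong selection)
and are flagged when both the mean and the HPD lower bound clear their
cutoffs.  `run_pipeline(run_config(out_dir = "out"))` chains simulation,
saturation survey, s_het, MTR, MAPS and doubleton stages and writes one
TSV per result plus a JSON manifest.

## Layout

* `R/` — mutation model, s_het, MTR, MAPS, knockouts, synthetic data,
  readers/writers, pipeline.
* `tests/testthat/` — unit tests per module, property-style invariant
  checks against brute-force oracles, and the end-to-end validation suite.
* `vignettes/constraint-statistics.Rmd` — the models, their assumptions,
  parameter defaults, and design decisions.
* `inst/extdata/` — the worked-example doubleton tally.
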