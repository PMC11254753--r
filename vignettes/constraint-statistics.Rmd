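---
title: "Constraint statistics from population exome summaries: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint statistics from population exome summaries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`excon` computes four families of selection and depletion statistics from
summary-level exome variant tables of very large cohorts:

1. **Gene constraint** — a per-gene heterozygous selection coefficient
   (s_het) estimated from the cumulative frequency of rare predicted
   loss-of-function (pLOF) alleles.
2. **Regional missense constraint** — the missense tolerance ratio (MTR) in
   sliding codon windows, with exome-wide FDR control, percentile
   thresholds and segmentation into constrained regions.
3. **MAPS** — the mutability-adjusted proportion of singletons, and its use
   to calibrate splice-prediction score thresholds against the 5/5-missense
   reference class.
4. **Human knockouts** — biallelic pLOF carrier detection, doubleton
   homozygote-excess and background inbreeding, and projected accrual of
   knockout genes at hypothetical cohort sizes.

A seeded synthetic-exome generator supplies the test substrate for all of
these; every estimator in the package is validated against data whose truth
is known by construction.

# The mutation model

Expected variant counts rest on a trinucleotide-context substitution-rate
table (`build_rate_table()`): a genome-wide base rate (default 1e-8 per
site per haploid generation), a transition multiplier (2), a CpG
deamination multiplier (10) for C>T transitions at CpG dinucleotides, and
methylation-tier multipliers (none/low = 1, mid = 3, high = 6) that act on
CpG deamination only.  Contexts are keyed pyrimidine-centered, so a context
and its reverse complement resolve to one entry.  The table is
parameterized rather than fitted: the analyses need a rate model with the
right *structure* (context dependence, CpG/methylation uplift), and every
rate enters the statistics only through ratios or aggregate expectations.

`enumerate_possible_variants()` expands a coding sequence into all `9L`
candidate substitutions and classifies each with the standard genetic code.
Start-codon and stop-codon substitutions form their own classes
(`start_loss`, `stop_loss`) and are excluded from the
synonymous/missense/stop-gained tallies used by the survey and MTR; a
stop-retaining change in the stop codon is synonymous.  Essential splice
sites are modelled abstractly as a per-gene count of donor/acceptor bases
with a fixed configurable context, which keeps the aggregate pLOF mutation
rate well defined for intronless toy gene models.  Frameshift indels are
not enumerated; their contribution enters through a multiplicative uplift
(default 1.25) on the pLOF rate, since no indel mutation model is
attempted.  The per-gene pLOF rate is therefore
`U = uplift × (Σ stop-gained rates + splice-site term)`.

# Gene-level selection coefficients

The estimator models the cumulative alternate allele count `X` of a gene's
rare pLOF variants (per-variant alternate allele frequency strictly below
0.1%) as

`X ~ Poisson(AN · U / s)`,

i.e. deterministic mutation–selection balance — at equilibrium the summed
frequency of loss-of-function alleles is `U/s` — with Poisson sampling of
allele copies among `AN` genotyped chromosomes.  Genetic drift and
demography are deliberately omitted from the likelihood; at the cohort
sizes targeted here the sampling term dominates, and the simulation studies
below quantify how the estimator behaves when its generating assumptions
hold exactly.

The posterior is computed on a fixed grid of 1,000 log-spaced points on
`[1e-6, 1]`, which spans effectively-neutral to lethal; `s` is capped at 1.
The Poisson mean is floored at 1e-12 to avoid `log(0)`.  Two priors are
supported: flat-in-log (equal mass per grid point) and an inverse-Gaussian
density discretized on the grid.  The inverse-Gaussian family is the
package's empirical-Bayes choice — a flexible, strictly positive,
two-parameter family whose mass concentrates at small `s` for realistic
parameters; `fit_shet_prior()` maximizes the marginal likelihood across
genes by Nelder–Mead on the log scale, deterministically.  The 95% highest
posterior density interval is the smallest contiguous run of grid points
holding at least 95% of posterior mass, with ties broken toward the
smaller start; the posterior is unimodal in practice, so the contiguous
restriction is harmless.

Two readings of "cumulative pLOF burden" are supported because both appear
in routine use: the default sums allele copies (`mode = "alleles"`), an
alternative counts distinct contributing variants (`mode = "variants"`).
The default is the allele-copy sum since that is what mutation–selection
balance predicts; the ambiguity is documented rather than resolved.

Genes are flagged highly constrained when the posterior mean exceeds 0.073
**and** the HPD lower bound exceeds 0.021 (both strict).  These defaults
are the cohort mean and median of the s_het distribution reported for
population-scale exome data, used as mean and lower-bound cutoffs
respectively so that the call reflects both effect size and uncertainty.

# Regional missense tolerance

For each codon, a window of `w` codons (21 or 31; truncated, not dropped,
at the protein termini) collects distinct observed synonymous and missense
variants and the corresponding possible-variant counts, and

`MTR = (obs_mis / (obs_mis + obs_syn)) / (exp_mis / (exp_mis + exp_syn))`.

A window with no observed variants is unscored (`NA`), not zero.  Expected
proportions use unweighted possible-variant counts — the original MTR
convention.  A mutation-rate-weighted mode is available
(`rate_table` argument): with strong CpG rate heterogeneity, synonymous
sites saturate faster than missense sites, which deflates the neutral
unweighted ratio by a few percent (about 0.97 at the default simulation
settings); the weighted mode compensates, slightly overcorrecting where
presence saturates.  The package validates neutrality of the default
convention on a rate-homogeneous simulation, which isolates the windowing
and ratio machinery; the residual composition bias under heterogeneous
rates is a documented property of the classic definition, not a defect of
the implementation.

Depletion significance is a per-codon one-sided binomial test of
`obs_mis` against the window's expected missense proportion, with
Benjamini–Hochberg adjustment across all scored codons exome-wide (not per
gene), because the thresholds the track feeds are exome-wide.  Percentile
ranks are likewise exome-wide, ascending (low MTR = low percentile = more
constrained), with average ranks on ties; by default all scored codons are
ranked and the FDR flag is carried alongside, with a
`fdr_gates_ranking = TRUE` alternative that ranks only FDR-passing codons.
Constrained regions are maximal runs of codons at or below the percentile
cutoff (default 15), merging runs separated by at most `max_gap`
non-qualifying codons (default 0) and dropping runs shorter than
`min_length` (default 5).  The minimum length and gap defaults are artifact
choices: published region catalogues imply post-filtering whose exact rules
are not described, so the package exposes the knobs and defaults to
conservative values.  The per-gene burden test is a one-sided binomial
`P(K ≥ k | n, π₀ = 0.15)` on the count of top-15-percentile codons, with
multiple-testing correction applied across the gene set by the caller.

# MAPS and threshold calibration

The mutability adjustment is a weighted least-squares regression of the
stratum singleton proportion on mutability `μ`, fitted on synonymous
variants grouped by distinct `μ` values, with stratum sizes as weights;
predictions are clipped to `[0, 1]`.  MAPS of a variant set is the observed
singleton proportion minus the mean prediction, and its standard error is
the binomial standard deviation of the observed proportion.  By WLS
orthogonality the training set itself scores exactly zero, which the test
suite asserts to 1e-9 — a useful canary for any change to the fitting
path.  Whether the original metric used per-context strata or a continuous
regressor is not restated in the material available; the stratified-WLS
choice here is a design decision.

Threshold calibration sweeps a grid (step 0.01) over a score in `[0, 1]`
and evaluates MAPS of the *cumulative* sets `{score ≥ t}`; the chosen
threshold is the smallest `t` whose MAPS reaches the reference class's MAPS
with at least `min_variants` (default 500) variants in the set.  Cumulative
sets make "minimum threshold" well defined; a disjoint-bin mode exists for
diagnostics.  No monotone smoothing is applied — the first crossing wins —
because noise is already controlled by the set-size floor.  The reference
class ("5/5 missense") is an input column: variants predicted deleterious
by five of five algorithms; the package does not reimplement those
predictors.

# Human knockouts

A sample is a biallelic pLOF carrier in a gene if it has one rare
(AAF < 1%) homozygous pLOF genotype, or two rare het pLOF variants phased
to opposite haplotype sides within a shared phase block.  Pairs whose
relative phase is unknown (unphased calls or different blocks) are tallied
as *potential* compound hets and never set the knockout flag; pairs known
to be in cis count as nothing.  Phase must be supplied — statistical
phasing is out of scope for a summary-level toolkit.

Doubletons (cohort allele count exactly 2) calibrate background
homozygosity: under random placement the two copies land in one individual
with probability `1/(2N−1)`, so the Hardy–Weinberg expectation of
homozygous doubletons is `D/(2N−1)` — well below one in any realistic
class.  The observed excess defines the background inbreeding coefficient
`F = Σ hom_obs / Σ D` pooled over missense and synonymous reference
classes.  The expected homozygote count of a target class under `F` is
`e_f = F·D` by default; the full expectation adds the random-pairing term,
`(F + (1−F)/(2N−1))·D`, and changes the result by under 1% at these cohort
sizes — the direct product is the default because it matches the published
worked arithmetic, and the rounded two-significant-figure `F` (0.37%) is
used in that worked example for the same reason.  The deficit
`1 − hom_obs/e_f` measures homozygotes missing relative to expectation;
significance comes from a two-sided Fisher's exact test of the homozygous
fraction in the target class against the pooled reference classes.  The
published analysis this mirrors does not print its 2×2 table, and plausible
reconstructions give different p-values, so the package documents its table
choice and treats the p-value as a supported statistic rather than a
reproduction target.

Accrual projection is exact: with `C_g` carriers of gene `g` among
`N_total` individuals, the expected number of genes with at least `k`
carriers in a random subsample of `n` is
`Σ_g (1 − HypergeometricCDF(k−1; N_total, C_g, n))`.

# The synthetic exome generator

`simulate_exome()` emulates the statistical structure the analyses assume,
not human genome content.  Design, with the reasoning behind each choice:

* **Presence of a variant at a site.**  The number of independent
  mutational origins of each possible variant is Poisson.  For neutral
  sites the intensity is `θ·μ·H(AN)` — the Watterson scaling, under which
  segregating sites grow with the harmonic number of the sample size —
  calibrated so that a site of canonical mutability 1e-8 is observed at
  35.6% of possible positions in a reference cohort of 1,643,958
  chromosomes, the saturation regime of current population exome
  resources.  An emergent check: highly methylated CpG deamination sites
  then saturate near 99% at the reference cohort, mirroring the
  near-complete discovery reported for that stratum.
* **Allele counts.**  Conditional on presence, each origin draws from a
  truncated tilted spectrum `P(AC = k) ∝ k^(−1) · exp(−k·s·λ)` on
  `[1, AN]` (λ = 2000 by default): the standard neutral `1/k` spectrum,
  exponentially suppressed for selected sites, which drives selected
  classes toward singletons.  This is a parametric stand-in, not a
  coalescent: there is no genealogy, linkage, or demography.
* **Loss-of-function sites** follow mutation–selection balance exactly:
  the presence intensity is set to `AN·μ/(s·m)` with `m` the mean of the
  tilted spectrum, so a gene's cumulative rare pLOF allele count is
  Poisson with mean `AN·U/s` — the generating model and the s_het
  likelihood coincide by construction, which is what a parameter-recovery
  test should test.  Frameshift alleles are generated from pseudo-sites
  carrying the uplift share of the pLOF rate, so the simulated burden
  matches the `U` used in estimation.
* **Missense sites** keep the mutation-limited presence intensity;
  selection shows in their frequency spectrum (a deleterious fraction,
  default 25%, at half the gene's `s`) and, in planted intervals, as a
  presence depletion (factor 0.3).  This deliberate asymmetry — balance
  thinning for pLOF, spectrum tilt for missense — keeps the MAPS class
  ordering (pLOF > missense > synonymous) and the MTR depletion signal
  realistic at these simulation sizes; fully equilibrium missense would all
  but vanish from the sample rather than appear as singletons.
* **Planted depleted intervals** cover a quarter of the codons in 45% of
  genes, about 11% of coding mass exome-wide — comparable to, and slightly
  inside, the top-15-percentile budget the segmentation uses, so percentile
  thresholding can in principle isolate them.
* **Inbreeding.**  Doubleton homozygosity is simulated mechanistically
  (second copy pairs with the first with probability `F`, default 0.37%,
  else lands uniformly on the remaining chromosomes); allele counts above
  2 use a binomial pairing approximation, and only doubletons feed the
  inbreeding analyses.
* **Scores.**  Splice-affecting truth sites (2% of variants) draw
  spliceai-like scores from a Beta concentrated near 1, background from a
  Beta near 0; the 5-algorithm deleteriousness count is Binomial(5, 0.85)
  at truly deleterious missense sites and Binomial(5, 0.25) elsewhere, so
  score columns correlate with deleteriousness without being determined by
  the observed frequencies.

What passing tests on this substrate do **not** show: robustness to
demography, ancestry structure, linkage, sequencing error, or
misannotation.  The generator validates the statistical machinery under
its stated assumptions, nothing more.

# Problem sizes and numerical choices

The validation runs use 500 genes for selection-coefficient recovery
(Spearman ≥ 0.7 against truth, ≥ 85% HPD coverage), 100-gene cohorts at
120,000 versus 2,000,000 chromosomes for the precision comparison, 40-gene
exomes for MTR neutrality and planted-region recovery (region/truth
Jaccard ≥ 0.5), and 100 seeded replicates for the MAPS ordering and
calibration-recovery rates — sizes chosen so the full validation completes
in minutes on one CPU while leaving the statistical checks well powered.
Degenerate inputs are handled explicitly: genes with no genotyped alleles
error; an all-zero cumulative burden across genes makes the empirical-Bayes
prior unidentifiable and falls back to the flat prior with a warning;
unscored MTR windows are `NA`; empty MAPS classes are omitted with a
warning; a calibration whose reference level is never reached returns a
missing threshold with the full curve for inspection.

# Known limitations

* The s_het likelihood ignores drift and demography; it is exact only
  under deterministic balance with Poisson sampling.
* The unweighted MTR carries a small class-composition bias under strong
  mutability heterogeneity (see above).
* `F·D` and Fisher-table conventions for the homozygote-deficit test are
  one of several defensible choices; alternatives are exposed via
  `mode = "full"` and the reference-class argument.
* The generator is non-genealogical; its site-frequency spectrum and
  saturation behaviour are parametric approximations.
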