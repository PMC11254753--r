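Package: excon
Title: Gene Constraint, Regional Missense Tolerance and Human Knockout
    Statistics from Population Exome Variant Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes selection and depletion statistics from summary-level
    exome variant tables at population scale.  Implements a trinucleotide
    context mutation-rate model with CpG methylation tiers and exhaustive
    enumeration of possible coding variants; Bayesian estimation of the
    heterozygous selection coefficient (s_het) per gene from the cumulative
    frequency of rare predicted loss-of-function alleles under
    mutation-selection balance, with highest-posterior-density intervals and
    constraint classification; the missense tolerance ratio (MTR) in sliding
    codon windows with exome-wide false-discovery-rate control, percentile
    thresholds and constrained-region segmentation; the mutability-adjusted
    proportion of singletons (MAPS) and MAPS-based calibration of splice
    prediction score thresholds; and biallelic loss-of-function ("human
    knockout") analyses including doubleton homozygote-excess, background
    inbreeding estimation and projected knockout-gene accrual.  A seeded
    synthetic-exome generator provides the test substrate for all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
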