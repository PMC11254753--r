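#' Build a trinucleotide-context mutation-rate table
#'
#' Constructs per-site, per-haploid-generation substitution rates for every
#' strand-normalized trinucleotide context, alternate base and methylation
#' tier.  The model is deliberately parametric: a genome-wide base rate, a
#' transition multiplier, a CpG deamination (C>T transition at CpG)
#' multiplier, and methylation-tier multipliers that act on CpG deamination
#' only.  Non-CpG contexts carry identical rates across tiers; methylation
#' tiers are meaningful only at CpG sites.
#'
#' @param base_rate baseline substitution rate per site per haploid
#'   generation (default `1e-8`).
#' @param transition_mult multiplier applied to transitions (default 2).
#' @param cpg_transition_mult multiplier applied to the C>T deamination
#'   change at CpG dinucleotides (default 10).
#' @param methylation_mult named multipliers for tiers `none`, `low`, `mid`,
#'   `high`, applied to CpG deamination on top of `cpg_transition_mult`.
#'   Must be non-decreasing from `low` to `high`.
#' @return object of class `mu_table`: a data frame with columns `context`
#'   (pyrimidine-centered 3-mer), `alt`, `tier`, `rate`, plus the
#'   configuration as attributes.
#' @export
build_rate_table <- function(base_rate = 1e-8,
                             transition_mult = 2,
                             cpg_transition_mult = 10,
                             methylation_mult = c(none = 1, low = 1, mid = 3, high = 6)) {
  if (!all(c("none", "low", "mid", "high") %in% names(methylation_mult)))
    stopf("methylation_mult must be named with tiers %s",
          paste(METH_TIERS, collapse = ", "))
  methylation_mult <- methylation_mult[METH_TIERS]
  mult <- c(base_rate, transition_mult, cpg_transition_mult, methylation_mult)
  if (any(!is.finite(mult)) || any(mult <= 0))
    stopf("all rate parameters must be positive and finite")
  if (methylation_mult[["high"]] < methylation_mult[["low"]] ||
      methylation_mult[["mid"]] < methylation_mult[["low"]] ||
      methylation_mult[["high"]] < methylation_mult[["mid"]])
    stopf("methylation multipliers must be non-decreasing from low to high")

  ctx <- as.vector(outer(outer(DNA_BASES, c("C", "T"), function(a, b) paste0(a, b)),
                         DNA_BASES, paste0))
  grid <- expand.grid(context = ctx, alt = DNA_BASES, tier = METH_TIERS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mid <- substr(grid$context, 2L, 2L)
  grid <- grid[grid$alt != mid, ]
  mid <- substr(grid$context, 2L, 2L)
  is_ts <- (mid == "C" & grid$alt == "T") | (mid == "T" & grid$alt == "C")
  is_cpg <- substr(grid$context, 2L, 3L) == "CG"
  is_deam <- is_cpg & mid == "C" & grid$alt == "T"
  rate <- rep(base_rate, nrow(grid))
  rate[is_ts] <- rate[is_ts] * transition_mult
  rate[is_deam] <- rate[is_deam] * cpg_transition_mult *
    methylation_mult[grid$tier[is_deam]]
  grid$rate <- rate
  grid <- grid[order(grid$context, grid$alt, match(grid$tier, METH_TIERS)), ]
  rownames(grid) <- NULL
  structure(grid,
            class = c("mu_table", "data.frame"),
            base_rate = base_rate,
            transition_mult = transition_mult,
            cpg_transition_mult = cpg_transition_mult,
            methylation_mult = methylation_mult,
            key = stats::setNames(grid$rate,
                                  paste(grid$context, grid$alt, grid$tier, sep = ":")))
}

#' Look up mutation rates
#'
#' Vectorised lookup with strand normalization: a context and its reverse
#' complement resolve to the same entry.
#'
#' @param table a `mu_table` from [build_rate_table()].
#' @param context 3-mer contexts (any strand).
#' @param alt alternate bases.
#' @param tier methylation tiers (default `"none"`).
#' @return numeric vector of rates.
#' @export
mu_rate <- function(table, context, alt, tier = "none") {
  stopifnot(inherits(table, "mu_table"))
  nz <- normalize_context(context, alt)
  n <- length(nz$context)
  tier <- rep_len(tier, n)
  key <- paste(nz$context, nz$alt, tier, sep = ":")
  out <- attr(table, "key")[key]
  if (anyNA(out))
    stopf("context/alt/tier not found in rate table: %s",
          paste(utils::head(key[is.na(out)], 3L), collapse = ", "))
  unname(out)
}

#' Mutation rate of a variant row
#'
#' Variant tables keep `ref`/`alt` on the coding strand while `context` is
#' stored pyrimidine-centered; when the stored context was flipped relative
#' to the coding strand (its middle base is the complement of `ref`), the
#' alternate allele is complemented before the lookup so the pair stays
#' consistent.
#'
#' @param table a `mu_table`.
#' @param context stored (strand-normalized) 3-mer contexts.
#' @param ref,alt coding-strand reference/alternate bases.
#' @param tier methylation tiers.
#' @return numeric vector of rates.
#' @export
variant_mu <- function(table, context, ref, alt, tier = "none") {
  mid <- substr(context, 2L, 2L)
  flipped <- mid != ref
  if (any(mid[flipped] != chartr("ACGT", "TGCA", ref[flipped])))
    stopf("context middle base matches neither ref nor its complement")
  alt[flipped] <- chartr("ACGT", "TGCA", alt[flipped])
  mu_rate(table, context, alt, tier)
}

#' Construct a gene model
#'
#' A gene model holds the coding sequence of one canonical transcript along
#' with the abstract pieces needed for loss-of-function mutation rates:
#' the count of essential splice-site bases (0 for intronless toys) and a
#' per-CDS-position methylation tier track.  Coordinates are 1-based on the
#' coding strand.
#'
#' @param gene_id,transcript_id identifiers.
#' @param cds coding sequence (character); length divisible by 3, starting
#'   with ATG and ending with a stop codon.
#' @param splice_site_count number of essential splice donor/acceptor bases.
#' @param meth_tier methylation tier per CDS position (recycled); tiers other
#'   than `"none"` are only meaningful at CpG positions.
#' @param flank5,flank3 single bases flanking the CDS, used to complete the
#'   trinucleotide context of the first and last position.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id = gene_id, cds,
                       splice_site_count = 0L,
                       meth_tier = "none",
                       flank5 = "T", flank3 = "A") {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stopf("CDS length of %s (%d) is not divisible by 3", gene_id, n)
  if (n < 9L)
    stopf("CDS of %s must contain at least start, one interior and stop codon", gene_id)
  if (!grepl("^[ACGT]+$", cds))
    stopf("CDS of %s contains non-ACGT characters", gene_id)
  if (substr(cds, 1L, 3L) != "ATG")
    stopf("CDS of %s does not start with ATG", gene_id)
  last <- substr(cds, n - 2L, n)
  if (!last %in% c("TAA", "TAG", "TGA"))
    stopf("CDS of %s does not end with a stop codon", gene_id)
  meth_tier <- rep_len(as.character(meth_tier), n)
  if (!all(meth_tier %in% METH_TIERS))
    stopf("unknown methylation tier in %s", gene_id)
  structure(list(gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 cds = cds,
                 codon_count = n %/% 3L,
                 splice_site_count = as.integer(splice_site_count),
                 meth_tier = meth_tier,
                 flank5 = flank5, flank3 = flank3,
                 U_plof = NA_real_),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s): %d codons, %d essential splice bases, U_plof = %s\n",
              x$gene_id, x$transcript_id, x$codon_count, x$splice_site_count,
              format(x$U_plof)))
  invisible(x)
}

#' Enumerate all possible coding substitutions of a gene
#'
#' Every CDS position admits exactly three alternate bases; each candidate
#' substitution is classified by translating the mutant codon with the
#' standard genetic code.  Substitutions in the start codon are classified
#' `start_loss` and those removing the terminal stop `stop_loss`; both are
#' their own classes, kept out of the synonymous/missense/stop-gained
#' tallies used elsewhere.  A stop-retaining change in the stop codon is
#' synonymous.
#'
#' @param gene a [gene_model()].
#' @return data frame with one row per candidate substitution: `gene_id`,
#'   `pos` (1-based CDS), `codon` (codon index), `ref`, `alt`, `consequence`,
#'   `context` (strand-normalized), `methylation_tier`.
#' @export
enumerate_possible_variants <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nchar(gene$cds)
  L <- n %/% 3L
  s <- strsplit(gene$cds, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  lag <- c(gene$flank5, s[-n])
  lead <- c(s[-1L], gene$flank3)
  ctx_raw <- paste0(lag, s, lead)

  pos <- rep(seq_len(n), each = 3L)
  ref <- s[pos]
  alt <- unlist(lapply(s, function(b) DNA_BASES[DNA_BASES != b]), use.names = FALSE)
  codon_idx <- (pos - 1L) %/% 3L + 1L
  pos_in_codon <- (pos - 1L) %% 3L + 1L

  codons <- substring(gene$cds, 3L * seq_len(L) - 2L, 3L * seq_len(L))
  ref_codon <- codons[codon_idx]
  mut_codon <- ref_codon
  substr(mut_codon, pos_in_codon, pos_in_codon) <- alt
  ref_aa <- unname(gc[ref_codon])
  mut_aa <- unname(gc[mut_codon])

  consequence <- ifelse(codon_idx == 1L, "start_loss",
                 ifelse(codon_idx == L,
                        ifelse(mut_aa == "*", "synonymous", "stop_loss"),
                 ifelse(mut_aa == "*", "stop_gained",
                 ifelse(mut_aa == ref_aa, "synonymous", "missense"))))

  nz <- normalize_context(ctx_raw[pos], alt)
  # methylation tiers only attach to CpG contexts; others are forced to none
  tier <- gene$meth_tier[pos]
  tier[substr(nz$context, 2L, 3L) != "CG"] <- "none"

  data.frame(gene_id = gene$gene_id, pos = pos, codon = codon_idx,
             ref = ref, alt = alt, consequence = consequence,
             context = nz$context, methylation_tier = tier,
             stringsAsFactors = FALSE)
}

#' Aggregate loss-of-function mutation rate of a gene
#'
#' Sums the context-specific rates over all stop-gained substitutions and the
#' gene's essential splice-site bases (each contributing the three alternate
#' alleles at a configurable fixed context), then applies a frameshift uplift
#' factor accounting for loss-of-function indels, which are not enumerated
#' site by site.
#'
#' @param gene a [gene_model()].
#' @param table a `mu_table`.
#' @param frameshift_uplift multiplicative uplift for frameshift indels
#'   (default 1.25).
#' @param splice_context fixed trinucleotide context assumed for essential
#'   splice bases.
#' @param possible optional pre-computed [enumerate_possible_variants()]
#'   output, to avoid re-enumeration.
#' @return the rate U (per haploid generation); also available via
#'   [set_gene_rate()] which stores it in the model.
#' @export
gene_mutation_rate <- function(gene, table, frameshift_uplift = 1.25,
                               splice_context = "ACT", possible = NULL) {
  stopifnot(inherits(gene, "gene_model"), inherits(table, "mu_table"))
  if (frameshift_uplift <= 0) stopf("frameshift_uplift must be positive")
  if (is.null(possible)) possible <- enumerate_possible_variants(gene)
  stopg <- possible[possible$consequence == "stop_gained", ]
  u_stop <- if (nrow(stopg)) sum(variant_mu(table, stopg$context, stopg$ref,
                                            stopg$alt, stopg$methylation_tier)) else 0
  u_splice <- 0
  if (gene$splice_site_count > 0L) {
    mid <- substr(normalize_context(splice_context, "A")$context, 2L, 2L)
    alts <- DNA_BASES[DNA_BASES != mid]
    u_splice <- gene$splice_site_count *
      sum(mu_rate(table, rep(splice_context, 3L), alts, "none"))
  }
  frameshift_uplift * (u_stop + u_splice)
}

#' @rdname gene_mutation_rate
#' @export
set_gene_rate <- function(gene, table, frameshift_uplift = 1.25,
                          splice_context = "ACT", possible = NULL) {
  gene$U_plof <- gene_mutation_rate(gene, table, frameshift_uplift,
                                    splice_context, possible)
  gene
}

#' Saturation survey of observed versus possible variants
#'
#' Tallies, per consequence class and per context stratum, how many of the
#' possible single-nucleotide substitutions have actually been observed in
#' the cohort — the "saturation" of the mutational target.  Strata are CpG
#' methylation tiers (non-CpG positions pooled as `nonCpG`); an `all`
#' stratum row per class is always included.  Classes surveyed are
#' synonymous, missense and stop-gained.
#'
#' @param observed data frame of observed variants with columns `gene_id`,
#'   `pos`, `ref`, `alt` (coding substitutions of the supplied genes).
#' @param genes list of [gene_model()] objects.
#' @param possible optional pre-computed enumeration (rbind over genes).
#' @return data frame with columns `class`, `stratum`, `n_possible`,
#'   `n_observed`, `fraction`.
#' @export
saturation_survey <- function(observed, genes, possible = NULL) {
  if (is.null(possible))
    possible <- do.call(rbind, lapply(genes, enumerate_possible_variants))
  pkey <- paste(possible$gene_id, possible$pos, possible$ref, possible$alt)
  okey <- unique(paste(observed$gene_id, observed$pos, observed$ref, observed$alt))
  hit <- match(okey, pkey)
  if (anyNA(hit))
    stopf("%d observed variant(s) are not possible under the supplied gene models (e.g. %s); gene models and sites are inconsistent",
          sum(is.na(hit)), okey[which(is.na(hit))[1L]])
  possible$observed <- pkey %in% okey
  keep <- possible$consequence %in% SURVEY_CLASSES
  possible <- possible[keep, ]
  is_cpg <- substr(possible$context, 2L, 3L) == "CG"
  possible$stratum <- ifelse(is_cpg, paste0("CpG_", possible$methylation_tier), "nonCpG")

  tally <- function(df, stratum_label) {
    agg_n <- stats::aggregate(list(n_possible = df$observed),
                              by = list(class = df$consequence), FUN = length)
    agg_o <- stats::aggregate(list(n_observed = df$observed),
                              by = list(class = df$consequence), FUN = sum)
    out <- merge(agg_n, agg_o, by = "class")
    out$stratum <- stratum_label
    out
  }
  res <- do.call(rbind, lapply(split(possible, possible$stratum),
                               function(df) tally(df, df$stratum[1L])))
  res <- rbind(res, tally(possible, "all"))
  res$fraction <- ifelse(res$n_possible > 0, res$n_observed / res$n_possible, NA_real_)
  res <- res[order(res$class, res$stratum), c("class", "stratum", "n_possible",
                                              "n_observed", "fraction")]
  rownames(res) <- NULL
  res
}
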