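#' Detect biallelic pLOF carriers (putative knockouts)
#'
#' Per gene, a sample is a biallelic carrier when it harbours at least one
#' rare homozygous pLOF genotype, or two rare heterozygous pLOF variants
#' phased to opposite haplotype sides within a shared phase block (in
#' trans, i.e. a compound heterozygote).  Samples with two or more rare het
#' pLOFs whose phase does not establish trans (unphased, different blocks,
#' or all in cis) are tallied separately as potential compound hets and do
#' not contribute to the knockout flag.
#'
#' @param calls genotype calls data frame: `sample_id`, `gene_id`, `pos`,
#'   `ref`, `alt`, `zygosity` (`het`/`hom_alt`), `phase_block` (NA when
#'   unphased), `hap_side` (1/2, NA when unphased).
#' @param variants sites data frame with `gene_id`, `pos`, `ref`, `alt`,
#'   `consequence`, `AC`, `AN` used to restrict to rare pLOF variants.
#' @param aaf_cutoff rarity cutoff on AAF (default 0.01, strict).
#' @return data frame (one row per gene with at least one carrier or
#'   potential carrier): `gene_id`, `n_hom_carriers`, `n_comphet_carriers`,
#'   `n_total_biallelic`, `n_potential_comphet`, `pko_flag`.
#' @export
find_biallelic <- function(calls, variants, aaf_cutoff = 0.01) {
  vkey <- paste(variants$gene_id, variants$pos, variants$ref, variants$alt)
  rare_plof <- vkey[is_plof(variants$consequence) &
                      variants$AC / variants$AN < aaf_cutoff]
  ckey <- paste(calls$gene_id, calls$pos, calls$ref, calls$alt)
  dup <- paste(calls$sample_id, ckey)
  if (anyDuplicated(dup)) {
    d <- calls[dup %in% dup[duplicated(dup)], ]
    zyg <- stats::aggregate(list(k = d$zygosity),
                            by = list(key = paste(d$sample_id, d$gene_id, d$pos,
                                                  d$ref, d$alt)),
                            FUN = function(z) length(unique(z)))
    if (any(zyg$k > 1L))
      stopf("inconsistent zygosity for duplicated (sample, variant) pair: %s",
            zyg$key[zyg$k > 1L][1L])
    calls <- calls[!duplicated(dup), ]
    ckey <- paste(calls$gene_id, calls$pos, calls$ref, calls$alt)
  }
  calls <- calls[ckey %in% rare_plof, , drop = FALSE]
  if (nrow(calls) == 0L)
    return(data.frame(gene_id = character(), n_hom_carriers = integer(),
                      n_comphet_carriers = integer(),
                      n_total_biallelic = integer(),
                      n_potential_comphet = integer(), pko_flag = logical(),
                      stringsAsFactors = FALSE))

  grp <- split(calls, list(calls$gene_id, calls$sample_id), drop = TRUE)
  status <- vapply(grp, function(g) {
    if (any(g$zygosity == "hom_alt")) return("hom")
    het <- g[g$zygosity == "het", , drop = FALSE]
    if (nrow(het) < 2L) return("none")
    # pairwise: trans needs opposite sides in a shared phase block; a pair
    # with unknown relative phase is only "potential"; known-cis pairs count
    # as nothing
    any_unknown <- FALSE
    for (i in seq_len(nrow(het) - 1L)) for (j in (i + 1L):nrow(het)) {
      bi <- het$phase_block[i]; bj <- het$phase_block[j]
      si <- het$hap_side[i]; sj <- het$hap_side[j]
      if (!is.na(bi) && !is.na(bj) && bi == bj && !is.na(si) && !is.na(sj)) {
        if (si != sj) return("comphet")
      } else {
        any_unknown <- TRUE
      }
    }
    if (any_unknown) "potential" else "none"
  }, "")
  gene_of <- vapply(grp, function(g) g$gene_id[1L], "")
  tab <- data.frame(gene_id = gene_of, status = status, stringsAsFactors = FALSE)
  count <- function(st) {
    t <- table(tab$gene_id[tab$status == st])
    function(g) as.integer(ifelse(is.na(t[g]), 0L, t[g]))
  }
  genes <- sort(unique(tab$gene_id[tab$status != "none"]))
  n_hom <- count("hom")(genes)
  n_ch <- count("comphet")(genes)
  n_pot <- count("potential")(genes)
  out <- data.frame(gene_id = genes, n_hom_carriers = n_hom,
                    n_comphet_carriers = n_ch,
                    n_total_biallelic = n_hom + n_ch,
                    n_potential_comphet = n_pot,
                    pko_flag = (n_hom + n_ch) >= 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Doubleton homozygote bookkeeping per functional class
#'
#' For each functional class, counts doubleton variants (cohort allele count
#' exactly 2) and how many are carried as a single homozygote, and compares
#' with the Hardy-Weinberg expectation `D / (2N - 1)` — the probability that
#' the two copies of a doubleton land in the same individual under random
#' placement, summed over doubletons.
#'
#' @param variants sites data frame with `consequence`, `AC`, `n_hom`.
#' @param N cohort size (diploid individuals).
#' @param classes named list mapping class label to consequence values;
#'   defaults to missense, synonymous and pLOF.
#' @return data frame (class `doubleton_summary`): `class`, `D`, `hom_obs`,
#'   `e_hwe`, `N`.
#' @export
doubleton_summary <- function(variants, N,
                              classes = list(missense = "missense",
                                             synonymous = "synonymous",
                                             plof = PLOF_CLASSES)) {
  if (!all(c("consequence", "AC", "n_hom") %in% names(variants)))
    stopf("variants need columns consequence, AC, n_hom")
  bad <- variants$AC == 2 & variants$n_hom > 1
  if (any(bad, na.rm = TRUE))
    stopf("doubleton with more than one homozygote (row %d); AC and n_hom are inconsistent",
          which(bad)[1L])
  rows <- lapply(names(classes), function(cl) {
    v <- variants[variants$consequence %in% classes[[cl]] & variants$AC == 2, ]
    data.frame(class = cl, D = nrow(v), hom_obs = sum(v$n_hom),
               e_hwe = nrow(v) / (2 * N - 1), N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("doubleton_summary", "data.frame")
  out
}

#' Build a doubleton summary from pre-tallied counts
#'
#' For worked examples where the per-class doubleton and homozygote counts
#' are supplied directly (e.g. from a published table) rather than from a
#' sites table.
#'
#' @param class character vector of class labels.
#' @param D doubleton counts per class.
#' @param hom_obs observed homozygous-doubleton counts per class.
#' @param N cohort size.
#' @return `doubleton_summary` data frame.
#' @export
doubleton_counts <- function(class, D, hom_obs, N) {
  stopifnot(length(class) == length(D), length(D) == length(hom_obs),
            all(hom_obs >= 0), all(hom_obs <= D))
  out <- data.frame(class = class, D = D, hom_obs = hom_obs,
                    e_hwe = D / (2 * N - 1), N = N, stringsAsFactors = FALSE)
  class(out) <- c("doubleton_summary", "data.frame")
  out
}

#' Background inbreeding coefficient from reference classes
#'
#' The pooled fraction of doubletons observed as homozygotes across the
#' reference classes (missense and synonymous in routine use):
#' `F = sum(hom_obs) / sum(D)`.  Attributed to population structure and
#' background inbreeding.
#'
#' @param summaries `doubleton_summary` rows for the reference classes.
#' @return the coefficient F (numeric scalar).
#' @export
estimate_inbreeding <- function(summaries) {
  D <- sum(summaries$D)
  if (D <= 0) stopf("pooled doubleton count is zero; cannot estimate F")
  sum(summaries$hom_obs) / D
}

#' Homozygote-deficit test for a target class
#'
#' Compares the observed homozygous-doubleton count of a target class with
#' the count expected under the background inbreeding coefficient F.  The
#' default expectation is `e_f = F * D` (the direct inbreeding term, which
#' dominates); `mode = "full"` adds the random-pairing Hardy-Weinberg term,
#' `e_f = (F + (1 - F)/(2N - 1)) * D`.  The deficit `1 - hom_obs/e_f`
#' measures homozygotes missing from the cohort relative to that
#' expectation.  Significance is a two-sided Fisher's exact test of the
#' homozygous fraction in the target versus the pooled reference classes.
#'
#' @param target one `doubleton_summary` row.
#' @param F inbreeding coefficient in [0, 1].
#' @param reference `doubleton_summary` rows pooled as comparator.
#' @param mode `"direct"` (default) or `"full"`.
#' @return list `e_f`, `deficit`, `p_value`.
#' @export
homozygote_deficit_test <- function(target, F, reference,
                                    mode = c("direct", "full")) {
  mode <- match.arg(mode)
  if (F < 0 || F > 1) stopf("F must lie in [0, 1]")
  rate <- if (mode == "direct") F else F + (1 - F) / (2 * target$N - 1)
  e_f <- rate * target$D
  deficit <- if (e_f > 0) 1 - target$hom_obs / e_f
             else if (target$hom_obs > 0) -Inf else 0
  tab <- matrix(c(target$hom_obs, target$D - target$hom_obs,
                  sum(reference$hom_obs), sum(reference$D) - sum(reference$hom_obs)),
                nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(e_f = e_f, deficit = deficit, p_value = p)
}

#' Projected accrual of knockout genes at hypothetical cohort sizes
#'
#' Given per-gene carrier counts `C_g` in a full cohort of `N_total`
#' individuals, the expected number of genes with at least `k` carriers in
#' a random subsample of size `n` is computed exactly from the
#' hypergeometric distribution:
#' `E[genes] = sum_g (1 - HypergeomCDF(k - 1; N_total, C_g, n))`.
#'
#' @param carriers integer vector of carrier counts per gene.
#' @param N_total full cohort size.
#' @param sizes subsample sizes to evaluate (each `<= N_total`).
#' @param k_values carrier-count thresholds (default 1, 5, 10).
#' @return data frame: `n`, `k`, `expected_genes`.
#' @export
project_accrual <- function(carriers, N_total, sizes, k_values = c(1L, 5L, 10L)) {
  if (any(carriers < 0) || any(carriers > N_total))
    stopf("carrier counts must lie in [0, N_total]")
  if (any(sizes > N_total) || any(sizes < 0))
    stopf("subsample sizes must lie in [0, N_total]")
  grid <- expand.grid(n = sizes, k = k_values, KEEP.OUT.ATTRS = FALSE)
  grid$expected_genes <- mapply(function(n, k) {
    sum(stats::phyper(k - 1, carriers, N_total - carriers, n,
                      lower.tail = FALSE))
  }, grid$n, grid$k)
  grid
}
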