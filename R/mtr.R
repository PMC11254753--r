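#' Missense tolerance ratio
#'
#' Ratio of the observed to the expected proportion of missense variants in
#' a codon window, adjusted by synonymous variation:
#' `(obs_mis/(obs_mis+obs_syn)) / (exp_mis/(exp_mis+exp_syn))`.
#' `NA` when no variants were observed in the window (the window is not
#' scored) or when the expected denominator is empty.
#'
#' @param obs_mis,obs_syn distinct observed missense/synonymous variants in
#'   the window.
#' @param exp_mis,exp_syn possible missense/synonymous substitution counts
#'   in the window.
#' @return numeric vector of ratios.
#' @export
mtr_value <- function(obs_mis, obs_syn, exp_mis, exp_syn) {
  if (any(c(obs_mis, obs_syn, exp_mis, exp_syn) < 0, na.rm = TRUE))
    stopf("counts must be non-negative")
  obs_n <- obs_mis + obs_syn
  exp_n <- exp_mis + exp_syn
  out <- rep(NA_real_, length(obs_n))
  ok <- obs_n > 0 & exp_n > 0 & exp_mis > 0
  out[ok] <- (obs_mis[ok] / obs_n[ok]) / (exp_mis[ok] / exp_n[ok])
  out
}

#' Per-codon MTR track of one gene
#'
#' Scores every codon of the CDS with the MTR of a sliding window of `w`
#' codons centered on it; windows are truncated (not dropped) at the protein
#' termini.  Observed variants are deduplicated to distinct
#' (position, ref, alt) and restricted to synonymous and missense classes,
#' as are the possible-variant counts.
#'
#' @param gene a [gene_model()].
#' @param variants observed sites data frame (columns `gene_id`, `pos`,
#'   `ref`, `alt`, `consequence`).
#' @param possible optional pre-computed [enumerate_possible_variants()].
#' @param w window width in codons, odd (21 or 31 in routine use).
#' @param rate_table optional `mu_table`; when supplied, expected counts are
#'   weighted by each possible variant's mutation rate instead of counting
#'   sites equally.  The unweighted proportion is the original MTR
#'   convention and the default; the weighted mode compensates for
#'   class-composition differences in mutability (e.g. CpG transitions
#'   enriched at synonymous positions).
#' @return data frame (class `mtr_track`): `gene_id`, `codon`, `obs_mis`,
#'   `obs_syn`, `exp_mis`, `exp_syn`, `mtr`, and placeholder columns `p`,
#'   `q`, `significant`, `percentile` filled by [mtr_fdr()] and
#'   [exome_percentiles()].
#' @export
compute_mtr_track <- function(gene, variants, possible = NULL, w = 31L,
                              rate_table = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  if (w %% 2L == 0L) stopf("window width w must be odd (got %d)", w)
  if (is.null(possible)) possible <- enumerate_possible_variants(gene)
  L <- gene$codon_count

  obs <- variants[variants$gene_id == gene$gene_id &
                    variants$consequence %in% c("synonymous", "missense"), ,
                  drop = FALSE]
  obs <- obs[!duplicated(paste(obs$pos, obs$ref, obs$alt)), , drop = FALSE]
  if (nrow(obs) && (any(obs$pos < 1L) || any(obs$pos > 3L * L)))
    stopf("observed variant position outside the CDS of %s", gene$gene_id)
  obs_codon <- (obs$pos - 1L) %/% 3L + 1L

  per_codon <- function(codon_idx, keep, wts = NULL) {
    if (is.null(wts)) return(tabulate(codon_idx[keep], nbins = L))
    out <- numeric(L)
    agg <- rowsum(wts[keep], codon_idx[keep])
    out[as.integer(rownames(agg))] <- agg
    out
  }
  c_obs_mis <- per_codon(obs_codon, obs$consequence == "missense")
  c_obs_syn <- per_codon(obs_codon, obs$consequence == "synonymous")
  pw <- NULL
  if (!is.null(rate_table)) {
    pw <- variant_mu(rate_table, possible$context, possible$ref,
                     possible$alt, possible$methylation_tier)
    pw <- pw / mean(pw)  # proportions are scale-free; keep counts comparable
  }
  c_exp_mis <- per_codon(possible$codon, possible$consequence == "missense", pw)
  c_exp_syn <- per_codon(possible$codon, possible$consequence == "synonymous", pw)

  h <- (w - 1L) %/% 2L
  win_sum <- function(v) {
    cs <- c(0, cumsum(v))
    i <- seq_len(L)
    cs[pmin(i + h, L) + 1L] - cs[pmax(i - h, 1L)]
  }
  obs_mis <- win_sum(c_obs_mis); obs_syn <- win_sum(c_obs_syn)
  exp_mis <- win_sum(c_exp_mis); exp_syn <- win_sum(c_exp_syn)

  structure(data.frame(gene_id = gene$gene_id, codon = seq_len(L),
                       obs_mis = obs_mis, obs_syn = obs_syn,
                       exp_mis = exp_mis, exp_syn = exp_syn,
                       mtr = mtr_value(obs_mis, obs_syn, exp_mis, exp_syn),
                       p = NA_real_, q = NA_real_, significant = NA,
                       percentile = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("mtr_track", "data.frame"))
}

#' Exome-wide FDR for missense depletion
#'
#' Per scored codon, a one-sided binomial test of missense depletion:
#' `p = P(K <= obs_mis | n = obs_mis + obs_syn, p0 = exp_mis/(exp_mis+exp_syn))`,
#' followed by Benjamini-Hochberg adjustment across all scored codons of all
#' supplied tracks (exome-wide, not per gene).
#'
#' @param tracks one `mtr_track` or several rbind-ed together.
#' @param alpha FDR significance level (default 0.1).
#' @return the tracks with `p`, `q` and `significant = (q < alpha)` filled
#'   for scored codons.
#' @export
mtr_fdr <- function(tracks, alpha = 0.1) {
  if (nrow(tracks) == 0L) return(tracks)
  scored <- !is.na(tracks$mtr)
  n <- tracks$obs_mis + tracks$obs_syn
  p0 <- tracks$exp_mis / (tracks$exp_mis + tracks$exp_syn)
  p <- rep(NA_real_, nrow(tracks))
  p[scored] <- stats::pbinom(tracks$obs_mis[scored], n[scored], p0[scored])
  q <- rep(NA_real_, nrow(tracks))
  q[scored] <- stats::p.adjust(p[scored], method = "BH")
  tracks$p <- p
  tracks$q <- q
  tracks$significant <- q < alpha
  tracks
}

#' Exome-wide MTR percentiles and threshold map
#'
#' Assigns each scored codon its percentile rank among all scored codons
#' (ascending: low MTR, i.e. strong missense depletion, gets a low
#' percentile; ties receive average rank), and reports the MTR value at the
#' requested percentiles as the threshold map.
#'
#' @param tracks rbind-ed `mtr_track` rows.
#' @param probs percentiles (in percent) to report thresholds for.
#' @return list with `tracks` (percentile column filled) and `thresholds`
#'   (named numeric: MTR cutoff at each requested percentile, the
#'   order-statistic quantile).
#' @export
exome_percentiles <- function(tracks, probs = c(1, 5, 10, 15, 20)) {
  scored <- !is.na(tracks$mtr)
  if (!any(scored)) stopf("no scored codons; cannot rank")
  v <- tracks$mtr[scored]
  tracks$percentile[scored] <- 100 * rank(v, ties.method = "average") / length(v)
  thresholds <- stats::quantile(v, probs / 100, type = 1, names = FALSE)
  names(thresholds) <- paste0("p", probs)
  list(tracks = tracks, thresholds = thresholds)
}

#' Segment constrained regions from a percentile-ranked track
#'
#' Maximal runs of consecutive codons whose exome-wide percentile is at or
#' below the cutoff; runs separated by at most `max_gap` non-qualifying
#' codons are merged (bridged codons are included in the region); merged
#' runs shorter than `min_length` codons are dropped.
#'
#' @param track one gene's `mtr_track` with percentiles assigned.
#' @param percentile_cutoff qualifying percentile (default 15).
#' @param min_length minimum region length in codons (default 5).
#' @param max_gap maximum bridged gap in codons (default 0).
#' @return data frame of regions: `gene_id`, `start_codon`, `end_codon`,
#'   `length`, `mean_mtr`, `min_mtr`.
#' @export
segment_regions <- function(track, percentile_cutoff = 15, min_length = 5L,
                            max_gap = 0L) {
  empty <- data.frame(gene_id = character(), start_codon = integer(),
                      end_codon = integer(), length = integer(),
                      mean_mtr = numeric(), min_mtr = numeric(),
                      stringsAsFactors = FALSE)
  qual <- which(!is.na(track$percentile) & track$percentile <= percentile_cutoff)
  if (length(qual) == 0L) return(empty)
  grp <- cumsum(c(1L, diff(qual) > max_gap + 1L))
  pieces <- lapply(split(qual, grp), function(idx) {
    start <- min(idx); end <- max(idx)
    if (end - start + 1L < min_length) return(NULL)
    m <- track$mtr[start:end]
    data.frame(gene_id = track$gene_id[1L], start_codon = start,
               end_codon = end, length = end - start + 1L,
               mean_mtr = mean(m, na.rm = TRUE),
               min_mtr = suppressWarnings(min(m, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Gene-level missense-constraint binomial test
#'
#' Tests whether a gene holds more codons in the exome-wide most-constrained
#' percentile band than expected: with `k` scored codons at percentile
#' `<= percentile_cutoff` out of `n` scored codons, the one-sided upper-tail
#' binomial p-value `P(K >= k | n, pi0)`.  Multiple-testing correction over
#' a gene set is the caller's responsibility (Bonferroni in routine use).
#'
#' @param track one gene's `mtr_track` with percentiles assigned.
#' @param pi0 null proportion (default 0.15, matching the 15th-percentile
#'   band).
#' @param percentile_cutoff percentile band counted (default 15).
#' @return list `k`, `n`, `p_value` (`NA` when no codon is scored).
#' @export
gene_constraint_test <- function(track, pi0 = 0.15, percentile_cutoff = 15) {
  scored <- !is.na(track$percentile)
  n <- sum(scored)
  if (n == 0L) return(list(k = 0L, n = 0L, p_value = NA_real_))
  k <- sum(track$percentile[scored] <= percentile_cutoff)
  p <- stats::pbinom(k - 1L, n, pi0, lower.tail = FALSE)
  list(k = k, n = n, p_value = p)
}

#' MTR tracks, FDR, percentiles and regions for a whole sites table
#'
#' Convenience wrapper: computes per-gene tracks at width `w`, applies
#' exome-wide FDR and percentile ranking, and segments constrained regions
#' per gene.  By default all scored codons are ranked and the FDR flag is
#' reported alongside; `fdr_gates_ranking = TRUE` restricts percentile
#' ranking to FDR-passing codons instead.
#'
#' @param genes list of [gene_model()] objects.
#' @param sites observed sites data frame.
#' @param w window width (odd).
#' @param alpha FDR level.
#' @param percentile_cutoff,min_length,max_gap segmentation parameters.
#' @param fdr_gates_ranking if `TRUE`, only FDR-significant codons are
#'   percentile-ranked (alternative reading of the significance filter).
#' @param possible optional named list of pre-computed enumerations.
#' @return list with `tracks`, `thresholds`, `regions`, `gene_tests`.
#' @export
mtr_analysis <- function(genes, sites, w = 31L, alpha = 0.1,
                         percentile_cutoff = 15, min_length = 5L, max_gap = 0L,
                         fdr_gates_ranking = FALSE, possible = NULL,
                         rate_table = NULL) {
  tracks <- do.call(rbind, lapply(genes, function(g)
    compute_mtr_track(g, sites, possible = possible[[g$gene_id]], w = w,
                      rate_table = rate_table)))
  tracks <- mtr_fdr(tracks, alpha)
  if (fdr_gates_ranking) {
    gated <- tracks
    gated$mtr[!gated$significant %in% TRUE] <- NA_real_
    pct <- exome_percentiles(gated)
    tracks$percentile <- pct$tracks$percentile
  } else {
    pct <- exome_percentiles(tracks)
    tracks <- pct$tracks
  }
  per_gene <- split(tracks, tracks$gene_id)
  regions <- do.call(rbind, lapply(per_gene, segment_regions,
                                   percentile_cutoff = percentile_cutoff,
                                   min_length = min_length, max_gap = max_gap))
  rownames(regions) <- NULL
  gt <- do.call(rbind, lapply(per_gene, function(tr) {
    res <- gene_constraint_test(tr, pi0 = percentile_cutoff / 100,
                                percentile_cutoff = percentile_cutoff)
    data.frame(gene_id = tr$gene_id[1L], k = res$k, n = res$n,
               p_value = res$p_value, stringsAsFactors = FALSE)
  }))
  gt$p_bonferroni <- pmin(1, gt$p_value * nrow(gt))
  rownames(gt) <- NULL
  list(tracks = tracks, thresholds = pct$thresholds,
       regions = regions, gene_tests = gt)
}
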