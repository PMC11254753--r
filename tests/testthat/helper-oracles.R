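# Brute-force oracles, deliberately independent of the package's code paths.

# Classify a substitution by translating the whole mutant CDS with
# Biostrings and comparing proteins position by position.
oracle_classify <- function(cds, pos, alt) {
  L <- nchar(cds) %/% 3L
  mut <- cds
  substr(mut, pos, pos) <- alt
  codon_idx <- (pos - 1L) %/% 3L + 1L
  if (codon_idx == 1L) return("start_loss")
  ref_aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE)), "")[[1]]
  mut_aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(mut), no.init.codon = TRUE)), "")[[1]]
  ra <- ref_aa[codon_idx]; ma <- mut_aa[codon_idx]
  if (codon_idx == L) {
    if (ma == "*") return("synonymous") else return("stop_loss")
  }
  if (ma == "*") return("stop_gained")
  if (ma == ra) return("synonymous")
  "missense"
}

# Window recount: per codon, count observed/possible syn and mis variants
# whose codon falls in the truncated window, by explicit looping.
oracle_window_counts <- function(L, obs_codon, obs_class, poss_codon,
                                 poss_class, w) {
  h <- (w - 1L) %/% 2L
  out <- matrix(0L, nrow = L, ncol = 4L,
                dimnames = list(NULL, c("obs_mis", "obs_syn", "exp_mis", "exp_syn")))
  for (i in seq_len(L)) {
    lo <- max(1L, i - h); hi <- min(L, i + h)
    in_obs <- obs_codon >= lo & obs_codon <= hi
    in_poss <- poss_codon >= lo & poss_codon <= hi
    out[i, ] <- c(sum(in_obs & obs_class == "missense"),
                  sum(in_obs & obs_class == "synonymous"),
                  sum(in_poss & poss_class == "missense"),
                  sum(in_poss & poss_class == "synonymous"))
  }
  out
}

# Run-length segmentation by explicit scanning.
oracle_runs <- function(qual, max_gap, min_length) {
  regions <- list()
  cur_start <- NA_integer_; cur_end <- NA_integer_
  idx <- which(qual)
  for (i in idx) {
    if (is.na(cur_start)) {
      cur_start <- i; cur_end <- i
    } else if (i - cur_end - 1L <= max_gap) {
      cur_end <- i
    } else {
      regions[[length(regions) + 1L]] <- c(cur_start, cur_end)
      cur_start <- i; cur_end <- i
    }
  }
  if (!is.na(cur_start)) regions[[length(regions) + 1L]] <- c(cur_start, cur_end)
  keep <- vapply(regions, function(r) r[2L] - r[1L] + 1L >= min_length, TRUE)
  regions[keep]
}

# Per-sample biallelic scan.
oracle_biallelic_status <- function(sample_calls) {
  if (any(sample_calls$zygosity == "hom_alt")) return("hom")
  het <- sample_calls[sample_calls$zygosity == "het", , drop = FALSE]
  if (nrow(het) < 2L) return("none")
  trans <- FALSE; unknown <- FALSE
  for (i in seq_len(nrow(het) - 1L)) for (j in (i + 1L):nrow(het)) {
    bi <- het$phase_block[i]; bj <- het$phase_block[j]
    si <- het$hap_side[i]; sj <- het$hap_side[j]
    resolved <- !is.na(bi) && !is.na(bj) && bi == bj && !is.na(si) && !is.na(sj)
    if (resolved && si != sj) trans <- TRUE
    if (!resolved) unknown <- TRUE
  }
  if (trans) "comphet" else if (unknown) "potential" else "none"
}

# Expected gene accrual by direct combinatorial summation.
oracle_accrual <- function(carriers, N_total, n, k) {
  per_gene <- vapply(carriers, function(C) {
    if (k > min(C, n)) return(0)
    js <- k:min(C, n)
    sum(exp(lchoose(C, js) + lchoose(N_total - C, n - js) - lchoose(N_total, n)))
  }, 0)
  sum(per_gene)
}

# Weighted least squares through the normal equations.
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1L]
}

# Independent grid-posterior summary: direct normalization, exhaustive
# O(n^2) search for the smallest contiguous HPD window.
oracle_shet_summary <- function(X, AN, U, grid, prior_mass, mass = 0.95) {
  lik <- stats::dpois(X, pmax(AN * U / grid, 1e-12))
  post <- prior_mass * lik
  post <- post / sum(post)
  best <- NULL; best_len <- Inf
  for (i in seq_along(grid)) {
    acc <- 0
    for (j in i:length(grid)) {
      acc <- acc + post[j]
      if (acc >= mass) {
        if (j - i + 1L < best_len) { best <- c(i, j); best_len <- j - i + 1L }
        break
      }
    }
  }
  list(mean = sum(grid * post),
       median = grid[which(cumsum(post) >= 0.5)[1L]],
       hpd = c(grid[best[1L]], grid[best[2L]]))
}

# Small sites-table builder for handwritten cases.
make_sites <- function(...) {
  rows <- list(...)
  defaults <- list(gene_id = "g1", transcript_id = "t1", pos = 4L, ref = "A",
                   alt = "T", consequence = "missense", context = "ATA",
                   methylation_tier = "none", AC = 1L, AN = 1000L,
                   n_hom = 0L, spliceai = 0, mmsplice = 0,
                   pred_del_count = NA_integer_, mu = 1e-8)
  do.call(rbind, lapply(rows, function(r) {
    row <- utils::modifyList(defaults, r)
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
}

random_test_cds <- function(L) {
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- c("TAA", "TAG", "TGA")
  paste0("ATG", paste(sample(setdiff(codons, stops), L - 2L, replace = TRUE),
                      collapse = ""), sample(stops, 1L))
}
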