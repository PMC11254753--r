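test_that("the tolerance ratio follows its defining arithmetic", {
  expect_equal(mtr_value(5, 5, 10, 10), 1.0)
  expect_equal(mtr_value(2, 8, 15, 10), (0.2) / (0.6))
  expect_equal(mtr_value(0, 4, 9, 3), 0)
  expect_true(is.na(mtr_value(0, 0, 9, 3)))   # unscored window
  expect_true(is.na(mtr_value(3, 1, 0, 0)))
  expect_error(mtr_value(-1, 0, 1, 1), "non-negative")
})

test_that("windows truncate at the termini and short genes collapse to one window", {
  g <- gene_model("g1", "t1", random_test_cds(9L))
  sites <- make_sites(list(pos = 10L, ref = substr(g$cds, 10, 10),
                           consequence = "missense"),
                      list(pos = 16L, ref = substr(g$cds, 16, 16),
                           consequence = "synonymous"))
  tr <- compute_mtr_track(g, sites, w = 31L)
  expect_equal(nrow(tr), 9L)
  expect_true(all(tr$obs_mis == tr$obs_mis[1]))  # whole gene in every window
  expect_equal(length(unique(tr$mtr)), 1L)

  none <- compute_mtr_track(g, sites[0, ], w = 31L)
  expect_true(all(is.na(none$mtr)))
  expect_error(compute_mtr_track(g, sites, w = 30L), "odd")
})

test_that("window counts equal a brute-force recount on a depleted toy gene", {
  set.seed(61)
  g <- gene_model("g1", "t1", random_test_cds(60L))
  pv <- enumerate_possible_variants(g)
  core <- pv[pv$consequence %in% c("missense", "synonymous"), ]
  # observe a thinned sample, with missense depleted in codons 25..40
  keep <- runif(nrow(core)) < ifelse(core$consequence == "missense" &
                                       core$codon >= 25 & core$codon <= 40,
                                     0.05, 0.35)
  obs <- core[keep, ]
  obs$gene_id <- "g1"; obs$AC <- 1L; obs$AN <- 1000L
  for (w in c(21L, 31L)) {
    tr <- compute_mtr_track(g, obs, w = w)
    orc <- oracle_window_counts(60L, obs$codon, obs$consequence,
                                core$codon, core$consequence, w)
    expect_equal(tr$obs_mis, unname(orc[, "obs_mis"]))
    expect_equal(tr$obs_syn, unname(orc[, "obs_syn"]))
    expect_equal(tr$exp_mis, unname(orc[, "exp_mis"]))
    expect_equal(tr$exp_syn, unname(orc[, "exp_syn"]))
  }
})

test_that("duplicate observed variants are counted once", {
  g <- gene_model("g1", "t1", random_test_cds(9L))
  pv <- enumerate_possible_variants(g)
  mis <- pv[pv$consequence == "missense", ][1, ]
  twice <- rbind(mis, mis)
  twice$gene_id <- "g1"
  tr <- compute_mtr_track(g, twice, w = 31L)
  expect_equal(max(tr$obs_mis), 1L)
})

test_that("depletion p-values follow the one-sided binomial and control FDR", {
  tr <- data.frame(gene_id = "g", codon = 1:2,
                   obs_mis = c(15L, 0L), obs_syn = c(5L, 30L),
                   exp_mis = c(30L, 30L), exp_syn = c(10L, 10L),
                   mtr = c(1, 0), p = NA_real_, q = NA_real_,
                   significant = NA, percentile = NA_real_)
  out <- mtr_fdr(tr, alpha = 0.1)
  expect_gte(out$p[1], 0.5)              # exactly at expectation
  expect_equal(out$p[2], 0.25^30)        # all-synonymous window, p0 = 0.75
  expect_true(out$significant[2])
  expect_false(out$significant[1])

  # null tracks: flagged fraction stays within the nominal level
  set.seed(62)
  n <- 2000L
  null_tr <- data.frame(gene_id = "g", codon = seq_len(n),
                        obs_mis = rbinom(n, 40, 0.75), obs_syn = 0L,
                        exp_mis = 30L, exp_syn = 10L,
                        mtr = 1, p = NA_real_, q = NA_real_,
                        significant = NA, percentile = NA_real_)
  null_tr$obs_syn <- 40L - null_tr$obs_mis
  out <- mtr_fdr(null_tr, alpha = 0.1)
  expect_lte(mean(out$significant), 0.1)
})

test_that("percentile ranks and threshold map behave like a sort", {
  tied <- data.frame(gene_id = "g", codon = 1:4, obs_mis = 1L, obs_syn = 1L,
                     exp_mis = 1L, exp_syn = 1L, mtr = c(0.5, 0.5, 0.5, 0.5),
                     p = NA_real_, q = NA_real_, significant = NA,
                     percentile = NA_real_)
  res <- exome_percentiles(tied)
  expect_equal(length(unique(res$tracks$percentile)), 1L)

  set.seed(63)
  v <- sample(seq(0.01, 1, length.out = 100))
  tr <- data.frame(gene_id = "g", codon = seq_along(v), obs_mis = 1L,
                   obs_syn = 1L, exp_mis = 1L, exp_syn = 1L, mtr = v,
                   p = NA_real_, q = NA_real_, significant = NA,
                   percentile = NA_real_)
  res <- exome_percentiles(tr)
  expect_equal(res$tracks$percentile[which(rank(v) == 15)], 15)
  sorted <- sort(v)
  expect_equal(unname(res$thresholds),
               sorted[ceiling(c(1, 5, 10, 15, 20) / 100 * length(v))])
})

test_that("segmentation matches the run-length oracle on random tracks", {
  set.seed(64)
  for (i in 1:1000) {
    L <- sample(10:60, 1)
    pct <- runif(L, 0, 100)
    pct[sample(L, sample(0:3, 1))] <- NA
    max_gap <- sample(0:2, 1)
    min_length <- sample(1:6, 1)
    tr <- data.frame(gene_id = "g", codon = seq_len(L), obs_mis = 1L,
                     obs_syn = 1L, exp_mis = 1L, exp_syn = 1L,
                     mtr = pct / 100, p = NA_real_, q = NA_real_,
                     significant = NA, percentile = pct)
    got <- segment_regions(tr, percentile_cutoff = 15, min_length = min_length,
                           max_gap = max_gap)
    want <- oracle_runs(!is.na(pct) & pct <= 15, max_gap, min_length)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_codon, vapply(want, `[`, 0L, 1L))
      expect_equal(got$end_codon, vapply(want, `[`, 0L, 2L))
    }
  }
})

test_that("segmentation handles the boundary patterns directly", {
  base <- data.frame(gene_id = "g", codon = 1:21, obs_mis = 1L, obs_syn = 1L,
                     exp_mis = 1L, exp_syn = 1L, mtr = 0.1, p = NA_real_,
                     q = NA_real_, significant = NA, percentile = 1)
  whole <- segment_regions(base)
  expect_equal(nrow(whole), 1L)
  expect_equal(c(whole$start_codon, whole$end_codon), c(1L, 21L))

  base$percentile <- 99
  expect_equal(nrow(segment_regions(base)), 0L)

  base$percentile <- c(rep(1, 10), 99, rep(1, 10))  # pass(10) fail(1) pass(10)
  expect_equal(nrow(segment_regions(base, max_gap = 0)), 2L)
  merged <- segment_regions(base, max_gap = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$length, 21L)
})

test_that("the gene-level binomial test has its closed forms", {
  tr <- function(pct) data.frame(gene_id = "g", codon = seq_along(pct),
                                 obs_mis = 1L, obs_syn = 1L, exp_mis = 1L,
                                 exp_syn = 1L, mtr = 1, p = NA_real_,
                                 q = NA_real_, significant = NA,
                                 percentile = pct)
  res <- gene_constraint_test(tr(c(1, 2, 3)))
  expect_equal(res$p_value, 0.15^3)
  expect_equal(gene_constraint_test(tr(c(99, 99)))$p_value, 1)
  big <- gene_constraint_test(tr(c(rep(1, 150), rep(99, 850))))
  manual <- 1 - sum(dbinom(0:149, 1000, 0.15))
  expect_equal(big$p_value, manual)
  expect_gt(big$p_value, 0.4)
  expect_lt(big$p_value, 0.6)
  expect_true(is.na(gene_constraint_test(tr(NA_real_))$p_value))
})

test_that("more cohort depth yields more FDR-significant depleted codons", {
  count_sig <- function(N) {
    ex <- simulate_exome(sim_config(seed = 65, n_genes = 15,
                                    n_individuals = N, depletion_factor = 0.2))
    res <- mtr_analysis(ex$genes, ex$sites, w = 31)
    sum(res$tracks$significant, na.rm = TRUE)
  }
  n_small <- count_sig(400000L)
  n_big <- count_sig(800000L)
  expect_gt(n_big, n_small)
})
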