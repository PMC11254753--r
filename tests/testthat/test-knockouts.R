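rare_plof_variants <- function() {
  make_sites(
    list(pos = 4L, consequence = "stop_gained", AC = 5L, AN = 10000L),
    list(pos = 7L, consequence = "frameshift", AC = 3L, AN = 10000L),
    list(pos = 10L, consequence = "splice_donor", AC = 2L, AN = 10000L),
    list(pos = 13L, consequence = "stop_gained", AC = 500L, AN = 10000L),  # common
    list(pos = 16L, consequence = "missense", AC = 1L, AN = 10000L))
}

call_row <- function(sample, pos, zyg, block = NA_integer_, side = NA_integer_) {
  data.frame(sample_id = sample, gene_id = "g1", pos = pos, ref = "A",
             alt = "T", zygosity = zyg, phase_block = block, hap_side = side,
             stringsAsFactors = FALSE)
}

test_that("biallelic detection separates hom, trans, cis and unphased pairs", {
  vars <- rare_plof_variants()
  calls <- rbind(
    call_row("s_hom", 4L, "hom_alt"),
    call_row("s_trans", 4L, "het", 1L, 1L), call_row("s_trans", 7L, "het", 1L, 2L),
    call_row("s_cis", 4L, "het", 1L, 1L), call_row("s_cis", 7L, "het", 1L, 1L),
    call_row("s_unph", 4L, "het"), call_row("s_unph", 7L, "het"),
    call_row("s_common", 13L, "hom_alt"),       # fails the rarity filter
    call_row("s_mis", 16L, "hom_alt"))          # not a pLOF
  res <- find_biallelic(calls, vars, aaf_cutoff = 0.01)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_hom_carriers, 1L)
  expect_equal(res$n_comphet_carriers, 1L)
  expect_equal(res$n_total_biallelic, 2L)
  expect_equal(res$n_potential_comphet, 1L)     # unphased pair; cis pair is none
  expect_true(res$pko_flag)
})

test_that("inconsistent duplicate genotypes are an error, consistent ones collapse", {
  vars <- rare_plof_variants()
  dup_bad <- rbind(call_row("s1", 4L, "het", 1L, 1L),
                   call_row("s1", 4L, "hom_alt"))
  expect_error(find_biallelic(dup_bad, vars), "inconsistent zygosity")
  dup_ok <- rbind(call_row("s1", 4L, "hom_alt"), call_row("s1", 4L, "hom_alt"))
  res <- find_biallelic(dup_ok, vars)
  expect_equal(res$n_hom_carriers, 1L)
})

test_that("biallelic detection matches the per-sample oracle on random cohorts", {
  set.seed(81)
  vars <- rare_plof_variants()
  for (rep in 1:300) {
    n_calls <- sample(1:12, 1)
    calls <- data.frame(
      sample_id = sample(paste0("s", 1:4), n_calls, replace = TRUE),
      gene_id = "g1",
      pos = sample(c(4L, 7L, 10L, 13L, 16L), n_calls, replace = TRUE),
      ref = "A", alt = "T",
      zygosity = sample(c("het", "hom_alt"), n_calls, TRUE, prob = c(0.8, 0.2)),
      phase_block = sample(c(1L, 2L, NA), n_calls, TRUE),
      hap_side = sample(c(1L, 2L, NA), n_calls, TRUE),
      stringsAsFactors = FALSE)
    calls$hap_side[is.na(calls$phase_block)] <- NA
    calls <- calls[!duplicated(calls[, c("sample_id", "pos")]), , drop = FALSE]
    res <- find_biallelic(calls, vars)
    # oracle: restrict to rare pLOF keys, then scan each sample
    rare <- c(4L, 7L, 10L)
    kept <- calls[calls$pos %in% rare, , drop = FALSE]
    st <- vapply(split(kept, kept$sample_id),
                 oracle_biallelic_status, "")
    expect_equal(sum(res$n_hom_carriers), sum(st == "hom"),
                 info = paste("rep", rep))
    expect_equal(sum(res$n_comphet_carriers), sum(st == "comphet"))
    expect_equal(sum(res$n_potential_comphet), sum(st == "potential"))
  }
})

test_that("doubleton bookkeeping reproduces the worked cohort numbers", {
  ds <- doubleton_example()
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$D, c(1580917L, 679335L, 129405L))
  # Hardy-Weinberg expectation below one homozygote for every class
  expect_true(all(ds$e_hwe < 1))
  expect_equal(ds$e_hwe[ds$class == "missense"], 1580917 / (2 * 821979 - 1),
               tolerance = 1e-12)

  refcls <- ds[ds$class %in% c("missense", "synonymous"), ]
  F <- estimate_inbreeding(refcls)
  expect_equal(F, 8347 / 2260252, tolerance = 1e-12)
  expect_equal(round(100 * F, 2), 0.37)

  plof <- ds[ds$class == "plof", ]
  res <- homozygote_deficit_test(plof, 0.0037, refcls)
  expect_equal(round(res$e_f), 479)
  expect_equal(res$deficit, 1 - 406 / (0.0037 * 129405), tolerance = 1e-12)
  expect_gt(res$deficit, 0.10)
  expect_lt(res$deficit, 0.20)
  expect_lt(res$p_value, 0.05)
})

test_that("doubleton summaries tally classes from a sites table", {
  sites <- make_sites(
    list(consequence = "missense", AC = 2L, n_hom = 1L),
    list(pos = 5L, consequence = "missense", AC = 2L, n_hom = 0L),
    list(pos = 6L, consequence = "missense", AC = 3L, n_hom = 1L),  # not a doubleton
    list(pos = 7L, consequence = "synonymous", AC = 2L, n_hom = 0L),
    list(pos = 8L, consequence = "stop_gained", AC = 2L, n_hom = 0L))
  ds <- doubleton_summary(sites, N = 1000L)
  expect_equal(ds$D, c(2L, 1L, 1L))
  expect_equal(ds$hom_obs, c(1L, 0L, 0L))
  expect_equal(ds$e_hwe, c(2, 1, 1) / 1999)

  none <- doubleton_summary(sites[0, ], N = 1000L)
  expect_true(all(none$D == 0) && all(none$e_hwe == 0))

  bad <- make_sites(list(consequence = "missense", AC = 2L, n_hom = 2L))
  expect_error(doubleton_summary(bad, N = 1000L), "inconsistent")
  expect_error(estimate_inbreeding(none), "zero")
})

test_that("inbreeding is recovered from a simulated doubleton cohort", {
  dt <- simulate_doubletons(1e5, N = 821979L, F = 0.004, seed = 82)
  ds <- doubleton_summary(dt, N = 821979L)
  refcls <- ds[ds$class %in% c("missense", "synonymous"), ]
  Fhat <- estimate_inbreeding(refcls)
  expect_lt(abs(Fhat - 0.004) / 0.004, 0.10)
})

test_that("a null cohort shows no homozygote excess beyond Hardy-Weinberg", {
  N <- 5000L
  dt <- simulate_doubletons(2e4, N = N, F = 0, seed = 83)
  ds <- doubleton_summary(dt, N = N)
  tot_hom <- sum(ds$hom_obs); tot_e <- sum(ds$e_hwe)
  expect_lt(abs(tot_hom - tot_e), 3 * sqrt(tot_e) + 1)
})

test_that("deficit test edge cases behave", {
  ds <- doubleton_counts(c("a", "b"), c(1000L, 1000L), c(10L, 10L), 10000L)
  res <- homozygote_deficit_test(ds[1, ], F = 0.01, ds[2, ])
  expect_equal(res$e_f, 10)
  expect_equal(res$deficit, 0)
  expect_gt(res$p_value, 0.9)
  full <- homozygote_deficit_test(ds[1, ], F = 0.01, ds[2, ], mode = "full")
  expect_gt(full$e_f, res$e_f)
  zero <- homozygote_deficit_test(doubleton_counts("a", 100L, 5L, 1000L),
                                  F = 0, ds[2, ])
  expect_equal(zero$e_f, 0)
  expect_equal(zero$deficit, -Inf)
  expect_error(homozygote_deficit_test(ds[1, ], F = 2, ds[2, ]), "0, 1")
})

test_that("accrual projection has exact ends and matches the combinatorial oracle", {
  set.seed(84)
  carriers <- sample(0:20, 20, replace = TRUE)
  N_total <- 50L
  full <- project_accrual(carriers, N_total, sizes = N_total)
  for (k in c(1L, 5L, 10L))
    expect_equal(full$expected_genes[full$k == k], sum(carriers >= k))
  zero <- project_accrual(carriers, N_total, sizes = 0L)
  expect_true(all(zero$expected_genes == 0))

  res <- project_accrual(carriers, N_total, sizes = c(10L, 25L, 40L))
  for (i in seq_len(nrow(res)))
    expect_equal(res$expected_genes[i],
                 oracle_accrual(carriers, N_total, res$n[i], res$k[i]),
                 tolerance = 1e-3)
  expect_error(project_accrual(carriers, N_total, sizes = 60L), "N_total")
})

test_that("accrual curves rise with cohort size and fall with the threshold", {
  set.seed(85)
  carriers <- rpois(50, 3)
  res <- project_accrual(carriers, 1000L, sizes = seq(0L, 1000L, by = 100L))
  for (k in unique(res$k)) {
    curve <- res$expected_genes[res$k == k][order(res$n[res$k == k])]
    expect_true(all(diff(curve) >= 0))
  }
  at500 <- res[res$n == 500L, ]
  expect_true(all(diff(at500$expected_genes[order(at500$k)]) <= 0))
})
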