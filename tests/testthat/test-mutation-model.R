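test_that("rate table honours the identity configuration and CpG multipliers", {
  flat <- build_rate_table(base_rate = 1e-8, transition_mult = 1,
                           cpg_transition_mult = 1,
                           methylation_mult = c(none = 1, low = 1, mid = 1, high = 1))
  expect_true(all(flat$rate == 1e-8))
  expect_equal(nrow(flat), 32L * 3L * 4L)  # normalized contexts x alts x tiers

  cpg <- build_rate_table(base_rate = 1e-8, transition_mult = 1,
                          cpg_transition_mult = 10,
                          methylation_mult = c(none = 1, low = 1, mid = 1, high = 1))
  expect_equal(mu_rate(cpg, "ACG", "T", "high"), 1e-7)
  expect_equal(mu_rate(cpg, "ACG", "G", "high"), 1e-8)
})

test_that("lookups are strand-normalized", {
  tb <- build_rate_table()
  bases <- c("A", "C", "G", "T")
  ctx <- expand.grid(a = bases, b = bases, c = bases, stringsAsFactors = FALSE)
  ctxs <- paste0(ctx$a, ctx$b, ctx$c)
  set.seed(5)
  for (cx in sample(ctxs, 12)) {
    mid <- substr(cx, 2, 2)
    alt <- sample(setdiff(bases, mid), 1)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", cx), "")[[1]]), collapse = "")
    alt_rc <- chartr("ACGT", "TGCA", alt)
    expect_equal(mu_rate(tb, cx, alt, "mid"), mu_rate(tb, rc, alt_rc, "mid"))
  }
  expect_equal(mu_rate(tb, "CAT", "G"), mu_rate(tb, "ATG", "C"))
})

test_that("non-CpG rates are identical across methylation tiers", {
  tb <- build_rate_table()
  df <- as.data.frame(tb)
  noncpg <- df[substr(df$context, 2, 3) != "CG", ]
  spread <- tapply(noncpg$rate, paste(noncpg$context, noncpg$alt),
                   function(r) diff(range(r)))
  expect_true(all(spread == 0))
  cpg <- df[substr(df$context, 2, 3) == "CG" & df$alt == "T", ]
  by_ctx <- split(cpg, cpg$context)
  for (b in by_ctx) {
    expect_gte(b$rate[b$tier == "high"], b$rate[b$tier == "low"])
  }
})

test_that("invalid rate parameters are rejected", {
  expect_error(build_rate_table(base_rate = 0), "positive")
  expect_error(build_rate_table(transition_mult = -1), "positive")
  expect_error(build_rate_table(methylation_mult = c(none = 1, low = 2, mid = 1, high = 0.5)),
               "non-decreasing")
})

test_that("possible-variant enumeration matches the genetic code", {
  g <- gene_model("g1", "t1", "ATGTGGTAA")
  pv <- enumerate_possible_variants(g)
  expect_equal(nrow(pv), 27L)  # 3 alts per position
  trp <- pv[pv$codon == 2L, ]  # TGG, the single-codon amino acid
  expect_equal(sum(trp$consequence == "synonymous"), 0L)
  expect_equal(sum(trp$consequence == "stop_gained"), 2L)
  expect_setequal(paste0(trp$ref, trp$pos, trp$alt)[trp$consequence == "stop_gained"],
                  c("G5A", "G6A"))  # TGG->TAG and TGG->TGA
  expect_true(all(pv$consequence[pv$codon == 1L] == "start_loss"))
})

test_that("enumeration agrees with a translate-and-compare oracle", {
  set.seed(41)
  for (cds in c("ATGTGGTAA", random_test_cds(8L), random_test_cds(15L))) {
    g <- gene_model("g", "t", cds)
    pv <- enumerate_possible_variants(g)
    expect_equal(nrow(pv), 9L * nchar(cds) / 3L)
    want <- mapply(function(p, a) oracle_classify(cds, p, a), pv$pos, pv$alt)
    expect_equal(pv$consequence, unname(want))
  }
})

test_that("enumeration is deterministic and class totals add up", {
  g <- gene_model("g1", "t1", random_test_cds(30L))
  pv1 <- enumerate_possible_variants(g)
  pv2 <- enumerate_possible_variants(g)
  expect_identical(pv1, pv2)
  counts <- table(pv1$consequence)
  core <- sum(counts[c("synonymous", "missense", "stop_gained")], na.rm = TRUE)
  excluded <- sum(counts[c("start_loss", "stop_loss")], na.rm = TRUE)
  expect_equal(core + excluded, 9L * g$codon_count)
})

test_that("gene pLOF mutation rate sums stop-gains and scales with uplift", {
  tb <- build_rate_table(1e-8, 1, 1, c(none = 1, low = 1, mid = 1, high = 1))
  g <- gene_model("g1", "t1", "ATGTGGTAA")
  # the only interior codon is TGG with exactly two stop-gains
  expect_equal(gene_mutation_rate(g, tb, frameshift_uplift = 1), 2e-8)
  expect_equal(gene_mutation_rate(g, tb, frameshift_uplift = 1.25), 2.5e-8)
  g2 <- gene_model("g2", "t2", "ATGTGGTAA", splice_site_count = 2L)
  expect_equal(gene_mutation_rate(g2, tb, frameshift_uplift = 1),
               2e-8 + 2 * 3 * 1e-8)
})

test_that("gene rate equals an enumeration-and-lookup oracle on a multi-context gene", {
  tb <- build_rate_table()
  set.seed(7)
  cds <- random_test_cds(20L)
  g <- gene_model("g1", "t1", cds)
  s <- strsplit(cds, "")[[1]]
  total <- 0
  for (p in seq_along(s)) for (a in setdiff(c("A", "C", "G", "T"), s[p])) {
    if (oracle_classify(cds, p, a) != "stop_gained") next
    lag <- if (p == 1L) g$flank5 else s[p - 1L]
    lead <- if (p == length(s)) g$flank3 else s[p + 1L]
    ctx <- paste0(lag, s[p], lead)
    alt <- a
    if (s[p] %in% c("A", "G")) {  # normalize by hand via Biostrings
      ctx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctx)))
      alt <- as.character(Biostrings::complement(Biostrings::DNAString(a)))
    }
    tier <- if (substr(ctx, 2, 3) == "CG") g$meth_tier[p] else "none"
    total <- total + mu_rate(tb, ctx, alt, tier)
  }
  expect_equal(gene_mutation_rate(g, tb, frameshift_uplift = 1), total)
})

test_that("gene rate is additive over its stop-gained sites", {
  tb <- build_rate_table()
  g <- gene_model("g1", "t1", random_test_cds(25L))
  pv <- enumerate_possible_variants(g)
  stopg <- pv[pv$consequence == "stop_gained", ]
  per_site <- vapply(seq_len(nrow(stopg)), function(i)
    variant_mu(tb, stopg$context[i], stopg$ref[i], stopg$alt[i],
               stopg$methylation_tier[i]), 0)
  expect_equal(gene_mutation_rate(g, tb, frameshift_uplift = 1), sum(per_site))
})

test_that("saturation survey fractions are correct and guarded", {
  set.seed(11)
  g <- gene_model("g1", "t1", random_test_cds(12L))
  pv <- enumerate_possible_variants(g)
  core <- pv[pv$consequence %in% c("synonymous", "missense", "stop_gained"), ]

  all_obs <- core[, c("gene_id", "pos", "ref", "alt")]
  res_all <- saturation_survey(all_obs, list(g))
  expect_true(all(res_all$fraction == 1))

  res_none <- saturation_survey(all_obs[0, ], list(g))
  expect_true(all(res_none$fraction == 0))

  syn <- core[core$consequence == "synonymous", ]
  four <- syn[sample(nrow(syn), 4L), c("gene_id", "pos", "ref", "alt")]
  res <- saturation_survey(four, list(g))
  row <- res[res$class == "synonymous" & res$stratum == "all", ]
  expect_equal(row$n_observed, 4L)
  expect_equal(row$fraction, 4L / sum(core$consequence == "synonymous"))

  rogue <- data.frame(gene_id = "g1", pos = 2L, ref = "X", alt = "Y")
  expect_error(saturation_survey(rogue, list(g)), "not possible")
})
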