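#' Simulation configuration for synthetic exomes
#'
#' Bundles and validates all generator parameters.  Defaults describe a
#' cohort of 100,000 diploid individuals (200,000 chromosomes) and an
#' inverse-Gaussian distribution of heterozygous selection coefficients
#' with mean 0.05 and shape 0.1.  The presence intensity of neutral sites
#' is calibrated so that a neutral site of baseline mutability is observed
#' in about 35.6% of possible positions at a reference cohort of 1,643,958
#' chromosomes, the saturation regime of current population exome
#' resources; smaller cohorts scale down proportionally.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_individuals cohort size N (AN = 2N).
#' @param n_genes number of genes G.
#' @param codon_meanlog,codon_sdlog log-normal parameters of the per-gene
#'   codon count.
#' @param base_rate,transition_mult,cpg_transition_mult,methylation_mult
#'   mutation-rate model parameters, see [build_rate_table()].
#' @param prior_mean,prior_shape inverse-Gaussian parameters of the
#'   per-gene selection coefficient.
#' @param selection if `FALSE`, all selection coefficients are zero and no
#'   depleted intervals are planted (fully neutral exome).
#' @param neutral_shape exponent of the neutral site-frequency weights
#'   `k^(-neutral_shape)` (default 1, the standard neutral spectrum).
#' @param selection_scaling multiplier linking a site's selection
#'   coefficient to the exponential tilt of its allele-count distribution,
#'   `P(AC = k) ~ k^(-neutral_shape) exp(-k s selection_scaling)`.
#' @param saturation_target,an_ref calibration of the neutral presence
#'   intensity (see Description).
#' @param inbreeding background inbreeding coefficient F in [0, 1].
#' @param missense_del_frac fraction of missense sites that are
#'   deleterious; their selection coefficient is
#'   `missense_attenuation * s_gene`.
#' @param missense_attenuation see above.
#' @param depleted_frac fraction of genes carrying one planted
#'   missense-depleted interval.
#' @param depleted_span fraction of the gene's codons covered by the
#'   planted interval.
#' @param depletion_factor multiplier on missense presence intensity inside
#'   planted intervals (default 0.3).
#' @param frameshift_uplift loss-of-function indel uplift, matching
#'   [gene_mutation_rate()].
#' @param sav_frac fraction of observed variants flagged as true
#'   splice-affecting (high splice scores, singleton-enriched).
#' @param cpg_tier_probs probabilities of low/mid/high methylation for CpG
#'   dinucleotides.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 100000L,
                       n_genes = 60L,
                       codon_meanlog = log(350), codon_sdlog = 0.4,
                       base_rate = 1e-8, transition_mult = 2,
                       cpg_transition_mult = 10,
                       methylation_mult = c(none = 1, low = 1, mid = 3, high = 6),
                       prior_mean = 0.05, prior_shape = 0.1,
                       selection = TRUE,
                       neutral_shape = 1, selection_scaling = 2000,
                       saturation_target = 0.356, an_ref = 1643958,
                       inbreeding = 0.0037,
                       missense_del_frac = 0.25, missense_attenuation = 0.5,
                       depleted_frac = 0.45, depleted_span = 0.25,
                       depletion_factor = 0.3,
                       frameshift_uplift = 1.25,
                       sav_frac = 0.02,
                       cpg_tier_probs = c(low = 0.2, mid = 0.3, high = 0.5)) {
  cfg <- as.list(environment())
  if (cfg$n_individuals < 1L || cfg$n_genes < 1L)
    stopf("n_individuals and n_genes must be >= 1")
  if (cfg$inbreeding < 0 || cfg$inbreeding > 1)
    stopf("inbreeding must lie in [0, 1]")
  if (any(c(base_rate, transition_mult, cpg_transition_mult,
            selection_scaling, frameshift_uplift) <= 0))
    stopf("rates and multipliers must be positive")
  if (saturation_target <= 0 || saturation_target >= 1)
    stopf("saturation_target must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

harmonic_number <- function(n) log(n) + 0.57721566490153286 + 1 / (2 * n)

# Neutral presence intensity per unit mu: theta * H(AN), the Watterson
# scaling of segregating-site counts with sample size, calibrated so a site
# of canonical genome-average mutability (1e-8) reaches the target
# saturation at the reference cohort.  Anchoring at a fixed reference rate
# keeps the intensity proportional to the configured rates.
sat_coefficient <- function(config) {
  -log(1 - config$saturation_target) / (harmonic_number(config$an_ref) * 1e-8)
}

# Tilted site-frequency weights w_k = k^(-shape) exp(-a k), k = 1..AN,
# truncated where the exponential tail becomes negligible.
sfs_weights <- function(a, shape, AN) {
  kmax <- if (a > 0) min(AN, max(10L, ceiling(60 / a))) else AN
  k <- seq_len(kmax)
  w <- k^(-shape) * exp(-a * k)
  list(k = k, w = w, cum = cumsum(w), total = sum(w),
       mean = sum(k * w) / sum(w))
}

# Smallest index k with cum[k] >= u; plain vectorized binary search to skip
# findInterval's per-call sortedness validation on long CDFs.
interval_index <- function(u, cum) {
  n <- length(cum)
  lo <- rep.int(1L, length(u))
  hi <- rep.int(n, length(u))
  for (iter in seq_len(ceiling(log2(n)) + 1L)) {
    mid <- (lo + hi) %/% 2L
    ge <- cum[mid] >= u
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge] + 1L
    if (all(lo == hi)) break
  }
  lo
}

sample_sfs <- function(n, weights) {
  if (n == 0L) return(integer())
  u <- stats::runif(n) * weights$total
  weights$k[interval_index(u, weights$cum)]
}

random_cds <- function(L) {
  codons <- names(Biostrings::GENETIC_CODE)
  stops <- c("TAA", "TAG", "TGA")
  body <- sample(setdiff(codons, stops), L - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
}

# Approximate homozygous-carrier count for a variant with AC copies in a
# cohort of N individuals with background inbreeding F.  Exact mechanism
# for doubletons (a second copy pairs with the first with probability
# F + (1 - F)/(2N - 1)); binomial pairing approximation for AC > 2.
hom_count <- function(AC, N, F) {
  out <- integer(length(AC))
  two <- AC == 2
  if (any(two)) {
    n2 <- sum(two)
    c1 <- sample.int(2L * N, n2, replace = TRUE)
    paired <- stats::runif(n2) < F
    c2 <- sample.int(2L * N - 1L, n2, replace = TRUE)
    c2 <- c2 + (c2 >= c1)
    out[two] <- as.integer(paired | ((c2 - 1L) %/% 2L == (c1 - 1L) %/% 2L))
  }
  big <- AC > 2
  if (any(big)) {
    pair_p <- pmin(1, F + (1 - F) * (AC[big] - 1) / (2 * N - 1))
    out[big] <- stats::rbinom(sum(big), AC[big] %/% 2L, pair_p)
  }
  out
}

#' Simulate a synthetic exome
#'
#' Generates gene models with random coding sequences, draws per-gene
#' selection coefficients, and emits an observed-variant table whose
#' statistical structure mirrors population exome summaries:
#' context-dependent mutation rates with CpG/methylation effects; per
#' possible variant, the number of independent mutational origins is
#' Poisson with an intensity that is mutation-limited for neutral sites and
#' follows mutation-selection balance for loss-of-function sites (so a
#' gene's cumulative rare pLOF allele count is Poisson with mean
#' `AN * U / s`); conditional allele counts follow a truncated power-law
#' spectrum with exponential selection tilt, pushing selected classes
#' toward singletons; background inbreeding inflates doubleton
#' homozygosity; and splice/deleteriousness score columns correlate with
#' the planted selection.  Frameshift alleles are generated as aggregate
#' pseudo-sites at the configured uplift over the stop-gained rate.
#'
#' Missense sites keep the mutation-limited presence intensity (selection
#' shows in their frequency spectrum, and as regional depletion in planted
#' intervals), a deliberate simplification documented in the methods
#' vignette.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_exome`: `config`, `rate_table`,
#'   `genes` (named list of [gene_model()]), `sites` (observed-variant data
#'   frame with `mu` and score columns), `truth` (list with per-gene `s`,
#'   planted `depleted` intervals, `sav` keys).
#' @export
simulate_exome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_individuals
  AN <- 2L * N
  table <- build_rate_table(config$base_rate, config$transition_mult,
                            config$cpg_transition_mult, config$methylation_mult)
  ksat <- sat_coefficient(config)
  h_an <- harmonic_number(AN)
  neutral_w <- sfs_weights(0, config$neutral_shape, AN)

  genes <- vector("list", config$n_genes)
  site_rows <- vector("list", config$n_genes)
  s_true <- numeric(config$n_genes)
  depleted <- vector("list", config$n_genes)

  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("G%04d", gi)
    L <- max(20L, round(stats::rlnorm(1L, config$codon_meanlog, config$codon_sdlog)))
    cds <- random_cds(L)
    n <- 3L * L
    s_chr <- strsplit(cds, "")[[1]]
    tier <- rep("none", n)
    cpg_start <- which(s_chr[-n] == "C" & s_chr[-1L] == "G")
    if (length(cpg_start)) {
      t <- sample(c("low", "mid", "high"), length(cpg_start), replace = TRUE,
                  prob = config$cpg_tier_probs)
      tier[cpg_start] <- t
      tier[cpg_start + 1L] <- t
    }
    gene <- gene_model(gid, paste0("T", substring(gid, 2L)), cds,
                       splice_site_count = 0L, meth_tier = tier)
    poss <- enumerate_possible_variants(gene)
    mu <- variant_mu(table, poss$context, poss$ref, poss$alt,
                     poss$methylation_tier)

    s_g <- if (config$selection)
      min(1, max(1e-6, rinvgauss(1L, config$prior_mean, config$prior_shape)))
    else 0
    s_true[gi] <- s_g

    plant <- NULL
    if (config$selection && stats::runif(1L) < config$depleted_frac) {
      len <- max(5L, round(config$depleted_span * L))
      len <- min(len, L - 4L)
      start <- sample.int(L - len + 1L, 1L)
      plant <- c(start, start + len - 1L)
      depleted[[gi]] <- data.frame(gene_id = gid, start_codon = plant[1L],
                                   end_codon = plant[2L])
    }

    is_mis <- poss$consequence == "missense"
    is_stop <- poss$consequence == "stop_gained"
    del_mis <- is_mis & stats::runif(nrow(poss)) < config$missense_del_frac
    s_site <- numeric(nrow(poss))
    s_site[is_stop] <- s_g
    s_site[del_mis] <- config$missense_attenuation * s_g

    # per-class presence intensity (expected mutational origins per site)
    intensity <- ksat * h_an * mu
    if (!is.null(plant)) {
      in_plant <- is_mis & poss$codon >= plant[1L] & poss$codon <= plant[2L]
      intensity[in_plant] <- intensity[in_plant] * config$depletion_factor
    }
    a_plof <- s_g * config$selection_scaling
    w_plof <- if (s_g > 0) sfs_weights(a_plof, config$neutral_shape, AN) else neutral_w
    if (s_g > 0)
      intensity[is_stop] <- AN * mu[is_stop] / (s_g * w_plof$mean)

    # frameshift pseudo-sites spread along the CDS
    u_stop <- sum(mu[is_stop])
    mu_fs <- (config$frameshift_uplift - 1) * u_stop / n
    fs_intensity <- if (s_g > 0) AN * mu_fs / (s_g * w_plof$mean)
                    else ksat * h_an * mu_fs
    fs_M <- stats::rpois(n, fs_intensity)

    M <- stats::rpois(nrow(poss), intensity)
    obs <- which(M > 0L)
    fs_obs <- which(fs_M > 0L)
    if (length(obs) == 0L && length(fs_obs) == 0L) {
      genes[[gi]] <- set_gene_rate(gene, table, config$frameshift_uplift,
                                   possible = poss)
      next
    }

    ac <- integer(length(obs))
    grp_a <- ifelse(s_site[obs] > 0, s_site[obs] * config$selection_scaling, 0)
    draw_group <- function(Ms, w) {
      res <- integer(length(Ms))
      one <- Ms == 1L
      res[one] <- sample_sfs(sum(one), w)
      for (j in which(!one)) res[j] <- min(AN, sum(sample_sfs(Ms[j], w)))
      res
    }
    for (a in unique(grp_a)) {
      idx <- which(grp_a == a)
      w <- if (a == 0) neutral_w else sfs_weights(a, config$neutral_shape, AN)
      ac[idx] <- draw_group(M[obs[idx]], w)
    }
    fs_ac <- draw_group(fs_M[fs_obs], w_plof)

    rows <- poss[obs, c("gene_id", "pos", "ref", "alt", "consequence",
                        "context", "methylation_tier")]
    rows$AC <- ac
    rows$mu <- mu[obs]
    rows$deleterious <- s_site[obs] > 0
    if (length(fs_obs)) {
      fs_rows <- data.frame(gene_id = gid, pos = fs_obs,
                            ref = s_chr[fs_obs],
                            alt = paste0(s_chr[fs_obs], "A"),
                            consequence = "frameshift",
                            context = poss$context[match(fs_obs, poss$pos)],
                            methylation_tier = "none",
                            AC = fs_ac, mu = mu_fs,
                            deleterious = s_g > 0,
                            stringsAsFactors = FALSE)
      rows <- rbind(rows, fs_rows)
    }
    rows$transcript_id <- gene$transcript_id
    site_rows[[gi]] <- rows
    genes[[gi]] <- set_gene_rate(gene, table, config$frameshift_uplift,
                                 possible = poss)
  }

  sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null, TRUE)])
  cols <- c("gene_id", "transcript_id", "pos", "ref", "alt", "consequence",
            "context", "methylation_tier", "AC", "AN", "n_hom",
            "spliceai", "mmsplice", "pred_del_count", "mu")
  sav <- logical(0)
  if (is.null(sites)) {
    sites <- data.frame(gene_id = character(), transcript_id = character(),
                        pos = integer(), ref = character(), alt = character(),
                        consequence = character(), context = character(),
                        methylation_tier = character(), AC = integer(),
                        AN = integer(), n_hom = integer(), spliceai = numeric(),
                        mmsplice = numeric(), pred_del_count = integer(),
                        mu = numeric(), stringsAsFactors = FALSE)
  } else {
    rownames(sites) <- NULL
    sites$AN <- AN
    sites$n_hom <- hom_count(sites$AC, N, config$inbreeding)
    nv <- nrow(sites)
    sav <- stats::runif(nv) < config$sav_frac
    # true splice-affecting sites behave like strongly selected variants
    if (any(sav)) sites$AC[sav] <- ifelse(stats::runif(sum(sav)) < 0.95, 1L,
                                          sites$AC[sav])
    sites$spliceai <- ifelse(sav, stats::rbeta(nv, 8, 1.5), stats::rbeta(nv, 0.6, 12))
    sites$mmsplice <- ifelse(sav, stats::rbeta(nv, 12, 1), stats::rbeta(nv, 1, 8))
    mis <- sites$consequence == "missense"
    # prediction algorithms track the site's true deleteriousness, noisily
    sites$pred_del_count <- NA_integer_
    sites$pred_del_count[mis] <- stats::rbinom(sum(mis), 5L,
                                               ifelse(sites$deleterious[mis], 0.85, 0.25))
    sites <- sites[, cols]
  }

  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  dep <- do.call(rbind, depleted[!vapply(depleted, is.null, TRUE)])
  if (is.null(dep))
    dep <- data.frame(gene_id = character(), start_codon = integer(),
                      end_codon = integer())
  structure(list(config = config,
                 rate_table = table,
                 genes = genes,
                 sites = sites,
                 truth = list(s = data.frame(gene_id = names(genes),
                                             s_het = s_true,
                                             stringsAsFactors = FALSE),
                              depleted = dep,
                              sav = paste(sites$gene_id, sites$pos,
                                          sites$ref, sites$alt)[sav])),
            class = "synthetic_exome")
}

#' @export
print.synthetic_exome <- function(x, ...) {
  cat(sprintf("<synthetic_exome> %d genes, %d observed variants, N = %d (seed %d)\n",
              length(x$genes), nrow(x$sites), x$config$n_individuals,
              x$config$seed))
  invisible(x)
}

#' Simulate individual-level genotype calls for a variant table
#'
#' Places the `AC` allele copies of each variant into a cohort of `N`
#' diploid individuals: each copy pairs into an existing single-copy
#' carrier of the same variant with probability `F` (producing a
#' homozygote), and otherwise lands on a chromosome drawn uniformly among
#' those not yet carrying it.  A doubleton is therefore homozygous with
#' probability `F + (1 - F)/(2N - 1)`.  Haplotype sides follow chromosome
#' parity, so two heterozygous variants of one sample are in cis when their
#' copies landed on the same chromosome.
#'
#' @param variants sites data frame with `gene_id`, `pos`, `ref`, `alt`,
#'   `AC` (and at most `2N` copies per variant).
#' @param N cohort size.
#' @param F background inbreeding coefficient.
#' @param seed integer seed.
#' @param phased_frac fraction of (sample, gene) call groups that carry
#'   phase information; the rest get `NA` phase.
#' @return list with `calls` (sample_id, gene_id, pos, ref, alt, zygosity,
#'   phase_block, hap_side) and `n_hom` (per input variant).
#' @export
simulate_genotypes <- function(variants, N, F = 0, seed = 1L,
                               phased_frac = 1) {
  if (F < 0 || F > 1) stopf("F must lie in [0, 1]")
  if (any(variants$AC > 2L * N))
    stopf("variant allele count exceeds 2N")
  set.seed(seed)
  out <- vector("list", nrow(variants))
  n_hom <- integer(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    c_i <- variants$AC[i]
    if (c_i == 0L) next
    chroms <- integer(0)
    for (copy in seq_len(c_i)) {
      carriers <- unique((chroms - 1L) %/% 2L)
      singles <- carriers[!vapply(carriers, function(ind)
        all(c(2L * ind + 1L, 2L * ind + 2L) %in% chroms), TRUE)]
      if (length(singles) && stats::runif(1L) < F) {
        ind <- singles[sample.int(length(singles), 1L)]
        side <- setdiff(c(2L * ind + 1L, 2L * ind + 2L), chroms)
        chroms <- c(chroms, side[1L])
      } else {
        free <- setdiff(seq_len(2L * N), chroms)
        chroms <- c(chroms, free[sample.int(length(free), 1L)])
      }
    }
    ind <- (chroms - 1L) %/% 2L + 1L
    tab <- table(ind)
    n_hom[i] <- sum(tab == 2L)
    out[[i]] <- data.frame(sample_id = sprintf("S%06d", as.integer(names(tab))),
                           gene_id = variants$gene_id[i],
                           pos = variants$pos[i], ref = variants$ref[i],
                           alt = variants$alt[i],
                           zygosity = ifelse(tab == 2L, "hom_alt", "het"),
                           hap_side = ifelse(tab == 2L, NA_integer_,
                                             (chroms[match(names(tab), as.character(ind))] - 1L) %% 2L + 1L),
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(calls))
    return(list(calls = data.frame(sample_id = character(), gene_id = character(),
                                   pos = integer(), ref = character(),
                                   alt = character(), zygosity = character(),
                                   phase_block = integer(), hap_side = integer()),
                n_hom = n_hom))
  rownames(calls) <- NULL
  key <- paste(calls$sample_id, calls$gene_id)
  phased <- stats::runif(length(unique(key))) < phased_frac
  names(phased) <- unique(key)
  calls$phase_block <- ifelse(phased[key], 1L, NA_integer_)
  calls$hap_side[is.na(calls$phase_block)] <- NA_integer_
  list(calls = calls, n_hom = n_hom)
}

#' Fast doubleton cohort generator
#'
#' Emits a table of doubleton variants (AC = 2) whose homozygosity is
#' simulated mechanistically: the first copy lands on a random chromosome;
#' the second pairs with it with probability `F`, otherwise lands uniformly
#' on one of the remaining `2N - 1` chromosomes.  Used for
#' homozygote-excess and inbreeding-recovery analyses at large doubleton
#' counts where full genotype placement is unnecessary.
#'
#' @param D number of doubleton variants.
#' @param N cohort size.
#' @param F background inbreeding coefficient.
#' @param seed integer seed.
#' @param class_probs named class proportions; names `missense`,
#'   `synonymous`, `plof` map to consequences missense, synonymous,
#'   stop_gained.
#' @return sites-like data frame with `consequence`, `AC = 2`, `AN`,
#'   `n_hom`.
#' @export
simulate_doubletons <- function(D, N, F = 0, seed = 1L,
                                class_probs = c(missense = 0.65,
                                                synonymous = 0.3,
                                                plof = 0.05)) {
  if (F < 0 || F > 1) stopf("F must lie in [0, 1]")
  set.seed(seed)
  cons_map <- c(missense = "missense", synonymous = "synonymous",
                plof = "stop_gained")
  cls <- sample(names(class_probs), D, replace = TRUE,
                prob = class_probs)
  c1 <- sample.int(2L * N, D, replace = TRUE)
  paired <- stats::runif(D) < F
  c2 <- sample.int(2L * N - 1L, D, replace = TRUE)
  c2 <- c2 + (c2 >= c1)
  hom <- paired | ((c2 - 1L) %/% 2L == (c1 - 1L) %/% 2L)
  data.frame(gene_id = sprintf("G%05d", seq_len(D)),
             consequence = unname(cons_map[cls]),
             AC = 2L, AN = 2L * N, n_hom = as.integer(hom),
             stringsAsFactors = FALSE)
}

#' Planted-threshold calibration benchmark set
#'
#' Generates per-variant scores uniform on [0, 1] with singleton
#' probability `p_bg` below the planted threshold and rising linearly from
#' `p0` at the threshold, plus an independent reference set whose singleton
#' probability equals the mean singleton probability of the above-threshold
#' variants, and a neutral two-stratum training set for the mutability
#' model.  Recovering `t_star` from these data exercises the full MAPS
#' calibration path.
#'
#' @param n number of scored variants.
#' @param n_ref reference-set size.
#' @param t_star planted threshold.
#' @param p_bg background singleton probability.
#' @param p0,slope singleton probability at and above the threshold:
#'   `p0 + slope * (score - t_star)`.
#' @param seed integer seed.
#' @return list `variants`, `reference`, `training` (data frames with `mu`,
#'   `AC`, and for `variants` the `score` column).
#' @export
simulate_calibration_set <- function(n = 100000L, n_ref = 150000L,
                                     t_star = 0.4, p_bg = 0.05,
                                     p0 = 0.15, slope = 1.4, seed = 1L) {
  set.seed(seed)
  stopifnot(p0 + slope * (1 - t_star) <= 1)
  mus <- c(1e-8, 2e-8)
  score <- stats::runif(n)
  p <- ifelse(score < t_star, p_bg, p0 + slope * (score - t_star))
  variants <- data.frame(mu = sample(mus, n, replace = TRUE),
                         AC = ifelse(stats::runif(n) < p, 1L, 2L),
                         score = score)
  p_ref <- p0 + slope * (1 - t_star) / 2
  reference <- data.frame(mu = sample(mus, n_ref, replace = TRUE),
                          AC = ifelse(stats::runif(n_ref) < p_ref, 1L, 2L))
  training <- data.frame(mu = sample(mus, n, replace = TRUE),
                         AC = ifelse(stats::runif(n) < p_bg, 1L, 2L))
  list(variants = variants, reference = reference, training = training,
       t_star = t_star)
}

#' Worked-example doubleton fixture
#'
#' Writes the in-cohort doubleton tally used in the worked homozygote-excess
#' example — per-class doubleton counts, observed homozygote counts and the
#' unrelated cohort size — as a TSV, and returns the corresponding
#' [doubleton_counts()] summary.  A copy ships with the package (see
#' [doubleton_example()]).
#'
#' @param dir directory to write `doubleton_class_counts.tsv` into.
#' @return invisible list with `path` and `summary`.
#' @export
make_worked_example_fixtures <- function(dir = tempdir()) {
  df <- data.frame(class = c("missense", "synonymous", "plof"),
                   D = c(1580917L, 679335L, 129405L),
                   hom_obs = c(5857L, 2490L, 406L),
                   N = 821979L)
  path <- file.path(dir, "doubleton_class_counts.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(path = path,
                 summary = doubleton_counts(df$class, df$D, df$hom_obs, df$N[1L])))
}

#' Load the shipped worked-example doubleton table
#'
#' @param path optional path to a fixture written by
#'   [make_worked_example_fixtures()]; defaults to the copy shipped in the
#'   package.
#' @return a `doubleton_summary` data frame.
#' @export
doubleton_example <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "doubleton_class_counts.tsv",
                        package = "excon", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  doubleton_counts(df$class, df$D, df$hom_obs, df$N[1L])
}
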