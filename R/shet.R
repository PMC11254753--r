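#' Default log-spaced selection-coefficient grid
#'
#' 1,000 log-spaced points spanning nearly neutral (1e-6) to lethal (1),
#' shared by prior, posterior and empirical-Bayes fitting.
#' @param n number of grid points.
#' @param lower,upper grid bounds.
#' @export
shet_grid <- function(n = 1000L, lower = 1e-6, upper = 1) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Prior over the heterozygous selection coefficient
#'
#' Discretized on the log-spaced grid.  `log-uniform` puts equal mass on
#' every grid point (flat in log s); `inverse-gaussian` discretizes an
#' inverse-Gaussian density, the empirical-Bayes family used by
#' [fit_shet_prior()].
#'
#' @param family `"log-uniform"` or `"inverse-gaussian"`.
#' @param mean,shape inverse-Gaussian mean and shape parameters.
#' @param grid selection-coefficient grid, strictly increasing.
#' @return object of class `shet_prior` with fields `family`, `mean`,
#'   `shape`, `grid`, `mass` (summing to one).
#' @export
shet_prior <- function(family = c("log-uniform", "inverse-gaussian"),
                       mean = NULL, shape = NULL, grid = shet_grid()) {
  family <- match.arg(family)
  if (any(diff(grid) <= 0)) stopf("grid must be strictly increasing")
  if (family == "log-uniform") {
    mass <- rep(1 / length(grid), length(grid))
  } else {
    if (is.null(mean) || is.null(shape) || mean <= 0 || shape <= 0)
      stopf("inverse-gaussian prior needs positive mean and shape")
    dens <- dinvgauss(grid, mean, shape)
    # cell widths from midpoints; turns the density into grid mass
    w <- diff(c(grid[1L], (grid[-1L] + grid[-length(grid)]) / 2, grid[length(grid)]))
    mass <- dens * w
    if (sum(mass) <= 0) stopf("prior mass underflow on the grid")
    mass <- mass / sum(mass)
  }
  structure(list(family = family, mean = mean, shape = shape,
                 grid = grid, mass = mass),
            class = "shet_prior")
}

# Inverse-Gaussian density and sampler (Michael-Schucany-Haas); small and
# self-contained, used for the empirical-Bayes prior and the simulator.
dinvgauss <- function(x, mean, shape) {
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- sqrt(shape / (2 * pi * x[ok]^3)) *
    exp(-shape * (x[ok] - mean)^2 / (2 * mean^2 * x[ok]))
  out
}

rinvgauss <- function(n, mean, shape) {
  z <- stats::rnorm(n)^2
  x <- mean + mean^2 * z / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * z + mean^2 * z^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Cumulative rare pLOF observation for one gene
#'
#' Aggregates the alternate allele counts of a gene's rare predicted
#' loss-of-function variants (stop-gained, essential splice, frameshift).
#' Only variants whose own alternate allele frequency is strictly below
#' `aaf_cutoff` contribute.  By default X sums allele copies; the
#' `"variants"` mode instead counts distinct contributing variants.
#'
#' @param variants sites data frame with columns `gene_id`, `consequence`,
#'   `AC`, `AN`.
#' @param gene_id gene to aggregate.
#' @param aaf_cutoff rarity cutoff on per-variant AAF (default 0.001,
#'   i.e. < 0.1%), strict inequality.
#' @param mode `"alleles"` (sum of AC, default) or `"variants"` (count of
#'   distinct contributing variants).
#' @return list of class `plof_observation`: `gene_id`, `X`, `AN`, `q`,
#'   `n_variants`.
#' @export
cumulative_plof_observation <- function(variants, gene_id, aaf_cutoff = 0.001,
                                        mode = c("alleles", "variants")) {
  mode <- match.arg(mode)
  g <- variants[variants$gene_id == gene_id, ]
  an <- suppressWarnings(max(g$AN, 0))
  if (!is.finite(an) || an <= 0)
    stopf("gene %s has no genotyped alleles (AN = 0)", gene_id)
  p <- g[is_plof(g$consequence) & g$AC / g$AN < aaf_cutoff & g$AC > 0, ]
  X <- if (mode == "alleles") sum(p$AC) else nrow(p)
  structure(list(gene_id = gene_id, X = as.numeric(X), AN = as.numeric(an),
                 q = X / an, n_variants = nrow(p)),
            class = "plof_observation")
}

#' Posterior of the heterozygous selection coefficient
#'
#' Grid posterior under a Poisson likelihood on the cumulative rare pLOF
#' allele count, `X ~ Poisson(AN * U / s)` — deterministic mutation-selection
#' balance (equilibrium cumulative frequency `q = U/s`) with Poisson sampling
#' of allele copies.  The 95% highest-posterior-density interval is the
#' smallest contiguous grid interval holding at least 95% of posterior mass,
#' ties broken toward the smaller interval start.
#'
#' @param obs a [cumulative_plof_observation()] or list with `X` and `AN`.
#' @param U aggregate pLOF mutation rate of the gene (per haploid
#'   generation), positive.
#' @param prior a [shet_prior()].
#' @param hpd_mass posterior mass of the HPD interval (default 0.95).
#' @return one-row data frame of class `shet_estimate`: `gene_id`, `X`,
#'   `AN`, `U`, `posterior_mean`, `posterior_median`, `hpd_low`, `hpd_high`.
#' @export
shet_posterior <- function(obs, U, prior = shet_prior(), hpd_mass = 0.95) {
  if (!is.finite(U) || U <= 0) stopf("U must be positive")
  X <- obs$X; AN <- obs$AN
  if (!is.finite(AN) || AN <= 0) stopf("AN must be positive")
  s <- prior$grid
  lam <- pmax(AN * U / s, 1e-12)
  logpost <- log(prior$mass) + stats::dpois(round(X), lam, log = TRUE)
  norm <- logsumexp(logpost)
  if (!is.finite(norm))
    stopf("posterior underflow for gene %s (X = %g, AN*U = %g); check inputs",
          obs$gene_id %||% "?", X, AN * U)
  p <- exp(logpost - norm)

  post_mean <- sum(s * p)
  cs <- cumsum(p)
  post_median <- s[which(cs >= 0.5)[1L]]
  hpd <- hpd_interval(s, p, hpd_mass)

  structure(data.frame(gene_id = obs$gene_id %||% NA_character_,
                       X = X, AN = AN, U = U,
                       posterior_mean = post_mean,
                       posterior_median = post_median,
                       hpd_low = hpd[1L], hpd_high = hpd[2L],
                       stringsAsFactors = FALSE),
            class = c("shet_estimate", "data.frame"))
}

# Smallest contiguous grid interval with >= mass; ties -> smaller start.
hpd_interval <- function(s, p, mass = 0.95) {
  n <- length(p)
  cs <- c(0, cumsum(p))
  best <- c(1L, n)
  best_len <- n
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && cs[j + 1L] - cs[i] < mass) j <- j + 1L
    if (j > n) break
    if (j - i < best_len - 1L) {  # strictly smaller only: ties keep earlier start
      best <- c(i, j)
      best_len <- j - i + 1L
    }
  }
  c(s[best[1L]], s[best[2L]])
}

#' Empirical-Bayes inverse-Gaussian prior across genes
#'
#' Maximizes the marginal likelihood
#' `sum_g log sum_s prior(s) Poisson(X_g; AN_g U_g / s)` over the
#' inverse-Gaussian mean and shape by Nelder-Mead on the log scale.
#' Deterministic given inputs.
#'
#' @param observations data frame with columns `X`, `AN`, `U` (one row per
#'   gene), e.g. built from [cumulative_plof_observation()] results.
#' @param grid selection-coefficient grid.
#' @param init initial `c(mean, shape)`.
#' @return a [shet_prior()] of family `inverse-gaussian`; if every gene has
#'   `X = 0` the data cannot identify the prior and a flat (log-uniform)
#'   fallback is returned with a warning.
#' @export
fit_shet_prior <- function(observations, grid = shet_grid(),
                           init = c(0.05, 0.1)) {
  need <- c("X", "AN", "U")
  if (!all(need %in% names(observations)))
    stopf("observations must have columns %s", paste(need, collapse = ", "))
  if (nrow(observations) < 50L)
    warnf("empirical-Bayes prior fitted on fewer than 50 genes; estimates may be unstable")
  if (all(observations$X == 0)) {
    warnf("all genes have X = 0; returning flat log-uniform fallback prior")
    return(shet_prior("log-uniform", grid = grid))
  }
  X <- round(observations$X)
  lam <- outer(observations$AN * observations$U, 1 / grid)  # genes x grid
  lam <- pmax(lam, 1e-12)
  loglik <- stats::dpois(X, lam)  # recycles X down columns
  dim(loglik) <- dim(lam)
  w <- diff(c(grid[1L], (grid[-1L] + grid[-length(grid)]) / 2, grid[length(grid)]))

  negll <- function(par) {
    m <- exp(par[1L]); lambda <- exp(par[2L])
    mass <- dinvgauss(grid, m, lambda) * w
    tot <- sum(mass)
    if (tot <= 0 || !is.finite(tot)) return(1e300)
    marg <- as.vector(loglik %*% (mass / tot))
    if (any(marg <= 0)) return(1e300)
    -sum(log(marg))
  }
  fit <- stats::optim(log(init), negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  shet_prior("inverse-gaussian", mean = exp(fit$par[1L]),
             shape = exp(fit$par[2L]), grid = grid)
}

#' Classify a gene as highly constrained
#'
#' A gene is flagged when its posterior mean exceeds `mean_cutoff` and its
#' HPD lower bound exceeds `lb_cutoff`; both inequalities are strict.  The
#' default cutoffs are the cohort mean (0.073) and median (0.021) of the
#' s_het distribution, used as mean and lower-bound thresholds respectively.
#'
#' @param est a `shet_estimate` (or data frame with `posterior_mean`,
#'   `hpd_low`).
#' @param mean_cutoff threshold on the posterior mean.
#' @param lb_cutoff threshold on the 2.5% HPD bound.
#' @return logical vector.
#' @export
classify_constrained <- function(est, mean_cutoff = 0.073, lb_cutoff = 0.021) {
  est$posterior_mean > mean_cutoff & est$hpd_low > lb_cutoff
}

#' Per-gene s_het table for a sites table
#'
#' Convenience wrapper running [cumulative_plof_observation()] and
#' [shet_posterior()] over all genes, with optional empirical-Bayes prior
#' fitting across genes.
#'
#' @param sites sites data frame.
#' @param rates named numeric vector of per-gene U (pLOF mutation rates).
#' @param prior a [shet_prior()], or `"fit"` to fit the inverse-Gaussian
#'   empirical-Bayes prior on these genes first.
#' @param aaf_cutoff,mode passed to [cumulative_plof_observation()].
#' @param mean_cutoff,lb_cutoff passed to [classify_constrained()].
#' @return data frame, one row per gene: observation, posterior summaries
#'   and `constrained` flag.
#' @export
shet_table <- function(sites, rates, prior = "fit", aaf_cutoff = 0.001,
                       mode = "alleles", mean_cutoff = 0.073, lb_cutoff = 0.021) {
  genes <- names(rates)
  if (is.null(genes)) stopf("rates must be a named vector (gene_id -> U)")
  obs <- lapply(genes, function(g)
    cumulative_plof_observation(sites, g, aaf_cutoff, mode))
  obs_df <- data.frame(gene_id = genes,
                       X = vapply(obs, `[[`, 0, "X"),
                       AN = vapply(obs, `[[`, 0, "AN"),
                       U = unname(rates),
                       n_plof_variants = vapply(obs, `[[`, 0L, "n_variants"))
  if (identical(prior, "fit")) prior <- fit_shet_prior(obs_df)
  est <- do.call(rbind, lapply(seq_along(genes), function(i)
    shet_posterior(obs[[i]], obs_df$U[i], prior)))
  est$n_plof_variants <- obs_df$n_plof_variants
  est$q <- est$X / est$AN
  est$constrained <- classify_constrained(est, mean_cutoff, lb_cutoff)
  attr(est, "prior") <- prior
  est
}
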