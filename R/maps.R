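#' Fit the singleton-versus-mutability model
#'
#' The mutability adjustment behind MAPS: synonymous variants are grouped
#' into strata of identical mutability mu, and the stratum proportion of
#' singletons (AC = 1) is regressed on mu by weighted least squares with
#' stratum variant counts as weights.  Predictions are clipped to [0, 1].
#'
#' @param variants data frame of (synonymous) training variants with columns
#'   `mu` and `AC`.
#' @param allow_constant with a single mutability stratum the slope is not
#'   identifiable; set `TRUE` to fall back to a constant model instead of
#'   erroring.
#' @return object of class `singleton_model` with `intercept`, `slope` and
#'   the training `strata` table.
#' @export
fit_singleton_model <- function(variants, allow_constant = FALSE) {
  if (!all(c("mu", "AC") %in% names(variants)))
    stopf("training variants need columns mu and AC")
  if (nrow(variants) == 0L) stopf("empty training set")
  singleton <- as.numeric(variants$AC == 1)
  strata <- stats::aggregate(list(ps = singleton),
                             by = list(mu = variants$mu), FUN = mean)
  strata$n <- as.vector(table(factor(variants$mu, levels = strata$mu)))
  if (nrow(strata) < 2L) {
    if (!allow_constant)
      stopf("only one mutability stratum; need >= 2 distinct mu values (or set allow_constant = TRUE)")
    intercept <- strata$ps[1L]; slope <- 0
  } else {
    fit <- stats::lm(ps ~ mu, data = strata, weights = strata$n)
    intercept <- unname(stats::coef(fit)[1L])
    slope <- unname(stats::coef(fit)[2L])
  }
  structure(list(intercept = intercept, slope = slope, strata = strata),
            class = "singleton_model")
}

#' @export
predict.singleton_model <- function(object, newdata, ...) {
  mu <- if (is.data.frame(newdata)) newdata$mu else newdata
  pmin(pmax(object$intercept + object$slope * mu, 0), 1)
}

#' @export
print.singleton_model <- function(x, ...) {
  cat(sprintf("<singleton_model> ps = %.4g + %.4g * mu (%d strata, %d variants)\n",
              x$intercept, x$slope, nrow(x$strata), sum(x$strata$n)))
  invisible(x)
}

#' Mutability-adjusted proportion of singletons
#'
#' MAPS of a variant set: the observed proportion of singletons minus the
#' mean proportion predicted from each variant's mutability by the
#' synonymous-trained [fit_singleton_model()].  Positive values indicate a
#' singleton excess beyond mutational expectation, a proxy for
#' deleteriousness of the class.  The standard error is the binomial
#' standard deviation of the observed singleton proportion.
#'
#' @param variants data frame with columns `mu` and `AC`.
#' @param model a `singleton_model`.
#' @param label optional class label carried into the result.
#' @return one-row data frame (class `maps_result`): `label`, `n_variants`,
#'   `n_singletons`, `ps`, `expected`, `maps`, `se`.
#' @export
maps_score <- function(variants, model, label = NA_character_) {
  stopifnot(inherits(model, "singleton_model"))
  if (!all(c("mu", "AC") %in% names(variants)))
    stopf("variants need columns mu and AC")
  n <- nrow(variants)
  if (n == 0L)
    return(structure(data.frame(label = label, n_variants = 0L,
                                n_singletons = 0L, ps = NA_real_,
                                expected = NA_real_, maps = NA_real_,
                                se = NA_real_, stringsAsFactors = FALSE),
                     class = c("maps_result", "data.frame")))
  ns <- sum(variants$AC == 1)
  ps <- ns / n
  expected <- mean(predict(model, variants))
  structure(data.frame(label = label, n_variants = n, n_singletons = ns,
                       ps = ps, expected = expected, maps = ps - expected,
                       se = sqrt(ps * (1 - ps) / n),
                       stringsAsFactors = FALSE),
            class = c("maps_result", "data.frame"))
}

#' MAPS profile across functional classes
#'
#' One MAPS result per functional class, ordered from the most to the least
#' selected class in routine data: pLOF, 5/5 missense (missense predicted
#' deleterious by all five algorithms), missense, synonymous, noncoding.
#' Classes absent from the input are omitted with a warning.
#'
#' @param variants sites data frame with `consequence`, `mu`, `AC` and
#'   (for the 5/5 class) `pred_del_count`.
#' @param model a `singleton_model`.
#' @return data frame of [maps_score()] rows.
#' @export
class_maps_profile <- function(variants, model) {
  sets <- list(
    pLOF = variants[is_plof(variants$consequence), ],
    missense_5of5 = variants[variants$consequence == "missense" &
                               !is.na(variants$pred_del_count %||% NA) &
                               (variants$pred_del_count %||% NA) == 5L, ],
    missense = variants[variants$consequence == "missense", ],
    synonymous = variants[variants$consequence == "synonymous", ],
    noncoding = variants[variants$consequence == "noncoding", ]
  )
  keep <- vapply(sets, nrow, 0L) > 0L
  if (any(!keep))
    warnf("empty class(es) omitted from MAPS profile: %s",
          paste(names(sets)[!keep], collapse = ", "))
  out <- do.call(rbind, lapply(names(sets)[keep], function(cl)
    maps_score(sets[[cl]], model, label = cl)))
  rownames(out) <- NULL
  out
}

#' Calibrate a deleteriousness-score threshold against a MAPS reference
#'
#' Sweeps a threshold grid over a per-variant score in [0, 1]; at each
#' threshold `t` the MAPS of the cumulative set `{score >= t}` is computed,
#' and the chosen threshold is the smallest `t` whose MAPS reaches the
#' reference's MAPS with at least `min_variants` variants in the set.  The
#' reference is typically the 5/5 missense class.  A disjoint-bin mode
#' (`[t, t + step)` sets) is available for diagnostics; the cumulative
#' reading is the default because it makes "minimum threshold" well defined.
#'
#' @param variants sites data frame carrying the score column, `mu`, `AC`.
#' @param score name of the score column (values in [0, 1]).
#' @param model a `singleton_model`.
#' @param reference a [maps_score()] row, or a data frame of variants from
#'   which the reference MAPS is computed.
#' @param grid_step threshold grid step (default 0.01).
#' @param min_variants minimum evaluated-set size (default 500).
#' @param mode `"cumulative"` (default) or `"bins"`.
#' @return object of class `maps_calibration`: `score`, `curve` (one row per
#'   threshold), `reference`, `chosen` (numeric or `NA` if the reference
#'   level is never reached).
#' @export
calibrate_threshold <- function(variants, score, model, reference,
                                grid_step = 0.01, min_variants = 500L,
                                mode = c("cumulative", "bins")) {
  mode <- match.arg(mode)
  if (!score %in% names(variants)) stopf("no score column '%s'", score)
  sc <- variants[[score]]
  keep <- !is.na(sc)
  variants <- variants[keep, ]; sc <- sc[keep]
  if (any(sc < 0 | sc > 1)) stopf("scores must lie in [0, 1]")
  if (is.data.frame(reference) && !inherits(reference, "maps_result"))
    reference <- maps_score(reference, model, label = "reference")
  if (!is.finite(reference$maps))
    stopf("reference MAPS is not computable")
  grid <- seq(0, 1, by = grid_step)
  rows <- lapply(grid, function(t) {
    set <- if (mode == "cumulative") variants[sc >= t, ]
           else variants[sc >= t & sc < t + grid_step, ]
    r <- maps_score(set, model, label = sprintf("t=%.4g", t))
    r$threshold <- t
    r
  })
  curve <- do.call(rbind, rows)
  eligible <- curve$n_variants >= min_variants & !is.na(curve$maps) &
    curve$maps >= reference$maps
  chosen <- if (any(eligible)) curve$threshold[which(eligible)[1L]] else NA_real_
  structure(list(score = score, curve = curve, reference = reference,
                 chosen = chosen, min_variants = min_variants, mode = mode),
            class = "maps_calibration")
}

#' @export
print.maps_calibration <- function(x, ...) {
  cat(sprintf("<maps_calibration> score '%s': reference MAPS = %.4f, chosen threshold = %s (%s sets, min %d variants)\n",
              x$score, x$reference$maps,
              if (is.na(x$chosen)) "none reached" else format(x$chosen),
              x$mode, x$min_variants))
  invisible(x)
}
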