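#' @title Standardised major axis regression and the two scaling tests
#' @description SMA (reduced major axis) line fitting on log-log axes, a
#'   hypothesis test of the SMA slope against a reference value, case
#'   bootstrap confidence intervals, and the two headline tests:
#'   proportionality of temperature-corrected rate to mass-corrected biomass
#'   (expected slope 1) and community-level metabolic compensation (expected
#'   slope -1 between log abundance and log average individual rate).
#' @name scaling_tests
NULL

#' Fit a standardised major axis line
#'
#' `slope = sign(r) * sd(y)/sd(x)`, `intercept = mean(y) - slope * mean(x)`.
#' SMA estimates the underlying line of best fit treating the axes
#' symmetrically, appropriate when testing a theoretical slope rather than
#' predicting y from x.
#'
#' @param x,y Numeric vectors (already on log scale for scaling analyses).
#' @param b0 Optional reference slope; when supplied, the slope test of
#'   [sma_slope_test()] is attached.
#' @return Object of class `sma_fit` with `slope`, `intercept`, `r2`, `n`,
#'   and optionally `slope_test`.
#' @export
sma_fit <- function(x, y, b0 = NULL) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance on an axis: SMA undefined")
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)  # r exactly 0
  fit <- structure(list(slope = slope,
                        intercept = mean(y) - slope * mean(x),
                        r2 = r^2, n = n,
                        ols_slope = r * stats::sd(y) / stats::sd(x)),
                   class = "sma_fit")
  if (!is.null(b0)) fit$slope_test <- sma_slope_test(x, y, b0)
  fit
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit: slope = %.4f, intercept = %.4f, R2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r2, x$n))
  if (!is.null(x$slope_test))
    cat(sprintf("  slope test vs b0 = %g: r = %.4f, df = %d, p = %.4g\n",
                x$slope_test$b0, x$slope_test$r, x$slope_test$df,
                x$slope_test$p))
  if (!is.null(x$boot_ci_slope))
    cat(sprintf("  bootstrap 95%% CI slope [%.4f, %.4f], intercept [%.4f, %.4f]\n",
                x$boot_ci_slope[1], x$boot_ci_slope[2],
                x$boot_ci_intercept[1], x$boot_ci_intercept[2]))
  invisible(x)
}

#' Test an SMA slope against a reference value
#'
#' The SMA slope equals `b0` exactly when the correlation between the
#' residual axis `y - b0*x` and the fitted axis `y + b0*x` is zero, so the
#' test is a Pearson correlation t-test between those two rotated variables
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param b0 Reference slope (1 for the proportionality test, -1 for the
#'   compensation test).
#' @return List with `b0`, `r`, `df`, `p`.
#' @export
sma_slope_test <- function(x, y, b0) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  resid_ax <- y - b0 * x
  fitted_ax <- y + b0 * x
  if (stats::sd(resid_ax) == 0 || stats::sd(fitted_ax) == 0)
    return(list(b0 = b0, r = 0, df = n - 2L, p = 1))
  r <- stats::cor(resid_ax, fitted_ax)
  df <- n - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(b0 = b0, r = r, df = df,
       p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}

#' Bootstrap confidence intervals for an SMA fit
#'
#' Case-resampling bootstrap with percentile intervals. Degenerate resamples
#' (zero variance on either axis) are redrawn and counted.
#'
#' @param x,y Numeric vectors.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return List with `slope` and `intercept` percentile intervals,
#'   `slopes`/`intercepts` replicate vectors, and `n_redrawn`.
#' @export
bootstrap_sma <- function(x, y, n_boot = 1000, seed = 1L, level = 0.95) {
  n <- length(x)
  set.seed(seed)
  slopes <- numeric(n_boot)
  ints <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100 * n_boot) stop("bootstrap cannot find non-degenerate resamples")
    }
    f <- sma_fit(x[idx], y[idx])
    slopes[b] <- f$slope
    ints[b] <- f$intercept
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(slope = unname(stats::quantile(slopes, probs)),
       intercept = unname(stats::quantile(ints, probs)),
       slopes = slopes, intercepts = ints, n_redrawn = redrawn)
}

# Shared machinery for the two scaling tests: SMA fit + slope test on the
# full data, plus a bootstrap of the data *and model* -- each resample of
# communities refits the scaling model before recomputing the axes, so the
# intervals propagate parameter-estimation uncertainty as well as sampling
# noise. Degenerate or non-identifiable resamples are redrawn and counted.
.scaling_sma <- function(communities, fit, xy_fun, b0, n_boot, seed) {
  obs <- xy_fun(communities, fit$params)
  out <- sma_fit(obs$x, obs$y, b0 = b0)
  n <- length(communities)
  set.seed(seed)
  slopes <- numeric(n_boot)
  ints <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      sf <- tryCatch({
        rf <- fit_mst(communities[idx], fit$flux, "shared",
                      alpha_range = fit$alpha_range, Tc = fit$params$Tc,
                      compute_ci = FALSE)
        xy <- xy_fun(communities[idx], rf$params)
        sma_fit(xy$x, xy$y)
      }, error = function(e) NULL)
      if (!is.null(sf)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100 * n_boot)
        stop("bootstrap cannot find non-degenerate resamples")
    }
    slopes[b] <- sf$slope
    ints[b] <- sf$intercept
  }
  out$boot_ci_slope <- unname(stats::quantile(slopes, c(0.025, 0.975)))
  out$boot_ci_intercept <- unname(stats::quantile(ints, c(0.025, 0.975)))
  out$n_boot_redrawn <- redrawn
  out$xy <- obs
  out
}

#' Proportionality test: temperature-corrected rate vs mass-corrected biomass
#'
#' The scaling model predicts that, after dividing out the direct
#' Boltzmann-Arrhenius temperature effect, community metabolism is directly
#' proportional to mass-corrected biomass: slope 1 and intercept 0 on
#' log-log axes. Fits the SMA line of
#' `ln(temperature-corrected rate)` on `ln(mass-corrected biomass)` using the
#' fitted parameters, tests the slope against 1, and attaches bootstrap CIs.
#'
#' @param communities List of [community()] objects with the fitted flux
#'   observed.
#' @param fit An [fit_mst()] result (pooled/shared parameters).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `sma_fit` object (slope test vs 1, bootstrap CIs, plus the
#'   per-community `table` of corrected values).
#' @export
proportionality_test <- function(communities, fit, n_boot = 1000, seed = 1L) {
  flux <- fit$flux
  xy_fun <- function(comms, p) {
    obs <- vapply(comms, function(cm)
      if (flux == "gpp") cm$gpp_obs else cm$cr_obs, numeric(1))
    list(x = log(vapply(comms, function(cm)
           mass_corrected_biomass(cm$masses, p$alpha, p$ln_b_Tc,
                                  cm$scale_to_litre), numeric(1))),
         y = log(vapply(seq_along(comms), function(j)
           temperature_correct(obs[j], p$E, comms[[j]]$incubator_T, p$Tc),
           numeric(1))))
  }
  out <- .scaling_sma(communities, fit, xy_fun, b0 = 1,
                      n_boot = n_boot, seed = seed)
  out$table <- data.frame(
    community_id = vapply(communities, `[[`, character(1), "id"),
    ln_mass_corrected_biomass = out$xy$x,
    ln_temp_corrected_rate = out$xy$y)
  out
}

#' Ordinary least squares companion fit
#'
#' OLS of y on x for cross-checking an SMA result (the magnitude of the SMA
#' slope always bounds the OLS slope from above).
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
ols_fit <- function(x, y) {
  f <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r2 = summary(f)$r.squared)
}

#' Compensation test: abundance vs average individual rate
#'
#' Under a fixed community energy budget (zero-sum dynamics), any increase in
#' the average individual metabolic rate must be offset by a proportional
#' decrease in total abundance: slope -1 on log-log axes. Fits the SMA line
#' of `ln(n_tot)` on `ln(average individual rate)` and tests the slope
#' against -1.
#'
#' @inheritParams proportionality_test
#' @return An `sma_fit` object (slope test vs -1, bootstrap CIs, plus the
#'   per-community `table`).
#' @export
compensation_test <- function(communities, fit, n_boot = 1000, seed = 1L) {
  xy_fun <- function(comms, p) {
    list(x = log(vapply(comms, function(cm)
           average_individual_rate(cm, p), numeric(1))),
         y = log(vapply(comms, function(cm)
           length(cm$masses) * cm$scale_to_litre, numeric(1))))
  }
  out <- .scaling_sma(communities, fit, xy_fun, b0 = -1,
                      n_boot = n_boot, seed = seed)
  out$table <- data.frame(
    community_id = vapply(communities, `[[`, character(1), "id"),
    ln_avg_individual_rate = out$xy$x, ln_n_tot = out$xy$y)
  out
}
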