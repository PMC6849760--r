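#' @title Maximum-likelihood inference for the scaling model
#' @description Estimates the metabolic normalisation, size-scaling exponent
#'   and activation energy simultaneously from measured community rates and
#'   individual size distributions, assuming lognormal observation error
#'   (Gaussian on log rates). Conditional on the size-scaling exponent alpha
#'   the model is linear in (ln b, E), so those parameters and the error SD
#'   are profiled out in closed form and the optimisation runs over alpha
#'   alone; this makes the fit exact, fast and deterministic.
#' @name mst_inference
NULL

# Prepare the fitting frame: log observed rates, centred inverse thermal
# energy, treatment index, and per-community log-mass vectors.
.mst_data <- function(communities, flux = c("gpp", "cr"), Tc = default_Tc) {
  flux <- match.arg(flux)
  obs <- vapply(communities, function(cm)
    if (flux == "gpp") cm$gpp_obs else cm$cr_obs, numeric(1))
  if (any(!is.finite(obs)) || any(obs <= 0))
    stop("all communities need a finite positive observed ", toupper(flux))
  list(flux = flux, Tc = Tc,
       y = log(obs),
       x = 1 / (boltzmann_k * Tc) -
         1 / (boltzmann_k * vapply(communities, `[[`, numeric(1),
                                   "incubator_T")),
       treat = factor(vapply(communities, `[[`, character(1),
                             "mesocosm_treatment"),
                      levels = c("ambient", "warm")),
       log_scale = log(vapply(communities, `[[`, numeric(1),
                              "scale_to_litre")),
       logm = lapply(communities, function(cm) log(cm$masses)))
}

# log(scale_j * sum_i m_i^alpha) for every community; alpha may be a length-2
# vector indexed by treatment.
.log_structure <- function(dat, alpha) {
  a <- if (length(alpha) == 2) alpha[as.integer(dat$treat)] else
    rep(alpha, length(dat$y))
  dat$log_scale + vapply(seq_along(dat$logm), function(j)
    log(sum(exp(a[j] * dat$logm[[j]]))), numeric(1))
}

# Closed-form inner fit at fixed alpha: OLS of z = y - log_structure(alpha)
# on the model's linear design. Optional constraints fix E or ln_b at given
# values (used for profiling). Returns RSS, coefficients, profile loglik.
.inner_fit <- function(dat, alpha, model = "shared",
                       fix_E = NULL, fix_b = NULL) {
  z <- dat$y - .log_structure(dat, alpha)
  n <- length(z)
  tw <- as.integer(dat$treat) - 1L  # 0 ambient, 1 warm
  cols <- list()
  if (is.null(fix_b)) {
    cols$b <- rep(1, n)
    if (model == "b_split") cols$b_warm <- tw
  } else {
    z <- z - fix_b
  }
  if (is.null(fix_E)) {
    cols$E <- dat$x
    if (model == "E_split") cols$E_warm <- dat$x * tw
  } else {
    z <- z - fix_E * dat$x
  }
  if (length(cols) == 0L) {
    rss <- sum(z^2)
    coef <- numeric(0)
  } else {
    X <- do.call(cbind, cols)
    f <- stats::lm.fit(X, z)
    rss <- sum(f$residuals^2)
    coef <- f$coefficients
  }
  loglik <- -n / 2 * (log(2 * pi * max(rss, 1e-300) / n) + 1)
  list(rss = rss, coef = coef, loglik = loglik, n = n)
}

# Maximise the profile likelihood over alpha (1D for shared/b_split/E_split,
# 2D for alpha_split). Deterministic: golden-section over a bracket for 1D,
# seeded multistart Nelder-Mead for 2D.
.fit_alpha <- function(dat, model, alpha_range = c(-1, 3), n_starts = 50,
                       seed = 1L, fix_E = NULL, fix_b = NULL) {
  negll <- function(a) -.inner_fit(dat, a, model, fix_E, fix_b)$loglik
  if (model == "alpha_split" && is.null(fix_E) && is.null(fix_b)) {
    # the shared-model optimum (equal alphas) is always among the starts, so
    # the split model can never fit worse than the model it nests
    a0 <- stats::optimize(function(a)
      -.inner_fit(dat, a, "shared")$loglik, alpha_range, tol = 1e-10)$minimum
    set.seed(seed)
    best <- NULL
    for (k in seq_len(max(n_starts, 1) + 1)) {
      start <- if (k == 1) c(a0, a0) else
        stats::runif(2, alpha_range[1], alpha_range[2])
      o <- stats::optim(start, function(a) negll(a), method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(alpha = best$par, negll = best$value)
  } else {
    o <- stats::optimize(negll, interval = alpha_range, tol = 1e-10)
    # polish: optimize() can stop early on flat stretches
    o2 <- stats::optim(o$minimum, negll, method = "Brent",
                       lower = alpha_range[1], upper = alpha_range[2],
                       control = list(reltol = 1e-14))
    if (o2$value < o$objective) list(alpha = o2$par, negll = o2$value)
    else list(alpha = o$minimum, negll = o$objective)
  }
}

#' Log-likelihood of the scaling model
#'
#' Gaussian log-likelihood of the observed log rates given scaling parameters:
#' each community contributes `dnorm(log(B_obs), log(B_pred), sigma, log =
#' TRUE)` where `B_pred` is [community_rate()]. The structural sum
#' `sum(m_i^alpha)` is recomputed exactly at the supplied alpha.
#'
#' @param params An [mst_params()] with `sigma > 0`.
#' @param communities List of [community()] objects with observed rates.
#' @param flux `"gpp"` or `"cr"`.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(params, communities, flux = c("gpp", "cr")) {
  flux <- match.arg(flux)
  if (params$sigma <= 0) stop("sigma must be > 0 to evaluate the likelihood")
  dat <- .mst_data(communities, flux, params$Tc)
  mu <- .log_structure(dat, params$alpha) + params$ln_b_Tc + params$E * dat$x
  sum(stats::dnorm(dat$y, mu, params$sigma, log = TRUE))
}

#' Fit the scaling model by maximum likelihood
#'
#' Simultaneously estimates `ln b(Tc)`, `alpha`, `E` and the error SD `sigma`
#' from observed rates and individual size distributions. `model_spec` allows
#' one parameter to differ between long-term treatments:
#' `"shared"` (all common), `"b_split"`, `"E_split"` or `"alpha_split"`.
#'
#' @param communities List of [community()] objects with the requested flux
#'   observed.
#' @param flux `"gpp"` or `"cr"`.
#' @param model_spec Which parameter varies by long-term treatment.
#' @param alpha_range Bracket for the size-scaling exponent (default
#'   c(-1, 3), generous around the biologically plausible 0.75-1.25).
#' @param n_starts Multistart count for the 2-dimensional `alpha_split`
#'   search (1-dimensional profiles are solved by bracketed optimisation and
#'   ignore this).
#' @param seed Seed for the multistart draws.
#' @param Tc Reference temperature (K).
#' @param compute_ci If `TRUE` (default) attach 95 percent profile-likelihood
#'   intervals for the shared model's parameters.
#' @return Object of class `mst_fit` with `params`, `loglik`, `aic`, `n_obs`,
#'   `ci`, `model_spec`, and the prepared data for later profiling.
#' @export
fit_mst <- function(communities, flux = c("gpp", "cr"),
                    model_spec = c("shared", "b_split", "E_split",
                                   "alpha_split"),
                    alpha_range = c(-1, 3), n_starts = 50, seed = 1L,
                    Tc = default_Tc, compute_ci = TRUE) {
  flux <- match.arg(flux)
  model_spec <- match.arg(model_spec)
  dat <- .mst_data(communities, flux, Tc)
  if (length(unique(dat$x)) < 2)
    stop("activation energy E is not identifiable: all communities were ",
         "assayed at a single temperature")
  mean_logm <- vapply(dat$logm, mean, numeric(1))
  if (stats::sd(mean_logm) < 1e-12)
    stop("size-scaling exponent alpha is not identifiable: no mass ",
         "variation across communities")
  n_par <- switch(model_spec, shared = 4L, 5L)
  if (length(dat$y) <= n_par)
    stop("need more communities than parameters (", n_par, ")")

  opt <- .fit_alpha(dat, model_spec, alpha_range, n_starts, seed)
  inner <- .inner_fit(dat, opt$alpha, model_spec)
  sigma_hat <- sqrt(max(inner$rss, 0) / inner$n)
  est <- c(ln_b_Tc = unname(inner$coef["b"]),
           alpha = unname(opt$alpha[1]),
           E = unname(inner$coef["E"]),
           sigma = sigma_hat)
  split_est <- switch(model_spec,
    b_split = c(ln_b_Tc_warm = unname(inner$coef["b"] +
                                        inner$coef["b_warm"])),
    E_split = c(E_warm = unname(inner$coef["E"] + inner$coef["E_warm"])),
    alpha_split = c(alpha_warm = unname(opt$alpha[2])),
    NULL)
  fit <- structure(list(
    params = mst_params(est["ln_b_Tc"], est["alpha"], est["E"],
                        sigma = est["sigma"], Tc = Tc),
    estimates = c(est, split_est),
    loglik = inner$loglik,
    aic = -2 * inner$loglik + 2 * n_par,
    n_obs = inner$n,
    n_par = n_par,
    model_spec = model_spec,
    flux = flux,
    alpha_range = alpha_range,
    data = dat,
    ci = NULL), class = "mst_fit")
  # in the zero-residual limit the Gaussian profile is degenerate (the
  # likelihood is unbounded as sigma -> 0); intervals collapse to the
  # estimate and are not profiled
  if (compute_ci && model_spec == "shared" && sigma_hat > 1e-8) {
    fit$ci <- t(vapply(c("ln_b_Tc", "alpha", "E"),
                       function(p) profile_ci(fit, p), numeric(2)))
    colnames(fit$ci) <- c("lower", "upper")
  }
  fit
}

#' @export
print.mst_fit <- function(x, ...) {
  cat(sprintf("Scaling-model ML fit (%s, model: %s), n = %d\n",
              toupper(x$flux), x$model_spec, x$n_obs))
  est <- x$estimates
  for (nm in names(est)) {
    line <- sprintf("  %-12s %8.4f", nm, est[nm])
    if (!is.null(x$ci) && nm %in% rownames(x$ci))
      line <- paste0(line, sprintf("   95%% CI [%.4f, %.4f]",
                                   x$ci[nm, 1], x$ci[nm, 2]))
    cat(line, "\n")
  }
  cat(sprintf("  logLik = %.4f, AIC = %.4f\n", x$loglik, x$aic))
  invisible(x)
}

#' Profile-likelihood confidence interval
#'
#' Interval at the log-likelihood drop `qchisq(level, 1)/2` (1.92 for 95
#' percent). The profile is computed exactly: with the target parameter
#' fixed, the remaining linear parameters are re-estimated in closed form and
#' alpha by bracketed optimisation. Falls back to a Wald-type quadratic
#' approximation with a warning if the profile hits the search bounds.
#'
#' @param fit A shared-model [fit_mst()] result.
#' @param parameter One of `"ln_b_Tc"`, `"alpha"`, `"E"`, `"sigma"`.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
profile_ci <- function(fit, parameter = c("E", "alpha", "ln_b_Tc", "sigma"),
                       level = 0.95) {
  parameter <- match.arg(parameter)
  if (fit$estimates["sigma"] <= 1e-8)
    stop("residuals are numerically zero: the profile interval is ",
         "degenerate (the fit is exact)")
  if (fit$model_spec != "shared")
    stop("profile_ci supports shared-model fits; for split models compare ",
         "nested fits with compare_treatment_models()")
  dat <- fit$data
  drop <- stats::qchisq(level, 1) / 2
  lmax <- fit$loglik
  est <- fit$estimates[parameter]

  prof <- switch(parameter,
    E = function(v) -.fit_alpha(dat, "shared", fit$alpha_range,
                                fix_E = v)$negll,
    ln_b_Tc = function(v) -.fit_alpha(dat, "shared", fit$alpha_range,
                                      fix_b = v)$negll,
    alpha = function(v) .inner_fit(dat, v, "shared")$loglik,
    sigma = function(v) {
      rss <- .inner_fit(dat, fit$estimates["alpha"], "shared")$rss
      n <- fit$n_obs
      -n / 2 * log(2 * pi * v^2) - rss / (2 * v^2)
    })

  target <- function(v) prof(v) - (lmax - drop)
  step0 <- switch(parameter, alpha = 0.2, E = 0.2, ln_b_Tc = 0.5,
                  sigma = max(0.5 * est, 0.05))
  side <- function(dir) {
    step <- step0
    lo <- est
    hi <- est + dir * step
    for (i in 1:40) {
      if (parameter == "sigma" && hi <= 0) hi <- est * 1e-4
      if (target(hi) < 0)
        return(stats::uniroot(target, sort(c(lo, hi)), tol = 1e-8)$root)
      lo <- hi
      step <- step * 2
      hi <- est + dir * step
      if (parameter == "sigma" && hi <= 0) { hi <- est / 2^i }
    }
    NA_real_
  }
  lower <- side(-1)
  upper <- side(+1)
  if (anyNA(c(lower, upper))) {
    warning("profile for ", parameter,
            " hit the search bounds; using quadratic approximation")
    h <- max(abs(est) * 1e-3, 1e-5)
    curv <- -(prof(est + h) - 2 * lmax + prof(est - h)) / h^2
    se <- 1 / sqrt(max(curv, 1e-12))
    z <- stats::qnorm(1 - (1 - level) / 2)
    if (is.na(lower)) lower <- est - z * se
    if (is.na(upper)) upper <- est + z * se
  }
  c(lower = unname(lower), upper = unname(upper))
}

#' Compare treatment-split model variants by likelihood ratio
#'
#' Fits the shared model and each one-parameter long-term-warming split
#' (`b_split`, `E_split`, `alpha_split`), and tests each split against the
#' shared model with a 1-df likelihood ratio test.
#'
#' @param communities List of [community()] objects.
#' @param flux `"gpp"` or `"cr"`.
#' @param ... Passed on to [fit_mst()].
#' @return Data frame with one row per split: `model`, `loglik`, `aic`,
#'   `statistic` (2 * delta logLik, floored at 0), `df`, `p_value`, and
#'   `preferred` (the lower-AIC model of the pair).
#' @export
compare_treatment_models <- function(communities, flux = c("gpp", "cr"),
                                     ...) {
  flux <- match.arg(flux)
  treats <- unique(vapply(communities, `[[`, character(1),
                          "mesocosm_treatment"))
  if (length(treats) < 2)
    stop("both long-term treatments must be present")
  shared <- fit_mst(communities, flux, "shared", compute_ci = FALSE, ...)
  rows <- lapply(c("b_split", "E_split", "alpha_split"), function(m) {
    f <- tryCatch(fit_mst(communities, flux, m, compute_ci = FALSE, ...),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(model = m, loglik = NA, aic = NA, statistic = NA,
                        df = 1L, p_value = NA, preferred = NA,
                        converged = FALSE))
    stat <- max(0, 2 * (f$loglik - shared$loglik))
    data.frame(model = m, loglik = f$loglik, aic = f$aic,
               statistic = stat, df = 1L,
               p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
               preferred = if (f$aic < shared$aic) m else "shared",
               converged = TRUE)
  })
  out <- rbind(data.frame(model = "shared", loglik = shared$loglik,
                          aic = shared$aic, statistic = NA_real_, df = NA,
                          p_value = NA_real_, preferred = NA,
                          converged = TRUE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
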