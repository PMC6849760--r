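# Maximum-likelihood estimation: likelihood oracle, recovery, invariances,
# model comparison, profile intervals.

make_obs_communities <- function(params, masses_list, temps, obs = NULL,
                                 treatments = NULL) {
  lapply(seq_along(masses_list), function(j) {
    cm <- community(paste0("c", j), masses_list[[j]], temps[j],
                    if (is.null(treatments)) "ambient" else treatments[j])
    cm$gpp_obs <- if (is.null(obs)) community_rate(params, cm) else obs[j]
    cm
  })
}

test_that("log_likelihood matches a hand-computed three-community oracle", {
  p <- mst_params(-1, 0.8, 0.5, sigma = 0.4)
  ml <- list(c(1e-5, 3e-5), c(2e-5), c(1e-5, 1e-5, 4e-5))
  temps <- c(289.15, 291.15, 293.15)
  obs <- c(2e-4, 1e-4, 5e-4)
  comms <- make_obs_communities(p, ml, temps, obs)
  # independent brute-force evaluation, term by term
  expected <- 0
  for (j in 1:3) {
    pred <- sum(exp(-1) * ml[[j]]^0.8 *
                  exp(0.5 * (1 / (k_eV * 291.15) - 1 / (k_eV * temps[j]))))
    expected <- expected + dnorm(log(obs[j]), log(pred), 0.4, log = TRUE)
  }
  expect_equal(log_likelihood(p, comms, "gpp"), expected)
})

test_that("a perfect single-community prediction contributes -log(sigma*sqrt(2*pi))", {
  p <- mst_params(-1, 0.8, 0.5, sigma = 0.3)
  cm <- community("c1", c(1e-5, 2e-5), 291.15)
  cm$gpp_obs <- community_rate(p, cm)
  expect_equal(log_likelihood(p, list(cm), "gpp"),
               -0.5 * log(2 * pi * 0.3^2))
  expect_error(log_likelihood(mst_params(-1, 0.8, 0.5), list(cm), "gpp"),
               "sigma")
  cm$gpp_obs <- -1
  expect_error(log_likelihood(p, list(cm), "gpp"), "positive")
})

test_that("noise-free simulated data recover the generating parameters", {
  cfg <- fast_config(noise_sd = 0, seed = 42)
  ex <- simulate_experiment(cfg)
  for (fl in c("gpp", "cr")) {
    f <- fit_mst(ex$communities, fl, compute_ci = FALSE)
    truth <- if (fl == "gpp") cfg$true_params_gpp else cfg$true_params_cr
    expect_lt(abs(f$estimates["E"] - truth$E), 1e-4)
    expect_lt(abs(f$estimates["alpha"] - truth$alpha), 1e-4)
    expect_lt(abs(f$estimates["ln_b_Tc"] - truth$ln_b_Tc), 1e-4)
  }
})

test_that("E for GPP is below E for CR when simulating from the reference truths", {
  cfg <- fast_config(noise_sd = 0.2, seed = 77)
  ex <- simulate_experiment(cfg)
  fg <- fit_mst(ex$communities, "gpp", compute_ci = FALSE)
  fc <- fit_mst(ex$communities, "cr", compute_ci = FALSE)
  expect_lt(fg$estimates["E"], fc$estimates["E"])
})

test_that("identifiability failures are reported by parameter name", {
  cfg <- fast_config(noise_sd = 0.1, incubator_temps = c(291.15, 291.15),
                     seed = 6)
  ex <- simulate_experiment(cfg)
  expect_error(fit_mst(ex$communities, "gpp"), "E is not identifiable")
  cfg2 <- fast_config(noise_sd = 0.1, mass_logsd = 0,
                      mean_mass_warm = 3.6e-5, seed = 6)
  ex2 <- simulate_experiment(cfg2)
  expect_error(fit_mst(ex2$communities, "gpp"), "alpha is not identifiable")
})

test_that("refitting mass-rescaled data shifts ln b by -alpha*log(c) only", {
  cfg <- fast_config(noise_sd = 0.2, seed = 55)
  ex <- simulate_experiment(cfg)
  f1 <- fit_mst(ex$communities, "gpp", compute_ci = FALSE)
  cc <- 10
  scaled <- lapply(ex$communities, function(cm) {
    cm$masses <- cm$masses * cc
    cm
  })
  f2 <- fit_mst(scaled, "gpp", compute_ci = FALSE)
  expect_equal(f2$estimates["E"], f1$estimates["E"], tolerance = 1e-5)
  expect_equal(f2$estimates["alpha"], f1$estimates["alpha"],
               tolerance = 1e-5)
  expect_equal(unname(f2$estimates["ln_b_Tc"]),
               unname(f1$estimates["ln_b_Tc"] -
                        f1$estimates["alpha"] * log(cc)),
               tolerance = 1e-3)
})

test_that("likelihood at the truth beats perturbed truth on average", {
  cfg <- fast_config(noise_sd = 0.3, seed = 14)
  ex <- simulate_experiment(cfg)
  p_true <- cfg$true_params_gpp
  p_true$sigma <- cfg$noise_sd
  p_off <- p_true
  p_off$E <- p_true$E + 0.5
  expect_gt(log_likelihood(p_true, ex$communities, "gpp"),
            log_likelihood(p_off, ex$communities, "gpp"))
})

test_that("treatment-split comparison behaves at both extremes", {
  # identical communities duplicated across treatments: statistic ~ 0
  cfg <- fast_config(noise_sd = 0.2, seed = 23)
  ex <- simulate_experiment(cfg)
  base <- ex$communities[c(1:5, 11:15)]  # ambient mesocosms, both incubators
  dup <- lapply(base, function(cm) {
    cm$mesocosm_treatment <- "warm"
    cm$id <- paste0(cm$id, "_dup")
    cm
  })
  cmp <- compare_treatment_models(c(base, dup), "gpp")
  expect_equal(cmp$statistic[cmp$model == "b_split"], 0, tolerance = 1e-6)
  expect_equal(cmp$statistic[cmp$model == "E_split"], 0, tolerance = 1e-6)
  # for the linear splits the statistic is exactly 0 by symmetry; the alpha
  # split enters nonlinearly under a shared intercept, so a sliver of
  # improvement off the diagonal is possible
  expect_lt(cmp$statistic[cmp$model == "alpha_split"], 0.1)
  expect_true(all(cmp$preferred[-1] == "shared"))

  # strong true E difference between treatments: E-split wins
  cfg_w <- fast_config(noise_sd = 0.1, seed = 31,
                       true_params_gpp = mst_params(-3.46, 0.88, 1.11))
  cfg_a <- fast_config(noise_sd = 0.1, seed = 31,
                       true_params_gpp = mst_params(-3.46, 0.88, 0.61))
  ex_a <- simulate_experiment(cfg_a)$communities
  ex_w <- simulate_experiment(cfg_w)$communities
  mixed <- c(Filter(function(cm) cm$mesocosm_treatment == "ambient", ex_a),
             Filter(function(cm) cm$mesocosm_treatment == "warm", ex_w))
  cmp2 <- compare_treatment_models(mixed, "gpp")
  expect_lt(cmp2$p_value[cmp2$model == "E_split"], 0.01)
  expect_equal(cmp2$preferred[cmp2$model == "E_split"], "E_split")
})

test_that("profile intervals bracket the estimate and widen with noise", {
  cfg_lo <- fast_config(noise_sd = 0.15, seed = 62)
  cfg_hi <- fast_config(noise_sd = 0.45, seed = 62)
  f_lo <- fit_mst(simulate_experiment(cfg_lo)$communities, "gpp")
  f_hi <- fit_mst(simulate_experiment(cfg_hi)$communities, "gpp",
                  compute_ci = FALSE)
  for (par in c("E", "alpha", "ln_b_Tc")) {
    ci <- f_lo$ci[par, ]
    expect_lt(ci[1], f_lo$estimates[par])
    expect_gt(ci[2], f_lo$estimates[par])
    ci_hi <- profile_ci(f_hi, par)
    expect_gt(diff(ci_hi), diff(unname(ci)))
  }
  # large-n: profile approximately equals the Wald interval implied by the
  # quadratic shape of the profile (symmetry check)
  ciE <- f_lo$ci["E", ]
  mid <- mean(ciE)
  expect_equal(mid, unname(f_lo$estimates["E"]), tolerance = 0.05)
})
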