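# Forward model: Boltzmann factor, Q10, individual and community rates,
# mass/temperature corrections.

test_that("boltzmann_factor matches its closed form and edge cases", {
  expect_equal(boltzmann_factor(0, 293.15, 291.15), 1.0)
  expect_equal(boltzmann_factor(0.74, 291.15, 291.15), 1.0)
  # independent evaluation of the exponential
  expect_equal(boltzmann_factor(0.61, 293.15, 291.15),
               exp(0.61 * (1 / (k_eV * 291.15) - 1 / (k_eV * 293.15))))
  expect_gt(boltzmann_factor(0.5, 295, 291.15), 1)
  expect_lt(boltzmann_factor(0.5, 288, 291.15), 1)
  expect_error(boltzmann_factor(0.5, -1, 291.15), "positive")
})

test_that("q10_from_E reproduces the conventional printed pairs", {
  expect_equal(round(q10_from_E(0.74), 2), 2.75)
  expect_equal(q10_from_E(1.42), 6.99, tolerance = 0.01 / 6.99)
  expect_equal(q10_from_E(0), 1.0)
  expect_error(q10_from_E(0.5, 286.15, 299.15), "10 K")
})

test_that("individual_rate evaluates the power-law Arrhenius form", {
  expect_equal(individual_rate(mst_params(0, 1, 0), 2, 300), 2.0)
  expect_equal(individual_rate(mst_params(0, 0.5, 0), 4, 280), 2.0)
  p <- mst_params(-3.46, 0.88, 0.61)
  expect_equal(individual_rate(p, 1e-4, 293.15),
               exp(-3.46) * (1e-4)^0.88 *
                 boltzmann_factor(0.61, 293.15, 291.15))
  expect_error(individual_rate(p, -1, 293.15), "> 0")
})

test_that("community_rate is additive over cells (brute-force oracle)", {
  p <- mst_params(0, 0.5, 0)
  expect_equal(community_rate(p, toy_community()), 1 + sqrt(2) + 2)
  # one-cell community equals the individual rate
  one <- toy_community(masses = 3.3, T_K = 295)
  expect_equal(community_rate(mst_params(-1, 0.7, 0.4), one),
               individual_rate(mst_params(-1, 0.7, 0.4), 3.3, 295))
  # random communities vs explicit per-cell sum
  set.seed(11)
  for (rep in 1:5) {
    p <- mst_params(runif(1, -5, 0), runif(1, 0.3, 1.3), runif(1, 0, 1.5))
    m <- rlnorm(sample(1:1000, 1), -9, 1)
    cm <- toy_community(m, T_K = runif(1, 285, 298), scale = runif(1, 1, 50))
    expect_equal(community_rate(p, cm),
                 cm$scale_to_litre *
                   sum(sapply(m, function(mi)
                     individual_rate(p, mi, cm$incubator_T))))
  }
})

test_that("mass_corrected_biomass: isometric identity and brute force", {
  m <- c(0.2, 1.7, 3.1)
  expect_equal(mass_corrected_biomass(m, alpha = 1, ln_b_Tc = 0), sum(m))
  expect_equal(mass_corrected_biomass(c(1, 2, 4), 0.5, 0), 1 + sqrt(2) + 2)
  expect_equal(mass_corrected_biomass(5, 0.7, 0), 5^0.7)
  # scale covariance: masses * c multiplies the result by c^alpha
  expect_equal(mass_corrected_biomass(3 * m, 0.8, -1),
               3^0.8 * mass_corrected_biomass(m, 0.8, -1))
})

test_that("temperature_correct inverts the Boltzmann factor", {
  expect_equal(temperature_correct(5, 0.61, 291.15), 5)
  expect_equal(temperature_correct(10, 1.27, 293.15),
               10 / exp(1.27 * (1 / (k_eV * 291.15) - 1 / (k_eV * 293.15))))
  expect_error(temperature_correct(-2, 0.61, 293.15), "> 0")
})

test_that("correction round-trip: corrected model rate = mass-corrected biomass", {
  set.seed(21)
  for (rep in 1:10) {
    p <- mst_params(runif(1, -6, 0), runif(1, 0.2, 1.4), runif(1, 0, 2))
    cm <- toy_community(rlnorm(50, -9, 1), T_K = runif(1, 285, 299),
                        scale = runif(1, 1, 1e4))
    lhs <- temperature_correct(community_rate(p, cm), p$E, cm$incubator_T,
                               p$Tc)
    rhs <- mass_corrected_biomass(cm$masses, p$alpha, p$ln_b_Tc,
                                  cm$scale_to_litre)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("community_rate is monotone in temperature and in mass", {
  p <- mst_params(-2, 0.8, 0.6)
  cm <- toy_community(c(1e-5, 2e-5))
  rates <- sapply(286:296 + 0.15, function(T_K) {
    cm$incubator_T <- T_K
    community_rate(p, cm)
  })
  expect_true(all(diff(rates) > 0))
  cm_big <- toy_community(c(2e-5, 4e-5))
  expect_gt(community_rate(p, cm_big), community_rate(p, cm))
})

test_that("average_individual_rate is invariant to abundance scaling", {
  p <- mst_params(0, 0.5, 0)
  expect_equal(average_individual_rate(toy_community(), p),
               (1 + sqrt(2) + 2) / 3)
  cm1 <- toy_community(c(1, 2, 4), scale = 1)
  cm2 <- toy_community(c(1, 2, 4, 1, 2, 4), scale = 1)  # duplicated cells
  expect_equal(average_individual_rate(cm1, p),
               average_individual_rate(cm2, p))
  one <- toy_community(0.5, T_K = 294)
  expect_equal(average_individual_rate(one, p),
               individual_rate(p, 0.5, 294))
})

test_that("constructors validate their invariants", {
  expect_error(mst_params(0, 1, 0, sigma = -1), "sigma")
  expect_error(community("x", numeric(0), 291.15), "non-empty")
  expect_error(community("x", c(1, -2), 291.15), "> 0")
  expect_error(community("x", 1, -5), "positive")
})
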