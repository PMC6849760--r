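#' @title Core metabolic scaling model
#' @description Forward (prediction) side of the metabolic scaling model:
#'   individual metabolic rate as a power law of carbon mass times a
#'   Boltzmann-Arrhenius temperature factor, summed over all individuals to
#'   give community metabolism, plus the temperature- and mass-correction
#'   transformations used by the two headline scaling tests.
#' @name core_mst
NULL

#' Boltzmann's constant in electron-volts per Kelvin
#'
#' Fixed at 8.62e-5 eV/K (the rounded value conventional in the metabolic
#' ecology literature, not the CODATA 8.617e-5).
#' @export
boltzmann_k <- 8.62e-5

#' Default reference temperature (18 degrees C, in Kelvin)
#' @export
default_Tc <- 291.15

#' Construct a set of metabolic scaling parameters
#'
#' @param ln_b_Tc Log metabolic normalisation at the reference temperature
#'   `Tc`: the log rate (umol O2 L^-1 h^-1) of a hypothetical individual of
#'   unit mass (1 ug C) at `Tc`.
#' @param alpha Dimensionless size-scaling exponent of metabolic rate.
#' @param E Activation energy (eV) describing the temperature dependence.
#' @param sigma Lognormal observation error SD (log units), >= 0.
#' @param Tc Reference temperature in Kelvin (default 291.15 K = 18 C).
#' @return An object of class `mst_params`.
#' @examples
#' p <- mst_params(ln_b_Tc = -3.46, alpha = 0.88, E = 0.61)
#' @export
mst_params <- function(ln_b_Tc, alpha, E, sigma = 0, Tc = default_Tc) {
  stopifnot(is.finite(ln_b_Tc), is.finite(alpha), is.finite(E))
  if (sigma < 0) stop("sigma must be >= 0")
  if (Tc <= 0) stop("Tc must be a positive absolute temperature (K)")
  structure(list(ln_b_Tc = ln_b_Tc, alpha = alpha, E = E,
                 sigma = sigma, Tc = Tc),
            class = "mst_params")
}

#' @export
print.mst_params <- function(x, ...) {
  cat("MST parameters:\n")
  cat(sprintf("  ln b(Tc) = %.4f   alpha = %.4f   E = %.4f eV   sigma = %.4f   Tc = %.2f K\n",
              x$ln_b_Tc, x$alpha, x$E, x$sigma, x$Tc))
  invisible(x)
}

#' Construct a community record
#'
#' A community is one laboratory microcosm: its treatment labels, assay
#' temperature, the list of individual carbon masses sampled from it, a
#' multiplier converting that sample to per-litre abundance, and (optionally)
#' its measured metabolic fluxes.
#'
#' @param id Community label.
#' @param masses Vector of individual carbon masses (ug C), all > 0.
#' @param incubator_T Assay temperature in Kelvin.
#' @param mesocosm_treatment `"ambient"` or `"warm"` (long-term history).
#' @param scale_to_litre Multiplier converting the sampled cell list to cells
#'   per litre (default 1).
#' @param gpp_obs,cr_obs Measured gross primary production and community
#'   respiration (umol O2 L^-1 h^-1); `NA` until flux extraction has run.
#' @return An object of class `mst_community`.
#' @export
community <- function(id, masses, incubator_T,
                      mesocosm_treatment = c("ambient", "warm"),
                      scale_to_litre = 1, gpp_obs = NA_real_,
                      cr_obs = NA_real_) {
  mesocosm_treatment <- match.arg(mesocosm_treatment)
  if (length(masses) < 1L) stop("masses must be non-empty")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all individual masses must be finite and > 0")
  if (incubator_T <= 0) stop("incubator_T must be a positive temperature (K)")
  if (scale_to_litre <= 0) stop("scale_to_litre must be > 0")
  structure(list(id = id, mesocosm_treatment = mesocosm_treatment,
                 incubator_T = incubator_T, masses = as.numeric(masses),
                 scale_to_litre = scale_to_litre,
                 gpp_obs = gpp_obs, cr_obs = cr_obs),
            class = "mst_community")
}

#' @export
print.mst_community <- function(x, ...) {
  cat(sprintf("Community %s: %s mesocosm, %.2f K incubator, %d cells sampled (x%.3g per litre)\n",
              x$id, x$mesocosm_treatment, x$incubator_T,
              length(x$masses), x$scale_to_litre))
  invisible(x)
}

#' Boltzmann-Arrhenius temperature factor
#'
#' Computes `exp(E * (1/(k*Tc) - 1/(k*T)))`, the factor by which a metabolic
#' rate at the reference temperature `Tc` is scaled at assay temperature `T`.
#' Greater than 1 when `T > Tc` and `E > 0`.
#'
#' @param E Activation energy (eV).
#' @param T_K Assay temperature (K).
#' @param Tc Reference temperature (K).
#' @return Dimensionless factor.
#' @export
boltzmann_factor <- function(E, T_K, Tc = default_Tc) {
  if (any(T_K <= 0) || any(Tc <= 0))
    stop("temperatures must be positive absolute temperatures (K)")
  exp(E * (1 / (boltzmann_k * Tc) - 1 / (boltzmann_k * T_K)))
}

#' Convert an activation energy to a Q10 factor
#'
#' Q10 is the factor by which a rate increases over a 10-degree warming. The
#' Q10 implied by an activation energy depends on the interval chosen; the
#' default interval is the 10 C window centred on the 18 C reference
#' temperature (286.15 K to 296.15 K), which reproduces the conventional
#' printed pairs E = 0.74 eV -> Q10 = 2.75 and E = 1.42 eV -> Q10 = 6.99.
#'
#' @param E Activation energy (eV).
#' @param T_low,T_high Interval endpoints (K); must differ by exactly 10 K.
#' @return Q10 factor.
#' @export
q10_from_E <- function(E, T_low = 286.15, T_high = 296.15) {
  if (abs((T_high - T_low) - 10) > 1e-9)
    stop("Q10 requires an interval of exactly 10 K")
  exp((E / boltzmann_k) * (1 / T_low - 1 / T_high))
}

#' Individual metabolic rate
#'
#' Rate of one cell of carbon mass `m` at temperature `T_K`:
#' `exp(ln_b_Tc) * m^alpha * boltzmann_factor(E, T_K, Tc)`.
#'
#' @param params An [mst_params()] object.
#' @param m Individual carbon mass (ug C), > 0. Vectorised.
#' @param T_K Assay temperature (K).
#' @return Rate per cell (umol O2 h^-1 cell^-1 scale).
#' @export
individual_rate <- function(params, m, T_K) {
  if (any(m <= 0)) stop("mass must be > 0")
  exp(params$ln_b_Tc + params$alpha * log(m)) *
    boltzmann_factor(params$E, T_K, params$Tc)
}

#' Community metabolic rate
#'
#' Sums [individual_rate()] over every sampled cell and scales to a litre:
#' per-litre community metabolism under the scaling model.
#'
#' @param params An [mst_params()] object.
#' @param comm An [community()] object.
#' @return Rate in umol O2 L^-1 h^-1.
#' @export
community_rate <- function(params, comm) {
  if (length(comm$masses) == 0L) stop("community has an empty mass vector")
  comm$scale_to_litre *
    sum(individual_rate(params, comm$masses, comm$incubator_T))
}

#' Mass-corrected biomass
#'
#' The size-structure-aware metabolic capacity of the standing biomass:
#' `exp(ln_b_Tc) * sum(m_i^alpha) * scale`. Algebraically this is total
#' biomass times a biomass-weighted average of `m^(alpha-1)` with a common
#' normalisation, and equals the community rate evaluated at the reference
#' temperature.
#'
#' @param masses Vector of individual masses (ug C).
#' @param alpha Size-scaling exponent.
#' @param ln_b_Tc Log normalisation at `Tc`.
#' @param scale_to_litre Per-litre multiplier (default 1).
#' @return Mass-corrected biomass on the rate scale.
#' @export
mass_corrected_biomass <- function(masses, alpha, ln_b_Tc = 0,
                                   scale_to_litre = 1) {
  if (length(masses) == 0L) stop("masses must be non-empty")
  if (any(masses <= 0)) stop("all masses must be > 0")
  scale_to_litre * exp(ln_b_Tc) * sum(exp(alpha * log(masses)))
}

#' Temperature-correct an observed rate
#'
#' Removes the direct Boltzmann-Arrhenius temperature effect from an observed
#' rate by *dividing* by the temperature factor, so that the corrected value
#' of a noise-free model rate equals the mass-corrected biomass exactly.
#'
#' Note on conventions: the correction must divide the observed rate by
#' `boltzmann_factor(E, T, Tc)` (equivalently multiply by the factor with the
#' temperatures' roles exchanged); multiplying instead would inflate rather
#' than remove the advantage of warm-assayed communities.
#'
#' @param rate_obs Observed rate, > 0.
#' @param E Activation energy (eV).
#' @param T_K Assay temperature (K).
#' @param Tc Reference temperature (K).
#' @return Temperature-corrected rate.
#' @export
temperature_correct <- function(rate_obs, E, T_K, Tc = default_Tc) {
  if (any(rate_obs <= 0)) stop("rate_obs must be > 0")
  rate_obs / boltzmann_factor(E, T_K, Tc)
}

#' Average individual metabolic rate
#'
#' Community rate divided by total abundance: the per-cell metabolic rate
#' averaged over the size distribution, including the temperature effect.
#' Invariant to duplicating every cell (abundance changes, size structure
#' does not).
#'
#' @param comm An [community()] object.
#' @param params An [mst_params()] object.
#' @return Rate per cell.
#' @export
average_individual_rate <- function(comm, params) {
  n_tot <- length(comm$masses) * comm$scale_to_litre
  if (n_tot <= 0) stop("community has zero abundance")
  community_rate(params, comm) / n_tot
}
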