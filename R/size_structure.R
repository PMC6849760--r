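#' @title Cytometry size conversion and size-distribution summaries
#' @description Converts flow-cytometer forward scatter to cell diameter via a
#'   configurable power-law calibration, diameter to carbon mass assuming
#'   spherical cells, checks the heterotrophic (bacterial) biomass fraction,
#'   and summarises individual size distributions.
#' @name size_structure
NULL

#' Convert forward scatter to cell diameter
#'
#' Power-law calibration `d = a * fsc^b`. The calibration coefficients are
#' instrument-specific and must be supplied; there is no default.
#'
#' @param fsc Forward scatter (instrument units), > 0. Vectorised.
#' @param calibration List with elements `a` and `b`.
#' @return Diameter in um.
#' @export
fsc_to_diameter <- function(fsc, calibration) {
  if (is.null(calibration$a) || is.null(calibration$b))
    stop("fsc input requires a calibration list(a, b); ",
         "supply diameters directly if no calibration is available")
  if (any(fsc <= 0)) stop("forward scatter must be > 0")
  if (calibration$b == 0)
    warning("calibration exponent b = 0: all diameters equal a")
  calibration$a * fsc^calibration$b
}

#' Convert cell diameter to carbon mass
#'
#' Spherical biovolume `V = (4/3) * pi * (d/2)^3` (um^3) converted to carbon
#' with the conversion factor 0.109e-6 ug C per um^3.
#'
#' @param d Diameter in um, > 0. Vectorised.
#' @return Carbon mass in ug C per cell.
#' @export
diameter_to_carbon <- function(d) {
  if (any(d <= 0)) stop("diameter must be > 0")
  0.109e-6 * (4 / 3) * pi * (d / 2)^3
}

#' Heterotrophic biomass fraction
#'
#' Fraction of total carbon biomass contributed by heterotroph-labelled
#' records. Warns above a threshold (default 5 percent), the level beyond
#' which bacterial respiration could bias community flux measurements; all
#' scaling analyses should use only the autotroph size distribution.
#'
#' @param masses Carbon masses (ug C).
#' @param population Character vector, `"autotroph"` or `"heterotroph"`, one
#'   per mass.
#' @param threshold Warning threshold on the fraction (default 0.05).
#' @return The heterotroph carbon fraction in [0, 1].
#' @export
heterotroph_biomass_fraction <- function(masses, population,
                                         threshold = 0.05) {
  stopifnot(length(masses) == length(population),
            all(population %in% c("autotroph", "heterotroph")))
  tot <- sum(masses)
  het <- sum(masses[population == "heterotroph"])
  frac <- if (tot > 0) het / tot else 0
  if (frac >= threshold)
    warning(sprintf("heterotrophs are %.1f%% of carbon biomass (threshold %.0f%%): community flux measurements may be biased",
                    100 * frac, 100 * threshold))
  frac
}

#' Summarise an individual size distribution
#'
#' Total abundance, total biomass, mean mass, and (given fitted parameters)
#' mass-corrected biomass and average individual rate; also a kernel density
#' of log10 mass for size-spectrum plots.
#'
#' @param comm An [community()] object.
#' @param params Optional [mst_params()] to add the model-based summaries.
#' @param density_n Grid points for the log-mass kernel density (default 256).
#' @return List of class `isd_summary`.
#' @export
summarise_isd <- function(comm, params = NULL, density_n = 256) {
  m <- comm$masses
  sc <- comm$scale_to_litre
  out <- list(id = comm$id,
              n_tot = length(m) * sc,
              M_tot = sum(m) * sc,
              mean_mass = mean(m))
  if (!is.null(params)) {
    out$mass_corrected_biomass <-
      mass_corrected_biomass(m, params$alpha, params$ln_b_Tc, sc)
    out$avg_individual_rate <- average_individual_rate(comm, params)
  }
  if (length(m) >= 2) {
    d <- stats::density(log10(m), n = density_n)
    out$log10_mass_density <- data.frame(log10_mass = d$x, density = d$y)
  }
  class(out) <- "isd_summary"
  out
}

#' Read a cytometry event table and build communities
#'
#' The CSV must have columns `community_id`, `population`
#' (autotroph/heterotroph), and exactly one of `fsc` or `diameter`.
#' Heterotrophs are excluded from the returned mass vectors after the biomass
#' fraction check.
#'
#' @param path CSV path.
#' @param calibration `list(a, b)` power-law FSC calibration (required when
#'   the file carries `fsc`).
#' @param meta Data frame with `community_id`, `mesocosm_treatment`,
#'   `incubator_T`, and optionally `scale_to_litre`.
#' @param het_threshold Heterotroph-fraction warning threshold.
#' @return List of [community()] objects (masses in ug C, autotrophs only).
#' @export
read_cytometry <- function(path, meta, calibration = NULL,
                           het_threshold = 0.05) {
  df <- utils::read.csv(path)
  if (!xor("fsc" %in% names(df), "diameter" %in% names(df)))
    stop("cytometry file must have exactly one of 'fsc' or 'diameter'")
  if ("fsc" %in% names(df))
    df$diameter <- fsc_to_diameter(df$fsc, calibration)
  df$mass <- diameter_to_carbon(df$diameter)
  if (!"population" %in% names(df)) df$population <- "autotroph"
  lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    sub <- df[df$community_id == row$community_id, ]
    if (nrow(sub) == 0) stop("no cytometry events for community ",
                             row$community_id)
    heterotroph_biomass_fraction(sub$mass, sub$population, het_threshold)
    community(id = row$community_id,
              masses = sub$mass[sub$population == "autotroph"],
              incubator_T = row$incubator_T,
              mesocosm_treatment = row$mesocosm_treatment,
              scale_to_litre = if ("scale_to_litre" %in% names(row))
                row$scale_to_litre else 1)
  })
}
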