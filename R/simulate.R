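#' @title Synthetic mesocosm communities
#' @description Generator for communities with the statistical structure the
#'   scaling analysis assumes: a 2 x 2 x 10 design (long-term warmed/ambient
#'   mesocosm crossed with warm/ambient incubator, 10 replicates), right-skewed
#'   lognormal individual size distributions with warmed communities dominated
#'   by larger cells, rates generated from the scaling model with lognormal
#'   noise, and a zero-sum energy budget linking abundance to average
#'   individual rate.
#' @name synthetic_communities
NULL

#' Simulation configuration
#'
#' Defaults encode the experiment the simulator emulates: 10 replicate
#' mesocosms per long-term treatment assayed at 16 and 20 C; ambient
#' communities with mean cell mass 3.6e-5 ug C and warm communities 1.06e-4
#' ug C; generating parameters equal to the maximum-likelihood estimates for
#' gross primary production (GPP) and community respiration (CR).
#'
#' @param n_mesocosms_per_treatment Replicates per long-term treatment
#'   (default 10).
#' @param incubator_temps Assay temperatures in Kelvin (default
#'   c(289.15, 293.15), i.e. 16 and 20 C).
#' @param mean_mass_ambient,mean_mass_warm Arithmetic mean individual carbon
#'   mass (ug C) per long-term treatment.
#' @param mass_logsd Log-scale SD of the lognormal mass distribution
#'   (default 1; unconstrained by observation, chosen for visible right skew).
#' @param true_params_gpp,true_params_cr Generating [mst_params()] for the
#'   two fluxes.
#' @param total_energy Zero-sum community energy budget (umol O2 L^-1 h^-1):
#'   every community's expected GPP under the budget (default 10, a typical
#'   productive-microcosm oxygen flux).
#' @param zero_sum If `TRUE` (default) abundance is set so expected GPP equals
#'   `total_energy` exactly (the log-log abundance vs average-rate slope is
#'   -1 by construction); if `FALSE` abundance is drawn around `n_tot_fixed`
#'   independently of the size structure (no compensation: the negative
#'   control).
#' @param n_tot_fixed Median per-litre abundance when `zero_sum = FALSE`.
#' @param abundance_logsd Lognormal dispersion of abundance around
#'   `n_tot_fixed` in the no-compensation mode (default 0.25, about a 25
#'   percent CV between replicate microcosms; constant abundance would make
#'   the log-log regression degenerate).
#' @param noise_sd Lognormal observation noise SD on rates (log units,
#'   default 0.3).
#' @param n_cells Cells sampled per community (default 10^4; reduce for fast
#'   tests).
#' @param seed RNG seed; identical configs give identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mesocosms_per_treatment = 10,
                       incubator_temps = c(289.15, 293.15),
                       mean_mass_ambient = 3.6e-5,
                       mean_mass_warm = 1.06e-4,
                       mass_logsd = 1,
                       true_params_gpp = mst_params(-3.46, 0.88, 0.61),
                       true_params_cr = mst_params(-5.50, 0.80, 1.27),
                       total_energy = 10,
                       zero_sum = TRUE,
                       n_tot_fixed = 1e6,
                       abundance_logsd = 0.25,
                       noise_sd = 0.3,
                       n_cells = 1e4,
                       seed = 1L) {
  stopifnot(n_mesocosms_per_treatment >= 1, n_cells >= 1,
            mean_mass_ambient > 0, mean_mass_warm > 0, mass_logsd >= 0,
            total_energy > 0, n_tot_fixed > 0, abundance_logsd >= 0,
            noise_sd >= 0, all(incubator_temps > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Draw an individual size distribution
#'
#' Lognormal masses with arithmetic mean equal to the treatment's mean mass
#' and log-scale SD `mass_logsd`. With `mass_logsd = 0` every cell has exactly
#' the treatment mean.
#'
#' @param config A [sim_config()].
#' @param treatment `"ambient"` or `"warm"`.
#' @param n_cells Number of cells to draw.
#' @return Vector of positive masses (ug C).
#' @export
simulate_size_distribution <- function(config, treatment = c("ambient", "warm"),
                                       n_cells = config$n_cells) {
  treatment <- match.arg(treatment)
  if (n_cells < 1) stop("n_cells must be >= 1")
  mbar <- if (treatment == "ambient") config$mean_mass_ambient else
    config$mean_mass_warm
  sdl <- config$mass_logsd
  # meanlog chosen so that E[m] = exp(meanlog + sdl^2/2) = mbar
  stats::rlnorm(n_cells, meanlog = log(mbar) - sdl^2 / 2, sdlog = sdl)
}

#' Simulate one community
#'
#' Draws a size distribution, sets abundance (zero-sum energy budget by
#' default, so that expected GPP is identical across communities and the
#' log-log abundance vs average-individual-rate relationship has slope -1 by
#' construction), and generates observed GPP and CR as the model rates times
#' lognormal noise.
#'
#' @param config A [sim_config()].
#' @param mesocosm_treatment Long-term treatment.
#' @param incubator_T Assay temperature (K).
#' @param id Community label.
#' @return An [community()] object with `gpp_obs`/`cr_obs` filled in.
#' @export
simulate_community <- function(config,
                               mesocosm_treatment = c("ambient", "warm"),
                               incubator_T = config$incubator_temps[1],
                               id = "sim") {
  mesocosm_treatment <- match.arg(mesocosm_treatment)
  masses <- simulate_size_distribution(config, mesocosm_treatment,
                                       config$n_cells)
  pg <- config$true_params_gpp
  # mean per-cell GPP at assay temperature
  rbar <- mean(individual_rate(pg, masses, incubator_T))
  n_tot <- if (config$zero_sum) config$total_energy / rbar else
    config$n_tot_fixed * exp(stats::rnorm(1, 0, config$abundance_logsd))
  comm <- community(id = id, masses = masses, incubator_T = incubator_T,
                    mesocosm_treatment = mesocosm_treatment,
                    scale_to_litre = n_tot / length(masses))
  noise <- function() exp(stats::rnorm(1, 0, config$noise_sd))
  comm$gpp_obs <- community_rate(pg, comm) * noise()
  comm$cr_obs <- community_rate(config$true_params_cr, comm) * noise()
  comm
}

#' Simulate the full factorial experiment
#'
#' The full 2 x 2 x `n_mesocosms_per_treatment` design (40 communities at the
#' defaults). Deterministic under the config's seed.
#'
#' @param config A [sim_config()].
#' @return List with `communities` (list of [community()] objects) and
#'   `truth` (the generating parameters and budget).
#' @export
simulate_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  comms <- list()
  i <- 0L
  for (meso in c("ambient", "warm")) {
    for (Tinc in config$incubator_temps) {
      for (rep in seq_len(config$n_mesocosms_per_treatment)) {
        i <- i + 1L
        comms[[i]] <- simulate_community(
          config, meso, Tinc,
          id = sprintf("%s_T%.0f_r%02d", meso, Tinc - 273.15, rep))
      }
    }
  }
  list(communities = comms,
       truth = list(gpp = config$true_params_gpp,
                    cr = config$true_params_cr,
                    total_energy = config$total_energy,
                    zero_sum = config$zero_sum,
                    noise_sd = config$noise_sd))
}

#' Simulate an amplicon (ASV) count table
#'
#' Dirichlet-multinomial counts with long-term-treatment-specific taxon
#' profiles; the incubator has no effect on composition, mirroring the
#' observation that long-term warming alters composition while short-term
#' warming does not. Library sizes are lognormal around `mean_reads`, and a
#' configurable fraction of samples is given a shallow library (< 1000 reads)
#' to exercise the read-count filter.
#'
#' @param config A [sim_config()].
#' @param n_taxa Number of taxa (default 50).
#' @param separation Effect size: 0 means identical treatment profiles (null);
#'   larger values shift the warm profile towards a disjoint set of taxa
#'   (default 2).
#' @param mean_reads Mean library size (default 5000).
#' @param concentration Dirichlet concentration controlling within-treatment
#'   overdispersion (default 50).
#' @param p_shallow Probability a sample's library is drawn below 1000 reads
#'   (default 0).
#' @return List with integer `counts` (samples x taxa) and `sample_meta`
#'   data frame (`mesocosm_treatment`, `incubator`).
#' @export
simulate_asv_table <- function(config = sim_config(), n_taxa = 50,
                               separation = 2, mean_reads = 5000,
                               concentration = 50, p_shallow = 0) {
  set.seed(config$seed + 1L)
  n_per <- config$n_mesocosms_per_treatment
  meta <- expand.grid(rep = seq_len(n_per),
                      incubator = c("ambient", "warm"),
                      mesocosm_treatment = c("ambient", "warm"),
                      stringsAsFactors = FALSE)[c("mesocosm_treatment",
                                                  "incubator")]
  n_samp <- nrow(meta)
  # smooth base profile; warm profile tilted towards the upper taxa
  base <- exp(-(seq_len(n_taxa) - n_taxa / 3)^2 / (2 * (n_taxa / 4)^2))
  warm <- exp(-(seq_len(n_taxa) - 2 * n_taxa / 3)^2 / (2 * (n_taxa / 4)^2))
  counts <- matrix(0L, n_samp, n_taxa,
                   dimnames = list(sprintf("s%02d", seq_len(n_samp)),
                                   sprintf("ASV%03d", seq_len(n_taxa))))
  for (s in seq_len(n_samp)) {
    w <- if (meta$mesocosm_treatment[s] == "warm") separation else 0
    prof <- base + w * warm
    prof <- prof / sum(prof)
    # Dirichlet draw via independent gammas
    g <- stats::rgamma(n_taxa, shape = concentration * prof, rate = 1)
    p <- g / sum(g)
    depth <- if (stats::runif(1) < p_shallow)
      sample(100:999, 1) else
      max(1000L, round(stats::rlnorm(1, log(mean_reads), 0.3)))
    counts[s, ] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
  }
  list(counts = counts, sample_meta = meta)
}

#' Write simulated communities to tidy CSV files
#'
#' Emits `communities.csv` (one row per community), `masses.csv` (long
#' format), and `truth.json` (generating parameters) into `dir`.
#'
#' @param experiment Output of [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_communities <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comms <- experiment$communities
  comm_df <- do.call(rbind, lapply(comms, function(cm)
    data.frame(community_id = cm$id,
               mesocosm_treatment = cm$mesocosm_treatment,
               incubator_T = cm$incubator_T,
               n_cells = length(cm$masses),
               scale_to_litre = cm$scale_to_litre,
               gpp_obs = cm$gpp_obs, cr_obs = cm$cr_obs)))
  mass_df <- do.call(rbind, lapply(comms, function(cm)
    data.frame(community_id = cm$id, mass = cm$masses)))
  f1 <- file.path(dir, "communities.csv")
  f2 <- file.path(dir, "masses.csv")
  f3 <- file.path(dir, "truth.json")
  utils::write.csv(format_floats(comm_df), f1, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(format_floats(mass_df), f2, row.names = FALSE,
                   quote = FALSE)
  truth <- experiment$truth
  truth$gpp <- unclass(truth$gpp)
  truth$cr <- unclass(truth$cr)
  jsonlite::write_json(truth, f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}

#' Read communities back from tidy CSV files
#'
#' Inverse of [write_communities()] (truth.json is not required).
#'
#' @param dir Directory holding `communities.csv` and `masses.csv`.
#' @return List of [community()] objects.
#' @export
read_communities <- function(dir) {
  cd <- utils::read.csv(file.path(dir, "communities.csv"))
  md <- utils::read.csv(file.path(dir, "masses.csv"))
  lapply(seq_len(nrow(cd)), function(i) {
    row <- cd[i, ]
    community(id = row$community_id,
              masses = md$mass[md$community_id == row$community_id],
              incubator_T = row$incubator_T,
              mesocosm_treatment = row$mesocosm_treatment,
              scale_to_litre = row$scale_to_litre,
              gpp_obs = row$gpp_obs, cr_obs = row$cr_obs)
  })
}

# 12-significant-digit serialisation of numeric columns, stable across runs
format_floats <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 12,
                                               format = "g")
  df
}
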