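#' @title End-to-end analysis pipeline
#' @description Orchestrates simulation (optional), size-structure summaries,
#'   PI-curve flux extraction (when PI tables are supplied), maximum
#'   likelihood fitting, the two scaling tests, and the composition
#'   statistics, writing tidy outputs and a manifest of seeds so a run can be
#'   reproduced exactly.
#' @name pipeline_cli
NULL

#' Build a pipeline configuration
#'
#' @param outdir Output directory.
#' @param sim A [sim_config()] to simulate inputs, or `NULL` to read them
#'   from `input_dir`.
#' @param input_dir Directory with `communities.csv` + `masses.csv` (used
#'   when `sim` is `NULL`).
#' @param pi_csv Optional per-community PI-curve CSV (columns `community_id`,
#'   `irradiance`, `o2_flux`, `is_dark`); when supplied, observed fluxes are
#'   re-derived from the curves.
#' @param asv Optional list with `counts` matrix and `sample_meta` data frame
#'   for the composition stage (simulated automatically when `sim` is given).
#' @param Tc Reference temperature (K).
#' @param n_starts Multistart budget for PI fitting.
#' @param n_boot Bootstrap replicates for the SMA intervals.
#' @param n_perm PERMANOVA permutations.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(), input_dir = NULL,
                            pi_csv = NULL, asv = NULL, Tc = default_Tc,
                            n_starts = 1000, n_boot = 1000, n_perm = 9999,
                            seed = 1L) {
  if (is.null(sim) && is.null(input_dir))
    stop("configuration error: supply either a simulation config or an input directory")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: simulate (optional) -> size structure -> flux extraction
#' (optional) -> ML fit + model comparison -> scaling tests -> composition.
#' All randomness is seeded from the config; `manifest.json` records every
#' derived seed and stage, so re-running the same config reproduces the
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the result bundle (a list); side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  out <- config$outdir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(seed = config$seed, Tc = config$Tc,
                   stages = character(0))

  # -- simulate or ingest ----------------------------------------------------
  if (!is.null(config$sim)) {
    config$sim$seed <- config$seed
    exper <- stage("simulate", simulate_experiment(config$sim))
    comms <- exper$communities
    write_communities(exper, out)
    asv <- stage("simulate", simulate_asv_table(config$sim))
    manifest$stages <- c(manifest$stages, "simulate")
  } else {
    comms <- stage("ingest", read_communities(config$input_dir))
    asv <- config$asv
  }

  # -- flux extraction (only when PI measurements exist) ---------------------
  if (!is.null(config$pi_csv)) {
    pi_df <- utils::read.csv(config$pi_csv)
    fits <- list()
    for (cm_i in seq_along(comms)) {
      id <- comms[[cm_i]]$id
      sub <- pi_df[pi_df$community_id == id, ]
      if (nrow(sub) == 0)
        stop("pipeline stage 'flux' failed: no PI data for community ", id)
      dark <- sub$o2_flux[sub$is_dark]
      curve <- pi_curve(sub$irradiance[!sub$is_dark],
                        sub$o2_flux[!sub$is_dark],
                        dark_flux = if (length(dark)) mean(dark) else NA)
      f <- fit_pi_curve(curve, n_starts = config$n_starts,
                        seed = config$seed + cm_i)
      if (!f$converged)
        stop("pipeline stage 'flux' failed: PI fit did not converge for ", id)
      comms[[cm_i]]$gpp_obs <- gpp_at_saturation(f)
      comms[[cm_i]]$cr_obs <- community_respiration(curve, f)
      fits[[id]] <- f
    }
    utils::write.csv(do.call(rbind, lapply(names(fits), function(id)
      data.frame(community_id = id, P_max = fits[[id]]$P_max,
                 I_opt = fits[[id]]$I_opt, s = fits[[id]]$s,
                 R_d = fits[[id]]$R_d, aic = fits[[id]]$aic))),
      file.path(out, "pi_fits.csv"), row.names = FALSE)
    manifest$stages <- c(manifest$stages, "flux_extraction")
  }

  # -- size structure --------------------------------------------------------
  isd <- stage("size_structure", lapply(comms, summarise_isd))
  utils::write.csv(do.call(rbind, lapply(isd, function(s)
    data.frame(community_id = s$id, n_tot = s$n_tot, M_tot = s$M_tot,
               mean_mass = s$mean_mass))),
    file.path(out, "isd_summary.csv"), row.names = FALSE)
  manifest$stages <- c(manifest$stages, "size_structure")

  # -- ML fit + model comparison --------------------------------------------
  fit_gpp <- stage("mst_inference",
                   fit_mst(comms, "gpp", Tc = config$Tc,
                           seed = config$seed))
  fit_cr <- stage("mst_inference",
                  fit_mst(comms, "cr", Tc = config$Tc, seed = config$seed))
  cmp_gpp <- stage("mst_inference",
                   compare_treatment_models(comms, "gpp", Tc = config$Tc,
                                            seed = config$seed))
  cmp_cr <- stage("mst_inference",
                  compare_treatment_models(comms, "cr", Tc = config$Tc,
                                           seed = config$seed))
  jsonlite::write_json(list(
    gpp = c(as.list(fit_gpp$estimates),
            list(loglik = fit_gpp$loglik, aic = fit_gpp$aic,
                 ci = as.data.frame(fit_gpp$ci))),
    cr = c(as.list(fit_cr$estimates),
           list(loglik = fit_cr$loglik, aic = fit_cr$aic,
                ci = as.data.frame(fit_cr$ci)))),
    file.path(out, "mst_fit.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(rbind(cbind(flux = "gpp", cmp_gpp),
                         cbind(flux = "cr", cmp_cr)),
                   file.path(out, "model_comparison.csv"), row.names = FALSE)
  manifest$stages <- c(manifest$stages, "mst_inference")

  # -- scaling tests ---------------------------------------------------------
  prop_gpp <- stage("scaling_tests",
                    proportionality_test(comms, fit_gpp,
                                         n_boot = config$n_boot,
                                         seed = config$seed))
  prop_cr <- stage("scaling_tests",
                   proportionality_test(comms, fit_cr,
                                        n_boot = config$n_boot,
                                        seed = config$seed))
  comp <- stage("scaling_tests",
                compensation_test(comms, fit_gpp, n_boot = config$n_boot,
                                  seed = config$seed))
  sma_json <- function(s) list(
    slope = s$slope, intercept = s$intercept, r2 = s$r2, n = s$n,
    boot_ci_slope = s$boot_ci_slope,
    boot_ci_intercept = s$boot_ci_intercept,
    slope_test = s$slope_test)
  jsonlite::write_json(list(proportionality_gpp = sma_json(prop_gpp),
                            proportionality_cr = sma_json(prop_cr),
                            compensation = sma_json(comp)),
                       file.path(out, "scaling_results.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(merge(prop_gpp$table, comp$table, by = "community_id"),
                   file.path(out, "scaling_table.csv"), row.names = FALSE)
  manifest$stages <- c(manifest$stages, "scaling_tests")

  # -- composition -----------------------------------------------------------
  comp_res <- NULL
  if (!is.null(asv)) {
    comp_res <- stage("composition", {
      rare <- filter_and_rarefy(asv$counts, seed = config$seed)
      keep <- rownames(asv$counts) %in% rownames(rare)
      d <- bray_curtis(rare)
      ord <- pcoa(d)
      perm <- permanova(d, asv$sample_meta[keep, , drop = FALSE],
                        n_perm = config$n_perm, seed = config$seed)
      utils::write.csv(d, file.path(out, "distances.csv"))
      utils::write.csv(data.frame(sample = rownames(ord$coordinates),
                                  ord$coordinates[, 1:2]),
                      file.path(out, "pcoa.csv"), row.names = FALSE)
      jsonlite::write_json(perm, file.path(out, "permanova.json"),
                           auto_unbox = TRUE, digits = NA)
      list(distances = d, pcoa = ord, permanova = perm)
    })
    manifest$stages <- c(manifest$stages, "composition")
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(communities = comms, fit_gpp = fit_gpp, fit_cr = fit_cr,
                 model_comparison = list(gpp = cmp_gpp, cr = cmp_cr),
                 proportionality = list(gpp = prop_gpp, cr = prop_cr),
                 compensation = comp, composition = comp_res,
                 manifest = manifest))
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates the six core parameter estimates (E, alpha, ln b(Tc) for GPP and
#' CR) with confidence intervals, the SMA slopes with bootstrap CIs and slope
#' tests, and the PERMANOVA table.
#'
#' @param bundle Result of [run_pipeline()].
#' @param file Optional path; when given the text is also written there.
#' @return The report, invisibly, as a character vector of lines.
#' @export
report <- function(bundle, file = NULL) {
  fmt_ci <- function(ci, nm) if (!is.null(ci) && nm %in% rownames(ci))
    sprintf(" [%.2f, %.2f]", ci[nm, 1], ci[nm, 2]) else ""
  lines <- c("== Scaling-model parameter estimates ==")
  for (fl in c("gpp", "cr")) {
    f <- bundle[[paste0("fit_", fl)]]
    lines <- c(lines, sprintf("-- %s --", toupper(fl)),
      sprintf("  E        = %6.2f eV%s", f$estimates["E"],
              fmt_ci(f$ci, "E")),
      sprintf("  alpha    = %6.2f   %s", f$estimates["alpha"],
              fmt_ci(f$ci, "alpha")),
      sprintf("  ln b(Tc) = %6.2f   %s", f$estimates["ln_b_Tc"],
              fmt_ci(f$ci, "ln_b_Tc")))
  }
  lines <- c(lines, "", "== Scaling tests (SMA) ==")
  sma_lines <- function(s, label, b0) c(
    sprintf("-- %s (expected slope %g) --", label, b0),
    sprintf("  slope = %.3f [%.3f, %.3f], intercept = %.3f [%.3f, %.3f], R2 = %.3f",
            s$slope, s$boot_ci_slope[1], s$boot_ci_slope[2],
            s$intercept, s$boot_ci_intercept[1], s$boot_ci_intercept[2],
            s$r2),
    sprintf("  test vs b0 = %g: r = %.3f, df = %d, p = %.3g",
            s$slope_test$b0, s$slope_test$r, s$slope_test$df,
            s$slope_test$p))
  lines <- c(lines,
             sma_lines(bundle$proportionality$gpp, "GPP proportionality", 1),
             sma_lines(bundle$proportionality$cr, "CR proportionality", 1),
             sma_lines(bundle$compensation, "Metabolic compensation", -1))
  if (!is.null(bundle$composition)) {
    lines <- c(lines, "", "== PERMANOVA (Bray-Curtis) ==",
               utils::capture.output(print(bundle$composition$permanova)))
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
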