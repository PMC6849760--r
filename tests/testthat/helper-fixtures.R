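# Small in-code fixtures shared across test files.

k_eV <- 8.62e-5

# a fast simulation config: few cells per community, everything else default
fast_config <- function(...) {
  sim_config(n_cells = 200, ...)
}

# hand-built three-cell community at a chosen temperature
toy_community <- function(masses = c(1, 2, 4), T_K = 291.15, scale = 1,
                          treatment = "ambient", gpp = NA_real_,
                          cr = NA_real_) {
  community("toy", masses, T_K, treatment, scale_to_litre = scale,
            gpp_obs = gpp, cr_obs = cr)
}

# noise-free PI observations from known truth
toy_pi_curve <- function(P_max = 6, I_opt = 300, s = 0.05, R_d = 1.5,
                         I = c(0, 25, 50, 100, 200, 300, 500, 800, 1200),
                         noise = 0, seed = 1) {
  set.seed(seed)
  pi_curve(I, eilers_gross(I, P_max, I_opt, s) - R_d +
             rnorm(length(I), 0, noise),
           dark_flux = -R_d)
}
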