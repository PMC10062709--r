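# shared fixtures: everything is generated in code, nothing read from disk

ref_params <- function(...) {
  update_parameters(celt419_parameters(), ...)
}

# single-site quadratic mass-balance oracle for R + L <-> RL
quadratic_rl <- function(R_tot, L_tot, Kd) {
  b <- R_tot + L_tot + Kd
  (b - sqrt(b^2 - 4 * R_tot * L_tot)) / 2
}

# small, fast synthetic experiment for smoke tests (overridable defaults)
quick_design <- function(...) {
  args <- utils::modifyList(
    list(n_dilutions = 2, interval_s = 600, horizon_s = 9000), list(...))
  do.call(saturation_kinetic_design, args)
}

quick_fit_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, iters_per_temp = 50, nm_budget = 25,
         n_uncertainty = 3, polish_maxit = 1500), list(...))
  do.call(fit_config, args)
}

quiet_fit_global <- function(...) {
  suppressWarnings(fit_global(...))
}

# brute-force grid oracle for the depletion-corrected Ki inversion
grid_ki <- function(log_ic50, Kd_L, probe_nM, receptor_nM) {
  base <- binding_parameters(kon_L = 1e-3, Kd_L = Kd_L)
  rl0 <- equilibrium_state(base, L_tot = probe_nM, R_tot = receptor_nM)$RL
  f <- function(lki) {
    p <- update_parameters(base, Ki_C = 10^lki)
    equilibrium_state(p, L_tot = probe_nM, R_tot = receptor_nM,
                      C_tot = 10^log_ic50)$RL - rl0 / 2
  }
  grid <- seq(-8, 10, by = 1e-3)
  vals <- vapply(grid, f, numeric(1))
  i <- which(vals > 0)[1]
  # linear interpolation of the sign change
  g0 <- grid[i - 1]; g1 <- grid[i]
  v0 <- vals[i - 1]; v1 <- vals[i]
  10^(g0 - v0 * (g1 - g0) / (v1 - v0))
}
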