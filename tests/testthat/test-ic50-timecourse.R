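pl384_params <- function() {
  # probe with reference kinetics vs a slower pharmacophore-linker style
  # competitor sharing a similar dissociation rate
  ref_params(kon_C = 2.0e-4, Ki_C = 2.7e-4 / 2.0e-4, NBV_stock = 1e-6)
}

tc_grid <- c(0, serial_dilution(1e4, 10^-0.5, 12))
tc_times <- seq(300, 18000, by = 900)

test_that("a competitor kinetically identical to the probe settles to a flat
           time course once the shared transient has passed", {
  # apparent IC50 always starts high (initial binding rates are
  # competitor-independent) and settles at the speed of the probe itself
  p <- ref_params(kon_C = 4.2e-4, Ki_C = 2.8e-4 / 4.2e-4, NBV_stock = 1e-6)
  tc <- theoretical_ic50_timecourse(p, tc_grid, tc_times, probe_nM = 1,
                                    bbv_dilution = 0.035)
  lic <- tc$log_ic50[tc$converged]
  expect_gt(length(lic), 10)
  expect_true(all(diff(lic) < 0))             # monotone settling from above
  late <- tc$log_ic50[tc$converged & tc$time_s >= 7200]
  expect_lt(max(late) - min(late), 0.02)      # flat at equilibrium
})

test_that("slow competitor: Log(IC50) decreases; fast competitor: increases", {
  tc_slow <- theoretical_ic50_timecourse(pl384_params(), tc_grid, tc_times,
                                         probe_nM = 1, bbv_dilution = 0.035)
  lic <- tc_slow$log_ic50[tc_slow$converged]
  expect_true(all(diff(lic) < 0))
  p_fast <- ref_params(kon_C = 100 * 4.2e-4, Ki_C = 2.8e-4 / 4.2e-4,
                       NBV_stock = 1e-6)
  tc_fast <- theoretical_ic50_timecourse(p_fast, tc_grid, tc_times,
                                         probe_nM = 1, bbv_dilution = 0.035)
  lic_f <- tc_fast$log_ic50[tc_fast$converged]
  expect_true(all(diff(lic_f) > 0))
})

test_that("direction of the late drift follows the kinetic ratio", {
  # judged after the probe-equilibration transient (t >= 90 min), where
  # the sign is set by whether the competitor is still equilibrating
  for (kr in c(0.1, 1, 10)) {
    p <- ref_params(kon_C = kr * 4.2e-4, Ki_C = 2.8e-4 / 4.2e-4,
                    NBV_stock = 1e-6)
    tc <- theoretical_ic50_timecourse(p, tc_grid,
                                      seq(600, 14400, 1800),
                                      probe_nM = 1, bbv_dilution = 0.035)
    sub <- tc[tc$converged & tc$time_s >= 5400, ]
    drift <- sub$log_ic50[nrow(sub)] - sub$log_ic50[1]
    if (kr < 1) expect_lt(drift, -0.02)
    if (kr > 1) expect_gt(drift, 0.02)
    if (kr == 1) expect_lt(abs(drift), 0.02)
  }
})

test_that("late-time Log(IC50) agrees with the equilibrium inversion", {
  p <- pl384_params()
  tc <- theoretical_ic50_timecourse(p, tc_grid, c(5e5, 1e6),
                                    probe_nM = 1, bbv_dilution = 0.035)
  # equilibrium IC50 by direct bisection on the competition equilibrium
  R_tot <- 0.035 * p$R_stock
  rl0 <- equilibrium_state(p, L_tot = 1, R_tot = R_tot)$RL
  f <- function(lc) {
    equilibrium_state(p, L_tot = 1, R_tot = R_tot, C_tot = 10^lc)$RL -
      rl0 / 2
  }
  lic_eq <- uniroot(f, c(-2, 4), tol = 1e-10)$root
  expect_lt(abs(tc$log_ic50[2] - lic_eq), 0.02)
})

test_that("observed time course equals the theoretical one without noise", {
  p <- pl384_params()
  design <- competition_kinetic_design(
    "linker_probe", competitor_nM = tc_grid, probe_nM = 1,
    bbv_dilution = 0.035, interval_s = 900, horizon_s = 10800)
  expt <- generate_experiment(design, p,
                              noise_model(channel_cv = 0, blank_par = 0,
                                          blank_perp = 0, seed = 1))
  tr <- experiment_traces(expt)
  tc_obs <- observed_ic50_timecourse(tr[tr$time_s > 0, ])
  tc_theo <- theoretical_ic50_timecourse(p, tc_grid,
                                         sort(unique(tr$time_s[tr$time_s > 0])),
                                         probe_nM = 1, bbv_dilution = 0.035)
  both <- is.finite(tc_obs$log_ic50) & is.finite(tc_theo$log_ic50)
  expect_gt(sum(both), 8)
  expect_equal(tc_obs$log_ic50[both], tc_theo$log_ic50[both],
               tolerance = 1e-3)
})

test_that("incomplete concentration series are skipped with a warning", {
  p <- pl384_params()
  design <- competition_kinetic_design(
    "linker_probe", competitor_nM = tc_grid, probe_nM = 1,
    bbv_dilution = 0.035, interval_s = 1800, horizon_s = 9000)
  expt <- generate_experiment(design, p, noise_model(seed = 2))
  tr <- experiment_traces(expt)
  drop <- tr$time_s == 3600 & tr$competitor_nM == max(tr$competitor_nM)
  expect_warning(tc <- observed_ic50_timecourse(tr[!drop & tr$time_s > 0, ]),
                 "skipped")
  expect_false(3600 %in% tc$time_s)
})

test_that("stabilization model has the right limits and half-life", {
  expect_equal(ic50_decay_model(0, -7, -8, 0.1), -7)
  expect_equal(ic50_decay_model(1e9, -7, -8, 0.1), -8)
  t_min <- seq(0, 120, by = 5)
  k <- 0.0866
  tc <- tibble::tibble(time_s = t_min * 60,
                       log_ic50 = ic50_decay_model(t_min, -7, -8, k),
                       se = 0.01, converged = TRUE, source = "observed")
  fit <- fit_ic50_decay(tc)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["log_ic50_t0"]], -7, tolerance = 1e-6)
  expect_equal(est[["log_ic50_eq"]], -8, tolerance = 1e-6)
  expect_equal(est[["k_per_min"]], k, tolerance = 1e-6)
  expect_equal(est[["half_life_min"]], log(2) / k, tolerance = 1e-6)
  expect_equal(est[["half_life_min"]], 8.0, tolerance = 0.01)
})

test_that("decay fit recovers a slow stabilization half-life", {
  t_min <- seq(5, 300, by = 15)
  k <- log(2) / 71
  set.seed(4)
  tc <- tibble::tibble(time_s = t_min * 60,
                       log_ic50 = ic50_decay_model(t_min, -6.2, -7.1, k) +
                         rnorm(length(t_min), sd = 0.01),
                       se = 0.01, converged = TRUE, source = "observed")
  fit <- fit_ic50_decay(tc)
  hl <- fit$estimates$estimate[fit$estimates$term == "half_life_min"]
  hl_se <- fit$estimates$std.error[fit$estimates$term == "half_life_min"]
  expect_lt(abs(hl - 71), 3 * hl_se + 1e-9)
})

test_that("degenerate time courses are refused", {
  flat <- tibble::tibble(time_s = seq(0, 6000, 600), log_ic50 = -7,
                         se = 0.01, converged = TRUE, source = "observed")
  expect_error(fit_ic50_decay(flat), "stabilization")
  short <- flat[1:3, ]
  expect_error(fit_ic50_decay(short), "4 valid")
})
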