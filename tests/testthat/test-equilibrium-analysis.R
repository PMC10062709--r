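make_saturation_dataset <- function(params, probe_nM = c(0.5, 3),
                                    dilutions = serial_dilution(0.25, 0.5, 8),
                                    noise_sd = 0) {
  grid <- expand.grid(probe_nM = probe_nM, bbv_dilution = dilutions,
                      condition = c("total", "nonspecific"),
                      stringsAsFactors = FALSE)
  grid$fa <- vapply(seq_len(nrow(grid)), function(i) {
    R_tot <- if (grid$condition[i] == "total")
      grid$bbv_dilution[i] * params$R_stock else 0
    st <- equilibrium_state(params, L_tot = grid$probe_nM[i], R_tot = R_tot,
                            NBV_tot = grid$bbv_dilution[i] * params$NBV_stock)
    anisotropy_from_states(st, params)
  }, numeric(1))
  if (noise_sd > 0) grid$fa <- grid$fa + rnorm(nrow(grid), sd = noise_sd)
  tibble::as_tibble(grid)
}

test_that("saturation fit recovers generating parameters exactly at zero noise", {
  truth <- ref_params(Kd_L = 0.42)
  ds <- make_saturation_dataset(truth)
  start <- update_parameters(truth, Kd_L = 1, R_stock = 5, NBV_stock = 30,
                             FA_free = 0.1, FA_bound = 0.25)
  fit <- fit_saturation(ds, params_init = start)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["Kd_L"]], 0.42, tolerance = 1e-4)
  expect_equal(est[["R_stock"]], 20, tolerance = 1e-4)
  expect_equal(est[["FA_free"]], 0.081, tolerance = 1e-5)
  expect_equal(est[["FA_bound"]], 0.20, tolerance = 1e-4)
})

test_that("saturation fit recovers Kd and R_stock from noisy endpoints", {
  truth <- ref_params(Kd_L = 0.42)
  set.seed(99)
  errs <- t(vapply(1:8, function(i) {
    ds <- make_saturation_dataset(truth, noise_sd = 0.004)
    fit <- fit_saturation(ds, params_init = update_parameters(
      truth, Kd_L = 1, R_stock = 5, FA_free = 0.1, FA_bound = 0.25))
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    c(kd = est[["Kd_L"]] / 0.42 - 1, r = est[["R_stock"]] / 20 - 1)
  }, numeric(2)))
  expect_lt(abs(median(errs[, "kd"])), 0.15)
  expect_lt(abs(median(errs[, "r"])), 0.15)
})

test_that("degenerate saturation designs are rejected", {
  truth <- ref_params()
  ds <- make_saturation_dataset(truth)
  expect_error(fit_saturation(ds[ds$condition == "nonspecific", ]),
               "unidentifiable")
  expect_error(fit_saturation(ds[ds$condition == "total", ]), "nonspecific")
  few <- ds[ds$bbv_dilution %in% unique(ds$bbv_dilution)[1:3], ]
  expect_error(fit_saturation(few), "4 distinct")
})

test_that("depletion-corrected Ki reduces to Cheng-Prusoff without depletion", {
  ki <- ki_from_ic50_depletion(log10(2), Kd_L = 1, probe_nM = 1,
                               receptor_nM = 1e-6)
  expect_equal(ki, 1, tolerance = 1e-4)
  # convergence rate: < 1% gap already at R_tot = Kd/100
  ki2 <- ki_from_ic50_depletion(log10(2), Kd_L = 1, probe_nM = 1,
                                receptor_nM = 0.01)
  expect_lt(abs(ki2 - 1) / 1, 0.02)
})

test_that("depletion-corrected Ki matches a brute-force grid search", {
  set.seed(5)
  for (i in 1:10) {
    Kd <- 10^runif(1, -1, 1)
    L <- 10^runif(1, -1, 0.5)
    R <- 10^runif(1, -1, 0.3)
    lic <- log10(max(2 * R, Kd) * 10^runif(1, 0.1, 1.5))
    ki <- ki_from_ic50_depletion(lic, Kd, L, R)
    expect_equal(log10(ki), log10(grid_ki(lic, Kd, L, R)),
                 tolerance = 1e-3)
  }
})

test_that("Ki is monotone in IC50 and floors on impossible IC50s", {
  kis <- vapply(seq(0.5, 2, length.out = 6), function(lic) {
    ki_from_ic50_depletion(lic, Kd_L = 1, probe_nM = 0.5, receptor_nM = 0.7)
  }, numeric(1))
  expect_true(all(diff(kis) > 0))
  expect_error(
    ki_from_ic50_depletion(log10(0.01), Kd_L = 1, probe_nM = 0.5,
                           receptor_nM = 0.7),
    "floor")
})

test_that("competition round trip: simulate with known Ki, fit, invert", {
  truth <- ref_params(kon_C = 2e-4, Ki_C = 5, NBV_stock = 1e-6)
  concs <- c(0, serial_dilution(1e4, 10^-0.5, 10))
  R_tot <- 0.7
  fa <- vapply(concs, function(cc) {
    st <- equilibrium_state(truth, L_tot = 0.5, R_tot = R_tot, C_tot = cc)
    anisotropy_from_states(st, truth)
  }, numeric(1))
  fit <- fit_sigmoid(tibble::tibble(conc = concs, response = fa))
  ki <- ki_from_ic50_depletion(sigmoid_coef(fit, "log_ic50"),
                               Kd_L = truth$Kd_L, probe_nM = 0.5,
                               receptor_nM = R_tot)
  expect_equal(ki, 5, tolerance = 0.05)
})

test_that("Cheng-Prusoff conversion matches its limiting and worked cases", {
  expect_equal(cheng_prusoff_ki(30.1, 1e-9, 1), 30.1, tolerance = 1e-6)
  expect_equal(cheng_prusoff_ki(30.1, 1, 1.090), 15.7, tolerance = 0.01)
  expect_equal(cheng_prusoff_ki(78, 1.5, 1.94), 44.0, tolerance = 0.01)
  expect_error(cheng_prusoff_ki(-1, 1, 1), "> 0")
})

test_that("Z' reproduces hand values and behaves under symmetry and noise", {
  expect_equal(z_prime(rep(0.2, 3), rep(0.08, 3))$z_prime, 1)
  z <- z_prime(c(0.19, 0.20, 0.21), c(0.07, 0.08, 0.09))
  expect_equal(z$z_prime, 1 - 3 * (z$sigma_pos + z$sigma_neg) / 0.12)
  swapped <- z_prime(c(0.07, 0.08, 0.09), c(0.19, 0.20, 0.21))
  expect_equal(swapped$z_prime, z$z_prime)
  expect_error(z_prime(c(0.1, 0.1), c(0.1, 0.1)), "equal")
  expect_error(z_prime(0.2, c(0.1, 0.1)), "2 replicates")
  # strictly decreasing in either control SD
  zs <- vapply(c(0.002, 0.004, 0.008), function(s) {
    set.seed(1)
    z_prime(rnorm(500, 0.2, s), rnorm(500, 0.08, 0.004))$z_prime
  }, numeric(1))
  expect_true(all(diff(zs) < 0))
})
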