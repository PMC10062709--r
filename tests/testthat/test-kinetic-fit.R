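noise_free_dataset <- function(params, design = quick_design()) {
  expt <- generate_experiment(design, params,
                              noise_model(channel_cv = 0, blank_par = 0,
                                          blank_perp = 0, seed = 1))
  experiment_dataset(expt)
}

test_that("loss is zero at the generating truth on noise-free data", {
  p <- ref_params()
  ds <- noise_free_dataset(p)
  expect_lt(kinetic_loss(p, ds), 1e-16)
})

test_that("a constant prediction offset yields a quadratic loss", {
  p <- ref_params()
  ds <- noise_free_dataset(p)
  delta <- 0.01
  ds_shift <- ds
  ds_shift$obs$fa <- ds$obs$fa + delta
  expect_equal(kinetic_loss(p, ds_shift), delta^2, tolerance = 1e-10)
})

test_that("loss matches a hand-computed three-point toy case", {
  p <- ref_params()
  ds <- noise_free_dataset(p)
  keep <- ds$obs[1:3, ]
  pred <- fabind:::predict_dataset(p, ds)[1:3]
  obs <- pred + c(0.01, -0.02, 0.005)
  # hand value: mean of squared residuals
  hand <- mean(c(0.01, -0.02, 0.005)^2)
  toy <- ds
  toy$obs$fa[1:3] <- obs
  w <- rep(0, nrow(ds$obs))
  w[1:3] <- 1
  # with indicator weights the mean runs over all points
  expect_equal(kinetic_loss(p, toy, w), hand * 3 / nrow(ds$obs),
               tolerance = 1e-12)
})

test_that("simulation failure maps to +Inf loss with a warning", {
  p <- ref_params()
  ds <- noise_free_dataset(p)
  bad <- unclass(p)
  bad$koff_L <- NaN
  class(bad) <- "binding_parameters"
  expect_warning(l <- kinetic_loss(bad, ds), "Inf")
  expect_identical(l, Inf)
})

test_that("time weights follow the declared scheme and normalization", {
  expect_equal(time_weights(c(0, 600), "uniform"), c(1, 1))
  w <- fabind:::raw_time_weight(c(0, 600, 1200), "less_timescaling", 600)
  expect_equal(w, c(1, 0.5, 1 / 3))
  wn <- time_weights(c(0, 600, 1200))
  expect_equal(mean(wn), 1)
  expect_true(all(diff(wn) < 0))
  expect_equal(which.max(time_weights(c(0, 100, 900))), 1L)
  expect_error(time_weights(c(-1, 0)), ">= 0")
})

test_that("dataset weights restart at each addition event", {
  p <- ref_params()
  ds <- noise_free_dataset(p)
  w <- dataset_time_weights(ds, tau = 600)
  chased <- unique(ds$events$well)[1]
  wt <- w[ds$obs$well == chased]
  tt <- ds$obs$time_s[ds$obs$well == chased]
  t_chase <- ds$events$time_s[ds$events$well == chased][1]
  at <- which(tt == t_chase)  # clock restarts at the chase event
  expect_gt(wt[at], wt[at - 1L])
  expect_equal(mean(w), 1)
})

test_that("global fit is reproducible and competent on a small dataset", {
  p <- ref_params()
  expt <- generate_experiment(quick_design(), p,
                              noise_model(seed = 21))
  ds <- experiment_dataset(expt)
  free <- c("kon_L", "Kd_L", "R_stock", "FA_free", "FA_bound")
  # fixed (non-free) parameters start at the generating values so the truth
  # lies inside the searched space and the competence property is testable
  init <- update_parameters(p, kon_L = 1e-3, Kd_L = 1, R_stock = 5,
                            FA_free = 0.1, FA_bound = 0.3)
  f1 <- quiet_fit_global(ds, quick_fit_config(seed = 7), params_init = init,
                         free = free)
  f2 <- quiet_fit_global(ds, quick_fit_config(seed = 7), params_init = init,
                         free = free)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$final_loss, f2$final_loss)
  # optimizer competence: at least as good as the generating truth
  w <- dataset_time_weights(ds)
  expect_lte(f1$final_loss, kinetic_loss(p, ds, w))
  # reported loss equals recomputed loss at the estimates
  expect_equal(f1$final_loss,
               kinetic_loss(f1$params, ds, w), tolerance = 1e-12)
  expect_true(all(f1$estimates$std.error >= 0))
})

test_that("noise-free self-consistency: kinetic parameters recovered within 1%", {
  p <- ref_params(NBV_stock = 1e-3)
  ds <- noise_free_dataset(p, quick_design(n_dilutions = 3))
  fit <- quiet_fit_global(
    ds, quick_fit_config(seed = 2),
    params_init = update_parameters(p, kon_L = 1e-3, Kd_L = 1, R_stock = 10),
    free = c("kon_L", "Kd_L", "R_stock"))
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[["kon_L"]], p$kon_L, tolerance = 0.01)
  expect_equal(est[["Kd_L"]], p$Kd_L, tolerance = 0.01)
  expect_equal(est[["R_stock"]], p$R_stock, tolerance = 0.01)
})

test_that("dropping the dissociation phase inflates kon-Kd uncertainty", {
  p <- ref_params()
  expt <- generate_experiment(quick_design(), p, noise_model(seed = 31))
  ds_full <- experiment_dataset(expt)
  tr <- experiment_traces(expt)
  t_chase <- expt$design$t_assoc_s
  ds_assoc <- kinetic_dataset(tr[tr$time_s <= t_chase, ])
  free <- c("kon_L", "Kd_L")
  cfg <- quick_fit_config(seed = 5, n_uncertainty = 10)
  f_full <- quiet_fit_global(ds_full, cfg, free = free)
  f_assoc <- quiet_fit_global(ds_assoc, cfg, free = free)
  rel_se <- function(f) {
    with(f$estimates, sum((std.error / estimate)^2))
  }
  expect_gt(rel_se(f_assoc) / rel_se(f_full), 2)
})

test_that("slope points plus flanking plateau points are selected", {
  conc <- c(0, 10^seq(-1.5, 2.5, 0.25))
  y <- 0.08 + 0.12 / (1 + 10^(log10(conc) - 0.5))
  mask <- select_competition_points(tibble::tibble(conc = conc, response = y))
  f <- 1 / (1 + 10^(log10(conc) - 0.5))
  expect_true(all(mask[f > 0.1 & f < 0.9]))
  dropped <- which(!mask)
  # extreme plateau points dropped, two nearest retained on each side
  expect_true(length(dropped) > 0)
  ord <- order(conc)
  slope_idx <- which((f > 0.1 & f < 0.9)[ord])
  expect_true(all(mask[ord][max(1, min(slope_idx) - 2):min(slope_idx)]))
  # permutation invariance
  set.seed(2)
  perm <- sample(seq_along(conc))
  mask_p <- select_competition_points(
    tibble::tibble(conc = conc[perm], response = y[perm]))
  expect_identical(mask_p, mask[perm])
})

test_that("curves without a usable slope fall back to all points", {
  conc <- c(0, 10^seq(0, 3, 0.5))
  set.seed(12)
  flat <- 0.15 + rnorm(length(conc), sd = 0.001)
  expect_warning(
    mask <- select_competition_points(
      tibble::tibble(conc = conc, response = flat)),
    "retained")
  expect_true(all(mask))
})
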