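test_that("parameter constructor validates and derives dissociation rates", {
  p <- binding_parameters(kon_L = 4.2e-4, Kd_L = 0.7, kon_C = 1e-3,
                          Ki_C = 2)
  expect_equal(p$koff_L, 4.2e-4 * 0.7)
  expect_equal(p$koff_C, 1e-3 * 2)
  expect_error(binding_parameters(kon_L = -1, Kd_L = 1), "kon_L")
  expect_error(binding_parameters(kon_L = 1e-3, Kd_L = 0), "Kd_L")
  expect_error(binding_parameters(kon_L = 1e-3, Kd_L = 1, FA_free = 1.2),
               "FA_free")
  p2 <- update_parameters(p, Kd_L = 2)
  expect_equal(p2$koff_L, 4.2e-4 * 2)
  expect_error(update_parameters(p, nope = 1), "Unknown")
})

test_that("protocol validation rejects malformed events and grids", {
  expect_error(assay_protocol(probe_nM = 0.5, times = c(0, 0, 10)),
               "strictly increasing")
  expect_error(
    assay_protocol(probe_nM = 0.5, times = c(0, 100),
                   events = data.frame(time_s = 200, species = "C",
                                       conc_nM = 1)),
    "inside")
  expect_error(
    assay_protocol(probe_nM = 0.5, times = c(0, 100),
                   events = data.frame(time_s = 50, species = "X",
                                       conc_nM = 1)),
    "species")
  expect_error(
    assay_protocol(probe_nM = 0.5, times = c(0, 100),
                   events = data.frame(time_s = 50, species = "C",
                                       conc_nM = -1)),
    ">= 0")
})

test_that("probe alone does not bind: RL stays zero, L constant", {
  p <- ref_params()
  pro <- assay_protocol(probe_nM = 0.5, bbv_dilution = 0,
                        times = seq(0, 3600, 300))
  sim <- simulate_system(p, pro)
  expect_true(all(sim$RL == 0))
  expect_true(all(abs(sim$L - 0.5) < 1e-9))
})

test_that("an inert competitor leaves probe trajectories unchanged", {
  p_no_c <- ref_params(NBV_stock = 1e-3)
  times <- seq(0, 5400, 600)
  base <- simulate_system(
    p_no_c, assay_protocol(probe_nM = 0.5, competitor_nM = 0,
                           bbv_dilution = 0.035, times = times))
  # competitor present but with vanishing on-rate
  slow <- simulate_system(
    ref_params(NBV_stock = 1e-3, kon_C = 1e-15, Ki_C = 1),
    assay_protocol(probe_nM = 0.5, competitor_nM = 100,
                   bbv_dilution = 0.035, times = times))
  expect_equal(slow$RL, base$RL, tolerance = 1e-7)
  expect_equal(slow$L, base$L, tolerance = 1e-7)
})

test_that("long-time simulation reaches the quadratic equilibrium", {
  p <- binding_parameters(kon_L = 4.2e-4, Kd_L = 2.8e-4 / 4.2e-4,
                          NBV_stock = 1e-9, R_stock = 0.7)
  pro <- assay_protocol(probe_nM = 0.5, bbv_dilution = 1,
                        times = c(3600, 1e6))
  sim <- simulate_system(p, pro)
  expect_equal(sim$RL[2], quadratic_rl(0.7, 0.5, p$Kd_L), tolerance = 1e-8)
})

test_that("mass balance is conserved along trajectories and across events", {
  p <- ref_params()
  pro <- assay_protocol(
    probe_nM = 0.5, competitor_nM = 1, bbv_dilution = 0.035,
    events = data.frame(time_s = 5400, species = "C", conc_nM = 333000),
    times = seq(0, 10800, 300))
  sim <- simulate_system(p, pro)
  L_tot <- sim$L + sim$RL + sim$NBVL
  R_tot <- sim$R + sim$RL + sim$RC
  expect_true(all(abs(L_tot - 0.5) < 1e-6 * 0.5))
  expect_true(all(abs(R_tot - 0.035 * 20) < 1e-6 * 0.035 * 20))
  C_tot <- sim$C + sim$RC
  pre <- sim$time_s < 5400
  expect_true(all(abs(C_tot[pre] - 1) < 1e-6))
  expect_true(all(abs(C_tot[!pre] - 333001) < 1e-6 * 333001))
})

test_that("event dilution factor rescales the whole well before the step", {
  p <- ref_params(NBV_stock = 1e-3)
  pro <- assay_protocol(
    probe_nM = 1, bbv_dilution = 0,
    events = data.frame(time_s = 100, species = "C", conc_nM = 5,
                        dilution_factor = 0.5),
    times = c(0, 99.999, 100, 200))
  sim <- simulate_system(p, pro)
  expect_equal(sim$L[3], 0.5, tolerance = 1e-9)  # halved by dilution
  expect_equal(sim$C[3], 5, tolerance = 1e-9)    # then incremented
})

test_that("equilibrium solver matches the quadratic closed form to 10+ digits", {
  set.seed(42)
  for (i in 1:20) {
    Kd <- 10^runif(1, -2, 2)
    R_tot <- 10^runif(1, -2, 2)
    L_tot <- 10^runif(1, -2, 2)
    p <- binding_parameters(kon_L = 1e-3, Kd_L = Kd, NBV_stock = 1e-12)
    st <- equilibrium_state(p, L_tot = L_tot, R_tot = R_tot)
    expect_equal(st$RL, quadratic_rl(R_tot, L_tot, Kd),
                 tolerance = 1e-11)
  }
})

test_that("equilibrium solver handles degenerate totals", {
  p <- ref_params()
  st <- equilibrium_state(p, L_tot = 1, R_tot = 0, C_tot = 0, NBV_tot = 0)
  expect_equal(st$RL, 0)
  expect_equal(st$L, 1)
  st0 <- equilibrium_state(p, L_tot = 0, R_tot = 1, C_tot = 1, NBV_tot = 1)
  expect_equal(st0$RL, 0)
  expect_equal(st0$NBVL, 0)
  expect_true(st0$RC > 0)
})

test_that("equilibrium RL is monotone in receptor and competitor totals", {
  p <- ref_params()
  rl_r <- vapply(seq(0.1, 5, length.out = 8), function(R) {
    equilibrium_state(p, L_tot = 0.5, R_tot = R, C_tot = 1,
                      NBV_tot = 2)$RL
  }, numeric(1))
  expect_true(all(diff(rl_r) > 0))
  rl_c <- vapply(10^seq(-2, 3, length.out = 8), function(C) {
    equilibrium_state(p, L_tot = 0.5, R_tot = 0.7, C_tot = C,
                      NBV_tot = 2)$RL
  }, numeric(1))
  expect_true(all(diff(rl_c) < 0))
})

test_that("first-order limit: occupancy ~ R*L/Kd when far below Kd", {
  p <- binding_parameters(kon_L = 1e-3, Kd_L = 10, NBV_stock = 1e-12)
  L_tot <- 0.01
  R_tot <- 0.01
  st <- equilibrium_state(p, L_tot = L_tot, R_tot = R_tot)
  expect_equal(st$RL, R_tot * L_tot / 10, tolerance = 0.02)
})
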