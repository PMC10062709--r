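#' Kinetic dataset for global fitting
#'
#' Bundles anisotropy traces from many wells that share one underlying
#' parameter set (a single experiment), together with the per-well
#' composition and timed reagent-addition events. Wells with identical
#' measurement grids and event times are grouped so the optimizer can
#' integrate a whole group as one stacked ODE system.
#'
#' @param traces A tibble as returned by [fa_traces()]: columns `well`,
#'   `time_s`, `fa`, `probe_nM`, `competitor_nM`, `bbv_dilution`.
#' @param events Optional tibble of per-well additions: columns `well`,
#'   `time_s`, `species`, `conc_nM`, optionally `dilution_factor`.
#' @return An object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(traces, events = NULL) {
  traces <- as_tibble(traces)
  need <- c("well", "time_s", "fa", "probe_nM", "competitor_nM",
            "bbv_dilution")
  if (!all(need %in% names(traces))) {
    abort(paste0("`traces` needs columns ", paste(need, collapse = ", "), "."))
  }
  if (is.null(events)) {
    events <- tibble(well = character(), time_s = numeric(),
                     species = character(), conc_nM = numeric(),
                     dilution_factor = numeric())
  } else {
    events <- as_tibble(events)
    if (!"dilution_factor" %in% names(events)) events$dilution_factor <- 1
  }
  wells <- traces |>
    dplyr::distinct(.data$well, .data$probe_nM, .data$competitor_nM,
                    .data$bbv_dilution)
  if (anyDuplicated(wells$well)) {
    abort("inconsistent well metadata across trace rows.")
  }
  obs <- traces[, c("well", "time_s", "fa")] |>
    dplyr::arrange(.data$well, .data$time_s)

  # group wells by measurement grid and event times; blocker-containing
  # wells are kept apart so their stiff transient does not throttle the
  # integrator steps of the whole stacked system
  sig <- vapply(seq_len(nrow(wells)), function(i) {
    w <- wells$well[i]
    paste(
      paste(obs$time_s[obs$well == w], collapse = ","),
      paste(events$time_s[events$well == w], collapse = ","),
      wells$competitor_nM[i] > 0,
      sep = "|")
  }, character(1))
  groups <- lapply(split(seq_len(nrow(wells)), sig), function(idx) {
    gw <- wells[idx, ]
    gtimes <- sort(unique(obs$time_s[obs$well %in% gw$well]))
    gev <- events[events$well %in% gw$well, ]
    gev$widx <- match(gev$well, gw$well)
    omask <- obs$well %in% gw$well
    list(
      wells = gw,
      times = gtimes,
      events = gev,
      obs_rows = which(omask),
      time_idx = match(obs$time_s[omask], gtimes),
      well_idx = match(obs$well[omask], gw$well)
    )
  })
  structure(list(obs = obs, wells = wells, events = events, groups = groups),
            class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("<kinetic_dataset: %d wells, %d observations, %d ODE group(s)>\n",
              nrow(x$wells), nrow(x$obs), length(x$groups)))
  invisible(x)
}

predict_dataset <- function(params, dataset, rtol = 1e-8, atol = 1e-10) {
  pred <- numeric(nrow(dataset$obs))
  for (g in dataset$groups) {
    init <- rbind(
      R = g$wells$bbv_dilution * params$R_stock,
      L = g$wells$probe_nM,
      C = g$wells$competitor_nM,
      NBV = g$wells$bbv_dilution * params$NBV_stock,
      RL = 0, RC = 0, NBVL = 0
    )
    block <- sim_block(params, init, g$events, g$times,
                       rtol = rtol, atol = atol)
    fa <- fa_from_block(block, params)
    pred[g$obs_rows] <- fa[cbind(g$time_idx, g$well_idx)]
  }
  pred
}

#' Weighted mean-squared-error loss for kinetic global fitting
#'
#' Mean over all observed (well, time) points of
#' `weight * (FA_predicted - FA_observed)^2`, where the prediction runs the
#' full ODE simulation and the state-weighted anisotropy model. A failed
#' simulation returns `+Inf` (with a warning carrying the diagnostic) so
#' that a stochastic optimizer can continue past pathological parameter
#' proposals.
#'
#' @param params A [binding_parameters()] object.
#' @param dataset A [kinetic_dataset()].
#' @param weights Per-observation weights (default: uniform). See
#'   [dataset_time_weights()].
#' @return Scalar loss.
#' @export
kinetic_loss <- function(params, dataset, weights = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (is.null(weights)) weights <- rep(1, nrow(dataset$obs))
  pred <- tryCatch(predict_dataset(params, dataset), error = function(e) e)
  if (inherits(pred, "error")) {
    warn(paste0("simulation failed, loss set to +Inf: ",
                conditionMessage(pred)))
    return(Inf)
  }
  mean(weights * (pred - dataset$obs$fa)^2)
}

#' Time-dependent weighting of kinetic measurement points
#'
#' Early points after reaction initiation carry most of the information
#' about association rates, so they receive larger weights. The default
#' `"less_timescaling"` scheme is the hyperbolic surrogate
#' `w(t) = 1 / (1 + t / tau)` (a mild down-weighting of late points; the
#' name follows the analysis setting it emulates). Weights are positive,
#' non-increasing in time and normalized to mean 1.
#'
#' @param times Times in seconds (>= 0, relative to the initiating event).
#' @param scheme `"less_timescaling"` or `"uniform"`.
#' @param tau Scale of the hyperbolic scheme, seconds.
#' @return Numeric weights, mean 1.
#' @examples
#' time_weights(c(0, 600, 1200))          # decreasing
#' time_weights(c(0, 600), "uniform")     # all 1
#' @export
time_weights <- function(times, scheme = c("less_timescaling", "uniform"),
                         tau = 600) {
  scheme <- match.arg(scheme)
  if (any(times < 0)) abort("`times` must be >= 0.")
  w <- raw_time_weight(times, scheme, tau)
  w / mean(w)
}

raw_time_weight <- function(times, scheme, tau) {
  switch(scheme,
         uniform = rep(1, length(times)),
         less_timescaling = 1 / (1 + times / tau))
}

#' Per-observation weights of a kinetic dataset
#'
#' Applies [time_weights()] with time measured from the most recent
#' reagent-addition event of each well (so points right after a
#' dissociation-initiating chase are up-weighted like points right after
#' association start), then normalizes to mean 1 over the whole dataset.
#'
#' @inheritParams time_weights
#' @param dataset A [kinetic_dataset()].
#' @return Numeric vector aligned with `dataset$obs`.
#' @export
dataset_time_weights <- function(dataset,
                                 scheme = c("less_timescaling", "uniform"),
                                 tau = 600) {
  scheme <- match.arg(scheme)
  obs <- dataset$obs
  ev <- dataset$events
  t_rel <- vapply(seq_len(nrow(obs)), function(i) {
    et <- ev$time_s[ev$well == obs$well[i] & ev$time_s <= obs$time_s[i]]
    obs$time_s[i] - if (length(et)) max(et) else 0
  }, numeric(1))
  w <- raw_time_weight(t_rel, scheme, tau)
  w / mean(w)
}

# ---- parameter transforms ------------------------------------------------

PARAM_KIND <- c(
  kon_L = "rate", Kd_L = "conc", kon_C = "rate", Ki_C = "conc",
  kon_NS = "rate", koff_NS = "rate", R_stock = "conc", NBV_stock = "conc",
  FA_free = "fa", FA_bound = "fa", FA_ns = "fa"
)

default_bounds <- function() {
  # anisotropy bounds follow the physical plausibility window: intrinsic
  # FA of an organic dye cannot exceed its limiting anisotropy (~0.4)
  list(rate = c(1e-8, 1e2), conc = c(1e-3, 1e4), fa = c(-0.2, 0.5))
}

encode_theta <- function(params, free) {
  vapply(free, function(nm) {
    v <- params[[nm]]
    if (PARAM_KIND[[nm]] == "fa") v else log10(v)
  }, numeric(1))
}

decode_theta <- function(theta, free, base, bounds) {
  penalty <- 0
  vals <- list()
  for (i in seq_along(free)) {
    nm <- free[i]
    kind <- PARAM_KIND[[nm]]
    b <- bounds[[kind]]
    x <- theta[i]
    if (kind == "fa") {
      lo <- b[1]; hi <- b[2]
    } else {
      lo <- log10(b[1]); hi <- log10(b[2])
    }
    if (x < lo) { penalty <- penalty + (lo - x)^2; x <- lo }
    if (x > hi) { penalty <- penalty + (x - hi)^2; x <- hi }
    vals[[nm]] <- if (kind == "fa") x else 10^x
  }
  list(params = do.call(update_parameters, c(list(base), vals)),
       penalty = penalty)
}

#' Configuration of the simulated-annealing global fit
#'
#' Controls of the hybrid Nelder-Mead / simulated-annealing optimizer and of
#' the loss weighting. The annealing schedule defaults to a start
#' temperature of 1000 with 10^3 loss evaluations per temperature and a
#' temperature reduction factor of 0.2, cooling until the temperature falls
#' below 0.1. Temperature here is the usual annealing control parameter (it
#' scales both the Metropolis acceptance test and the proposal magnitude on
#' the log-parameter scale), not an experimental temperature.
#'
#' @param start_temp,iters_per_temp,temp_reduction,stop_temp Annealing
#'   schedule.
#' @param scheme,tau Time-weighting scheme, see [dataset_time_weights()].
#' @param seed Integer RNG seed; the whole fit is deterministic given it.
#' @param n_uncertainty Number of perturbed refits used for uncertainty
#'   estimation (the spread of re-estimates is reported as the SE).
#' @param nm_budget Nelder-Mead iteration budget of each annealing restart.
#' @param sigma0 Proposal magnitude at the start temperature, decades on the
#'   log-parameter scale (scaled by `temp / start_temp` as cooling proceeds).
#' @param sigma0_fa Proposal magnitude for anisotropy parameters, FA units.
#' @param polish_maxit Iteration budget of the final plain Nelder-Mead polish.
#' @param bounds Named list with elements `rate`, `conc`, `fa`, each a
#'   length-2 range; defaults: rates 1e-8..1e2, concentrations 1e-3..1e4 nM,
#'   anisotropies -0.2..0.5, matching the physical plausibility window.
#' @return An object of class `fa_fit_config`.
#' @export
fit_config <- function(start_temp = 1000, iters_per_temp = 1000,
                       temp_reduction = 0.2, stop_temp = 0.1,
                       scheme = "less_timescaling", tau = 600,
                       seed = 1L, n_uncertainty = 25, nm_budget = 25,
                       sigma0 = 3, sigma0_fa = 0.3, polish_maxit = 2000,
                       bounds = default_bounds()) {
  if (temp_reduction <= 0 || temp_reduction >= 1) {
    abort("`temp_reduction` must lie in (0, 1).")
  }
  if (stop_temp >= start_temp) abort("`stop_temp` must be < `start_temp`.")
  structure(list(
    start_temp = start_temp, iters_per_temp = iters_per_temp,
    temp_reduction = temp_reduction, stop_temp = stop_temp,
    scheme = scheme, tau = tau, seed = as.integer(seed),
    n_uncertainty = n_uncertainty, nm_budget = nm_budget,
    sigma0 = sigma0, sigma0_fa = sigma0_fa, polish_maxit = polish_maxit,
    bounds = bounds
  ), class = "fa_fit_config")
}

# Neutral starting point: anisotropy levels guessed from the data extremes,
# everything else at mid-range magnitudes. Assay constants of the reference
# system (blocker kinetics, NS dissociation) come from `base`.
data_driven_init <- function(dataset, base) {
  fa <- dataset$obs$fa
  lo <- stats::quantile(fa, 0.02, names = FALSE)
  hi <- stats::quantile(fa, 0.98, names = FALSE)
  update_parameters(base,
                    kon_L = 1e-3, Kd_L = 1, kon_NS = 1e-5,
                    R_stock = 10, NBV_stock = 50,
                    FA_free = max(min(lo, 0.45), -0.15),
                    FA_bound = max(min(hi + 0.02, 0.45), -0.15),
                    FA_ns = max(min((lo + hi) / 2, 0.45), -0.15))
}

#' Global kinetic parameter estimation by simulated annealing
#'
#' Estimates the free parameters of the binding model from a multi-well
#' kinetic dataset by minimizing the time-weighted mean-squared error of the
#' predicted anisotropy ([kinetic_loss()]). The optimizer is a seeded hybrid
#' of Nelder-Mead simplex refinement inside a Metropolis simulated-annealing
#' temperature ladder: at each temperature, restart points are drawn around
#' the best state found so far with magnitude proportional to temperature on the
#' log-parameter scale, each is refined by a short Nelder-Mead run, and the
#' refined candidate is accepted by the Metropolis criterion on the loss
#' (with the Boltzmann scale calibrated so the initial loss is borderline
#' acceptable at the start temperature). The ladder is initialized by a
#' deterministic iterated simplex descent from the starting point, and a
#' plain Nelder-Mead polish (iterated until the loss stops improving) is
#' run from the best point after it. Uncertainty is estimated
#' by `n_uncertainty` perturbed refits around the optimum; their spread is
#' reported as the SE of each estimate.
#'
#' @param dataset A [kinetic_dataset()].
#' @param config A [fit_config()].
#' @param params_init Starting [binding_parameters()]; fixed (non-free)
#'   parameters keep these values. Defaults to a crude data-driven guess on
#'   top of [celt419_parameters()].
#' @param free Character vector of free parameter names.
#' @param weights Per-observation weights; default
#'   [dataset_time_weights()] under the config's scheme.
#' @return An object of class `fa_global_fit`: `estimates` (term, estimate,
#'   std.error), `params` (full parameter set at the optimum), `final_loss`,
#'   `residuals` (per-point), `log` (annealing trace), `seed`, `config`,
#'   `n_evals`.
#' @export
fit_global <- function(dataset, config = fit_config(), params_init = NULL,
                       free = c("kon_L", "Kd_L", "kon_NS", "R_stock",
                                "NBV_stock", "FA_free", "FA_bound", "FA_ns"),
                       weights = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"),
            inherits(config, "fa_fit_config"))
  if (length(free) < 1L) abort("need at least one free parameter.")
  bad <- setdiff(free, names(PARAM_KIND))
  if (length(bad)) {
    abort(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(params_init)) {
    params_init <- data_driven_init(dataset, celt419_parameters())
  }
  if (is.null(weights)) {
    weights <- dataset_time_weights(dataset, config$scheme, config$tau)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n_evals <- 0L
  loss_fn <- function(theta) {
    n_evals <<- n_evals + 1L
    dec <- tryCatch(decode_theta(theta, free, params_init, config$bounds),
                    error = function(e) NULL)
    if (is.null(dec)) return(1e6)
    l <- suppressWarnings(kinetic_loss(dec$params, dataset, weights))
    if (!is.finite(l)) return(1e6)
    l * (1 + dec$penalty) + dec$penalty * 1e-3
  }

  is_fa <- PARAM_KIND[free] == "fa"
  step_scale <- function(temp) {
    s <- rep(config$sigma0 * temp / config$start_temp, length(free))
    s[is_fa] <- config$sigma0_fa * temp / config$start_temp
    s
  }

  polish_from <- function(theta, loss_at, max_rounds = 8L, rel_gain = 1e-7) {
    for (round in seq_len(max_rounds)) {
      nm <- stats::optim(theta, loss_fn, method = "Nelder-Mead",
                         control = list(maxit = config$polish_maxit,
                                        reltol = 1e-12,
                                        warn.1d.NelderMead = FALSE))
      gain <- loss_at - nm$value
      if (nm$value <= loss_at) {
        theta <- nm$par
        loss_at <- nm$value
      }
      if (gain < rel_gain * max(loss_at, 1e-300)) break
    }
    list(theta = theta, loss = loss_at)
  }

  theta_cur <- encode_theta(params_init, free)
  loss_cur <- loss_fn(theta_cur)
  kB <- max(loss_cur, 1e-12) / config$start_temp
  # deterministic initialization: iterated simplex descent from the start
  # point, so the stochastic ladder explores around a near-converged
  # solution (loose stopping: the ladder and final polish refine further)
  pre <- polish_from(theta_cur, loss_cur, max_rounds = 6L, rel_gain = 1e-4)
  theta_cur <- pre$theta
  loss_cur <- pre$loss
  theta_best <- theta_cur
  loss_best <- loss_cur

  temps <- c()
  temp <- config$start_temp
  while (temp > config$stop_temp) {
    temps <- c(temps, temp)
    temp <- temp * config$temp_reduction
  }
  n_restarts <- max(1L, floor(config$iters_per_temp / config$nm_budget))
  log_rows <- vector("list", length(temps) * n_restarts)
  li <- 0L
  for (temp in temps) {
    s <- step_scale(temp)
    for (r in seq_len(n_restarts)) {
      prop <- theta_best + rnorm(length(free), sd = s)
      nm <- stats::optim(prop, loss_fn, method = "Nelder-Mead",
                         control = list(maxit = config$nm_budget,
                                        warn.1d.NelderMead = FALSE))
      delta <- nm$value - loss_cur
      accept <- delta < 0 || runif(1) < exp(-delta / (kB * temp))
      if (accept) {
        theta_cur <- nm$par
        loss_cur <- nm$value
      }
      if (nm$value < loss_best) {
        theta_best <- nm$par
        loss_best <- nm$value
      }
      li <- li + 1L
      log_rows[[li]] <- tibble(temp = temp, restart = r,
                               loss_proposal = nm$value,
                               loss_current = loss_cur, accepted = accept)
    }
  }
  # final plain Nelder-Mead polish, iterated (simplex restarts) until the
  # loss stops improving; a single run stalls on the long shallow ridges
  # typical of jointly fitted stock concentrations and anisotropies
  fin <- polish_from(theta_best, loss_best, max_rounds = 10L)
  theta_best <- fin$theta
  loss_best <- fin$loss
  if (!is.finite(loss_best) || loss_best >= 1e6) {
    abort(sprintf(
      "all annealing restarts diverged; best loss %.4g at theta = [%s].",
      loss_best, paste(signif(theta_best, 4), collapse = ", ")))
  }

  # uncertainty: spread of perturbed refits around the optimum
  refits <- matrix(NA_real_, nrow = config$n_uncertainty,
                   ncol = length(free), dimnames = list(NULL, free))
  for (k in seq_len(config$n_uncertainty)) {
    pert <- theta_best + rnorm(length(free), sd = ifelse(is_fa, 0.02, 0.05))
    nm <- stats::optim(pert, loss_fn, method = "Nelder-Mead",
                       control = list(maxit = 200,
                                      warn.1d.NelderMead = FALSE))
    refits[k, ] <- nm$par
  }
  est_nat <- ifelse(is_fa, theta_best, 10^theta_best)
  se_nat <- vapply(seq_along(free), function(j) {
    sd(if (is_fa[j]) refits[, j] else 10^refits[, j])
  }, numeric(1))

  params_hat <- decode_theta(theta_best, free, params_init,
                             config$bounds)$params
  pred <- predict_dataset(params_hat, dataset)
  resid_tbl <- dplyr::bind_cols(dataset$obs,
                                tibble(pred = pred,
                                       resid = dataset$obs$fa - pred,
                                       weight = weights))
  final_loss <- mean(weights * resid_tbl$resid^2)

  structure(list(
    estimates = tibble(term = free, estimate = unname(est_nat),
                       std.error = unname(se_nat)),
    params = params_hat,
    final_loss = final_loss,
    residuals = resid_tbl,
    log = dplyr::bind_rows(log_rows[seq_len(li)]),
    seed = config$seed,
    config = config,
    free = free,
    n_evals = n_evals
  ), class = "fa_global_fit")
}

#' @export
print.fa_global_fit <- function(x, ...) {
  cat(sprintf(
    "<fa_global_fit: %d free parameters, loss %.4g, %d evaluations, seed %d>\n",
    nrow(x$estimates), x$final_loss, x$n_evals, x$seed))
  print(x$estimates)
  invisible(x)
}

#' Select informative concentration points of a competition curve
#'
#' Plateau points of a concentration-response curve carry little information
#' about competitor kinetics, so kinetic fits use the points on the slope
#' (fitted response between 10% and 90% of the window) plus the one or two
#' plateau points nearest the slope on each side. The rule is deterministic
#' and invariant to the ordering of the input.
#'
#' @param curve A data frame with columns `conc` and `response`.
#' @param fit Optional [fit_sigmoid()] result for the curve; fitted
#'   internally when omitted.
#' @param n_plateau Plateau points retained on each side (default 2).
#' @return Logical inclusion mask aligned with the rows of `curve`.
#' @export
select_competition_points <- function(curve, fit = NULL, n_plateau = 2L) {
  curve <- as_tibble(curve)
  if (is.null(fit)) {
    fit <- tryCatch(fit_sigmoid(curve), error = function(e) e)
    if (inherits(fit, "error")) {
      warn(paste0("sigmoid fit failed (", conditionMessage(fit),
                  "); all points retained."))
      return(rep(TRUE, nrow(curve)))
    }
  }
  top <- sigmoid_coef(fit, "top")
  bottom <- sigmoid_coef(fit, "bottom")
  lic <- sigmoid_coef(fit, "log_ic50")
  frac <- function(conc) 1 / (1 + 10^(log10(conc) - lic)) # 1 at c=0, 0 at inf
  f <- frac(curve$conc)
  slope <- f > 0.1 & f < 0.9
  if (sum(slope) < 4L) {
    warn("fewer than 4 points on the slope; all points retained.")
    return(rep(TRUE, nrow(curve)))
  }
  keep <- slope
  ord <- order(curve$conc)
  slope_pos <- which(slope[ord])
  below <- ord[seq_len(min(slope_pos) - 1L)]
  above <- if (max(slope_pos) < length(ord)) {
    ord[(max(slope_pos) + 1L):length(ord)]
  } else {
    integer()
  }
  keep[tail(below, n_plateau)] <- TRUE
  keep[head(above, n_plateau)] <- TRUE
  keep
}
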