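#' Theoretical Log(IC50) time course predicted by the kinetic model
#'
#' Simulates the anisotropy of a full competitor dilution series (one well
#' per concentration, identical protocol otherwise), then fits the
#' three-parameter sigmoid at every simulation time point and records the
#' fitted Log(IC50). Before equilibrium the apparent IC50 moves in time: it
#' decreases when the competitor equilibrates more slowly than the probe
#' and increases when it equilibrates faster; the direction and rate carry
#' kinetic information about the competitor.
#'
#' @param params A [binding_parameters()] object (competitor kinetics in
#'   `kon_C`, `Ki_C`).
#' @param competitor_nM Competitor concentration grid, nM; must include 0
#'   (the competitor-free anchor) and span the sigmoid.
#' @param times Simulation/measurement time grid, seconds.
#' @param probe_nM Total probe, nM.
#' @param bbv_dilution Receptor-particle dilution of the wells.
#' @return A tibble of class `fa_ic50_timecourse`: columns `time_s`,
#'   `log_ic50`, `se`, `converged`, `source = "theoretical"`. Times where
#'   the sigmoid fit fails are flagged (`converged = FALSE`, `log_ic50 =
#'   NA`), never interpolated.
#' @export
theoretical_ic50_timecourse <- function(params, competitor_nM, times,
                                        probe_nM = 0.5,
                                        bbv_dilution = 0.035) {
  stopifnot(inherits(params, "binding_parameters"))
  competitor_nM <- sort(unique(competitor_nM))
  if (!0 %in% competitor_nM) {
    abort("`competitor_nM` must include 0 (competitor-free anchor).")
  }
  if (length(competitor_nM) < 6L) {
    abort("need at least 6 competitor concentrations.")
  }
  init <- rbind(
    R = rep(bbv_dilution * params$R_stock, length(competitor_nM)),
    L = probe_nM, C = competitor_nM,
    NBV = bbv_dilution * params$NBV_stock,
    RL = 0, RC = 0, NBVL = 0
  )
  ev <- tibble(time_s = numeric(), species = character(),
               conc_nM = numeric(), dilution_factor = numeric(),
               widx = integer())
  block <- sim_block(params, init, ev, times)
  fa <- fa_from_block(block, params) # [time, conc]
  fits_at_times(times, competitor_nM, fa, source = "theoretical")
}

fits_at_times <- function(times, conc, fa_mat, source) {
  rows <- lapply(seq_along(times), function(i) {
    fit <- tryCatch(
      fit_sigmoid(tibble(conc = conc, response = fa_mat[i, ])),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      tibble(time_s = times[i], log_ic50 = NA_real_, se = NA_real_,
             converged = FALSE)
    } else {
      tibble(time_s = times[i],
             log_ic50 = sigmoid_coef(fit, "log_ic50"),
             se = fit$estimates$std.error[fit$estimates$term == "log_ic50"],
             converged = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$source <- source
  class(out) <- c("fa_ic50_timecourse", class(out))
  out
}

#' Observed Log(IC50) time course from measured competition kinetics
#'
#' Per-time three-parameter sigmoid fits of measured anisotropy against
#' competitor concentration. Each time point must carry the complete
#' concentration series; times with missing concentrations are skipped with
#' a warning, and times where the fit fails are flagged, not interpolated.
#'
#' @param traces A tibble with columns `time_s`, `fa`, `competitor_nM`
#'   (e.g. from [fa_traces()] of a competition experiment); replicate wells
#'   at the same concentration are averaged within the fit.
#' @return A tibble of class `fa_ic50_timecourse` with
#'   `source = "observed"`.
#' @export
observed_ic50_timecourse <- function(traces) {
  traces <- as_tibble(traces)
  if (!all(c("time_s", "fa", "competitor_nM") %in% names(traces))) {
    abort("`traces` needs columns time_s, fa, competitor_nM.")
  }
  concs <- sort(unique(traces$competitor_nM))
  times <- sort(unique(traces$time_s))
  keep <- vapply(times, function(t) {
    all(concs %in% traces$competitor_nM[traces$time_s == t])
  }, logical(1))
  if (any(!keep)) {
    warn(sprintf("%d time point(s) skipped: incomplete concentration series.",
                 sum(!keep)))
  }
  times <- times[keep]
  fa_mat <- t(vapply(times, function(t) {
    sub <- traces[traces$time_s == t, ]
    vapply(concs, function(cc) mean(sub$fa[sub$competitor_nM == cc]),
           numeric(1))
  }, numeric(length(concs))))
  fits_at_times(times, concs, fa_mat, source = "observed")
}

#' Exponential stabilization fit of a Log(IC50) time course
#'
#' Fits the single-phase exponential decay towards the equilibrium plateau
#' \deqn{Log(IC50)_t = (Log(IC50)_{t=0} - Log(IC50)_{eq})\,e^{-k t} + Log(IC50)_{eq}}
#' with `t` in minutes from reaction initiation and `k` in 1/min; the
#' stabilization half-life is `ln(2)/k`. Points are weighted by their
#' inverse squared per-time SE by default (switchable).
#'
#' @param tc A `fa_ic50_timecourse` (needs >= 4 valid time points).
#' @param weighted Use inverse-variance weights from the per-time SEs.
#' @return An object of class `fa_ic50_decay` with `estimates` (terms
#'   `log_ic50_t0`, `log_ic50_eq`, `k_per_min`, `half_life_min` with SEs),
#'   `fitted`, `data`.
#' @export
fit_ic50_decay <- function(tc, weighted = TRUE) {
  tc <- as_tibble(tc)
  ok <- is.finite(tc$log_ic50)
  if (sum(ok) < 4L) abort("need at least 4 valid time points.")
  d <- tc[ok, ]
  t_min <- d$time_s / 60
  w <- if (weighted && all(is.finite(d$se)) && all(d$se > 0)) {
    1 / d$se^2
  } else {
    rep(1, nrow(d))
  }
  w <- w / mean(w)
  model <- function(th) {
    (th[["l0"]] - th[["leq"]]) * exp(-exp(th[["log_k"]]) * t_min) + th[["leq"]]
  }
  start <- c(l0 = d$log_ic50[1], leq = d$log_ic50[nrow(d)],
             log_k = log(log(2) / max(t_min[2], 1)))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(th) sqrt(w) * (d$log_ic50 - model(th)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  th <- coef(fit)
  k <- exp(th[["log_k"]])
  if (!fit$info %in% 1:4 || !is.finite(k) || k <= 0) {
    abort("stabilization not detected: decay rate not identifiable.")
  }
  se_th <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) rep(NA_real_, 3))
  if (!all(is.finite(se_th))) {
    abort("stabilization not detected: time course is flat or degenerate.")
  }
  se_k <- k * se_th[["log_k"]]
  hl <- log(2) / k
  est <- tibble(
    term = c("log_ic50_t0", "log_ic50_eq", "k_per_min", "half_life_min"),
    estimate = c(th[["l0"]], th[["leq"]], k, hl),
    std.error = c(se_th[["l0"]], se_th[["leq"]], se_k, hl * se_th[["log_k"]])
  )
  structure(list(estimates = est, fitted = model(th), data = d,
                 weighted = weighted),
            class = "fa_ic50_decay")
}

#' @export
print.fa_ic50_decay <- function(x, ...) {
  cat("<fa_ic50_decay>\n")
  print(x$estimates)
  invisible(x)
}

#' Evaluate the stabilization model
#'
#' @param t_min Times in minutes.
#' @param log_ic50_t0,log_ic50_eq,k Model parameters (`k` in 1/min).
#' @return Predicted Log(IC50) values.
#' @export
ic50_decay_model <- function(t_min, log_ic50_t0, log_ic50_eq, k) {
  (log_ic50_t0 - log_ic50_eq) * exp(-k * t_min) + log_ic50_eq
}
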