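#' Saturation binding analysis with full ligand-depletion treatment
#'
#' Fits endpoint anisotropy from a two-probe-concentration saturation design
#' (serial receptor-particle dilutions, total and nonspecific conditions)
#' with one global parameter set. Predicted anisotropy per well is computed
#' through the exact coupled equilibrium ([equilibrium_state()]) and the
#' state-weighted anisotropy ([anisotropy_from_states()]), so probe and
#' receptor depletion are fully accounted for. Nonspecific wells (receptor
#' blocked by excess unlabeled ligand) are modelled with zero available
#' receptor; non-specific sites remain active.
#'
#' Free parameters: `Kd_L`, `R_stock`, `NBV_stock`, `FA_free`, `FA_bound`
#' (positivity enforced by fitting concentration-like terms on the log
#' scale). The non-specific equilibrium constant `koff_NS/kon_NS` and
#' `FA_ns` are taken from `params_init` and held fixed: at working dilutions
#' non-specific binding is far from saturation, so only the ratio
#' `NBV_stock * FA-shift / K_NS` is identifiable and the scale is carried by
#' `NBV_stock`.
#'
#' @param dataset A data frame with columns `bbv_dilution`, `probe_nM`,
#'   `fa`, `condition` (`"total"` or `"nonspecific"`).
#' @param params_init A [binding_parameters()] object providing starting
#'   values and the fixed parameters.
#' @return `fa_saturation_fit` object: `estimates` (term, estimate,
#'   std.error on the natural scale), `params` (fitted parameter set),
#'   `fitted`, `data`, `residual_sd`.
#' @export
fit_saturation <- function(dataset, params_init = celt419_parameters()) {
  dataset <- as_tibble(dataset)
  need <- c("bbv_dilution", "probe_nM", "fa", "condition")
  if (!all(need %in% names(dataset))) {
    abort(paste0("`dataset` needs columns ", paste(need, collapse = ", "), "."))
  }
  if (!"total" %in% dataset$condition) {
    abort("no total-binding wells: FA_bound is unidentifiable from nonspecific wells alone.")
  }
  if (!"nonspecific" %in% dataset$condition) {
    abort("no nonspecific wells in dataset.")
  }
  if (length(unique(dataset$bbv_dilution)) < 4L) {
    abort("need at least 4 distinct BBV dilutions.")
  }

  predict_fa <- function(p) {
    vapply(seq_len(nrow(dataset)), function(i) {
      d <- dataset$bbv_dilution[i]
      R_tot <- if (dataset$condition[i] == "total") d * p$R_stock else 0
      st <- equilibrium_state(p, L_tot = dataset$probe_nM[i], R_tot = R_tot,
                              C_tot = 0, NBV_tot = d * p$NBV_stock)
      anisotropy_from_states(st, p)
    }, numeric(1))
  }

  make_params <- function(th) {
    update_parameters(params_init,
                      Kd_L = 10^th[["log_Kd_L"]],
                      R_stock = 10^th[["log_R_stock"]],
                      NBV_stock = 10^th[["log_NBV_stock"]],
                      FA_free = th[["FA_free"]], FA_bound = th[["FA_bound"]])
  }
  start <- c(log_Kd_L = log10(params_init$Kd_L),
             log_R_stock = log10(params_init$R_stock),
             log_NBV_stock = log10(max(params_init$NBV_stock, 1e-3)),
             FA_free = params_init$FA_free, FA_bound = params_init$FA_bound)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(th) {
      p <- tryCatch(make_params(th), error = function(e) NULL)
      if (is.null(p)) return(rep(1e3, nrow(dataset)))
      dataset$fa - predict_fa(p)
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  th <- coef(fit)
  p_hat <- make_params(th)
  resid_sd <- sqrt(sum(fit$fvec^2) / max(1, nrow(dataset) - length(th)))
  se_th <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) rep(NA_real_, length(th)))
  if (any(!is.finite(se_th[c("log_Kd_L", "log_R_stock")])) ||
      any(se_th[c("log_Kd_L", "log_R_stock")] > 2)) {
    abort(paste0(
      "Kd/R_stock not identifiable (no curvature: receptor never limiting); ",
      "widen the BBV dilution range."))
  }
  # delta method back to the natural scale for log-fitted terms
  nat <- c(Kd_L = 10^th[["log_Kd_L"]], R_stock = 10^th[["log_R_stock"]],
           NBV_stock = 10^th[["log_NBV_stock"]],
           FA_free = th[["FA_free"]], FA_bound = th[["FA_bound"]])
  se_nat <- c(nat[1:3] * log(10) * se_th[1:3], se_th[4:5])
  structure(list(
    estimates = tibble(term = names(nat), estimate = unname(nat),
                       std.error = unname(se_nat)),
    params = p_hat,
    fitted = predict_fa(p_hat),
    data = dataset,
    residual_sd = resid_sd,
    converged = fit$info %in% 1:4
  ), class = "fa_saturation_fit")
}

#' @export
print.fa_saturation_fit <- function(x, ...) {
  cat(sprintf("<fa_saturation_fit: %d wells, residual SD %.4g FA units>\n",
              nrow(x$data), x$residual_sd))
  print(x$estimates)
  invisible(x)
}

#' Depletion-corrected Ki from an IC50
#'
#' Inverts the competition equilibrium numerically: returns the competitor
#' equilibrium constant `Ki` for which, at competitor total equal to the
#' IC50, the specific signal (`RL` at equilibrium) is exactly half of its
#' competitor-free value — the definition of an IC50 under ligand depletion.
#' As the receptor total tends to zero this reduces to the Cheng-Prusoff
#' relation `Ki = IC50 / (1 + L/Kd)`.
#'
#' @param log_ic50 Log10 of the IC50 in nM.
#' @param Kd_L Probe equilibrium dissociation constant, nM.
#' @param probe_nM Total probe concentration, nM.
#' @param receptor_nM Total receptor concentration in the well, nM.
#' @return Ki in nM.
#' @examples
#' # negligible depletion: Cheng-Prusoff limit
#' ki_from_ic50_depletion(log10(2), Kd_L = 1, probe_nM = 1,
#'                        receptor_nM = 1e-6) # ~1 nM
#' @export
ki_from_ic50_depletion <- function(log_ic50, Kd_L, probe_nM, receptor_nM) {
  if (!is.finite(log_ic50)) abort("`log_ic50` must be finite.")
  if (Kd_L <= 0 || probe_nM <= 0 || receptor_nM <= 0) {
    abort("Kd_L, probe_nM and receptor_nM must be > 0.")
  }
  ic50 <- 10^log_ic50
  base <- binding_parameters(kon_L = 1e-3, Kd_L = Kd_L)
  rl0 <- equilibrium_state(base, L_tot = probe_nM, R_tot = receptor_nM)$RL
  rl_at <- function(log_ki) {
    p <- update_parameters(base, Ki_C = 10^log_ki)
    equilibrium_state(p, L_tot = probe_nM, R_tot = receptor_nM,
                      C_tot = ic50)$RL
  }
  f <- function(log_ki) rl_at(log_ki) - rl0 / 2
  lo <- -10
  hi <- 12
  if (f(lo) > 0) {
    abort(paste0(
      "IC50 below the theoretical floor set by ligand depletion: even an ",
      "infinitely potent competitor at this concentration cannot halve the ",
      "specific signal."))
  }
  10^uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Cheng-Prusoff conversion of an IC50 to a Ki
#'
#' `Ki = IC50 / (1 + L / Kd)`, valid when neither probe nor competitor is
#' depleted by binding.
#'
#' @param ic50 IC50, nM.
#' @param radioligand_nM Probe (radioligand) concentration, nM.
#' @param radioligand_Kd Probe equilibrium dissociation constant, nM.
#' @return Ki in nM.
#' @examples
#' cheng_prusoff_ki(30.1, 1, 1.090) # ~15.7
#' @export
cheng_prusoff_ki <- function(ic50, radioligand_nM, radioligand_Kd) {
  if (any(c(ic50, radioligand_nM, radioligand_Kd) <= 0)) {
    abort("all inputs must be > 0.")
  }
  ic50 / (1 + radioligand_nM / radioligand_Kd)
}

#' Z'-factor screening-window quality metric
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|}}
#' with sample (n-1) standard deviations. Z' > 0.5 is the conventional
#' threshold for an assay suitable for high-throughput screening.
#'
#' @param positive,negative Numeric vectors of control anisotropies
#'   (>= 2 replicates each).
#' @return An object of class `fa_zprime` with fields `mu_pos`, `mu_neg`,
#'   `sigma_pos`, `sigma_neg`, `z_prime`, `n_pos`, `n_neg`.
#' @examples
#' z_prime(rep(0.20, 3), rep(0.08, 3))$z_prime # 1: zero variance
#' @export
z_prime <- function(positive, negative) {
  if (length(positive) < 2L || length(negative) < 2L) {
    abort("need at least 2 replicates per control.")
  }
  mu_p <- mean(positive)
  mu_n <- mean(negative)
  if (mu_p == mu_n) abort("Z' undefined: control means are equal.")
  s_p <- sd(positive)
  s_n <- sd(negative)
  structure(list(
    mu_pos = mu_p, mu_neg = mu_n, sigma_pos = s_p, sigma_neg = s_n,
    z_prime = 1 - 3 * (s_p + s_n) / abs(mu_p - mu_n),
    n_pos = length(positive), n_neg = length(negative)
  ), class = "fa_zprime")
}

#' @export
print.fa_zprime <- function(x, ...) {
  cat(sprintf(
    "<fa_zprime> Z' = %.3f (pos %.4g +/- %.2g, n=%d; neg %.4g +/- %.2g, n=%d)\n",
    x$z_prime, x$mu_pos, x$sigma_pos, x$n_pos, x$mu_neg, x$sigma_neg, x$n_neg))
  invisible(x)
}
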