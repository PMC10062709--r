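#' @importFrom deSolve lsoda
NULL

SPECIES <- c("R", "L", "C", "NBV", "RL", "RC", "NBVL")

rate_vector <- function(params) {
  c(params$kon_L, params$koff_L, params$kon_C, params$koff_C,
    params$kon_NS, params$koff_NS)
}

#' Simulate the binding reaction system for one well
#'
#' Integrates the mass-action system
#' \deqn{R + L \rightleftharpoons RL,\quad R + C \rightleftharpoons RC,\quad
#'       NBV + L \rightleftharpoons NBVL}
#' as seven coupled ordinary differential equations (compiled derivatives,
#' stiff-capable `lsoda`, rtol 1e-8 / atol 1e-10 nM). Integration is
#' restarted at every reagent-addition event; between events the totals
#' L + RL + NBVL, R + RL + RC, C + RC and NBV + NBVL are conserved to
#' integrator tolerance.
#'
#' @param params A [binding_parameters()] object.
#' @param protocol An [assay_protocol()] object.
#' @param rtol,atol Integrator tolerances (relative; absolute, nM).
#' @return A tibble with column `time_s` and one column per species
#'   (`R`, `L`, `C`, `NBV`, `RL`, `RC`, `NBVL`), all nM, at every
#'   measurement time of the protocol.
#' @examples
#' p <- celt419_parameters()
#' pro <- assay_protocol(probe_nM = 0.5, bbv_dilution = 0.035,
#'                       times = seq(0, 5400, 300))
#' sim <- simulate_system(p, pro)
#' head(sim)
#' @export
simulate_system <- function(params, protocol, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(protocol, "assay_protocol"))
  init <- matrix(c(protocol$bbv_dilution * params$R_stock,
                   protocol$probe_nM,
                   protocol$competitor_nM,
                   protocol$bbv_dilution * params$NBV_stock,
                   0, 0, 0), ncol = 1)
  ev <- protocol$events
  ev$widx <- rep(1L, nrow(ev))
  out <- sim_block(params, init, ev, protocol$times, rtol = rtol, atol = atol)
  res <- as_tibble(as.data.frame(matrix(out[, , 1], ncol = 7,
                                        dimnames = list(NULL, SPECIES))))
  dplyr::bind_cols(tibble(time_s = protocol$times), res)
}

# Integrate a block of wells sharing one rate-parameter set.
# init: 7 x n matrix of initial states; events: tibble with widx column
# identifying the well each addition applies to. Returns array
# [n_times, 7, n_wells] at the requested measurement times.
sim_block <- function(params, init, events, times, rtol = 1e-8, atol = 1e-10) {
  n <- ncol(init)
  p <- rate_vector(params)
  if (any(!is.finite(p)) || any(p < 0)) {
    abort("non-finite or negative rate constants; cannot simulate.")
  }
  bounds <- sort(unique(c(0, events$time_s, max(times))))
  y <- as.numeric(init)
  out <- array(NA_real_, dim = c(length(times), 7L, n))
  if (any(times == 0)) out[times == 0, , ] <- rep(init, each = sum(times == 0))

  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]
    t1 <- bounds[i + 1L]
    # apply additions scheduled at the segment start
    if (i > 1L) {
      evs <- events[events$time_s == t0, , drop = FALSE]
      for (j in seq_len(nrow(evs))) {
        w <- evs$widx[j]
        idx <- (w - 1L) * 7L + seq_len(7L)
        f <- evs$dilution_factor[j]
        if (f < 1) y[idx] <- y[idx] * f
        sp <- match(evs$species[j], SPECIES)
        y[idx[sp]] <- y[idx[sp]] + evs$conc_nM[j]
      }
      if (any(times == t0)) out[times == t0, , ] <- y
    }
    want <- times[times > t0 & times <= t1]
    seg_times <- sort(unique(c(t0, want, t1)))
    if (length(seg_times) < 2L) seg_times <- c(t0, t1)
    # wells are independent, so the Jacobian is block diagonal (7x7 blocks):
    # a banded internally-generated Jacobian makes stiff segments cheap
    sol <- tryCatch(
      lsoda(y, seg_times, func = "fabind_derivs", parms = p,
            dllname = "fabind", initfunc = "fabind_init",
            rtol = rtol, atol = atol,
            jactype = "bandint", bandup = 6L, banddown = 6L),
      error = function(e) e, warning = function(w) w
    )
    if (inherits(sol, "condition")) {
      abort(paste0(
        "ODE integration failed (", conditionMessage(sol), ") for rates kon_L=",
        signif(params$kon_L, 3), ", koff_L=", signif(params$koff_L, 3),
        ", kon_C=", signif(params$kon_C, 3), ", koff_C=",
        signif(params$koff_C, 3), ", kon_NS=", signif(params$kon_NS, 3),
        ", koff_NS=", signif(params$koff_NS, 3)))
    }
    states <- sol[, -1, drop = FALSE]
    if (min(states) < -100 * atol) {
      abort(sprintf(
        "negative concentration (%.3g nM) beyond tolerance during integration.",
        min(states)))
    }
    states[states < 0] <- 0
    if (length(want)) {
      rows <- match(want, sol[, 1])
      out[match(want, times), , ] <- states[rows, , drop = FALSE]
    }
    y <- states[nrow(states), ]
  }
  out
}

#' Exact equilibrium of the coupled binding system
#'
#' Solves the mass-action equilibrium of the three binding reactions for
#' given total concentrations: the unique non-negative root of the coupled
#' mass-balance equations. Reduction to two unknowns (free probe and free
#' receptor) gives nested monotone one-dimensional problems which are
#' bracketed and then polished by Newton iteration to near machine
#' precision; each equilibrium relation's residual is below 1e-10 relative.
#'
#' @param params A [binding_parameters()] object (only the equilibrium
#'   constants `Kd_L`, `Ki_C` and `koff_NS/kon_NS` are used).
#' @param L_tot,R_tot,C_tot,NBV_tot Total concentrations, nM (>= 0).
#' @return A one-row tibble with species columns `R`, `L`, `C`, `NBV`,
#'   `RL`, `RC`, `NBVL` (nM).
#' @examples
#' p <- celt419_parameters()
#' equilibrium_state(p, L_tot = 0.5, R_tot = 0.7)
#' @export
equilibrium_state <- function(params, L_tot, R_tot, C_tot = 0, NBV_tot = 0) {
  stopifnot(inherits(params, "binding_parameters"))
  tot <- c(L_tot, R_tot, C_tot, NBV_tot)
  if (any(!is.finite(tot)) || any(tot < 0)) {
    abort("total concentrations must be finite and >= 0.")
  }
  Kd <- params$Kd_L
  Ki <- params$Ki_C
  Kns <- params$koff_NS / params$kon_NS

  # free-species mass balances, eliminating C and NBV analytically:
  #   RC  = C_tot * R / (Ki + R),  NBVL = NBV_tot * L / (Kns + L)
  gL <- function(L, R) L * (1 + R / Kd) + NBV_tot * L / (Kns + L) - L_tot
  gR <- function(R, L) R * (1 + L / Kd) + C_tot * R / (Ki + R) - R_tot

  solve_L <- function(R) {
    if (L_tot == 0) return(0)
    uniroot(gL, c(0, L_tot), R = R, tol = 1e-14 * max(L_tot, 1))$root
  }
  if (R_tot == 0) {
    R <- 0
    L <- solve_L(0)
  } else {
    outer_f <- function(R) gR(R, solve_L(R))
    R <- uniroot(outer_f, c(0, R_tot), tol = 1e-14 * max(R_tot, 1))$root
    L <- solve_L(R)
  }

  # Newton polish on (L, R) with analytic Jacobian
  for (it in 1:50) {
    f1 <- gL(L, R)
    f2 <- gR(R, L)
    if (abs(f1) < 1e-14 * max(L_tot, 1e-12) &&
        abs(f2) < 1e-14 * max(R_tot, 1e-12)) break
    j11 <- 1 + R / Kd + NBV_tot * Kns / (Kns + L)^2
    j12 <- L / Kd
    j21 <- R / Kd
    j22 <- 1 + L / Kd + C_tot * Ki / (Ki + R)^2
    det <- j11 * j22 - j12 * j21
    if (!is.finite(det) || abs(det) < 1e-300) break
    dL <- (f1 * j22 - f2 * j12) / det
    dR <- (j11 * f2 - j21 * f1) / det
    L <- min(max(L - dL, 0), L_tot)
    R <- min(max(R - dR, 0), R_tot)
  }

  # complexes via cancellation-free forms (RC = C_tot - C underflows when
  # the competitor is effectively inert)
  st <- tibble(
    R = R, L = L,
    C = C_tot * Ki / (Ki + R),
    NBV = NBV_tot * Kns / (Kns + L),
    RL = R * L / Kd,
    RC = C_tot * R / (Ki + R),
    NBVL = NBV_tot * L / (Kns + L)
  )
  res <- equilibrium_residuals(st, params, L_tot, R_tot, C_tot, NBV_tot)
  if (max(res) > 1e-10) {
    abort(sprintf(
      "equilibrium solver did not converge (max relative residual %.3g).",
      max(res)))
  }
  st
}

# relative residuals of the four mass balances and three equilibrium
# relations, each scaled by its largest participating term
equilibrium_residuals <- function(st, params, L_tot, R_tot, C_tot, NBV_tot) {
  rel <- function(resid, ...) {
    abs(resid) / max(abs(c(...)), 1e-300)
  }
  Kns <- params$koff_NS / params$kon_NS
  c(
    if (L_tot > 0) rel(st$L + st$RL + st$NBVL - L_tot,
                       st$L, st$RL, st$NBVL, L_tot) else 0,
    if (R_tot > 0) rel(st$R + st$RL + st$RC - R_tot,
                       st$R, st$RL, st$RC, R_tot) else 0,
    if (C_tot > 0) rel(st$C + st$RC - C_tot, st$C, st$RC, C_tot) else 0,
    if (NBV_tot > 0) rel(st$NBV + st$NBVL - NBV_tot,
                         st$NBV, st$NBVL, NBV_tot) else 0,
    if (R_tot > 0 && L_tot > 0)
      rel(st$RL * params$Kd_L - st$R * st$L,
          st$RL * params$Kd_L, st$R * st$L, 1e-30) else 0,
    if (R_tot > 0 && C_tot > 0)
      rel(st$RC * params$Ki_C - st$R * st$C,
          st$RC * params$Ki_C, st$R * st$C, 1e-30) else 0,
    if (NBV_tot > 0 && L_tot > 0)
      rel(st$NBVL * Kns - st$NBV * st$L,
          st$NBVL * Kns, st$NBV * st$L, 1e-30) else 0
  )
}
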