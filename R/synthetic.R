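#' Geometric serial dilution series
#'
#' @param start Starting concentration (or dilution factor), > 0.
#' @param factor Step factor in (0, 1).
#' @param n Number of points, >= 1.
#' @return Numeric vector `start * factor^(0:(n-1))`.
#' @examples
#' serial_dilution(4, 0.5, 3) # 4, 2, 1
#' @export
serial_dilution <- function(start, factor, n) {
  if (start <= 0) abort("`start` must be > 0.")
  if (factor <= 0 || factor >= 1) abort("`factor` must lie in (0, 1).")
  if (n < 1) abort("`n` must be >= 1.")
  start * factor^(0:(n - 1))
}

#' Experiment designs for the synthetic plate generator
#'
#' Constructors for the three emulated 384-well assay designs:
#'
#' * `saturation_kinetic_design()` — two probe concentrations (0.5 and
#'   3 nM), a two-fold receptor-particle (BBV) dilution series, a 90-minute
#'   association phase, then dissociation initiated in dedicated chase wells
#'   by excess unlabeled blocker; parallel association-control and
#'   blocked (nonspecific) wells; 5-minute sampling.
#' * `saturation_endpoint_design()` — the same layout read at a single
#'   endpoint time for equilibrium analysis, with a wider dilution range so
#'   the receptor becomes non-limiting.
#' * `competition_kinetic_design()` — constant probe and BBV, a competitor
#'   dilution series plus a competitor-free well, 5-minute sampling over
#'   5 hours.
#'
#' Every design carries matched blank wells (same BBV dilution, no probe)
#' for channel-wise blank correction.
#'
#' @param probe_nM Probe concentration(s), nM.
#' @param bbv_start_dilution,bbv_dilution_factor,n_dilutions BBV dilution
#'   series (start, step factor, count).
#' @param interval_s Sampling interval, s.
#' @param t_assoc_s Association phase length (chase time), s.
#' @param horizon_s Total measurement horizon, s.
#' @param chase_nM Blocker concentration initiating dissociation, nM.
#' @param block_nM Blocker concentration defining nonspecific wells, nM.
#' @param replicates Replicate wells per condition.
#' @param endpoint_s Endpoint read time, s.
#' @param bbv_dilution Single BBV dilution (competition design).
#' @param competitor_name Competitor label (competition design).
#' @param competitor_nM Competitor concentrations incl. 0 (competition design).
#' @return An object of class `fa_design`.
#' @name fa_designs
NULL

#' @rdname fa_designs
#' @export
saturation_kinetic_design <- function(probe_nM = c(0.5, 3),
                                      bbv_start_dilution = 0.2,
                                      bbv_dilution_factor = 0.5,
                                      n_dilutions = 6,
                                      interval_s = 300,
                                      t_assoc_s = 5400,
                                      horizon_s = 10800,
                                      chase_nM = 333000,
                                      block_nM = 50000,
                                      replicates = 1) {
  structure(list(
    kind = "saturation_kinetic", probe_nM = probe_nM,
    bbv_dilutions = serial_dilution(bbv_start_dilution, bbv_dilution_factor,
                                    n_dilutions),
    times = seq(0, horizon_s, by = interval_s),
    t_assoc_s = t_assoc_s, chase_nM = chase_nM, block_nM = block_nM,
    replicates = replicates, competitor_name = "blocker"
  ), class = "fa_design")
}

#' @rdname fa_designs
#' @export
saturation_endpoint_design <- function(probe_nM = c(0.5, 3),
                                       bbv_start_dilution = 0.25,
                                       bbv_dilution_factor = 0.5,
                                       n_dilutions = 8,
                                       endpoint_s = 7200,
                                       block_nM = 50000,
                                       replicates = 1) {
  structure(list(
    kind = "saturation_endpoint", probe_nM = probe_nM,
    bbv_dilutions = serial_dilution(bbv_start_dilution, bbv_dilution_factor,
                                    n_dilutions),
    times = endpoint_s, t_assoc_s = NA_real_, chase_nM = 0,
    block_nM = block_nM, replicates = replicates,
    competitor_name = "blocker"
  ), class = "fa_design")
}

#' @rdname fa_designs
#' @export
competition_kinetic_design <- function(competitor_name,
                                       competitor_nM = c(0, serial_dilution(1e4, 10^-0.5, 10)),
                                       probe_nM = 0.5,
                                       bbv_dilution = 1 / 30,
                                       interval_s = 300,
                                       horizon_s = 18000,
                                       replicates = 1) {
  structure(list(
    kind = "competition_kinetic", probe_nM = probe_nM,
    bbv_dilutions = bbv_dilution,
    competitor_name = competitor_name,
    competitor_nM = sort(unique(competitor_nM)),
    times = seq(0, horizon_s, by = interval_s),
    replicates = replicates
  ), class = "fa_design")
}

#' @export
print.fa_design <- function(x, ...) {
  cat(sprintf("<fa_design: %s>\n", x$kind))
  invisible(x)
}

#' Plate-reader noise and intensity model
#'
#' Multiplicative Gaussian per-channel intensity noise (plate readers show a
#' roughly constant coefficient of variation at assay intensities), a blank
#' intensity baseline per channel proportional to the BBV dilution
#' (autofluorescence / light-scattering surrogate), and the probe
#' brightness converting concentration into total intensity.
#'
#' @param channel_cv Relative per-channel intensity noise SD (default 1%).
#' @param brightness Total intensity per nM of probe, a.u.
#' @param blank_par,blank_perp Blank baseline per channel at dilution 1, a.u.
#' @param seed Integer RNG seed; generation is byte-identical given it.
#' @return An object of class `fa_noise_model`.
#' @export
noise_model <- function(channel_cv = 0.01, brightness = 1000,
                        blank_par = 150, blank_perp = 120, seed = 1L) {
  if (channel_cv < 0) abort("`channel_cv` must be >= 0.")
  if (brightness <= 0) abort("`brightness` must be > 0.")
  structure(list(channel_cv = channel_cv, brightness = brightness,
                 blank_par = blank_par, blank_perp = blank_perp,
                 seed = as.integer(seed)),
            class = "fa_noise_model")
}

add_channel_noise <- function(intensity, cv) {
  if (cv == 0) return(intensity)
  intensity * (1 + rnorm(length(intensity), sd = cv))
}

well_ids <- function(n) {
  if (n > 384) abort("design exceeds 384-well plate capacity.")
  grid <- expand.grid(col = 1:24, row = LETTERS[1:16])
  sprintf("%s%02d", grid$row[seq_len(n)], grid$col[seq_len(n)])
}

design_layout <- function(design) {
  d <- design
  if (d$kind %in% c("saturation_kinetic", "saturation_endpoint")) {
    combos <- expand.grid(probe_nM = d$probe_nM, bbv_dilution = d$bbv_dilutions,
                          rep = seq_len(d$replicates))
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      pr <- combos$probe_nM[i]
      dil <- combos$bbv_dilution[i]
      # kinetic design: one total well is chased (dissociation phase), a
      # second association-control well runs on to its equilibrium plateau —
      # the plateau levels across the dilution series are what make the
      # stock concentration identifiable
      base <- tibble(role = "total", probe_nM = pr,
                     competitor_name = "none", competitor_nM = 0,
                     bbv_dilution = dil, chase = FALSE)
      if (d$kind == "saturation_kinetic") {
        base <- dplyr::bind_rows(dplyr::mutate(base, chase = TRUE), base)
      }
      ns <- tibble(role = "nonspecific", probe_nM = pr,
                   competitor_name = d$competitor_name,
                   competitor_nM = d$block_nM,
                   bbv_dilution = dil, chase = FALSE)
      rows[[i]] <- dplyr::bind_rows(base, ns)
    }
    wells <- dplyr::bind_rows(rows)
    blanks <- tibble(role = "blank", probe_nM = 0, competitor_name = "none",
                     competitor_nM = 0, bbv_dilution = d$bbv_dilutions,
                     chase = FALSE)
  } else {
    combos <- expand.grid(competitor_nM = d$competitor_nM,
                          rep = seq_len(d$replicates))
    wells <- tibble(
      role = ifelse(combos$competitor_nM == 0, "total", "total"),
      probe_nM = d$probe_nM[1],
      competitor_name = ifelse(combos$competitor_nM == 0, "none",
                               d$competitor_name),
      competitor_nM = combos$competitor_nM,
      bbv_dilution = d$bbv_dilutions[1], chase = FALSE)
    blanks <- tibble(role = "blank", probe_nM = 0, competitor_name = "none",
                     competitor_nM = 0, bbv_dilution = d$bbv_dilutions[1],
                     chase = FALSE)
  }
  layout <- dplyr::bind_rows(wells, blanks)
  layout <- dplyr::arrange(layout, dplyr::desc(.data$bbv_dilution),
                           .data$role != "blank")
  # blanks sorted adjacent to their dilution group; row-major fill
  layout$well <- well_ids(nrow(layout))
  layout
}

#' Generate a complete synthetic plate experiment
#'
#' Builds the well layout of a design, simulates every measurement well
#' with the full ODE binding model, converts the predicted anisotropy into
#' parallel/perpendicular intensities (total intensity = brightness x probe
#' concentration), adds the dilution-proportional blank baseline and
#' multiplicative channel noise, and emits the raw long-format plate table
#' plus well map, addition events and the ground truth — the same formats
#' the analysis side reads, so the whole pipeline can be exercised without
#' real data.
#'
#' @param design An [fa_designs] object.
#' @param params Ground-truth [binding_parameters()].
#' @param noise An [noise_model()].
#' @return An object of class `fa_experiment`: list with `plate`,
#'   `well_map`, `events`, `truth` (params), `design`, `noise`.
#' @export
generate_experiment <- function(design, params = celt419_parameters(),
                                noise = noise_model()) {
  stopifnot(inherits(design, "fa_design"),
            inherits(params, "binding_parameters"),
            inherits(noise, "fa_noise_model"))
  layout <- design_layout(design)
  times <- design$times

  events <- layout[layout$chase, c("well", "bbv_dilution")]
  events <- if (nrow(events)) {
    tibble(well = events$well, time_s = design$t_assoc_s, species = "C",
           conc_nM = design$chase_nM, dilution_factor = 1)
  } else {
    tibble(well = character(), time_s = numeric(), species = character(),
           conc_nM = numeric(), dilution_factor = numeric())
  }

  meas <- layout[layout$role != "blank", ]
  fa <- matrix(NA_real_, nrow = length(times), ncol = nrow(meas))
  key <- paste(meas$chase, meas$competitor_nM > 0)
  for (k in unique(key)) {
    idx <- which(key == k)
    init <- rbind(
      R = meas$bbv_dilution[idx] * params$R_stock,
      L = meas$probe_nM[idx],
      C = meas$competitor_nM[idx],
      NBV = meas$bbv_dilution[idx] * params$NBV_stock,
      RL = 0, RC = 0, NBVL = 0
    )
    ev <- events[events$well %in% meas$well[idx], ]
    ev$widx <- match(ev$well, meas$well[idx])
    block <- sim_block(params, init, ev, times)
    fa[, idx] <- fa_from_block(block, params)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(noise$seed)

  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    if (w$role == "blank") {
      ip <- rep(0, length(times))
      is <- rep(0, length(times))
    } else {
      j <- match(w$well, meas$well)
      ch <- polarized_intensities(fa[, j], noise$brightness * w$probe_nM)
      ip <- ch$I_par
      is <- ch$I_perp
    }
    ip <- add_channel_noise(ip + noise$blank_par * w$bbv_dilution,
                            noise$channel_cv)
    is <- add_channel_noise(is + noise$blank_perp * w$bbv_dilution,
                            noise$channel_cv)
    rows[[i]] <- tibble(
      well = w$well, time_s = rep(times, 2),
      channel = rep(c("par", "perp"), each = length(times)),
      intensity = c(ip, is))
  }
  plate <- dplyr::bind_rows(rows)
  well_map <- layout[, c("well", "role", "probe_nM", "competitor_name",
                         "competitor_nM", "bbv_dilution")]
  structure(list(plate = plate, well_map = well_map, events = events,
                 truth = params, design = design, noise = noise),
            class = "fa_experiment")
}

#' @export
print.fa_experiment <- function(x, ...) {
  cat(sprintf("<fa_experiment: %s, %d wells, %d time points, seed %d>\n",
              x$design$kind, nrow(x$well_map),
              length(unique(x$plate$time_s)), x$noise$seed))
  invisible(x)
}

#' Anisotropy traces of a synthetic experiment
#'
#' Blank-corrects the raw plate table of an experiment and computes
#' per-well anisotropy traces (the same path real data takes).
#'
#' @param experiment An `fa_experiment`.
#' @return A tibble of traces, see [fa_traces()].
#' @export
experiment_traces <- function(experiment) {
  stopifnot(inherits(experiment, "fa_experiment"))
  fa_traces(experiment$plate, experiment$well_map)
}

#' Kinetic dataset of a synthetic experiment
#'
#' @param experiment An `fa_experiment`.
#' @return A [kinetic_dataset()] including the experiment's addition events.
#' @export
experiment_dataset <- function(experiment) {
  kinetic_dataset(experiment_traces(experiment), experiment$events)
}

#' Generate positive/negative control replicates for Z' scoring
#'
#' Gaussian anisotropy replicates at the negative-control mean and at
#' `mu_neg + delta_fa` (the assay signal window between total and
#' nonspecific binding).
#'
#' @param n_pos,n_neg Replicates per control (>= 2).
#' @param delta_fa Signal window, FA units (default 0.12).
#' @param control_sd Per-control SD, FA units.
#' @param mu_neg Negative-control mean, FA units.
#' @param seed RNG seed.
#' @return A tibble with columns `role` (`"positive"`/`"negative"`), `fa`.
#' @export
generate_controls_plate <- function(n_pos, n_neg, delta_fa = 0.12,
                                    control_sd = 0.0058, mu_neg = 0.08,
                                    seed = 1L) {
  if (n_pos < 2L || n_neg < 2L) abort("need >= 2 replicates per control.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  tibble(
    role = rep(c("positive", "negative"), c(n_pos, n_neg)),
    fa = c(rnorm(n_pos, mu_neg + delta_fa, control_sd),
           rnorm(n_neg, mu_neg, control_sd))
  )
}
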