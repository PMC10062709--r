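#' Run a reproducible analysis pipeline step
#'
#' Thin orchestration layer tying the package stages into config-driven
#' runs: each call executes one subcommand on CSV/YAML inputs and writes
#' its results (JSON + CSV tables) and a run log (package version, seed,
#' config hash, every fixed and fitted parameter) into an output directory.
#' An executable wrapper for shell use ships in `inst/cli/fabind.R`.
#'
#' Subcommands and their config fields:
#' * `simulate` — `design` (list: `kind` plus the matching
#'   [fa_designs] arguments), optional `params` (overrides of
#'   [celt419_parameters()]), optional `noise` ([noise_model()] arguments);
#'   writes `plate.csv`, `well_map.csv`, `events.csv`, `truth.json`.
#' * `fit-kinetic` — `plate`, `well_map`, optional `events` (paths),
#'   optional `free`, optional `fit` ([fit_config()] overrides); writes
#'   `global_fit.json`, `residuals.csv`.
#' * `fit-saturation` — `plate`, `well_map`, `endpoint_s`; writes
#'   `saturation_fit.json`.
#' * `fit-competition` — `plate`, `well_map`, `endpoint_s`, `kd_nM`,
#'   `receptor_nM`; writes `competition_fit.json` (sigmoid estimates plus
#'   the depletion-corrected Ki).
#' * `ic50-timecourse` — `plate`, `well_map`; writes `ic50_timecourse.csv`,
#'   `ic50_decay.json`.
#' * `zprime` — `controls` (CSV with columns `role`, `fa`); writes
#'   `zprime.json`.
#'
#' @param config A named list, or path to a YAML file holding one, with at
#'   least `subcommand` and `seed`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the result objects; artifacts on disk.
#' @export
run_fa_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$subcommand)) abort("config needs a `subcommand` field.")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("fabind %s", as.character(utils::packageVersion("fabind"))),
    sprintf("subcommand: %s", config$subcommand),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", rlang::hash(config)),
    sprintf("config: %s", jsonlite::toJSON(config, auto_unbox = TRUE))
  )
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res <- switch(
    config$subcommand,
    "simulate" = {
      dcfg <- config$design %||% list(kind = "saturation_kinetic")
      ctor <- switch(dcfg$kind,
                     saturation_kinetic = saturation_kinetic_design,
                     saturation_endpoint = saturation_endpoint_design,
                     competition_kinetic = competition_kinetic_design,
                     abort(paste0("unknown design kind: ", dcfg$kind)))
      design <- do.call(ctor, dcfg[setdiff(names(dcfg), "kind")])
      params <- do.call(update_parameters,
                        c(list(celt419_parameters()),
                          config$params %||% list()))
      noise <- do.call(noise_model,
                       modifyList(config$noise %||% list(),
                                  list(seed = seed)))
      expt <- generate_experiment(design, params, noise)
      write_plate_csv(expt$plate, file.path(out_dir, "plate.csv"))
      write_well_map(expt$well_map, file.path(out_dir, "well_map.csv"))
      readr::write_csv(expt$events, file.path(out_dir, "events.csv"),
                       progress = FALSE)
      wj(unclass(params), "truth.json")
      expt
    },
    "fit-kinetic" = {
      plate <- read_plate_csv(config$plate)
      wm <- read_well_map(config$well_map)
      ev <- if (!is.null(config$events) && file.exists(config$events)) {
        readr::read_csv(config$events, show_col_types = FALSE)
      } else {
        NULL
      }
      ds <- kinetic_dataset(fa_traces(plate, wm), ev)
      cfg <- do.call(fit_config, modifyList(config$fit %||% list(),
                                            list(seed = seed)))
      fit <- if (is.null(config$free)) {
        fit_global(ds, cfg)
      } else {
        fit_global(ds, cfg, free = unlist(config$free))
      }
      readr::write_csv(fit$residuals, file.path(out_dir, "residuals.csv"),
                       progress = FALSE)
      wj(list(estimates = fit$estimates, final_loss = fit$final_loss,
              seed = fit$seed, n_evals = fit$n_evals), "global_fit.json")
      fit
    },
    "fit-saturation" = {
      plate <- read_plate_csv(config$plate)
      wm <- read_well_map(config$well_map)
      tr <- fa_traces(plate, wm)
      endpoint <- config$endpoint_s %||% max(tr$time_s)
      ds <- tr[tr$time_s == endpoint & tr$role %in% c("total", "nonspecific"), ]
      ds$condition <- ds$role
      fit <- fit_saturation(ds)
      wj(list(estimates = fit$estimates, residual_sd = fit$residual_sd,
              endpoint_s = endpoint), "saturation_fit.json")
      fit
    },
    "fit-competition" = {
      plate <- read_plate_csv(config$plate)
      wm <- read_well_map(config$well_map)
      tr <- fa_traces(plate, wm)
      endpoint <- config$endpoint_s %||% 10800
      sub <- tr[tr$time_s == endpoint, ]
      fit <- fit_sigmoid(tibble(conc = sub$competitor_nM, response = sub$fa))
      ki <- ki_from_ic50_depletion(
        sigmoid_coef(fit, "log_ic50"),
        Kd_L = config$kd_nM, probe_nM = sub$probe_nM[1],
        receptor_nM = config$receptor_nM)
      wj(list(estimates = fit$estimates, ki_nM = ki,
              endpoint_s = endpoint), "competition_fit.json")
      list(sigmoid = fit, ki_nM = ki)
    },
    "ic50-timecourse" = {
      plate <- read_plate_csv(config$plate)
      wm <- read_well_map(config$well_map)
      tc <- observed_ic50_timecourse(fa_traces(plate, wm))
      readr::write_csv(tc, file.path(out_dir, "ic50_timecourse.csv"),
                       progress = FALSE)
      decay <- tryCatch(fit_ic50_decay(tc), error = function(e) NULL)
      if (!is.null(decay)) wj(list(estimates = decay$estimates),
                              "ic50_decay.json")
      list(timecourse = tc, decay = decay)
    },
    "zprime" = {
      ctrl <- readr::read_csv(config$controls, show_col_types = FALSE)
      z <- z_prime(ctrl$fa[ctrl$role == "positive"],
                   ctrl$fa[ctrl$role == "negative"])
      wj(unclass(z), "zprime.json")
      z
    },
    abort(paste0("unknown subcommand: ", config$subcommand))
  )
  writeLines(log_lines, log_path)
  invisible(res)
}
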