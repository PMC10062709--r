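#' Fluorescence anisotropy from polarized intensities
#'
#' \deqn{FA = (I_{\parallel} - I_{\perp}) / (I_{\parallel} + 2 I_{\perp})}
#' The mathematical range is (-0.5, 1]. Values outside a plausibility window
#' (default (-0.2, 0.5)) trigger a warning — after blank correction such
#' values usually indicate a blanking or mixing problem — but are never
#' altered. Channels are assumed pre-calibrated (no G-factor).
#'
#' @param I_par,I_perp Parallel and perpendicular intensities (vectors,
#'   arbitrary units).
#' @param warn_range Length-2 numeric plausibility window for warnings.
#' @param strict If `TRUE` (default), a zero total intensity
#'   (`I_par + 2*I_perp == 0`) is an error; if `FALSE` it yields `NA` with a
#'   warning.
#' @return Numeric vector of anisotropies.
#' @examples
#' anisotropy(100, 100)      # isotropic -> 0
#' anisotropy(150, 100)      # 50/350
#' @export
anisotropy <- function(I_par, I_perp, warn_range = c(-0.2, 0.5),
                       strict = TRUE) {
  if (any(!is.finite(I_par)) || any(!is.finite(I_perp))) {
    abort("intensities must be finite.")
  }
  tot <- I_par + 2 * I_perp
  zero <- tot == 0
  if (any(zero)) {
    if (strict) {
      abort(sprintf(
        "undefined anisotropy: total intensity I_par + 2*I_perp is zero at %d point(s).",
        sum(zero)))
    }
    warn(sprintf("anisotropy undefined (zero total intensity) at %d point(s); NA returned.",
                 sum(zero)))
  }
  fa <- (I_par - I_perp) / tot
  fa[zero] <- NA_real_
  out <- fa[!is.na(fa)]
  if (length(out) && (any(out <= warn_range[1]) || any(out >= warn_range[2]))) {
    warn(sprintf(
      "%d anisotropy value(s) outside the plausibility window (%g, %g).",
      sum(out <= warn_range[1] | out >= warn_range[2]),
      warn_range[1], warn_range[2]))
  }
  fa
}

#' Polarized intensities from anisotropy (inverse transform)
#'
#' Splits a total intensity `I_total = I_par + 2*I_perp` into channel
#' intensities reproducing a given anisotropy:
#' `I_par = I_total*(1 + 2*FA)/3`, `I_perp = I_total*(1 - FA)/3`.
#' Round-trips through [anisotropy()] to floating precision.
#'
#' @param fa Anisotropy values in (-0.5, 1].
#' @param I_total Total intensity `I_par + 2*I_perp` (>= 0).
#' @return A tibble with columns `I_par`, `I_perp`.
#' @examples
#' polarized_intensities(0, 300)   # (100, 100)
#' @export
polarized_intensities <- function(fa, I_total) {
  if (any(!is.finite(fa)) || any(fa <= -0.5) || any(fa > 1)) {
    abort("`fa` must lie in (-0.5, 1].")
  }
  if (any(I_total < 0)) abort("`I_total` must be >= 0.")
  tibble(I_par = I_total * (1 + 2 * fa) / 3,
         I_perp = I_total * (1 - fa) / 3)
}

#' Predicted anisotropy from binding-state concentrations
#'
#' The observable anisotropy is the concentration-weighted mean of the
#' intrinsic anisotropies of the probe's binding states (free,
#' receptor-bound, non-specifically bound):
#' \deqn{FA = (L\,FA_{free} + RL\,FA_{bound} + NBVL\,FA_{ns}) / (L + RL + NBVL)}
#' A convex combination: the result never leaves the range spanned by the
#' intrinsic values.
#'
#' @param state A data frame with columns `L`, `RL`, `NBVL` (nM); rows are
#'   time points or wells (e.g. output of [simulate_system()] or
#'   [equilibrium_state()]).
#' @param params A [binding_parameters()] object supplying `FA_free`,
#'   `FA_bound`, `FA_ns`.
#' @return Numeric vector of anisotropies, one per row of `state`.
#' @export
anisotropy_from_states <- function(state, params) {
  stopifnot(inherits(params, "binding_parameters"))
  tot <- state$L + state$RL + state$NBVL
  if (any(tot <= 0)) {
    abort("total probe concentration is zero; anisotropy undefined.")
  }
  (state$L * params$FA_free + state$RL * params$FA_bound +
     state$NBVL * params$FA_ns) / tot
}

# fast path used inside fitting loops: columns of sim_block output
fa_from_block <- function(block, params) {
  # block: [time, species, well]; species order SPECIES
  L <- block[, 2, , drop = FALSE]
  RL <- block[, 5, , drop = FALSE]
  NBVL <- block[, 7, , drop = FALSE]
  num <- L * params$FA_free + RL * params$FA_bound + NBVL * params$FA_ns
  den <- L + RL + NBVL
  matrix(num / den, nrow = dim(block)[1])
}

#' Channel-wise blank correction of a plate table
#'
#' Subtracts, channel by channel and time by time, the intensity of a blank
#' well containing the same receptor-particle dilution (and nothing else)
#' from each measurement well, before any anisotropy is computed. This
#' removes particle autofluorescence and light scattering. When several
#' blanks share a dilution their mean trace is used.
#'
#' @param plate A long plate table: columns `well`, `time_s`, `channel`
#'   (`"par"`/`"perp"`), `intensity`.
#' @param well_map Well metadata: columns `well`, `role` (`"total"`,
#'   `"nonspecific"`, `"blank"`, `"free-ligand"`), `probe_nM`,
#'   `competitor_name`, `competitor_nM`, `bbv_dilution`.
#' @return The corrected plate table (blank wells removed), with a
#'   `blank_wells` column recording the blank(s) used for each well.
#' @export
blank_correct <- function(plate, well_map) {
  check_plate(plate)
  check_well_map(well_map)
  blanks <- well_map[well_map$role == "blank", ]
  meas <- well_map[well_map$role != "blank", ]
  unmatched <- meas$well[!meas$bbv_dilution %in% blanks$bbv_dilution]
  if (length(unmatched)) {
    abort(paste0("no matched blank (same bbv_dilution) for well(s): ",
                 paste(unmatched, collapse = ", ")))
  }
  blank_label <- vapply(
    split(blanks$well, blanks$bbv_dilution),
    paste, character(1), collapse = "+"
  )
  blank_tr <- plate |>
    dplyr::inner_join(blanks[, c("well", "bbv_dilution")], by = "well") |>
    dplyr::group_by(.data$bbv_dilution, .data$time_s, .data$channel) |>
    dplyr::summarise(blank_intensity = mean(.data$intensity), .groups = "drop")
  out <- plate |>
    dplyr::inner_join(meas[, c("well", "bbv_dilution")], by = "well") |>
    dplyr::left_join(blank_tr, by = c("bbv_dilution", "time_s", "channel"))
  if (anyNA(out$blank_intensity)) {
    bad <- unique(out$well[is.na(out$blank_intensity)])
    abort(paste0("blank trace missing time/channel coverage for well(s): ",
                 paste(bad, collapse = ", ")))
  }
  out$intensity <- out$intensity - out$blank_intensity
  out$blank_wells <- blank_label[as.character(out$bbv_dilution)]
  out[, c("well", "time_s", "channel", "intensity", "blank_wells")]
}

check_plate <- function(plate) {
  need <- c("well", "time_s", "channel", "intensity")
  if (!all(need %in% names(plate))) {
    abort("plate table needs columns well, time_s, channel, intensity.")
  }
  if (any(!plate$channel %in% c("par", "perp"))) {
    abort("plate channel must be 'par' or 'perp'.")
  }
  invisible(plate)
}

check_well_map <- function(well_map) {
  need <- c("well", "role", "probe_nM", "competitor_name", "competitor_nM",
            "bbv_dilution")
  if (!all(need %in% names(well_map))) {
    abort(paste0("well map needs columns ", paste(need, collapse = ", "), "."))
  }
  ok <- c("total", "nonspecific", "blank", "free-ligand")
  if (any(!well_map$role %in% ok)) {
    abort(paste0("well roles must be one of ", paste(ok, collapse = ", "), "."))
  }
  invisible(well_map)
}

#' Anisotropy traces from a raw plate table
#'
#' Convenience pipeline: blank-correct the raw polarized intensities, pivot
#' channels wide, compute anisotropy per well and time, and attach well
#' metadata.
#'
#' @inheritParams blank_correct
#' @param strict Passed to [anisotropy()].
#' @return A tibble with columns `well`, `time_s`, `fa`, plus the well-map
#'   metadata columns.
#' @export
fa_traces <- function(plate, well_map, strict = TRUE) {
  corr <- blank_correct(plate, well_map)
  wide <- tidyr::pivot_wider(corr[, c("well", "time_s", "channel", "intensity")],
                             names_from = "channel", values_from = "intensity")
  wide$fa <- anisotropy(wide$par, wide$perp, strict = strict)
  dplyr::left_join(
    wide[, c("well", "time_s", "fa")],
    well_map[well_map$role != "blank", ],
    by = "well"
  ) |> dplyr::arrange(.data$well, .data$time_s)
}
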