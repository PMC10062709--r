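#' Assay protocol for a single well
#'
#' Describes what is in a well at reaction start, which timed reagent
#' additions occur, and when the plate reader samples it. Time zero is the
#' initiation of binding (addition of the receptor preparation, which is
#' always pipetted last); the receptor and non-specific site totals are
#' derived from the stock concentrations in [binding_parameters()] scaled by
#' `bbv_dilution`.
#'
#' Additions are modelled as instantaneous concentration steps. An event may
#' carry a volume-dilution factor `f` in (0, 1]: all concentrations in the
#' well are first rescaled by `f`, then the named species is incremented by
#' `conc_nM` (a final-concentration increment). The default `f = 1` ignores
#' the added volume, appropriate when addition volumes are negligible or
#' unrecorded.
#'
#' @param probe_nM Total fluorescent probe concentration at t = 0, nM.
#' @param competitor_nM Total unlabeled competitor at t = 0, nM.
#' @param bbv_dilution Dilution factor in (0, 1] applied to `R_stock` and
#'   `NBV_stock` for this well; 0 is allowed for receptor-free wells.
#' @param events A data frame with columns `time_s`, `species` (one of
#'   `"R"`, `"L"`, `"C"`, `"NBV"`), `conc_nM` (increment, nM) and optionally
#'   `dilution_factor`; or `NULL` for none.
#' @param times Measurement time grid in seconds (non-negative, strictly
#'   increasing).
#'
#' @return An object of class `assay_protocol`.
#' @examples
#' # 90-min association, then dissociation initiated by excess competitor
#' pro <- assay_protocol(
#'   probe_nM = 0.5, bbv_dilution = 0.035,
#'   events = data.frame(time_s = 5400, species = "C", conc_nM = 333000),
#'   times = seq(0, 14400, by = 300)
#' )
#' @export
assay_protocol <- function(probe_nM, competitor_nM = 0, bbv_dilution = 0,
                           events = NULL, times) {
  if (!is.numeric(probe_nM) || probe_nM < 0) abort("`probe_nM` must be >= 0.")
  if (!is.numeric(competitor_nM) || competitor_nM < 0) {
    abort("`competitor_nM` must be >= 0.")
  }
  if (!is.numeric(bbv_dilution) || bbv_dilution < 0 || bbv_dilution > 1) {
    abort("`bbv_dilution` must lie in [0, 1].")
  }
  if (!is.numeric(times) || length(times) < 1L || any(times < 0) ||
      is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be non-negative and strictly increasing.")
  }
  events <- normalize_events(events, horizon = max(times))
  structure(
    list(probe_nM = probe_nM, competitor_nM = competitor_nM,
         bbv_dilution = bbv_dilution, events = events, times = as.numeric(times)),
    class = "assay_protocol"
  )
}

normalize_events <- function(events, horizon) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0L)) {
    return(tibble(time_s = numeric(), species = character(),
                  conc_nM = numeric(), dilution_factor = numeric()))
  }
  events <- as_tibble(events)
  need <- c("time_s", "species", "conc_nM")
  if (!all(need %in% names(events))) {
    abort("`events` needs columns time_s, species, conc_nM.")
  }
  if (!"dilution_factor" %in% names(events)) events$dilution_factor <- 1
  events$dilution_factor[is.na(events$dilution_factor)] <- 1
  if (any(!events$species %in% c("R", "L", "C", "NBV"))) {
    abort("event species must be one of R, L, C, NBV.")
  }
  if (is.unsorted(events$time_s, strictly = TRUE) && nrow(events) > 1L &&
      anyDuplicated(events$time_s) == 0L) {
    abort("event times must be increasing.")
  }
  if (any(events$time_s <= 0) || any(events$time_s >= horizon)) {
    abort("event times must lie strictly inside (0, max(times)).")
  }
  if (any(events$conc_nM < 0)) abort("event increments must be >= 0.")
  if (any(events$dilution_factor <= 0 | events$dilution_factor > 1)) {
    abort("event dilution factors must lie in (0, 1].")
  }
  events[order(events$time_s), c("time_s", "species", "conc_nM",
                                 "dilution_factor")]
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat("<assay_protocol>\n")
  cat(sprintf("  probe %.4g nM, competitor %.4g nM, BBV dilution %.4g\n",
              x$probe_nM, x$competitor_nM, x$bbv_dilution))
  cat(sprintf("  %d measurement times over [%g, %g] s, %d addition event(s)\n",
              length(x$times), min(x$times), max(x$times), nrow(x$events)))
  invisible(x)
}
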