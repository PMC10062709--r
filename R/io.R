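#' Read and write plate tables and well maps
#'
#' Long-format plate CSV (columns `well`, `time_s`, `channel`, `intensity`)
#' and well-map CSV (columns `well`, `role`, `probe_nM`, `competitor_name`,
#' `competitor_nM`, `bbv_dilution`). One canonical dialect: UTF-8, comma
#' separator, `.` decimal, header row. Doubles are written with
#' shortest-round-trip precision, so a write/read cycle is bit-exact.
#'
#' @param path File path.
#' @return `read_plate_csv()` and `read_well_map()` return tibbles;
#'   the writers return their input invisibly.
#' @name plate_io
NULL

#' @rdname plate_io
#' @export
read_plate_csv <- function(path) {
  plate <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # base-R numeric parsing is correctly rounded, keeping round trips exact
  plate$time_s <- as.numeric(plate$time_s)
  plate$intensity <- as.numeric(plate$intensity)
  check_plate(plate)
  plate
}

# serialize doubles at full binary precision so read(write(x)) is bit-exact
format_full <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df
}

#' @rdname plate_io
#' @param plate A plate table.
#' @export
write_plate_csv <- function(plate, path) {
  check_plate(plate)
  readr::write_csv(format_full(plate), path, progress = FALSE)
  invisible(plate)
}

#' @rdname plate_io
#' @export
read_well_map <- function(path) {
  wm <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in c("probe_nM", "competitor_nM", "bbv_dilution")) {
    wm[[col]] <- as.numeric(wm[[col]])
  }
  check_well_map(wm)
  wm
}

#' @rdname plate_io
#' @param well_map A well-map table.
#' @export
write_well_map <- function(well_map, path) {
  check_well_map(well_map)
  readr::write_csv(format_full(well_map), path, progress = FALSE)
  invisible(well_map)
}
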