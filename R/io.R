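#' Read and write the package's CSV dialects
#'
#' Three plain CSV formats (header row, UTF-8, "." decimal separator) carry
#' data between pipeline stages:
#' \describe{
#'   \item{trace}{`time_s`, `chamber_id`, `o2_mg_per_l`, `o2_sat_pct`,
#'     `temp_c`, `phase` (flush/wait/measure), `cycle_index`.}
#'   \item{mo2}{`fish_id`, `time_min`, `mo2`, `qc_pass`, `r2`,
#'     `end_sat_pct`.}
#'   \item{activity}{`day`, `bin_start_hhmm` (e.g. "0830"), `counts`.}
#' }
#' Readers validate mandatory columns (errors name the missing column),
#' check time monotonicity, report malformed rows with their line numbers,
#' and preserve extra columns untouched; `write_*()` then `read_*()` is the
#' identity on the canonical columns.
#'
#' @param path File path.
#' @param trace,mo2,activity Tibbles in the corresponding dialect.
#'
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name respirhythm-io
NULL

read_checked <- function(path, required, numeric_cols) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(paste0("File '", path, "' is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  for (col in intersect(numeric_cols, names(d))) {
    vals <- d[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(vals))))
    if (length(bad)) {
      abort(paste0("Malformed '", col, "' values in '", path, "' at line(s) ",
                   paste(utils::head(bad + 1L, 5), collapse = ", "),
                   " (header is line 1)."))
    }
    d[[col]] <- as.numeric(vals)
  }
  d
}

#' @rdname respirhythm-io
#' @export
read_trace <- function(path) {
  d <- read_checked(path,
                    c("time_s", "o2_mg_per_l", "phase", "cycle_index"),
                    c("time_s", "o2_mg_per_l", "o2_sat_pct", "temp_c"))
  if (is.unsorted(d$time_s, strictly = TRUE)) {
    abort(paste0("Non-monotonic `time_s` in '", path, "'."))
  }
  bad_phase <- which(!d$phase %in% c("flush", "wait", "measure"))
  if (length(bad_phase)) {
    abort(paste0("Invalid `phase` values in '", path, "' at line(s) ",
                 paste(utils::head(bad_phase + 1L, 5), collapse = ", "), "."))
  }
  d
}

#' @rdname respirhythm-io
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname respirhythm-io
#' @export
read_mo2 <- function(path) {
  d <- read_checked(path, c("fish_id", "time_min", "mo2"),
                    c("time_min", "mo2", "r2", "end_sat_pct"))
  if ("qc_pass" %in% names(d)) d$qc_pass <- as.logical(d$qc_pass)
  d
}

#' @rdname respirhythm-io
#' @export
write_mo2 <- function(mo2, path) {
  readr::write_csv(mo2, path)
  invisible(path)
}

#' @rdname respirhythm-io
#' @export
read_activity <- function(path) {
  d <- read_checked(path, c("day", "bin_start_hhmm", "counts"), c("counts"))
  hhmm <- sprintf("%04d", as.integer(d$bin_start_hhmm))
  hh <- as.integer(substr(hhmm, 1, 2))
  mm <- as.integer(substr(hhmm, 3, 4))
  bad <- which(is.na(hh) | hh > 23 | mm > 59)
  if (length(bad)) {
    abort(paste0("Malformed `bin_start_hhmm` in '", path, "' at line(s) ",
                 paste(utils::head(bad + 1L, 5), collapse = ", "), "."))
  }
  d$clock_h <- hh + mm / 60
  first_clock <- d$clock_h[1]
  d$time_h <- (d$day - min(d$day)) * 24 + (d$clock_h - first_clock) %% 24
  d
}

#' @rdname respirhythm-io
#' @export
write_activity <- function(activity, path) {
  out <- tibble::tibble(
    day = activity$day,
    bin_start_hhmm = sprintf("%02d%02d",
                             floor(activity$clock_h),
                             round(60 * (activity$clock_h %% 1))),
    counts = activity$counts)
  extra <- setdiff(names(activity), c("day", "clock_h", "time_h", "counts"))
  for (col in extra) out[[col]] <- activity[[col]]
  readr::write_csv(out, path)
  invisible(path)
}

#' Zeitgeber-time converters
#'
#' Clock time and Zeitgeber time (ZT) interconvert given the lights-on hour
#' (ZT0); the study photoperiod anchors ZT0 at 08:00.
#'
#' @param clock_h Clock hours since midnight.
#' @param zt_h Zeitgeber hours.
#' @param lights_on_h Clock hour of lights-on (default 8).
#'
#' @return Numeric hours in `[0, 24)`.
#' @export
#' @examples
#' clock_to_zt(13.2)  # 5.2 h after lights-on
clock_to_zt <- function(clock_h, lights_on_h = 8) {
  (clock_h - lights_on_h) %% 24
}

#' @rdname clock_to_zt
#' @export
zt_to_clock <- function(zt_h, lights_on_h = 8) {
  (zt_h + lights_on_h) %% 24
}
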