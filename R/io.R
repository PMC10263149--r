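# CSV round-trip helpers for the pipeline's tabular interchange formats.
# All tables are written in plain CSV with full double precision; unknown
# columns survive a round trip, and missing required columns raise a
# schema error naming the column.

write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path, required, what) {
  df <- read.csv(path, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write pipeline tables
#'
#' Track tables hold per-frame linked detections (\code{track_id, frame,
#' t_s, x_px, y_px, area_px, ellipse_major_px, ellipse_minor_px,
#' ellipse_angle_deg, kalman_vx, kalman_vy}); flight tables hold one row
#' per flight with its kinematic summary; choice tables hold per-day
#' counts (\code{day, n_total, n_upwind, n_right}). Values round-trip
#' losslessly to well below 1e-9 and unrecognised columns are preserved.
#'
#' @param df the table to write.
#' @param path CSV file path.
#' @return readers return a data.frame (choice tables with derived
#'   proportions recomputed); writers return the path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_track_table <- function(df, path) write_table_csv(df, path)

#' @rdname table_io
#' @export
read_track_table <- function(path) {
  read_table_csv(path, c("track_id", "frame", "x_px", "y_px"), "track table")
}

#' @rdname table_io
#' @export
write_flight_table <- function(df, path) write_table_csv(df, path)

#' @rdname table_io
#' @export
read_flight_table <- function(path) {
  read_table_csv(path, c("flight_id", "direction", "u_mps", "mean_vg",
                         "sinuosity"), "flight table")
}

#' @rdname table_io
#' @export
write_choice_table <- function(df, path) {
  keep <- setdiff(names(df), c("p_upwind_day", "p_right_day"))
  write_table_csv(as.data.frame(df)[, keep, drop = FALSE], path)
}

#' @rdname table_io
#' @export
read_choice_table <- function(path) {
  df <- read_table_csv(path, c("day", "n_total", "n_upwind", "n_right"),
                       "choice table")
  as_choice_table(df)
}
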