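# Plain-text serialization of the pipeline's tables.

#' Write / read an uptake curve as CSV
#'
#' Columns `rigidity_kpa`, `value`, `value_kind`, `radius_um`.
#'
#' @param curve An `uptake_curve` data.frame.
#' @param path CSV file path.
#' @return `write_uptake_curve` returns `path` invisibly; `read_uptake_curve`
#'   returns an `uptake_curve`.
#' @export
write_uptake_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uptake_curve
#' @export
read_uptake_curve <- function(path) {
  df <- utils::read.csv(path)
  need <- c("rigidity_kpa", "value", "value_kind", "radius_um")
  if (!all(need %in% names(df)))
    stop("uptake-curve CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(df, class = c("uptake_curve", "data.frame"))
}

#' Write / read an event table as CSV
#'
#' @param events Event-table data.frame.
#' @param path CSV file path.
#' @return `write_event_table` returns `path` invisibly; `read_event_table`
#'   returns the data.frame.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("focus_rms", "aspect_ratio", "area_px", "bead_count",
            "rigidity_kpa")
  if (!all(need %in% names(df)))
    stop("event CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a compression record as CSV
#'
#' Columns `displacement_um`, `force_un`, `side_pre_um`; readable with
#' [read_compression_csv()].
#'
#' @param rec A [compression_record()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_compression_csv <- function(rec, path) {
  utils::write.csv(data.frame(displacement_um = rec$displacement,
                              force_un = rec$force,
                              side_pre_um = rec$side_pre),
                   path, row.names = FALSE)
  invisible(path)
}
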