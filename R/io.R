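# Plain-CSV readers/writers for the session data schemas.

#' Write a simulated session to CSV files
#'
#' Emits `trajectory.csv` (`t_s,x_mm,y_mm`) and `events.csv`
#' (`egg_id,ovulation_start_s,search_start_s,bend_complete_s,
#' deposition_s,substrate`) into `dir`.
#'
#' @param session A `sim_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session_csvs <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "trajectory.csv")
  p2 <- file.path(dir, "events.csv")
  utils::write.csv(session$trajectory, p1, row.names = FALSE)
  utils::write.csv(session$egg_events, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a trajectory CSV (`t_s,x_mm,y_mm`)
#' @param path File path.
#' @return Data frame.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an egg-events CSV
#' @param path File path.
#' @return Data frame.
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a fluorescence CSV (`volume_t_s,F_cell,F_background`)
#' @param rec Recording data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fluorescence_csv <- function(rec, path) {
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fluorescence_csv
#' @export
read_fluorescence_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a synapse-table CSV
#'
#' Schema `pre_id,post_id,pre_class,post_class,pre_side,post_side,
#' n_synapses`; a named `column_map` allows reading connectome-service
#' exports with different column names.
#'
#' @param table Synapse data frame.
#' @param path File path.
#' @param column_map Named character vector mapping schema names to the
#'   file's column names.
#' @return The path (write) or the data frame (read).
#' @export
write_synapse_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapse_csv
#' @export
read_synapse_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(df))
        stop("column not found: ", column_map[[nm]])
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  df
}
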