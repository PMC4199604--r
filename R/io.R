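# Diff-stable writers for the package's tabular and JSON products.
# CSV: comma-separated, UTF-8, '.' decimal, mandatory header, numbers at 12
# significant digits.  JSON: sorted keys, auto-unboxed scalars.  Re-running
# any writer on the same inputs produces byte-identical files.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a concentration profile to CSV
#'
#' Schema: \code{position,concentration,method,mode,r_s,r_max}; positions in
#' wall-thickness units, concentrations in J/D units.  Solver profiles gain
#' \code{residual,n_cells} columns.
#'
#' @param profile A profile tibble (from [profile_table()]) or a
#'   \code{solver_result}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (inherits(profile, "solver_result")) {
    df <- profile$profile
    df$residual <- profile$residual
    df$n_cells <- profile$grid$n_cells
  } else {
    df <- profile
  }
  stopifnot(all(c("position", "concentration", "method", "mode",
                  "r_s", "r_max") %in% names(df)))
  write_table_csv(df, path)
}

#' Write a scalar summary to JSON
#'
#' Keys are sorted so repeated runs diff clean.
#'
#' @param summary A named list (e.g. from [apposed_summary()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_keys)
    } else x
  }
  jsonlite::write_json(sort_keys(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-cell lysis event records to CSV
#'
#' Schema: \code{cell_id,condition,onset_min,breach_min,lysis_min,max_conc}.
#'
#' @param records Event records from [simulate_population()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(records, path) {
  stopifnot(all(c("cell_id", "condition", "onset_min", "breach_min",
                  "lysis_min", "max_conc") %in% names(records)))
  write_table_csv(records, path)
}

#' Write an occupancy estimate to CSV
#'
#' Schema: \code{bin_lo,bin_hi,concentration,se,n_events}.
#'
#' @param estimate An \code{occupancy_estimate} from [occupancy_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_occupancy_csv <- function(estimate, path) {
  stopifnot(inherits(estimate, "occupancy_estimate"))
  n <- length(estimate$concentration)
  df <- data.frame(bin_lo = estimate$bin_edges[seq_len(n)],
                   bin_hi = estimate$bin_edges[seq_len(n) + 1L],
                   concentration = estimate$concentration,
                   se = estimate$standard_error,
                   n_events = estimate$n_events)
  write_table_csv(df, path)
}

#' Read and write run configuration JSON
#'
#' A configuration is a named list of scalar parameters (for instance the
#' output of [lysis_params()] plus a seed).  Round-trips losslessly.
#'
#' @param config Named list.
#' @param path File path.
#' @return \code{write_config_json}: the path, invisibly;
#'   \code{read_config_json}: the configuration list.
#' @export
write_config_json <- function(config, path) {
  write_summary_json(config, path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
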