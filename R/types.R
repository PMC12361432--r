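#' Plate map
#'
#' Annotates wells of a kinetic plate: which cell line / receptor variant,
#' which ligand at which molar concentration, the well's role, replicate
#' index, and experiment identifier. Buffer and vehicle wells carry
#' concentration 0.
#'
#' @param df data.frame with columns `well_id`, `variant`, `ligand`,
#'   `concentration` (molar), `role` (one of `"agonist"`, `"buffer"`,
#'   `"vehicle"`, `"antagonist_probe"`), `replicate`, `experiment_id`.
#' @return The validated data.frame with class `plate_map` prepended.
#' @export
plate_map <- function(df) {
  req <- c("well_id", "variant", "ligand", "concentration", "role",
           "replicate", "experiment_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("plate map missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$well_id))
    stop("duplicated well_id in plate map: ",
         paste(unique(df$well_id[duplicated(df$well_id)]), collapse = ", "))
  roles <- c("agonist", "buffer", "vehicle", "antagonist_probe")
  if (!all(df$role %in% roles))
    stop("invalid role values: ",
         paste(setdiff(unique(df$role), roles), collapse = ", "))
  if (any(df$concentration < 0)) stop("negative concentration in plate map")
  bad <- df$role == "agonist" & df$concentration <= 0
  if (any(bad))
    stop("agonist wells with nonpositive concentration: ",
         paste(df$well_id[bad], collapse = ", "))
  if (any(df$replicate < 1)) stop("replicate indices must be >= 1")
  for (ex in unique(df$experiment_id)) {
    sub <- df[df$experiment_id == ex, ]
    for (v in unique(sub$variant))
      if (!any(sub$role %in% c("buffer", "vehicle") & sub$variant == v))
        stop("experiment ", ex, ": no buffer/vehicle well for variant ", v)
  }
  class(df) <- c("plate_map", class(df))
  df
}

#' Kinetic trace
#'
#' One well's time series: a strictly increasing time grid (seconds), one or
#' more emission channels (calcium assays use `"fluo"`; BRET assays use
#' `"em540"` and `"em470"`), and one or two injection times.
#'
#' @param well_id well identifier.
#' @param times numeric vector of seconds, strictly increasing.
#' @param channels named list of numeric series, each the length of `times`.
#' @param injections numeric vector of 1 or 2 injection times, inside the
#'   time range.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(well_id, times, channels, injections) {
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list of numeric series")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (length(v) != length(times))
      stop("channel '", ch, "' length ", length(v),
           " != times length ", length(times))
    if (!all(is.finite(v)))
      stop("channel '", ch, "' contains non-finite values")
  }
  injections <- as.numeric(injections)
  if (!length(injections) %in% 1:2) stop("need 1 or 2 injection times")
  if (any(injections < times[1] | injections > times[length(times)]))
    stop("injection time outside the recorded time range")
  structure(list(well_id = well_id, times = as.numeric(times),
                 channels = lapply(channels, as.numeric),
                 injections = sort(injections)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s: %d points, channels [%s], injection at %s s\n",
              x$well_id, length(x$times),
              paste(names(x$channels), collapse = ", "),
              paste(x$injections, collapse = ", ")))
  invisible(x)
}

#' Flow cytometry record table
#'
#' Per-sample median fluorescence intensities (MFI) with the paired
#' autofluorescence (AF) of the same cell line measured without ligand in the
#' same experiment. All intensities must be positive (ratios are formed on
#' the log scale).
#'
#' @param df data.frame with columns `cell_line`, `ligand`, `concentration`
#'   (molar; 0 for no-ligand rows), `mfi`, `autofluorescence_mfi`, `events`,
#'   `experiment_id`.
#' @return The validated data.frame with class `flow_table` prepended.
#' @export
flow_table <- function(df) {
  req <- c("cell_line", "ligand", "concentration", "mfi",
           "autofluorescence_mfi", "events", "experiment_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("flow table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$mfi <= 0) || any(df$autofluorescence_mfi <= 0))
    stop("MFI and autofluorescence must be > 0 (log-transform domain)")
  if (any(df$concentration < 0)) stop("negative concentration in flow table")
  class(df) <- c("flow_table", class(df))
  df
}

# ---- delimited-text IO ------------------------------------------------------

#' Write a tabular record set as delimited text
#'
#' Plain CSV with header, UTF-8, round-trips losslessly through
#' [read_tables()] (including unicode variant names).
#'
#' @param records data.frame (a plate map, flow table, response table, ...).
#' @param path output file.
#' @export
write_tables <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a delimited table written by [write_tables()]
#'
#' @param path CSV file.
#' @param type optional validator to apply: `"plate_map"` or `"flow_table"`.
#' @return data.frame (validated and classed if `type` is given).
#' @export
read_tables <- function(path, type = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (is.null(type)) return(df)
  switch(type,
         plate_map = plate_map(df),
         flow_table = flow_table(df),
         stop("unknown table type: ", type))
}

#' Write kinetic traces in long format
#'
#' Long CSV with columns `well_id, time_s, channel, value`; injection times
#' are stored as rows with the reserved channel name `"_injection"` so the
#' file is self-contained.
#'
#' @param traces list of [kinetic_trace] objects.
#' @param path output CSV.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "kinetic_trace"))
    chans <- do.call(rbind, lapply(names(tr$channels), function(ch)
      data.frame(well_id = tr$well_id, time_s = tr$times, channel = ch,
                 value = tr$channels[[ch]])))
    inj <- data.frame(well_id = tr$well_id, time_s = NA_real_,
                      channel = "_injection", value = tr$injections)
    rbind(chans, inj)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read kinetic traces from long-format CSV
#'
#' @param path CSV written by [write_traces()].
#' @return Named list of [kinetic_trace] objects (names are well ids).
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("well_id", "time_s", "channel", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trace file ", path, " missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$well_id), function(sub) {
    inj <- sub$value[sub$channel == "_injection"]
    sub <- sub[sub$channel != "_injection", ]
    if (!nrow(sub)) stop("well ", sub$well_id[1], ": no channel data")
    times <- sort(unique(sub$time_s))
    chans <- lapply(split(sub, sub$channel), function(cc)
      cc$value[order(cc$time_s)])
    kinetic_trace(sub$well_id[1], times, chans, inj)
  })
  out[order(names(out))]
}
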