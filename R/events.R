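#' Construct an event table for one well
#'
#' Holds the per-event channel intensities recorded for a single well, with
#' channels already relabelled by role: `scatter1`/`scatter2` (light scatter,
#' used for singlet gating), `dye1`/`dye2` (the bead-identification channels,
#' e.g. FITC and PE), `detect` (the reporter channel, e.g. APC) and optionally
#' `detect2` (a second reporter). Intensities are stored linear, as a
#' cytometer records them; scale transforms are applied downstream by
#' [transform_events()], never at I/O time.
#'
#' @param events Data frame of per-event intensities with at least columns
#'   `scatter1`, `scatter2`, `dye1`, `dye2`, `detect`; all values finite and
#'   non-negative.
#' @param well_id Well identifier.
#' @param instrument_id Acquiring instrument identifier (optional).
#' @return An `ev_events` object.
#' @export
event_table <- function(events, well_id = "W1", instrument_id = "unknown") {
  ev <- tibble::as_tibble(events)
  required <- c("scatter1", "scatter2", "dye1", "dye2", "detect")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    abort_format(paste0("event table is missing channels: ",
                        paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(ev[intersect(c(required, "detect2"), names(ev))])
  if (nrow(ev) > 0 && (any(!is.finite(vals)) || any(vals < 0))) {
    abort_validation("event intensities must be finite and >= 0")
  }
  structure(list(events = ev,
                 well_id = well_id,
                 instrument_id = instrument_id,
                 n_events = nrow(ev),
                 transformed = FALSE),
            class = "ev_events")
}

#' @export
print.ev_events <- function(x, ...) {
  cat(sprintf("<ev_events> well '%s' (%s): %d events, channels: %s%s\n",
              x$well_id, x$instrument_id, x$n_events,
              paste(names(x$events), collapse = ", "),
              if (isTRUE(x$transformed)) " [dye channels transformed]" else ""))
  invisible(x)
}

event_channels <- function(table) names(table$events)

#' Read flow-cytometry events from file
#'
#' Reads a well's event data from either an FCS 3.x file or the package's
#' plain-text CSV event dialect (header line of channel roles, optional
#' `#key=value` metadata comment lines). The format is detected from the file
#' content (FCS magic bytes), not the extension.
#'
#' @param path Input file.
#' @param channel_map Named character vector mapping file channel names to
#'   roles, e.g. `c(FSC = "scatter1", SSC = "scatter2", FITC = "dye1",
#'   PE = "dye2", APC = "detect")`. May be `NULL` when the file's channel
#'   names already are roles (always true for files written by
#'   [write_events()]). Must cover the five mandatory roles.
#' @return An [event_table()].
#' @export
read_events <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("cannot read events: file not found: ", path)
  magic <- readBin(path, "raw", n = 6)
  if (length(magic) >= 3 && rawToChar(magic[1:3]) == "FCS") {
    raw <- read_fcs(path)
  } else {
    raw <- read_events_csv(path)
  }
  ev <- raw$events
  if (!is.null(channel_map)) {
    idx <- match(names(channel_map), names(ev))
    if (anyNA(idx)) {
      abort_format(paste0("mapped channel(s) not present in file: ",
                          paste(names(channel_map)[is.na(idx)], collapse = ", ")))
    }
    names(ev)[idx] <- unname(channel_map)
  }
  required <- c("scatter1", "scatter2", "dye1", "dye2", "detect")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0) {
    abort_format(paste0("no channel mapped to role(s): ",
                        paste(missing, collapse = ", ")))
  }
  event_table(ev[c(required, intersect("detect2", names(ev)))],
              well_id = raw$well_id %||% "W1",
              instrument_id = raw$instrument_id %||% "unknown")
}

#' Write flow-cytometry events to file
#'
#' Writes an [event_table()] either as FCS 3.1 (list mode, 32-bit float data)
#' or as the CSV event dialect, chosen by file extension (`.fcs` vs anything
#' else). Both round-trip through [read_events()]: CSV losslessly at full
#' double precision, FCS at 32-bit float precision.
#'
#' @param table An [event_table()].
#' @param path Output file; extension `.fcs` selects FCS 3.1.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "ev_events"))
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    write_fcs(table, path)
  } else {
    write_events_csv(table, path)
  }
  invisible(path)
}

# CSV event dialect: '#key=value' metadata lines, then a header of channel
# roles, then one row per event. Numbers printed with %.17g so that
# write -> read -> write is byte-identical.
write_events_csv <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#well_id=%s", table$well_id),
               sprintf("#instrument_id=%s", table$instrument_id)), con)
  ev <- table$events
  writeLines(paste(names(ev), collapse = ","), con)
  if (nrow(ev) > 0) {
    cols <- lapply(ev, function(x) sprintf("%.17g", x))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

read_events_csv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- if (length(meta_idx) > 0) lines[-meta_idx] else lines
  if (length(body) < 1) abort_format("CSV event file has no header line")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (length(body) > 1) {
    ev <- utils::read.csv(text = body[-1], header = FALSE,
                          col.names = header, colClasses = "numeric")
  } else {
    ev <- as.data.frame(matrix(numeric(0), ncol = length(header),
                               dimnames = list(NULL, header)))
  }
  list(events = tibble::as_tibble(ev),
       well_id = meta$well_id, instrument_id = meta$instrument_id)
}
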