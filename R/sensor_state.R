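## Event-driven capacitance state. A module reports all eight of its field
## capacitances whenever at least one of them changed enough since the last
## report; the floor-wide snapshot at any time is the fold of all messages
## received so far, starting from an all-zero state.

#' Construct a sensor message
#'
#' @param t arrival time in seconds since recording start.
#' @param module module id.
#' @param caps numeric vector of 8 capacitances in [0, 1], slot order 1..8.
#' @return a \linkS4class{SensorMessage}.
#' @export
sensorMessage <- function(t, module, caps) {
  new("SensorMessage", t = as.numeric(t), module = as.character(module),
      c = as.numeric(caps))
}

#' Initialise the sensor state for a layout
#'
#' All capacitances and last-measurement times start at zero; there is
#' exactly one entry per field in the layout and the entry set never changes
#' afterwards.
#'
#' @param layout a \linkS4class{FloorLayout}.
#' @return a \linkS4class{SensorState}.
#' @export
initState <- function(layout) {
  stopifnot(is(layout, "FloorLayout"))
  f <- layout@fields
  new("SensorState", entries = data.frame(
    field_id = f$field_id, module_id = f$module_id, x = f$x, y = f$y,
    t = numeric(nrow(f)), c = numeric(nrow(f)), stringsAsFactors = FALSE))
}

#' Apply one message to a sensor state
#'
#' Replacement semantics: the eight entries of the message's module take the
#' message time and capacitances; every other entry is unchanged. Messages
#' must not run backwards in time for their module.
#'
#' @param state a \linkS4class{SensorState}.
#' @param msg a \linkS4class{SensorMessage}.
#' @return the updated \linkS4class{SensorState}.
#' @export
applyMessage <- function(state, msg) {
  stopifnot(is(state, "SensorState"), is(msg, "SensorMessage"))
  e <- state@entries
  idx <- which(e$module_id == msg@module)
  if (length(idx) != 8L)
    stop("unknown module id: ", msg@module)
  ## entries are built in slot order, so idx is the module's slots 1..8
  if (msg@t < max(e$t[idx]))
    stop("out-of-order message: t = ", msg@t, " before module time ",
         max(e$t[idx]))
  e$t[idx] <- msg@t
  e$c[idx] <- msg@c
  new("SensorState", entries = e)
}

#' Replay a time-ordered message stream into a state series
#'
#' Folds \code{applyMessage} over the stream, recording one snapshot per
#' message. The stream must already be sorted by time (ties between
#' different modules are allowed and applied in stream order); unsorted
#' input is an error, never silently re-sorted.
#'
#' @param layout a \linkS4class{FloorLayout}.
#' @param messages data.frame with columns \code{t}, \code{module},
#'   \code{c1}..\code{c8} (see \code{\link{readMessageLog}}).
#' @return a \linkS4class{StateSeries} with one state per message.
#' @export
replayMessages <- function(layout, messages) {
  stopifnot(is(layout, "FloorLayout"))
  messages <- as.data.frame(messages)
  k <- nrow(messages)
  f <- layout@fields
  n <- nrow(f)
  if (k > 0 && is.unsorted(messages$t))
    stop("message stream is not sorted by time")
  capcols <- paste0("c", 1:8)
  if (k > 0 && !all(capcols %in% names(messages)))
    stop("messages must carry columns c1..c8")
  ## module id -> indices of its 8 fields (slot order)
  modIdx <- split(seq_len(n), f$module_id)
  cap <- matrix(0, k, n)
  tup <- matrix(0, k, n)
  cvec <- numeric(n)
  tvec <- numeric(n)
  if (k > 0) {
    cm <- as.matrix(messages[, capcols])
    if (any(cm < 0 | cm > 1)) stop("capacitances must lie in [0, 1]")
    mods <- as.character(messages$module)
    for (i in seq_len(k)) {
      idx <- modIdx[[mods[i]]]
      if (is.null(idx)) stop("unknown module id: ", mods[i])
      if (messages$t[i] < tvec[idx[1]])
        stop("out-of-order message for module ", mods[i])
      cvec[idx] <- cm[i, ]
      tvec[idx] <- messages$t[i]
      cap[i, ] <- cvec
      tup[i, ] <- tvec
    }
  }
  new("StateSeries",
      fields = data.frame(field_id = f$field_id, module_id = f$module_id,
                          x = f$x, y = f$y, stringsAsFactors = FALSE),
      times = if (k > 0) as.numeric(messages$t) else numeric(0),
      cap = cap, tupd = tup)
}

#' Per-field maximum capacitance over a recording
#'
#' Footfall map: for every field, the maximum capacitance observed anywhere
#' in the state series. Plotted over the field centroid positions this shows
#' where (and how firmly) feet touched the floor.
#'
#' @param series a \linkS4class{StateSeries} with at least one state.
#' @return data.frame with columns \code{field_id}, \code{x}, \code{y},
#'   \code{max_c}.
#' @export
footfallMap <- function(series) {
  stopifnot(is(series, "StateSeries"))
  if (length(series@times) == 0L) stop("empty state series")
  data.frame(field_id = series@fields$field_id, x = series@fields$x,
             y = series@fields$y,
             max_c = apply(series@cap, 2, max), stringsAsFactors = FALSE)
}

#' @rdname footfallMap
#' @param map data.frame as returned by \code{footfallMap}.
#' @param path output CSV path.
#' @export
writeFootfallMap <- function(map, path) {
  write.csv(map, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an event message log
#'
#' Two on-disk formats are supported: JSON-lines with one object per message
#' (\code{{"t": seconds, "module": id, "c": [8 capacitances]}}) and CSV with
#' columns \code{t}, \code{module}, \code{c1}..\code{c8}. The format is
#' chosen from the file extension (\code{.jsonl} vs \code{.csv}) unless
#' given explicitly.
#'
#' @param path file path.
#' @param format \code{"jsonl"}, \code{"csv"} or \code{"auto"}.
#' @return a data.frame with columns \code{t}, \code{module},
#'   \code{c1}..\code{c8}.
#' @export
readMessageLog <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) {
      o <- jsonlite::fromJSON(l)
      c(list(t = o$t, module = o$module), as.list(o$c))
    })
    df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
    names(df) <- c("t", "module", paste0("c", 1:8))
  }
  df$module <- as.character(df$module)
  df
}

#' @rdname readMessageLog
#' @param messages data.frame with columns \code{t}, \code{module},
#'   \code{c1}..\code{c8}.
#' @export
writeMessageLog <- function(messages, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  if (format == "csv") {
    write.csv(messages, path, row.names = FALSE)
  } else {
    capm <- as.matrix(messages[, paste0("c", 1:8)])
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(messages))) {
      writeLines(jsonlite::toJSON(
        list(t = messages$t[i], module = messages$module[i], c = capm[i, ]),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

setMethod("stateEntries", "SensorState", function(object) object@entries)

setMethod("show", "SensorState", function(object) {
  e <- object@entries
  cat("SensorState with", nrow(e), "field entries;",
      sum(e$c > 0), "non-zero, max capacitance",
      if (nrow(e)) format(max(e$c), digits = 3) else NA, "\n")
})

setMethod("stateTimes", "StateSeries", function(object) object@times)

setMethod("capacitanceMatrix", "StateSeries", function(object) object@cap)

setMethod("stateAt", "StateSeries", function(object, i) {
  stopifnot(i >= 1, i <= length(object@times))
  f <- object@fields
  new("SensorState", entries = data.frame(
    field_id = f$field_id, module_id = f$module_id, x = f$x, y = f$y,
    t = object@tupd[i, ], c = object@cap[i, ], stringsAsFactors = FALSE))
})

setMethod("show", "StateSeries", function(object) {
  cat("StateSeries:", length(object@times), "states over",
      nrow(object@fields), "fields")
  if (length(object@times))
    cat(sprintf("; t in [%.2f, %.2f] s", min(object@times), max(object@times)))
  cat("\n")
})

## Subset a state series to a contiguous (or general) set of state indices.
.subsetSeries <- function(series, idx) {
  new("StateSeries", fields = series@fields, times = series@times[idx],
      cap = series@cap[idx, , drop = FALSE],
      tupd = series@tupd[idx, , drop = FALSE])
}
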