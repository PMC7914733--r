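#' @import methods
#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib capgait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' FloorLayout: modular capacitive floor geometry
#'
#' Represents a floor built from square sensor modules, each carrying eight
#' triangular capacitive fields around a central microcontroller. The layout
#' stores per-module centers and edge lengths (metres, global floor frame)
#' and a derived field table with one row per triangular field, including the
#' field centroid position.
#'
#' @slot modules data.frame with columns \code{module_id} (unique character),
#'   \code{center_x}, \code{center_y}, \code{edge} (metres, > 0).
#' @slot fields data.frame with one row per field: \code{field_id},
#'   \code{module_id}, \code{slot} (1..8), \code{x}, \code{y} (centroid,
#'   metres).
#' @export
setClass("FloorLayout",
  representation(modules = "data.frame", fields = "data.frame"))

setValidity("FloorLayout", function(object) {
  m <- object@modules
  f <- object@fields
  msgs <- character()
  need <- c("module_id", "center_x", "center_y", "edge")
  if (!all(need %in% names(m)))
    msgs <- c(msgs, "modules must have columns module_id, center_x, center_y, edge")
  else {
    if (anyDuplicated(m$module_id)) msgs <- c(msgs, "module ids must be unique")
    if (nrow(m) > 0 && any(m$edge <= 0)) msgs <- c(msgs, "module edge lengths must be positive")
  }
  if (nrow(f) != 8L * nrow(m)) msgs <- c(msgs, "layout must carry exactly 8 fields per module")
  if (nrow(f) > 0 && anyDuplicated(f$field_id)) msgs <- c(msgs, "field ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' SensorState: snapshot of all field capacitances
#'
#' The event-driven snapshot of every field's last measured capacitance and
#' measurement time, reconstructed by folding sensor messages. The entry set
#' is fixed at initialisation (one entry per field in the layout) and never
#' grows or shrinks.
#'
#' @slot entries data.frame with columns \code{field_id}, \code{module_id},
#'   \code{x}, \code{y}, \code{t} (seconds since recording start), \code{c}
#'   (capacitance in [0, 1]).
#' @export
setClass("SensorState", representation(entries = "data.frame"))

setValidity("SensorState", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("field_id", "module_id", "x", "y", "t", "c")
  if (!all(need %in% names(e)))
    return("entries must have columns field_id, module_id, x, y, t, c")
  if (nrow(e) > 0) {
    if (anyDuplicated(e$field_id)) msgs <- c(msgs, "field ids must be unique")
    if (any(e$c < 0 | e$c > 1)) msgs <- c(msgs, "capacitances must lie in [0, 1]")
    if (any(e$t < 0)) msgs <- c(msgs, "measurement times must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' SensorMessage: one module's eight-field capacitance report
#'
#' @slot t numeric scalar, seconds since recording start (>= 0).
#' @slot module character scalar, module id.
#' @slot c numeric vector of length 8, capacitances in [0, 1].
#' @export
setClass("SensorMessage",
  representation(t = "numeric", module = "character", c = "numeric"))

setValidity("SensorMessage", function(object) {
  msgs <- character()
  if (length(object@t) != 1L || is.na(object@t) || object@t < 0)
    msgs <- c(msgs, "t must be a single non-negative number")
  if (length(object@module) != 1L) msgs <- c(msgs, "module must be a single id")
  if (length(object@c) != 8L) msgs <- c(msgs, "a message carries exactly 8 capacitances")
  else if (any(is.na(object@c)) || any(object@c < 0 | object@c > 1))
    msgs <- c(msgs, "capacitances must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' StateSeries: replayed time series of sensor states
#'
#' One row per applied message: the full capacitance snapshot (and per-field
#' last-measurement times) after folding the message stream up to that point.
#'
#' @slot fields data.frame of the layout's fields (field_id, module_id, x, y).
#' @slot times numeric vector, message arrival times (non-decreasing).
#' @slot cap numeric matrix, length(times) x nrow(fields), capacitances.
#' @slot tupd numeric matrix, same shape, per-field last-measurement times.
#' @export
setClass("StateSeries",
  representation(fields = "data.frame", times = "numeric",
                 cap = "matrix", tupd = "matrix"))

setValidity("StateSeries", function(object) {
  msgs <- character()
  k <- length(object@times)
  n <- nrow(object@fields)
  if (!identical(dim(object@cap), c(k, n))) msgs <- c(msgs, "cap must be k x n")
  if (!identical(dim(object@tupd), c(k, n))) msgs <- c(msgs, "tupd must be k x n")
  if (k > 1 && any(diff(object@times) < 0)) msgs <- c(msgs, "times must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' GridSpec: receptive-field grid in the walker-local frame
#'
#' The fixed lattice of sample points (spacing \code{spacing}, strict radius
#' cut \code{radius}) whose capacitance values form the network input vector.
#' Points are stored in a fixed, documented meander order: rows from the most
#' negative y upward, alternating x direction row by row, so that
#' geometrically adjacent points stay adjacent in the unrolled vector.
#'
#' @slot spacing grid spacing l_s in metres (> 0).
#' @slot radius cutoff radius r_s in metres (> 0); points satisfy |p| < r_s.
#' @slot points numeric matrix (n x 2) of lattice point positions, metres.
#' @export
setClass("GridSpec",
  representation(spacing = "numeric", radius = "numeric", points = "matrix"))

setValidity("GridSpec", function(object) {
  msgs <- character()
  if (object@spacing <= 0) msgs <- c(msgs, "spacing must be positive")
  if (object@radius <= 0) msgs <- c(msgs, "radius must be positive")
  if (ncol(object@points) != 2L) msgs <- c(msgs, "points must be an n x 2 matrix")
  nrm <- sqrt(rowSums(object@points^2))
  if (any(nrm >= object@radius)) msgs <- c(msgs, "all grid points must lie strictly inside the radius")
  if (length(msgs)) msgs else TRUE
})

#' LocalGrid: a GridSpec with capacitance values
#'
#' @slot spec a \linkS4class{GridSpec}.
#' @slot values numeric vector of grid capacitances, one per grid point, in
#'   the grid's meander order.
#' @export
setClass("LocalGrid", representation(spec = "GridSpec", values = "numeric"))

setValidity("LocalGrid", function(object) {
  if (length(object@values) != nrow(object@spec@points))
    "values must have one entry per grid point"
  else TRUE
})
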