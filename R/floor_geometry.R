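## Floor geometry: modular capacitive floor with 8 triangular fields per
## module. A square module of edge l is divided by its two diagonals and the
## two edge-midlines into 8 right triangles, each with the right angle at an
## edge midpoint; the triangle centroids sit at all sign combinations of
## (+-2h/3, +-h/3) and (+-h/3, +-2h/3) around the module center, with
## h = l / 2.

## Slot order j = 1..8: quadrants counter-clockwise starting at (+x, +y);
## within a quadrant the x-major triangle (centroid farther out in x) comes
## before the y-major one. Fixed and documented so downstream learning uses
## a stable association between slot and position.
.SLOT_OFFSETS <- matrix(c(
   2,  1,   # j = 1: quadrant (+,+), x-major
   1,  2,   # j = 2: quadrant (+,+), y-major
  -2,  1,   # j = 3: quadrant (-,+), x-major
  -1,  2,   # j = 4: quadrant (-,+), y-major
  -2, -1,   # j = 5: quadrant (-,-), x-major
  -1, -2,   # j = 6: quadrant (-,-), y-major
   2, -1,   # j = 7: quadrant (+,-), x-major
   1, -2),  # j = 8: quadrant (+,-), y-major
  ncol = 2, byrow = TRUE) / 3

#' Centroid positions of the eight triangular fields of a module
#'
#' Approximating each sensor field as a right-angled triangle, the eight
#' field centroids of a square module of edge length \code{edge} lie at all
#' sign combinations of \code{(±2h/3, ±h/3)} and \code{(±h/3, ±2h/3)} around
#' the module center, with \code{h = edge/2}. For a rectangular module whose
#' long side is twice the short side (the low-resolution 1 m x 0.5 m
#' variant), the module is treated as two adjacent half-squares, each
#' contributing four diagonal-cut triangles.
#'
#' @param center numeric length-2, module center position in metres.
#' @param edge module edge length in metres (scalar, square module), or a
#'   length-2 vector \code{c(lx, ly)} for a rectangular module.
#' @return an 8 x 2 matrix of centroid positions in slot order j = 1..8.
#' @export
fieldCentroids <- function(center, edge) {
  stopifnot(length(center) == 2)
  if (any(!is.finite(edge)) || any(edge <= 0))
    stop("invalid geometry: module edge length must be positive")
  if (length(edge) == 1L || edge[1] == edge[2]) {
    h <- edge[1] / 2
    return(sweep(.SLOT_OFFSETS * h, 2, center, "+"))
  }
  if (length(edge) != 2L)
    stop("invalid geometry: edge must be a scalar or a length-2 vector")
  lx <- edge[1]; ly <- edge[2]
  long <- max(lx, ly); short <- min(lx, ly)
  if (abs(long - 2 * short) > 1e-9 * long)
    stop("invalid geometry: rectangular modules must be two half-squares (long = 2 x short)")
  ## two half-squares along the long axis, each split by its diagonals into
  ## four triangles with centroids at (+-2h/3, 0) and (0, +-2h/3)
  h <- short / 2
  quad <- matrix(c(2, 0, 0, 2, -2, 0, 0, -2), ncol = 2, byrow = TRUE) * h / 3
  shift <- if (lx >= ly) c(short / 2, 0) else c(0, short / 2)
  pts <- rbind(sweep(quad, 2, shift, "+"), sweep(quad, 2, -shift, "+"))
  sweep(pts, 2, center, "+")
}

#' Sensor-field density of a module type
#'
#' Number of triangular sensor fields per square metre of floor for modules
#' of the given outline.
#'
#' @param lx,ly module outline dimensions in metres (> 0).
#' @param fieldsPerModule number of fields per module (default 8).
#' @return fields per square metre.
#' @examples
#' fieldsPerSquareMeter(1.0, 0.5)    # low resolution: 16 / m^2
#' fieldsPerSquareMeter(0.38, 0.38)  # gait resolution: ~55 / m^2
#' @export
fieldsPerSquareMeter <- function(lx, ly = lx, fieldsPerModule = 8) {
  if (!is.finite(lx) || !is.finite(ly) || lx <= 0 || ly <= 0)
    stop("invalid geometry: module dimensions must be positive")
  if (fieldsPerModule < 1) stop("invalid geometry: fieldsPerModule must be >= 1")
  fieldsPerModule / (lx * ly)
}

#' Area of one triangular sensor field
#'
#' @param edge square module edge length in metres (> 0).
#' @param fieldsPerModule number of fields per module (default 8).
#' @return field area in square metres.
#' @export
fieldArea <- function(edge, fieldsPerModule = 8) {
  if (!is.finite(edge) || edge <= 0)
    stop("invalid geometry: module edge length must be positive")
  edge^2 / fieldsPerModule
}

.fieldId <- function(module_id, slot) sprintf("%s/%d", module_id, slot)

.buildFields <- function(modules) {
  if (nrow(modules) == 0L)
    return(data.frame(field_id = character(), module_id = character(),
                      slot = integer(), x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE))
  parts <- lapply(seq_len(nrow(modules)), function(i) {
    ctr <- fieldCentroids(c(modules$center_x[i], modules$center_y[i]),
                          modules$edge[i])
    data.frame(field_id = .fieldId(modules$module_id[i], 1:8),
               module_id = modules$module_id[i], slot = 1:8,
               x = ctr[, 1], y = ctr[, 2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Construct a FloorLayout from a module table
#'
#' @param modules data.frame with columns \code{module_id}, \code{center_x},
#'   \code{center_y}, \code{edge} (metres).
#' @return a \linkS4class{FloorLayout}.
#' @export
floorLayout <- function(modules) {
  modules <- as.data.frame(modules, stringsAsFactors = FALSE)
  modules$module_id <- as.character(modules$module_id)
  new("FloorLayout", modules = modules, fields = .buildFields(modules))
}

#' Build a rectangular grid of square modules
#'
#' Convenience constructor for an nx x ny arrangement of square modules, as
#' used when covering a rectangular room. Module centers are placed at
#' \code{origin + ((i - 1/2) edge, (j - 1/2) edge)}; y increases into the
#' room.
#'
#' @param nx,ny module counts along x and y.
#' @param edge module edge length in metres (default 0.38, the
#'   gait-resolution module).
#' @param origin numeric length-2, position of the floor corner (metres).
#' @return a \linkS4class{FloorLayout}.
#' @export
makeFloorGrid <- function(nx, ny, edge = 0.38, origin = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1)
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  floorLayout(data.frame(
    module_id = sprintf("m%02d_%02d", ij$i, ij$j),
    center_x = origin[1] + (ij$i - 0.5) * edge,
    center_y = origin[2] + (ij$j - 0.5) * edge,
    edge = edge, stringsAsFactors = FALSE))
}

#' Read / write a floor layout file
#'
#' The layout file is a CSV with columns \code{module_id}, \code{center_x_m},
#' \code{center_y_m}, \code{edge_m} in metric units and the global floor
#' frame (y increasing into the room).
#'
#' @param path file path.
#' @return \code{readFloorLayout} returns a \linkS4class{FloorLayout};
#'   \code{writeFloorLayout} returns \code{path} invisibly.
#' @export
readFloorLayout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("module_id", "center_x_m", "center_y_m", "edge_m")
  if (!all(need %in% names(df)))
    stop("layout file must have columns ", paste(need, collapse = ", "))
  floorLayout(data.frame(module_id = df$module_id, center_x = df$center_x_m,
                         center_y = df$center_y_m, edge = df$edge_m,
                         stringsAsFactors = FALSE))
}

#' @rdname readFloorLayout
#' @param layout a \linkS4class{FloorLayout}.
#' @export
writeFloorLayout <- function(layout, path) {
  m <- layout@modules
  write.csv(data.frame(module_id = m$module_id, center_x_m = m$center_x,
                       center_y_m = m$center_y, edge_m = m$edge),
            path, row.names = FALSE)
  invisible(path)
}

setMethod("nModules", "FloorLayout", function(object) nrow(object@modules))

setMethod("nFields", "FloorLayout", function(object) nrow(object@fields))

setMethod("fieldTable", "FloorLayout", function(object) object@fields)

setMethod("moduleTable", "FloorLayout", function(object) object@modules)

setMethod("show", "FloorLayout", function(object) {
  cat("FloorLayout with", nModules(object), "modules /", nFields(object),
      "triangular fields\n")
  if (nModules(object) > 0) {
    e <- unique(object@modules$edge)
    cat("  module edge(s):", paste(format(e), collapse = ", "), "m\n")
    cat(sprintf("  extent: x [%.2f, %.2f] m, y [%.2f, %.2f] m\n",
                min(object@modules$center_x - object@modules$edge / 2),
                max(object@modules$center_x + object@modules$edge / 2),
                min(object@modules$center_y - object@modules$edge / 2),
                max(object@modules$center_y + object@modules$edge / 2)))
  }
})
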