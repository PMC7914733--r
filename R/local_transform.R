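## Walker-local transformation. Gait is translation- and rotation-invariant,
## so the floor-frame activations are moved into the coordinate system of
## the tracked walker: translate to the capacitance-weighted centroid,
## rotate so the walking direction becomes +y, cut everything beyond a
## radius r_s, and resample onto a fixed lattice whose values feed the
## network input layer in a fixed association.

#' Threshold a sensor state into its sparse representation
#'
#' Keeps exactly the fields whose capacitance is strictly above the
#' threshold. The default threshold of 0.03 (3 % of the measuring range)
#' accounts for baseline sensor fluctuations.
#'
#' @param state a \linkS4class{SensorState}.
#' @param cThreshold capacitance threshold in [0, 1).
#' @return data.frame with columns \code{x}, \code{y}, \code{c} (possibly
#'   zero rows).
#' @export
sparsify <- function(state, cThreshold = 0.03) {
  stopifnot(is(state, "SensorState"))
  if (cThreshold < 0 || cThreshold >= 1)
    stop("cThreshold must lie in [0, 1)")
  e <- state@entries
  keep <- e$c > cThreshold
  data.frame(x = e$x[keep], y = e$y[keep], c = e$c[keep])
}

#' Capacitance-weighted walker position
#'
#' Centre-of-mass style tracker: position vectors of the active fields are
#' weighted with their capacitances and normalised by the total capacitance.
#' Valid for a single person on the floor.
#'
#' @param sparse data.frame with columns \code{x}, \code{y}, \code{c} as
#'   returned by \code{\link{sparsify}}.
#' @return numeric length-2 position, or \code{NULL} when the sparse state
#'   is empty (no position defined; callers carry the last one forward).
#' @export
trackedPosition <- function(sparse) {
  if (nrow(sparse) == 0L) return(NULL)
  Ct <- sum(sparse$c)
  c(sum(sparse$c * sparse$x), sum(sparse$c * sparse$y)) / Ct
}

#' Signed walking angle
#'
#' The signed angle theta such that rotating by theta maps the unit walking
#' direction (from the first to the last tracked position) onto the local
#' reference axis (0, 1). Computed with the two-argument arctangent so the
#' sign is defined; its magnitude agrees with acos(d . (0,1)).
#'
#' @param first,last numeric length-2 tracked positions (metres).
#' @return angle in radians.
#' @export
walkingAngle <- function(first, last) {
  d <- c(last[1] - first[1], last[2] - first[2])
  if (sqrt(sum(d^2)) == 0)
    stop("degenerate walk: first and last tracked positions coincide")
  unname(atan2(d[1], d[2]))
}

.rotation <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Transform a sparse state into the walker-local frame
#'
#' Translates field centroids to the tracked position, rotates by the
#' walking angle so the walking direction points along +y, and removes
#' entries at distance >= \code{radius} from the walker (strict < keeps).
#'
#' @param sparse data.frame with columns \code{x}, \code{y}, \code{c}.
#' @param position numeric length-2 tracked position (metres, global frame).
#' @param theta walking angle in radians (see \code{\link{walkingAngle}}).
#' @param radius cutoff radius r_s in metres (> 0).
#' @return data.frame with columns \code{x}, \code{y} (local frame),
#'   \code{c}.
#' @export
toLocal <- function(sparse, position, theta, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (nrow(sparse) == 0L) return(data.frame(x = numeric(), y = numeric(), c = numeric()))
  dx <- sparse$x - position[1]
  dy <- sparse$y - position[2]
  keep <- sqrt(dx^2 + dy^2) < radius
  R <- .rotation(theta)
  lx <- R[1, 1] * dx[keep] + R[1, 2] * dy[keep]
  ly <- R[2, 1] * dx[keep] + R[2, 2] * dy[keep]
  data.frame(x = lx, y = ly, c = sparse$c[keep])
}

#' Build the walker-local receptive-field grid
#'
#' All lattice points \code{(i * spacing, j * spacing)} with integer i, j
#' strictly inside the cutoff radius, ordered in a fixed meander: rows from
#' the most negative y upward, x ascending in the first row and alternating
#' direction row by row.
#'
#' @param spacing grid spacing l_s in metres (> 0).
#' @param radius cutoff radius r_s in metres (> 0).
#' @return a \linkS4class{GridSpec}; use \code{\link{resampleToGrid}} to
#'   fill it from a local sparse state.
#' @export
makeGrid <- function(spacing, radius) {
  if (!is.finite(spacing) || spacing <= 0 || !is.finite(radius) || radius <= 0)
    stop("invalid grid: spacing and radius must be positive")
  imax <- floor(radius / spacing)
  rows <- list()
  r <- 0L
  for (j in seq(-imax, imax)) {
    xs <- seq(-imax, imax)
    xs <- xs[(xs * spacing)^2 + (j * spacing)^2 < radius^2]
    if (!length(xs)) next
    if (r %% 2L == 1L) xs <- rev(xs)  # meander: alternate direction
    rows[[length(rows) + 1L]] <- cbind(xs * spacing, j * spacing)
    r <- r + 1L
  }
  pts <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, 2)
  colnames(pts) <- c("x", "y")
  new("GridSpec", spacing = spacing, radius = radius, points = pts)
}

setMethod("gridPoints", "GridSpec", function(object) object@points)

setMethod("gridSize", "GridSpec", function(object) nrow(object@points))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: spacing %.3g m, radius %.3g m, %d points (meander order)\n",
              object@spacing, object@radius, nrow(object@points)))
})

#' Resample a local sparse state onto the receptive-field grid
#'
#' Every local field entry deposits its capacitance on the Euclidean-nearest
#' grid point; points receiving nothing stay 0. When several entries land on
#' the same point the maximum capacitance wins (preserving the strongest
#' activation); exact distance ties go to the point with the lower x, then
#' lower y.
#'
#' @param local data.frame with columns \code{x}, \code{y}, \code{c} in the
#'   walker-local frame (entries within the grid radius).
#' @param grid a \linkS4class{GridSpec}.
#' @return a \linkS4class{LocalGrid} holding the grid capacitances.
#' @export
resampleToGrid <- function(local, grid) {
  stopifnot(is(grid, "GridSpec"))
  vals <- numeric(nrow(grid@points))
  if (nrow(local) > 0L) {
    pts <- grid@points
    for (i in seq_len(nrow(local))) {
      d2 <- (pts[, 1] - local$x[i])^2 + (pts[, 2] - local$y[i])^2
      cand <- which(d2 <= min(d2) + 1e-12)
      if (length(cand) > 1L) {
        cand <- cand[order(pts[cand, 1], pts[cand, 2])]
      }
      j <- cand[1]
      vals[j] <- max(vals[j], local$c[i])
    }
  }
  new("LocalGrid", spec = grid, values = vals)
}

setMethod("unroll", "LocalGrid", function(object) object@values)

setMethod("show", "LocalGrid", function(object) {
  cat(sprintf("LocalGrid: %d points, %d active, max %.3g\n",
              length(object@values), sum(object@values > 0),
              if (length(object@values)) max(object@values) else NA))
})

## Tracked positions for every state of a series, with empty sparse states
## carrying the previous position forward. Returns a list with the k x 2
## position matrix, a logical 'defined' vector (position known at step), and
## a logical 'active' vector (sparse state non-empty at step).
.trackSeries <- function(series, cThreshold) {
  cap <- series@cap
  xs <- series@fields$x
  ys <- series@fields$y
  w <- cap
  w[w <= cThreshold] <- 0
  Ct <- rowSums(w)
  active <- Ct > 0
  px <- ifelse(active, as.numeric(w %*% xs) / Ct, NA_real_)
  py <- ifelse(active, as.numeric(w %*% ys) / Ct, NA_real_)
  ## carry last defined position forward
  defined <- active
  lastx <- NA_real_; lasty <- NA_real_
  for (i in seq_along(px)) {
    if (active[i]) { lastx <- px[i]; lasty <- py[i] }
    else if (!is.na(lastx)) { px[i] <- lastx; py[i] <- lasty; defined[i] <- TRUE }
  }
  list(pos = cbind(px, py), defined = defined, active = active)
}

#' Preprocess a walk into a time series of grid activation vectors
#'
#' Runs the full per-state chain sparsify -> track -> transform to the
#' walker-local frame -> resample -> unroll, using one walk-level walking
#' angle derived from the first and last tracked positions. States with an
#' empty sparse representation carry the last tracked position forward and
#' contribute a zero vector; leading states with no position yet are
#' dropped.
#'
#' @param series a \linkS4class{StateSeries} for one (single-pass) walk.
#' @param cThreshold capacitance threshold (default 0.03).
#' @param spacing grid spacing l_s in metres (default 0.10).
#' @param radius cutoff radius r_s in metres (default 1.0).
#' @param grid optionally a prebuilt \linkS4class{GridSpec} (overrides
#'   \code{spacing} / \code{radius}).
#' @return numeric matrix (one row per state with a defined position, one
#'   column per grid point) with attributes \code{theta}, \code{spacing},
#'   \code{radius}, \code{cThreshold}, \code{times}.
#' @export
preprocessWalk <- function(series, cThreshold = 0.03, spacing = 0.10,
                           radius = 1.0, grid = NULL) {
  stopifnot(is(series, "StateSeries"))
  if (is.null(grid)) grid <- makeGrid(spacing, radius)
  trk <- .trackSeries(series, cThreshold)
  keep <- which(trk$defined)
  if (sum(trk$active) < 2L)
    stop("degenerate walk: fewer than 2 trackable states")
  firstIdx <- keep[1]
  lastIdx <- keep[length(keep)]
  theta <- walkingAngle(trk$pos[firstIdx, ], trk$pos[lastIdx, ])
  xs <- series@fields$x
  ys <- series@fields$y
  out <- matrix(0, length(keep), nrow(grid@points))
  for (r in seq_along(keep)) {
    i <- keep[r]
    if (!trk$active[i]) next  # empty sparse state: zero vector
    sel <- series@cap[i, ] > cThreshold
    sp <- data.frame(x = xs[sel], y = ys[sel], c = series@cap[i, sel])
    loc <- toLocal(sp, trk$pos[i, ], theta, grid@radius)
    out[r, ] <- resampleToGrid(loc, grid)@values
  }
  structure(out, theta = theta, spacing = grid@spacing, radius = grid@radius,
            cThreshold = cThreshold, times = series@times[keep])
}

#' Write / read a preprocessed walk
#'
#' The activation matrix is stored as CSV (rows = event steps, columns =
#' grid cells) next to a JSON sidecar carrying the preprocessing parameters
#' (spacing, radius, threshold, walking angle, grid ordering version).
#'
#' @param mat matrix from \code{\link{preprocessWalk}}.
#' @param path output CSV path; the sidecar goes to \code{<path>.json}.
#' @export
writePreprocessedWalk <- function(mat, path) {
  write.table(mat, path, sep = ",", row.names = FALSE, col.names = FALSE)
  side <- list(spacing = attr(mat, "spacing"), radius = attr(mat, "radius"),
               cThreshold = attr(mat, "cThreshold"), theta = attr(mat, "theta"),
               times = as.numeric(attr(mat, "times")),
               grid_ordering = "meander-v1")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePreprocessedWalk
#' @export
readPreprocessedWalk <- function(path) {
  mat <- as.matrix(read.csv(path, header = FALSE))
  dimnames(mat) <- NULL
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(mat, theta = side$theta, spacing = side$spacing,
            radius = side$radius, cThreshold = side$cThreshold,
            times = side$times)
}
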