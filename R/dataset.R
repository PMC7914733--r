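## Dataset construction: segment out-and-back recordings into straight
## single-pass walks (dropping the steps around the turning point, where
## gait is not steady), slide a fixed-length window over each walk's vector
## series, and build the two leave-one-out cross-validation designs.

.WALK_MODES <- c("normal", "fast", "slow", "closed_eyes", "dual_task", "post_uhr")

#' Segment a recording into straight walk passes
#'
#' An out-and-back recording is split at the turning point (the extremum of
#' displacement along the dominant axis of the tracked trajectory); states
#' whose tracked position lies within \code{trimRadius} of the turning
#' position are excluded from both segments, because gait right before and
#' after the turn is not representative of steady walking. A single-pass
#' recording comes back as one segment with nothing trimmed.
#'
#' @param series a \linkS4class{StateSeries} of a full recording.
#' @param cThreshold capacitance threshold for tracking (default 0.03).
#' @param trimRadius metres to exclude around the turning point (default
#'   0.5).
#' @return list of \linkS4class{StateSeries} segments (possibly empty when
#'   there is no motion), each with attribute \code{"indices"} giving the
#'   original state indices.
#' @export
segmentWalks <- function(series, cThreshold = 0.03, trimRadius = 0.5) {
  stopifnot(is(series, "StateSeries"))
  trk <- .trackSeries(series, cThreshold)
  def <- which(trk$defined)
  if (length(def) < 2L) return(list())
  pos <- trk$pos
  ## dominant axis: larger positional range over defined states
  rng <- apply(pos[def, , drop = FALSE], 2, function(v) diff(range(v)))
  ax <- which.max(rng)
  proj <- pos[, ax]
  excursion <- proj - proj[def[1]]
  turnRel <- which.max(abs(excursion[def]))
  turnIdx <- def[turnRel]
  returns <- abs(proj[def[length(def)]] - proj[turnIdx])
  segIdx <- if (turnRel == length(def) || turnRel == 1L || returns < trimRadius) {
    list(def)  # single pass: no turn inside the recording
  } else {
    turnPos <- pos[turnIdx, ]
    d2turn <- sqrt((pos[, 1] - turnPos[1])^2 + (pos[, 2] - turnPos[2])^2)
    keepMask <- d2turn >= trimRadius
    list(def[def <= turnIdx & keepMask[def]],
         def[def > turnIdx & keepMask[def]])
  }
  segIdx <- Filter(function(ix) length(ix) >= 2, segIdx)
  lapply(segIdx, function(ix) {
    s <- .subsetSeries(series, ix)
    attr(s, "indices") <- ix
    s
  })
}

#' Sliding windows over a vector series
#'
#' Moves a window of \code{length} consecutive steps over the series in
#' increments of \code{stride}. A series shorter than the window yields zero
#' windows.
#'
#' @param n number of steps in the series (or a matrix whose rows are
#'   steps).
#' @param length window length in steps (default 30).
#' @param stride step increment between window starts (default 1).
#' @return integer vector of window start indices (1-based).
#' @export
windowStarts <- function(n, length = 30, stride = 1) {
  if (is.matrix(n)) n <- nrow(n)
  stopifnot(length >= 1, stride >= 1)
  if (n < length) return(integer(0))
  seq.int(1L, n - length + 1L, by = stride)
}

#' @rdname windowStarts
#' @param mat matrix whose rows are the per-step activation vectors.
#' @return \code{windowSeries} returns a list of \code{length} x ncol
#'   matrices.
#' @export
windowSeries <- function(mat, length = 30, stride = 1) {
  starts <- windowStarts(nrow(mat), length, stride)
  lapply(starts, function(s) mat[s:(s + length - 1L), , drop = FALSE])
}

#' Build a leave-one-out cross-validation split plan
#'
#' Two designs: \code{"idiosyncratic"} (intrapersonal; all walks from one
#' participant, one fold per walk with that walk as the test set, the next
#' walk in a fixed rotation as the validation set, the rest training) and
#' \code{"generalised"} (one fold per participant as the test set, a
#' different participant by fixed rotation as the validation set, the rest
#' training; no participant ever appears in more than one of the three sets
#' of a fold).
#'
#' @param walks data.frame with one row per walk, columns \code{walk_id},
#'   \code{participant}, \code{mode}.
#' @param design \code{"idiosyncratic"} or \code{"generalised"}.
#' @return an object of class \code{SplitPlan}: list with elements
#'   \code{design} and \code{folds}, each fold a list of integer row-index
#'   vectors \code{train}, \code{validation}, \code{test}.
#' @export
makeSplits <- function(walks, design = c("idiosyncratic", "generalised")) {
  design <- match.arg(design)
  walks <- as.data.frame(walks)
  n <- nrow(walks)
  if (design == "idiosyncratic") {
    if (length(unique(walks$participant)) != 1L)
      stop("idiosyncratic design requires walks from a single participant")
    if (n < 3L) stop("insufficient data: need at least 3 walks")
    folds <- lapply(seq_len(n), function(i) {
      v <- i %% n + 1L
      list(train = setdiff(seq_len(n), c(i, v)), validation = v, test = i)
    })
  } else {
    parts <- unique(walks$participant)
    if (length(parts) < 3L)
      stop("insufficient data: generalised design needs >= 3 participants")
    folds <- lapply(seq_along(parts), function(i) {
      pTest <- parts[i]
      pVal <- parts[i %% length(parts) + 1L]
      list(train = which(!walks$participant %in% c(pTest, pVal)),
           validation = which(walks$participant == pVal),
           test = which(walks$participant == pTest))
    })
  }
  structure(list(design = design, folds = folds, walk_ids = walks$walk_id),
            class = "SplitPlan")
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat("SplitPlan (", x$design, "): ", length(x$folds), " folds over ",
      length(x$walk_ids), " walks\n", sep = "")
  invisible(x)
}

#' Serialise / load a split plan
#'
#' @param plan a \code{SplitPlan}.
#' @param path JSON file path.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  o$folds <- lapply(o$folds, function(f) lapply(f, as.integer))
  structure(o, class = "SplitPlan")
}

#' Summarise class balance per fold
#'
#' @param walks walk manifest data.frame (with \code{mode}).
#' @param plan a \code{SplitPlan} over those walks.
#' @return data.frame with per-fold walk counts by set and mode.
#' @export
foldBalance <- function(walks, plan) {
  do.call(rbind, lapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    data.frame(fold = i,
               n_train = length(f$train), n_val = length(f$validation),
               n_test = length(f$test),
               train_pos = sum(walks$mode[f$train] != "normal"),
               test_pos = sum(walks$mode[f$test] != "normal"))
  }))
}
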