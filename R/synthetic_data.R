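## Synthetic capacitive-floor gait simulator. Emulates what the analysis
## assumes about real recordings: a walker crossing a floor of square
## modules with 8 triangular fields, capacitance rising where a foot covers
## a field (both feet on one field accumulate), fixed-rate 10 Hz sampling
## with change-triggered per-module message emission, straight out-and-back
## walks, and mode-dependent shifts of the generative gait parameters.

#' Generative gait parameters of a synthetic walking mode
#'
#' Defaults describe a relaxed adult walk: speed 1.35 m/s, step length
#' 0.70 m, step width 0.12 m, 20 % double support. The cadence implied by
#' speed and step length is reported in steps/min. All spreads are standard
#' deviations; the step-time coefficient of variation jitters individual
#' step durations.
#'
#' @param speed walking speed, m/s (> 0).
#' @param stepLength,stepLengthSD mean/SD of step length, m.
#' @param stepWidth,stepWidthSD mean/SD of step width (lateral distance
#'   between left and right footfall lines), m.
#' @param doubleSupport fraction of a step time both feet are grounded, in
#'   [0, 1).
#' @param sway lateral sway amplitude (SD of lateral footfall noise), m.
#' @param stepTimeCV coefficient of variation of individual step times.
#' @param stanceAsymmetry relative extra stance time of the left foot
#'   (e.g. 0.1 = 10 % longer left stance).
#' @return list of class \code{GaitParams} (including the derived
#'   \code{cadence} in steps/min).
#' @export
gaitParams <- function(speed = 1.35, stepLength = 0.70, stepLengthSD = 0.025,
                       stepWidth = 0.12, stepWidthSD = 0.02,
                       doubleSupport = 0.2, sway = 0.015,
                       stepTimeCV = 0.03, stanceAsymmetry = 0) {
  if (speed <= 0 || stepLength <= 0 || stepWidth <= 0)
    stop("invalid gait parameters: means must be positive")
  if (stepLengthSD < 0 || stepWidthSD < 0 || sway < 0 || stepTimeCV < 0)
    stop("invalid gait parameters: spreads must be non-negative")
  if (doubleSupport < 0 || doubleSupport >= 1)
    stop("invalid gait parameters: doubleSupport must lie in [0, 1)")
  structure(list(speed = speed, stepLength = stepLength,
                 stepLengthSD = stepLengthSD, stepWidth = stepWidth,
                 stepWidthSD = stepWidthSD, doubleSupport = doubleSupport,
                 sway = sway, stepTimeCV = stepTimeCV,
                 stanceAsymmetry = stanceAsymmetry,
                 cadence = 60 * speed / stepLength),
            class = "GaitParams")
}

#' Library of walking-mode perturbations
#'
#' Maps each walking mode to a multiplicative/additive perturbation of the
#' baseline (normal) gait parameters. The default magnitudes are qualitative
#' knobs motivated by the gait literature (visual impairment slows walking
#' and increases spatial variability; dual-tasking increases step-time
#' variability; calf fatigue shortens push-off on the loaded side); they are
#' configuration, not measured effect sizes. \code{"strong"} doubles down on
#' the closed-eyes perturbation for clearly separated synthetic conditions;
#' \code{"none"} zeroes every perturbation (all modes generate identical
#' statistics), the null condition for chance-level checks.
#'
#' @param separation \code{"default"}, \code{"strong"} or \code{"none"}.
#' @return named list: mode -> list(mul = multiplicative factors,
#'   add = additive offsets) over \code{\link{gaitParams}} fields.
#' @export
modeLibrary <- function(separation = c("default", "strong", "none")) {
  separation <- match.arg(separation)
  ident <- list(mul = list(), add = list())
  lib <- list(
    normal = ident,
    fast = list(mul = list(speed = 1.25, stepLength = 1.08), add = list()),
    slow = list(mul = list(speed = 0.75, stepLength = 0.92), add = list()),
    closed_eyes = list(mul = list(speed = 0.85, stepLength = 0.90,
                                  stepWidthSD = 2, stepTimeCV = 2),
                       add = list()),
    dual_task = list(mul = list(stepTimeCV = 1.5), add = list()),
    post_uhr = list(mul = list(), add = list(stanceAsymmetry = 0.10)))
  if (separation == "strong")
    lib$closed_eyes <- list(mul = list(speed = 0.75, stepLength = 0.80,
                                       stepWidthSD = 3, stepTimeCV = 3,
                                       sway = 2),
                            add = list())
  if (separation == "none")
    lib <- lapply(lib, function(x) ident)
  lib
}

#' Apply a mode perturbation to baseline gait parameters
#'
#' @param params a \code{\link{gaitParams}} baseline.
#' @param pert one entry of a \code{\link{modeLibrary}}.
#' @return perturbed \code{GaitParams}.
#' @export
applyMode <- function(params, pert) {
  p <- unclass(params)
  for (nm in names(pert$mul)) p[[nm]] <- p[[nm]] * pert$mul[[nm]]
  for (nm in names(pert$add)) p[[nm]] <- p[[nm]] + pert$add[[nm]]
  do.call(gaitParams, p[setdiff(names(p), "cadence")])
}

#' Simulate a straight sequence of footfalls
#'
#' Alternating left/right footfalls along a straight path: forward spacing
#' step length (with noise), lateral offsets of +-(step width)/2 around the
#' path line (with width noise and sway), step times jittered by the
#' step-time CV, and stance intervals of consecutive feet overlapping by the
#' double-support fraction. Uses the R random number generator.
#'
#' @param params a \code{\link{gaitParams}}.
#' @param pathLength path length in metres (> 0).
#' @param start numeric length-2 start position (metres).
#' @param direction numeric length-2 unit walking direction (default +y).
#' @param tStart start time offset in seconds.
#' @param firstFoot \code{"left"} or \code{"right"}.
#' @return data.frame with columns \code{foot}, \code{x}, \code{y},
#'   \code{heading} (radians, walking direction), \code{t_down},
#'   \code{t_up}.
#' @export
simulateFootfalls <- function(params, pathLength, start = c(0, 0),
                              direction = c(0, 1), tStart = 0,
                              firstFoot = "left") {
  stopifnot(inherits(params, "GaitParams"))
  if (pathLength <= 0) stop("pathLength must be positive")
  u <- direction / sqrt(sum(direction^2))
  lat <- c(u[2], -u[1])            # right-hand lateral
  K <- max(2L, floor(pathLength / params$stepLength))
  feet <- rep(if (firstFoot == "left") c("left", "right") else c("right", "left"),
              length.out = K)
  side <- ifelse(feet == "right", 1, -1)
  forward <- seq_len(K) * params$stepLength +
    rnorm(K, 0, params$stepLengthSD)
  lateral <- side * (params$stepWidth + rnorm(K, 0, params$stepWidthSD)) / 2 +
    rnorm(K, 0, params$sway)
  stepTime <- params$stepLength / params$speed
  tDown <- tStart + cumsum(stepTime * (1 + rnorm(K, 0, params$stepTimeCV)))
  stance <- (1 + params$doubleSupport) * stepTime *
    ifelse(feet == "left", 1 + params$stanceAsymmetry, 1)
  data.frame(foot = feet,
             x = start[1] + forward * u[1] + lateral * lat[1],
             y = start[2] + forward * u[2] + lateral * lat[2],
             heading = atan2(u[1], u[2]),
             t_down = tDown, t_up = tDown + stance,
             stringsAsFactors = FALSE)
}

## Regular-grid module indexer for fast point -> module lookup; falls back
## to NULL (full search) for irregular layouts.
.gridIndexer <- function(layout) {
  m <- layout@modules
  if (nrow(m) == 0) return(NULL)
  e <- m$edge[1]
  if (any(abs(m$edge - e) > 1e-12)) return(NULL)
  x0 <- min(m$center_x) - e / 2
  y0 <- min(m$center_y) - e / 2
  ix <- round((m$center_x - x0) / e + 0.5)
  iy <- round((m$center_y - y0) / e + 0.5)
  if (any(abs((ix - 0.5) * e + x0 - m$center_x) > 1e-9) ||
      any(abs((iy - 0.5) * e + y0 - m$center_y) > 1e-9)) return(NULL)
  nx <- max(ix); ny <- max(iy)
  idx <- matrix(0L, nx, ny)
  idx[cbind(ix, iy)] <- seq_len(nrow(m))
  list(x0 = x0, y0 = y0, edge = e, nx = nx, ny = ny, idx = idx)
}

## Deterministic unit-disc sample points (fixed association, no RNG).
.discPoints <- local({
  g <- (seq_len(14) - 0.5) / 7 - 1
  pts <- as.matrix(expand.grid(u = g, v = g))
  pts[pts[, 1]^2 + pts[, 2]^2 <= 1, , drop = FALSE]
})

## Slot of a point in module-local coordinates: quadrants CCW from (+,+),
## x-major triangle first (|lx| >= |ly|), matching .SLOT_OFFSETS.
.slotOf <- function(lx, ly) {
  xmaj <- abs(lx) >= abs(ly)
  qpp <- lx >= 0 & ly >= 0
  qmp <- lx < 0 & ly >= 0
  qmm <- lx < 0 & ly < 0
  ifelse(qpp, ifelse(xmaj, 1L, 2L),
  ifelse(qmp, ifelse(xmaj, 3L, 4L),
  ifelse(qmm, ifelse(xmaj, 5L, 6L), ifelse(xmaj, 7L, 8L))))
}

#' Capacitance contribution of one foot on the floor
#'
#' The foot is modelled as an ellipse; a field's capacitance contribution is
#' \code{gain} times the fraction of the field's area the foot covers
#' (clipped to [0, 1] downstream). The overlap is estimated by deterministic
#' sub-sampling of the ellipse with a fixed point pattern.
#'
#' @param center numeric length-2 foot center (metres).
#' @param heading walking direction in radians (ellipse long axis).
#' @param layout a \linkS4class{FloorLayout} (uniform square modules).
#' @param gain capacitance per fully covered field.
#' @param footLength,footWidth ellipse axes in metres.
#' @return named numeric vector: capacitance contribution per touched
#'   field id.
#' @export
footprintToCapacitance <- function(center, heading, layout, gain = 0.9,
                                   footLength = 0.26, footWidth = 0.10) {
  gi <- .gridIndexer(layout)
  a <- footLength / 2; b <- footWidth / 2
  ## ellipse long axis along the walking direction (+y rotated by heading)
  ex <- .discPoints[, 1] * b; ey <- .discPoints[, 2] * a
  cs <- cos(heading); sn <- sin(heading)
  px <- center[1] + cs * ex + sn * ey
  py <- center[2] - sn * ex + cs * ey
  npts <- length(px)
  ellipseArea <- pi * a * b
  if (is.null(gi)) {
    m <- layout@modules
    mi <- integer(npts)
    for (k in seq_len(npts)) {
      hit <- which(abs(px[k] - m$center_x) <= m$edge / 2 &
                   abs(py[k] - m$center_y) <= m$edge / 2)
      mi[k] <- if (length(hit)) hit[1] else 0L
    }
  } else {
    ix <- floor((px - gi$x0) / gi$edge) + 1
    iy <- floor((py - gi$y0) / gi$edge) + 1
    ok <- ix >= 1 & ix <= gi$nx & iy >= 1 & iy <= gi$ny
    mi <- integer(npts)
    mi[ok] <- gi$idx[cbind(ix[ok], iy[ok])]
  }
  on <- mi > 0L
  if (!any(on)) return(setNames(numeric(0), character(0)))
  m <- layout@modules
  lx <- px[on] - m$center_x[mi[on]]
  ly <- py[on] - m$center_y[mi[on]]
  slot <- .slotOf(lx, ly)
  fid <- .fieldId(m$module_id[mi[on]], slot)
  counts <- tapply(rep(1, length(fid)), fid, sum)
  fArea <- fieldArea(m$edge[1])
  contrib <- gain * pmin(1, (as.numeric(counts) / npts) * ellipseArea / fArea)
  setNames(contrib, names(counts))
}

#' Simulation configuration
#'
#' @param sampleRate capacitance sampling rate in Hz (default 10).
#' @param emissionThreshold per-field capacitance change that triggers a
#'   module message (default 0.02, below the 0.03 analysis threshold so
#'   footfalls are never silently invisible to the tracker).
#' @param footLength,footWidth foot ellipse axes, m (defaults 0.26 x 0.10).
#' @param gain capacitance of a fully covered field (default 0.9).
#' @param noiseSD Gaussian sensor noise SD, clipped to [0, 1] (default
#'   0.005, small against the emission threshold so baseline noise rarely
#'   triggers messages).
#' @param ramp load/unload ramp time in seconds (default 0.2): the foot's
#'   capacitance contribution rises linearly over \code{ramp} after foot
#'   down and falls over \code{ramp} before foot up, emulating roll-over
#'   loading instead of an instantaneous on/off.
#' @param pathLength straight-walk length in metres (default 6).
#' @param turnPause pause at the turning point in seconds (default 1).
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(sampleRate = 10, emissionThreshold = 0.02,
                      footLength = 0.26, footWidth = 0.10, gain = 0.9,
                      noiseSD = 0.005, ramp = 0.2, pathLength = 6,
                      turnPause = 1.0) {
  if (sampleRate <= 0) stop("sampleRate must be positive")
  if (emissionThreshold < 0) stop("emissionThreshold must be >= 0")
  if (ramp < 0) stop("ramp must be >= 0")
  structure(list(sampleRate = sampleRate,
                 emissionThreshold = emissionThreshold,
                 footLength = footLength, footWidth = footWidth, gain = gain,
                 noiseSD = noiseSD, ramp = ramp, pathLength = pathLength,
                 turnPause = turnPause), class = "SimConfig")
}

## Stance loading envelope in [0, 1]: linear rise after foot-down, plateau,
## linear fall before foot-up.
.stanceEnvelope <- function(t, tDown, tUp, ramp) {
  if (ramp <= 0) return(1)
  min(1, (t - tDown) / ramp, (tUp - t) / ramp)
}

#' Change-triggered message emission from a sampled capacitance series
#'
#' A module emits a message at a tick iff at least one of its 8 fields
#' changed by more than the emission threshold since the module's last
#' emitted values; the message then carries all 8 current values. Replaying
#' the emitted stream reconstructs the sampled series to within the
#' threshold per field at every tick.
#'
#' @param cap numeric matrix (ticks x fields) of sampled capacitances.
#' @param times numeric vector of tick times (seconds).
#' @param fields data.frame of fields (\code{field_id}, \code{module_id}) in
#'   column order of \code{cap}.
#' @param threshold emission threshold.
#' @return data.frame of messages (\code{t}, \code{module},
#'   \code{c1}..\code{c8}) in time order.
#' @export
emitMessages <- function(cap, times, fields, threshold) {
  stopifnot(nrow(cap) == length(times), ncol(cap) == nrow(fields))
  modIdx <- split(seq_len(nrow(fields)), fields$module_id)
  ## keep the layout's module order (split() sorts alphabetically)
  modIdx <- modIdx[unique(fields$module_id)]
  last <- matrix(0, length(modIdx), 8)
  rows <- vector("list", 256); nr <- 0L
  for (ti in seq_along(times)) {
    for (mi in seq_along(modIdx)) {
      cur <- cap[ti, modIdx[[mi]]]
      if (any(abs(cur - last[mi, ]) > threshold)) {
        last[mi, ] <- cur
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- c(times[ti], mi, cur)
      }
    }
  }
  if (nr == 0L) {
    out <- as.data.frame(matrix(numeric(), 0, 10))
    names(out) <- c("t", "module", paste0("c", 1:8))
    out$module <- character(0)
    return(out)
  }
  mat <- do.call(rbind, rows[seq_len(nr)])
  out <- data.frame(t = mat[, 1], module = names(modIdx)[mat[, 2]],
                    stringsAsFactors = FALSE)
  caps <- mat[, 3:10, drop = FALSE]
  colnames(caps) <- paste0("c", 1:8)
  cbind(out, as.data.frame(caps))
}

#' Simulate one recording (out-and-back walk) on a floor
#'
#' Simulates footfalls for a pass away from the door and (optionally) a
#' return pass after a turning pause, samples per-field capacitances at the
#' configured rate (contributions of both feet accumulate and are clipped to
#' [0, 1], plus clipped Gaussian sensor noise), and emits change-triggered
#' module messages.
#'
#' @param params a \code{\link{gaitParams}}.
#' @param layout a \linkS4class{FloorLayout}.
#' @param cfg a \code{\link{simConfig}}.
#' @param lane x position of the walking line (default: floor center).
#' @param startY y position where the first footfall line begins (default
#'   0.3 m into the floor).
#' @param outAndBack simulate the return pass (default TRUE).
#' @return list with \code{messages} (data.frame), \code{sampled}
#'   (list \code{times}, \code{cap} of the underlying fixed-rate series),
#'   and \code{footfalls} (ground-truth footfall table).
#' @export
simulateRecording <- function(params, layout, cfg = simConfig(),
                              lane = NULL, startY = 0.3, outAndBack = TRUE) {
  stopifnot(inherits(params, "GaitParams"), is(layout, "FloorLayout"),
            inherits(cfg, "SimConfig"))
  m <- layout@modules
  if (is.null(lane)) lane <- mean(range(c(m$center_x)))
  ff1 <- simulateFootfalls(params, cfg$pathLength, start = c(lane, startY),
                           direction = c(0, 1), tStart = 0.2)
  ff <- ff1
  if (outAndBack) {
    tTurn <- max(ff1$t_up) + cfg$turnPause
    topY <- startY + cfg$pathLength
    ff2 <- simulateFootfalls(params, cfg$pathLength, start = c(lane, topY),
                             direction = c(0, -1), tStart = tTurn,
                             firstFoot = "right")
    ff <- rbind(ff1, ff2)
  }
  duration <- max(ff$t_up) + 0.3
  times <- seq(0, duration, by = 1 / cfg$sampleRate)
  f <- layout@fields
  n <- nrow(f)
  fidIndex <- setNames(seq_len(n), f$field_id)
  cap <- matrix(0, length(times), n)
  for (ti in seq_along(times)) {
    t <- times[ti]
    act <- which(ff$t_down <= t & t <= ff$t_up)
    if (length(act)) {
      acc <- numeric(n)
      for (k in act) {
        env <- .stanceEnvelope(t, ff$t_down[k], ff$t_up[k], cfg$ramp)
        if (env <= 0) next
        contrib <- footprintToCapacitance(c(ff$x[k], ff$y[k]), ff$heading[k],
                                          layout, cfg$gain, cfg$footLength,
                                          cfg$footWidth)
        if (length(contrib)) {
          j <- fidIndex[names(contrib)]
          acc[j] <- acc[j] + env * contrib  # both feet on a field accumulate
        }
      }
      cap[ti, ] <- acc
    }
  }
  if (cfg$noiseSD > 0)
    cap <- cap + rnorm(length(cap), 0, cfg$noiseSD)
  cap <- pmin(pmax(cap, 0), 1)  # first arg keeps the matrix shape
  msgs <- emitMessages(cap, times, f, cfg$emissionThreshold)
  list(messages = msgs, sampled = list(times = times, cap = cap),
       footfalls = ff)
}

#' Generate a synthetic cohort of recordings
#'
#' Draws per-participant latent traits (a latent strength that sets the
#' heel-rise capacity and, with \code{uhrCoupling} > 0, shifts the baseline
#' gait; plus independent participant-to-participant gait variation), then
#' simulates every (participant, mode, repetition) out-and-back recording.
#' Heel-rise counts are a deterministic function of the latent strength plus
#' noise, bounded to the configured range.
#'
#' @param nParticipants number of participants (>= 1).
#' @param layout a \linkS4class{FloorLayout}.
#' @param modes character vector of walking modes to record.
#' @param repsPerMode recordings per participant and mode (default 5).
#' @param modeLib a \code{\link{modeLibrary}}.
#' @param cfg a \code{\link{simConfig}}.
#' @param uhrCoupling strength of the latent-strength -> gait coupling
#'   (0 = none, 1 = strong; default 1).
#' @param uhrRange bounds on heel-rise counts (default c(10, 45)).
#' @param seed integer seed (all randomness funnels through one
#'   \code{set.seed}).
#' @return list with \code{recordings} (list of \code{simulateRecording}
#'   outputs), \code{manifest} (one row per recording: \code{recording_id},
#'   \code{participant}, \code{mode}, \code{rep}), \code{participants}
#'   (latents and heel-rise counts) and \code{layout}.
#' @export
generateCohort <- function(nParticipants, layout,
                           modes = c("normal", "closed_eyes"),
                           repsPerMode = 5, modeLib = modeLibrary(),
                           cfg = simConfig(), uhrCoupling = 1,
                           uhrRange = c(10, 45), seed = 1L) {
  stopifnot(nParticipants >= 1)
  if (!all(modes %in% .WALK_MODES)) stop("unknown walking mode")
  if (!all(modes %in% names(modeLib))) stop("mode missing from mode library")
  set.seed(seed)
  parts <- lapply(seq_len(nParticipants), function(p) {
    s <- rnorm(1)
    base <- gaitParams(
      speed = 1.35 * (1 + 0.08 * uhrCoupling * s) * exp(rnorm(1, 0, 0.04)),
      stepLength = 0.70 * (1 + 0.05 * uhrCoupling * s) * exp(rnorm(1, 0, 0.03)),
      stepWidth = 0.12 * exp(rnorm(1, 0, 0.10)))
    list(id = sprintf("p%02d", p), strength = s, base = base,
         uhr_right = min(uhrRange[2], max(uhrRange[1],
                     round(25 + 7.8 * s + rnorm(1, 0, 2)))),
         uhr_left = min(uhrRange[2], max(uhrRange[1],
                    round(24 + 7.8 * s + rnorm(1, 0, 2)))))
  })
  recordings <- list()
  manifest <- list()
  rid <- 0L
  for (p in parts) {
    for (mode in modes) {
      prm <- applyMode(p$base, modeLib[[mode]])
      for (rep in seq_len(repsPerMode)) {
        rid <- rid + 1L
        recordings[[rid]] <- simulateRecording(prm, layout, cfg)
        manifest[[rid]] <- data.frame(
          recording_id = sprintf("r%04d", rid), participant = p$id,
          mode = mode, rep = rep, stringsAsFactors = FALSE)
      }
    }
  }
  list(recordings = recordings, manifest = do.call(rbind, manifest),
       participants = data.frame(
         participant = vapply(parts, `[[`, "", "id"),
         strength = vapply(parts, `[[`, 1, "strength"),
         speed = vapply(parts, function(p) p$base$speed, 1),
         uhr_left = vapply(parts, `[[`, 1, "uhr_left"),
         uhr_right = vapply(parts, `[[`, 1, "uhr_right"),
         stringsAsFactors = FALSE),
       layout = layout)
}
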