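## Pipeline orchestration: simulate -> preprocess -> train/evaluate, in
## memory or via on-disk run directories with YAML configs, message logs,
## manifests and metrics files.

#' Preprocess a cohort of recordings into labelled walks
#'
#' Replays every recording's message stream, segments it into straight
#' single-pass walks at the turning point, and preprocesses each segment
#' into its grid-activation matrix with its own walking angle. Segment 1 of
#' an out-and-back recording is labelled direction \code{"out"}, segment 2
#' \code{"back"}.
#'
#' @param cohort output of \code{\link{generateCohort}} (or a list with
#'   \code{recordings} carrying \code{messages}, a \code{manifest} and a
#'   \code{layout}).
#' @param cThreshold capacitance threshold (default 0.03).
#' @param spacing,radius receptive-field grid parameters (defaults 0.10 m /
#'   1.0 m).
#' @param trimRadius metres excluded around the turning point (default
#'   0.5).
#' @param windowLength used only to count prospective windows in the
#'   manifest (default 30).
#' @return list with \code{manifest} (one row per walk: \code{walk_id},
#'   \code{participant}, \code{mode}, \code{direction}, \code{n_vectors},
#'   \code{n_windows}, \code{uhr_left}, \code{uhr_right}) and
#'   \code{matrices} (per-walk activation matrices).
#' @export
cohortToWalks <- function(cohort, cThreshold = 0.03, spacing = 0.10,
                          radius = 1.0, trimRadius = 0.5, windowLength = 30) {
  grid <- makeGrid(spacing, radius)
  man <- cohort$manifest
  uhr <- cohort$participants
  matrices <- list()
  rows <- list()
  wid <- 0L
  for (i in seq_len(nrow(man))) {
    msgs <- cohort$recordings[[i]]$messages
    if (nrow(msgs) == 0) next
    series <- replayMessages(cohort$layout, msgs)
    segs <- segmentWalks(series, cThreshold, trimRadius)
    for (si in seq_along(segs)) {
      mat <- tryCatch(
        preprocessWalk(segs[[si]], cThreshold, grid = grid),
        error = function(e) NULL)
      if (is.null(mat)) next
      wid <- wid + 1L
      matrices[[wid]] <- mat
      urow <- uhr[uhr$participant == man$participant[i], , drop = FALSE]
      rows[[wid]] <- data.frame(
        walk_id = sprintf("w%04d", wid),
        recording_id = man$recording_id[i],
        participant = man$participant[i], mode = man$mode[i],
        rep = man$rep[i], direction = if (si == 1) "out" else "back",
        n_vectors = nrow(mat),
        n_windows = max(0L, nrow(mat) - windowLength + 1L),
        uhr_left = if (nrow(urow)) urow$uhr_left else NA_real_,
        uhr_right = if (nrow(urow)) urow$uhr_right else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(manifest = if (wid) do.call(rbind, rows) else NULL,
       matrices = matrices, grid = grid)
}

.resolveConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

.writeRunStamp <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  writeLines(c(paste("capgait", as.character(utils::packageVersion("capgait"))),
               R.version.string),
             file.path(outDir, "versions.txt"))
}

#' Simulate a cohort to disk
#'
#' Writes one JSONL message log per recording, the recording manifest, the
#' participant table, the layout file and the resolved configuration into
#' \code{outDir}.
#'
#' @param config list or YAML path with fields \code{n_participants},
#'   \code{modes}, \code{reps_per_mode}, \code{seed}, optional
#'   \code{separation}, \code{uhr_coupling}, \code{floor} (list nx, ny,
#'   edge) and \code{sim} (overrides for \code{\link{simConfig}}).
#' @param outDir output directory (created).
#' @return the cohort manifest data.frame, invisibly.
#' @export
runSimulate <- function(config, outDir) {
  config <- .resolveConfig(config)
  if (is.null(config$n_participants) || config$n_participants < 1)
    stop("config must give a positive n_participants")
  fl <- config$floor
  layout <- makeFloorGrid(fl$nx %||% 4, fl$ny %||% 18, fl$edge %||% 0.38)
  cfg <- do.call(simConfig, config$sim %||% list())
  cohort <- generateCohort(
    nParticipants = config$n_participants, layout = layout,
    modes = config$modes %||% c("normal", "closed_eyes"),
    repsPerMode = config$reps_per_mode %||% 5,
    modeLib = modeLibrary(config$separation %||% "default"),
    cfg = cfg, uhrCoupling = config$uhr_coupling %||% 1,
    seed = config$seed %||% 1L)
  .writeRunStamp(config, outDir)
  writeFloorLayout(layout, file.path(outDir, "layout.csv"))
  logDir <- file.path(outDir, "messages")
  dir.create(logDir, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$manifest)))
    writeMessageLog(cohort$recordings[[i]]$messages,
                    file.path(logDir, paste0(cohort$manifest$recording_id[i],
                                             ".jsonl")))
  write.csv(cohort$manifest, file.path(outDir, "recordings.csv"),
            row.names = FALSE)
  write.csv(cohort$participants, file.path(outDir, "participants.csv"),
            row.names = FALSE)
  invisible(cohort$manifest)
}

#' Preprocess simulated (or recorded) message logs to walk matrices
#'
#' @param config list or YAML path; fields \code{c_threshold},
#'   \code{spacing}, \code{radius}, \code{trim_radius}, \code{window}.
#' @param simDir directory produced by \code{\link{runSimulate}} (layout,
#'   message logs, manifests).
#' @param outDir output directory for walk matrices and the walk manifest.
#' @return the walk manifest data.frame, invisibly.
#' @export
runPreprocess <- function(config, simDir, outDir) {
  config <- .resolveConfig(config)
  layout <- readFloorLayout(file.path(simDir, "layout.csv"))
  man <- read.csv(file.path(simDir, "recordings.csv"), stringsAsFactors = FALSE)
  participants <- read.csv(file.path(simDir, "participants.csv"),
                           stringsAsFactors = FALSE)
  recs <- lapply(man$recording_id, function(id)
    list(messages = readMessageLog(file.path(simDir, "messages",
                                             paste0(id, ".jsonl")))))
  cohort <- list(recordings = recs, manifest = man,
                 participants = participants, layout = layout)
  walks <- cohortToWalks(cohort,
                         cThreshold = config$c_threshold %||% 0.03,
                         spacing = config$spacing %||% 0.10,
                         radius = config$radius %||% 1.0,
                         trimRadius = config$trim_radius %||% 0.5,
                         windowLength = config$window %||% 30)
  .writeRunStamp(config, outDir)
  matDir <- file.path(outDir, "walks")
  dir.create(matDir, showWarnings = FALSE)
  for (i in seq_along(walks$matrices))
    writePreprocessedWalk(walks$matrices[[i]],
                          file.path(matDir, paste0(walks$manifest$walk_id[i],
                                                   ".csv")))
  write.csv(walks$manifest, file.path(outDir, "walks.csv"), row.names = FALSE)
  invisible(walks$manifest)
}

#' Train and evaluate an experiment design from preprocessed walks
#'
#' Runs \code{\link{runExperiment}} for the configured design and repeats,
#' writing per-fold metrics CSV, the aggregate JSON and (for every repeat)
#' the training seed into \code{outDir}.
#'
#' @param config list or YAML path; fields \code{design} (idio_mode /
#'   gen_mode / gen_uhr), \code{modes}, \code{leg}, \code{window},
#'   \code{stride}, \code{max_windows_per_walk}, \code{repeats},
#'   \code{seed_policy} ("fixed" or "random"), \code{seed}, and training
#'   overrides \code{max_epochs}, \code{patience}, \code{learning_rate},
#'   \code{batch_size}.
#' @param preDir directory produced by \code{\link{runPreprocess}}.
#' @param outDir output directory.
#' @return list of per-repeat experiment results, invisibly.
#' @export
runTrainEval <- function(config, preDir, outDir) {
  config <- .resolveConfig(config)
  man <- read.csv(file.path(preDir, "walks.csv"), stringsAsFactors = FALSE)
  matrices <- lapply(man$walk_id, function(id)
    readPreprocessedWalk(file.path(preDir, "walks", paste0(id, ".csv"))))
  tcfg <- trainingConfig(
    maxEpochs = config$max_epochs %||% 60,
    patience = config$patience %||% 12,
    learningRate = config$learning_rate %||% 1e-3,
    batchSize = config$batch_size %||% 32)
  repeats <- config$repeats %||% 1
  policy <- config$seed_policy %||% "fixed"
  baseSeed <- config$seed %||% 1L
  set.seed(baseSeed)
  seeds <- if (policy == "random") sample.int(1e6, repeats)
           else baseSeed + seq_len(repeats) - 1L
  .writeRunStamp(config, outDir)
  results <- list()
  for (r in seq_len(repeats)) {
    res <- runExperiment(
      design = config$design %||% "gen_mode", manifest = man,
      matrices = matrices,
      modes = config$modes %||% c("normal", "closed_eyes"),
      leg = config$leg %||% "right", tcfg = tcfg,
      windowLength = config$window %||% 30,
      stride = config$stride %||% 1,
      maxWindowsPerWalk = config$max_windows_per_walk %||% Inf,
      seed = seeds[r])
    write.csv(res$folds, file.path(outDir, sprintf("folds_rep%d.csv", r)),
              row.names = FALSE)
    jsonlite::write_json(res$aggregate,
                         file.path(outDir, sprintf("aggregate_rep%d.json", r)),
                         auto_unbox = TRUE, digits = NA)
    results[[r]] <- res
  }
  summary <- data.frame(repeat_ = seq_len(repeats), seed = seeds)
  write.csv(summary, file.path(outDir, "repeats.csv"), row.names = FALSE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
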