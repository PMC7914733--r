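## Recurrent walking-mode classifier / heel-rise regressor. Architecture:
## LSTM layer (output size 20, only the final-step output forwarded) ->
## four dense ReLU layers of 20 units -> head: two softmax units
## (classification) or one ReLU unit (regression). Losses: binary
## cross-entropy / mean squared error. Training: Adam, early stopping on
## the validation loss (patience 12, max 60 epochs by default).

#' Network architecture configuration
#'
#' @param inputSize number of grid cells per step vector.
#' @param windowLength steps per window (default 30).
#' @param recurrentSize LSTM output size (default 20).
#' @param nDenseLayers number of dense layers after the LSTM (default 4).
#' @param denseWidth neurons per dense layer (default 20).
#' @param head \code{"binary_softmax"} (2 softmax outputs) or
#'   \code{"regression_relu"} (1 ReLU output).
#' @return a list of class \code{NetworkConfig}.
#' @export
networkConfig <- function(inputSize, windowLength = 30, recurrentSize = 20,
                          nDenseLayers = 4, denseWidth = 20,
                          head = c("binary_softmax", "regression_relu")) {
  head <- match.arg(head)
  stopifnot(inputSize >= 1, windowLength >= 1, recurrentSize >= 1,
            nDenseLayers >= 1, denseWidth >= 1)
  structure(list(inputSize = as.integer(inputSize),
                 windowLength = as.integer(windowLength),
                 recurrentSize = as.integer(recurrentSize),
                 nDenseLayers = as.integer(nDenseLayers),
                 denseWidth = as.integer(denseWidth), head = head),
            class = "NetworkConfig")
}

#' Training configuration
#'
#' The loss follows the head: binary cross-entropy for classification, mean
#' squared error for regression. Early stopping: any strict improvement of
#' the validation loss resets the patience counter; training never runs past
#' \code{maxEpochs}; the returned weights are those of the best validation
#' epoch.
#'
#' @param maxEpochs maximum training epochs (default 60).
#' @param patience early-stopping patience in epochs (default 12; must be
#'   smaller than \code{maxEpochs}).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize minibatch size (default 32).
#' @return a list of class \code{TrainingConfig}.
#' @export
trainingConfig <- function(maxEpochs = 60, patience = 12,
                           learningRate = 1e-3, batchSize = 32) {
  stopifnot(maxEpochs >= 1, patience >= 1, patience < maxEpochs,
            learningRate > 0, batchSize >= 1)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize)),
            class = "TrainingConfig")
}

.headCode <- function(head) if (head == "binary_softmax") 0L else 1L

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise network weights
#'
#' Glorot-uniform weight initialisation; the LSTM forget-gate bias starts at
#' 1 so memory is retained early in training. Uses the R random number
#' generator, so \code{set.seed} before calling makes the initialisation
#' reproducible.
#'
#' @param cfg a \code{\link{networkConfig}}.
#' @return a list of class \code{capgaitNetwork} holding \code{cfg} and the
#'   weight arrays.
#' @export
buildNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "NetworkConfig"))
  H <- cfg$recurrentSize; D <- cfg$inputSize; W <- cfg$denseWidth
  K <- if (cfg$head == "binary_softmax") 2L else 1L
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget gate bias
  Wd <- vector("list", cfg$nDenseLayers)
  bd <- vector("list", cfg$nDenseLayers)
  prev <- H
  for (l in seq_len(cfg$nDenseLayers)) {
    Wd[[l]] <- .glorot(W, prev)
    bd[[l]] <- numeric(W)
    prev <- W
  }
  ## the regression head starts with a positive bias so the output ReLU is
  ## live at initialisation (count targets are strictly positive)
  bo <- if (cfg$head == "regression_relu") rep(1, K) else numeric(K)
  params <- list(Wx = .glorot(4 * H, D), Wh = .glorot(4 * H, H), b = b,
                 Wd = Wd, bd = bd, Wo = .glorot(K, prev), bo = bo)
  structure(list(cfg = cfg, params = params, history = NULL),
            class = "capgaitNetwork")
}

#' Number of trainable parameters of a network
#'
#' @param model a \code{capgaitNetwork}.
#' @return integer parameter count.
#' @export
nParameters <- function(model) {
  p <- model$params
  n <- length(p$Wx) + length(p$Wh) + length(p$b) +
    sum(vapply(p$Wd, length, 1L)) + sum(vapply(p$bd, length, 1L)) +
    length(p$Wo) + length(p$bo)
  as.integer(n)
}

#' @export
print.capgaitNetwork <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "capgait network: %d inputs x %d steps -> LSTM(%d) -> %d x dense(%d, ReLU) -> %s (%d parameters)\n",
    cfg$inputSize, cfg$windowLength, cfg$recurrentSize, cfg$nDenseLayers,
    cfg$denseWidth, cfg$head, nParameters(x)))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs run, best validation epoch %d (loss %.4g)\n",
                x$history$epochsRun, x$history$bestEpoch, x$history$bestValLoss))
  invisible(x)
}

#' Train a network on windowed sequences
#'
#' Windows are addressed into a stacked step matrix (rows = steps of all
#' walks concatenated) by their start rows, so overlapping windows share
#' storage. Training is fully deterministic for a given \code{seed}.
#'
#' @param model a \code{capgaitNetwork} from \code{\link{buildNetwork}}.
#' @param X numeric matrix of stacked step vectors (rows x inputSize).
#' @param starts integer vector of window start rows (1-based); each window
#'   spans \code{windowLength} consecutive rows.
#' @param y labels: class index 0/1 (classification) or numeric target
#'   (regression), one per window.
#' @param valX,valStarts,valY the validation set in the same format.
#' @param tcfg a \code{\link{trainingConfig}}.
#' @param seed integer seed for minibatch shuffling.
#' @return the trained \code{capgaitNetwork} with a \code{history} element
#'   (per-epoch train/validation losses, best epoch, epochs run).
#' @export
trainNetwork <- function(model, X, starts, y, valX, valStarts, valY,
                         tcfg = trainingConfig(), seed = 1L) {
  stopifnot(inherits(model, "capgaitNetwork"), inherits(tcfg, "TrainingConfig"))
  if (length(starts) == 0L) stop("insufficient data: empty training set")
  cfg <- model$cfg
  stopifnot(ncol(X) == cfg$inputSize,
            max(starts) + cfg$windowLength - 1L <= nrow(X))
  res <- .cg_train(model$params, X, as.integer(starts), as.numeric(y),
                   valX, as.integer(valStarts), as.numeric(valY),
                   list(window = cfg$windowLength, head = .headCode(cfg$head),
                        maxEpochs = tcfg$maxEpochs, patience = tcfg$patience,
                        learningRate = tcfg$learningRate,
                        batchSize = tcfg$batchSize,
                        seed = as.integer(seed %% .Machine$integer.max)))
  model$params <- res$params
  model$history <- list(trainLoss = res$trainLoss, valLoss = res$valLoss,
                        bestEpoch = res$bestEpoch, epochsRun = res$epochsRun,
                        bestValLoss = res$bestValLoss, seed = seed)
  model
}

#' Network predictions for windowed sequences
#'
#' @inheritParams trainNetwork
#' @return classification head: matrix (n x 2) of class probabilities
#'   (columns: class 0, class 1); regression head: numeric vector of
#'   non-negative predictions.
#' @export
predictNetwork <- function(model, X, starts) {
  stopifnot(inherits(model, "capgaitNetwork"))
  out <- .cg_forward(model$params, X, as.integer(starts),
                     model$cfg$windowLength, .headCode(model$cfg$head))
  if (model$cfg$head == "regression_relu") as.numeric(out) else out
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 from binary truth/prediction vectors,
#' with class 1 the positive (interference) class. Ratios with a zero
#' denominator are reported as \code{NA}, never silently as 0.
#'
#' @param truth integer/logical vector of true classes (0/1).
#' @param pred integer/logical vector of predicted classes, or a probability
#'   matrix from \code{\link{predictNetwork}} (argmax is taken).
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1} and the confusion counts \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @export
evaluateClassification <- function(truth, pred) {
  if (is.matrix(pred)) pred <- as.integer(pred[, 2] > pred[, 1])
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(accuracy = (tp + tn) / length(truth), precision = prec, recall = rec,
       f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Regression metrics
#'
#' Root mean square error and the Pearson correlation of predictions against
#' targets. The correlation is \code{NA} when either side is constant.
#'
#' @param truth numeric targets.
#' @param pred numeric predictions.
#' @return list with \code{rmse} and \code{pearson}.
#' @export
evaluateRegression <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  rmse <- sqrt(mean((pred - truth)^2))
  pearson <- if (length(truth) >= 2 && sd(truth) > 0 && sd(pred) > 0)
    cor(truth, pred) else NA_real_
  list(rmse = rmse, pearson = pearson)
}

## Build the window-level design from per-walk activation matrices: stack
## all steps, record window start rows, labels and walk ids. Windows always
## stay within one walk. maxWindowsPerWalk < Inf selects evenly spaced
## starts from the stride-1 set (used to scale experiments down).
#' Assemble windows from per-walk activation matrices
#'
#' @param matrices list of per-walk activation matrices (equal column
#'   counts).
#' @param labels numeric/integer label per walk.
#' @param windowLength steps per window (default 30).
#' @param stride increment between window starts (default 1).
#' @param maxWindowsPerWalk cap on windows per walk; when exceeded, evenly
#'   spaced starts are kept (default \code{Inf}).
#' @return list with \code{X} (stacked step matrix), \code{starts},
#'   \code{y}, \code{walk} (window -> walk index), \code{nWindows} per walk.
#' @export
buildWindowSet <- function(matrices, labels, windowLength = 30, stride = 1,
                           maxWindowsPerWalk = Inf) {
  stopifnot(length(matrices) == length(labels))
  widths <- vapply(matrices, ncol, 1L)
  if (length(unique(widths)) > 1) stop("walks have differing vector widths")
  X <- do.call(rbind, matrices)
  offs <- cumsum(c(0L, vapply(matrices, nrow, 1L)))
  starts <- integer(0); y <- numeric(0); walk <- integer(0)
  nW <- integer(length(matrices))
  for (i in seq_along(matrices)) {
    st <- windowStarts(nrow(matrices[[i]]), windowLength, stride)
    if (length(st) > maxWindowsPerWalk)
      st <- st[round(seq(1, length(st), length.out = maxWindowsPerWalk))]
    nW[i] <- length(st)
    if (length(st)) {
      starts <- c(starts, st + offs[i])
      y <- c(y, rep(labels[i], length(st)))
      walk <- c(walk, rep(i, length(st)))
    }
  }
  list(X = X, starts = starts, y = y, walk = walk, nWindows = nW)
}

.walkMajority <- function(truthByWalk, predClass, walk) {
  walks <- sort(unique(walk))
  wPred <- vapply(walks, function(w)
    as.integer(mean(predClass[walk == w]) > 0.5), 1L)
  list(truth = truthByWalk[walks], pred = wPred)
}

#' Run a cross-validated experiment
#'
#' Orchestrates split construction, per-fold training and evaluation for the
#' three experiment designs: \code{"idio_mode"} (idiosyncratic, per
#' participant, leave-one-walk-out binary mode classification),
#' \code{"gen_mode"} (generalised leave-one-participant-out mode
#' classification) and \code{"gen_uhr"} (generalised heel-rise-count
#' regression from normal-pace walks). Window-level metrics are the primary
#' report; walk-level majority-vote metrics are reported alongside for the
#' classification designs.
#'
#' @param design one of \code{"idio_mode"}, \code{"gen_mode"},
#'   \code{"gen_uhr"}.
#' @param manifest walk manifest data.frame (columns \code{walk_id},
#'   \code{participant}, \code{mode}, and \code{uhr_left}/\code{uhr_right}
#'   for the regression design).
#' @param matrices list of per-walk activation matrices aligned with
#'   \code{manifest} rows.
#' @param modes length-2 character vector \code{c(negative, positive)} for
#'   the classification designs (default normal vs closed eyes).
#' @param leg \code{"right"} or \code{"left"}: which heel-rise count to
#'   regress (default right).
#' @param netCfg \code{\link{networkConfig}} template; \code{inputSize} and
#'   head are filled in automatically when \code{NULL}.
#' @param tcfg a \code{\link{trainingConfig}}.
#' @param windowLength,stride,maxWindowsPerWalk window construction
#'   parameters (see \code{\link{buildWindowSet}}).
#' @param seed integer; per-fold training seeds are derived from it
#'   deterministically.
#' @return list with \code{folds} (per-fold metrics data.frame),
#'   \code{aggregate} (means/SDs over folds), \code{design}, \code{seed};
#'   for the regression design also \code{participants}, the pooled
#'   per-participant table with \code{predicted} (counts),
#'   \code{predicted_norm} (fold-normalised predictions used for the pooled
#'   correlation) and \code{truth}.
#' @export
runExperiment <- function(design = c("idio_mode", "gen_mode", "gen_uhr"),
                          manifest, matrices,
                          modes = c("normal", "closed_eyes"), leg = "right",
                          netCfg = NULL, tcfg = trainingConfig(),
                          windowLength = 30, stride = 1,
                          maxWindowsPerWalk = Inf, seed = 1L) {
  design <- match.arg(design)
  manifest <- as.data.frame(manifest)
  stopifnot(nrow(manifest) == length(matrices))
  classification <- design != "gen_uhr"

  if (classification) {
    sel <- which(manifest$mode %in% modes)
    labels <- as.numeric(manifest$mode[sel] == modes[2])  # positive = interference
  } else {
    sel <- which(manifest$mode == "normal")
    ucol <- paste0("uhr_", leg)
    if (!ucol %in% names(manifest)) stop("manifest lacks column ", ucol)
    labels <- as.numeric(manifest[[ucol]][sel])
  }
  man <- manifest[sel, , drop = FALSE]
  mats <- matrices[sel]
  keep <- vapply(mats, nrow, 1L) >= windowLength
  nDropped <- sum(!keep)
  man <- man[keep, , drop = FALSE]
  mats <- mats[keep]
  labels <- labels[keep]
  if (nrow(man) == 0L) stop("insufficient data: no walk reaches the window length")

  ws <- buildWindowSet(mats, labels, windowLength, stride, maxWindowsPerWalk)
  inputSize <- ncol(ws$X)
  if (is.null(netCfg))
    netCfg <- networkConfig(inputSize, windowLength = windowLength,
                            head = if (classification) "binary_softmax"
                                   else "regression_relu")
  stopifnot(netCfg$inputSize == inputSize,
            (netCfg$head == "binary_softmax") == classification)

  plan <- makeSplits(man, if (design == "idio_mode") "idiosyncratic"
                          else "generalised")
  folds <- list()
  predPool <- list()
  for (fi in seq_along(plan$folds)) {
    f <- plan$folds[[fi]]
    wTrain <- ws$walk %in% f$train
    wVal <- ws$walk %in% f$validation
    wTest <- ws$walk %in% f$test
    if (!any(wTest)) next
    foldSeed <- (seed * 1000L + fi) %% .Machine$integer.max
    set.seed(foldSeed)
    net <- buildNetwork(netCfg)
    ## regression targets are normalised by the training-set mean so the
    ## count scale (tens) stays reachable within Adam's per-parameter step
    ## budget; the unit output bias then starts at the training mean
    yScale <- if (classification) 1 else mean(ws$y[wTrain])
    net <- trainNetwork(net, ws$X, ws$starts[wTrain], ws$y[wTrain] / yScale,
                        ws$X, ws$starts[wVal], ws$y[wVal] / yScale, tcfg,
                        seed = foldSeed)
    pred <- predictNetwork(net, ws$X, ws$starts[wTest])
    predNorm <- pred
    if (!classification) pred <- pred * yScale
    if (classification) {
      m <- evaluateClassification(ws$y[wTest], pred)
      mv <- .walkMajority(setNames(labels, seq_along(labels)),
                          as.integer(pred[, 2] > pred[, 1]),
                          ws$walk[wTest])
      mWalk <- evaluateClassification(mv$truth, mv$pred)
      folds[[length(folds) + 1L]] <- data.frame(
        fold = fi, seed = foldSeed, epochs = net$history$epochsRun,
        best_epoch = net$history$bestEpoch,
        n_test_windows = sum(wTest), accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1,
        walk_accuracy = mWalk$accuracy)
    } else {
      part <- man$participant[ws$walk[wTest]]
      byPart <- tapply(pred, part, mean)
      byPartNorm <- tapply(predNorm, part, mean)
      truthPart <- tapply(ws$y[wTest], part, mean)
      m <- evaluateRegression(ws$y[wTest], pred)
      folds[[length(folds) + 1L]] <- data.frame(
        fold = fi, seed = foldSeed, epochs = net$history$epochsRun,
        best_epoch = net$history$bestEpoch,
        n_test_windows = sum(wTest), rmse = m$rmse)
      predPool[[length(predPool) + 1L]] <- data.frame(
        participant = names(byPart), predicted = as.numeric(byPart),
        predicted_norm = as.numeric(byPartNorm),
        truth = as.numeric(truthPart))
    }
  }
  folds <- do.call(rbind, folds)
  agg <- list(design = design, n_folds = nrow(folds),
              n_dropped_walks = nDropped)
  if (classification) {
    for (col in c("accuracy", "precision", "recall", "f1", "walk_accuracy")) {
      v <- folds[[col]]
      agg[[paste0("mean_", col)]] <- mean(v, na.rm = TRUE)
      agg[[paste0("sd_", col)]] <- sd(v, na.rm = TRUE)
      agg[[paste0("n_na_", col)]] <- sum(is.na(v))
    }
    participants <- list()
  } else {
    participants <- do.call(rbind, predPool)
    agg$mean_rmse <- mean(folds$rmse)
    agg$participant_rmse <-
      evaluateRegression(participants$truth, participants$predicted)$rmse
    ## pooled correlation on the fold-normalised predictions: rescaling each
    ## fold by its own training mean injects a leave-one-out anti-correlation
    ## (the held-out participant is missing from the scale), and correlation
    ## is scale-free anyway
    agg$participant_pearson <-
      evaluateRegression(participants$truth, participants$predicted_norm)$pearson
  }
  list(design = design, seed = seed, folds = folds, aggregate = agg,
       participants = participants, config = list(net = netCfg, train = tcfg,
       windowLength = windowLength, stride = stride,
       maxWindowsPerWalk = maxWindowsPerWalk))
}
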