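# balanced in-memory draw: one seeded stream per category
.sampleBalanced <- function(nPerClass, seed) {
  cats <- names(categoryLabels())
  do.call(rbind, lapply(seq_along(cats), function(i)
    sampleFeatures(cats[i], nPerClass, seed = as.integer(seed) + (i - 1L))))
}

#' Run one full grading experiment
#'
#' Draws a balanced training pool (default 20 lemons per category) and an
#' independent second set (default 10 per category) from the calibrated
#' generator, trains the 7-5-3 network with scaled conjugate gradient, and
#' evaluates both sets: the training-pool accuracy (all 60 lemons, the
#' development data) and the second-set accuracy (held-out fruit).
#'
#' @param seed integer seed controlling generation, splitting and
#'   initialisation.
#' @param nTrainPerClass training-pool lemons per category.
#' @param nSecondPerClass second-set lemons per category.
#' @param config optional \linkS4class{TrainingConfig}; defaults to the
#'   standard setup re-seeded with \code{seed}.
#' @return list with \code{model}, \code{trainReport}, \code{secondReport}
#'   (\linkS4class{EvalReport}s), \code{trainAccuracy},
#'   \code{secondAccuracy}, \code{meanAccuracy} (all percent).
#' @examples
#' ex <- runExperiment(seed = 1)
#' c(ex$trainAccuracy, ex$secondAccuracy)
#' @export
runExperiment <- function(seed = 1, nTrainPerClass = 20, nSecondPerClass = 10,
                          config = NULL) {
  seed <- as.integer(seed)
  if (is.null(config)) config <- trainingConfig(seed = seed)
  pool <- .sampleBalanced(nTrainPerClass, seed)
  second <- .sampleBalanced(nSecondPerClass, seed + 7919L)
  model <- trainGrader(pool, config)
  predPool <- predictGrader(model, pool)
  predSecond <- predictGrader(model, second)
  trainReport <- confusionAndRoc(pool$code, predPool$code,
                                 predPool$probabilities)
  secondReport <- confusionAndRoc(second$code, predSecond$code,
                                  predSecond$probabilities)
  list(model = model, trainReport = trainReport, secondReport = secondReport,
       trainAccuracy = accuracy(trainReport),
       secondAccuracy = accuracy(secondReport),
       meanAccuracy = (accuracy(trainReport) + accuracy(secondReport)) / 2)
}

#' Replicate the grading experiment across seeds
#'
#' Repeats \code{\link{runExperiment}} for \code{nSeeds} consecutive seeds
#' and summarises: per-seed accuracies, their means, the mean of the
#' per-seed {training-pool, second-set} accuracy average, and the modal
#' (majority) training-pool accuracy.
#'
#' @param nSeeds number of replicate seeds (>= 1).
#' @param seed first seed; replicates use seed, seed+1, ...
#' @param nTrainPerClass,nSecondPerClass dataset sizes per category.
#' @param config optional shared \linkS4class{TrainingConfig} template; each
#'   replicate is re-seeded.
#' @return list with \code{perSeed} (data.frame: seed, train_acc, second_acc,
#'   mean_acc), \code{meanTrain}, \code{meanSecond}, \code{meanOfBoth},
#'   \code{majorityTrain} (all percent).
#' @examples
#' replicateExperiment(nSeeds = 2, seed = 1)$meanOfBoth
#' @export
replicateExperiment <- function(nSeeds = 20, seed = 1, nTrainPerClass = 20,
                                nSecondPerClass = 10, config = NULL) {
  if (nSeeds < 1) stop("nSeeds must be >= 1")
  seeds <- as.integer(seed) + seq_len(nSeeds) - 1L
  rows <- lapply(seeds, function(s) {
    cfg <- if (is.null(config)) trainingConfig(seed = s) else
      trainingConfig(splitFractions = config@splitFractions,
                     maxEpochs = config@maxEpochs, patience = config@patience,
                     sigma0 = config@sigma0, lambda0 = config@lambda0,
                     initScale = config@initScale, seed = s)
    ex <- runExperiment(s, nTrainPerClass, nSecondPerClass, cfg)
    data.frame(seed = s, train_acc = ex$trainAccuracy,
               second_acc = ex$secondAccuracy, mean_acc = ex$meanAccuracy)
  })
  perSeed <- do.call(rbind, rows)
  tab <- table(round(perSeed$train_acc, 6))
  majority <- as.numeric(names(tab)[which.max(tab)])
  list(perSeed = perSeed,
       meanTrain = mean(perSeed$train_acc),
       meanSecond = mean(perSeed$second_acc),
       meanOfBoth = mean(perSeed$mean_acc),
       majorityTrain = majority)
}
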