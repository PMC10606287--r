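#' Stratified train/validation/test split
#'
#' Random assignment within each class so the three-way balance survives
#' small n (e.g. 20 per class splits 14/3/3).
#'
#' @param y class labels (codes 1..3).
#' @param fractions length-3 vector (train, validation, test) summing to 1.
#' @param seed integer RNG seed.
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @examples
#' splitStratified(rep(1:3, each = 20), c(0.7, 0.15, 0.15), seed = 1)
#' @export
splitStratified <- function(y, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  .withSeed(seed, {
    tr <- va <- te <- integer(0)
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      n <- length(idx)
      nTr <- round(fractions[1] * n)
      nVa <- round(fractions[2] * n)
      nVa <- min(nVa, n - nTr)
      tr <- c(tr, idx[seq_len(nTr)])
      if (nVa > 0) va <- c(va, idx[nTr + seq_len(nVa)])
      if (n - nTr - nVa > 0) te <- c(te, idx[(nTr + nVa + 1):n])
    }
    list(train = sort(tr), val = sort(va), test = sort(te))
  })
}

#' Train the 7-5-3 network by scaled conjugate gradient
#'
#' Full-batch scaled conjugate gradient (Moller's algorithm): conjugate
#' direction updates with a model-trust scaling parameter lambda adapted by
#' the comparison ratio, and no line search. Training stops at the epoch
#' cap, when the gradient norm falls below \code{gradTol}, or when the
#' validation cross-entropy has not improved for \code{patience} consecutive
#' accepted steps; the weights at the best validation loss are returned.
#'
#' Features must already be standardized with a \linkS4class{Standardizer}
#' fitted on the training split only (see \code{\link{trainGrader}} for the
#' packaged workflow).
#'
#' @param x numeric n x 7 matrix of standardized features.
#' @param y integer labels 1..3.
#' @param config a \linkS4class{TrainingConfig}.
#' @param split optional list(train, val, test) of row indices; by default a
#'   stratified split using the config's fractions and seed.
#' @param gradTol stop when the gradient norm falls below this.
#' @return list with \code{net} (\linkS4class{LemonNet} at the best
#'   validation loss), \code{history} (per-epoch train/val/test
#'   cross-entropy), \code{bestEpoch}, \code{split}.
#' @examples
#' recs <- do.call(rbind, lapply(1:3, function(k) sampleFeatures(k, 20, k)))
#' std <- fitStandardizer(featureMatrix(recs))
#' fit <- scgTrain(standardize(std, featureMatrix(recs)), recs$code,
#'                 trainingConfig(seed = 1, maxEpochs = 50))
#' tail(fit$history, 1)
#' @export
scgTrain <- function(x, y, config = trainingConfig(), split = NULL,
                     gradTol = 1e-6) {
  stopifnot(is(config, "TrainingConfig"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes present")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  if (is.null(split))
    split <- splitStratified(y, config@splitFractions, config@seed)
  Xtr <- x[split$train, , drop = FALSE]; Ytr <- .oneHot(y[split$train])
  Xva <- x[split$val, , drop = FALSE]
  Yva <- if (length(split$val)) .oneHot(y[split$val]) else NULL
  Xte <- x[split$test, , drop = FALSE]
  Yte <- if (length(split$test)) .oneHot(y[split$test]) else NULL

  fE <- function(w) .lossGrad(w, Xtr, Ytr)$loss
  fG <- function(w) .lossGrad(w, Xtr, Ytr)$grad
  valCE <- function(w) if (is.null(Yva)) NA_real_ else
    crossEntropy(.forward(.unflattenNet(w), Xva)$P, Yva)
  testCE <- function(w) if (is.null(Yte)) NA_real_ else
    crossEntropy(.forward(.unflattenNet(w), Xte)$P, Yte)

  w <- .flattenNet(initNetwork(config@seed, config@initScale))
  lambda <- config@lambda0; lambdaBar <- 0
  r <- -fG(w); p <- r
  success <- TRUE
  delta <- 0; p2 <- sum(p^2)
  hist <- vector("list", config@maxEpochs)
  bestVal <- Inf; bestW <- w; bestEpoch <- 0L; stall <- 0L

  for (epoch in seq_len(config@maxEpochs)) {
    if (success) {
      p2 <- sum(p^2)
      if (sqrt(p2) < gradTol) break
      sigmaK <- config@sigma0 / sqrt(p2)
      s <- (fG(w + sigmaK * p) + r) / sigmaK     # r = -grad(w)
      delta <- sum(p * s)
    }
    # model-trust scaling of the local curvature estimate
    delta <- delta + (lambda - lambdaBar) * p2
    if (delta <= 0) {                            # make the Hessian estimate pd
      lambdaBar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    Ew <- fE(w)
    Enew <- fE(w + alpha * p)
    if (!is.finite(Enew) || !is.finite(Ew))
      stop("non-finite training loss at epoch ", epoch,
           " (lambda=", signif(lambda, 3), ", alpha=", signif(alpha, 3), ")")
    Delta <- 2 * delta * (Ew - Enew) / mu^2      # comparison ratio

    if (Delta >= 0) {                            # accept the step
      w <- w + alpha * p
      rNew <- -fG(w)
      lambdaBar <- 0; success <- TRUE
      if (epoch %% .N_PAR == 0) {
        p <- rNew                                # periodic restart
      } else {
        beta <- (sum(rNew^2) - sum(rNew * r)) / mu
        p <- rNew + beta * p
      }
      r <- rNew
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambdaBar <- lambda; success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2

    ce <- c(train = fE(w), val = valCE(w), test = testCE(w))
    hist[[epoch]] <- c(epoch = epoch, ce, accepted = as.numeric(Delta >= 0))

    if (success && !is.na(ce["val"])) {          # early stopping on validation
      if (ce["val"] < bestVal - 1e-12) {
        bestVal <- ce["val"]; bestW <- w; bestEpoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config@patience) break
      }
    }
  }

  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  finalW <- if (is.finite(bestVal)) bestW else w
  if (!is.finite(bestVal)) bestEpoch <- nrow(history)
  list(net = .unflattenNet(finalW), history = history,
       bestEpoch = bestEpoch, split = split)
}

#' Train a full grading model from raw records
#'
#' Packaged workflow: stratified 70/15/15 split, standardizer fitted on the
#' training split only, scaled-conjugate-gradient training with early
#' stopping on the validation split.
#'
#' @param records data.frame of lemon records (needs the seven properties
#'   and a \code{code} column of labels 1..3).
#' @param config a \linkS4class{TrainingConfig}.
#' @return A \linkS4class{LemonGrader}.
#' @examples
#' recs <- do.call(rbind, lapply(1:3, function(k) sampleFeatures(k, 20, k)))
#' model <- trainGrader(recs, trainingConfig(seed = 1, maxEpochs = 60))
#' model
#' @export
trainGrader <- function(records, config = trainingConfig()) {
  x <- featureMatrix(records)
  y <- as.integer(records$code)
  split <- splitStratified(y, config@splitFractions, config@seed)
  std <- fitStandardizer(x[split$train, , drop = FALSE])
  fit <- scgTrain(standardize(std, x), y, config, split = split)
  new("LemonGrader", net = fit$net, standardizer = std,
      history = fit$history, config = config)
}

#' Predict lemon categories
#'
#' Standardizes raw feature rows with the model's fitted standardizer, runs
#' the forward pass, and takes the arg-max class (ties broken toward the
#' lowest class code). A warning is raised when standardized inputs are far
#' outside the training distribution (|z| > 6).
#'
#' @param model a \linkS4class{LemonGrader}.
#' @param records record data.frame or raw n x 7 feature matrix.
#' @return list with \code{code} (integer 1..3), \code{category} (names),
#'   and \code{probabilities} (n x 3 matrix).
#' @examples
#' recs <- do.call(rbind, lapply(1:3, function(k) sampleFeatures(k, 20, k)))
#' model <- trainGrader(recs, trainingConfig(seed = 1, maxEpochs = 60))
#' predictGrader(model, sampleFeatures("CAT_II", 3, 9))$category
#' @export
predictGrader <- function(model, records) {
  stopifnot(is(model, "LemonGrader"))
  x <- if (is.matrix(records)) records else featureMatrix(records)
  z <- standardize(model@standardizer, x)
  if (any(abs(z) > 6))
    warning("feature magnitudes far outside the training distribution")
  p <- forwardPass(model@net, z)
  code <- apply(p, 1, which.max)               # first max = lowest class code
  list(code = as.integer(code),
       category = names(categoryLabels())[code],
       probabilities = p)
}

#' @rdname predictGrader
#' @param object a \linkS4class{LemonGrader}.
#' @param newdata records or feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "LemonGrader", function(object, newdata, ...)
  predictGrader(object, newdata))

#' Save / load a trained grading model as JSON
#'
#' @param model a \linkS4class{LemonGrader}.
#' @param path JSON file path.
#' @return \code{readGraderModel} returns a \linkS4class{LemonGrader};
#'   \code{writeGraderModel} returns \code{path} invisibly.
#' @export
writeGraderModel <- function(model, path) {
  stopifnot(is(model, "LemonGrader"))
  obj <- list(
    shapes = list(input = 7, hidden = 5, output = 3),
    W1 = as.numeric(model@net@W1), b1 = model@net@b1,   # column-major flat
    W2 = as.numeric(model@net@W2), b2 = model@net@b2,
    standardizer = list(center = model@standardizer@center,
                        scale = model@standardizer@scale),
    config = list(splitFractions = model@config@splitFractions,
                  maxEpochs = model@config@maxEpochs,
                  patience = model@config@patience,
                  sigma0 = model@config@sigma0,
                  lambda0 = model@config@lambda0,
                  initScale = model@config@initScale,
                  seed = model@config@seed))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGraderModel
#' @export
readGraderModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- trainingConfig(splitFractions = o$config$splitFractions,
                        maxEpochs = o$config$maxEpochs,
                        patience = o$config$patience,
                        sigma0 = o$config$sigma0, lambda0 = o$config$lambda0,
                        initScale = o$config$initScale, seed = o$config$seed)
  new("LemonGrader",
      net = new("LemonNet", W1 = matrix(o$W1, 7, 5), b1 = as.numeric(o$b1),
                W2 = matrix(o$W2, 5, 3), b2 = as.numeric(o$b2)),
      standardizer = new("Standardizer",
                         center = unlist(o$standardizer$center),
                         scale = unlist(o$standardizer$scale)),
      history = data.frame(), config = cfg)
}
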