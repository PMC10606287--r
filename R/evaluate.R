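#' Confusion matrix, accuracy, per-class TPR and one-vs-rest ROC
#'
#' Builds the 3 x 3 confusion matrix (rows = true class, columns =
#' predicted), the overall accuracy (100 x trace / total), per-class
#' true-positive rates, and — when class probabilities are supplied —
#' one-vs-rest ROC point lists obtained by sweeping a threshold over each
#' class's predicted probability.
#'
#' @param truth true labels (codes 1..3 or category names).
#' @param predictions predicted labels, same length.
#' @param probabilities optional n x 3 matrix of class probabilities.
#' @return An \linkS4class{EvalReport}.
#' @examples
#' truth <- rep(1:3, each = 10)
#' pred <- truth; pred[11:12] <- 3L   # two Category I lemons called II
#' accuracy(confusionAndRoc(truth, pred))  # 93.33
#' @export
confusionAndRoc <- function(truth, predictions, probabilities = NULL) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predictions)) stop("length mismatch")
  tc <- match(.checkCategory(truth), names(categoryLabels()))
  pc <- match(.checkCategory(predictions), names(categoryLabels()))
  cm <- matrix(0L, 3, 3,
               dimnames = list(true = names(categoryLabels()),
                               predicted = names(categoryLabels())))
  for (i in seq_along(tc)) cm[tc[i], pc[i]] <- cm[tc[i], pc[i]] + 1L
  acc <- 100 * sum(diag(cm)) / sum(cm)
  tpr <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)

  roc <- list(); ce <- NA_real_
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    if (nrow(probabilities) != length(tc) || ncol(probabilities) != 3)
      stop("probabilities must be n x 3")
    roc <- lapply(1:3, function(k) {
      pk <- probabilities[, k]
      pos <- tc == k
      thr <- sort(unique(c(-Inf, pk, Inf)), decreasing = TRUE)
      pts <- t(vapply(thr, function(t_) {
        call_pos <- pk >= t_
        c(fpr = sum(call_pos & !pos) / max(sum(!pos), 1),
          tpr = sum(call_pos & pos) / max(sum(pos), 1))
      }, numeric(2)))
      data.frame(fpr = pts[, 1], tpr = pts[, 2], threshold = thr)
    })
    names(roc) <- names(categoryLabels())
    ce <- crossEntropy(probabilities, tc)
  }
  new("EvalReport", confusion = cm, accuracy = acc,
      perClassTPR = as.numeric(tpr), roc = roc, crossEntropy = ce)
}

#' One-way analysis of variance across the three quality groups
#'
#' Classical between/within mean-square F with (k-1, N-k) degrees of
#' freedom and its upper-tail p-value, via \code{stats::oneway.test} with
#' equal variances assumed. The degenerate case of zero variance both
#' between and within groups is flagged rather than erroring.
#'
#' @param groups list of numeric vectors, one per group (each length >= 2).
#' @return list with \code{statistic} (F), \code{p.value}, \code{df1},
#'   \code{df2}, and logical \code{degenerate}.
#' @examples
#' anovaOneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))  # F = 0, p = 1
#' @export
anovaOneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("need at least 2 samples per group")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); N <- length(values)
  within0 <- all(vapply(groups, function(v) stats::var(v) == 0, TRUE))
  if (within0) {
    means <- vapply(groups, mean, 1)
    if (stats::var(means) == 0)
      return(list(statistic = NA_real_, p.value = NA_real_,
                  df1 = k - 1, df2 = N - k, degenerate = TRUE))
    return(list(statistic = Inf, p.value = 0,
                df1 = k - 1, df2 = N - k, degenerate = FALSE))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p.value = unname(fit$p.value),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       degenerate = FALSE)
}
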