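.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.N_W1 <- 7L * 5L; .N_B1 <- 5L; .N_W2 <- 5L * 3L; .N_B2 <- 3L
.N_PAR <- .N_W1 + .N_B1 + .N_W2 + .N_B2

.flattenNet <- function(net)
  c(as.numeric(net@W1), net@b1, as.numeric(net@W2), net@b2)

.unflattenNet <- function(w) {
  stopifnot(length(w) == .N_PAR)
  i <- 0L
  W1 <- matrix(w[i + seq_len(.N_W1)], 7, 5); i <- i + .N_W1
  b1 <- w[i + seq_len(.N_B1)]; i <- i + .N_B1
  W2 <- matrix(w[i + seq_len(.N_W2)], 5, 3); i <- i + .N_W2
  b2 <- w[i + seq_len(.N_B2)]
  new("LemonNet", W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Initialise a 7-5-3 network
#'
#' Weights drawn uniformly on [-initScale, initScale] divided by the square
#' root of each layer's fan-in; biases start at zero.
#'
#' @param seed integer RNG seed.
#' @param initScale half-width of the uniform draw before fan-in scaling.
#' @return A \linkS4class{LemonNet}.
#' @examples
#' initNetwork(seed = 1)
#' @export
initNetwork <- function(seed = 1, initScale = 0.5) {
  .withSeed(seed, {
    new("LemonNet",
        W1 = matrix(stats::runif(35, -initScale, initScale) / sqrt(7), 7, 5),
        b1 = rep(0, 5),
        W2 = matrix(stats::runif(15, -initScale, initScale) / sqrt(5), 5, 3),
        b2 = rep(0, 3))
  })
}

# forward pass keeping hidden activations (for backprop)
.forward <- function(net, X) {
  H <- .sigmoid(sweep(X %*% net@W1, 2, net@b1, "+"))
  P <- .softmax(sweep(H %*% net@W2, 2, net@b2, "+"))
  list(H = H, P = P)
}

#' Forward pass: class probabilities
#'
#' Sigmoid hidden layer then softmax output: rows of the result are valid
#' three-class distributions.
#'
#' @param net a \linkS4class{LemonNet}.
#' @param x numeric matrix n x 7 of standardized features (a single vector
#'   is accepted).
#' @return n x 3 matrix of class probabilities, each row summing to 1.
#' @examples
#' net <- initNetwork(1)
#' forwardPass(net, matrix(0, 1, 7))
#' @export
forwardPass <- function(net, x) {
  stopifnot(is(net, "LemonNet"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != 7) stop("expected 7 features")
  if (any(!is.finite(x))) stop("non-finite feature values")
  .forward(net, x)$P
}

.oneHot <- function(y, k = 3L) {
  y <- as.integer(y)
  stopifnot(all(y %in% seq_len(k)))
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

#' Mean cross-entropy of predicted distributions
#'
#' Mean over samples of -sum(target * log(probability)); probabilities are
#' floored at 1e-12 inside the log for numerical safety.
#'
#' @param p n x 3 matrix of class probabilities.
#' @param y one-hot n x 3 matrix, or integer labels 1..3.
#' @return Scalar loss in nats per sample.
#' @examples
#' crossEntropy(matrix(1/3, 2, 3), c(1L, 2L))  # log(3)
#' @export
crossEntropy <- function(p, y) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  Y <- if (is.matrix(y)) y else .oneHot(y)
  if (!all(dim(p) == dim(Y))) stop("shape mismatch between p and targets")
  -mean(rowSums(Y * log(pmax(p, 1e-12))))
}

# loss and flat gradient of mean cross-entropy w.r.t. all parameters
.lossGrad <- function(w, X, Y) {
  net <- .unflattenNet(w)
  fw <- .forward(net, X)
  n <- nrow(X)
  dZ2 <- (fw$P - Y) / n
  gW2 <- crossprod(fw$H, dZ2)
  gb2 <- colSums(dZ2)
  dH <- (dZ2 %*% t(net@W2)) * fw$H * (1 - fw$H)
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  list(loss = crossEntropy(fw$P, Y),
       grad = c(as.numeric(gW1), gb1, as.numeric(gW2), gb2))
}

#' Gradient of the training loss
#'
#' Analytic backpropagation gradient of the mean cross-entropy with respect
#' to every weight and bias, flattened in (W1, b1, W2, b2) order.
#'
#' @param net a \linkS4class{LemonNet}.
#' @param x n x 7 standardized feature matrix.
#' @param y labels 1..3 or one-hot matrix.
#' @return list(loss, grad) with \code{grad} a length-58 numeric vector.
#' @export
netGradient <- function(net, x, y) {
  stopifnot(is(net, "LemonNet"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  Y <- if (is.matrix(y)) y else .oneHot(y)
  .lossGrad(.flattenNet(net), x, Y)
}
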