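test_that("forward pass produces exact probability simplices", {
  net <- initNetwork(seed = 1)
  x <- matrix(rnorm(70), 10, 7)
  p <- forwardPass(net, x)
  expect_equal(dim(p), c(10L, 3L))
  expect_true(all(p > 0))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-12)
  expect_error(forwardPass(net, matrix(0, 2, 6)), "7 features")
  expect_error(forwardPass(net, c(0, NA, 0, 0, 0, 0, 0)), "non-finite")
})

test_that("a zero network with one output bias has the closed-form softmax", {
  net <- new("LemonNet", W1 = matrix(0, 7, 5), b1 = rep(0, 5),
             W2 = matrix(0, 5, 3), b2 = c(0, 0, 0))
  expect_equal(as.numeric(forwardPass(net, rep(0, 7))), rep(1 / 3, 3),
               tolerance = 1e-14)
  B <- 0.7
  net@b2 <- c(B, 0, 0)
  p <- as.numeric(forwardPass(net, rnorm(7)))   # input is killed by W1 = 0
  expect_equal(p[1], exp(B) / (exp(B) + 2), tolerance = 1e-14)
  expect_equal(p[2], p[3], tolerance = 1e-14)
})

test_that("cross entropy hits its analytic anchors", {
  expect_equal(crossEntropy(matrix(1 / 3, 4, 3), rep(1:2, 2)), log(3),
               tolerance = 1e-14)
  expect_equal(crossEntropy(diag(3), 1:3), 0, tolerance = 1e-12)
  # floor keeps an impossible prediction finite
  expect_true(is.finite(crossEntropy(matrix(c(0, 1, 0), 1, 3), 1L)))
  expect_error(crossEntropy(matrix(1 / 3, 2, 3), 1L), "shape mismatch")
})

test_that("backpropagation matches central finite differences", {
  set.seed(3)
  x <- matrix(rnorm(8 * 7), 8, 7)
  y <- sample(1:3, 8, TRUE)
  net <- initNetwork(seed = 3)
  g <- netGradient(net, x, y)
  expect_length(g$grad, 58)
  w <- lemonGrader:::.flattenNet(net)
  Y <- lemonGrader:::.oneHot(y)
  eps <- 1e-6
  num <- vapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    (lemonGrader:::.lossGrad(wp, x, Y)$loss -
     lemonGrader:::.lossGrad(wm, x, Y)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g$grad)), 1e-6)
})

test_that("the standardizer round-trips and centres the training block", {
  x <- featureMatrix(balancedRecords(10, seed = 2))
  std <- fitStandardizer(x)
  z <- standardize(std, x)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(unstandardize(std, z) - x)), 1e-10)
})

test_that("the stratified split respects fractions and partitions the data", {
  y <- rep(1:3, each = 20)
  sp <- splitStratified(y, c(0.70, 0.15, 0.15), seed = 1)
  expect_length(sp$train, 42); expect_length(sp$val, 9); expect_length(sp$test, 9)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_along(y))
  for (k in 1:3) expect_equal(sum(y[sp$train] == k), 14)
  expect_identical(sp, splitStratified(y, seed = 1))
  expect_false(identical(sp$train, splitStratified(y, seed = 2)$train))
})

test_that("scaled conjugate gradient descends and stops on validation stall", {
  recs <- balancedRecords(20, seed = 1)
  x <- featureMatrix(recs); y <- recs$code
  sp <- splitStratified(y, seed = 1)
  std <- fitStandardizer(x[sp$train, ])
  z <- standardize(std, x)
  fit <- scgTrain(z, y, trainingConfig(seed = 1), split = sp)
  h <- fit$history
  expect_true(all(c("epoch", "train", "val", "test", "accepted") %in% names(h)))
  # training loss at the selected epoch beats the initial loss
  expect_lt(h$train[fit$bestEpoch], h$train[1])
  # best epoch carries the minimum recorded validation cross-entropy
  expect_equal(h$val[fit$bestEpoch], min(h$val), tolerance = 1e-12)
  # early stopping: at most `patience` accepted epochs recorded past the best
  accAfter <- sum(h$accepted[h$epoch > fit$bestEpoch] == 1)
  expect_lte(accAfter, trainingConfig()@patience)
  # the returned network realises the recorded best validation loss
  valCE <- crossEntropy(forwardPass(fit$net, z[sp$val, ]), y[sp$val])
  expect_equal(valCE, min(h$val), tolerance = 1e-10)
})

test_that("training is bit-reproducible for a seed and responsive to it", {
  recs <- balancedRecords(15, seed = 4)
  m1 <- trainGrader(recs, trainingConfig(seed = 9))
  m2 <- trainGrader(recs, trainingConfig(seed = 9))
  expect_identical(lemonGrader:::.flattenNet(m1@net),
                   lemonGrader:::.flattenNet(m2@net))
  m3 <- trainGrader(recs, trainingConfig(seed = 10))
  expect_false(identical(lemonGrader:::.flattenNet(m1@net),
                         lemonGrader:::.flattenNet(m3@net)))
})

test_that("SCG is exactly invariant to a row permutation given the same split", {
  recs <- balancedRecords(15, seed = 6)
  x <- featureMatrix(recs); y <- recs$code
  sp <- splitStratified(y, seed = 2)
  std <- fitStandardizer(x[sp$train, ])
  z <- standardize(std, x)
  set.seed(99); perm <- sample(nrow(z))
  inv <- order(perm)                      # position of original row i in z[perm,]
  sp2 <- lapply(sp, function(ix) sort(inv[ix]))
  f1 <- scgTrain(z, y, trainingConfig(seed = 2), split = sp)
  f2 <- scgTrain(z[perm, ], y[perm], trainingConfig(seed = 2), split = sp2)
  expect_equal(lemonGrader:::.flattenNet(f1$net),
               lemonGrader:::.flattenNet(f2$net), tolerance = 1e-7)
})

test_that("a one-epoch SCG run never worsens the training loss", {
  set.seed(5)
  x <- matrix(rnorm(4 * 7), 4, 7)
  y <- c(1L, 1L, 2L, 2L)
  fit <- scgTrain(x, y, trainingConfig(seed = 1, maxEpochs = 1L),
                  split = list(train = 1:4, val = 1:4, test = integer(0)))
  net0 <- initNetwork(seed = 1, initScale = 0.5)
  l0 <- crossEntropy(forwardPass(net0, x), y)
  l1 <- crossEntropy(forwardPass(fit$net, x), y)
  expect_lte(l1, l0)
})

test_that("prediction reports codes, names and simplex probabilities", {
  recs <- balancedRecords(20, seed = 1)
  model <- trainGrader(recs, trainingConfig(seed = 1))
  pred <- predictGrader(model, recs)
  expect_length(pred$code, nrow(recs))
  expect_true(all(pred$code %in% 1:3))
  expect_identical(pred$category, names(categoryLabels())[pred$code])
  expect_lt(max(abs(rowSums(pred$probabilities) - 1)), 1e-10)
  expect_identical(pred$code,
                   as.integer(apply(pred$probabilities, 1, which.max)))
  # predict() generic delegates
  expect_identical(predict(model, recs)$code, pred$code)
  # out-of-distribution input warns rather than failing
  odd <- recs[1, ]; odd$weight <- 1e4
  expect_warning(predictGrader(model, odd), "outside")
})

test_that("a trained model separates the three grades far above chance", {
  recs <- balancedRecords(20, seed = 1)
  model <- trainGrader(recs, trainingConfig(seed = 1))
  fresh <- balancedRecords(30, seed = 777)
  acc <- mean(predictGrader(model, fresh)$code == fresh$code) * 100
  expect_gt(acc, 80)
})
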