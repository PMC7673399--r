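# End-to-end analytic gradients are validated against central differences
# on a tiny model covering every layer type (graph conv with edge masks,
# batch norm, temporal conv with stride, residual projection, attention,
# pooling, classifier head).

test_that("convolution forward matches the sliding-window oracle", {
  ad <- asNamespace("adcascade")
  set.seed(51)
  for (trial in 1:5) {
    C <- sample(1:3, 1); Cout <- sample(1:4, 1)
    H <- sample(4:9, 1); W <- sample(4:9, 1)
    KH <- sample(1:3, 1); KW <- sample(1:3, 1)
    sh <- sample(1:2, 1); sw <- sample(1:2, 1)
    ph <- sample(0:1, 1); pw <- sample(0:1, 1)
    if ((H + 2 * ph - KH) < 0 || (W + 2 * pw - KW) < 0) next
    x <- array(rnorm(C * H * W * 2), c(C, H, W, 2))
    warr <- array(rnorm(C * KH * KW * Cout), c(C, KH, KW, Cout))
    b <- rnorm(Cout)
    got <- ad$.conv2d_fwd(x, dim(x), matrix(warr, C * KH * KW, Cout), b,
                          KH, KW, sh, sw, ph, pw)
    for (n in 1:2) {
      ref <- oracleConv2d(array(x[, , , n], dim(x)[1:3]), warr, b,
                          sh, sw, ph, pw)
      expect_equal(dim(got)[1:3], dim(ref))
      expect_lt(max(abs(as.numeric(got[, , , n, drop = FALSE]) -
                          as.numeric(ref))), 1e-10)
    }
  }
})

test_that("analytic gradients agree with central differences", {
  ad <- asNamespace("adcascade")
  cfg <- astGcnConfig(channels = c(4, 6), strides = c(1, 2), tKernel = 3,
                      attention = 2, dropout = 0,
                      jointSubset = c(1, 13, 14, 15), attentionKernel = 3)
  m <- astGcnModel(cfg, seed = 3)
  set.seed(52)
  x <- array(rnorm(3 * 32 * 4 * 3), c(3, 32, 4, 3))
  y <- c(1L, 2L, 1L)
  f <- ad$nnModelForward(m@layers, x, training = TRUE)
  ce <- ad$softmaxCrossEntropy(f$y, y)
  bk <- ad$nnModelBackward(f$layers, f$caches, ce$dlogits)
  lossAt <- function(layers) {
    ff <- ad$nnModelForward(layers, x, training = TRUE)
    ad$softmaxCrossEntropy(ff$y, y)$loss
  }
  checks <- list(
    list(2, c("sub", "gc", "params", "W"), 5),
    list(2, c("sub", "gc", "params", "M"), 7),
    list(2, c("sub", "tconv", "params", "W"), 11),
    list(2, c("sub", "bn2", "params", "gamma"), 2),
    list(3, c("sub", "resconv", "params", "W"), 2),
    list(3, c("sub", "resbn", "params", "beta"), 1),
    list(4, c("sub", "c1", "params", "W"), 2),
    list(4, c("sub", "c3", "params", "b"), 1),
    list(6, c("params", "W"), 4),
    list(1, c("params", "beta"), 2))
  eps <- 1e-5
  for (ck in checks) {
    li <- ck[[1]]; path <- ck[[2]]; idx <- ck[[3]]
    mutate <- function(layers, delta) {
      node <- layers[[li]]
      if (length(path) == 4) {
        node$sub[[path[2]]]$params[[path[4]]][idx] <-
          node$sub[[path[2]]]$params[[path[4]]][idx] + delta
      } else {
        node$params[[path[2]]][idx] <- node$params[[path[2]]][idx] + delta
      }
      layers[[li]] <- node
      layers
    }
    num <- (lossAt(mutate(m@layers, eps)) -
              lossAt(mutate(m@layers, -eps))) / (2 * eps)
    g <- bk$grads[[li]]
    for (p in path) g <- g[[p]]
    expect_equal(num, g[idx], tolerance = 1e-4)
  }
})

test_that("stochastic-gradient steps reduce the loss they follow", {
  ad <- asNamespace("adcascade")
  plan <- data.frame(inCh = c(3L, 4L), outCh = c(4L, 8L), ks = c(1L, 4L),
                     kt = c(9L, 9L), stride = c(2L, 4L))
  m <- stCnnModel(stCnnConfig(C = 4, timeExtent = 32, plan = plan),
                  seed = 6)
  set.seed(53)
  x <- array(rnorm(3 * 4 * 32 * 8), c(3, 4, 32, 8))
  y <- rep(1:2, 4)
  layers <- m@layers
  losses <- numeric(20)
  for (i in 1:20) {
    f <- ad$nnModelForward(layers, x, training = TRUE)
    ce <- ad$softmaxCrossEntropy(f$y, y)
    losses[i] <- ce$loss
    b <- ad$nnModelBackward(f$layers, f$caches, ce$dlogits)
    layers <- ad$nnSgdStep(f$layers, b$grads, 0.01)
  }
  expect_lt(losses[20], losses[1])
})
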