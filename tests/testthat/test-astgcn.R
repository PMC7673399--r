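test_that("spatial graph convolution matches the nested-loop oracle", {
  set.seed(11)
  for (trial in 1:10) {
    v <- sample(3:10, 1)
    g <- randomConnectedGraph(v, sample(0:3, 1))
    p <- partitionSpatialConfiguration(g)
    cin <- sample(1:4, 1); cout <- sample(1:5, 1); tt <- sample(1:6, 1)
    x <- array(rnorm(cin * tt * v), c(cin, tt, v))
    w <- array(rnorm(cin * cout * 3), c(cin, cout, 3))
    m <- array(runif(v * v * 3, 0.5, 1.5), c(v, v, 3))
    got <- spatialGraphConv(x, p, w, m)
    ref <- oracleGraphConv(x, p@normalized, m, w)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
  }
})

test_that("unit edge masks reduce the masked form to the unmasked one", {
  set.seed(12)
  g <- randomConnectedGraph(6)
  p <- partitionSpatialConfiguration(g)
  x <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  w <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  ones <- array(1, c(6, 6, 3))
  expect_equal(spatialGraphConv(x, p, w, ones),
               spatialGraphConv(x, p, w))
  # single node with self-loop and identity weights: output equals input
  g1 <- buildSkeletonGraph(matrix(integer(0), 2, 0), 1, 1)
  p1 <- partitionSpatialConfiguration(g1)
  x1 <- array(rnorm(3 * 5 * 1), c(3, 5, 1))
  wId <- array(0, c(3, 3, 3)); wId[, , 1] <- diag(3)
  expect_equal(spatialGraphConv(x1, p1, wId), x1)
})

test_that("st-gcn blocks obey the temporal shape contract", {
  cfg <- astGcnConfig(channels = c(8, 8), strides = c(1, 2), tKernel = 9,
                      attention = "none", dropout = 0)
  m <- astGcnModel(cfg, seed = 2)
  ad <- asNamespace("adcascade")
  x <- array(rnorm(3 * 60 * 15 * 2), c(3, 60, 15, 2))
  f1 <- ad$nnForward(m@layers[[2]], x, training = FALSE)
  expect_equal(dim(f1$y), c(8, 60, 15, 2))        # stride 1 keeps T
  f2 <- ad$nnForward(m@layers[[3]], f1$y, training = FALSE)
  expect_equal(dim(f2$y), c(8, 30, 15, 2))        # stride 2 halves T
})

test_that("a zeroed temporal kernel with no residual yields zero output", {
  cfg <- astGcnConfig(channels = c(8), strides = c(1), tKernel = 9,
                      attention = "none", dropout = 0)
  m <- astGcnModel(cfg, seed = 2)
  blk <- m@layers[[2]]                            # first block: no residual
  blk$sub$tconv$params$W[] <- 0
  blk$sub$tconv$params$b[] <- 0
  ad <- asNamespace("adcascade")
  x <- array(rnorm(3 * 20 * 15), c(3, 20, 15, 1))
  expect_true(all(ad$nnForward(blk, x, training = FALSE)$y == 0))
})

test_that("hourglass attention gates multiplicatively in (1x, 2x)", {
  set.seed(3)
  x <- array(rnorm(4 * 32 * 5 * 2), c(4, 32, 5, 2))
  mod <- hourglassModule(4, kernel = 5, seed = 9)
  y <- hourglassAttention(x, mod)
  expect_equal(dim(y), dim(x))
  ratio <- y / x
  expect_true(all(ratio > 1 & ratio < 2))
  # zeroed gate head gives sigmoid(0) = 0.5, so output = 1.5x
  mod$sub$c3$params$W[] <- 0
  mod$sub$c3$params$b[] <- 0
  expect_equal(hourglassAttention(x, mod), 1.5 * x)
  # temporal extents not divisible by 16 are padded internally
  x2 <- array(rnorm(4 * 15 * 5), c(4, 15, 5))
  expect_equal(dim(hourglassAttention(x2, hourglassModule(4))), dim(x2))
})

test_that("forward scores are softmax-normalized, batched and order-stable", {
  cfg <- tinyGaitConfig()
  m <- astGcnModel(cfg, seed = 5)
  set.seed(6)
  x <- array(rnorm(3 * 60 * 15 * 5), c(3, 60, 15, 5))
  s <- astGcnForward(m, x)
  expect_equal(dim(s), c(2, 5))
  expect_equal(colSums(s), rep(1, 5))
  # permuting clips permutes outputs identically (no cross-clip mixing)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(astGcnForward(m, x[, , , perm]), s[, perm])
  # determinism in evaluation mode
  expect_identical(astGcnForward(m, x), s)
  # zeroed classification head gives uniform scores
  m2 <- m
  m2@layers[[length(m2@layers)]]$params$W[] <- 0
  m2@layers[[length(m2@layers)]]$params$b[] <- 0
  expect_equal(astGcnForward(m2, x), matrix(0.5, 2, 5),
               ignore_attr = TRUE)
  # joint-count mismatch is rejected
  expect_error(astGcnForward(m, array(0, c(3, 60, 25, 1))),
               "does not match")
})

test_that("attention placement 'none' leaves no gate parameters", {
  mNone <- astGcnModel(tinyGaitConfig("none"), seed = 1)
  mAtt <- astGcnModel(tinyGaitConfig("att"), seed = 1)
  types <- vapply(mNone@layers, function(l) l$type, character(1))
  expect_false("attention" %in% types)
  expect_true("attention" %in%
                vapply(mAtt@layers, function(l) l$type, character(1)))
  expect_lt(parameterCount(mNone), parameterCount(mAtt))
  expect_error(astGcnConfig(channels = c(8, 8), strides = c(1, 1),
                            attention = "after-9"),
               "outside")
})

test_that("parameter counting sums every learnable scalar", {
  ad <- asNamespace("adcascade")
  fc <- ad$withSeed(1, ad$nnFC(256, 2))
  expect_equal(ad$countLayerParams(fc), 514)      # 256*2 weights + 2 biases
  fc4 <- ad$withSeed(1, ad$nnFC(256, 4))
  expect_equal(ad$countLayerParams(fc4) - ad$countLayerParams(fc), 514)
  # count is an architecture property: unchanged by a training step
  m <- astGcnModel(tinyGaitConfig(), seed = 3)
  n0 <- parameterCount(m)
  clips <- extractClips(randomRecord(T = 60, seed = 2), 60, 3,
                        label = "HC")
  sel <- selectJoints(clips, defaultJointSubset())
  fit <- trainModel(m, sel, config = trainConfig("gait", epochs = 1L,
                                                 batchSize = 4L))
  expect_equal(parameterCount(fit$model), n0)
})
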