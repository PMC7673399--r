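test_that("st-cnn modules meet the shape contracts", {
  set.seed(21)
  x <- array(rnorm(3 * 62 * 512), c(3, 62, 512))
  m1 <- stCnnModule(x, 3, 4, ks = 1, kt = 33, stride = 1, seed = 1)
  expect_equal(dim(m1$y), c(4, 62, 512))
  m2 <- stCnnModule(m1$y, 4, 4, ks = 15, kt = 33, stride = 4, seed = 2)
  expect_equal(dim(m2$y), c(4, 62, 128))
  m3 <- stCnnModule(m2$y, 4, 16, ks = 62, kt = 33, stride = 1, seed = 3)
  expect_equal(dim(m3$y), c(16, 1, 128))     # full-extent valid convolution
  expect_error(stCnnModule(m3$y, 16, 8, ks = 2, kt = 33),
               "exceeds electrode extent")
})

test_that("modules equal the composition of two brute-force convolutions", {
  set.seed(22)
  for (trial in 1:6) {
    cin <- sample(1:3, 1); cout <- sample(1:4, 1)
    h <- sample(4:8, 1); w <- sample(8:16, 1)
    ks <- sample(seq(1, h, by = 2), 1)
    kt <- sample(c(3, 5), 1)
    stride <- sample(c(1, 2), 1)
    x <- array(rnorm(cin * h * w), c(cin, h, w))
    res <- stCnnModule(x, cin, cout, ks, kt, stride, seed = trial)
    wgt <- res$weights
    ws4 <- array(wgt$spatialW, c(cin, ks, 1, cout))
    mid <- oracleConv2d(x, ws4, wgt$spatialB, 1, 1,
                        if (ks < h) (ks - 1) %/% 2 else 0, 0)
    wt4 <- array(0, c(cout, 1, kt, cout))
    wt4[, 1, , ] <- wgt$temporalW
    ref <- oracleConv2d(mid, wt4, wgt$temporalB, 1, stride, 0,
                        (kt - 1) %/% 2)
    expect_lt(max(abs(res$y - ref)) / max(1, max(abs(ref))), 1e-5)
  }
})

test_that("the default network flattens to 256 features and runs", {
  m <- stCnnModel(seed = 7)
  expect_equal(flattenLength(m), 256L)
  set.seed(23)
  x <- array(rnorm(3 * 62 * 512 * 3), c(3, 62, 512, 3))
  s <- stCnnForward(m, x)
  expect_equal(dim(s), c(2, 3))
  expect_equal(colSums(s), rep(1, 3))
  expect_identical(stCnnForward(m, x), s)        # eval-mode determinism
  # zeroed head -> uniform scores
  m2 <- m
  m2@layers[[length(m2@layers)]]$params$W[] <- 0
  m2@layers[[length(m2@layers)]]$params$b[] <- 0
  expect_equal(stCnnForward(m2, x), matrix(0.5, 2, 3), ignore_attr = TRUE)
  expect_error(stCnnForward(m, array(0, c(3, 62, 256, 1))),
               "does not match")
})

test_that("identical depth planes make the first layers plane-symmetric", {
  m <- stCnnModel(seed = 8)
  set.seed(24)
  plane <- array(rnorm(62 * 512), c(62, 512, 1))
  ep <- methods::new("EEGEpochSet", data = plane, subjectId = "s",
                     label = NA_character_, window = 256L,
                     channelLabels = sprintf("ch%02d", 1:62))
  x <- epochTensor(ep, 1)
  expect_identical(x[1, , ], x[2, , ])
  expect_identical(x[1, , ], x[3, , ])
  s1 <- stCnnForward(m, array(x, c(dim(x), 1)))
  xperm <- x[c(3, 1, 2), , ]
  s2 <- stCnnForward(m, array(xperm, c(dim(x), 1)))
  expect_equal(s1, s2)
})
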