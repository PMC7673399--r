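test_that("common-average re-referencing drops Ref/Gnd and zero-means", {
  set.seed(31)
  rec <- eegRecord("e1", matrix(rnorm(64 * 200), 64, 200), 250)
  car <- rereferenceCommonAverage(rec)
  expect_equal(nrow(car@data), 62L)
  expect_false(any(c("Ref", "Gnd") %in% car@channelLabels))
  expect_lt(max(abs(colMeans(car@data))), 1e-10)
  # constant channels become exactly zero
  flat <- flatEegRecord(3.7)
  expect_true(all(rereferenceCommonAverage(flat)@data == 0))
  # once Ref/Gnd are gone, re-applying (skipping removal) is a no-op
  again <- rereferenceCommonAverage(car, refLabels = character(0))
  expect_lt(max(abs(again@data - car@data)), 1e-12)
  expect_error(rereferenceCommonAverage(car), "not found")
})

test_that("downsampling decimates with an anti-alias filter", {
  n <- 5000
  t <- seq_len(n) / 5000
  rec <- eegRecord("e1", rbind(rep(2.5, n), sin(2 * pi * 10 * t)),
                   5000, channelLabels = c("a", "b"))
  ds <- downsampleRecord(rec, 250)
  expect_equal(ncol(ds@data), 250L)
  expect_equal(ds@samplingRate, 250)
  # DC preserved
  expect_lt(max(abs(ds@data[1, ] - 2.5)), 1e-6)
  # 10 Hz amplitude within 1%: sine-fit oracle
  tt <- seq_len(250) / 250
  fit <- lm(ds@data[2, ] ~ sin(2 * pi * 10 * tt) + cos(2 * pi * 10 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.01)
  # unit factor is the identity
  expect_identical(downsampleRecord(ds, 250)@data, ds@data)
  expect_error(downsampleRecord(rec, 313), "not an integer multiple")
})

test_that("epoching concatenates index-aligned pairs and replicates depth", {
  set.seed(32)
  mk <- function(cond) {
    r <- eegRecord("s1", matrix(rnorm(62 * 2100), 62, 2100), 250, cond,
                   channelLabels = sprintf("ch%02d", 1:62))
    r
  }
  open <- mk("eyes_open"); closed <- mk("eyes_closed")
  # floor(2100/256) = 8 windows available
  ep <- extractEpochs(open, closed, window = 256, epochsPerSubject = 8)
  expect_equal(nEpochs(ep), 8L)
  # index-aligned pairing: epoch 3 = open window 3 then closed window 3
  w3 <- 2 * 256 + 1:256
  expect_equal(ep@data[, 1:256, 3], open@data[, w3])
  expect_equal(ep@data[, 257:512, 3], closed@data[, w3])
  # depth replication is exact
  tens <- epochTensor(ep, 5)
  expect_equal(dim(tens), c(3, 62, 512))
  expect_identical(tens[1, , ], tens[2, , ])
  expect_identical(tens[2, , ], tens[3, , ])
  # requesting more than available names the achievable count
  expect_error(extractEpochs(open, closed, epochsPerSubject = 9),
               "only 8")
  # available window count matches brute-force enumeration
  for (n in c(256, 300, 511, 512, 1024, 2100)) {
    sub <- eegRecord("s1", open@data[, seq_len(n), drop = FALSE], 250,
                     "eyes_open", sprintf("ch%02d", 1:62))
    subC <- eegRecord("s1", closed@data[, seq_len(n), drop = FALSE], 250,
                      "eyes_closed", sprintf("ch%02d", 1:62))
    avail <- n %/% 256
    if (avail >= 1) {
      got <- extractEpochs(sub, subC, 256, epochsPerSubject = avail)
      expect_equal(nEpochs(got), avail)
    }
    if (avail < 9)
      expect_error(extractEpochs(sub, subC, 256, epochsPerSubject = 9))
  }
})

test_that("epoch-wise splitting is exact, disjoint and reproducible", {
  set.seed(33)
  sets <- lapply(1:8, function(i) {
    plane <- array(rnorm(4 * 20 * 15), c(4, 20, 15))
    methods::new("EEGEpochSet", data = plane,
                 subjectId = rep(sprintf("s%d", i), 15),
                 label = rep(if (i <= 4) "MCI" else "AD", 15),
                 window = 10L, channelLabels = sprintf("c%d", 1:4))
  })
  all <- bindEpochSets(sets)
  expect_equal(nEpochs(all), 120L)
  sp <- splitEpochs(all, 0.75, seed = 5)
  expect_equal(nEpochs(sp$train), 90L)
  expect_equal(nEpochs(sp$test), 30L)
  # reproducible and disjoint/exhaustive
  sp2 <- splitEpochs(all, 0.75, seed = 5)
  expect_identical(sp$train@data, sp2$train@data)
  key <- function(s) paste(s@subjectId,
                           round(apply(s@data, 3, sum), 10))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(all))
  # subject-wise mode keeps each subject on one side
  sps <- splitEpochs(all, 0.75, seed = 5, by = "subject")
  expect_length(intersect(unique(sps$train@subjectId),
                          unique(sps$test@subjectId)), 0L)
  expect_error(splitEpochs(subsetEpochs(all, integer(0))), "empty")
})
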