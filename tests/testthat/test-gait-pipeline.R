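test_that("x-axis rotation matches the direct matrix-vector oracle", {
  rec <- skeletonRecord("s", array(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                                   c(3, 3, 1)))
  rot <- rotateRecord(rec, -27)
  # x-axis vector is invariant
  expect_equal(rot@coords[, 1, 1], c(1, 0, 0))
  # unit y vector: cos/sin of -27 degrees
  expect_equal(round(rot@coords[, 2, 1], 5), c(0, 0.89101, -0.45399))
  expect_equal(rot@coords[, 2, 1], oracleRotateX(c(0, 1, 0), -27))
  expect_equal(rot@coords[, 3, 1], oracleRotateX(c(0, 0, 1), -27))
  # zero angle is the identity
  expect_equal(rotateRecord(rec, 0)@coords, rec@coords)
})

test_that("rotation preserves norms and composes with its inverse", {
  rec <- randomRecord(V = 25, T = 7, seed = 42)
  for (theta in c(-27, 13.5, 161)) {
    rot <- rotateRecord(rec, theta)
    n0 <- sqrt(colSums(matrix(rec@coords, 3)^2))
    n1 <- sqrt(colSums(matrix(rot@coords, 3)^2))
    expect_lt(max(abs(n0 - n1)), 1e-9)
    back <- rotateRecord(rot, -theta)
    expect_lt(max(abs(back@coords - rec@coords)), 1e-9)
  }
})

test_that("rotation rejects non-finite coordinates with a diagnostic", {
  bad <- randomRecord(seed = 1)
  expect_error(skeletonRecord("s", array(c(NaN, bad@coords[-1]),
                                         dim(bad@coords))),
               "non-finite")
})

test_that("centering subtracts the root joint frame-wise", {
  rec <- randomRecord(V = 25, T = 6, seed = 7)
  cen <- centerRecord(rec)
  # root joint exactly zero in every frame
  expect_true(all(cen@coords[, 1, ] == 0))
  # the example: root (1,1,1), joint (2,3,4) -> (1,2,3)
  x <- array(0, c(3, 2, 1))
  x[, 1, 1] <- c(1, 1, 1); x[, 2, 1] <- c(2, 3, 4)
  expect_equal(centerRecord(skeletonRecord("s", x))@coords[, 2, 1],
               c(1, 2, 3))
  # idempotent
  expect_equal(centerRecord(cen)@coords, cen@coords)
  # already-centered frame unchanged
  expect_equal(centerRecord(cen, 1)@coords, cen@coords)
  expect_error(centerRecord(rec, 26), "out of range")
})

test_that("clip extraction follows the sliding-window arithmetic", {
  expect_equal(nClips(extractClips(randomRecord(T = 60), 60, 3)), 1L)
  cl66 <- extractClips(randomRecord(T = 66), 60, 3)
  expect_equal(nClips(cl66), 3L)
  expect_warning(cl59 <- extractClips(randomRecord(T = 59), 60, 3),
                 "no clips")
  expect_equal(nClips(cl59), 0L)
  # starts are 0, stride, 2*stride: clip 2 equals frames 4..63
  rec <- randomRecord(T = 66, seed = 3)
  expect_equal(clipArray(cl66 <- extractClips(rec, 60, 3), 2),
               aperm(rec@coords[, , 4:63], c(1, 3, 2)))
  expect_equal(dim(cl66@data)[1:3], c(3L, 60L, 25L))
})

test_that("clip counts match brute-force window enumeration (L in 0..400)", {
  rec400 <- randomRecord(T = 400, seed = 9)
  for (L in c(1:5, 57:63, 100, 399, 400)) {
    sub <- skeletonRecord("s", rec400@coords[, , seq_len(L), drop = FALSE])
    got <- suppressWarnings(nClips(extractClips(sub, 60, 3)))
    expect_identical(got, oracleWindowCount(L, 60L, 3L))
  }
})

test_that("joint selection keeps the right slices in ascending order", {
  rec <- randomRecord(T = 62, seed = 5)
  clips <- extractClips(rec, 60, 3)
  sel <- selectJoints(clips, defaultJointSubset())
  expect_equal(dim(sel@data), c(3, 60, 15, 1))
  expect_equal(sel@jointIndices, defaultJointSubset())
  # slice-comparison oracle
  expect_equal(sel@data[, , , 1], clips@data[, , defaultJointSubset(), 1])
  # full subset is the identity
  all25 <- selectJoints(clips, 1:25)
  expect_equal(all25@data, clips@data)
  expect_error(selectJoints(clips, c(1, 26)), "not present")
  # second selection from an already-reduced set works on original indices
  again <- selectJoints(sel, c(1, 13, 14))
  expect_equal(dim(again@data)[3], 3L)
})
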