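test_that("graph construction validates and exposes binary adjacency", {
  g <- buildSkeletonGraph(matrix(c(1, 2), 2), 2, 1)
  expect_equal(adjacencyMatrix(g), matrix(c(0, 1, 1, 0), 2))
  expect_error(buildSkeletonGraph(matrix(c(1, 1), 2), 2, 1), "self-edge")
  expect_error(buildSkeletonGraph(matrix(c(1, 3), 2), 2, 1), "out of range")
  expect_error(buildSkeletonGraph(matrix(c(1, 2, 2, 1), 2), 2, 1),
               "duplicate")
})

test_that("the 25-joint skeleton is a connected spanning tree", {
  g <- buildSkeletonGraph(kinectEdges(), 25, 1)
  expect_equal(ncol(g@edges), 24L)
  d <- oracleBfs(adjacencyMatrix(g), 1)
  expect_true(all(is.finite(d)))
})

test_that("the induced key-point subgraph is bridged and connected", {
  g <- buildSkeletonGraph(kinectEdges(), 25, 1)
  sub <- inducedSkeletonGraph(g, defaultJointSubset())
  expect_equal(sub@V, 15L)
  expect_equal(ncol(sub@edges), 14L)          # still a tree
  expect_true(all(is.finite(oracleBfs(adjacencyMatrix(sub),
                                      sub@centerIndex))))
  # set-membership oracle: every non-bridge edge exists in the full graph
  # under the index remap
  keep <- defaultJointSubset()
  fullKeys <- paste(pmin(kinectEdges()[1, ], kinectEdges()[2, ]),
                    pmax(kinectEdges()[1, ], kinectEdges()[2, ]))
  bridgeKeys <- paste(pmin(defaultJointBridges()[1, ],
                           defaultJointBridges()[2, ]),
                      pmax(defaultJointBridges()[1, ],
                           defaultJointBridges()[2, ]))
  mapped <- rbind(keep[sub@edges[1, ]], keep[sub@edges[2, ]])
  keys <- paste(pmin(mapped[1, ], mapped[2, ]), pmax(mapped[1, ], mapped[2, ]))
  expect_true(all(keys %in% c(fullKeys, bridgeKeys)))
})

test_that("spatial-configuration partition follows center distances", {
  # 3-node path a-b-c with center a: for root b, a is centripetal and c
  # centrifugal
  g <- buildSkeletonGraph(matrix(c(1, 2, 2, 3), 2), 3, 1)
  p <- partitionSpatialConfiguration(g)
  expect_equal(p@masks[2, 1, 2], 1)   # neighbour a of root b: centripetal
  expect_equal(p@masks[2, 3, 3], 1)   # neighbour c of root b: centrifugal
  expect_equal(p@masks[, , 1], diag(3))
})

test_that("partition masks are binary, disjoint and complete wrt A + I", {
  set.seed(20)
  graphs <- c(lapply(c(5, 12, 25), function(v) randomConnectedGraph(v)),
              lapply(c(8, 25), function(v) randomConnectedGraph(v, 4L)),
              list(buildSkeletonGraph(kinectEdges(), 25, 1)))
  for (g in graphs) {
    p <- partitionSpatialConfiguration(g)
    a <- adjacencyMatrix(g)
    expect_true(all(p@masks %in% c(0, 1)))
    total <- p@masks[, , 1] + p@masks[, , 2] + p@masks[, , 3]
    expect_identical(total, a + diag(g@V))
    expect_identical(p@masks, oracleMasks(a, g@centerIndex))
  }
})

test_that("disconnected graphs are rejected naming the stranded nodes", {
  g <- buildSkeletonGraph(matrix(c(1, 2), 2), 4, 1)
  expect_error(partitionSpatialConfiguration(g), "3, 4")
})

test_that("degree normalization matches closed forms and stays symmetric", {
  expect_equal(normalizeAdjacency(matrix(1, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalizeAdjacency(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  set.seed(4)
  for (rep in 1:5) {
    g <- randomConnectedGraph(10, 3L)
    ai <- adjacencyMatrix(g) + diag(10)
    norm <- normalizeAdjacency(ai)
    expect_lt(max(abs(norm - t(norm))), 1e-12)
    expect_lt(max(abs(eigen(norm, only.values = TRUE)$values)), 1 + 1e-9)
  }
  # zero-degree rows are guarded
  m <- matrix(0, 2, 2); m[1, 1] <- 1
  expect_equal(normalizeAdjacency(m)[2, ], c(0, 0))
})

test_that("subset normalization shares the degrees of the full A + I", {
  g <- buildSkeletonGraph(kinectEdges(), 25, 1)
  p <- partitionSpatialConfiguration(g)
  degrees <- rowSums(adjacencyMatrix(g)) + 1
  for (k in 1:3) {
    expect_equal(p@normalized[[k]],
                 p@masks[, , k] * outer(1 / sqrt(degrees),
                                        1 / sqrt(degrees)))
  }
  # the three normalized subsets sum to the normalized full operator
  full <- normalizeAdjacency(adjacencyMatrix(g) + diag(25))
  expect_equal(p@normalized[[1]] + p@normalized[[2]] + p@normalized[[3]],
               full)
})
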