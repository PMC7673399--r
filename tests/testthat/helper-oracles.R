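# Brute-force oracles and small fixtures shared across tests. Each oracle is
# an independent, naive re-derivation of the quantity it checks; none calls
# the package's optimized code paths.

# random skeleton record with V joints and T frames
randomRecord <- function(subjectId = "s1", V = 25L, T = 10L, seed = 1L) {
  set.seed(seed)
  skeletonRecord(subjectId, array(rnorm(3 * V * T), c(3L, V, T)))
}

# direct 3x3 rotation about the x axis (degrees), matrix-vector oracle
oracleRotateX <- function(v, thetaDeg) {
  th <- thetaDeg * pi / 180
  r <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  as.numeric(r %*% v)
}

# enumerate sliding-window start offsets
oracleWindowCount <- function(L, window, stride) {
  starts <- seq(1L, max(L, 1L), by = stride)
  sum(starts + window - 1L <= L)
}

# breadth-first-search hop distances on an adjacency matrix
oracleBfs <- function(a, from) {
  v <- nrow(a)
  dist <- rep(Inf, v)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    for (j in which(a[i, ] > 0)) {
      if (!is.finite(dist[j])) {
        dist[j] <- dist[i] + 1
        queue <- c(queue, j)
      }
    }
  }
  dist
}

# spatial-configuration assignment from first principles
oracleMasks <- function(a, center) {
  v <- nrow(a)
  d <- oracleBfs(a, center)
  m <- array(0, c(v, v, 3L))
  for (i in seq_len(v)) {
    m[i, i, 1L] <- 1
    for (j in which(a[i, ] > 0)) {
      if (d[j] <= d[i]) m[i, j, 2L] <- 1 else m[i, j, 3L] <- 1
    }
  }
  m
}

# random connected graph on v nodes: random spanning tree + optional extras
randomConnectedGraph <- function(v, extra = 0L) {
  edges <- cbind(2:v, vapply(2:v, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  if (extra > 0L && v > 2L) {
    for (k in seq_len(extra)) {
      pair <- sort(sample.int(v, 2L))
      key <- paste(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
      if (!paste(pair[1], pair[2]) %in% key)
        edges <- rbind(edges, pair)
    }
  }
  buildSkeletonGraph(t(edges), v, 1L)
}

# nested-loop spatial graph convolution (loops over nodes, subsets,
# channels and frames; no matrix algebra)
oracleGraphConv <- function(features, ahat, masks, weights) {
  dIn <- dim(features)
  cin <- dIn[1L]; tt <- dIn[2L]; v <- dIn[3L]
  cout <- dim(weights)[2L]
  out <- array(0, c(cout, tt, v))
  for (k in 1:3) {
    ak <- ahat[[k]] * masks[, , k]
    for (i in seq_len(v)) {
      for (j in seq_len(v)) {
        if (ak[i, j] == 0) next
        for (co in seq_len(cout)) {
          for (ci in seq_len(cin)) {
            out[co, , i] <- out[co, , i] +
              ak[i, j] * weights[ci, co, k] * features[ci, , j]
          }
        }
      }
    }
  }
  out
}

# sliding-window 2-D convolution oracle (channel-fastest layout)
oracleConv2d <- function(x, warr, b, sh, sw, ph, pw) {
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  KH <- dim(warr)[2L]; KW <- dim(warr)[3L]; Cout <- dim(warr)[4L]
  OH <- (H + 2 * ph - KH) %/% sh + 1L
  OW <- (W + 2 * pw - KW) %/% sw + 1L
  out <- array(0, c(Cout, OH, OW))
  for (co in seq_len(Cout)) for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
    acc <- b[co]
    for (ci in seq_len(C)) for (kh in seq_len(KH)) for (kw in seq_len(KW)) {
      h <- (oh - 1L) * sh - ph + kh
      w <- (ow - 1L) * sw - pw + kw
      if (h >= 1 && h <= H && w >= 1 && w <= W)
        acc <- acc + x[ci, h, w] * warr[ci, kh, kw, co]
    }
    out[co, oh, ow] <- acc
  }
  out
}

# direct reading of the voting text: strictly more than half
oracleVote <- function(k, n) if (k / n > 0.5) "second" else "first"

# tiny EEG record with known content
flatEegRecord <- function(value = 0, nCh = 64, n = 100, fs = 250,
                          subjectId = "e1", condition = "eyes_open") {
  eegRecord(subjectId, matrix(value, nCh, n), fs, condition,
            channelLabels = eegChannelLabels64())
}

# small trained-free cascade fixture: models with deterministic weights
tinyGaitConfig <- function(attention = "none") {
  astGcnConfig(channels = c(4L, 8L), strides = c(1L, 2L), tKernel = 3L,
               attention = if (identical(attention, "none")) "none" else 2L,
               dropout = 0, jointSubset = defaultJointSubset(),
               attentionKernel = 3L)
}
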