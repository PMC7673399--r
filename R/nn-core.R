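# Minimal reverse-mode layer engine backing the two classifiers.
#
# A layer is a plain list with fields:
#   type   : character tag dispatched in nnForward()/nnBackward()
#   params : named list of numeric arrays (learnable)
#   sub    : named list of child layers (for compound blocks)
# plus layer-specific configuration and, for batch norm, running statistics.
# Forward passes return the updated layer so running statistics can be carried
# functionally; gradients mirror the params/sub structure.
#
# Array layout everywhere is column-major with channels fastest and the batch
# axis last: features are (C, H, W, N); for skeleton data H = frames (T) and
# W = joints (V); for EEG data H = electrodes and W = time samples.

heInit <- function(fanIn, n) {
  stats::rnorm(n, sd = sqrt(2 / fanIn))
}

nnConv <- function(cin, cout, kh, kw, sh = 1L, sw = 1L, ph = 0L, pw = 0L) {
  k <- cin * kh * kw
  list(type = "conv",
       params = list(W = matrix(heInit(k, k * cout), k, cout),
                     b = numeric(cout)),
       kh = as.integer(kh), kw = as.integer(kw),
       sh = as.integer(sh), sw = as.integer(sw),
       ph = as.integer(ph), pw = as.integer(pw))
}

nnBN <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn",
       params = list(gamma = rep(1, c), beta = numeric(c)),
       rmean = numeric(c), rvar = rep(1, c),
       momentum = momentum, eps = eps)
}

nnReLU <- function() list(type = "relu")
nnELU <- function(alpha = 1) list(type = "elu", alpha = alpha)
nnDropout <- function(p) list(type = "dropout", p = p)
nnFlatten <- function() list(type = "flatten")
nnGAPool <- function() list(type = "gapool")

nnFC <- function(din, dout) {
  list(type = "fc",
       params = list(W = matrix(heInit(din, din * dout), din, dout),
                     b = numeric(dout)))
}

# Partitioned graph convolution: one weight matrix and one learnable edge
# importance mask per neighbourhood subset (root/centripetal/centrifugal).
nnGraphConv <- function(cin, cout, ahat) {
  stopifnot(is.list(ahat), length(ahat) == 3L)
  v <- nrow(ahat[[1L]])
  list(type = "graphconv",
       params = list(W = array(heInit(cin, cin * cout * 3), c(cin, cout, 3L)),
                     M = array(1, c(v, v, 3L))),
       ahat = ahat)
}

nnSTGCNBlock <- function(cin, cout, ahat, tKernel = 9L, stride = 1L,
                         dropout = 0.5, residual = TRUE) {
  pad <- (tKernel - 1L) %/% 2L
  res <- if (!residual) {
    NULL
  } else if (cin == cout && stride == 1L) {
    "identity"
  } else {
    list(conv = nnConv(cin, cout, 1L, 1L, sh = stride),
         bn = nnBN(cout))
  }
  sub <- list(gc = nnGraphConv(cin, cout, ahat),
              bn1 = nnBN(cout),
              tconv = nnConv(cout, cout, tKernel, 1L, sh = stride, ph = pad),
              bn2 = nnBN(cout),
              drop = nnDropout(dropout))
  if (is.list(res)) sub <- c(sub, list(resconv = res$conv, resbn = res$bn))
  list(type = "stgcn_block", sub = sub,
       residual = if (is.list(res)) "project" else if (is.null(res)) "none" else "identity")
}

# Hourglass attention: mask branch downsamples T by stride-4 temporal
# convolutions twice, upsamples back by nearest-neighbour repetition, then a
# 1x1 convolution and sigmoid produce a gate g; output is x * (1 + g).
nnAttention <- function(c, kernel = 5L) {
  pad <- (kernel - 1L) %/% 2L
  list(type = "attention",
       sub = list(c1 = nnConv(c, c, kernel, 1L, sh = 4L, ph = pad),
                  c2 = nnConv(c, c, kernel, 1L, sh = 4L, ph = pad),
                  c3 = nnConv(c, c, 1L, 1L)),
       kernel = kernel)
}

convF <- function(layer, x) {
  .conv2d_fwd(x, dim(x), layer$params$W, layer$params$b,
              layer$kh, layer$kw, layer$sh, layer$sw, layer$ph, layer$pw)
}

convB <- function(layer, x, dy) {
  .conv2d_bwd(x, dim(x), layer$params$W, dy,
              layer$kh, layer$kw, layer$sh, layer$sw, layer$ph, layer$pw)
}

upsampleT <- function(x, r) {
  d <- dim(x)
  idx <- rep(seq_len(d[2L]), each = r)
  y <- x[, idx, , , drop = FALSE]
  y
}

downsampleTSum <- function(dy, r) {
  d <- dim(dy)
  dim(dy) <- c(d[1L], r, d[2L] %/% r, d[3L], d[4L])
  y <- colSums(aperm(dy, c(2L, 1L, 3L, 4L, 5L)))
  dim(y) <- c(d[1L], d[2L] %/% r, d[3L], d[4L])
  y
}

padT <- function(x, tpad) {
  d <- dim(x)
  if (d[2L] == tpad) return(x)
  y <- array(0, c(d[1L], tpad, d[3L], d[4L]))
  y[, seq_len(d[2L]), , ] <- x
  y
}

# Apply a (V x V) operator along the joint axis: y[c,t,v,n] = sum_w A[v,w] x[c,t,w,n]
applyJointOp <- function(x, a) {
  d <- dim(x)
  ap <- aperm(x, c(1L, 2L, 4L, 3L))
  m <- matrix(ap, ncol = d[3L])
  y <- m %*% t(a)
  dim(y) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(y, c(1L, 2L, 4L, 3L))
}

nnForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      list(y = convF(layer, x), cache = list(x = x), layer = layer)
    },
    bn = {
      c <- dim(x)[1L]
      if (training) {
        f <- .bn_fwd(x, c, layer$params$gamma, layer$params$beta,
                     layer$eps)
        m <- layer$momentum
        layer$rmean <- (1 - m) * layer$rmean + m * f$mean
        layer$rvar <- (1 - m) * layer$rvar + m * f$var
        list(y = f$y, cache = list(x = x, mean = f$mean, var = f$var),
             layer = layer)
      } else {
        y <- .bn_eval(x, c, layer$params$gamma, layer$params$beta,
                      layer$rmean, layer$rvar, layer$eps)
        list(y = y, cache = NULL, layer = layer)
      }
    },
    relu = {
      y <- .relu_fwd(x)
      list(y = y, cache = list(y = y), layer = layer)
    },
    elu = {
      y <- .elu_fwd(x, layer$alpha)
      list(y = y, cache = list(y = y), layer = layer)
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- 1 - layer$p
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(y = x, cache = list(mask = NULL), layer = layer)
      }
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[-length(d)]), d[length(d)])
      list(y = y, cache = list(d = d), layer = layer)
    },
    gapool = {
      d <- dim(x)
      tv <- d[2L] * d[3L]
      z <- x
      dim(z) <- c(d[1L], tv, d[4L])
      y <- colSums(aperm(z, c(2L, 1L, 3L))) / tv
      dim(y) <- c(d[1L], d[4L])
      list(y = y, cache = list(d = d), layer = layer)
    },
    fc = {
      y <- crossprod(layer$params$W, x) + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    graphconv = {
      d <- dim(x)
      cin <- d[1L]
      cout <- dim(layer$params$W)[2L]
      xm <- matrix(x, cin)
      y <- 0
      for (k in 1:3) {
        h <- crossprod(matrix(layer$params$W[, , k], cin, cout), xm)
        dim(h) <- c(cout, d[2L], d[3L], d[4L])
        ak <- layer$ahat[[k]] * matrix(layer$params$M[, , k], d[3L], d[3L])
        y <- y + applyJointOp(h, ak)
      }
      list(y = y, cache = list(x = x), layer = layer)
    },
    stgcn_block = {
      s <- layer$sub
      caches <- list()
      f <- nnForward(s$gc, x, training); s$gc <- f$layer; caches$gc <- f$cache
      f2 <- nnForward(s$bn1, f$y, training); s$bn1 <- f2$layer; caches$bn1 <- f2$cache
      a1 <- .relu_fwd(f2$y)
      caches$relu1 <- a1
      f3 <- nnForward(s$tconv, a1, training); s$tconv <- f3$layer; caches$tconv <- f3$cache
      f4 <- nnForward(s$bn2, f3$y, training); s$bn2 <- f4$layer; caches$bn2 <- f4$cache
      f5 <- nnForward(s$drop, f4$y, training); caches$drop <- f5$cache
      r <- switch(layer$residual,
        none = 0,
        identity = x,
        project = {
          fr <- nnForward(s$resconv, x, training)
          s$resconv <- fr$layer; caches$resconv <- fr$cache
          fb <- nnForward(s$resbn, fr$y, training)
          s$resbn <- fb$layer; caches$resbn <- fb$cache
          fb$y
        })
      pre <- f5$y + r
      y <- .relu_fwd(pre)
      caches$relu2 <- y
      layer$sub <- s
      list(y = y, cache = caches, layer = layer)
    },
    attention = {
      s <- layer$sub
      d <- dim(x)
      tin <- d[2L]
      tp <- 16L * ceiling(tin / 16L)
      xp <- padT(x, tp)
      caches <- list(tin = tin, tp = tp, x = x)
      f1 <- nnForward(s$c1, xp, training); caches$c1 <- list(x = xp)
      a1 <- .relu_fwd(f1$y); caches$relu1 <- a1
      f2 <- nnForward(s$c2, a1, training); caches$c2 <- list(x = a1)
      a2 <- .relu_fwd(f2$y); caches$relu2 <- a2
      u <- upsampleT(upsampleT(a2, 4L), 4L)
      u <- u[, seq_len(tin), , , drop = FALSE]
      f3 <- nnForward(s$c3, u, training); caches$c3 <- list(x = u)
      g <- 1 / (1 + exp(-f3$y))
      caches$g <- g
      layer$sub <- s
      list(y = x * (1 + g), cache = caches, layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nnBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      b <- convB(layer, cache$x, dy)
      list(dx = b$dx, grads = list(params = list(W = b$dW, b = b$db)))
    },
    bn = {
      c <- dim(cache$x)[1L]
      b <- .bn_bwd(cache$x, dy, c, layer$params$gamma, cache$mean,
                   cache$var, layer$eps)
      list(dx = b$dx,
           grads = list(params = list(gamma = b$dgamma,
                                      beta = b$dbeta)))
    },
    relu = list(dx = .relu_bwd(cache$y, dy), grads = NULL),
    elu = list(dx = .elu_bwd(cache$y, dy, layer$alpha), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    flatten = {
      dim(dy) <- cache$d
      list(dx = dy, grads = NULL)
    },
    gapool = {
      d <- cache$d
      tv <- d[2L] * d[3L]
      dx <- dy[, rep(seq_len(d[4L]), each = tv), drop = FALSE] / tv
      dim(dx) <- d
      list(dx = dx, grads = NULL)
    },
    fc = {
      dW <- cache$x %*% t(dy)
      db <- rowSums(dy)
      dx <- layer$params$W %*% dy
      list(dx = dx, grads = list(params = list(W = dW, b = db)))
    },
    graphconv = {
      x <- cache$x
      d <- dim(x)
      cin <- d[1L]
      cout <- dim(layer$params$W)[2L]
      xm <- matrix(x, cin)
      dW <- array(0, dim(layer$params$W))
      dM <- array(0, dim(layer$params$M))
      dxm <- matrix(0, cin, ncol(xm))
      dyp <- aperm(dy, c(1L, 2L, 4L, 3L))
      dypm <- matrix(dyp, ncol = d[3L])
      for (k in 1:3) {
        ak <- layer$ahat[[k]] * matrix(layer$params$M[, , k], d[3L], d[3L])
        # recompute the per-subset hidden features (cheaper than caching 3x)
        h <- crossprod(matrix(layer$params$W[, , k], cin, cout), xm)
        dim(h) <- c(cout, d[2L], d[3L], d[4L])
        hp <- aperm(h, c(1L, 2L, 4L, 3L))
        hpm <- matrix(hp, ncol = d[3L])
        dM[, , k] <- crossprod(dypm, hpm) * layer$ahat[[k]]
        dhm <- dypm %*% ak
        dim(dhm) <- c(cout, d[2L], d[4L], d[3L])
        dh <- aperm(dhm, c(1L, 2L, 4L, 3L))
        dhmat <- matrix(dh, cout)
        dW[, , k] <- xm %*% t(dhmat)
        dxm <- dxm + matrix(layer$params$W[, , k], cin, cout) %*% dhmat
      }
      dim(dxm) <- d
      list(dx = dxm, grads = list(params = list(W = dW, M = dM)))
    },
    stgcn_block = {
      s <- layer$sub
      grads <- list(sub = list())
      dpre <- .relu_bwd(cache$relu2, dy)
      b5 <- nnBackward(s$drop, cache$drop, dpre)
      b4 <- nnBackward(s$bn2, cache$bn2, b5$dx)
      grads$sub$bn2 <- b4$grads
      b3 <- nnBackward(s$tconv, cache$tconv, b4$dx)
      grads$sub$tconv <- b3$grads
      da1 <- .relu_bwd(cache$relu1, b3$dx)
      b2 <- nnBackward(s$bn1, cache$bn1, da1)
      grads$sub$bn1 <- b2$grads
      b1 <- nnBackward(s$gc, cache$gc, b2$dx)
      grads$sub$gc <- b1$grads
      dx <- b1$dx
      if (layer$residual == "identity") {
        dx <- dx + dpre
      } else if (layer$residual == "project") {
        br <- nnBackward(s$resbn, cache$resbn, dpre)
        grads$sub$resbn <- br$grads
        bc <- nnBackward(s$resconv, cache$resconv, br$dx)
        grads$sub$resconv <- bc$grads
        dx <- dx + bc$dx
      }
      list(dx = dx, grads = grads)
    },
    attention = {
      s <- layer$sub
      grads <- list(sub = list())
      x <- cache$x
      g <- cache$g
      dxDirect <- dy * (1 + g)
      dg <- dy * x
      dpre3 <- dg * g * (1 - g)
      b3 <- nnBackward(s$c3, cache$c3, dpre3)
      grads$sub$c3 <- b3$grads
      du <- b3$dx
      if (cache$tp != cache$tin) du <- padT(du, cache$tp)
      da2 <- downsampleTSum(downsampleTSum(du, 4L), 4L)
      da2 <- .relu_bwd(cache$relu2, da2)
      b2 <- nnBackward(s$c2, cache$c2, da2)
      grads$sub$c2 <- b2$grads
      da1 <- .relu_bwd(cache$relu1, b2$dx)
      b1 <- nnBackward(s$c1, cache$c1, da1)
      grads$sub$c1 <- b1$grads
      dxp <- b1$dx[, seq_len(cache$tin), , , drop = FALSE]
      list(dx = dxDirect + dxp, grads = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nnModelForward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- nnForward(layers[[i]], x, training)
    x <- f$y
    caches[[i]] <- f$cache
    layers[[i]] <- f$layer
  }
  list(y = x, caches = caches, layers = layers)
}

nnModelBackward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- nnBackward(layers[[i]], caches[[i]], dy)
    dy <- b$dx
    grads[i] <- list(b$grads)   # keep NULL slots (parameter-free layers)
  }
  list(dx = dy, grads = grads)
}

updateLayer <- function(layer, grad, lr) {
  if (is.null(grad)) return(layer)
  if (!is.null(grad$params)) {
    for (nm in names(grad$params)) {
      layer$params[[nm]] <- layer$params[[nm]] - lr * grad$params[[nm]]
    }
  }
  if (!is.null(grad$sub)) {
    for (nm in names(grad$sub)) {
      layer$sub[[nm]] <- updateLayer(layer$sub[[nm]], grad$sub[[nm]], lr)
    }
  }
  layer
}

nnSgdStep <- function(layers, grads, lr) {
  for (i in seq_along(layers)) {
    layers[[i]] <- updateLayer(layers[[i]], grads[[i]], lr)
  }
  layers
}

countLayerParams <- function(layer) {
  n <- 0
  if (!is.null(layer$params)) {
    n <- n + sum(vapply(layer$params, length, integer(1)))
  }
  if (!is.null(layer$sub)) {
    n <- n + sum(vapply(layer$sub, countLayerParams, numeric(1)))
  }
  n
}

nnParamCount <- function(layers) {
  sum(vapply(layers, countLayerParams, numeric(1)))
}

# Softmax cross-entropy on logits (K x N); y is an integer class index vector.
softmaxCrossEntropy <- function(logits, y) {
  k <- nrow(logits)
  n <- ncol(logits)
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  p <- sweep(e, 2L, colSums(e), "/")
  idx <- cbind(y, seq_len(n))
  pi <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(pi, 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

softmaxProbs <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

sliceLast <- function(x, idx) {
  d <- dim(x)
  if (length(d) == 4L) x[, , , idx, drop = FALSE]
  else if (length(d) == 3L) x[, , idx, drop = FALSE]
  else x[, idx, drop = FALSE]
}
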