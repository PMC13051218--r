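# Minimal neural-network layer library: 2D convolutions (im2col on BLAS
# matmuls), max-pooling, nearest upsampling, layer norm, multi-head
# self-attention, and AdamW. Forward passes return caches consumed by the
# matching backward passes; parameters live in a flat named list of arrays.
# Everything is deterministic given the R RNG state.

convOffsets <- function() expand.grid(dy = -1:1, dx = -1:1)

# x: (C, H, W) -> M: (9C, H*W), zero padding, 'same' output size
im2col3 <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  pad <- array(0, c(C, H + 2L, W + 2L))
  pad[, 2:(H + 1), 2:(W + 1)] <- x
  M <- matrix(0, 9L * C, H * W)
  offs <- convOffsets()
  for (o in seq_len(9)) {
    dy <- offs$dy[o]; dx <- offs$dx[o]
    blk <- pad[, (1:H) + dy + 1L, (1:W) + dx + 1L, drop = FALSE]
    M[((o - 1L) * C + 1L):(o * C), ] <- matrix(blk, C, H * W)
  }
  M
}

col2im3 <- function(dM, C, H, W) {
  dpad <- array(0, c(C, H + 2L, W + 2L))
  offs <- convOffsets()
  for (o in seq_len(9)) {
    dy <- offs$dy[o]; dx <- offs$dx[o]
    blk <- array(dM[((o - 1L) * C + 1L):(o * C), ], c(C, H, W))
    dpad[, (1:H) + dy + 1L, (1:W) + dx + 1L] <-
      dpad[, (1:H) + dy + 1L, (1:W) + dx + 1L, drop = FALSE] + blk
  }
  dpad[, 2:(H + 1), 2:(W + 1), drop = FALSE]
}

# W: (C_out, 9*C_in), b: C_out
conv3Forward <- function(W, b, x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  M <- im2col3(x)
  Y <- W %*% M + b
  list(out = array(Y, c(nrow(W), H, Wd)), M = M, dims = d)
}

conv3Backward <- function(W, cache, dout) {
  d <- cache$dims; H <- d[2]; Wd <- d[3]
  dY <- matrix(dout, dim(dout)[1], H * Wd)
  dW <- dY %*% t(cache$M)
  db <- rowSums(dY)
  dM <- crossprod(W, dY)
  dx <- col2im3(dM, d[1], H, Wd)
  list(dx = dx, dW = dW, db = db)
}

conv1Forward <- function(W, b, x) {
  d <- dim(x)
  X <- matrix(x, d[1], d[2] * d[3])
  Y <- W %*% X + b
  list(out = array(Y, c(nrow(W), d[2], d[3])), X = X, dims = d)
}

conv1Backward <- function(W, cache, dout) {
  d <- cache$dims
  dY <- matrix(dout, dim(dout)[1], d[2] * d[3])
  list(dx = array(crossprod(W, dY), d),
       dW = dY %*% t(cache$X), db = rowSums(dY))
}

reluForward <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}
reluBackward <- function(cache, dout) dout * cache$mask

# 2x2 max pooling, stride 2; H, W must be even
poolForward <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  oh <- seq(1L, H, 2L); eh <- oh + 1L
  ow <- seq(1L, W, 2L); ew <- ow + 1L
  a <- list(x[, oh, ow, drop = FALSE], x[, eh, ow, drop = FALSE],
            x[, oh, ew, drop = FALSE], x[, eh, ew, drop = FALSE])
  best <- a[[1]]; arg <- array(1L, dim(best))
  for (k in 2:4) {
    upd <- a[[k]] > best
    best[upd] <- a[[k]][upd]
    arg[upd] <- k
  }
  list(out = best, arg = arg, dims = d)
}

poolBackward <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  oh <- seq(1L, d[2], 2L); ow <- seq(1L, d[3], 2L)
  sel <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- cache$arg == k
    g <- dout * m
    dx[, oh + sel[[k]][1], ow + sel[[k]][2]] <-
      dx[, oh + sel[[k]][1], ow + sel[[k]][2], drop = FALSE] + g
  }
  dx
}

upsampleForward <- function(x) {
  d <- dim(x)
  iy <- rep(seq_len(d[2]), each = 2L)
  ix <- rep(seq_len(d[3]), each = 2L)
  list(out = x[, iy, ix, drop = FALSE], dims = d)
}

upsampleBackward <- function(cache, dout) {
  d <- cache$dims
  oh <- seq(1L, 2L * d[2], 2L); ow <- seq(1L, 2L * d[3], 2L)
  dout[, oh, ow, drop = FALSE] + dout[, oh + 1L, ow, drop = FALSE] +
    dout[, oh, ow + 1L, drop = FALSE] + dout[, oh + 1L, ow + 1L, drop = FALSE]
}

# tokens T: (N, D); g, b: length D
lnForward <- function(Tm, g, b, eps = 1e-5) {
  mu <- rowMeans(Tm)
  v <- rowMeans(Tm^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (Tm - mu) * inv
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(out = out, xhat = xhat, inv = inv, Tm = Tm, mu = mu)
}

lnBackward <- function(cache, g, dout) {
  D <- ncol(dout)
  dxhat <- sweep(dout, 2, g, "*")
  xhat <- cache$xhat; inv <- cache$inv
  # per-row: dT = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dT <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dT, dg = colSums(dout * xhat), db = colSums(dout))
}

linForward <- function(Tm, W, b) {
  list(out = sweep(Tm %*% W, 2, b, "+"), Tm = Tm)
}
linBackward <- function(cache, W, dout) {
  list(dx = tcrossprod(dout, W), dW = crossprod(cache$Tm, dout),
       db = colSums(dout))
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Multi-head self-attention over tokens T (N, D)
mhsaForward <- function(Tm, p, prefix, heads) {
  D <- ncol(Tm); dh <- D %/% heads
  q <- linForward(Tm, p[[paste0(prefix, "Wq")]], p[[paste0(prefix, "bq")]])
  k <- linForward(Tm, p[[paste0(prefix, "Wk")]], p[[paste0(prefix, "bk")]])
  v <- linForward(Tm, p[[paste0(prefix, "Wv")]], p[[paste0(prefix, "bv")]])
  hs <- vector("list", heads)
  O <- matrix(0, nrow(Tm), D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- q$out[, cols, drop = FALSE]
    Kh <- k$out[, cols, drop = FALSE]
    Vh <- v$out[, cols, drop = FALSE]
    A <- softmaxRows(tcrossprod(Qh, Kh) / sqrt(dh))
    O[, cols] <- A %*% Vh
    hs[[h]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh, cols = cols)
  }
  o <- linForward(O, p[[paste0(prefix, "Wo")]], p[[paste0(prefix, "bo")]])
  list(out = o$out, q = q, k = k, v = v, heads = hs, O = O, oc = o,
       nheads = heads, dh = dh)
}

mhsaBackward <- function(cache, p, prefix, dout) {
  g <- list()
  ob <- linBackward(cache$oc, p[[paste0(prefix, "Wo")]], dout)
  g[[paste0(prefix, "Wo")]] <- ob$dW; g[[paste0(prefix, "bo")]] <- ob$db
  dO <- ob$dx
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (h in seq_len(cache$nheads)) {
    hc <- cache$heads[[h]]; cols <- hc$cols
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, hc$Vh)
    dV[, cols] <- crossprod(hc$A, dOh)
    # softmax backward per row
    dZ <- (dA - rowSums(dA * hc$A)) * hc$A
    dZ <- dZ / sqrt(cache$dh)
    dQ[, cols] <- dZ %*% hc$Kh
    dK[, cols] <- crossprod(dZ, hc$Qh)
  }
  qb <- linBackward(cache$q, p[[paste0(prefix, "Wq")]], dQ)
  kb <- linBackward(cache$k, p[[paste0(prefix, "Wk")]], dK)
  vb <- linBackward(cache$v, p[[paste0(prefix, "Wv")]], dV)
  g[[paste0(prefix, "Wq")]] <- qb$dW; g[[paste0(prefix, "bq")]] <- qb$db
  g[[paste0(prefix, "Wk")]] <- kb$dW; g[[paste0(prefix, "bk")]] <- kb$db
  g[[paste0(prefix, "Wv")]] <- vb$dW; g[[paste0(prefix, "bv")]] <- vb$db
  list(dx = qb$dx + kb$dx + vb$dx, grads = g)
}

# ---- AdamW -----------------------------------------------------------------

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamwStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 1e-4) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

accumGrads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g))
    total[[nm]] <- if (is.null(total[[nm]])) g[[nm]] else total[[nm]] + g[[nm]]
  total
}

scaleGrads <- function(g, s) lapply(g, function(x) x * s)
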