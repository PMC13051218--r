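# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops / all-pairs matrices) and never call the package's
# vectorised implementations.

tinyGrid <- c(16L, 32L, 32L)

tinyPhantom <- function(seed = 1L, noiseFree = FALSE, grid = tinyGrid, ...) {
  cfg <- if (noiseFree) noiseFreeConfig(grid_shape = grid, seed = seed, ...)
         else phantomConfig(grid_shape = grid, seed = seed, ...)
  generatePhantom(cfg)
}

randVol <- function(d = c(16, 16, 16), seed = 1, mean = 50, sd = 100) {
  set.seed(seed)
  array(rnorm(prod(d), mean, sd), d)
}

randMask <- function(d = c(16, 16, 16), seed = 1, p = 0.2) {
  set.seed(seed)
  array(runif(prod(d)) < p, d)
}

# --- brute-force oracles ----------------------------------------------------

bruteMSE <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

bruteStats <- function(x) {
  n <- length(x)
  mu <- 0
  for (i in seq_len(n)) mu <- mu + x[i]
  mu <- mu / n
  v <- 0
  for (i in seq_len(n)) v <- v + (x[i] - mu)^2
  list(mu = mu, v = v / n)
}

bruteCov <- function(x, y) {
  n <- length(x)
  mx <- bruteStats(x)$mu; my <- bruteStats(y)$mu
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - mx) * (y[i] - my)
  s / n
}

bruteUQI <- function(x, y) {
  sx <- bruteStats(x); sy <- bruteStats(y)
  cxy <- bruteCov(x, y)
  4 * sx$mu * sy$mu * cxy / ((sx$mu^2 + sy$mu^2) * (sx$v + sy$v))
}

bruteSSIM <- function(x, y, c1, c2) {
  sx <- bruteStats(x); sy <- bruteStats(y)
  cxy <- bruteCov(x, y)
  (2 * sx$mu * sy$mu + c1) * (2 * cxy + c2) /
    ((sx$mu^2 + sy$mu^2 + c1) * (sx$v + sy$v + c2))
}

bruteDice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  2 * inter / (na + nb)
}

# boundary voxels by explicit 6-neighbour scan
bruteSurface <- function(mask, spacing) {
  d <- dim(mask)
  pts <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x]) next
    onb <- FALSE
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      zz <- z + o[1]; yy <- y + o[2]; xx <- x + o[3]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 ||
          xx > d[3] || !mask[zz, yy, xx]) { onb <- TRUE; break }
    }
    if (onb)
      pts <- rbind(pts, (c(z, y, x) - 1) * spacing)
  }
  pts
}

# all-pairs distance matrix route (independent of the chunked k-NN scan)
bruteHD <- function(a, b, spacing, percentile = 95) {
  A <- bruteSurface(a, spacing)
  B <- bruteSurface(b, spacing)
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    D[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
  dab <- apply(D, 1, min)
  dba <- apply(D, 2, min)
  list(hd95 = unname(quantile(c(dab, dba), percentile / 100, type = 7)),
       hdmax = max(c(dab, dba)))
}

# naive weighted SSIM loss: per-region loop, global-window statistics
bruteWSSIM <- function(x, y, masks, epsilon, c1, c2) {
  areas <- vapply(masks, sum, numeric(1))
  keep <- areas > 0
  masks <- masks[keep]; areas <- areas[keep]
  inv <- 1 / (areas + epsilon)
  w <- inv / sum(inv)
  tot <- 0
  for (i in seq_along(masks)) {
    xi <- x[masks[[i]]]; yi <- y[masks[[i]]]
    tot <- tot + w[[i]] * bruteSSIM(xi, yi, c1, c2)
  }
  1 - tot
}

# tiny train/val manifests used by model and acceptance tests
smallModelSetup <- function(n_train = 3, grid = c(16, 64, 64),
                            seed_base = 0) {
  train <- lapply(seq_len(n_train), function(i)
    generatePhantom(phantomConfig(grid_shape = grid, seed = seed_base + i)))
  val <- list(generatePhantom(phantomConfig(grid_shape = grid,
                                            seed = seed_base + 11)))
  list(train = train, val = val)
}

microModelConfig <- function() {
  modelConfig(in_shape = 32L, enc_channels = c(8L, 16L), trans_layers = 1L,
              trans_heads = 2L, embed_dim = 32L)
}

smokeRunConfig <- function(seed = 1L) {
  runConfig(
    n_samples = 5L,
    split = c(train = 0.4, val = 0.2, test = 0.4),
    phantom = phantomConfig(grid_shape = c(16, 32, 32)),
    model = microModelConfig(),
    train = trainConfig(batch_size = 16L, max_epochs = 2L, patience = 1L,
                        lr = 1e-3, seed = seed),
    loss = lossConfig(),
    seed = seed
  )
}
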