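test_that("inverse-area weights: hand values, symmetry, monotonicity", {
  mk <- function(n) {
    m <- array(FALSE, c(2, 2, 2)); m[seq_len(n)] <- TRUE; m
  }
  rw <- regionWeights(list(a = mk(1), b = mk(3)), epsilon = 1e-12)
  expect_equal(unname(rw$weights), c(0.75, 0.25), tolerance = 1e-9)
  # equal areas -> uniform weights
  rw2 <- regionWeights(list(a = mk(2), b = mk(2), c = mk(2)), epsilon = 1)
  expect_equal(unname(rw2$weights), rep(1 / 3, 3))
  # the largest region always gets the smallest weight
  ph <- tinyPhantom(seed = 1)
  kl <- maskSet(ph)@masks[kappaRegions()]
  rw3 <- regionWeights(kl)
  expect_equal(names(which.min(rw3$weights)), "Body")
  expect_true(all(rw3$weights > 0))
  ord <- order(rw3$areas)
  expect_equal(order(rw3$weights, decreasing = TRUE), ord)
})

test_that("weights form a convex combination on random mask sets", {
  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    masks <- lapply(seq_len(k), function(j) randMask(c(6, 6, 6), seed = i * 31 + j,
                                                     p = runif(1, 0.05, 0.6)))
    names(masks) <- paste0("r", seq_len(k))
    areas <- vapply(masks, sum, numeric(1))
    if (all(areas == 0)) next
    rw <- suppressWarnings(regionWeights(masks, epsilon = 1))
    expect_lt(abs(sum(rw$weights) - 1), 1e-9)
  }
})

test_that("empty regions are dropped with a warning; all-empty errors", {
  e <- array(FALSE, c(2, 2, 2))
  f <- array(TRUE, c(2, 2, 2))
  expect_warning(rw <- regionWeights(list(a = e, b = f)), "empty")
  expect_equal(rw$region_names, "b")
  expect_equal(unname(rw$weights), 1)
  expect_error(regionWeights(list(a = e, b = e)), "empty")
  x <- randVol(c(2, 2, 2), 1)
  expect_error(regionSSIM(x, x, e), "mpty mask")
})

test_that("region SSIM: identity, anti-correlation sign, brute oracle", {
  x <- randVol(c(4, 8, 8), seed = 10)
  m <- randMask(c(4, 8, 8), seed = 11, p = 0.5)
  for (win in c("global", "gaussian11"))
    expect_equal(regionSSIM(x, x, m, ssimParams(window = win)), 1)
  # anti-correlated pair with vanishing constants: negative structure term
  y <- -x + 2 * mean(x)
  p0 <- ssimParams(dynamicRange = 3000, k1 = 1e-9, k2 = 1e-9,
                   window = "global")
  expect_lt(regionSSIM(x, y, m, p0), 0)
  # constant-plus-checkerboard patch against the hand formula
  chk <- outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  a <- 100 + 10 * chk
  b <- 100 + 6 * chk + 2
  pa <- ssimParams(window = "global")
  got <- regionSSIM(array(a, c(1, 8, 8)), array(b, c(1, 8, 8)),
                    array(TRUE, c(1, 8, 8)), pa)
  expect_equal(got, bruteSSIM(as.vector(a), as.vector(b), pa$c1, pa$c2),
               tolerance = 1e-10)
})

test_that("weighted loss: identity zero, hand example, permutation", {
  ph <- tinyPhantom(seed = 2)
  en <- voxelData(enhanced(ph))
  kl <- maskSet(ph)@masks[kappaRegions()]
  for (win in c("global", "gaussian11"))
    expect_equal(weightedSSIMLoss(en, en, kl,
                                  params = ssimParams(window = win)), 0)
  # areas {1, 3} with region SSIMs {1.0, 0.5} -> 1 - 0.875 = 0.125
  mk <- function(n) { m <- array(FALSE, c(2, 2, 2)); m[seq_len(n)] <- TRUE; m }
  w <- regionWeights(list(a = mk(1), b = mk(3)), epsilon = 1e-12)$weights
  expect_equal(1 - sum(w * c(1.0, 0.5)), 0.125)
  # permuting the region order leaves the loss unchanged
  x <- randVol(c(4, 8, 8), 20); y <- randVol(c(4, 8, 8), 21)
  masks <- list(A = randMask(c(4, 8, 8), 22, 0.3),
                B = randMask(c(4, 8, 8), 23, 0.6),
                C = randMask(c(4, 8, 8), 24, 0.1))
  l1 <- weightedSSIMLoss(x, y, masks, regions = c("A", "B", "C"))
  l2 <- weightedSSIMLoss(x, y, masks[c(3, 1, 2)], regions = c("C", "A", "B"))
  expect_equal(l1, l2, tolerance = 1e-12)
  # loss is the convex combination of per-region SSIMs
  pa <- ssimParams(window = "global")
  rw <- regionWeights(masks)
  manual <- 1 - sum(rw$weights * vapply(names(masks), function(nm)
    regionSSIM(x, y, masks[[nm]], pa), numeric(1)))
  expect_equal(weightedSSIMLoss(x, y, masks, params = pa), manual,
               tolerance = 1e-12)
})

test_that("global-window loss equals the naive double-loop oracle", {
  for (i in 1:5) {
    x <- randVol(c(16, 16, 16), seed = 100 + i)
    y <- randVol(c(16, 16, 16), seed = 200 + i)
    masks <- list(a = randMask(c(16, 16, 16), 300 + i, 0.1),
                  b = randMask(c(16, 16, 16), 400 + i, 0.4),
                  c = randMask(c(16, 16, 16), 500 + i, 0.8))
    pa <- ssimParams(window = "global")
    expect_equal(weightedSSIMLoss(x, y, masks, epsilon = 1, params = pa),
                 bruteWSSIM(x, y, masks, 1, pa$c1, pa$c2),
                 tolerance = 1e-8)
  }
})

test_that("analytic gradient matches finite differences", {
  d <- c(2, 8, 8)
  x <- randVol(d, 31); y <- randVol(d, 32)
  masks <- list(small = randMask(d, 33, 0.15), big = randMask(d, 34, 0.7))
  for (win in c("global", "gaussian11")) {
    p <- ssimParams(window = win)
    lg <- weightedSSIMLossGrad(x, y, masks, params = p)
    eps <- 1e-3
    set.seed(35)
    for (i in sample(prod(d), 25)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (weightedSSIMLoss(xp, y, masks, params = p) -
               weightedSSIMLoss(xm, y, masks, params = p)) / (2 * eps)
      denom <- max(abs(fd), abs(lg$grad[i]), 1e-10)
      expect_lt(abs(fd - lg$grad[i]) / denom, 1e-4)
    }
  }
})

test_that("loss falls monotonically as y blends toward x", {
  d <- c(2, 16, 16)
  x <- randVol(d, 41)
  z <- randVol(d, 42)
  masks <- list(a = randMask(d, 43, 0.3), b = randMask(d, 44, 0.8))
  for (win in c("global", "gaussian11")) {
    p <- ssimParams(window = win)
    losses <- vapply(seq(0, 1, length.out = 11), function(t)
      weightedSSIMLoss((1 - t) * z + t * x, x, masks, params = p),
      numeric(1))
    expect_true(all(diff(losses) <= 1e-6))
    expect_equal(losses[11], 0, tolerance = 1e-12)
  }
})
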