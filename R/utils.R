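# Internal helpers: seed streams, smoothing kernels, connected components.

# Derive a child seed from a parent seed and a stage label, staying within
# 32-bit integer range. Deterministic, label-sensitive.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 2654435 + h * 97 + 13) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normalized 1D Gaussian kernel, length 2*radius+1.
gaussKernel1d <- function(radius = 5L, sigma = 1.5) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2D convolution of a matrix with a symmetric 1D kernel along both
# axes, "same" size, zero padding. Self-adjoint because the kernel is
# symmetric and the padding is zero.
filter2Sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  # rows
  pad <- matrix(0, n1 + 2L * r, n2)
  pad[(r + 1L):(r + n1), ] <- m
  out <- matrix(0, n1, n2)
  for (i in seq_along(k))
    out <- out + k[i] * pad[i:(i + n1 - 1L), , drop = FALSE]
  # cols
  pad2 <- matrix(0, n1, n2 + 2L * r)
  pad2[, (r + 1L):(r + n2)] <- out
  out2 <- matrix(0, n1, n2)
  for (i in seq_along(k))
    out2 <- out2 + k[i] * pad2[, i:(i + n2 - 1L), drop = FALSE]
  out2
}

# Shift a logical/numeric 3D array by one voxel along one axis, zero/FALSE
# filling. Used for surface extraction.
shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  if (d[axis] == 1L) return(out)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1L) {
    dst[[axis]] <- 2L:d[axis]; src[[axis]] <- 1L:(d[axis] - 1L)
  } else {
    dst[[axis]] <- 1L:(d[axis] - 1L); src[[axis]] <- 2L:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Label connected components of a logical 3D array.
# connectivity: 6 (faces) or 26 (faces+edges+corners).
# Returns an integer array, 0 outside, component id inside.
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  zo <- offs$dz; yo <- offs$dy; xo <- offs$dx
  co <- arrayInd(idx, d)
  keyenv <- new.env(hash = TRUE, size = length(idx) * 2L)
  for (i in seq_along(idx))
    assign(as.character(idx[i]), i, envir = keyenv)
  visited <- logical(length(idx))
  cur <- 0L
  for (i in seq_along(idx)) {
    if (visited[i]) next
    cur <- cur + 1L
    queue <- i
    visited[i] <- TRUE
    while (length(queue)) {
      j <- queue[length(queue)]
      queue <- queue[-length(queue)]
      lab[idx[j]] <- cur
      z <- co[j, 1]; y <- co[j, 2]; x <- co[j, 3]
      nz <- z + zo; ny <- y + yo; nx <- x + xo
      ok <- nz >= 1L & nz <= d[1] & ny >= 1L & ny <= d[2] &
            nx >= 1L & nx <= d[3]
      lin <- (nx[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nz[ok]
      for (l in lin) {
        pos <- keyenv[[as.character(l)]]
        if (!is.null(pos) && !visited[pos]) {
          visited[pos] <- TRUE
          queue <- c(queue, pos)
        }
      }
    }
  }
  lab
}

# Minimum Euclidean distance from each row of A (n x 3, mm) to the point set
# B (m x 3, mm), chunked to bound memory.
minDistToSet <- function(A, B, chunk = 512L) {
  n <- nrow(A)
  out <- numeric(n)
  b2 <- rowSums(B^2)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Ac <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, "+") - 2 * Ac %*% t(B)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

stopifnotMask <- function(m, what = "mask") {
  if (!is.logical(m)) stop(what, " must be logical")
  if (length(dim(m)) != 3L) stop(what, " must be a 3D array")
}

asArray3 <- function(x) {
  if (is(x, "CTVolume")) return(x@data)
  if (is.matrix(x)) return(array(x, c(1L, nrow(x), ncol(x))))
  if (length(dim(x)) == 3L) return(x)
  stop("expected a CTVolume, matrix, or 3D array")
}
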