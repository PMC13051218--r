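# Noncontrast -> enhanced translation network.
#
# A compact U-shaped network: convolutional encoder stages (3x3 conv + ReLU
# + 2x2 max pool), a transformer bottleneck over 1x1 tokens of the deepest
# feature map (learned positional embedding, pre-norm blocks of multi-head
# self-attention and an MLP with residual connections), and a convolutional
# decoder with per-stage skip concatenation. The head is a zero-initialised
# 1x1 convolution added to the input (global residual), so the network
# predicts the contrast-enhancement field. With trans_layers = 0 the
# architecture reduces to a plain U-Net (ablation mode).

#' Network architecture configuration
#'
#' @param in_shape square slice size in voxels; must be divisible by
#'   2^length(enc_channels).
#' @param enc_channels channel width per encoder stage (depth = length).
#' @param trans_layers number of transformer blocks in the bottleneck; 0
#'   gives the plain U-Net ablation.
#' @param trans_heads attention heads; must divide embed_dim.
#' @param embed_dim token embedding width of the bottleneck.
#' @param skip logical, per-stage skip connections (recycled to depth).
#' @param residual global input-plus-delta residual head.
#' @return validated list of class \code{modelConfig}.
#' @export
modelConfig <- function(in_shape = 64L, enc_channels = c(16L, 32L),
                        trans_layers = 2L, trans_heads = 4L,
                        embed_dim = 64L, skip = TRUE, residual = TRUE) {
  n_stages <- length(enc_channels)
  if (in_shape %% (2^n_stages) != 0)
    stop("in_shape must be divisible by 2^n_stages")
  if (trans_layers > 0 && embed_dim %% trans_heads != 0)
    stop("embed_dim must be divisible by trans_heads")
  structure(list(in_shape = as.integer(in_shape),
                 enc_channels = as.integer(enc_channels),
                 n_stages = n_stages,
                 trans_layers = as.integer(trans_layers),
                 trans_heads = as.integer(trans_heads),
                 embed_dim = as.integer(embed_dim),
                 skip = rep_len(as.logical(skip), n_stages),
                 residual = isTRUE(residual)),
            class = "modelConfig")
}

#' Optimisation configuration
#'
#' Desk-scale defaults (batch 8, AdamW at 1e-3, a few tens of epochs) suit
#' phantom training on one CPU; the full-scale protocol (batch 32, lr 1e-4,
#' up to 1000 epochs) is reachable through these fields.
#'
#' @param batch_size slices per optimisation step.
#' @param max_epochs epoch budget.
#' @param patience early-stop epochs without validation-loss improvement.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param selection_metric checkpoint selection; validation region-weighted
#'   SSIM ("val_wssim") is the default.
#' @param min_delta smallest validation-loss decrease counted as an
#'   improvement by early stopping.
#' @param folds k for cross-validation.
#' @param augment apply paired geometric/intensity augmentation.
#' @param seed training RNG seed.
#' @return validated list of class \code{trainConfig}.
#' @export
trainConfig <- function(batch_size = 8L, max_epochs = 40L, patience = 10L,
                        lr = 1e-3, weight_decay = 1e-4,
                        selection_metric = "val_wssim", folds = 5L,
                        augment = FALSE, min_delta = 1e-6, seed = 1L) {
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  if (lr <= 0) stop("learning rate must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr = lr, weight_decay = weight_decay,
                 selection_metric = selection_metric,
                 min_delta = min_delta,
                 folds = as.integer(folds),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Build (initialise) the translation network
#'
#' He initialisation for convolutions, Xavier for the transformer
#' projections, zeros for the output head (so the initial network is the
#' identity in residual mode). Deterministic given \code{seed}.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed RNG seed for the initial parameters.
#' @return list with \code{params} (flat named list of arrays),
#'   \code{config}, and \code{n_parameters}.
#' @export
buildModel <- function(config = modelConfig(), seed = 1L) {
  withSeed(seed, {
    p <- list()
    he <- function(co, ci9) matrix(rnorm(co * ci9, 0, sqrt(2 / ci9)), co, ci9)
    xav <- function(a, b) matrix(rnorm(a * b, 0, sqrt(1 / a)), a, b)
    chans <- c(1L, config$enc_channels)
    for (s in seq_len(config$n_stages)) {
      p[[paste0("enc", s, "_W")]] <- he(chans[s + 1], 9L * chans[s])
      p[[paste0("enc", s, "_b")]] <- numeric(chans[s + 1])
    }
    cb <- config$enc_channels[config$n_stages]
    hb <- config$in_shape %/% (2^config$n_stages)
    if (config$trans_layers > 0) {
      D <- config$embed_dim
      p$proj_in_W <- xav(cb, D); p$proj_in_b <- numeric(D)
      p$pos <- matrix(rnorm(hb * hb * D, 0, 0.02), hb * hb, D)
      for (l in seq_len(config$trans_layers)) {
        pre <- paste0("t", l, "_")
        p[[paste0(pre, "ln1_g")]] <- rep(1, D)
        p[[paste0(pre, "ln1_b")]] <- numeric(D)
        for (nm in c("Wq", "Wk", "Wv", "Wo"))
          p[[paste0(pre, nm)]] <- xav(D, D)
        for (nm in c("bq", "bk", "bv", "bo"))
          p[[paste0(pre, nm)]] <- numeric(D)
        p[[paste0(pre, "ln2_g")]] <- rep(1, D)
        p[[paste0(pre, "ln2_b")]] <- numeric(D)
        p[[paste0(pre, "W1")]] <- xav(D, 4L * D)
        p[[paste0(pre, "b1")]] <- numeric(4L * D)
        p[[paste0(pre, "W2")]] <- xav(4L * D, D)
        p[[paste0(pre, "b2")]] <- numeric(D)
      }
      p$proj_out_W <- xav(D, cb); p$proj_out_b <- numeric(cb)
    }
    for (s in rev(seq_len(config$n_stages))) {
      cin <- if (s == config$n_stages) cb else config$enc_channels[s + 1]
      cin <- cin + if (config$skip[s]) config$enc_channels[s] else 0L
      p[[paste0("dec", s, "_W")]] <- he(config$enc_channels[s], 9L * cin)
      p[[paste0("dec", s, "_b")]] <- numeric(config$enc_channels[s])
    }
    p$head_W <- matrix(0, 1L, config$enc_channels[1])
    p$head_b <- 0
    list(params = p, config = config,
         n_parameters = sum(vapply(p, length, numeric(1))))
  })
}

# Forward pass over one slice (H x W matrix, normalized intensities).
netForward <- function(params, config, x, keepCache = FALSE) {
  S <- config$n_stages
  h <- array(x, c(1L, nrow(x), ncol(x)))
  cache <- list(skips = vector("list", S))
  for (s in seq_len(S)) {
    cv <- conv3Forward(params[[paste0("enc", s, "_W")]],
                       params[[paste0("enc", s, "_b")]], h)
    rl <- reluForward(cv$out)
    pl <- poolForward(rl$out)
    h <- pl$out
    if (keepCache)
      cache[[paste0("enc", s)]] <- list(cv = cv, rl = rl, pl = pl)
    cache$skips[[s]] <- rl$out
  }
  if (config$trans_layers > 0) {
    d <- dim(h); cb <- d[1]; hb <- d[2]
    Tm <- t(matrix(h, cb, hb * hb))                     # tokens x channels
    pi_ <- linForward(Tm, params$proj_in_W, params$proj_in_b)
    Tt <- pi_$out + params$pos
    tcaches <- vector("list", config$trans_layers)
    for (l in seq_len(config$trans_layers)) {
      pre <- paste0("t", l, "_")
      ln1 <- lnForward(Tt, params[[paste0(pre, "ln1_g")]],
                       params[[paste0(pre, "ln1_b")]])
      at <- mhsaForward(ln1$out, params, pre, config$trans_heads)
      T1 <- Tt + at$out
      ln2 <- lnForward(T1, params[[paste0(pre, "ln2_g")]],
                       params[[paste0(pre, "ln2_b")]])
      l1 <- linForward(ln2$out, params[[paste0(pre, "W1")]],
                       params[[paste0(pre, "b1")]])
      r1 <- reluForward(l1$out)
      l2 <- linForward(r1$out, params[[paste0(pre, "W2")]],
                       params[[paste0(pre, "b2")]])
      Tt <- T1 + l2$out
      if (keepCache)
        tcaches[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2, l1 = l1,
                             r1 = r1, l2 = l2)
    }
    po <- linForward(Tt, params$proj_out_W, params$proj_out_b)
    h <- array(t(po$out), c(cb, hb, hb))
    if (keepCache) {
      cache$trans <- list(pi_ = pi_, tcaches = tcaches, po = po,
                          cb = cb, hb = hb)
    }
  }
  for (s in rev(seq_len(S))) {
    up <- upsampleForward(h)
    hin <- if (config$skip[s]) {
      d1 <- dim(up$out); d2 <- dim(cache$skips[[s]])
      out <- array(0, c(d1[1] + d2[1], d1[2], d1[3]))
      out[seq_len(d1[1]), , ] <- up$out
      out[d1[1] + seq_len(d2[1]), , ] <- cache$skips[[s]]
      out
    } else up$out
    cv <- conv3Forward(params[[paste0("dec", s, "_W")]],
                       params[[paste0("dec", s, "_b")]], hin)
    rl <- reluForward(cv$out)
    h <- rl$out
    if (keepCache)
      cache[[paste0("dec", s)]] <- list(up = up, cv = cv, rl = rl,
                                        nup = dim(up$out)[1])
  }
  hd <- conv1Forward(params$head_W, params$head_b, h)
  out <- hd$out[1, , ]
  if (config$residual) out <- out + x
  if (keepCache) cache$head <- hd
  list(out = out, cache = if (keepCache) cache else NULL)
}

# Backward pass: dout is d(loss)/d(output slice), same shape as the slice.
netBackward <- function(params, config, cache, dout) {
  g <- list()
  S <- config$n_stages
  dh <- array(dout, c(1L, nrow(dout), ncol(dout)))
  hb_ <- conv1Backward(params$head_W, cache$head, dh)
  g$head_W <- hb_$dW; g$head_b <- hb_$db
  dh <- hb_$dx
  dskips <- vector("list", S)
  for (s in seq_len(S)) {
    dc <- cache[[paste0("dec", s)]]
    dr <- reluBackward(dc$rl, dh)
    cb_ <- conv3Backward(params[[paste0("dec", s, "_W")]], dc$cv, dr)
    g[[paste0("dec", s, "_W")]] <- cb_$dW
    g[[paste0("dec", s, "_b")]] <- cb_$db
    dhin <- cb_$dx
    if (config$skip[s]) {
      nup <- dc$nup
      dskips[[s]] <- dhin[nup + seq_len(dim(dhin)[1] - nup), , ,
                          drop = FALSE]
      dup <- dhin[seq_len(nup), , , drop = FALSE]
    } else dup <- dhin
    dh <- upsampleBackward(dc$up, dup)
  }
  if (config$trans_layers > 0) {
    tc <- cache$trans
    dT <- t(matrix(dh, tc$cb, tc$hb * tc$hb))
    pb <- linBackward(tc$po, params$proj_out_W, dT)
    g$proj_out_W <- pb$dW; g$proj_out_b <- pb$db
    dTt <- pb$dx
    for (l in rev(seq_len(config$trans_layers))) {
      pre <- paste0("t", l, "_")
      lc <- tc$tcaches[[l]]
      # Tt = T1 + l2(relu(l1(ln2(T1))))
      l2b <- linBackward(lc$l2, params[[paste0(pre, "W2")]], dTt)
      g[[paste0(pre, "W2")]] <- l2b$dW; g[[paste0(pre, "b2")]] <- l2b$db
      drl <- reluBackward(lc$r1, l2b$dx)
      l1b <- linBackward(lc$l1, params[[paste0(pre, "W1")]], drl)
      g[[paste0(pre, "W1")]] <- l1b$dW; g[[paste0(pre, "b1")]] <- l1b$db
      ln2b <- lnBackward(lc$ln2, params[[paste0(pre, "ln2_g")]], l1b$dx)
      g[[paste0(pre, "ln2_g")]] <- ln2b$dg
      g[[paste0(pre, "ln2_b")]] <- ln2b$db
      dT1 <- dTt + ln2b$dx
      # T1 = Tt_in + mhsa(ln1(Tt_in))
      ab <- mhsaBackward(lc$at, params, pre, dT1)
      for (nm in names(ab$grads)) g[[nm]] <- ab$grads[[nm]]
      ln1b <- lnBackward(lc$ln1, params[[paste0(pre, "ln1_g")]], ab$dx)
      g[[paste0(pre, "ln1_g")]] <- ln1b$dg
      g[[paste0(pre, "ln1_b")]] <- ln1b$db
      dTt <- dT1 + ln1b$dx
    }
    g$pos <- dTt
    pib <- linBackward(tc$pi_, params$proj_in_W, dTt)
    g$proj_in_W <- pib$dW; g$proj_in_b <- pib$db
    dh <- array(t(pib$dx), c(tc$cb, tc$hb, tc$hb))
  }
  for (s in rev(seq_len(S))) {
    ec <- cache[[paste0("enc", s)]]
    dpool <- poolBackward(ec$pl, dh)
    if (!is.null(dskips[[s]])) dpool <- dpool + dskips[[s]]
    dr <- reluBackward(ec$rl, dpool)
    cb_ <- conv3Backward(params[[paste0("enc", s, "_W")]], ec$cv, dr)
    g[[paste0("enc", s, "_W")]] <- cb_$dW
    g[[paste0("enc", s, "_b")]] <- cb_$db
    dh <- cb_$dx
  }
  g
}

# ---- Preprocessing ---------------------------------------------------------

#' Intensity normalisation with an exact inverse
#'
#' Clips to the HU window, then z-scores with dataset-level statistics. When
#' \code{stats} is NULL the statistics are computed from the supplied data
#' and tagged with their provenance; training-set statistics must be reused
#' verbatim on validation/test data (no leakage).
#'
#' @param x array or \code{CTVolume} of HU values.
#' @param hu_window c(low, high) clipping window.
#' @param stats optional list(mean, sd, hu_window, source) from the
#'   training split.
#' @param source provenance tag recorded when computing fresh statistics.
#' @return list: \code{data} (normalised array), \code{stats}.
#' @export
normalizeIntensity <- function(x, hu_window = c(-1000, 2000), stats = NULL,
                               source = "train") {
  xa <- asArray3(if (is(x, "CTVolume")) voxelData(x) else x)
  xa <- pmin(pmax(xa, hu_window[1]), hu_window[2])
  if (is.null(stats)) {
    s <- sd(xa)
    if (s == 0) stop("zero intensity SD: cannot normalise a constant volume")
    stats <- list(mean = mean(xa), sd = s, hu_window = hu_window,
                  source = source)
  } else {
    if (!identical(as.numeric(stats$hu_window), as.numeric(hu_window)))
      hu_window <- stats$hu_window
  }
  list(data = (xa - stats$mean) / stats$sd, stats = stats)
}

#' Invert the intensity normalisation
#' @param x normalised array.
#' @param stats the statistics used to normalise.
#' @return array of HU values.
#' @export
denormalizeIntensity <- function(x, stats) x * stats$sd + stats$mean

# ---- Augmentation ----------------------------------------------------------

# Sample a 2D grid with bilinear (image) or nearest (mask) interpolation.
warpSlice <- function(m, theta, ty, tx, nearest = FALSE, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  sy <- cos(theta) * yy - sin(theta) * xx + cy - ty
  sx <- sin(theta) * yy + cos(theta) * xx + cx - tx
  if (nearest) {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(iy[ok], ix[ok])]
    return(out)
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gv <- function(iy, ix) {
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    v <- matrix(fill, H, W)
    v[ok] <- m[cbind(iy[ok], ix[ok])]
    v
  }
  gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0 + 1, x0) * fy * (1 - fx) +
    gv(y0, x0 + 1) * (1 - fy) * fx + gv(y0 + 1, x0 + 1) * fy * fx
}

#' Paired slice augmentation
#'
#' One geometric transform (left-right flip with probability 1/2, rotation
#' within +/-10 degrees, translation up to 5% of the extent) applied
#' identically to input, target and masks (nearest-neighbour for masks, so
#' they stay binary); an intensity scale jitter within +/-10% applied to
#' the input only. Seeded and reproducible.
#'
#' @param x,y input and target slices (matrices, HU).
#' @param masks named list of logical matrices.
#' @param seed RNG seed for this draw.
#' @param max_rotate_deg,max_translate_frac,intensity_jitter transform
#'   bounds.
#' @return list(x, y, masks, transform).
#' @export
augmentPair <- function(x, y, masks, seed,
                        max_rotate_deg = 10, max_translate_frac = 0.05,
                        intensity_jitter = 0.1) {
  withSeed(seed, {
    flip <- runif(1) < 0.5
    theta <- runif(1, -max_rotate_deg, max_rotate_deg) * pi / 180
    ty <- runif(1, -1, 1) * max_translate_frac * nrow(x)
    tx <- runif(1, -1, 1) * max_translate_frac * ncol(x)
    gain <- 1 + runif(1, -intensity_jitter, intensity_jitter)
    doFlip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    tr <- function(m, nearest, fill) {
      if (flip) m <- doFlip(m)
      warpSlice(m, theta, ty, tx, nearest = nearest, fill = fill)
    }
    xa <- tr(x, FALSE, -1000) * gain
    ya <- tr(y, FALSE, -1000)
    ma <- lapply(masks, function(m) tr(m * 1, TRUE, 0) > 0.5)
    list(x = xa, y = ya, masks = ma,
         transform = list(flip = flip, theta = theta, ty = ty, tx = tx,
                          gain = gain))
  })
}

# ---- Slice dataset ---------------------------------------------------------

cropCenter <- function(m, size) {
  H <- nrow(m); W <- ncol(m)
  if (H < size || W < size)
    stop("slice smaller than the model input size")
  y0 <- (H - size) %/% 2L; x0 <- (W - size) %/% 2L
  m[(y0 + 1L):(y0 + size), (x0 + 1L):(x0 + size), drop = FALSE]
}

# Flatten a list of PairedSamples into per-slice training records.
sliceDataset <- function(samples, in_shape, regions = kappaRegions()) {
  recs <- list()
  for (si in seq_along(samples)) {
    ph <- samples[[si]]
    nc <- voxelData(noncontrast(ph)); en <- voxelData(enhanced(ph))
    ml <- maskSet(ph)@masks
    regs <- intersect(regions, names(ml))
    for (z in seq_len(dim(nc)[1])) {
      msl <- lapply(ml[regs], function(m) cropCenter(m[z, , ], in_shape))
      msl <- msl[vapply(msl, any, logical(1))]
      if (!length(msl)) next
      recs[[length(recs) + 1L]] <-
        list(x = cropCenter(nc[z, , ], in_shape),
             y = cropCenter(en[z, , ], in_shape),
             masks = msl, sample = si, z = z)
    }
  }
  recs
}

sliceLoss <- function(out_hu, rec, lcfg, params_ssim) {
  weightedSSIMLoss(out_hu, rec$y, rec$masks, epsilon = lcfg$epsilon,
                   params = params_ssim, regions = names(rec$masks))
}

# ---- Training --------------------------------------------------------------

#' Train the translation network
#'
#' Minimises the region-weighted SSIM loss on training slices with AdamW.
#' Early stopping monitors the validation loss; the returned best
#' checkpoint is the epoch with the highest validation region-weighted
#' SSIM. Fully reproducible given the training seed.
#'
#' @param manifest dataset manifest from \code{\link{generateDataset}}, or
#'   a list with \code{train} / \code{val} lists of \code{PairedSample}s.
#' @param model_config \code{\link{modelConfig}}.
#' @param train_config \code{\link{trainConfig}}.
#' @param loss_config \code{\link{lossConfig}}.
#' @param verbose print per-epoch progress.
#' @return list of class \code{trainState}: \code{history} (per-epoch
#'   train/val loss and val wSSIM), \code{best} (epoch, params),
#'   \code{params} (final), \code{norm_stats}, configs, and
#'   \code{init_val_loss}.
#' @export
trainModel <- function(manifest, model_config = modelConfig(),
                       train_config = trainConfig(),
                       loss_config = lossConfig(), verbose = FALSE) {
  sets <- resolveSplits(manifest)
  if (!length(sets$train)) stop("manifest has no training samples")
  if (!length(sets$val)) stop("manifest has no validation samples")
  checkKappaMasks(sets$train)

  # dataset-level normalisation statistics from the training split only
  trainvox <- unlist(lapply(sets$train, function(ph) {
    pmin(pmax(voxelData(noncontrast(ph)), loss_config$hu_window[1]),
         loss_config$hu_window[2])
  }))
  s <- sd(trainvox)
  if (s == 0) stop("zero intensity SD on the training split")
  stats <- list(mean = mean(trainvox), sd = s,
                hu_window = loss_config$hu_window, source = "train")

  ds_train <- sliceDataset(sets$train, model_config$in_shape)
  ds_val <- sliceDataset(sets$val, model_config$in_shape)
  if (!length(ds_train)) stop("no usable training slices")
  pssim <- paramsFromLossConfig(loss_config)

  model <- buildModel(model_config,
                      seed = deriveSeed(train_config$seed, "init"))
  params <- model$params
  opt <- adamwInit(params)

  evalLoss <- function(params, ds) {
    tot <- 0
    for (rec in ds) {
      xn <- (pmin(pmax(rec$x, stats$hu_window[1]), stats$hu_window[2]) -
               stats$mean) / stats$sd
      fw <- netForward(params, model_config, xn)
      out_hu <- denormalizeIntensity(fw$out, stats)
      tot <- tot + sliceLoss(out_hu, rec, loss_config, pssim)
    }
    tot / length(ds)
  }

  init_val <- evalLoss(params, ds_val)
  if (verbose) message(sprintf("init val loss %.5f", init_val))

  nbatch <- max(1L, ceiling(length(ds_train) / train_config$batch_size))
  history <- data.frame()
  best <- list(val_wssim = -Inf, epoch = 0L, params = params)
  bad_epochs <- 0L
  best_val_loss <- Inf
  step <- 0L

  for (epoch in seq_len(train_config$max_epochs)) {
    ord <- withSeed(deriveSeed(train_config$seed, paste0("epoch", epoch)),
                    sample.int(length(ds_train)))
    epoch_loss <- 0
    for (bi in seq_len(nbatch)) {
      idx <- ord[((bi - 1L) * train_config$batch_size + 1L):
                   min(bi * train_config$batch_size, length(ds_train))]
      idx <- idx[!is.na(idx)]
      gacc <- NULL
      bl <- 0
      for (ii in idx) {
        rec <- ds_train[[ii]]
        if (train_config$augment) {
          aug <- augmentPair(rec$x, rec$y, rec$masks,
                             seed = deriveSeed(train_config$seed,
                                               paste0("aug", epoch, "_", ii)))
          rec$x <- aug$x; rec$y <- aug$y
          rec$masks <- aug$masks[vapply(aug$masks, any, logical(1))]
          if (!length(rec$masks)) next
        }
        xn <- (pmin(pmax(rec$x, stats$hu_window[1]), stats$hu_window[2]) -
                 stats$mean) / stats$sd
        fw <- netForward(params, model_config, xn, keepCache = TRUE)
        out_hu <- denormalizeIntensity(fw$out, stats)
        lg <- weightedSSIMLossGrad(out_hu, rec$y, rec$masks,
                                   epsilon = loss_config$epsilon,
                                   params = pssim,
                                   regions = names(rec$masks))
        bl <- bl + lg$loss
        dout <- lg$grad[1, , ] * stats$sd        # chain through denorm
        gs <- netBackward(params, model_config, fw$cache, dout)
        gacc <- accumGrads(gacc, gs)
      }
      if (is.null(gacc)) next
      gacc <- scaleGrads(gacc, 1 / length(idx))
      up <- adamwStep(params, gacc, opt, lr = train_config$lr,
                      weight_decay = train_config$weight_decay)
      params <- up$params; opt <- up$state
      step <- step + 1L
      epoch_loss <- epoch_loss + bl / length(idx)
    }
    val_loss <- evalLoss(params, ds_val)
    val_wssim <- 1 - val_loss
    history <- rbind(history,
                     data.frame(epoch = epoch, step = step,
                                train_loss = epoch_loss / nbatch,
                                val_loss = val_loss,
                                val_wssim = val_wssim))
    if (verbose)
      message(sprintf("epoch %d  train %.5f  val %.5f  wSSIM %.5f",
                      epoch, epoch_loss / nbatch, val_loss, val_wssim))
    if (val_wssim > best$val_wssim)
      best <- list(val_wssim = val_wssim, epoch = epoch, params = params)
    if (val_loss < best_val_loss - train_config$min_delta) {
      best_val_loss <- val_loss
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= train_config$patience) break
    }
  }
  structure(list(history = history, best = best, params = params,
                 norm_stats = stats, model_config = model_config,
                 train_config = train_config, loss_config = loss_config,
                 init_val_loss = init_val, n_parameters = model$n_parameters),
            class = "trainState")
}

resolveSplits <- function(manifest) {
  if (!is.null(manifest$samples)) {
    sp <- as.numeric(manifest$spacing_mm)
    out <- list(train = list(), val = list(), test = list())
    for (s in manifest$samples)
      out[[s$split]] <- c(out[[s$split]], list(loadSample(s, spacing = sp)))
    return(out)
  }
  manifest
}

checkKappaMasks <- function(samples) {
  for (i in seq_along(samples)) {
    present <- maskNames(samples[[i]])
    miss <- setdiff(kappaRegions(), present)
    if (length(miss) == length(kappaRegions()))
      stop("training sample ", i, " carries none of the loss regions (",
           paste(miss, collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' Inference: noncontrast volume to virtual enhanced volume
#'
#' Slice-wise forward pass through a trained checkpoint, inverse-normalised
#' back to HU and reassembled on the input grid (spacing and origin
#' preserved). Deterministic given the checkpoint.
#'
#' @param volume noncontrast \code{CTVolume}.
#' @param state a \code{trainState} (or checkpoint list) with params,
#'   configs and normalisation statistics.
#' @param useBest use the best-validation-wSSIM parameters (default) rather
#'   than the final ones.
#' @return virtual enhanced \code{CTVolume}.
#' @export
inferVolume <- function(volume, state, useBest = TRUE) {
  params <- if (useBest && !is.null(state$best)) state$best$params
            else state$params
  cfg <- state$model_config
  stats <- state$norm_stats
  va <- voxelData(volume)
  d <- dim(va)
  if (d[2] < cfg$in_shape || d[3] < cfg$in_shape)
    stop("volume in-plane size smaller than the model input")
  out <- va
  y0 <- (d[2] - cfg$in_shape) %/% 2L
  x0 <- (d[3] - cfg$in_shape) %/% 2L
  for (z in seq_len(d[1])) {
    xs <- cropCenter(va[z, , ], cfg$in_shape)
    xn <- (pmin(pmax(xs, stats$hu_window[1]), stats$hu_window[2]) -
             stats$mean) / stats$sd
    fw <- netForward(params, cfg, xn)
    out[z, (y0 + 1L):(y0 + cfg$in_shape), (x0 + 1L):(x0 + cfg$in_shape)] <-
      denormalizeIntensity(fw$out, stats)
  }
  CTVolume(out, spacing = voxelSpacing(volume), origin = gridOrigin(volume))
}

#' k-fold cross-validation on the training split
#'
#' Seeded disjoint fold assignment stratified on target-volume tertiles (a
#' documented stand-in for the unstated stratification variable); trains
#' one model per fold and evaluates it on the held-out fold with the full
#' metric suite.
#'
#' @param manifest dataset manifest or list of \code{PairedSample}s.
#' @param k number of folds (>= 2).
#' @param model_config,train_config,loss_config configurations.
#' @return list: \code{folds} (assignment), \code{states} (per-fold
#'   trainState), \code{reports} (per-fold \code{MetricReport} lists),
#'   \code{summary} (mean/sd of held-out overall metrics).
#' @export
crossValidate <- function(manifest, k = 5L, model_config = modelConfig(),
                          train_config = trainConfig(),
                          loss_config = lossConfig()) {
  if (k < 2) stop("k must be >= 2")
  sets <- resolveSplits(manifest)
  samples <- c(sets$train, sets$val)
  n <- length(samples)
  if (n < k) stop("not enough samples for ", k, " folds")
  ctvvol <- vapply(samples, function(ph) sum(getMask(ph, "CTV")), numeric(1))
  folds <- stratifiedFolds(ctvvol, k,
                           seed = deriveSeed(train_config$seed, "folds"))
  states <- list(); reports <- list()
  overall <- data.frame()
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    if (!length(hold)) stop("fold ", f, " has zero samples")
    rest <- which(folds != f)
    nval <- max(1L, floor(length(rest) / 5))
    man <- list(train = samples[rest[-seq_len(nval)]],
                val = samples[rest[seq_len(nval)]])
    tc <- train_config
    tc$seed <- deriveSeed(train_config$seed, paste0("fold", f))
    st <- trainModel(man, model_config, tc, loss_config)
    reps <- lapply(samples[hold], function(ph) {
      pred <- inferVolume(noncontrast(ph), st)
      evaluateVolume(pred, enhanced(ph), maskSet(ph))
    })
    states[[f]] <- st
    reports[[f]] <- reps
    for (r in reps)
      overall <- rbind(overall, as.data.frame(as.list(r@overall)))
  }
  list(folds = folds, states = states, reports = reports,
       summary = data.frame(metric = names(overall),
                            mean = vapply(overall, mean, numeric(1)),
                            sd = vapply(overall, sd, numeric(1))))
}

stratifiedFolds <- function(strat, k, seed) {
  n <- length(strat)
  tert <- cut(rank(strat, ties.method = "first"), breaks = 3, labels = FALSE)
  folds <- integer(n)
  withSeed(seed, {
    # deal folds round-robin across strata with a global counter so every
    # fold is populated even when strata are smaller than k
    pos <- 0L
    for (g in sort(unique(tert))) {
      idx <- which(tert == g)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (pos + seq_along(idx) - 1L) %% k + 1L
      pos <- pos + length(idx)
    }
  })
  folds
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint directory holds the parameters, normalisation statistics
#' and all three configuration blocks.
#' @param state a \code{trainState}.
#' @param dir checkpoint directory.
#' @return \code{dir} (save) or a checkpoint list (load).
#' @export
saveCheckpoint <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(state, file.path(dir, "checkpoint.rds"))
  jsonlite::write_json(
    list(model_config = unclass(state$model_config),
         loss_config = state$loss_config,
         norm_stats = state$norm_stats,
         n_parameters = state$n_parameters,
         best_epoch = state$best$epoch),
    file.path(dir, "checkpoint.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) readRDS(file.path(dir, "checkpoint.rds"))
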