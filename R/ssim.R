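# ROI-area-weighted SSIM loss.
#
# The training objective is
#   L = 1 - sum_k w_k * SSIM_{Omega_k}(X, Y),
#   w_k = (A_k + eps)^-1 / sum_j (A_j + eps)^-1,
# where A_k is the voxel area of region Omega_k, so smaller regions (the
# clinical target volume in particular) contribute proportionally more than
# large ones (the body outline). The weights are a convex combination:
# positive, summing to one.

#' Default region set of the weighted SSIM loss
#'
#' The anatomically prioritised mask set used by the training loss: clinical
#' target volume, rectum, bladder, both kidneys, liver, and the body outline.
#' @return character vector of region labels.
#' @export
kappaRegions <- function() {
  c("CTV", "Rectum", "Bladder", "Kidney_Left", "Kidney_Right", "Liver", "Body")
}

#' SSIM stabilising constants
#'
#' Builds the c1, c2 constants from the dynamic range L of the intensity
#' scale: c1 = (k1 L)^2, c2 = (k2 L)^2 with the usual k1 = 0.01, k2 = 0.03.
#' For CT the range is the width of the HU display window after clipping
#' (default [-1000, 2000], so L = 3000).
#'
#' @param dynamicRange intensity range L.
#' @param k1,k2 stabiliser fractions.
#' @param window \code{"gaussian11"} for an 11x11 Gaussian (sigma 1.5) local
#'   SSIM map per axial slice, or \code{"global"} for the single-statistic
#'   SSIM over all in-scope voxels.
#' @return list with c1, c2, dynamicRange, window.
#' @export
ssimParams <- function(dynamicRange = 3000, k1 = 0.01, k2 = 0.03,
                       window = c("gaussian11", "global")) {
  window <- match.arg(window)
  stopifnot(dynamicRange > 0, k1 > 0, k2 > 0)
  list(c1 = (k1 * dynamicRange)^2, c2 = (k2 * dynamicRange)^2,
       dynamicRange = dynamicRange, window = window)
}

#' Loss configuration block
#'
#' @param epsilon area stabiliser (voxels) in the inverse-area weights.
#' @param window SSIM window mode, see \code{\link{ssimParams}}.
#' @param k1,k2 SSIM stabiliser fractions.
#' @param hu_window HU clipping window defining the dynamic range.
#' @param l1_weight optional voxelwise L1 term coefficient (default 0, off).
#' @return validated list.
#' @export
lossConfig <- function(epsilon = 1, window = "gaussian11",
                       k1 = 0.01, k2 = 0.03,
                       hu_window = c(-1000, 2000), l1_weight = 0) {
  stopifnot(epsilon >= 0, hu_window[2] > hu_window[1], l1_weight >= 0)
  list(epsilon = epsilon, window = window, k1 = k1, k2 = k2,
       hu_window = hu_window, l1_weight = l1_weight)
}

paramsFromLossConfig <- function(cfg) {
  ssimParams(dynamicRange = diff(cfg$hu_window), k1 = cfg$k1, k2 = cfg$k2,
             window = cfg$window)
}

#' Inverse-area region weights
#'
#' Computes w_k = (A_k + eps)^-1 / sum_j (A_j + eps)^-1 over the regions of a
#' mask set. Empty regions carry no usable similarity statistic and are
#' dropped (with a warning) before normalisation.
#'
#' @param masks a \code{MaskSet}, or a named list of logical arrays,
#'   restricted to the region set of interest.
#' @param epsilon area stabiliser in voxels.
#' @return list with \code{region_names}, \code{areas}, \code{epsilon},
#'   \code{weights} (named, summing to 1).
#' @export
regionWeights <- function(masks, epsilon = 1) {
  ml <- if (is(masks, "MaskSet")) masks@masks else masks
  if (!length(ml)) stop("no regions supplied")
  areas <- vapply(ml, sum, numeric(1))
  empty <- areas == 0
  if (all(empty)) stop("all regions are empty; cannot form weights")
  if (any(empty)) {
    warning("dropping empty region(s): ",
            paste(names(ml)[empty], collapse = ", "))
    areas <- areas[!empty]
  }
  inv <- 1 / (areas + epsilon)
  w <- inv / sum(inv)
  list(region_names = names(areas), areas = areas, epsilon = epsilon,
       weights = w)
}

# Pointwise SSIM value and partial derivatives with respect to the raw
# statistics mu_x, E[x^2] (mxx) and E[xy] (mxy); shared by the global and
# windowed modes. vx = mxx - mu_x^2, cxy = mxy - mu_x mu_y.
ssimTerms <- function(mux, muy, vx, vy, cxy, c1, c2, grad = FALSE) {
  a1 <- 2 * mux * muy + c1
  a2 <- 2 * cxy + c2
  b1 <- mux^2 + muy^2 + c1
  b2 <- vx + vy + c2
  s <- (a1 * a2) / (b1 * b2)
  if (!grad) return(list(s = s))
  dmxx <- -s / b2                       # via vx
  dmxy <- 2 * a1 / (b1 * b2)            # via cxy
  dmux <- 2 * muy * a2 / (b1 * b2) - s * 2 * mux / b1 +
    dmxx * (-2 * mux) + dmxy * (-muy)
  list(s = s, dmux = dmux, dmxx = dmxx, dmxy = dmxy)
}

# Per-slice local SSIM map (and stat maps) for the gaussian11 window.
ssimMapSlice <- function(xs, ys, c1, c2, kern) {
  mux <- filter2Sep(xs, kern); muy <- filter2Sep(ys, kern)
  mxx <- filter2Sep(xs * xs, kern); myy <- filter2Sep(ys * ys, kern)
  mxy <- filter2Sep(xs * ys, kern)
  vx <- mxx - mux^2; vy <- myy - muy^2
  cxy <- mxy - mux * muy
  list(mux = mux, muy = muy, vx = vx, vy = vy, cxy = cxy)
}

#' SSIM restricted to a region
#'
#' With \code{window = "gaussian11"}, the local SSIM map (11x11 Gaussian,
#' sigma 1.5, per axial slice, zero-padded) is averaged over the masked
#' voxels. With \code{window = "global"} the single SSIM statistic is
#' computed from the mean, variance and covariance of the masked voxels.
#'
#' @param x,y \code{CTVolume}s or arrays on the same grid.
#' @param mask logical array; must be nonempty.
#' @param params see \code{\link{ssimParams}}.
#' @return scalar in [-1, 1].
#' @export
regionSSIM <- function(x, y, mask, params = ssimParams()) {
  xa <- asArray3(x); ya <- asArray3(y); ma <- asArray3Mask(mask)
  if (!identical(dim(xa), dim(ya)) || !identical(dim(xa), dim(ma)))
    stop("x, y and mask must share a grid")
  if (!any(ma)) stop("empty mask: region SSIM undefined")
  if (params$window == "global") {
    xi <- xa[ma]; yi <- ya[ma]
    n <- length(xi)
    mux <- mean(xi); muy <- mean(yi)
    vx <- mean(xi^2) - mux^2; vy <- mean(yi^2) - muy^2
    cxy <- mean(xi * yi) - mux * muy
    return(ssimTerms(mux, muy, vx, vy, cxy, params$c1, params$c2)$s)
  }
  kern <- gaussKernel1d(5L, 1.5)
  tot <- 0; nn <- 0
  for (z in seq_len(dim(xa)[1])) {
    mz <- ma[z, , ]
    if (!any(mz)) next
    st <- ssimMapSlice(xa[z, , ], ya[z, , ], params$c1, params$c2, kern)
    s <- ssimTerms(st$mux, st$muy, st$vx, st$vy, st$cxy,
                   params$c1, params$c2)$s
    tot <- tot + sum(s[mz]); nn <- nn + sum(mz)
  }
  tot / nn
}

#' ROI-area-weighted SSIM loss
#'
#' One minus the convex combination of per-region SSIMs, with weights
#' inversely proportional to region area (see \code{\link{regionWeights}}).
#' Small clinically critical regions therefore dominate the objective.
#'
#' @param x,y \code{CTVolume}s or arrays on the same grid (x: prediction,
#'   y: ground truth when used for training).
#' @param masks \code{MaskSet} or named list of logical arrays; only regions
#'   named in \code{regions} and present are used.
#' @param epsilon weight stabiliser, voxels.
#' @param params see \code{\link{ssimParams}}.
#' @param regions region labels forming the set kappa; defaults to
#'   \code{\link{kappaRegions}} intersected with the available masks.
#' @return scalar loss in [0, 2].
#' @export
weightedSSIMLoss <- function(x, y, masks, epsilon = 1, params = ssimParams(),
                             regions = NULL) {
  wssimLossCore(x, y, masks, epsilon, params, regions, grad = FALSE)$loss
}

#' Weighted SSIM loss with analytic gradient
#'
#' As \code{\link{weightedSSIMLoss}} but also returns d(loss)/dx, the exact
#' gradient with respect to the first image, used by the training loop.
#'
#' @inheritParams weightedSSIMLoss
#' @return list with \code{loss} and \code{grad} (array shaped like x).
#' @export
weightedSSIMLossGrad <- function(x, y, masks, epsilon = 1,
                                 params = ssimParams(), regions = NULL) {
  wssimLossCore(x, y, masks, epsilon, params, regions, grad = TRUE)
}

asArray3Mask <- function(m) {
  if (is.matrix(m)) m <- array(m, c(1L, nrow(m), ncol(m)))
  stopifnotMask(m)
  m
}

selectKappa <- function(masks, regions) {
  ml <- if (is(masks, "MaskSet")) masks@masks else masks
  if (is.null(regions)) {
    regions <- intersect(kappaRegions(), names(ml))
    if (!length(regions)) regions <- names(ml)
  } else {
    missing <- setdiff(regions, names(ml))
    if (length(missing))
      stop("regions not present in mask set: ",
           paste(missing, collapse = ", "))
  }
  ml[regions]
}

wssimLossCore <- function(x, y, masks, epsilon, params, regions, grad) {
  xa <- asArray3(x); ya <- asArray3(y)
  ml <- lapply(selectKappa(masks, regions), asArray3Mask)
  for (nm in names(ml))
    if (!identical(dim(ml[[nm]]), dim(xa)))
      stop("mask '", nm, "' grid differs from images")
  rw <- regionWeights(ml, epsilon)
  ml <- ml[rw$region_names]
  c1 <- params$c1; c2 <- params$c2

  if (params$window == "global") {
    loss <- 1
    g <- if (grad) array(0, dim(xa)) else NULL
    for (i in seq_along(ml)) {
      m <- ml[[i]]; w <- unname(rw$weights[i])
      xi <- xa[m]; yi <- ya[m]; n <- length(xi)
      mux <- mean(xi); muy <- mean(yi)
      vx <- mean(xi^2) - mux^2; vy <- mean(yi^2) - muy^2
      cxy <- mean(xi * yi) - mux * muy
      tt <- ssimTerms(mux, muy, vx, vy, cxy, c1, c2, grad = grad)
      loss <- loss - w * tt$s
      if (grad) {
        ds <- tt$dmux / n + tt$dmxx * 2 * xi / n + tt$dmxy * yi / n
        g[m] <- g[m] - w * ds
      }
    }
    out <- list(loss = loss, grad = g)
    return(out)
  }

  # gaussian11: pool the masked voxels of the per-slice SSIM maps; the
  # per-region mean becomes a single weight map G so each slice is filtered
  # once.
  counts <- vapply(ml, sum, numeric(1))
  G <- array(0, dim(xa))
  for (i in seq_along(ml))
    G[ml[[i]]] <- G[ml[[i]]] + rw$weights[i] / counts[i]
  kern <- gaussKernel1d(5L, 1.5)
  acc <- 0
  g <- if (grad) array(0, dim(xa)) else NULL
  for (z in seq_len(dim(xa)[1])) {
    Gz <- G[z, , ]
    if (!any(Gz != 0)) next
    xs <- xa[z, , ]; ys <- ya[z, , ]
    st <- ssimMapSlice(xs, ys, c1, c2, kern)
    tt <- ssimTerms(st$mux, st$muy, st$vx, st$vy, st$cxy, c1, c2, grad = grad)
    acc <- acc + sum(Gz * tt$s)
    if (grad) {
      # adjoint of the (self-adjoint) smoothing operator
      gz <- filter2Sep(Gz * tt$dmux, kern) +
        2 * xs * filter2Sep(Gz * tt$dmxx, kern) +
        ys * filter2Sep(Gz * tt$dmxy, kern)
      g[z, , ] <- -gz
    }
  }
  list(loss = 1 - acc, grad = g)
}
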