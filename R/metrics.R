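# Image-similarity and geometry metrics: MSE, PSNR, UQI, SSIM (whole image
# or ROI-restricted), Dice overlap, 95th-percentile Hausdorff distance,
# per-organ CT statistics, line profiles, and a peri-target hallucination
# screening proxy.

scopeVoxels <- function(x, y, mask) {
  xa <- asArray3(x); ya <- asArray3(y)
  if (!identical(dim(xa), dim(ya))) stop("image grids differ")
  if (is.null(mask)) return(list(x = as.vector(xa), y = as.vector(ya)))
  ma <- asArray3Mask(mask)
  if (!identical(dim(ma), dim(xa))) stop("mask grid differs from images")
  if (!any(ma)) stop("empty mask")
  list(x = xa[ma], y = ya[ma])
}

#' Mean squared error
#'
#' (1/n) sum (x_i - y_i)^2 over all voxels, or over the masked voxels when a
#' mask is supplied (ROI-restricted evaluation).
#'
#' @param x,y \code{CTVolume}s or arrays on the same grid.
#' @param mask optional logical array restricting the scope.
#' @return nonnegative scalar.
#' @export
mseMetric <- function(x, y, mask = NULL) {
  s <- scopeVoxels(x, y, mask)
  mean((s$x - s$y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' 10 log10(m^2 / MSE), where m is the peak attainable intensity. For HU
#' images the default peak is the width of the clipping window (3000).
#' Identical images have zero MSE; \code{Inf} is returned (a defined
#' sentinel) rather than an error.
#'
#' @inheritParams mseMetric
#' @param m peak intensity value.
#' @return scalar in dB (possibly \code{Inf}).
#' @export
psnrMetric <- function(x, y, m = 3000, mask = NULL) {
  e <- mseMetric(x, y, mask)
  if (e == 0) return(Inf)
  10 * log10(m^2 / e)
}

#' Universal quality index
#'
#' 4 mu_x mu_y sigma_xy / ((mu_x^2 + mu_y^2)(sigma_x^2 + sigma_y^2)) over
#' the in-scope voxels. Though commonly quoted on [0, 1], the statistic is
#' negative for anti-correlated images; the true value is reported.
#'
#' @inheritParams mseMetric
#' @return scalar, 1 for identical non-constant images.
#' @export
uqiMetric <- function(x, y, mask = NULL) {
  s <- scopeVoxels(x, y, mask)
  if (length(s$x) < 2) stop("need at least 2 voxels in scope")
  mux <- mean(s$x); muy <- mean(s$y)
  vx <- mean(s$x^2) - mux^2; vy <- mean(s$y^2) - muy^2
  cxy <- mean(s$x * s$y) - mux * muy
  den <- (mux^2 + muy^2) * (vx + vy)
  if (den == 0)
    stop("degenerate input: UQI undefined (both images constant or zero-mean)")
  4 * mux * muy * cxy / den
}

#' Global structural similarity index
#'
#' The single-statistic SSIM evaluated from the mean, variance and
#' covariance of the in-scope voxels, stabilised by c1, c2.
#'
#' @inheritParams mseMetric
#' @param params see \code{\link{ssimParams}}; the window setting is ignored
#'   (this is always the global statistic).
#' @return scalar in [-1, 1], 1 for identical images.
#' @export
ssimGlobal <- function(x, y, params = ssimParams(), mask = NULL) {
  s <- scopeVoxels(x, y, mask)
  mux <- mean(s$x); muy <- mean(s$y)
  vx <- mean(s$x^2) - mux^2; vy <- mean(s$y^2) - muy^2
  cxy <- mean(s$x * s$y) - mux * muy
  ssimTerms(mux, muy, vx, vy, cxy, params$c1, params$c2)$s
}

#' Dice similarity coefficient
#'
#' 2|A intersect B| / (|A| + |B|). Two empty masks agree perfectly on
#' absence and score 1 (with a warning).
#'
#' @param a,b logical arrays on the same grid.
#' @return scalar in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  a <- asArray3Mask(a); b <- asArray3Mask(b)
  if (!identical(dim(a), dim(b))) stop("mask grids differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1 by convention")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Extract the boundary surface of a voxel mask
#'
#' Surface voxels are mask voxels with at least one 6-connected neighbour
#' outside the mask (the volume border counts as outside). Returned points
#' are voxel centres in mm.
#'
#' @param mask logical 3D array (z, y, x).
#' @param spacing numeric(3), mm per axis.
#' @return list with \code{points} (n x 3 matrix, mm, columns z/y/x) and
#'   \code{n}.
#' @export
extractSurface <- function(mask, spacing = c(1, 1, 1)) {
  mask <- asArray3Mask(mask)
  if (!any(mask)) stop("empty mask has no surface")
  interior <- mask
  for (ax in 1:3) for (by in c(1L, -1L))
    interior <- interior & shift3(mask, ax, by)
  surf <- mask & !interior
  idx <- which(surf)
  co <- arrayInd(idx, dim(mask))
  pts <- sweep(co - 1, 2, spacing, "*")   # voxel-centre mm, origin at voxel 1
  colnames(pts) <- c("z", "y", "x")
  list(points = pts, n = nrow(pts))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Directed nearest-surface distances are computed both ways between the two
#' mask surfaces, pooled, and the 95th percentile (linear interpolation
#' between order statistics) of the pooled set is returned. With
#' \code{pooled = FALSE} the maximum of the two per-direction 95th
#' percentiles is returned instead.
#'
#' @param a,b logical masks on the same grid, both nonempty.
#' @param spacing numeric(3), mm per (z, y, x) axis.
#' @param percentile defaults to 95.
#' @param pooled pool the two directed distance sets before the percentile.
#' @return distance in mm.
#' @export
hausdorff95 <- function(a, b, spacing = c(1, 1, 1), percentile = 95,
                        pooled = TRUE) {
  sa <- extractSurface(a, spacing)
  sb <- extractSurface(b, spacing)
  dab <- minDistToSet(sa$points, sb$points)
  dba <- minDistToSet(sb$points, sa$points)
  if (pooled) {
    unname(quantile(c(dab, dba), percentile / 100, type = 7))
  } else {
    max(quantile(dab, percentile / 100, type = 7),
        quantile(dba, percentile / 100, type = 7))
  }
}

#' Per-tissue CT value statistics
#'
#' Mask-mean and mask-SD of the HU values per requested tissue, shaped like
#' a CT-value distribution table row set. Missing tissues are reported as
#' absent (NA row) rather than silently skipped.
#'
#' @param volume \code{CTVolume} or array.
#' @param masks \code{MaskSet} or named list of logical arrays.
#' @param tissues tissue labels to report; defaults to all masks.
#' @return data.frame with columns tissue, mean_hu, sd_hu, n_voxels,
#'   present.
#' @export
ctStatistics <- function(volume, masks, tissues = NULL) {
  va <- asArray3(volume)
  ml <- if (is(masks, "MaskSet")) masks@masks else masks
  if (is.null(tissues)) tissues <- names(ml)
  rows <- lapply(tissues, function(tn) {
    if (!tn %in% names(ml))
      return(data.frame(tissue = tn, mean_hu = NA_real_, sd_hu = NA_real_,
                        n_voxels = 0L, present = FALSE))
    m <- ml[[tn]]
    v <- va[m]
    data.frame(tissue = tn, mean_hu = mean(v),
               sd_hu = if (length(v) > 1) sd(v) else 0,
               n_voxels = length(v), present = TRUE)
  })
  do.call(rbind, rows)
}

#' Line profile of CT numbers
#'
#' HU values along one row (horizontal) or column (vertical) of an axial
#' slice, with mm coordinates along the profile.
#'
#' @param volume \code{CTVolume}.
#' @param axis \code{"vertical"} (varying y at fixed x) or
#'   \code{"horizontal"} (varying x at fixed y).
#' @param sliceIndex axial slice (z index).
#' @param lineIndex the fixed x (vertical) or y (horizontal) index.
#' @return data.frame with columns position_mm and hu.
#' @export
lineProfile <- function(volume, axis = c("vertical", "horizontal"),
                        sliceIndex, lineIndex) {
  axis <- match.arg(axis)
  va <- asArray3(volume)
  sp <- if (is(volume, "CTVolume")) volume@spacing else c(1, 1, 1)
  d <- dim(va)
  if (sliceIndex < 1 || sliceIndex > d[1]) stop("slice index out of range")
  if (axis == "vertical") {
    if (lineIndex < 1 || lineIndex > d[3]) stop("line index out of range")
    hu <- va[sliceIndex, , lineIndex]
    pos <- (seq_len(d[2]) - 1) * sp[2]
  } else {
    if (lineIndex < 1 || lineIndex > d[2]) stop("line index out of range")
    hu <- va[sliceIndex, lineIndex, ]
    pos <- (seq_len(d[3]) - 1) * sp[3]
  }
  data.frame(position_mm = pos, hu = hu)
}

#' Peri-target hallucination screening proxy
#'
#' Screens the band extending a fixed distance above and below the clinical
#' target volume (default +/- 50 mm along z) for connected components
#' (26-connectivity) of large prediction errors (|pred - truth| above
#' \code{delta_hu}) lying outside every true enhancing-tissue mask. A case
#' is flagged when at least one sufficiently large component exists. This is
#' an automated proxy for radiologist hallucination screening, not a
#' reimplementation of any subjective score; its thresholds are exposed.
#'
#' @param predicted,groundTruth \code{CTVolume}s or arrays on one grid.
#' @param masks \code{MaskSet} containing at least a CTV mask.
#' @param band_mm band half-width along z beyond the CTV extent.
#' @param delta_hu absolute HU error threshold.
#' @param min_component_voxels smallest component size that counts.
#' @param enhancingMasks labels of true enhancing tissues excluded from
#'   screening (their enhancement is expected, not hallucinated).
#' @param ctvName label of the target-volume mask.
#' @param spacing mm per (z, y, x); taken from \code{masks} if a MaskSet.
#' @return list: \code{rate} (0 or 1 for a single case), \code{flagged},
#'   \code{n_components}, \code{components} (data.frame of sizes).
#' @export
hallucinationRate <- function(predicted, groundTruth, masks,
                              band_mm = 50, delta_hu = 100,
                              min_component_voxels = 10,
                              enhancingMasks = c("Vessels", "Marrow",
                                                 "Kidney_Left", "Kidney_Right",
                                                 "Liver", "CTV"),
                              ctvName = "CTV", spacing = NULL) {
  pa <- asArray3(predicted); ta <- asArray3(groundTruth)
  ml <- if (is(masks, "MaskSet")) masks@masks else masks
  if (is.null(spacing))
    spacing <- if (is(masks, "MaskSet")) masks@spacing else c(1, 1, 1)
  if (!ctvName %in% names(ml))
    stop("CTV mask '", ctvName, "' missing: cannot define the peri-target band")
  ctv <- ml[[ctvName]]
  if (!any(ctv)) stop("CTV mask is empty")
  d <- dim(pa)
  zs <- which(apply(ctv, 1, any))
  nband <- ceiling(band_mm / spacing[1])
  zmin <- max(1L, min(zs) - nband)
  zmax <- min(d[1], max(zs) + nband)
  band <- array(FALSE, d)
  band[zmin:zmax, , ] <- TRUE
  excl <- array(FALSE, d)
  for (nm in intersect(enhancingMasks, names(ml)))
    excl <- excl | ml[[nm]]
  cand <- band & !excl & (abs(pa - ta) > delta_hu)
  if (!any(cand)) {
    return(list(rate = 0, flagged = FALSE, n_components = 0L,
                components = data.frame(id = integer(), voxels = integer())))
  }
  lab <- labelComponents(cand, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_component_voxels)
  comp <- data.frame(id = keep, voxels = sizes[keep])
  flagged <- length(keep) >= 1
  list(rate = as.numeric(flagged), flagged = flagged,
       n_components = length(keep), components = comp)
}

#' Full evaluation report for one predicted volume
#'
#' Computes the per-ROI and whole-image similarity metrics, geometric
#' overlap of delineated structures, per-tissue CT statistics, and the
#' hallucination proxy, mirroring a per-case evaluation table.
#'
#' @param predicted,groundTruth \code{CTVolume}s on one grid.
#' @param masks \code{MaskSet}.
#' @param regions ROI labels for the per-region metric rows; defaults to
#'   \code{\link{kappaRegions}} minus Body plus an "overall" row.
#' @param geometryMasks labels evaluated with Dice/HD95 (prediction-side
#'   masks equal truth-side masks here, giving the fidelity ceiling, unless
#'   \code{predictedMasks} is supplied).
#' @param predictedMasks optional \code{MaskSet} of structures delineated on
#'   the predicted image.
#' @param params SSIM constants, see \code{\link{ssimParams}}.
#' @param psnr_peak PSNR peak value m.
#' @param tissueNames labels for the CT-statistics block.
#' @param ... passed to \code{\link{hallucinationRate}}.
#' @return a \code{MetricReport}.
#' @export
evaluateVolume <- function(predicted, groundTruth, masks,
                           regions = NULL,
                           geometryMasks = c("CTV"),
                           predictedMasks = NULL,
                           params = ssimParams(),
                           psnr_peak = 3000,
                           tissueNames = c("Vessels", "Muscle", "Fat",
                                           "Vertebrae", "Marrow"),
                           ...) {
  ml <- masks@masks
  if (is.null(regions))
    regions <- intersect(setdiff(kappaRegions(), "Body"), names(ml))
  perRegion <- do.call(rbind, lapply(regions, function(rn) {
    m <- ml[[rn]]
    if (is.null(m) || !any(m))
      return(data.frame(region = rn, mse = NA_real_, psnr = NA_real_,
                        uqi = NA_real_, ssim = NA_real_))
    # a constant region of identical images has undefined UQI but is a
    # perfect match; report 1 there, NA for other degeneracies
    uqi <- tryCatch(uqiMetric(predicted, groundTruth, m),
                    error = function(e) {
                      pa <- asArray3(predicted); ta <- asArray3(groundTruth)
                      if (isTRUE(all.equal(pa[m], ta[m]))) 1 else NA_real_
                    })
    data.frame(region = rn,
               mse = mseMetric(predicted, groundTruth, m),
               psnr = psnrMetric(predicted, groundTruth, m = psnr_peak,
                                 mask = m),
               uqi = uqi,
               ssim = ssimGlobal(predicted, groundTruth, params, m))
  }))
  overall <- c(mse = mseMetric(predicted, groundTruth),
               psnr = psnrMetric(predicted, groundTruth, m = psnr_peak),
               uqi = uqiMetric(predicted, groundTruth),
               ssim = ssimGlobal(predicted, groundTruth, params))
  pm <- if (is.null(predictedMasks)) masks else predictedMasks
  geometry <- do.call(rbind, lapply(intersect(geometryMasks, names(ml)),
    function(gn) {
      a <- ml[[gn]]; b <- pm@masks[[gn]]
      data.frame(structure = gn,
                 dsc = diceCoefficient(a, b),
                 hd95_mm = hausdorff95(a, b, spacing = masks@spacing))
    }))
  if (is.null(geometry))
    geometry <- data.frame(structure = character(), dsc = numeric(),
                           hd95_mm = numeric())
  cs_pred <- ctStatistics(predicted, masks, tissueNames)
  cs_true <- ctStatistics(groundTruth, masks, tissueNames)
  cs_pred$image <- "predicted"; cs_true$image <- "ground_truth"
  halluc <- hallucinationRate(predicted, groundTruth, masks, ...)
  new("MetricReport",
      perRegion = perRegion, overall = overall, geometry = geometry,
      ctStats = rbind(cs_pred, cs_true), hallucination = halluc)
}
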