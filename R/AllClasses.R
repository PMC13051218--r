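#' @import methods
#' @importFrom stats rnorm runif quantile sd setNames
#' @importFrom utils write.csv head tail
NULL

#' CTVolume: a 3D scalar field of Hounsfield units
#'
#' A 3D array of CT numbers (HU) indexed (z, y, x) — axial slice first —
#' together with the physical voxel size in mm per axis and the scanner-space
#' origin of the first voxel centre.
#'
#' @slot data 3D numeric array, dimensions (z, y, x).
#' @slot spacing numeric(3), voxel size in mm per (z, y, x) axis.
#' @slot origin numeric(3), mm coordinate of voxel (1,1,1) centre.
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(3, 1.5, 1.5), origin = c(0, 0, 0))
)

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (z, y, x)")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param data 3D numeric array (z, y, x) of HU values.
#' @param spacing numeric(3) voxel size in mm (z, y, x).
#' @param origin numeric(3) position of the first voxel centre in mm.
#' @return A \code{CTVolume}.
#' @examples
#' v <- CTVolume(array(0, c(4, 8, 8)), spacing = c(3, 1.5, 1.5))
#' dim(v)
#' @export
CTVolume <- function(data, spacing = c(3, 1.5, 1.5), origin = c(0, 0, 0)) {
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' MaskSet: named binary ROI masks on a shared grid
#'
#' Holds one logical 3D array per region of interest; all masks share a grid
#' and voxel spacing with the volume they annotate.
#'
#' @slot masks named list of logical 3D arrays.
#' @slot spacing numeric(3), mm per (z, y, x) axis.
#' @export
setClass("MaskSet",
  representation(masks = "list", spacing = "numeric"),
  prototype(spacing = c(3, 1.5, 1.5))
)

setValidity("MaskSet", function(object) {
  msg <- character()
  if (length(object@masks)) {
    if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
      msg <- c(msg, "masks must be a named list")
    d <- dim(object@masks[[1]])
    for (nm in names(object@masks)) {
      m <- object@masks[[nm]]
      if (!is.logical(m) || length(dim(m)) != 3L)
        msg <- c(msg, sprintf("mask '%s' must be a logical 3D array", nm))
      else if (!identical(dim(m), d))
        msg <- c(msg, sprintf("mask '%s' has a different grid shape", nm))
    }
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a MaskSet
#'
#' @param masks named list of logical 3D arrays (z, y, x), one per ROI.
#' @param spacing numeric(3) voxel size in mm.
#' @return A \code{MaskSet}.
#' @export
MaskSet <- function(masks, spacing = c(3, 1.5, 1.5)) {
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  new("MaskSet", masks = masks, spacing = as.numeric(spacing))
}

#' PairedSample: an aligned noncontrast / contrast-enhanced training unit
#'
#' @slot noncontrast \code{CTVolume} before contrast injection.
#' @slot enhanced \code{CTVolume} at the venous phase.
#' @slot masks \code{MaskSet} of per-organ ROIs on the same grid.
#' @slot provenance list of generation or acquisition metadata.
#' @export
setClass("PairedSample",
  representation(noncontrast = "CTVolume", enhanced = "CTVolume",
                 masks = "MaskSet", provenance = "list")
)

setValidity("PairedSample", function(object) {
  msg <- character()
  dn <- dim(object@noncontrast@data)
  de <- dim(object@enhanced@data)
  if (!identical(dn, de))
    msg <- c(msg, "noncontrast and enhanced grids differ")
  if (length(object@masks@masks) &&
      !identical(dim(object@masks@masks[[1]]), dn))
    msg <- c(msg, "mask grid differs from volume grid")
  if (!isTRUE(all.equal(object@noncontrast@spacing, object@enhanced@spacing)))
    msg <- c(msg, "volume spacings differ")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedSample
#'
#' @param noncontrast,enhanced \code{CTVolume}s on the same grid.
#' @param masks \code{MaskSet} on the same grid.
#' @param provenance list of metadata (e.g. the \code{phantomConfig} used).
#' @return A \code{PairedSample}.
#' @export
PairedSample <- function(noncontrast, enhanced, masks, provenance = list()) {
  new("PairedSample", noncontrast = noncontrast, enhanced = enhanced,
      masks = masks, provenance = provenance)
}

#' MetricReport: per-ROI and whole-image evaluation results
#'
#' @slot perRegion data.frame with one row per ROI: mse, psnr, uqi, ssim.
#' @slot overall named numeric: whole-image mse, psnr, uqi, ssim.
#' @slot geometry data.frame of dsc and hd95_mm per delineated structure.
#' @slot ctStats data.frame of per-tissue mean and sd HU per image.
#' @slot hallucination list with at least \code{rate} and \code{components}.
#' @export
setClass("MetricReport",
  representation(perRegion = "data.frame", overall = "numeric",
                 geometry = "data.frame", ctStats = "data.frame",
                 hallucination = "list")
)

setValidity("MetricReport", function(object) {
  msg <- character()
  pr <- object@perRegion
  if (nrow(pr) && !all(c("region", "mse", "psnr", "uqi", "ssim") %in% names(pr)))
    msg <- c(msg, "perRegion must have columns region, mse, psnr, uqi, ssim")
  if (nrow(pr) && any(pr$mse < 0, na.rm = TRUE))
    msg <- c(msg, "mse must be >= 0")
  g <- object@geometry
  if (nrow(g)) {
    if (any(g$dsc < 0 | g$dsc > 1, na.rm = TRUE))
      msg <- c(msg, "dsc must lie in [0, 1]")
    if (any(g$hd95_mm < 0, na.rm = TRUE))
      msg <- c(msg, "hd95 must be >= 0")
  }
  if (length(msg)) msg else TRUE
})
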