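#' @describeIn voxelSpacing spacing of a CTVolume
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @describeIn voxelSpacing spacing of a MaskSet
#' @export
setMethod("voxelSpacing", "MaskSet", function(x) x@spacing)

#' @describeIn gridOrigin origin of a CTVolume
#' @export
setMethod("gridOrigin", "CTVolume", function(x) x@origin)

#' @describeIn voxelData voxel array of a CTVolume
#' @export
setMethod("voxelData", "CTVolume", function(x) x@data)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@data))

#' @describeIn maskNames labels of a MaskSet
#' @export
setMethod("maskNames", "MaskSet", function(x) names(x@masks))

#' @describeIn maskNames labels of a PairedSample's masks
#' @export
setMethod("maskNames", "PairedSample", function(x) names(x@masks@masks))

#' @describeIn getMask mask from a MaskSet
#' @export
setMethod("getMask", "MaskSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("mask '", name, "' not present; available: ",
         paste(names(x@masks), collapse = ", "))
  x@masks[[name]]
})

#' @describeIn getMask mask from a PairedSample
#' @export
setMethod("getMask", "PairedSample", function(x, name) getMask(x@masks, name))

#' @describeIn noncontrast accessor
#' @export
setMethod("noncontrast", "PairedSample", function(x) x@noncontrast)

#' @describeIn enhanced accessor
#' @export
setMethod("enhanced", "PairedSample", function(x) x@enhanced)

#' @describeIn maskSet accessor
#' @export
setMethod("maskSet", "PairedSample", function(x) x@masks)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat("CTVolume:", paste(d, collapse = " x "), "(z y x) voxels\n")
  cat("  spacing:", paste(format(object@spacing), collapse = " x "), "mm\n")
  cat("  HU range: [", format(min(object@data)), ",",
      format(max(object@data)), "]\n")
})

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet with", length(object@masks), "ROIs\n")
  for (nm in names(object@masks))
    cat(sprintf("  %-14s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "PairedSample", function(object) {
  d <- dim(object@noncontrast@data)
  cat("PairedSample:", paste(d, collapse = " x "), "(z y x),",
      length(object@masks@masks), "masks\n")
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat("  overall:",
      paste(names(object@overall), format(object@overall, digits = 4),
            sep = "=", collapse = "  "), "\n")
  cat("  per-region rows:", nrow(object@perRegion),
      " geometry rows:", nrow(object@geometry), "\n")
  if (length(object@hallucination))
    cat("  hallucination rate:", object@hallucination$rate, "\n")
})

# ---- NIfTI I/O -------------------------------------------------------------

#' Write a CTVolume or mask to a NIfTI-1 file
#'
#' Volumes are stored as float32, masks as uint8. The (z, y, x) internal
#' array is transposed to NIfTI's (x, y, z) order so files interoperate with
#' other NIfTI readers; spacing is recorded in the header pixdim.
#'
#' @param x a \code{CTVolume}, or a logical 3D array (mask).
#' @param file output path (.nii or .nii.gz).
#' @param spacing mm per (z, y, x) axis; taken from \code{x} for CTVolumes.
#' @return \code{file}, invisibly.
#' @export
writeVolume <- function(x, file, spacing = NULL) {
  if (is(x, "CTVolume")) {
    arr <- x@data
    spacing <- x@spacing
    dtype <- "float"
  } else {
    arr <- x
    if (is.null(spacing)) stop("spacing required for raw arrays")
    dtype <- if (is.logical(arr)) "uint8" else "float"
    storage.mode(arr) <- if (is.logical(arr)) "integer" else "double"
  }
  nii <- aperm(arr, c(3, 2, 1))          # (x, y, z) on disk
  attr(nii, "pixdim") <- spacing[c(3, 2, 1)]
  img <- RNifti::asNifti(nii, datatype = dtype)
  RNifti::writeNifti(img, file, datatype = dtype)
  invisible(file)
}

#' Read a CTVolume from a NIfTI-1 file
#'
#' @param file path to a .nii/.nii.gz written by \code{\link{writeVolume}}
#'   (or any NIfTI scalar volume in (x, y, z) order).
#' @param origin optional origin override in mm (z, y, x).
#' @return a \code{CTVolume} with (z, y, x) indexing.
#' @export
readVolume <- function(file, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(img)
  arr <- aperm(as.array(img), c(3, 2, 1))
  CTVolume(arr, spacing = sp[c(3, 2, 1)], origin = origin)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' @param file path written by \code{\link{writeVolume}} for a mask.
#' @return logical 3D array (z, y, x).
#' @export
readMask <- function(file) {
  img <- RNifti::readNifti(file)
  arr <- aperm(as.array(img), c(3, 2, 1))
  arr > 0.5
}
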