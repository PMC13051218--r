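#' Voxel spacing in mm
#' @param x a \code{CTVolume} or \code{MaskSet}.
#' @return numeric(3), mm per (z, y, x) axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Grid origin in mm
#' @param x a \code{CTVolume}.
#' @return numeric(3).
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Raw voxel array
#' @param x a \code{CTVolume}.
#' @return 3D numeric array (z, y, x).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Names of the masks in a set
#' @param x a \code{MaskSet} or \code{PairedSample}.
#' @return character vector of ROI labels.
#' @export
setGeneric("maskNames", function(x) standardGeneric("maskNames"))

#' Extract one binary mask
#' @param x a \code{MaskSet} or \code{PairedSample}.
#' @param name ROI label.
#' @return logical 3D array.
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))

#' Noncontrast volume of a pair
#' @param x a \code{PairedSample}.
#' @return a \code{CTVolume}.
#' @export
setGeneric("noncontrast", function(x) standardGeneric("noncontrast"))

#' Contrast-enhanced volume of a pair
#' @param x a \code{PairedSample}.
#' @return a \code{CTVolume}.
#' @export
setGeneric("enhanced", function(x) standardGeneric("enhanced"))

#' Mask set of a pair
#' @param x a \code{PairedSample}.
#' @return a \code{MaskSet}.
#' @export
setGeneric("maskSet", function(x) standardGeneric("maskSet"))
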