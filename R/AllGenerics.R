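# Accessors and show methods. Slot access from user code is discouraged;
# these generics are the supported surface.

#' Physical voxel spacing
#'
#' @param x a [VoxelGrid-class] or [Mask3D-class]
#' @return numeric(3), micrometers per voxel along (z, y, x)
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "Mask3D", function(x) x@spacing)

#' Physical pixel size
#'
#' @param x an [Image2D-class] or [Mask2D-class]
#' @return numeric(2), micrometers per pixel along (y, x)
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Image2D", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Mask2D", function(x) x@pixelSize)

#' Underlying array of an image or mask
#'
#' @param x a [VoxelGrid-class], [Image2D-class], [Mask3D-class] or
#'   [Mask2D-class]
#' @return the numeric array/matrix (images) or logical array/matrix (masks)
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "VoxelGrid", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "Image2D", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "Mask3D", function(x) x@data)

#' @rdname imageData
#' @export
setMethod("imageData", "Mask2D", function(x) x@data)

#' Channel label
#'
#' @param x a [VoxelGrid-class] or [Image2D-class]
#' @return character channel label
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' @rdname channel
#' @export
setMethod("channel", "VoxelGrid", function(x) x@channel)

#' @rdname channel
#' @export
setMethod("channel", "Image2D", function(x) x@channel)

#' Ellipsoid semi-axes as a named vector
#'
#' @param x an [EllipsoidAxes-class] or [Morphometrics3D-class]
#' @return named numeric(3) `c(a=, b=, c=)`, micrometers
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))

#' @rdname semiAxes
#' @export
setMethod("semiAxes", "EllipsoidAxes", function(x) c(a = x@a, b = x@b, c = x@c))

#' @rdname semiAxes
#' @export
setMethod("semiAxes", "Morphometrics3D", function(x) semiAxes(x@axes))

#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@data))

#' @export
setMethod("dim", "Mask3D", function(x) dim(x@data))

#' @export
setMethod("dim", "Image2D", function(x) dim(x@data))

#' @export
setMethod("dim", "Mask2D", function(x) dim(x@data))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid %s: %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g um\n",
              if (nzchar(object@channel)) object@channel else "<unlabelled>",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Image2D %s: %d x %d pixels (y,x), pixel %.3g/%.3g um\n",
              if (nzchar(object@channel)) object@channel else "<unlabelled>",
              d[1], d[2], object@pixelSize[1], object@pixelSize[2]))
})

setMethod("show", "Mask3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Mask3D: %d x %d x %d voxels, %d foreground, spacing %.3g/%.3g/%.3g um\n",
              d[1], d[2], d[3], sum(object@data),
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "Mask2D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Mask2D: %d x %d pixels, %d foreground\n",
              d[1], d[2], sum(object@data)))
})

setMethod("show", "EllipsoidAxes", function(object) {
  cat(sprintf("EllipsoidAxes: a = %.4g, b = %.4g, c = %.4g um\n",
              object@a, object@b, object@c))
})

setMethod("show", "Morphometrics2D", function(object) {
  cat("Morphometrics2D\n")
  cat(sprintf("  area        %.4g mm^2   perimeter %.4g mm\n",
              object@area, object@perimeter))
  cat(sprintf("  circularity %.3f  sphericity index %.3f  roundness %.3f  solidity %.3f\n",
              object@circularity, object@sphericityIndex, object@roundness,
              object@solidity))
  cat(sprintf("  projected radius %.4g mm, projected volume %.4g mm^3\n",
              object@radius, object@volume))
})

setMethod("show", "Morphometrics3D", function(object) {
  cat("Morphometrics3D\n")
  cat(sprintf("  volume  %.4g mm^3   surface %.4g mm^2\n",
              object@volume, object@surface))
  cat(sprintf("  semi-axes a/b/c: %.4g / %.4g / %.4g um\n",
              object@axes@a, object@axes@b, object@axes@c))
  cat(sprintf("  e1 %.3f  e2 %.3f  sphericity %.3f  roundness %.3f\n",
              object@e1, object@e2, object@sphericity, object@roundness))
  cat(sprintf("  max thickness %.4g um, max diameter %.4g um\n",
              object@maxThickness, object@maxDiameter))
})

setMethod("show", "DeathMetrics", function(object) {
  cat("DeathMetrics\n")
  cat(sprintf("  BF area %.4g mm^2, PI area %.4g mm^2 (ratio %.3f)\n",
              object@bfArea, object@piArea, object@piAreaRatio))
  cat(sprintf("  PI intensity %.4g a.u. (%.4g a.u./mm^2), threshold %.4g, background %.4g\n",
              object@piIntensity, object@piIntensityRatio,
              object@piThreshold, object@background))
})

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(
    "SegmentationParams: low/high = %.2f/%.2f x Otsu, denoise h = %.2f sigma,\n",
    object@lowFactor, object@highFactor, object@denoiseStrength))
  cat(sprintf("  target spacing %s um, min component %d voxels, patch %d^3, search %d^3\n",
              ifelse(is.na(object@targetSpacing), "auto",
                     format(object@targetSpacing)),
              as.integer(object@minComponentVoxels),
              2L * object@patchRadius + 1L, 2L * object@searchRadius + 1L))
})

#' @export
#' @method as.data.frame Morphometrics2D
as.data.frame.Morphometrics2D <- function(x, row.names = NULL,
                                          optional = FALSE, clip = FALSE,
                                          ...) {
  clip1 <- function(v) if (clip) pmin(v, 1) else v
  data.frame(area_mm2 = x@area, perimeter_mm = x@perimeter,
             circularity = clip1(x@circularity),
             sphericity_index = clip1(x@sphericityIndex),
             roundness = clip1(x@roundness), solidity = clip1(x@solidity),
             projected_radius_mm = x@radius, projected_volume_mm3 = x@volume,
             row.names = row.names)
}

#' @export
#' @method as.data.frame Morphometrics3D
as.data.frame.Morphometrics3D <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(volume_mm3 = x@volume, surface_mm2 = x@surface,
             a_um = x@axes@a, b_um = x@axes@b, c_um = x@axes@c,
             e1 = x@e1, e2 = x@e2, sphericity = x@sphericity,
             roundness = x@roundness, max_thickness_um = x@maxThickness,
             max_diameter_um = x@maxDiameter, row.names = row.names)
}

#' @export
#' @method as.data.frame DeathMetrics
as.data.frame.DeathMetrics <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(bf_area_mm2 = x@bfArea, pi_area_mm2 = x@piArea,
             pi_intensity = x@piIntensity, pi_area_ratio = x@piAreaRatio,
             pi_intensity_ratio = x@piIntensityRatio,
             pi_threshold = x@piThreshold, pi_background = x@background,
             row.names = row.names)
}
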