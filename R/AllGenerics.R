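# Accessor generics: slot access stays behind these.

#' @rdname DigitalPhantom-class
#' @param object,x a package object.
#' @export
setGeneric("huVolume", function(x) standardGeneric("huVolume"))
#' @rdname DigitalPhantom-class
#' @export
setGeneric("activityVolume", function(x) standardGeneric("activityVolume"))
#' @rdname DigitalPhantom-class
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname MuMap-class
#' @export
setGeneric("lacVolume", function(x) standardGeneric("lacVolume"))
#' @rdname MuMap-class
#' @export
setGeneric("variant", function(x) standardGeneric("variant"))
#' @rdname DigitalPhantom-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname Sinogram-class
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname SUVImage-class
#' @export
setGeneric("suvVolume", function(x) standardGeneric("suvVolume"))
#' @rdname LungMask-class
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname DigitalPhantom-class
#' @export
setMethod("huVolume", "DigitalPhantom", function(x) x@huVolume)
#' @rdname DigitalPhantom-class
#' @export
setMethod("activityVolume", "DigitalPhantom", function(x) x@activityVolume)
#' @rdname DigitalPhantom-class
#' @export
setMethod("labelVolume", "DigitalPhantom", function(x) x@labelVolume)
#' @rdname MuMap-class
#' @export
setMethod("lacVolume", "MuMap", function(x) x@lac)
#' @rdname MuMap-class
#' @export
setMethod("variant", "MuMap", function(x) x@variant)
#' @rdname DigitalPhantom-class
#' @export
setMethod("voxelSpacing", "DigitalPhantom", function(x) x@spacing)
#' @rdname MuMap-class
#' @export
setMethod("voxelSpacing", "MuMap", function(x) x@spacing)
#' @rdname Sinogram-class
#' @export
setMethod("sinogramValues", "Sinogram", function(x) x@values)
#' @rdname Sinogram-class
#' @export
setMethod("sinogramValues", "AttenuationFactors", function(x) x@values)
#' @rdname SUVImage-class
#' @export
setMethod("suvVolume", "SUVImage", function(x) x@suv)
#' @rdname LungMask-class
#' @export
setMethod("maskVolume", "LungMask", function(x) x@mask)

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", object@gridSize, "x", object@gridSize, "x",
      object@nSlices, "voxels @", object@voxelSpacing, "mm\n")
  cat("  lung HU targets (ant/mid/post):",
      paste(object@lungHU[c("anterior", "middle", "posterior")],
            collapse = " / "),
      sprintf(" [%s gradient, noise SD %g HU]\n",
              object@gradientModel, object@huNoiseSD))
  cat("  bone:", if (isTRUE(object@boneGeometry$enabled)) "spine + ribs"
      else "disabled", " seed:", object@rngSeed, "\n")
})

setMethod("show", "DigitalPhantom", function(object) {
  d <- dim(object@huVolume)
  lab <- tissueLabels()
  nl <- sum(object@labelVolume %in% lab[c("lung_left", "lung_right")])
  cat(sprintf("DigitalPhantom %d x %d x %d @ %g mm (%d lung voxels)\n",
              d[1], d[2], d[3], object@spacing, nl))
  cat(sprintf("  HU range [%.0f, %.0f]; total activity %.3g Bq/mL-voxels\n",
              min(object@huVolume), max(object@huVolume),
              sum(object@activityVolume)))
})

setMethod("show", "MuMap", function(object) {
  d <- dim(object@lac)
  cat(sprintf("MuMap [%s] %d x %d x %d @ %g mm, LAC range [%.4f, %.4f] cm^-1\n",
              object@variant, d[1], d[2], d[3], object@spacing,
              min(object@lac), max(object@lac)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d bins (bin %g mm), total %.4g\n",
              nrow(object@values), ncol(object@values),
              object@geometry@binWidth, sum(object@values)))
})

setMethod("show", "AttenuationFactors", function(object) {
  cat(sprintf("AttenuationFactors: %d angles x %d bins, min %.4f\n",
              nrow(object@values), ncol(object@values), min(object@values)))
})

setMethod("show", "SUVImage", function(object) {
  cat(sprintf("SUVImage %s, SUV range [%.3f, %.3f]\n",
              paste(dim(object@suv), collapse = " x "),
              min(object@suv), max(object@suv)))
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport: %d subjects, %d ROI measurements\n",
              object@config@nSubjects, nrow(object@measurements)))
  cat("Mean relative difference vs CTAC (%):\n")
  print(object@relDiff[, c("variant", "position", "mean", "sd")],
        row.names = FALSE)
})
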