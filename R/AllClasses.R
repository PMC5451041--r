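#' @import methods
NULL

#' Tissue label codes used in phantom label volumes
#'
#' Integer codes identifying the tissue compartment of each voxel in a
#' [DigitalPhantom] label volume.
#'
#' @return Named integer vector with elements `air`, `lung_left`,
#'   `lung_right`, `fat`, `soft`, `bone`.
#' @export
#' @examples
#' tissueLabels()
tissueLabels <- function() {
  c(air = 0L, lung_left = 1L, lung_right = 2L,
    fat = 3L, soft = 4L, bone = 5L)
}

#' @rdname MuMap-class
#' @export
muMapVariants <- function() {
  c("CTAC", "CTAC_MRLUNG", "CTAC_MRLUNG_NOBONE", "MRAC")
}

#' PhantomConfig: parameters of the digital thorax phantom
#'
#' Holds every knob of the synthetic thorax generator: grid geometry,
#' the anterior/middle/posterior lung Hounsfield-unit (HU) targets whose
#' linear-in-depth interpolation produces the gravity-dependent density
#' gradient, tissue HU values, bone geometry, activity concentrations
#' (in SUV units), and the random seed.
#'
#' @slot gridSize integer, in-plane matrix size (square), >= 64.
#' @slot nSlices integer, number of axial slices (>= 1).
#' @slot voxelSpacing numeric, isotropic voxel spacing in mm.
#' @slot lungHU named numeric of length 3 (`anterior`, `middle`,
#'   `posterior`): band-mean HU targets for the lung density gradient.
#' @slot gradientModel `"linear"` (depth-interpolated gradient) or
#'   `"constant"` (uniform lung at the middle target).
#' @slot huNoiseSD numeric, SD of additive Gaussian HU noise (HU).
#' @slot softTissueHU,fatHU,boneHU numeric scalar HU per compartment.
#' @slot bodyAxes numeric(2), lateral/anteroposterior semi-axes of the
#'   body ellipse (mm).
#' @slot fatThickness numeric, subcutaneous fat layer thickness (mm).
#' @slot lungAxes numeric(2), lateral/anteroposterior semi-axes of each
#'   lung ellipse (mm).
#' @slot lungOffset numeric, lateral distance of each lung centre from
#'   the midline (mm).
#' @slot boneGeometry list with elements `enabled`, `spineRadius` (mm),
#'   `spineCenterY` (mm, posterior of centre), `ribInner`, `ribOuter`
#'   (fractions of the inner body ellipse), `ribMinYFrac` (anterior
#'   cut-off as a fraction of the AP semi-axis).
#' @slot activity named numeric (`lung`, `soft`, `fat`, `bone`):
#'   compartment activity in SUV units (converted to Bq/mL through
#'   `injectedDose` / `subjectWeight`).
#' @slot activityGradient numeric, optional fractional anterior->posterior
#'   linear modulation of lung activity (0 = uniform lung uptake).
#' @slot subjectWeight numeric, g.
#' @slot injectedDose numeric, Bq.
#' @slot rngSeed integer.
#' @aliases PhantomConfig
#' @seealso [phantomConfig()], [generateThoraxPhantom()]
#' @export
setClass("PhantomConfig",
  representation(
    gridSize = "integer", nSlices = "integer", voxelSpacing = "numeric",
    lungHU = "numeric", gradientModel = "character", huNoiseSD = "numeric",
    softTissueHU = "numeric", fatHU = "numeric", boneHU = "numeric",
    bodyAxes = "numeric", fatThickness = "numeric",
    lungAxes = "numeric", lungOffset = "numeric",
    boneGeometry = "list",
    activity = "numeric", activityGradient = "numeric",
    subjectWeight = "numeric", injectedDose = "numeric",
    rngSeed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  hu <- c(object@lungHU, object@softTissueHU, object@fatHU, object@boneHU)
  if (any(!is.finite(hu)) || any(hu < -1000) || any(hu > 3071))
    msg <- c(msg, "all HU values must lie in [-1000, 3071]")
  if (length(object@lungHU) != 3 ||
      !all(c("anterior", "middle", "posterior") %in% names(object@lungHU)))
    msg <- c(msg, "lungHU must be named c(anterior=, middle=, posterior=)")
  if (object@gridSize < 64L) msg <- c(msg, "gridSize must be >= 64")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@voxelSpacing <= 0) msg <- c(msg, "voxelSpacing must be > 0")
  if (!object@gradientModel %in% c("linear", "constant"))
    msg <- c(msg, "gradientModel must be 'linear' or 'constant'")
  if (object@gradientModel == "linear" &&
      length(object@lungHU) == 3 &&
      !is.na(object@lungHU["anterior"]) &&
      object@lungHU["anterior"] >= object@lungHU["posterior"])
    msg <- c(msg, "lung gradient requires anterior HU < posterior HU (denser tissue posteriorly)")
  if (object@huNoiseSD < 0) msg <- c(msg, "huNoiseSD must be >= 0")
  if (any(object@activity < 0)) msg <- c(msg, "activity values must be >= 0")
  if (object@subjectWeight <= 0 || object@injectedDose <= 0)
    msg <- c(msg, "subjectWeight and injectedDose must be > 0")
  if (length(msg)) msg else TRUE
})

#' DigitalPhantom: co-registered HU, activity and label volumes
#'
#' The synthetic stand-in for a patient: a CT-like HU volume, a
#' ground-truth activity concentration volume (Bq/mL), and a per-voxel
#' tissue label volume (codes from [tissueLabels()]), all on one grid,
#' together with the [PhantomConfig] that produced them.
#'
#' @slot huVolume,activityVolume 3-D numeric arrays (row = anterior ->
#'   posterior, column = right -> left, third index = slice).
#' @slot labelVolume 3-D integer array of tissue codes.
#' @slot spacing numeric, voxel spacing in mm.
#' @slot config the generating [PhantomConfig].
#' @aliases DigitalPhantom
#' @seealso [generateThoraxPhantom()]
#' @export
setClass("DigitalPhantom",
  representation(huVolume = "array", activityVolume = "array",
                 labelVolume = "array", spacing = "numeric",
                 config = "PhantomConfig"))

setValidity("DigitalPhantom", function(object) {
  msg <- character()
  d <- dim(object@huVolume)
  if (!identical(d, dim(object@activityVolume)) ||
      !identical(d, dim(object@labelVolume)))
    msg <- c(msg, "hu, activity and label volumes must share dimensions")
  lab <- tissueLabels()
  if (!all(object@labelVolume %in% lab))
    msg <- c(msg, "labelVolume contains unknown tissue codes")
  if (any(object@activityVolume[object@labelVolume == lab["air"]] != 0))
    msg <- c(msg, "activity must be 0 in air voxels")
  if (length(msg)) msg else TRUE
})

#' BilinearTransform: piecewise bilinear HU to 511 keV LAC conversion
#'
#' The two-segment linear map used by PET/CT scanners to convert CT
#' Hounsfield units to linear attenuation coefficients (LAC) at 511 keV.
#' Both segments are anchored so that air (-1000 HU) maps exactly to 0;
#' above the break the LAC is `slopeAbove * (HU + 1000) + interceptAbove`.
#' The default parameters correspond to a 120 kVp acquisition: break at
#' 47 HU, slope 9.6e-5 cm^-1/HU below, 5.1e-5 cm^-1/HU above with the
#' intercept chosen for continuity at the break (0.04712 cm^-1).
#'
#' @slot breakHU numeric, HU of the segment break.
#' @slot slopeBelow,slopeAbove numeric, cm^-1 per HU.
#' @slot interceptAbove numeric, cm^-1 (continuity-derived by default).
#' @aliases BilinearTransform
#' @seealso [bilinearTransform()], [huToLac()]
#' @export
setClass("BilinearTransform",
  representation(breakHU = "numeric", slopeBelow = "numeric",
                 slopeAbove = "numeric", interceptAbove = "numeric"))

setValidity("BilinearTransform", function(object) {
  msg <- character()
  if (object@slopeBelow < 0 || object@slopeAbove < 0)
    msg <- c(msg, "both slopes must be >= 0 (transform must be monotone)")
  lo <- object@slopeBelow * (object@breakHU + 1000)
  hi <- object@slopeAbove * (object@breakHU + 1000) + object@interceptAbove
  if (abs(lo - hi) > 1e-9)
    msg <- c(msg, "transform must be continuous at breakHU")
  if (length(msg)) msg else TRUE
})

#' TissueClassLACs: fixed per-class LACs of segmentation-based AC
#'
#' The four linear attenuation coefficients a Dixon-type 4-class
#' segmentation method assigns: air 0, lung 0.0224, fat 0.0854 and soft
#' tissue 0.1 cm^-1. Bone is not a class: segmentation-based attenuation
#' maps treat bone as soft tissue.
#'
#' @slot air,lung,fat,soft numeric, cm^-1.
#' @aliases TissueClassLACs
#' @seealso [tissueClassLACs()], [buildSegmentationMuMap()]
#' @export
setClass("TissueClassLACs",
  representation(air = "numeric", lung = "numeric",
                 fat = "numeric", soft = "numeric"))

setValidity("TissueClassLACs", function(object) {
  if (!(object@air < object@lung && object@lung < object@fat &&
        object@fat < object@soft))
    "class LACs must satisfy air < lung < fat < soft"
  else TRUE
})

#' MuMap: a 511 keV attenuation map
#'
#' A voxel grid of linear attenuation coefficients (cm^-1) at 511 keV,
#' tagged with which of the four experimental variants it represents:
#' `CTAC` (CT-derived, continuous LACs), `CTAC_MRLUNG` (lung LACs
#' replaced by the fixed segmentation lung class), `CTAC_MRLUNG_NOBONE`
#' (additionally bone replaced by soft tissue) or `MRAC` (pure 4-class
#' segmentation map).
#'
#' @slot lac 3-D numeric array of LACs, cm^-1.
#' @slot spacing numeric, voxel spacing in mm.
#' @slot variant one of [muMapVariants()].
#' @aliases MuMap
#' @seealso [buildCTMuMap()], [replaceLungLac()], [stripBone()],
#'   [buildSegmentationMuMap()]
#' @export
setClass("MuMap",
  representation(lac = "array", spacing = "numeric", variant = "character"))

setValidity("MuMap", function(object) {
  msg <- character()
  if (!object@variant %in% muMapVariants())
    msg <- c(msg, sprintf("variant must be one of %s",
                          paste(muMapVariants(), collapse = ", ")))
  if (any(!is.finite(object@lac)) || any(object@lac < 0))
    msg <- c(msg, "all LAC values must be finite and >= 0")
  if (object@variant %in% c("CTAC_MRLUNG_NOBONE", "MRAC") &&
      max(object@lac) > 0.1 + 1e-12)
    msg <- c(msg, "bone-free variants must not exceed the soft-tissue LAC (0.1 cm^-1)")
  if (object@variant == "MRAC" && length(unique(as.numeric(object@lac))) > 4)
    msg <- c(msg, "an MRAC map carries at most the four class LAC values")
  if (length(msg)) msg else TRUE
})

#' LungMask: region-growing lung segmentation result
#'
#' @slot mask 3-D logical array.
#' @slot seeds integer matrix of seed voxel indices (row, col, slice).
#' @slot huThreshold numeric, HU threshold used for growth.
#' @aliases LungMask
#' @seealso [growLungMask()]
#' @export
setClass("LungMask",
  representation(mask = "array", seeds = "matrix", huThreshold = "numeric"))

#' ProjectionGeometry: 2-D parallel-beam acquisition geometry
#'
#' @slot angles numeric, projection angles in radians over [0, pi).
#' @slot nBins integer, radial bins.
#' @slot binWidth numeric, mm.
#' @slot imageSize integer, reconstruction matrix size (square).
#' @slot spacing numeric, image pixel spacing in mm.
#' @slot step numeric, ray sampling step in mm.
#' @aliases ProjectionGeometry
#' @seealso [projectionGeometry()]
#' @export
setClass("ProjectionGeometry",
  representation(angles = "numeric", nBins = "integer", binWidth = "numeric",
                 imageSize = "integer", spacing = "numeric", step = "numeric"))

setValidity("ProjectionGeometry", function(object) {
  msg <- character()
  if (length(object@angles) < 1) msg <- c(msg, "need at least one angle")
  if (object@nBins < 1) msg <- c(msg, "nBins must be >= 1")
  if (object@binWidth <= 0 || object@spacing <= 0 || object@step <= 0)
    msg <- c(msg, "binWidth, spacing and step must be > 0")
  if (length(msg)) msg else TRUE
})

#' Sinogram: parallel-beam projection data
#'
#' Line integrals (activity * mm) or Poisson counts, one value per
#' (angle, radial bin).
#'
#' @slot values numeric matrix, `length(angles)` x `nBins`.
#' @slot geometry the [ProjectionGeometry].
#' @slot countScale numeric; for count data, expected counts per unit
#'   attenuated line integral (the calibration factor linking
#'   reconstructed values back to activity concentration). 1 for plain
#'   line-integral sinograms.
#' @aliases Sinogram
#' @export
setClass("Sinogram",
  representation(values = "matrix", geometry = "ProjectionGeometry",
                 countScale = "numeric"))

setValidity("Sinogram", function(object) {
  msg <- character()
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "sinogram values must be finite and >= 0")
  if (nrow(object@values) != length(object@geometry@angles) ||
      ncol(object@values) != object@geometry@nBins)
    msg <- c(msg, "sinogram dimensions must match geometry")
  if (length(msg)) msg else TRUE
})

#' AttenuationFactors: per-LOR photon survival probabilities
#'
#' The factor exp(-integral of mu along the line of response) for every
#' (angle, bin); values in (0, 1].
#'
#' @slot values numeric matrix.
#' @slot geometry the [ProjectionGeometry].
#' @aliases AttenuationFactors
#' @seealso [attenuationFactors()]
#' @export
setClass("AttenuationFactors",
  representation(values = "matrix", geometry = "ProjectionGeometry"))

setValidity("AttenuationFactors", function(object) {
  if (any(!is.finite(object@values)) || any(object@values <= 0) ||
      any(object@values > 1))
    "attenuation factors must lie in (0, 1]"
  else TRUE
})

#' ReconConfig: OSEM reconstruction parameters
#'
#' Defaults mirror a typical clinical whole-body protocol: 2 iterations,
#' 21 subsets, 4 mm Gaussian post-filter.
#'
#' @slot iterations integer, full OSEM iterations.
#' @slot subsets integer, number of angle-interleaved subsets; must
#'   divide the number of projection angles.
#' @slot postFilterFWHM numeric, mm (0 disables the filter).
#' @slot initValue numeric, uniform initial image value.
#' @slot epsilon numeric, division guard.
#' @aliases ReconConfig
#' @seealso [reconConfig()], [osemReconstruct()]
#' @export
setClass("ReconConfig",
  representation(iterations = "integer", subsets = "integer",
                 postFilterFWHM = "numeric", initValue = "numeric",
                 epsilon = "numeric"))

setValidity("ReconConfig", function(object) {
  msg <- character()
  if (object@iterations < 1) msg <- c(msg, "iterations must be >= 1")
  if (object@subsets < 1) msg <- c(msg, "subsets must be >= 1")
  if (object@postFilterFWHM < 0) msg <- c(msg, "postFilterFWHM must be >= 0")
  if (object@initValue <= 0) msg <- c(msg, "initValue must be > 0")
  if (length(msg)) msg else TRUE
})

#' SUVImage: reconstructed activity rescaled to standardized uptake values
#'
#' SUV = activity concentration (Bq/mL) / (injected dose / body weight).
#'
#' @slot suv numeric matrix or array, dimensionless.
#' @slot dose numeric, Bq.
#' @slot weight numeric, g.
#' @slot calibration numeric, counts per unit line integral used to map
#'   reconstructed values back to Bq/mL.
#' @aliases SUVImage
#' @seealso [suvScale()]
#' @export
setClass("SUVImage",
  representation(suv = "array", dose = "numeric", weight = "numeric",
                 calibration = "numeric"))

setValidity("SUVImage", function(object) {
  if (any(!is.finite(object@suv)) || any(object@suv < 0))
    "SUV values must be finite and >= 0"
  else TRUE
})

#' ExperimentConfig: the full four-arm experiment configuration
#'
#' @slot phantom [PhantomConfig] shared by all subjects (per-subject
#'   jitter and noise seeds are derived from `seed`).
#' @slot transform [BilinearTransform] for the CT-based map.
#' @slot lacs [TissueClassLACs] for the segmentation-based maps.
#' @slot recon [ReconConfig].
#' @slot nAngles integer, projection angles (divisible by the subset count).
#' @slot totalCounts numeric, expected true coincidences per slice.
#' @slot nSubjects integer.
#' @slot seed integer, master seed; per-subject seeds are distinct
#'   deterministic offsets.
#' @slot jitterFrac numeric, SD of the per-subject fractional jitter of
#'   body/lung axes (inter-subject anatomy variation).
#' @slot poisson logical, simulate Poisson counts (FALSE = noise-free).
#' @slot lungMaskThreshold numeric, HU threshold of the region-growing
#'   lung mask.
#' @aliases ExperimentConfig
#' @seealso [experimentConfig()], [runExperiment()]
#' @export
setClass("ExperimentConfig",
  representation(phantom = "PhantomConfig", transform = "BilinearTransform",
                 lacs = "TissueClassLACs", recon = "ReconConfig",
                 nAngles = "integer", totalCounts = "numeric",
                 nSubjects = "integer", seed = "integer",
                 jitterFrac = "numeric", poisson = "logical",
                 lungMaskThreshold = "numeric"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@totalCounts <= 0) msg <- c(msg, "totalCounts must be > 0")
  if (object@nAngles %% object@recon@subsets != 0)
    msg <- c(msg, "nAngles must be divisible by the OSEM subset count")
  if (length(msg)) msg else TRUE
})

#' ExperimentReport: pooled results of a four-arm run
#'
#' @slot measurements data.frame of per-ROI values (subject, side, level,
#'   position, variant, suv, hu).
#' @slot suvRegion,relDiff,contrasts,huRegion data.frames of pooled
#'   summaries (see [regionalSummary()]).
#' @slot mld data.frame, mean-lung-density screen per subject.
#' @slot config the [ExperimentConfig].
#' @slot provenance list: config hash, per-subject seeds, package version.
#' @aliases ExperimentReport
#' @seealso [runExperiment()], [reportToTables()]
#' @export
setClass("ExperimentReport",
  representation(measurements = "data.frame", suvRegion = "data.frame",
                 relDiff = "data.frame", contrasts = "data.frame",
                 huRegion = "data.frame", mld = "data.frame",
                 config = "ExperimentConfig", provenance = "list"))
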