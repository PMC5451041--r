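#' Construct the bilinear HU to LAC transform
#'
#' @param breakHU break point, HU (default 47, the 120 kVp value).
#' @param slopeBelow slope below the break, cm^-1/HU (default 9.6e-5,
#'   anchored so that -1000 HU maps to exactly 0).
#' @param slopeAbove slope above the break, cm^-1/HU (default 5.1e-5).
#' @param interceptAbove intercept of the above-break segment in the
#'   air-anchored form `slopeAbove * (HU + 1000) + interceptAbove`;
#'   `NULL` (default) derives it from continuity at the break.
#' @return A [BilinearTransform].
#' @export
#' @examples
#' tr <- bilinearTransform()
#' huToLac(c(-1000, 0, 47, 1000), tr)
bilinearTransform <- function(breakHU = 47, slopeBelow = 9.6e-5,
                              slopeAbove = 5.1e-5, interceptAbove = NULL) {
  if (is.null(interceptAbove))
    interceptAbove <- (slopeBelow - slopeAbove) * (breakHU + 1000)
  new("BilinearTransform", breakHU = breakHU, slopeBelow = slopeBelow,
      slopeAbove = slopeAbove, interceptAbove = interceptAbove)
}

#' Construct the four-class segmentation LAC set
#'
#' @param air,lung,fat,soft class LACs in cm^-1; defaults 0, 0.0224,
#'   0.0854, 0.1 (the values assigned by Dixon-based 4-class
#'   segmentation at 511 keV).
#' @return A [TissueClassLACs].
#' @export
tissueClassLACs <- function(air = 0, lung = 0.0224, fat = 0.0854,
                            soft = 0.1) {
  new("TissueClassLACs", air = air, lung = lung, fat = fat, soft = soft)
}

#' Convert Hounsfield units to 511 keV linear attenuation coefficients
#'
#' Elementwise piecewise bilinear transform; output clipped at 0.
#'
#' @param hu numeric vector, matrix or array of HU in [-1024, 3071].
#' @param transform a [BilinearTransform].
#' @return Object of the same shape, LAC in cm^-1.
#' @export
huToLac <- function(hu, transform = bilinearTransform()) {
  validObject(transform)
  if (any(!is.finite(hu)))
    stop("input error: non-finite HU values")
  lac <- ifelse(hu <= transform@breakHU,
                transform@slopeBelow * (hu + 1000),
                transform@slopeAbove * (hu + 1000) + transform@interceptAbove)
  out <- pmax(lac, 0)
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

.as3d <- function(x) {
  if (is.null(dim(x))) stop("expected a matrix or array")
  if (length(dim(x)) == 2) array(x, dim = c(dim(x), 1)) else x
}

#' Build the CT-based attenuation map (variant CTAC)
#'
#' Applies [huToLac()] to a phantom's HU volume (or a raw HU array).
#'
#' @param x a [DigitalPhantom], or a numeric HU matrix/array.
#' @param transform a [BilinearTransform].
#' @param spacing voxel spacing in mm (taken from the phantom when `x`
#'   is a [DigitalPhantom]).
#' @return A [MuMap] with variant `"CTAC"`.
#' @export
buildCTMuMap <- function(x, transform = bilinearTransform(), spacing = NULL) {
  if (is(x, "DigitalPhantom")) {
    spacing <- x@spacing
    x <- x@huVolume
  }
  if (is.null(spacing)) stop("spacing required for raw HU input")
  new("MuMap", lac = .as3d(huToLac(x, transform)), spacing = spacing,
      variant = "CTAC")
}

#' Build the segmentation-based attenuation map (variant MRAC)
#'
#' Assigns one fixed LAC per tissue class: air -> 0, lung -> lung class,
#' fat -> fat class, soft tissue AND bone -> soft class. Mapping bone to
#' soft tissue is deliberate: segmentation-based attenuation correction
#' does not see bone.
#'
#' @param x a [DigitalPhantom] or an integer label matrix/array with
#'   codes from [tissueLabels()].
#' @param lacs a [TissueClassLACs].
#' @param spacing voxel spacing in mm (from the phantom if omitted).
#' @return A [MuMap] with variant `"MRAC"`.
#' @export
buildSegmentationMuMap <- function(x, lacs = tissueClassLACs(),
                                   spacing = NULL) {
  if (is(x, "DigitalPhantom")) {
    spacing <- x@spacing
    x <- x@labelVolume
  }
  if (is.null(spacing)) stop("spacing required for raw label input")
  lab <- tissueLabels()
  if (!all(x %in% lab))
    stop("input error: unknown tissue label codes")
  lut <- c(lacs@air, lacs@lung, lacs@lung, lacs@fat, lacs@soft, lacs@soft)
  lac <- lut[as.integer(x) + 1L]
  dim(lac) <- dim(x)
  new("MuMap", lac = .as3d(lac), spacing = spacing, variant = "MRAC")
}

# vectorized face-connected flood fill (4-neighbourhood in-plane,
# 6-neighbourhood across slices)
.floodFill <- function(cond, seedIdx) {
  d <- dim(cond)
  mask <- array(FALSE, d)
  mask[seedIdx] <- TRUE
  repeat {
    grown <- mask
    grown[-1, , ] <- grown[-1, , ] | mask[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | mask[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | mask[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | mask[, -1, ]
    if (d[3] > 1) {
      grown[, , -1] <- grown[, , -1] | mask[, , -d[3]]
      grown[, , -d[3]] <- grown[, , -d[3]] | mask[, , -1]
    }
    grown <- grown & cond
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

#' Grow a lung mask by thresholded region growing
#'
#' Flood fill from seed voxels through face-connected voxels whose HU
#' lies strictly below the threshold.
#'
#' @param hu HU matrix/array, or a [DigitalPhantom].
#' @param seeds integer matrix of seed voxel indices, one row per seed:
#'   (row, col) or (row, col, slice).
#' @param huThreshold HU growth threshold (default -300).
#' @return A [LungMask].
#' @export
growLungMask <- function(hu, seeds, huThreshold = -300) {
  if (is(hu, "DigitalPhantom")) hu <- hu@huVolume
  hu <- .as3d(hu)
  seeds <- as.matrix(seeds)
  if (ncol(seeds) == 2) seeds <- cbind(seeds, 1L)
  storage.mode(seeds) <- "integer"
  seedIdx <- seeds[, 1] + (seeds[, 2] - 1L) * dim(hu)[1] +
    (seeds[, 3] - 1L) * dim(hu)[1] * dim(hu)[2]
  if (any(hu[seedIdx] >= huThreshold))
    stop("seed error: seed voxel HU not below the growth threshold")
  mask <- .floodFill(hu < huThreshold, seedIdx)
  new("LungMask", mask = mask, seeds = seeds, huThreshold = huThreshold)
}

#' Replace lung LACs by the fixed segmentation lung class (variant CTAC_MRLUNG)
#'
#' Sets every voxel inside the lung mask to the lung class LAC; all
#' other voxels are passed through unchanged.
#'
#' @param mumap a [MuMap] (typically variant `"CTAC"`).
#' @param mask a [LungMask] or logical array on the same grid.
#' @param lacs a [TissueClassLACs].
#' @return A [MuMap] with variant `"CTAC_MRLUNG"`.
#' @export
replaceLungLac <- function(mumap, mask, lacs = tissueClassLACs()) {
  m <- if (is(mask, "LungMask")) mask@mask else .as3d(mask)
  if (!identical(dim(m), dim(mumap@lac)))
    stop("geometry error: mask and mu-map grids differ")
  lac <- mumap@lac
  lac[m] <- lacs@lung
  new("MuMap", lac = lac, spacing = mumap@spacing, variant = "CTAC_MRLUNG")
}

#' Replace bone LACs by soft tissue (variant CTAC_MRLUNG_NOBONE)
#'
#' Voxels with LAC strictly greater than the threshold (default
#' 0.10 cm^-1) are set to the soft-tissue class LAC; all others are
#' unchanged. Idempotent.
#'
#' @param mumap a [MuMap].
#' @param lacs a [TissueClassLACs].
#' @param threshold LAC threshold in cm^-1 (strict `>`).
#' @return A [MuMap] with variant `"CTAC_MRLUNG_NOBONE"`.
#' @export
stripBone <- function(mumap, lacs = tissueClassLACs(), threshold = 0.10) {
  if (threshold <= 0) stop("threshold must be > 0")
  lac <- mumap@lac
  lac[lac > threshold] <- lacs@soft
  new("MuMap", lac = lac, spacing = mumap@spacing,
      variant = "CTAC_MRLUNG_NOBONE")
}

#' Voxelwise difference histogram between two attenuation maps
#'
#' Quality-control comparison of two attenuation maps inside a body
#' mask: histogram of the voxelwise difference (a - b) and the fraction
#' of voxels whose absolute difference is within `tol` times the
#' soft-tissue LAC.
#'
#' @param a,b [MuMap]s on the same grid.
#' @param bodyMask logical array selecting body (non-background) voxels.
#' @param tol tolerance as a fraction of the soft-tissue LAC
#'   (default 0.10).
#' @param nBins histogram bin count.
#' @param lacs a [TissueClassLACs] (supplies the soft-tissue reference).
#' @return A list with `breaks`, `counts`, `mids` (histogram of a - b)
#'   and `fractionWithin` (proportion with |a - b| <= tol * soft LAC).
#' @export
muMapDifferenceHistogram <- function(a, b, bodyMask, tol = 0.10,
                                     nBins = 101,
                                     lacs = tissueClassLACs()) {
  if (!identical(dim(a@lac), dim(b@lac)))
    stop("geometry error: mu-map grids differ")
  bodyMask <- .as3d(bodyMask)
  if (!identical(dim(bodyMask), dim(a@lac)))
    stop("geometry error: body mask grid differs")
  dif <- (a@lac - b@lac)[bodyMask]
  rng <- range(dif, 0)
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * 1e-6
  h <- graphics::hist(dif, breaks = seq(rng[1], rng[2], length.out = nBins + 1),
                      plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       fractionWithin = mean(abs(dif) <= tol * lacs@soft))
}
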