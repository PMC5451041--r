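#' Create a 2-D parallel-beam projection geometry
#'
#' @param nAngles projection angles, evenly spaced over [0, pi)
#'   (default 168, divisible by the 21 OSEM subsets).
#' @param imageSize reconstruction matrix size.
#' @param spacing image pixel spacing, mm.
#' @param nBins radial bins (default `imageSize`).
#' @param binWidth radial bin width, mm (default `spacing`).
#' @param step ray sampling step, mm (default `spacing / 2`).
#' @return A [ProjectionGeometry].
#' @export
projectionGeometry <- function(nAngles = 168L, imageSize = 256L,
                               spacing = 2.6, nBins = imageSize,
                               binWidth = spacing, step = spacing / 2) {
  angles <- (seq_len(nAngles) - 1) * pi / nAngles
  new("ProjectionGeometry", angles = angles, nBins = as.integer(nBins),
      binWidth = binWidth, imageSize = as.integer(imageSize),
      spacing = spacing, step = step)
}

.asSlice <- function(x) {
  if (is(x, "MuMap")) x <- x@lac
  if (is(x, "DigitalPhantom")) x <- x@activityVolume
  if (length(dim(x)) == 3) {
    if (dim(x)[3] != 1)
      stop("projection operates on a single axial slice; subset the volume")
    x <- x[, , 1]
  }
  x
}

.checkGeom <- function(img, geometry) {
  if (nrow(img) != geometry@imageSize || ncol(img) != geometry@imageSize)
    stop("geometry mismatch: image size does not match geometry")
}

#' Forward project an image into a sinogram
#'
#' Ray-driven line integrals (value x mm) along every line of response,
#' exactly adjoint to [backProject()].
#'
#' @param image numeric matrix (or single-slice array) on the geometry
#'   grid.
#' @param geometry a [ProjectionGeometry].
#' @return A [Sinogram] of line integrals (`countScale = 1`).
#' @export
forwardProject <- function(image, geometry) {
  img <- .asSlice(image)
  .checkGeom(img, geometry)
  vals <- .cppForwardProject(img, geometry@angles, geometry@nBins,
                             geometry@binWidth, geometry@spacing,
                             geometry@step)
  new("Sinogram", values = pmax(vals, 0), geometry = geometry,
      countScale = 1)
}

#' Backproject a sinogram into image space
#'
#' The exact adjoint of [forwardProject()].
#'
#' @param sinogram a [Sinogram] or a numeric matrix (angles x bins).
#' @param geometry a [ProjectionGeometry].
#' @return Numeric matrix of size `imageSize` x `imageSize`.
#' @export
backProject <- function(sinogram, geometry = NULL) {
  if (is(sinogram, "Sinogram")) {
    if (is.null(geometry)) geometry <- sinogram@geometry
    sinogram <- sinogram@values
  }
  if (is.null(geometry)) stop("geometry required")
  .cppBackProject(sinogram, geometry@angles, geometry@imageSize,
                  geometry@binWidth, geometry@spacing, geometry@step)
}

#' Compute per-LOR attenuation factors from an attenuation map
#'
#' factor = exp(-integral of mu along the LOR), with mu in cm^-1 and
#' path lengths converted from mm to cm.
#'
#' @param mumap a [MuMap] (or numeric LAC matrix in cm^-1).
#' @param geometry a [ProjectionGeometry].
#' @return An [AttenuationFactors].
#' @export
attenuationFactors <- function(mumap, geometry) {
  lac <- if (is(mumap, "MuMap")) .asSlice(mumap@lac) else .asSlice(mumap)
  if (any(lac < 0)) stop("input error: negative attenuation coefficients")
  .checkGeom(lac, geometry)
  integrals <- .cppForwardProject(lac, geometry@angles, geometry@nBins,
                                  geometry@binWidth, geometry@spacing,
                                  geometry@step) / 10  # mm -> cm
  new("AttenuationFactors", values = exp(-pmax(integrals, 0)),
      geometry = geometry)
}

#' Simulate attenuated PET emission data
#'
#' Forward projects the activity map, attenuates each LOR with the TRUE
#' attenuation map, scales so the expected total equals `totalCounts`,
#' and (optionally) draws Poisson counts.
#'
#' @param activity activity matrix/array (Bq/mL) or a [DigitalPhantom].
#' @param mumapTrue the attenuation map that physically attenuates the
#'   emission (a [MuMap]).
#' @param geometry a [ProjectionGeometry].
#' @param totalCounts expected total counts over the sinogram.
#' @param rngSeed integer seed for the Poisson draw.
#' @param poisson simulate Poisson noise (`FALSE` returns the noise-free
#'   expectation).
#' @return A [Sinogram] of counts; its `countScale` slot is the
#'   calibration factor (expected counts per unit attenuated line
#'   integral) needed to recover activity units after reconstruction.
#' @export
simulateEmission <- function(activity, mumapTrue, geometry,
                             totalCounts = 3e6, rngSeed = 1L,
                             poisson = TRUE) {
  if (totalCounts <= 0) stop("configuration error: totalCounts must be > 0")
  act <- .asSlice(activity)
  .checkGeom(act, geometry)
  proj <- forwardProject(act, geometry)@values
  af <- attenuationFactors(mumapTrue, geometry)@values
  expected <- proj * af
  tot <- sum(expected)
  if (tot <= 0)
    stop("configuration error: zero-activity volume with totalCounts > 0")
  scale <- totalCounts / tot
  lambda <- scale * expected
  if (poisson) {
    set.seed(as.integer(rngSeed))
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow(lambda), ncol(lambda))
  } else counts <- lambda
  new("Sinogram", values = counts, geometry = geometry, countScale = scale)
}

#' Create an OSEM reconstruction configuration
#'
#' @param iterations full iterations (default 2).
#' @param subsets angle-interleaved subsets (default 21).
#' @param postFilterFWHM Gaussian post-filter FWHM in mm (default 4).
#' @param initValue uniform initial image value.
#' @param epsilon division guard.
#' @return A [ReconConfig].
#' @export
reconConfig <- function(iterations = 2L, subsets = 21L, postFilterFWHM = 4,
                        initValue = 1, epsilon = 1e-12) {
  new("ReconConfig", iterations = as.integer(iterations),
      subsets = as.integer(subsets), postFilterFWHM = postFilterFWHM,
      initValue = initValue, epsilon = epsilon)
}

# separable Gaussian convolution; truncated kernels are renormalized at
# the edges so flat fields stay flat
.gaussianSmooth <- function(img, fwhm, spacing) {
  if (fwhm <= 0) return(img)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / spacing
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img)
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    wsum <- numeric(nrow(m))
    for (o in -r:r) {
      w <- k[o + r + 1]
      src <- pmin(pmax(seq_len(nrow(m)) + o, 1L), nrow(m))
      out <- out + w * m[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Reconstruct activity with attenuation-corrected OSEM
#'
#' Ordered-subsets expectation maximization with the attenuation factors
#' inside the system model: the forward model for subset S is
#' `diag(af_S) %*% A_S x` and the sensitivity is `t(A_S) af_S`. Subsets
#' take angle-interleaved views (subset k uses angles k, k + subsets,
#' ...). A Gaussian post-filter is applied once after the final
#' iteration. Deterministic given its inputs.
#'
#' @param counts a [Sinogram] of counts (from [simulateEmission()]).
#' @param af an [AttenuationFactors] on the same geometry — the
#'   correction map, which need not equal the map that attenuated the
#'   data.
#' @param config a [ReconConfig].
#' @return Numeric image matrix in the count-scaled activity units of
#'   the sinogram; divide by `countScale` (see [suvScale()]) to recover
#'   Bq/mL.
#' @export
osemReconstruct <- function(counts, af, config = reconConfig()) {
  validObject(config)
  geom <- counts@geometry
  nAng <- length(geom@angles)
  if (nAng %% config@subsets != 0)
    stop("configuration error: subset count must divide the number of angles")
  if (!identical(dim(counts@values), dim(af@values)))
    stop("geometry mismatch: counts and attenuation factors differ")
  y <- counts@values
  a <- af@values
  n <- geom@imageSize
  eps <- config@epsilon
  x <- matrix(config@initValue, n, n)

  subsetAngles <- lapply(seq_len(config@subsets),
                         function(k) seq(k, nAng, by = config@subsets))
  # per-subset sensitivity images t(A_S) af_S
  sens <- lapply(subsetAngles, function(ia) {
    .cppBackProject(a[ia, , drop = FALSE], geom@angles[ia], n,
                    geom@binWidth, geom@spacing, geom@step)
  })

  for (it in seq_len(config@iterations)) {
    for (k in seq_len(config@subsets)) {
      ia <- subsetAngles[[k]]
      proj <- .cppForwardProject(x, geom@angles[ia], geom@nBins,
                                 geom@binWidth, geom@spacing, geom@step)
      yhat <- a[ia, , drop = FALSE] * proj
      ratio <- y[ia, , drop = FALSE] / pmax(yhat, eps)
      ratio[y[ia, , drop = FALSE] == 0 & yhat <= eps] <- 0
      bp <- .cppBackProject(a[ia, , drop = FALSE] * ratio, geom@angles[ia],
                            n, geom@binWidth, geom@spacing, geom@step)
      s <- sens[[k]]
      upd <- bp / pmax(s, eps)
      upd[s <= eps] <- 0
      x <- x * upd
    }
  }
  .gaussianSmooth(x, config@postFilterFWHM, geom@spacing)
}

#' Rescale a reconstructed image to standardized uptake values
#'
#' SUV = concentration (Bq/mL) / (injected dose / body weight).
#'
#' @param image reconstructed image matrix (count-scaled units).
#' @param dose injected dose, Bq (> 0).
#' @param weight body weight, g (> 0).
#' @param calibration counts per unit line integral (the `countScale`
#'   of the simulated sinogram); default 1 if the image is already in
#'   Bq/mL.
#' @return An [SUVImage].
#' @export
suvScale <- function(image, dose, weight, calibration = 1) {
  if (dose <= 0 || weight <= 0)
    stop("dose and weight must be > 0")
  conc <- image / calibration
  suv <- conc / (dose / weight)
  new("SUVImage", suv = .as3d(pmax(suv, 0)), dose = dose, weight = weight,
      calibration = calibration)
}
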