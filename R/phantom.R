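#' Create a phantom configuration
#'
#' Constructor for [PhantomConfig]. Defaults reproduce the study
#' conditions of the regional lung-density analysis: 256 x 256 matrix at
#' 2.6 mm isotropic spacing, lung band-mean HU targets of -779 / -746 /
#' -685 (anterior / middle / posterior, i.e. a 94 HU gravity-dependent
#' gradient), soft tissue at 40 HU, subcutaneous fat at -90 HU, bone at
#' +700 HU, near-uniform lung uptake around SUV 0.4 and a 351.8 MBq
#' injected dose in a 70 kg subject.
#'
#' @param gridSize in-plane matrix size (>= 64).
#' @param nSlices axial slices (default 1; the regional analysis is
#'   per-level so a single slice suffices at desk scale).
#' @param voxelSpacing isotropic voxel spacing, mm.
#' @param lungHU named numeric, band-mean HU targets
#'   (`anterior`, `middle`, `posterior`).
#' @param gradientModel `"linear"` or `"constant"`.
#' @param huNoiseSD additive Gaussian HU noise SD (all non-air voxels).
#' @param softTissueHU,fatHU,boneHU compartment HU.
#' @param bodyAxes,fatThickness,lungAxes,lungOffset geometry, mm.
#' @param boneGeometry list(`enabled`, `spineRadius`, `spineCenterY`,
#'   `ribInner`, `ribOuter`, `ribMinYFrac`); partial lists are completed
#'   with defaults.
#' @param activity named numeric, compartment activity in SUV units.
#' @param activityGradient fractional anterior->posterior lung activity
#'   modulation (0 = uniform uptake, so any reconstructed gradient is
#'   attributable to attenuation correction).
#' @param subjectWeight g.
#' @param injectedDose Bq.
#' @param rngSeed integer seed.
#' @return A validated [PhantomConfig].
#' @export
#' @examples
#' cfg <- phantomConfig(gridSize = 128)
#' cfg
phantomConfig <- function(gridSize = 256L, nSlices = 1L, voxelSpacing = 2.6,
                          lungHU = c(anterior = -779, middle = -746,
                                     posterior = -685),
                          gradientModel = c("linear", "constant"),
                          huNoiseSD = 25,
                          softTissueHU = 40, fatHU = -90, boneHU = 700,
                          bodyAxes = c(150, 105), fatThickness = 8,
                          lungAxes = c(52, 68), lungOffset = 72,
                          boneGeometry = list(),
                          activity = c(lung = 0.4, soft = 1.0,
                                       fat = 0.3, bone = 0.3),
                          activityGradient = 0,
                          subjectWeight = 70000, injectedDose = 351.8e6,
                          rngSeed = 1L) {
  gradientModel <- match.arg(gradientModel)
  bg <- utils::modifyList(
    list(enabled = TRUE, spineRadius = 16, spineCenterY = 50,
         ribInner = 0.88, ribOuter = 0.96, ribMinYFrac = -0.25),
    boneGeometry)
  new("PhantomConfig",
      gridSize = as.integer(gridSize), nSlices = as.integer(nSlices),
      voxelSpacing = voxelSpacing, lungHU = lungHU,
      gradientModel = gradientModel, huNoiseSD = huNoiseSD,
      softTissueHU = softTissueHU, fatHU = fatHU, boneHU = boneHU,
      bodyAxes = bodyAxes, fatThickness = fatThickness,
      lungAxes = lungAxes, lungOffset = lungOffset, boneGeometry = bg,
      activity = activity, activityGradient = activityGradient,
      subjectWeight = subjectWeight, injectedDose = injectedDose,
      rngSeed = as.integer(rngSeed))
}

# world coordinates of voxel centres; row = y (anterior -> posterior),
# col = x (lateral); origin at the grid centre
.gridCoords <- function(n, spacing) {
  ((0:(n - 1)) - (n - 1) / 2) * spacing
}

#' Generate a digital thorax phantom
#'
#' Renders a single- or multi-slice axial thorax: an elliptical body
#' with a subcutaneous fat layer, two elliptical lungs with a
#' linear-in-depth HU gradient calibrated so that the anterior / middle /
#' posterior band means equal the configured targets exactly before
#' noise, a posterior-medial spine cylinder with posterior-lateral rib
#' arcs, and a ground-truth activity map. Anterior is the smaller row
#' index.
#'
#' The depth gradient is piecewise linear in the normalized
#' anterior->posterior coordinate of each lung, re-centred per band so
#' the band-mean HU equals the target irrespective of the lung outline.
#' Gaussian HU noise (SD `huNoiseSD`) is then added to all non-air
#' voxels.
#'
#' @param config a [PhantomConfig].
#' @return A [DigitalPhantom].
#' @export
#' @examples
#' ph <- generateThoraxPhantom(phantomConfig(gridSize = 128, huNoiseSD = 0))
#' ph
generateThoraxPhantom <- function(config) {
  validObject(config)
  n <- config@gridSize
  sp <- config@voxelSpacing
  lab <- tissueLabels()

  xs <- .gridCoords(n, sp)
  X <- matrix(xs, n, n, byrow = TRUE)   # lateral coordinate per voxel
  Y <- matrix(xs, n, n)                 # anterior->posterior coordinate

  a <- config@bodyAxes[1]; b <- config@bodyAxes[2]
  if (a >= n * sp / 2 || b >= n * sp / 2)
    stop("configuration error: body ellipse exceeds the field of view")
  ai <- a - config@fatThickness; bi <- b - config@fatThickness

  body <- (X / a)^2 + (Y / b)^2 <= 1
  inner <- (X / ai)^2 + (Y / bi)^2 <= 1

  la <- config@lungAxes[1]; lb <- config@lungAxes[2]; off <- config@lungOffset
  if (off + la >= ai || lb >= bi)
    stop("geometry error: lungs exceed the inner body contour")
  lungR <- ((X + off) / la)^2 + (Y / lb)^2 <= 1   # smaller x = image right
  lungL <- ((X - off) / la)^2 + (Y / lb)^2 <= 1

  label <- matrix(lab["air"], n, n)
  label[body] <- lab["fat"]
  label[inner] <- lab["soft"]
  label[lungR] <- lab["lung_right"]
  label[lungL] <- lab["lung_left"]

  bg <- config@boneGeometry
  if (isTRUE(bg$enabled)) {
    sy <- bg$spineCenterY; sr <- bg$spineRadius
    if (abs(sy) + sr >= bi)
      stop("geometry error: spine exceeds the inner body contour")
    spine <- X^2 + (Y - sy)^2 <= sr^2
    re <- sqrt((X / ai)^2 + (Y / bi)^2)
    ribs <- re >= bg$ribInner & re <= bg$ribOuter &
      Y > bg$ribMinYFrac * b & label == lab["soft"]
    label[spine] <- lab["bone"]
    label[ribs] <- lab["bone"]
  }

  hu <- matrix(-1000, n, n)
  hu[label == lab["fat"]] <- config@fatHU
  hu[label == lab["soft"]] <- config@softTissueHU
  hu[label == lab["bone"]] <- config@boneHU

  # lung gradient: linear in per-lung depth fraction, band means calibrated
  tgt <- config@lungHU[c("anterior", "middle", "posterior")]
  for (lg in c("lung_left", "lung_right")) {
    idx <- which(label == lab[lg])
    if (!length(idx)) next
    if (config@gradientModel == "constant") {
      hu[idx] <- tgt["middle"]
      next
    }
    yv <- Y[idx]
    d <- (yv - min(yv)) / (max(yv) - min(yv))   # 0 anterior .. 1 posterior
    band <- findInterval(d, c(1 / 3, 2 / 3)) + 1L  # 1 ant, 2 mid, 3 post
    slope <- c((tgt[2] - tgt[1]) * 3, (tgt[3] - tgt[1]) * 1.5,
               (tgt[3] - tgt[2]) * 3)
    for (bnd in 1:3) {
      sel <- band == bnd
      if (!any(sel)) next
      hu[idx[sel]] <- tgt[bnd] + slope[bnd] * (d[sel] - mean(d[sel]))
    }
  }

  act <- matrix(0, n, n)
  suv <- config@activity
  doseConc <- config@injectedDose / config@subjectWeight  # Bq/mL per SUV
  act[label == lab["fat"]] <- suv["fat"] * doseConc
  act[label == lab["soft"]] <- suv["soft"] * doseConc
  act[label == lab["bone"]] <- suv["bone"] * doseConc
  for (lg in c("lung_left", "lung_right")) {
    idx <- which(label == lab[lg])
    if (!length(idx)) next
    base <- suv["lung"] * doseConc
    if (config@activityGradient != 0) {
      yv <- Y[idx]
      d <- (yv - min(yv)) / (max(yv) - min(yv))
      act[idx] <- base * (1 + config@activityGradient * (d - 0.5))
    } else act[idx] <- base
  }

  nz <- config@nSlices
  huV <- array(hu, dim = c(n, n, nz))
  actV <- array(act, dim = c(n, n, nz))
  labV <- array(as.integer(label), dim = c(n, n, nz))

  if (config@huNoiseSD > 0) {
    set.seed(config@rngSeed)
    nonair <- labV != lab["air"]
    noise <- stats::rnorm(sum(nonair), sd = config@huNoiseSD)
    huV[nonair] <- pmin(pmax(huV[nonair] + noise, -1000), 3071)
  }

  new("DigitalPhantom", huVolume = huV, activityVolume = actV,
      labelVolume = labV, spacing = sp, config = config)
}

#' Check left-right mirror symmetry of a phantom
#'
#' Compares the HU volume with its left-right reflection. A noise-free
#' phantom generated from the default symmetric geometry is exactly
#' invariant; HU noise or one-sided structure breaks the symmetry.
#'
#' @param phantom a [DigitalPhantom].
#' @param tol maximum tolerated absolute voxelwise HU difference
#'   (default 0: exact).
#' @return `TRUE` iff the maximum voxelwise |HU - mirrored HU| is <= `tol`.
#' @export
mirrorSymmetryCheck <- function(phantom, tol = 0) {
  hu <- phantom@huVolume
  flipped <- hu[, rev(seq_len(dim(hu)[2])), , drop = FALSE]
  max(abs(hu - flipped)) <= tol
}
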