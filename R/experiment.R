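#' Create a full four-arm experiment configuration
#'
#' @param phantom a [PhantomConfig] (defaults to [phantomConfig()]).
#' @param transform a [BilinearTransform].
#' @param lacs a [TissueClassLACs].
#' @param recon a [ReconConfig].
#' @param nAngles projection angles (must be divisible by the subset
#'   count; default 168).
#' @param totalCounts expected true coincidences per slice (default 3e6).
#' @param nSubjects cohort size (default 5).
#' @param seed master seed; per-subject phantom/noise seeds are derived
#'   as distinct deterministic offsets.
#' @param jitterFrac SD of per-subject fractional anatomy jitter
#'   (default 0.03).
#' @param poisson simulate Poisson counts (default TRUE).
#' @param lungMaskThreshold region-growing HU threshold (default -300).
#' @return An [ExperimentConfig].
#' @export
experimentConfig <- function(phantom = phantomConfig(),
                             transform = bilinearTransform(),
                             lacs = tissueClassLACs(),
                             recon = reconConfig(),
                             nAngles = 168L, totalCounts = 3e6,
                             nSubjects = 5L, seed = 1L,
                             jitterFrac = 0.03, poisson = TRUE,
                             lungMaskThreshold = -300) {
  new("ExperimentConfig", phantom = phantom, transform = transform,
      lacs = lacs, recon = recon, nAngles = as.integer(nAngles),
      totalCounts = totalCounts, nSubjects = as.integer(nSubjects),
      seed = as.integer(seed), jitterFrac = jitterFrac, poisson = poisson,
      lungMaskThreshold = lungMaskThreshold)
}

.subjectSeeds <- function(config) {
  (config@seed %% 100000L) * 10000L + 17L * seq_len(config@nSubjects)
}

# per-subject anatomy: jitter body/lung axes and assign the subject seed
.subjectPhantomConfig <- function(config, subject) {
  pc <- config@phantom
  seed <- .subjectSeeds(config)[subject]
  if (config@jitterFrac > 0) {
    set.seed(seed + 1L)
    f <- 1 + stats::rnorm(3, sd = config@jitterFrac)
    f <- pmin(pmax(f, 0.9), 1.1)
    pc@bodyAxes <- pc@bodyAxes * f[1]
    pc@lungAxes <- pc@lungAxes * f[2]
    pc@lungOffset <- pc@lungOffset * f[3]
  }
  pc@rngSeed <- seed
  pc
}

#' Build all four attenuation-map variants for one phantom
#'
#' @param phantom a [DigitalPhantom].
#' @param transform a [BilinearTransform].
#' @param lacs a [TissueClassLACs].
#' @param lungMaskThreshold HU threshold of the region-growing lung mask.
#' @return List with elements `CTAC`, `CTAC_MRLUNG`,
#'   `CTAC_MRLUNG_NOBONE`, `MRAC` ([MuMap]s) and `lungMask`
#'   (the [LungMask]).
#' @export
buildMuMaps <- function(phantom, transform = bilinearTransform(),
                        lacs = tissueClassLACs(),
                        lungMaskThreshold = -300) {
  lab <- tissueLabels()
  ctac <- buildCTMuMap(phantom, transform)
  seeds <- do.call(rbind, lapply(lab[c("lung_left", "lung_right")],
    function(code) {
      vox <- which(phantom@labelVolume == code, arr.ind = TRUE)
      round(colMeans(vox))
    }))
  mask <- growLungMask(phantom@huVolume, seeds, lungMaskThreshold)
  mrlung <- replaceLungLac(ctac, mask, lacs)
  nobone <- stripBone(mrlung, lacs)
  mrac <- buildSegmentationMuMap(phantom, lacs)
  list(CTAC = ctac, CTAC_MRLUNG = mrlung, CTAC_MRLUNG_NOBONE = nobone,
       MRAC = mrac, lungMask = mask)
}

#' Run the four-arm attenuation-correction experiment end to end
#'
#' For every subject: generate a phantom draw, build the four
#' attenuation-map variants, simulate emission data attenuated by the
#' CT-based (true) map, reconstruct one SUV image per variant with OSEM
#' using that variant's attenuation factors, place the 12-ROI scheme
#' once on the lung mask and copy it to all arms, and screen mean lung
#' density. Results are pooled with [regionalSummary()]. Fully
#' deterministic given the config seed.
#'
#' @param config an [ExperimentConfig].
#' @param verbose print per-stage progress.
#' @return An [ExperimentReport].
#' @export
runExperiment <- function(config, verbose = FALSE) {
  validObject(config)
  geom <- projectionGeometry(nAngles = config@nAngles,
                             imageSize = config@phantom@gridSize,
                             spacing = config@phantom@voxelSpacing)
  seeds <- .subjectSeeds(config)
  arms <- muMapVariants()
  rows <- list()
  mldRows <- list()
  for (s in seq_len(config@nSubjects)) {
    stage <- "phantom"
    res <- tryCatch({
      pc <- .subjectPhantomConfig(config, s)
      ph <- generateThoraxPhantom(pc)

      stage <- "mumaps"
      mm <- buildMuMaps(ph, config@transform, config@lacs,
                        config@lungMaskThreshold)

      stage <- "simulation"
      counts <- simulateEmission(ph, mm$CTAC, geom,
                                 totalCounts = config@totalCounts,
                                 rngSeed = seeds[s] + 2L,
                                 poisson = config@poisson)

      stage <- "reconstruction"
      suvs <- lapply(arms, function(a) {
        af <- attenuationFactors(mm[[a]], geom)
        img <- osemReconstruct(counts, af, config@recon)
        suvScale(img, dose = pc@injectedDose, weight = pc@subjectWeight,
                 calibration = counts@countScale)
      })
      names(suvs) <- arms

      stage <- "analysis"
      rois <- placeROIs(mm$lungMask, spacing = ph@spacing)
      meas <- do.call(rbind, lapply(arms, function(a) {
        df <- rois
        df$subject <- s
        df$variant <- a
        df$suv <- vapply(seq_len(nrow(rois)), function(i)
          roiMean(suvs[[a]], rois[i, ], spacing = ph@spacing), 0)
        df$hu <- vapply(seq_len(nrow(rois)), function(i)
          roiMean(ph@huVolume, rois[i, ], spacing = ph@spacing), 0)
        df
      }))
      mld <- mldScreen(ph, mm$lungMask)
      mld$subject <- s
      list(meas = meas, mld = mld)
    }, error = function(e) {
      stop(sprintf("subject %d, stage '%s': %s", s, stage,
                   conditionMessage(e)), call. = FALSE)
    })
    rows[[s]] <- res$meas
    mldRows[[s]] <- res$mld
    if (verbose) message(sprintf("subject %d/%d done", s, config@nSubjects))
  }
  measurements <- do.call(rbind, rows)
  summ <- regionalSummary(measurements)
  prov <- list(configHash = .configHash(config), seeds = seeds,
               version = as.character(utils::packageVersion("thoraxAC")))
  new("ExperimentReport", measurements = summ$measurements,
      suvRegion = summ$suvRegion, relDiff = summ$relDiff,
      contrasts = summ$contrasts, huRegion = summ$huRegion,
      mld = do.call(rbind, mldRows), config = config, provenance = prov)
}

.configToList <- function(config) {
  asL <- function(obj) {
    sl <- methods::slotNames(class(obj))
    out <- lapply(sl, function(s) {
      v <- methods::slot(obj, s)
      if (isVirtualClass(class(v)) || is(v, "PhantomConfig") ||
          is(v, "BilinearTransform") || is(v, "TissueClassLACs") ||
          is(v, "ReconConfig")) asL(v) else v
    })
    names(out) <- sl
    out
  }
  asL(config)
}

.configHash <- function(config) {
  js <- jsonlite::toJSON(.configToList(config), auto_unbox = TRUE,
                         digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Write an experiment report as CSV/JSON artifacts
#'
#' Writes `table_hu.csv` (regional HU summary), `table_suv.csv`
#' (SUVmean per region and arm), `table_reldiff.csv` (relative
#' differences vs the CT-based arm), `mld.csv`, `measurements.csv` and
#' `report.json` (summaries + provenance) with stable column order.
#'
#' @param report an [ExperimentReport].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
reportToTables <- function(report, dir) {
  if (nrow(report@measurements) == 0)
    stop("empty report: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    hu = file.path(dir, "table_hu.csv"),
    suv = file.path(dir, "table_suv.csv"),
    rd = file.path(dir, "table_reldiff.csv"),
    mld = file.path(dir, "mld.csv"),
    meas = file.path(dir, "measurements.csv"),
    json = file.path(dir, "report.json"))
  utils::write.csv(report@huRegion, paths["hu"], row.names = FALSE)
  utils::write.csv(report@suvRegion, paths["suv"], row.names = FALSE)
  utils::write.csv(report@relDiff, paths["rd"], row.names = FALSE)
  utils::write.csv(report@mld, paths["mld"], row.names = FALSE)
  utils::write.csv(report@measurements, paths["meas"], row.names = FALSE)
  jsonlite::write_json(
    list(suvRegion = report@suvRegion, relDiff = report@relDiff,
         contrasts = report@contrasts, huRegion = report@huRegion,
         provenance = report@provenance),
    paths["json"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
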