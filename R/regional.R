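#' Place the 12-ROI lung scheme on a lung mask
#'
#' Places 12 circular ROIs (default 10 mm diameter): 2 lungs x 2 levels
#' (hilum = medial column, basal = lateral column; on single-slice
#' volumes both levels share the axial slice) x 3 depth positions
#' (anterior / middle / posterior, centred at 20% / 50% / 80% of the
#' local anterior-posterior lung extent). Centres are nudged inward if
#' needed so every ROI voxel lies inside the mask.
#'
#' @param mask a [LungMask] or logical array with two connected lungs.
#' @param spacing voxel spacing, mm.
#' @param diameter ROI diameter, mm.
#' @param depthFracs depth fractions for anterior/middle/posterior.
#' @param slice axial slice index to place ROIs on (default: middle).
#' @return data.frame with columns `side`, `level`, `position`, `row`,
#'   `col`, `slice`, `diameter`.
#' @export
placeROIs <- function(mask, spacing, diameter = 10,
                      depthFracs = c(anterior = 0.2, middle = 0.5,
                                     posterior = 0.8),
                      slice = NULL) {
  m <- if (is(mask, "LungMask")) mask@mask else .as3d(mask)
  if (is.null(slice)) slice <- (dim(m)[3] + 1L) %/% 2L
  sl <- m[, , slice]
  comp <- .labelComponents(sl)
  ncomp <- max(comp)
  if (ncomp != 2)
    stop(sprintf("placement error: expected 2 lungs in the mask, found %d",
                 ncomp))
  meanCol <- tapply(which(comp > 0) %/% nrow(sl), comp[comp > 0], mean)
  # radiological convention: smaller column = patient's right
  rightId <- as.integer(names(which.min(meanCol)))
  rad <- diameter / 2
  rv <- floor(rad / spacing)
  offs <- expand.grid(dr = -rv:rv, dc = -rv:rv)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * spacing <= rad, ]

  fits <- function(r, c) {
    rr <- r + offs$dr; cc <- c + offs$dc
    if (any(rr < 1 | rr > nrow(sl) | cc < 1 | cc > ncol(sl))) return(FALSE)
    all(sl[cbind(rr, cc)])
  }

  out <- list()
  for (id in 1:2) {
    side <- if (id == rightId) "right" else "left"
    vox <- which(comp == id, arr.ind = TRUE)
    colCentre <- mean(range(vox[, 2]))
    halfW <- diff(range(vox[, 2])) / 2
    medialSign <- if (mean(vox[, 2]) < ncol(sl) / 2) +1 else -1
    colTargets <- c(hilum = colCentre + medialSign * 0.4 * halfW,
                    basal = colCentre - medialSign * 0.4 * halfW)
    rowMin <- min(vox[, 1]); rowMax <- max(vox[, 1])
    for (level in c("hilum", "basal")) {
      cTar <- round(colTargets[level])
      for (pos in names(depthFracs)) {
        found <- FALSE
        for (dc in c(0, 1, -1, 2, -2, 3, -3)) {
          cc <- cTar + dc
          rows <- vox[vox[, 2] == cc, 1]
          if (length(rows) < 2) next
          # depth fraction of the whole lung's AP extent, clamped to
          # the rows available in this column
          r0 <- min(max(rowMin + depthFracs[pos] * (rowMax - rowMin),
                        min(rows)), max(rows))
          rMid <- mean(range(rows))
          for (dr in 0:12) {
            rr <- round(r0 + sign(rMid - r0) * dr)
            if (fits(rr, cc)) {
              out[[length(out) + 1]] <- data.frame(
                side = side, level = level, position = pos,
                row = rr, col = cc, slice = slice, diameter = diameter)
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (!found)
          stop("placement error: lung too small to fit the ROI")
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# connected components (face connectivity) of a logical slice
.labelComponents <- function(sl) {
  comp <- matrix(0L, nrow(sl), ncol(sl))
  cur <- 0L
  remaining <- sl
  while (any(remaining)) {
    cur <- cur + 1L
    seed <- which(remaining)[1]
    filled <- .floodFill(array(remaining, c(dim(sl), 1)), seed)[, , 1]
    comp[filled] <- cur
    remaining <- remaining & !filled
  }
  comp
}

#' Voxel indices covered by an ROI
#'
#' @param roi one row of the data.frame returned by [placeROIs()].
#' @param dim volume dimensions.
#' @param spacing voxel spacing, mm.
#' @return Integer matrix of (row, col, slice) voxel indices whose
#'   centres fall within the ROI disc.
#' @export
roiVoxels <- function(roi, dim, spacing) {
  rad <- roi$diameter / 2
  rv <- floor(rad / spacing)
  offs <- expand.grid(dr = -rv:rv, dc = -rv:rv)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * spacing <= rad, ]
  rr <- roi$row + offs$dr
  cc <- roi$col + offs$dc
  keep <- rr >= 1 & rr <= dim[1] & cc >= 1 & cc <= dim[2]
  if (!all(keep)) stop("out-of-bounds ROI")
  cbind(row = rr, col = cc, slice = roi$slice)
}

#' Mean image value inside an ROI
#'
#' @param image numeric matrix/array, or [SUVImage] / [MuMap] /
#'   [DigitalPhantom] (HU volume).
#' @param roi one row of the [placeROIs()] data.frame.
#' @param spacing voxel spacing, mm (taken from the object if available).
#' @return Mean over voxels whose centres fall within the ROI disc.
#' @export
roiMean <- function(image, roi, spacing = NULL) {
  if (is(image, "SUVImage")) image <- image@suv
  if (is(image, "MuMap")) { spacing <- image@spacing; image <- image@lac }
  if (is(image, "DigitalPhantom")) {
    spacing <- image@spacing; image <- image@huVolume
  }
  image <- .as3d(image)
  if (is.null(spacing)) stop("spacing required")
  vox <- roiVoxels(roi, dim(image), spacing)
  mean(image[vox])
}

#' Relative difference in percent
#'
#' `(x - ref) / ref * 100`, the per-ROI statistic comparing each
#' reconstruction arm with the CT-based reference.
#'
#' @param x,ref numeric (ref > 0).
#' @return Percent difference.
#' @export
relativeDifference <- function(x, ref) {
  if (any(ref <= 0))
    stop("undefined-reference error: reference SUV must be > 0")
  (x - ref) / ref * 100
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' @param valuesByGroup named list of numeric vectors (>= 2 groups with
#'   >= 2 values each).
#' @param varEqual use pooled-variance t-tests (classic post-hoc
#'   behaviour; default `TRUE`).
#' @return List with `F`, `p` (ANOVA) and `pairwise` (data.frame of
#'   group pairs with raw and Bonferroni-multiplied p-values, capped
#'   at 1). Identical groups yield p = 1; zero within-group variance
#'   with unequal means yields p = 0.
#' @export
compareGroups <- function(valuesByGroup, varEqual = TRUE) {
  stopifnot(length(valuesByGroup) >= 2)
  if (any(vapply(valuesByGroup, length, 1L) < 2))
    stop("each group needs at least 2 values")
  df <- data.frame(
    value = unlist(valuesByGroup, use.names = FALSE),
    group = factor(rep(names(valuesByGroup),
                       vapply(valuesByGroup, length, 1L))))
  # variances at or below numerical noise are treated as exactly zero
  vtol <- 1e-20 * (mean(abs(df$value)) + 1)^2
  grandVar <- stats::var(df$value)
  vars <- vapply(valuesByGroup, stats::var, 0)
  if (grandVar <= vtol) {
    fit <- list(F = 0, p = 1)
  } else if (all(vars <= vtol)) {
    fit <- list(F = Inf, p = 0)   # zero within-group variance, means differ
  } else {
    an <- stats::anova(stats::lm(value ~ group, data = df))
    fit <- list(F = an$`F value`[1], p = an$`Pr(>F)`[1])
    if (is.nan(fit$p)) fit$p <- if (fit$F > 0) 0 else 1
  }
  pairs <- utils::combn(names(valuesByGroup), 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p = NA_real_, p_bonferroni = NA_real_)
  for (i in seq_len(m)) {
    a <- valuesByGroup[[pairs[1, i]]]
    b <- valuesByGroup[[pairs[2, i]]]
    if (stats::var(a) <= vtol && stats::var(b) <= vtol) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      p <- tryCatch(stats::t.test(a, b, var.equal = varEqual)$p.value,
                    error = function(e)
                      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    pw$p[i] <- p
    pw$p_bonferroni[i] <- min(1, p * m)
  }
  list(F = fit$F, p = fit$p, pairwise = pw)
}

#' Pool ROI measurements into a regional report
#'
#' Pools hilum + basal and left + right per depth position (12 ROIs ->
#' 3 regions), summarises SUVmean per region and variant, computes
#' per-ROI relative differences of every arm against the CT-based
#' reference, and tests regional contrasts.
#'
#' @param measurements data.frame with columns `subject`, `side`,
#'   `level`, `position`, `variant`, `suv` and optionally `hu`.
#' @param reference reference variant name (default `"CTAC"`).
#' @return List with data.frames `suvRegion` (mean/SD of SUVmean per
#'   position x variant), `relDiff` (mean/SD of per-ROI relative
#'   differences vs the reference, plus the SD of per-subject means),
#'   `contrasts` (ANOVA and Bonferroni-corrected anterior-posterior
#'   p-values per variant) and `huRegion` when `hu` is present.
#' @export
regionalSummary <- function(measurements, reference = "CTAC") {
  req <- c("subject", "side", "level", "position", "variant", "suv")
  if (!all(req %in% names(measurements)))
    stop("input error: missing measurement columns")
  counts <- table(measurements$subject, measurements$variant)
  if (any(counts != 12))
    stop("input error: each subject x variant needs a full 12-ROI set")
  if (!reference %in% measurements$variant)
    stop("input error: reference variant absent")

  positions <- c("anterior", "middle", "posterior")
  variants <- unique(measurements$variant)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))

  suvRegion <- do.call(rbind, lapply(variants, function(va) {
    do.call(rbind, lapply(positions, function(po) {
      v <- measurements$suv[measurements$variant == va &
                              measurements$position == po]
      data.frame(variant = va, position = po, mean = mean(v),
                 sd = stats::sd(v), n = length(v))
    }))
  }))

  key <- function(d) paste(d$subject, d$side, d$level, d$position)
  ref <- measurements[measurements$variant == reference, ]
  refSuv <- stats::setNames(ref$suv, key(ref))
  md <- measurements
  md$rd <- relativeDifference(md$suv, refSuv[key(md)])

  relDiff <- do.call(rbind, lapply(variants, function(va) {
    do.call(rbind, lapply(positions, function(po) {
      sel <- md[md$variant == va & md$position == po, ]
      perSubj <- tapply(sel$rd, sel$subject, mean)
      data.frame(variant = va, position = po, mean = mean(sel$rd),
                 sd = stats::sd(sel$rd),
                 sd_subject = stats::sd(as.numeric(perSubj)),
                 n = nrow(sel))
    }))
  }))

  contrasts <- do.call(rbind, lapply(variants, function(va) {
    sel <- md[md$variant == va, ]
    bySuv <- split(sel$suv, sel$position)[positions]
    cgS <- compareGroups(bySuv)
    apS <- cgS$pairwise
    apS <- apS$p_bonferroni[(apS$group1 == "anterior" &
                               apS$group2 == "posterior") |
                              (apS$group1 == "posterior" &
                                 apS$group2 == "anterior")]
    row <- data.frame(variant = va, anova_F_suv = cgS$F,
                      anova_p_suv = cgS$p, p_ant_post_suv = apS,
                      anova_p_rd = NA_real_, p_ant_post_rd = NA_real_)
    if (va != reference) {
      byRd <- split(sel$rd, sel$position)[positions]
      cgR <- compareGroups(byRd)
      apR <- cgR$pairwise
      apR <- apR$p_bonferroni[(apR$group1 == "anterior" &
                                 apR$group2 == "posterior") |
                                (apR$group1 == "posterior" &
                                   apR$group2 == "anterior")]
      row$anova_p_rd <- cgR$p
      row$p_ant_post_rd <- apR
    }
    row
  }))

  out <- list(suvRegion = suvRegion, relDiff = relDiff,
              contrasts = contrasts, measurements = md)
  if ("hu" %in% names(measurements)) {
    huSrc <- measurements[measurements$variant == reference, ]
    out$huRegion <- do.call(rbind, lapply(positions, function(po) {
      v <- huSrc$hu[huSrc$position == po]
      data.frame(position = po, mean = mean(v), sd = stats::sd(v),
                 n = length(v))
    }))
  }
  out
}

#' Mean lung density screen for emphysema
#'
#' Splits each lung into three equal-extent segments (along the slice
#' axis when >= 3 slices are available, otherwise along the in-plane
#' anterior-posterior axis as a surrogate), measures the mean lung
#' density (MLD) per segment, and flags segments whose MLD lies
#' strictly below the cutoff.
#'
#' @param hu HU array or [DigitalPhantom].
#' @param mask a [LungMask] or logical array with two lungs.
#' @param cutoff HU cutoff (default -950; strict `<`).
#' @return data.frame with columns `lung`, `segment`, `mld`, `flagged`
#'   (6 rows).
#' @export
mldScreen <- function(hu, mask, cutoff = -950) {
  if (is(hu, "DigitalPhantom")) hu <- hu@huVolume
  hu <- .as3d(hu)
  m <- if (is(mask, "LungMask")) mask@mask else .as3d(mask)
  if (!identical(dim(hu), dim(m)))
    stop("geometry error: HU and mask grids differ")
  sl <- (dim(m)[3] + 1L) %/% 2L
  comp <- .labelComponents(m[, , sl])
  if (max(comp) != 2)
    stop("segmentation error: expected 2 lungs in the mask")
  axis3d <- dim(m)[3] >= 3
  meanCol <- tapply(which(comp > 0) %/% nrow(comp), comp[comp > 0], mean)
  rightId <- as.integer(names(which.min(meanCol)))
  out <- list()
  for (id in 1:2) {
    side <- if (id == rightId) "right" else "left"
    inLung <- array(FALSE, dim(m))
    for (s in seq_len(dim(m)[3])) inLung[, , s] <- comp == id
    inLung <- inLung & m
    vox <- which(inLung, arr.ind = TRUE)
    ax <- if (axis3d) vox[, 3] else vox[, 1]
    lo <- min(ax); hi <- max(ax)
    cuts <- lo + (hi - lo + 1) * c(1, 2) / 3
    seg <- findInterval(ax, cuts) + 1L
    for (sg in 1:3) {
      sel <- vox[seg == sg, , drop = FALSE]
      if (!nrow(sel)) stop("segmentation error: empty lung segment")
      mld <- mean(hu[sel])
      out[[length(out) + 1]] <- data.frame(
        lung = side, segment = c("upper", "middle", "lower")[sg],
        mld = mld, flagged = mld < cutoff)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
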