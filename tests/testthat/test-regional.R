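test_that("the ROI scheme yields 12 contained, mirror-symmetric ROIs", {
  ph <- generateThoraxPhantom(quietConfig())
  mm <- buildMuMaps(ph)
  rois <- placeROIs(mm$lungMask, spacing = 2.6)
  expect_equal(nrow(rois), 12)
  expect_equal(sort(unique(rois$side)), c("left", "right"))
  expect_equal(sort(unique(rois$level)), c("basal", "hilum"))
  expect_equal(sort(unique(rois$position)),
               c("anterior", "middle", "posterior"))

  # containment: every ROI voxel inside the mask (voxel-membership oracle)
  mk <- maskVolume(mm$lungMask)
  for (i in seq_len(nrow(rois))) {
    vox <- roiVoxels(rois[i, ], dim(mk), 2.6)
    expect_true(all(mk[vox]))
  }

  # left-right mirror symmetry of the centres on the symmetric phantom
  n <- dim(mk)[2]
  for (lev in c("hilum", "basal")) for (pos in unique(rois$position)) {
    l <- rois[rois$side == "left" & rois$level == lev &
                rois$position == pos, ]
    r <- rois[rois$side == "right" & rois$level == lev &
                rois$position == pos, ]
    expect_equal(l$row, r$row)
    expect_equal(l$col, n + 1 - r$col)
  }

  # anterior ROIs sit at smaller row indices than posterior ones
  expect_true(all(rois$row[rois$position == "anterior"] <
                    rois$row[rois$position == "posterior"]))

  # lungs too small for a 1 cm ROI
  tiny <- array(FALSE, c(64, 64, 1))
  tiny[30, 20, 1] <- TRUE; tiny[30, 40, 1] <- TRUE
  expect_error(placeROIs(tiny, spacing = 2.6), "placement error")
})

test_that("ROI means equal a voxel-loop brute force", {
  set.seed(13)
  img <- array(runif(64 * 64), c(64, 64, 1))
  roi <- data.frame(row = 30, col = 25, slice = 1, diameter = 10)
  got <- roiMean(img, roi, spacing = 2.6)
  acc <- c()
  for (i in 1:64) for (j in 1:64) {
    if (sqrt((i - 30)^2 + (j - 25)^2) * 2.6 <= 5)
      acc <- c(acc, img[i, j, 1])
  }
  expect_equal(got, mean(acc), tolerance = 1e-12)
  # constant image
  expect_equal(roiMean(array(3.7, c(64, 64, 1)), roi, 2.6), 3.7)
  expect_error(roiMean(img, data.frame(row = 1, col = 1, slice = 1,
                                       diameter = 10), 2.6),
               "out-of-bounds")
})

test_that("HU sampled in posterior ROIs matches the phantom target", {
  ph <- generateThoraxPhantom(quietConfig())
  mm <- buildMuMaps(ph)
  rois <- placeROIs(mm$lungMask, spacing = 2.6)
  post <- rois[rois$position == "posterior", ]
  hu <- vapply(seq_len(nrow(post)),
               function(i) roiMean(ph, post[i, ]), 0)
  # ROI centres at 80% depth: inside the posterior band, near its target
  expect_true(all(hu > -779 & hu < -600))
  expect_lt(abs(mean(hu) - (-685)), 40)
})

test_that("relative difference follows its definition", {
  expect_equal(relativeDifference(0.47, 0.47), 0)
  expect_equal(relativeDifference(0.42, 0.47), -10.63829787, tolerance = 1e-8)
  expect_equal(relativeDifference(0.94, 0.47), 100)
  expect_error(relativeDifference(0.4, 0), "undefined-reference")
})

test_that("group comparison matches a textbook ANOVA fixture", {
  # hand-computed one-way ANOVA, 3 groups x 5 values
  g <- list(a = c(5, 7, 6, 8, 9), b = c(4, 5, 6, 5, 5), c = c(9, 10, 8, 11, 12))
  # grand mean 7.333..; SSB = 5*((7-22/3)^2+(5-22/3)^2+(10-22/3)^2) = 63.33..
  # SSW = 10 + 2 + 10 = 22; F = (63.333/2)/(22/12) = 17.2727..
  res <- compareGroups(g)
  expect_equal(res$F, (63.33333333 / 2) / (22 / 12), tolerance = 1e-6)
  expect_equal(res$p, stats::pf(res$F, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
  # Bonferroni factor equals the number of pairs (3)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p * 3), tolerance = 1e-12)
  # identical groups: adjusted p = 1
  same <- compareGroups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$pairwise$p_bonferroni, 1)
  # degenerate variance with unequal means: p -> 0
  degen <- compareGroups(list(a = c(2, 2), b = c(3, 3)))
  expect_equal(degen$pairwise$p, 0)
  expect_error(compareGroups(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("group ranking agrees with a permutation-test oracle", {
  set.seed(41)
  base <- rnorm(6)
  gaps <- c(big = 3, small = 0.6)
  pPerm <- pT <- c()
  for (nm in names(gaps)) {
    a <- base; b <- base + gaps[nm]
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    cnt <- 0; B <- 2000
    set.seed(7)
    for (k in 1:B) {
      idx <- sample(12, 6)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
        cnt <- cnt + 1
    }
    pPerm[nm] <- cnt / B
    pT[nm] <- compareGroups(list(a = a, b = b))$pairwise$p
  }
  expect_equal(order(pPerm), order(pT))
  expect_lt(pT["big"], pT["small"])
})

test_that("regional summary pools ROIs correctly on a hand fixture", {
  # 1 subject, 12 ROIs, 2 variants with a known offset pattern
  grid <- expand.grid(side = c("left", "right"),
                      level = c("hilum", "basal"),
                      position = c("anterior", "middle", "posterior"),
                      stringsAsFactors = FALSE)
  ref <- grid; ref$subject <- 1; ref$variant <- "CTAC"
  ref$suv <- c(0.30, 0.32, 0.34, 0.36, 0.40, 0.50,
               0.31, 0.33, 0.35, 0.37, 0.45, 0.55)
  alt <- ref; alt$variant <- "MRAC"
  alt$suv <- ref$suv * c(rep(1.10, 4), rep(0.90, 4), rep(0.80, 4))
  meas <- rbind(ref, alt)
  rs <- regionalSummary(meas)

  sel <- function(df, v, p) df[df$variant == v & df$position == p, ]
  antRef <- ref$suv[ref$position == "anterior"]
  expect_equal(sel(rs$suvRegion, "CTAC", "anterior")$mean, mean(antRef))
  expect_equal(sel(rs$suvRegion, "CTAC", "anterior")$sd, sd(antRef))
  # per-ROI relative differences: exact multiplicative offsets
  expect_equal(sel(rs$relDiff, "MRAC", "anterior")$mean, 10,
               tolerance = 1e-10)
  expect_equal(sel(rs$relDiff, "MRAC", "middle")$mean, -10,
               tolerance = 1e-10)
  expect_equal(sel(rs$relDiff, "MRAC", "posterior")$mean, -20,
               tolerance = 1e-10)
  expect_equal(sel(rs$relDiff, "MRAC", "posterior")$sd, 0,
               tolerance = 1e-10)
  expect_true(all(sel(rs$relDiff, "CTAC", "anterior")$mean == 0))

  # identical SUVs everywhere: zero SD, zero differences
  flat <- meas; flat$suv <- 0.4
  rsF <- regionalSummary(flat)
  expect_true(all(rsF$suvRegion$sd == 0))
  expect_true(all(rsF$relDiff$mean == 0))

  # incomplete ROI set rejected
  expect_error(regionalSummary(meas[-1, ]), "12-ROI")
})

test_that("MLD screen flags only segments strictly below the cutoff", {
  ph <- generateThoraxPhantom(quietConfig())
  lab <- tissueLabels()
  lungMask <- labelVolume(ph) %in% lab[c("lung_left", "lung_right")]
  dim(lungMask) <- dim(labelVolume(ph))
  scr <- mldScreen(ph, lungMask)
  expect_equal(nrow(scr), 6)
  expect_equal(sort(unique(scr$segment)), c("lower", "middle", "upper"))
  expect_true(all(!scr$flagged))  # healthy defaults: nothing pathologic

  # one emphysematous lung: exactly its 3 segments flagged
  hu <- huVolume(ph)
  hu[labelVolume(ph) == lab["lung_left"]] <- -980
  scr2 <- mldScreen(hu, lungMask)
  expect_equal(sum(scr2$flagged), 3)
  expect_true(all(scr2$flagged[scr2$lung == "left"]))

  # boundary: MLD exactly at the cutoff is not flagged (strict <)
  hu3 <- huVolume(ph)
  hu3[lungMask] <- -950
  scr3 <- mldScreen(hu3, lungMask)
  expect_equal(unique(scr3$mld), -950)
  expect_true(all(!scr3$flagged))
})
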