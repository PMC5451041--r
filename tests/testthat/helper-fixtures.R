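# Shared fixtures: small phantoms and analytic test images.

smallConfig <- function(...) {
  phantomConfig(gridSize = 128L, ...)
}

quietConfig <- function(...) {
  phantomConfig(gridSize = 128L, huNoiseSD = 0, ...)
}

# anti-aliased disc image (fractional edge coverage via supersampling),
# value inside, 0 outside; n x n grid with given spacing (mm)
discImage <- function(n, spacing, radius, value = 1, center = c(0, 0),
                      ss = 4L) {
  xs <- ((0:(n - 1)) - (n - 1) / 2) * spacing
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * spacing
  img <- matrix(0, n, n)
  for (ox in offs) for (oy in offs) {
    r2 <- outer((xs + oy - center[2])^2, (xs + ox - center[1])^2, "+")
    img <- img + (r2 <= radius^2) / ss^2
  }
  img * value
}

# independent queue-based flood fill (face connectivity, 2-D)
bfsFill <- function(cond, seedRow, seedCol) {
  d <- dim(cond)
  visited <- matrix(FALSE, d[1], d[2])
  if (!cond[seedRow, seedCol]) return(visited)
  queue <- list(c(seedRow, seedCol))
  visited[seedRow, seedCol] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]
    queue <- queue[-1]
    for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + step
      if (q[1] >= 1 && q[1] <= d[1] && q[2] >= 1 && q[2] <= d[2] &&
          cond[q[1], q[2]] && !visited[q[1], q[2]]) {
        visited[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  visited
}

# MuMap wrapper for raw matrices
asMuMap <- function(m, spacing, variant = "CTAC") {
  new("MuMap", lac = array(m, c(dim(m), 1)), spacing = spacing,
      variant = variant)
}

lungBandMeans <- function(phantom) {
  lab <- tissueLabels()
  hu <- huVolume(phantom)
  lv <- labelVolume(phantom)
  n <- dim(hu)[1]
  res <- list()
  for (lg in c("lung_left", "lung_right")) {
    idx <- which(lv == lab[lg], arr.ind = TRUE)
    d <- (idx[, 1] - min(idx[, 1])) / (max(idx[, 1]) - min(idx[, 1]))
    band <- findInterval(d, c(1 / 3, 2 / 3)) + 1L
    vals <- hu[idx]
    res[[lg]] <- tapply(vals, band, mean)
  }
  res
}
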