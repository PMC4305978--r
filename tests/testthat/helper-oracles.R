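# Independent oracles used across the suite. These deliberately avoid the
# package's implementation paths: labeling by BFS flood fill, counting by a
# literal double loop over frames and marks, matching by exhaustive greedy
# search, regression/Bland-Altman by direct formula evaluation.

# 8-connected component labeling by breadth-first flood fill.
floodLabels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- cur
      while (nrow(queue)) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue <- rbind(queue, c(ii, jj))
          }
        }
      }
    }
  }
  lab
}

# Component centroids (0-based, round half up), filtered by area, sorted
# raster order.
oracleCentroids <- function(mask, minArea) {
  lab <- floodLabels(mask)
  out <- data.frame(x = integer(0), y = integer(0))
  for (k in seq_len(max(lab, 0))) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) >= minArea) {
      out <- rbind(out, data.frame(x = floor(mean(pix[, 2] - 1) + 0.5),
                                   y = floor(mean(pix[, 1] - 1) + 0.5)))
    }
  }
  out[order(out$y, out$x), , drop = FALSE]
}

# The forbidden-line rule written out longhand (left/bottom forbidden,
# top/right accepting, y-down coordinates).
oracleCounted <- function(x0, y0, w, h, x, y) {
  x > x0 && x <= x0 + w && y >= y0 && y < y0 + h
}

# Literal double loop: per-frame label tallies.
oracleCountInGrid <- function(fr, mx, my, mlab) {
  res <- data.frame(frameId = fr$frameId, nPositive = 0L, nNegative = 0L)
  for (i in seq_len(nrow(fr))) for (k in seq_along(mx)) {
    if (oracleCounted(fr$x0[i], fr$y0[i], fr$width[i], fr$height[i],
                      mx[k], my[k])) {
      col <- if (mlab[k] == "POSITIVE") "nPositive" else "nNegative"
      res[i, col] <- res[i, col] + 1L
    }
  }
  res
}

# Exhaustive greedy matching: repeatedly pick the globally closest free
# pair within tolerance, ties by (dd index, cd index).
oracleGreedyMatch <- function(A, B, tol) {
  freeA <- rep(TRUE, nrow(A)); freeB <- rep(TRUE, nrow(B))
  pairs <- data.frame(dd = integer(0), cd = integer(0))
  repeat {
    best <- NULL; bestD <- Inf
    for (i in which(freeA)) for (j in which(freeB)) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2)
      if (d <= tol && d < bestD) { bestD <- d; best <- c(i, j) }
    }
    if (is.null(best)) break
    pairs <- rbind(pairs, data.frame(dd = best[1], cd = best[2]))
    freeA[best[1]] <- FALSE; freeB[best[2]] <- FALSE
  }
  pairs
}

# Random MarkSet with distinct integer coordinates.
randomMarkSet <- function(n, w, h, role = "dD", spot = "s") {
  idx <- sample.int(w * h, n)
  MarkSet(spot, role,
          data.frame(x = (idx - 1) %% w, y = (idx - 1) %/% w,
                     label = sample(c("POSITIVE", "NEGATIVE"), n, replace = TRUE),
                     provenance = sample(c("AUTO", "EXPERT_ADDED"), n,
                                         replace = TRUE)))
}

# Run the full synthetic chain for one seed and return everything the
# oracle comparisons need.
runSpotChain <- function(seed, nNuclei = 500, ki67 = 25, size = 1024,
                         em = ErrorModel(seed = seed),
                         frame = 150, spacing = 300) {
  spot <- generateSpot(nNuclei, ki67, size, em)
  dd <- markupToMarks(spot@markupMask, spotId = paste0("s", seed))
  cd <- simulateCd(spot, dd)
  grid <- generateGrid(size, size, frame, frame, spacing, spacing, seed = seed)
  list(spot = spot, dd = dd, cd = cd, grid = grid,
       audit = auditSpot(dd, cd, grid, spot@tissueMask),
       events = eventsInGrid(eventLog(spot), grid))
}

errorCategories <- c("FALSE_POSITIVE_LABEL", "FALSE_NEGATIVE_LABEL",
                     "FALSE_DETECTION", "UNDETECTED_BY_TISSUE_MASK",
                     "UNDETECTED_BY_NUCLEAR")
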