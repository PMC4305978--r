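test_that("zero-offset tiling places the expected frames", {
  g <- stereoKi67:::.buildGrid(1000, 1000, 100, 100, 500, 500, 0, 0, 1L)
  f <- frames(g)
  expect_equal(nrow(f), 4)
  expect_equal(f[, c("x0", "y0")],
               data.frame(x0 = c(0, 500, 0, 500), y0 = c(0, 0, 500, 500)))
  expect_equal(f$frameId, 0:3)
})

test_that("frame count equals lattice enumeration for arbitrary offsets", {
  # loop oracle: enumerate all offset + i*spacing positions that fit
  countFit <- function(W, H, w, h, sx, sy, ox, oy) {
    n <- 0
    for (x0 in seq(ox, W, by = sx)) for (y0 in seq(oy, H, by = sy))
      if (x0 + w <= W && y0 + h <= H) n <- n + 1
    n
  }
  g <- stereoKi67:::.buildGrid(1000, 1000, 100, 100, 500, 500, 450, 450, 1L)
  expect_equal(nFrames(g), countFit(1000, 1000, 100, 100, 500, 500, 450, 450))
  set.seed(11)
  for (rep in 1:20) {
    W <- sample(200:900, 1); H <- sample(200:900, 1)
    w <- sample(30:120, 1); h <- sample(30:120, 1)
    sx <- w + sample(0:100, 1); sy <- h + sample(0:100, 1)
    g <- generateGrid(W, H, w, h, sx, sy, seed = rep)
    expect_equal(nFrames(g),
                 countFit(W, H, w, h, sx, sy, g@offsetX, g@offsetY))
    expect_true(validObject(g))
  }
})

test_that("degenerate grid requests are rejected", {
  expect_error(generateGrid(90, 90, 100, 100, 200, 200), "no frame fits")
  expect_error(generateGrid(500, 500, 100, 100, 80, 200), "overlap")
})

test_that("grids are deterministic under the seed", {
  g1 <- generateGrid(800, 600, 90, 70, 200, 180, seed = 42)
  g2 <- generateGrid(800, 600, 90, 70, 200, 180, seed = 42)
  g3 <- generateGrid(800, 600, 90, 70, 200, 180, seed = 43)
  expect_identical(frames(g1), frames(g2))
  expect_identical(c(g1@offsetX, g1@offsetY), c(g2@offsetX, g2@offsetY))
  expect_false(identical(c(g1@offsetX, g1@offsetY), c(g3@offsetX, g3@offsetY)))
})

test_that("forbidden-line rule matches the hand-checked edge and corner table", {
  f <- list(x0 = 0, y0 = 0, width = 100, height = 100)
  expect_true(isCounted(f, 50, 50))     # interior
  # corners: only the top-right (accepting ^ accepting) corner counts
  expect_false(isCounted(f, 0, 0))
  expect_true(isCounted(f, 100, 0))
  expect_false(isCounted(f, 0, 100))
  expect_false(isCounted(f, 100, 100))
  # edge midpoints: top and right accept, left and bottom forbid
  expect_true(isCounted(f, 50, 0))
  expect_true(isCounted(f, 100, 50))
  expect_false(isCounted(f, 0, 50))
  expect_false(isCounted(f, 50, 100))
})

test_that("each mark is counted by at most one frame of a grid", {
  set.seed(7)
  for (rep in 1:10) {
    g <- generateGrid(400, 400, sample(40:80, 1), sample(40:80, 1),
                      sample(80:160, 1), sample(80:160, 1), seed = rep)
    x <- runif(300, 0, 400); y <- runif(300, 0, 400)
    f <- frames(g)
    hits <- sapply(seq_len(nrow(f)), function(i) isCounted(f[i, ], x, y))
    expect_true(all(rowSums(hits) <= 1))
  }
})

test_that("countInGrid equals the brute-force double loop", {
  set.seed(99)
  for (rep in 1:10) {
    g <- generateGrid(300, 300, 60, 60, 110, 110, seed = rep)
    ms <- randomMarkSet(200, 300, 300)
    m <- marks(ms)
    expect_equal(countInGrid(g, ms),
                 oracleCountInGrid(frames(g), m$x, m$y, m$label))
  }
})

test_that("forbidden corner marks are excluded from frame tallies", {
  g <- stereoKi67:::.buildGrid(200, 200, 100, 100, 200, 200, 0, 0, 1L)
  ms <- MarkSet("s", "dD",
                data.frame(x = c(10, 20, 30, 40), y = c(10, 20, 30, 40),
                           label = c("POSITIVE", "POSITIVE", "POSITIVE",
                                     "NEGATIVE")))
  expect_equal(countInGrid(g, ms),
               data.frame(frameId = 0L, nPositive = 3L, nNegative = 1L))
  origin <- MarkSet("s", "dD",
                    data.frame(x = 0, y = 0, label = "POSITIVE"))
  expect_equal(countInGrid(g, origin),
               data.frame(frameId = 0L, nPositive = 0L, nNegative = 0L))
})

test_that("autosizeGrid follows the closed-form spacing rule", {
  # saturation: target >= detected gives a full tiling
  g <- autosizeGrid(1000, 1000, 100, 100, 200, 500, seed = 1)
  expect_equal(c(g@spacingX, g@spacingY), c(100, 100))
  # f = 0.25 -> spacing 200; f = 1/9 -> spacing 300
  g <- autosizeGrid(2000, 2000, 100, 100, 1000, 250, seed = 1)
  expect_equal(c(g@spacingX, g@spacingY), c(200, 200))
  g <- autosizeGrid(2000, 2000, 100, 100, 900, 100, seed = 1)
  expect_equal(c(g@spacingX, g@spacingY), c(300, 300))
  expect_error(autosizeGrid(1000, 1000, 100, 100, 0, 10), "positive")
  expect_error(autosizeGrid(1000, 1000, 100, 100, 10, 0), "positive")
})

test_that("counted fraction of scattered points matches the frame-area fraction", {
  set.seed(5)
  diffs <- replicate(50, {
    g <- generateGrid(600, 600, 100, 100, 250, 250,
                      seed = sample.int(1e6, 1))
    x <- runif(400, 0, 600); y <- runif(400, 0, 600)
    frac <- mean(!is.na(stereoKi67:::.assignFrames(g, x, y)))
    frac - nFrames(g) * 100 * 100 / (600 * 600)
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})
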