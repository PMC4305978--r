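test_that("identical sets pair completely even at zero tolerance", {
  set.seed(12)
  ms <- randomMarkSet(20, 200, 200)
  m <- matchMarks(ms, ms, tolerance = 0)
  expect_equal(nrow(m$pairs), 20)
  expect_length(m$ddOnly, 0)
  expect_length(m$cdOnly, 0)
  expect_equal(m$pairs$dd, m$pairs$cd)   # distance-0 self pairs
})

test_that("far-apart sets yield no pairs", {
  a <- MarkSet("s", "dD", data.frame(x = c(0, 1), y = c(0, 0),
                                     label = "POSITIVE"))
  b <- MarkSet("s", "cD", data.frame(x = c(150, 180), y = c(150, 150),
                                     label = "POSITIVE"))
  m <- matchMarks(a, b, tolerance = 5)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$ddOnly, 1:2)
  expect_equal(m$cdOnly, 1:2)
})

test_that("greedy matching equals the exhaustive greedy oracle", {
  set.seed(77)
  for (rep in 1:20) {
    a <- randomMarkSet(sample(3:10, 1), 40, 40)
    b <- randomMarkSet(sample(3:10, 1), 40, 40, role = "cD")
    tol <- sample(c(3, 8, 20), 1)
    got <- matchMarks(a, b, tol)$pairs
    want <- oracleGreedyMatch(marks(a), marks(b), tol)
    got <- got[order(got$dd), ]; rownames(got) <- NULL
    want <- want[order(want$dd), ]; rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("edit classification covers the category taxonomy", {
  dd <- MarkSet("s", "dD", data.frame(
    x = c(10, 20, 30, 90), y = c(10, 20, 30, 90),
    label = c("POSITIVE", "NEGATIVE", "POSITIVE", "NEGATIVE")))
  # pair 1 kept, pair 2 kept, pair 3 relabeled, dd 4 deleted;
  # cd adds one inside tissue and one outside
  cd <- MarkSet("s", "cD", data.frame(
    x = c(10, 20, 30, 50, 70), y = c(10, 20, 30, 50, 70),
    label = c("POSITIVE", "NEGATIVE", "NEGATIVE", "POSITIVE", "NEGATIVE")))
  tissue <- matrix(FALSE, 100, 100)
  tissue[1:60, 1:60] <- TRUE           # (70,70) falls outside
  m <- matchMarks(dd, cd, 5)
  recs <- classifyEdits(m, dd, cd, tissue)
  expect_equal(sort(recs$category),
               sort(c("TRUE_POSITIVE", "TRUE_NEGATIVE", "FALSE_POSITIVE_LABEL",
                      "FALSE_DETECTION", "UNDETECTED_BY_NUCLEAR",
                      "UNDETECTED_BY_TISSUE_MASK")))
  expect_equal(recs$editKind[recs$category == "FALSE_POSITIVE_LABEL"], "RELABEL")
  expect_equal(recs$editKind[recs$category == "FALSE_DETECTION"], "DELETE")
  expect_equal(sort(recs$editKind[grepl("UNDETECTED", recs$category)]),
               c("ADD", "ADD"))
  # out-of-raster coordinate is a bounds error
  cdBad <- MarkSet("s", "cD", data.frame(x = 300, y = 300, label = "POSITIVE"))
  mBad <- matchMarks(dd, cdBad, 5)
  expect_error(classifyEdits(mBad, dd, cdBad, tissue), "outside")
})

test_that("ki67Percent handles counts and the undefined case", {
  expect_equal(ki67Percent(3, 1), 75)
  expect_equal(ki67Percent(0, 5), 0)
  expect_true(is.na(ki67Percent(0, 0)))
  expect_error(ki67Percent(-1, 2), ">= 0")
})

test_that("auditing identical sets yields zero edits and equal Ki67", {
  set.seed(2)
  ms <- randomMarkSet(60, 400, 400)
  g <- generateGrid(400, 400, 100, 100, 150, 150, seed = 3)
  a <- auditSpot(ms, MarkSet("s", "cD", marks(ms)), g,
                 matrix(TRUE, 400, 400))
  expect_equal(nEdits(a), 0)
  expect_equal(unname(diff(ki67Values(a))), 0)
  expect_equal(sum(tallies(a)[c("TRUE_POSITIVE", "TRUE_NEGATIVE")]),
               a@nCdNuclei)
})

test_that("expert additions lower Ki67% and are attributed to the nuclear component", {
  dd <- MarkSet("s", "dD", data.frame(
    x = c(10, 20, 30), y = c(10, 20, 30),
    label = c("POSITIVE", "POSITIVE", "NEGATIVE")))
  cd <- MarkSet("s", "cD", data.frame(
    x = c(10, 20, 30, 40, 50), y = c(10, 20, 30, 40, 50),
    label = c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE", "NEGATIVE")))
  g <- stereoKi67:::.buildGrid(100, 100, 100, 100, 100, 100, 0, 0, 1L)
  a <- auditSpot(dd, cd, g, matrix(TRUE, 100, 100))
  expect_equal(nEdits(a), 2)
  expect_equal(unname(tallies(a)["UNDETECTED_BY_NUCLEAR"]), 2L)
  k <- ki67Values(a)
  expect_equal(unname(k["dD"]), 100 * 2 / 3)
  expect_equal(unname(k["cD"]), 40)
  expect_lt(k["cD"], k["dD"])
})

test_that("every cD mark is classified exactly once (conservation)", {
  set.seed(41)
  for (rep in 1:8) {
    dd <- randomMarkSet(40, 300, 300)
    cd <- randomMarkSet(45, 300, 300, role = "cD")
    g <- generateGrid(300, 300, 120, 120, 150, 150, seed = rep)
    tissue <- matrix(runif(300 * 300) < 0.7, 300, 300)
    a <- auditSpot(dd, cd, g, tissue)
    expect_equal(sum(tallies(a)[setdiff(names(tallies(a)), "FALSE_DETECTION")]),
                 a@nCdNuclei)
    # FALSE_DETECTION records correspond one-to-one with unmatched dd marks
    ddG <- restrictToGrid(dd, g); cdG <- restrictToGrid(cd, g)
    m <- matchMarks(ddG, cdG, 5)
    expect_equal(unname(tallies(a)["FALSE_DETECTION"]), length(m$ddOnly))
  }
})

test_that("swapping dD and cD swaps adds with deletes and the label categories", {
  set.seed(17)
  for (rep in 1:5) {
    dd <- randomMarkSet(35, 250, 250)
    cd <- randomMarkSet(30, 250, 250, role = "cD")
    g <- generateGrid(250, 250, 100, 100, 120, 120, seed = rep)
    tissue <- matrix(TRUE, 250, 250)
    a <- tallies(auditSpot(dd, cd, g, tissue))
    b <- tallies(auditSpot(MarkSet("s", "dD", marks(cd)),
                           MarkSet("s", "cD", marks(dd)), g, tissue))
    expect_equal(unname(a["FALSE_DETECTION"]),
                 unname(b["UNDETECTED_BY_TISSUE_MASK"] + b["UNDETECTED_BY_NUCLEAR"]))
    expect_equal(unname(b["FALSE_DETECTION"]),
                 unname(a["UNDETECTED_BY_TISSUE_MASK"] + a["UNDETECTED_BY_NUCLEAR"]))
    expect_equal(unname(a["FALSE_POSITIVE_LABEL"]), unname(b["FALSE_NEGATIVE_LABEL"]))
    expect_equal(unname(a["FALSE_NEGATIVE_LABEL"]), unname(b["FALSE_POSITIVE_LABEL"]))
  }
})
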