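test_that("an empty mark set round-trips through a parseable document", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeAnnotations(MarkSet("s0", "dD"), path)
  doc <- readAnnotations(path)
  expect_equal(nMarks(doc$marks), 0)
  expect_null(doc$grid)
  expect_equal(length(xml2::xml_find_all(xml2::read_xml(path), "//Annotation")), 2)
})

test_that("a single mark is written as one point region in its label layer", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeAnnotations(MarkSet("s1", "dD",
                           data.frame(x = 10, y = 20, label = "POSITIVE")), path)
  doc <- xml2::read_xml(path)
  regs <- xml2::xml_find_all(doc, "//Annotation[@Name='POSITIVE']/Regions/Region")
  expect_equal(length(regs), 1)
  v <- xml2::xml_find_first(regs[[1]], "./Vertices/Vertex")
  expect_equal(as.numeric(c(xml2::xml_attr(v, "X"), xml2::xml_attr(v, "Y"))),
               c(10, 20))
  expect_equal(length(xml2::xml_find_all(
    doc, "//Annotation[@Name='NEGATIVE']/Regions/Region")), 0)
})

test_that("randomized mark sets and grids round-trip losslessly", {
  set.seed(31)
  for (rep in 1:25) {
    ms <- randomMarkSet(sample(0:40, 1), 500, 400, role = sample(c("dD", "cD"), 1),
                        spot = paste0("spot", rep))
    grid <- if (rep %% 2 == 0)
      generateGrid(500, 400, sample(40:80, 1), sample(40:80, 1),
                   sample(90:150, 1), sample(90:150, 1), seed = rep)
    else NULL
    path <- withr::local_tempfile(fileext = ".xml")
    writeAnnotations(ms, path, grid)
    back <- readAnnotations(path)
    expect_identical(marks(back$marks), marks(ms))
    expect_identical(spotId(back$marks), spotId(ms))
    expect_identical(role(back$marks), role(ms))
    if (is.null(grid)) {
      expect_null(back$grid)
    } else {
      expect_equal(frames(back$grid), frames(grid))
      for (s in c("spacingX", "spacingY", "offsetX", "offsetY",
                  "imageWidth", "imageHeight", "seed"))
        expect_equal(slot(back$grid, s), slot(grid, s))
    }
  }
})

test_that("writing is byte-stable for identical inputs", {
  set.seed(5)
  ms <- randomMarkSet(15, 300, 300)
  g <- generateGrid(300, 300, 50, 50, 100, 100, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeAnnotations(ms, p1, g)
  writeAnnotations(ms, p2, g)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("unknown layers are ignored with a warning", {
  path <- withr::local_tempfile(fileext = ".xml")
  ms <- MarkSet("s2", "cD", data.frame(x = 5, y = 6, label = "NEGATIVE"))
  writeAnnotations(ms, path)
  doc <- xml2::read_xml(path)
  extra <- xml2::xml_add_child(doc, "Annotation", Name = "SCRIBBLES")
  xml2::xml_add_child(extra, "Regions")
  xml2::write_xml(doc, path)
  expect_warning(back <- readAnnotations(path), "unknown annotation layer")
  expect_identical(marks(back$marks), marks(ms))
})

test_that("a hand-written document yields its marks in document order", {
  txt <- paste0(
    '<Annotations SpotId="hand" Role="cD">',
    '<Annotation Name="POSITIVE" Type="Marks"><Regions>',
    '<Region Type="Point"><Vertices><Vertex X="7" Y="3"/></Vertices></Region>',
    '<Region Type="Point" Provenance="EXPERT_ADDED">',
    '<Vertices><Vertex X="1" Y="2"/></Vertices></Region>',
    '</Regions></Annotation>',
    '<Annotation Name="NEGATIVE" Type="Marks"><Regions>',
    '<Region Type="Point"><Vertices><Vertex X="9" Y="9"/></Vertices></Region>',
    '</Regions></Annotation></Annotations>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, path)
  back <- readAnnotations(path)
  expect_equal(spotId(back$marks), "hand")
  expect_equal(role(back$marks), "cD")
  m <- marks(back$marks)          # canonical raster order: (1,2),(7,3),(9,9)
  expect_equal(m$x, c(1L, 7L, 9L))
  expect_equal(m$y, c(2L, 3L, 9L))
  expect_equal(m$label, c("POSITIVE", "POSITIVE", "NEGATIVE"))
  expect_equal(m$provenance, c("EXPERT_ADDED", "AUTO", "AUTO"))
})

test_that("malformed files raise parse and schema errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<Annotations><Annotation></Annotations>", bad)
  expect_error(readAnnotations(bad))
  twoVert <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<Annotations><Annotation Name="POSITIVE"><Regions><Region Type="Point">',
    '<Vertices><Vertex X="1" Y="1"/><Vertex X="2" Y="2"/></Vertices>',
    '</Region></Regions></Annotation></Annotations>'), twoVert)
  expect_error(readAnnotations(twoVert), "schema error")
})

test_that("CSV export carries one labeled row per mark", {
  ms <- MarkSet("s3", "dD",
                data.frame(x = c(1, 2), y = c(3, 4),
                           label = c("POSITIVE", "NEGATIVE")))
  path <- withr::local_tempfile(fileext = ".csv")
  writeMarksCSV(ms, path)
  back <- read.csv(path)
  expect_equal(back$spot_id, c("s3", "s3"))
  expect_equal(back$x, c(1, 2))
  expect_equal(back$label, c("POSITIVE", "NEGATIVE"))
})
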