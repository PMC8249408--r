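# Data model, validation and tabular I/O.

test_that("a small pattern constructs, counts lymphocytes, and partitions phenotypes", {
  pat <- fixture_pattern_3()
  expect_s3_class(pat, "til_pattern")
  expect_equal(nrow(pat$cells), 3)
  expect_equal(sum(is_lymphocyte(pat$cells$phenotype)), 2)
  # every cell is exactly one of lymphocyte / cancer / other
  kinds <- is_lymphocyte(pat$cells$phenotype) +
    (pat$cells$phenotype == "cancer") + (pat$cells$phenotype == "other")
  expect_true(all(kinds == 1))
})

test_that("write then read round-trips every field", {
  pat <- fixture_pattern_3(roi_area = 1.5)
  path <- file.path(tempdir(), "rt.csv")
  write_pattern_table(pat, path)
  expect_equal(length(readLines(path)), 4) # header + 3 rows
  back <- read_pattern_table(path, roi_area_mm2 = 1.5, patient_id = "fix3")
  expect_equal(back$cells$cell_id, pat$cells$cell_id)
  expect_equal(back$cells$x, pat$cells$x, tolerance = 1e-6)
  expect_equal(back$cells$y, pat$cells$y, tolerance = 1e-6)
  expect_equal(back$cells$phenotype, pat$cells$phenotype)
  expect_equal(back$cells$tissue_category, pat$cells$tissue_category)
  expect_equal(back$roi$area_mm2, pat$roi$area_mm2)
})

test_that("degenerate and malformed tables are rejected with clear errors", {
  empty <- file.path(tempdir(), "empty.csv")
  writeLines("cell_id,x_um,y_um,phenotype,tissue_category", empty)
  expect_error(read_pattern_table(empty), "empty")

  missing <- file.path(tempdir(), "missing.csv")
  writeLines(c("cell_id,x_um,phenotype,tissue_category", "a,1,B,stroma"), missing)
  expect_error(read_pattern_table(missing), "missing required column")

  badlab <- file.path(tempdir(), "bad.csv")
  writeLines(c("cell_id,x_um,y_um,phenotype,tissue_category",
               "a,1,1,Martian,stroma"), badlab)
  expect_error(read_pattern_table(badlab), "unmappable phenotype.*Martian")
})

test_that("raw marker labels are normalized through the alias tables", {
  path <- file.path(tempdir(), "alias.csv")
  writeLines(c("cell_id,x_um,y_um,phenotype,tissue_category",
               "a,1,1,CD20,Stroma",
               "b,2,2,CD3,CancerIsland",
               "c,3,3,PanCK,CancerIsland"), path)
  pat <- suppressWarnings(read_pattern_table(path, roi_area_mm2 = 1))
  expect_equal(pat$cells$phenotype, c("B", "T", "cancer"))
  expect_equal(pat$cells$tissue_category,
               c("stroma", "cancer_island", "cancer_island"))
  w <- capture_warnings(read_pattern_table(path, roi_area_mm2 = 1))
  expect_true(all(grepl("normalized", w)))
  expect_length(w, 2) # one per mark column
})

test_that("validation reports violations and warnings as specified", {
  ok <- fixture_pattern_3()
  rep <- validate_pattern(ok)
  expect_length(rep$violations, 0)
  expect_length(rep$warnings, 0)

  bad <- ok
  bad$cells$tissue_category[1] <- "Unknown"
  expect_true(any(grepl("tissue category", validate_pattern(bad)$violations)))

  dup <- ok
  dup$cells$x <- c(5, 5, 9); dup$cells$y <- c(5, 5, 9)
  rep <- validate_pattern(dup)
  expect_length(rep$violations, 0)
  expect_true(any(grepl("duplicate coordinates", rep$warnings)))

  dupid <- ok
  dupid$cells$cell_id <- c("a", "a", "c")
  expect_true(any(grepl("cell_id", validate_pattern(dupid)$violations)))
})

test_that("missing ROI area falls back to the cell bounding box, flagged", {
  path <- file.path(tempdir(), "noroi.csv")
  writeLines(c("cell_id,x_um,y_um,phenotype,tissue_category",
               "a,0,0,B,stroma", "b,1000,0,B,stroma",
               "c,0,500,B,stroma", "d,1000,500,B,stroma"), path)
  pat <- read_pattern_table(path)
  expect_equal(pat$roi$area_mm2, 0.5)
  expect_true(any(grepl("bounding box", validate_pattern(pat)$warnings)))
})

test_that("polygon geometry: shoelace area, containment, sidecar round trip", {
  tri <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  expect_equal(polygon_area(tri), 5e5)
  expect_true(point_in_polygon(100, 100, tri))
  expect_true(point_in_polygon(0, 0, tri))      # vertex counts as inside
  expect_false(point_in_polygon(900, 900, tri))

  # ROI whose declared area disagrees with its polygon by > 0.1 percent
  expect_error(roi(area_mm2 = 0.6, boundary = tri), "disagrees")
  r <- roi(boundary = tri)
  expect_equal(r$area_mm2, 0.5)

  cells <- data.frame(cell_id = c("a", "b"), x = c(100, 200), y = c(100, 100),
                      phenotype = "B", tissue_category = "stroma")
  pat <- til_pattern(cells, r)
  path <- file.path(tempdir(), "poly.csv")
  write_pattern_table(pat, path)
  sidecar <- file.path(tempdir(), "poly.roi.geojson")
  expect_true(file.exists(sidecar))
  back <- read_pattern_table(path)
  expect_equal(back$roi$area_mm2, 0.5, tolerance = 1e-9)
  expect_equal(nrow(back$roi$boundary), 3)

  # a cell outside the polygon is a violation
  out <- til_pattern(data.frame(cell_id = "z", x = 990, y = 990,
                                phenotype = "B", tissue_category = "stroma"),
                     r, validate = FALSE)
  expect_true(any(grepl("outside", validate_pattern(out)$violations)))
})

test_that("deposited ppp-style lists convert to readable per-patient tables", {
  # synthetic stand-in built structurally like a ppp: $x, $y, $marks, $window
  ppp <- list(
    x = c(10, 20, 30), y = c(10, 20, 30),
    marks = data.frame(Phenotype = c("CD20", "CD3", "PanCK"),
                       Tissue.Category = c("Stroma", "Stroma", "CancerIsland")),
    window = list(type = "rectangle", xrange = c(0, 1000), yrange = c(0, 1000))
  )
  rds <- file.path(tempdir(), "pats.rds")
  saveRDS(list(p1 = ppp), rds)
  out_dir <- file.path(tempdir(), "converted")
  paths <- suppressWarnings(read_deposited_patterns(rds, out_dir))
  expect_true(file.exists(paths[1]))
  pat <- read_pattern_table(paths[1], roi_area_mm2 = 1)
  expect_equal(pat$cells$phenotype, c("B", "T", "cancer"))
})
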