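test_that("surface_model validates points, labels and side", {
  p <- matrix(rnorm(30), 10, 3)
  m <- surface_model(p, "left", labels = list(head = 1:6))
  expect_s3_class(m, "surface_model")
  expect_equal(nrow(region_points(m, "head")), 6L)

  expect_error(surface_model(p, "up"), class = "hipcongruity_validation_error")
  expect_error(surface_model(p, "left", labels = list(head = c(1, 11))),
               class = "hipcongruity_validation_error")
  expect_error(surface_model(p, "left", labels = list(head = integer(0))),
               class = "hipcongruity_validation_error")
  p[1, 1] <- NA
  expect_error(surface_model(p, "left"),
               class = "hipcongruity_validation_error")
})

test_that("a minimal ascii STL triangle reads as 3 points", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0",
               "      vertex 0 1 0", "    endloop", "  endfacet",
               "endsolid t"), path)
  m <- read_surface(path, side = "right")
  expect_equal(nrow(m$points), 3L)
  expect_equal(m$points[2, ], c(1, 0, 0))
})

test_that("duplicate vertices are merged and sidecar labels remapped", {
  # two facets sharing an edge: 6 file vertices, 4 unique points
  path <- withr::local_tempfile(fileext = ".stl")
  v <- function(x, y, z) sprintf("      vertex %g %g %g", x, y, z)
  writeLines(c("solid t",
               "  facet normal 0 0 1", "    outer loop",
               v(0, 0, 0), v(1, 0, 0), v(0, 1, 0),
               "    endloop", "  endfacet",
               "  facet normal 0 0 1", "    outer loop",
               v(1, 0, 0), v(1, 1, 0), v(0, 1, 0),
               "    endloop", "  endfacet",
               "endsolid t"), path)
  lab <- withr::local_tempfile(fileext = ".json")
  # 0-based indices into the file's vertex stream, both copies of (1,0,0)
  jsonlite::write_json(list(head = c(1L, 3L, 4L)), lab)
  m <- read_surface(path, labels_path = lab, side = "right")
  expect_equal(nrow(m$points), 4L)
  expect_equal(length(m$labels$head), 2L)  # (1,0,0) deduplicated
  expect_error(
    {
      jsonlite::write_json(list(head = 99L), lab)
      read_surface(path, labels_path = lab, side = "right")
    },
    class = "hipcongruity_validation_error")
})

test_that("write/read round-trips preserve points and labels across formats", {
  withr::local_seed(42)
  pts <- matrix(runif(300, -30, 30), 100, 3)
  m <- surface_model(pts, "left", labels = list(head = 1:60, neck = 61:80))
  for (ext in c(".ply", ".obj", ".stl")) {
    path <- withr::local_tempfile(fileext = ext)
    lab <- withr::local_tempfile(fileext = ".json")
    write_surface(m, path, lab)
    m2 <- read_surface(path, labels_path = lab, side = "left")
    expect_lt(max(abs(m2$points - m$points)), 1e-6)
    expect_equal(m2$labels, m$labels)
  }
})

test_that("binary PLY and binary STL vertices are read", {
  # binary little-endian PLY written by hand
  path <- withr::local_tempfile(fileext = ".ply")
  pts <- matrix(c(1.5, -2, 3, 4, 5.25, -6), 2, 3, byrow = TRUE)
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 2", "property float x", "property float y",
               "property float z", "end_header"), con)
  writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  close(con)
  m <- read_surface(path, side = "right")
  expect_equal(m$points, pts, tolerance = 1e-6)

  # binary STL: 80-byte header, count, one 50-byte facet
  path2 <- withr::local_tempfile(fileext = ".stl")
  con <- file(path2, "wb")
  writeBin(raw(80), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(0, 0, 1, 0, 0, 0, 2, 0, 0, 0, 3, 0), con, size = 4,
           endian = "little")
  writeBin(raw(2), con)
  close(con)
  m2 <- read_surface(path2, side = "right")
  expect_equal(nrow(m2$points), 3L)
  expect_equal(m2$points[3, ], c(0, 3, 0), tolerance = 1e-6)
})

test_that("result records round-trip through JSON, cohort table has one row per hip", {
  hip <- demo_hip(seed = 2)
  rec <- fit_hip(hip$femur, hip$coxal, id = "rt")
  path <- withr::local_tempfile(fileext = ".json")
  write_results(rec, path)
  rec2 <- read_results(path)
  expect_equal(rec2$head_fit$center, rec$head_fit$center, tolerance = 1e-12)
  expect_equal(rec2$indices$mismatch_ratio, rec$indices$mismatch_ratio,
               tolerance = 1e-12)
  expect_equal(rec2$indices$cd_unit, as.numeric(rec$indices$cd_unit),
               tolerance = 1e-12)
  expect_equal(rec2$excluded, rec$excluded)
  expect_equal(rec2$params$step, rec$params$step)

  tbl <- cohort_table(list(rec, rec, rec), group = c("a", "a", "b"))
  expect_equal(nrow(tbl), 3L)
  expect_named(tbl, c("id", "side", "group", "rf", "ra", "head_sd",
                      "acet_sd", "ratio", "cd_distance", "cd_ml", "cd_pa",
                      "cd_si", "aspherical", "excluded"))
})

test_that("aspherical warning survives serialization", {
  hip <- generate_hip(synthetic_hip_spec(noise_sigma = 0,
                                         cam = c(17.5, 0, 30, 4), seed = 3))
  rec <- fit_hip(hip$femur, hip$coxal, id = "cam")
  expect_true(rec$excluded)
  path <- withr::local_tempfile(fileext = ".json")
  write_results(rec, path)
  rec2 <- read_results(path)
  expect_true(rec2$excluded)
  expect_true(any(grepl("aspherical", rec2$warnings)))
})
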