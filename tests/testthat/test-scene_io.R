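test_that("raster write/read round-trips values, mask and grid exactly", {
  grid <- grid_spec(10, 8, pixel_size = 30, xll = 1000, yll = 2000)
  set.seed(1)
  field <- matrix(rnorm(80), 8, 10)
  field[c(3, 17, 55)] <- NA
  path <- file.path(tempdir(), "rt.asc")
  write_raster(field, grid, path, units = "mm/day")
  back <- read_raster(path)
  expect_identical(back$field, field)
  expect_identical(sum(is.na(back$field)), 3L)
  expect_true(grids_identical <- mptet:::grids_identical(grid, back$grid))
  expect_equal(back$units, "mm/day")
  unlink(c(path, paste0(path, ".json")))
})

test_that("constant rasters round-trip and unwritable paths error", {
  grid <- grid_spec(10, 10)
  field <- matrix(2, 10, 10)
  path <- file.path(tempdir(), "const.asc")
  write_raster(field, grid, path)
  expect_identical(read_raster(path)$field, field)
  expect_error(write_raster(field, grid, "/no/such/dir/x.asc"),
               "cannot open")
  unlink(c(path, paste0(path, ".json")))
})

test_that("MTL parsing yields metadata; missing keys are named errors", {
  mtl_path <- file.path(tempdir(), "MTL.txt")
  writeLines(c(
    "GROUP = LANDSAT_METADATA_FILE",
    "  DATE_ACQUIRED = 2022-12-17",
    '  SCENE_CENTER_TIME = "05:12:30.000000Z"',
    "  SUN_ELEVATION = 45.0",
    "END_GROUP = LANDSAT_METADATA_FILE"
  ), mtl_path)
  mtl <- read_mtl(mtl_path)
  expect_equal(mtl$SUN_ELEVATION, 45.0)
  expect_equal(mtl$DATE_ACQUIRED, "2022-12-17")

  grid <- grid_spec(4, 4)
  paths <- character(0)
  for (b in paste0("rho", 2:7)) {
    p <- file.path(tempdir(), paste0(b, "_t.asc"))
    write_raster(matrix(0.2, 4, 4), grid, p)
    paths[b] <- p
  }
  lst <- file.path(tempdir(), "lst_t.asc")
  write_raster(matrix(300, 4, 4), grid, lst)

  sc <- read_landsat_scene(paths, mtl_path, lst)
  expect_equal(sc$meta$sun_elevation_deg, 45)
  expect_equal(sc$meta$doy, 351)  # 17 Dec of a non-leap year
  expect_equal(sc$meta$overpass_time, 5 + 12 / 60 + 30 / 3600)

  # drop SUN_ELEVATION -> error naming the key
  writeLines(c("DATE_ACQUIRED = 2022-12-17",
               'SCENE_CENTER_TIME = "05:12:30Z"'), mtl_path)
  expect_error(read_landsat_scene(paths, mtl_path, lst), "SUN_ELEVATION")
  unlink(c(paths, lst, mtl_path, paste0(c(paths, lst), ".json")))
})

test_that("grid mismatch between rasters is an error naming both files", {
  mtl_path <- file.path(tempdir(), "MTL2.txt")
  writeLines(c("DATE_ACQUIRED = 2023-03-15",
               'SCENE_CENTER_TIME = "05:00:00Z"',
               "SUN_ELEVATION = 50.0"), mtl_path)
  grid <- grid_spec(4, 4)
  shifted <- grid_spec(4, 4, xll = 30)  # one-pixel shift
  paths <- character(0)
  for (b in paste0("rho", 2:7)) {
    p <- file.path(tempdir(), paste0(b, "_g.asc"))
    write_raster(matrix(0.2, 4, 4), if (b == "rho3") shifted else grid, p)
    paths[b] <- p
  }
  lst <- file.path(tempdir(), "lst_g.asc")
  write_raster(matrix(300, 4, 4), grid, lst)
  err <- expect_error(read_landsat_scene(paths, mtl_path, lst),
                      "grid mismatch")
  expect_match(conditionMessage(err), "rho3_g")
  unlink(c(paths, lst, mtl_path, paste0(c(paths, lst), ".json")))
})

test_that("MTL reflectance scale/offset keys rescale band values", {
  mtl_path <- file.path(tempdir(), "MTL3.txt")
  lines <- c("DATE_ACQUIRED = 2023-03-15",
             'SCENE_CENTER_TIME = "05:00:00Z"',
             "SUN_ELEVATION = 50.0",
             sprintf("REFLECTANCE_MULT_BAND_%d = 2.75e-05", 2:7),
             sprintf("REFLECTANCE_ADD_BAND_%d = -0.2", 2:7))
  writeLines(lines, mtl_path)
  grid <- grid_spec(3, 3)
  paths <- character(0)
  for (b in paste0("rho", 2:7)) {
    p <- file.path(tempdir(), paste0(b, "_s.asc"))
    write_raster(matrix(10000, 3, 3), grid, p)  # digital numbers
    paths[b] <- p
  }
  lst <- file.path(tempdir(), "lst_s.asc")
  write_raster(matrix(300, 3, 3), grid, lst)
  sc <- read_landsat_scene(paths, mtl_path, lst)
  expect_equal(sc$reflectance$rho5[1, 1], 10000 * 2.75e-05 - 0.2)
  unlink(c(paths, lst, mtl_path, paste0(c(paths, lst), ".json")))
})

test_that("scene_summary masks, reports sample SD and rejects empties", {
  f <- matrix(c(1, 2, 3, 4), 2, 2)
  s <- scene_summary(f)
  expect_equal(s$mean, 2.5)
  expect_equal(s$max, 4)
  expect_equal(s$sd, sd(1:4))
  expect_equal(s$n_valid, 4L)

  s2 <- scene_summary(f, mask = f < 4)
  expect_equal(s2$max, 3)
  expect_equal(s2$n_valid, 3L)

  expect_equal(scene_summary(matrix(2, 3, 3))$sd, 0)
  expect_error(scene_summary(matrix(NA_real_, 2, 2)), "no valid pixels")
})

test_that("summary mean of any raster lies within its valid range", {
  set.seed(9)
  for (i in 1:20) {
    f <- matrix(rnorm(100, sd = 10), 10, 10)
    f[sample(100, 10)] <- NA
    s <- scene_summary(f)
    expect_gte(s$mean, min(f, na.rm = TRUE))
    expect_lte(s$mean, max(f, na.rm = TRUE))
  }
})
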