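test_that("mpt fit exposes the model through the standard S3 surface", {
  x <- make_test_fit(n = 80, seed = 42)
  fit <- x$fit
  expect_s3_class(fit, "mpt")
  expect_output(print(fit), "dry edge")
  co <- coef(fit)
  expect_named(co, c("dry_intercept", "dry_slope", "t_min"))
  expect_lt(co[["dry_slope"]], 0)

  sm <- summary(fit)
  expect_s3_class(sm, "summary.mpt")
  expect_true(all(c("et_d", "rn", "phi") %in% sm$table$field))
  expect_output(print(sm), "et_d")

  r <- residuals(fit)
  expect_true(is.numeric(r) && length(r) == nrow(fit$edges$bins))

  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("predict evaluates the fitted interpolation at new pixels", {
  x <- make_test_fit(n = 80, seed = 42)
  fit <- x$fit
  # the wet edge predicts the ceiling coefficient
  expect_equal(predict(fit, ts_K = fit$edges$t_min, fr = 0.5), 1.26)
  phi <- predict(fit, ts_K = c(300, 310), fr = c(0.5, 0.2))
  expect_true(all(phi >= 0 & phi <= 1.26))
  ef <- predict(fit, ts_K = 300, fr = 0.5, type = "ef")
  d <- fit$atmosphere$delta_kPa_per_C; g <- fit$atmosphere$gamma_kPa_per_C
  expect_equal(ef, predict(fit, ts_K = 300, fr = 0.5) * d / (d + g))
  expect_gt(predict(fit, ts_K = 298, fr = 0.5, type = "et_d"), 0)
})

test_that("fitted fields satisfy the energy-balance orderings", {
  x <- make_test_fit(n = 100, seed = 7)
  f <- x$fit$fields
  ok <- is.finite(f$le) & is.finite(f$rn) & is.finite(f$g)
  avail <- (f$rn - f$g)[ok]
  expect_true(all(f$le[ok] <= 1.26 * pmax(avail, 0) + 1e-9))
  ratio <- attr(f$g, "ratio")
  expect_true(all(ratio[is.finite(ratio)] >= 0 &
                    ratio[is.finite(ratio)] <= 0.5))
  # EF equals phi * Delta/(Delta+gamma) wherever defined
  d <- x$fit$atmosphere$delta_kPa_per_C
  g <- x$fit$atmosphere$gamma_kPa_per_C
  okf <- is.finite(f$ef)
  expect_lt(max(abs(f$ef[okf] - f$phi[okf] * d / (d + g))), 1e-12)
})

test_that("moving a pixel toward the wet edge never lowers daily ET", {
  x <- make_test_fit(n = 80, seed = 11)
  fit <- x$fit
  fr0 <- 0.4
  ts_seq <- seq(fit$edges$t_min,
                fit$edges$dry_intercept + fit$edges$dry_slope * fr0,
                length.out = 40)
  et <- predict(fit, ts_K = ts_seq, fr = rep(fr0, 40), type = "et_d")
  expect_true(all(diff(et) <= 1e-9))
})

test_that("aoi mask excludes pixels from every derived field", {
  syn <- generate_triangle_scene(triangle_params(n_rows = 60,
                                                 n_cols = 60, seed = 2))
  mask <- matrix(TRUE, 60, 60); mask[1:10, ] <- FALSE
  scene <- mpt_scene(syn$scene$grid, syn$scene$meta,
                     syn$scene$reflectance, syn$scene$ts_K,
                     aoi_mask = mask)
  met <- meteo_snapshot(ta_K = 298, pair_kPa = 101, ea_kPa = 1.5)
  fit <- mpt(scene, met, latitude = 29,
             control = mpt_control(ndvi_bounds = c(0.1, 0.9)))
  expect_true(all(is.na(fit$fields$et_d[1:10, ])))
  expect_true(all(is.finite(fit$fields$et_d[11:60, ])))
})

test_that("run_scene writes rasters, edge sidecar, summary and manifest", {
  syn <- generate_triangle_scene(triangle_params(n_rows = 60,
                                                 n_cols = 60, seed = 15))
  indir <- file.path(tempdir(), "run_in")
  outdir <- file.path(tempdir(), "run_out")
  paths <- write_scene(syn$scene, indir)
  config <- list(bands = as.list(paths$band_paths),
                 mtl = paths$mtl_path, lst = paths$lst_path,
                 ta_K = 298, pair_kPa = 101, ea_kPa = 1.5,
                 latitude = 29, outdir = outdir,
                 ndvi_bounds = c(0.1, 0.9))
  man <- run_scene(config)
  expect_length(man$rasters, 7)
  for (f in c("albedo", "rn", "g", "phi", "le", "ef", "et_d"))
    expect_true(file.exists(file.path(outdir, paste0(f, ".asc"))))
  edges <- jsonlite::read_json(file.path(outdir, "edges.json"))
  expect_lt(edges$dry_slope, 0)
  sm <- read.csv(file.path(outdir, "summary.csv"))
  expect_true(all(c("date", "field", "mean", "max", "sd", "n_valid")
                  %in% names(sm)))
  # re-run is reproducible
  et1 <- read_raster(file.path(outdir, "et_d.asc"))$field
  run_scene(config)
  et2 <- read_raster(file.path(outdir, "et_d.asc"))$field
  expect_identical(et1, et2)
  # units tag on the daily ET raster
  expect_equal(read_raster(file.path(outdir, "et_d.asc"))$units,
               "mm/day")
  # validation errors name the missing field
  expect_error(run_scene(config[setdiff(names(config), "lst")]), "lst")
  unlink(c(indir, outdir), recursive = TRUE)
})

test_that("run_validate reports the five statistics from a paired CSV", {
  pairs <- generate_validation_pairs(n = 8, bias = 0, noise_sd = 0.2,
                                     seed = 5)
  path <- file.path(tempdir(), "pairs.csv")
  write.csv(pairs, path, row.names = FALSE)
  out <- file.path(tempdir(), "report.json")
  rep <- run_validate(path, out = out)
  expect_equal(rep$n, 8L)
  js <- jsonlite::read_json(out)
  expect_equal(js$n, 8L)
  expect_equal(js$rmse, rep$rmse, tolerance = 1e-12)

  # identical columns give a perfect report
  pairs$predicted_mm_day <- pairs$observed_mm_day
  write.csv(pairs, path, row.names = FALSE)
  expect_equal(run_validate(path)$r2, 1)

  writeLines("date,observed_mm_day,predicted_mm_day", path)
  expect_error(run_validate(path), "at least 2")
  writeLines("", path)
  expect_error(run_validate(path), "")
  unlink(c(path, out))
})
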