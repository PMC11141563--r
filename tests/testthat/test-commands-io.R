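test_that("measurement tables round-trip through CSV", {
  sol <- make_solid("frustum", r0 = 0.4, r1 = 0.2, L = 1)
  st <- slice_stations(seq(0, 1, 0.25), 5)
  sec <- sol$section(st$station)
  tab <- data.frame(station = st$station, d = sec$d,
                    S = ifelse(st$is_boundary, sec$S, NA),
                    C = ifelse(st$is_boundary, sec$C, NA),
                    label = ifelse(st$is_boundary, "boundary", ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(back$station, tab$station)
  expect_equal(back$d, tab$d)
  expect_equal(back$S, tab$S)
  # and a second write is byte-identical (determinism)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("csm_estimate runs all three methods on consistent inputs", {
  r <- 0.3; L <- 1
  cyl <- make_solid("cylinder", r = r, L = L)
  body <- sample_measurements(cyl, seq(0, 1, 0.25), 5)
  est <- csm_estimate(body, "csm")
  expect_equal(est$volume, pi * r^2 * L, tolerance = 1e-12)
  est_d <- csm_estimate(body, "csm", density = density_model(1000))
  expect_equal(est_d$mass, 1000 * pi * r^2 * L, tolerance = 1e-12)
  expect_equal(est_d$cm_station, 0.5, tolerance = 1e-12)
  expect_equal(nrow(est_d$slab_table), 4)

  prof <- solid_profile(cyl, 61)
  g <- csm_estimate(prof, "gdi")
  expect_equal(g$n_slabs, 120)  # the conventional default slicing
  expect_equal(g$volume, pi * r^2 * L, tolerance = 1e-12)
  se <- csm_estimate(prof, "superellipse", k_range = c(2, 2.3))
  expect_equal(se$volume_low, pi * r^2 * L, tolerance = 1e-12)
  # method/input mismatch: comparators need a two-view profile
  expect_error(csm_estimate(data.frame(station = 1, d = 1, S = 1, C = 4),
                            "superellipse"), "two-view profile")
})

test_that("the packaged worked example yields a plausible dolphin mass", {
  csv <- system.file("extdata", "dolphin_synthetic.csv", package = "crossvol")
  cfg <- read_run_config(system.file("extdata", "dolphin_synthetic.yaml",
                                     package = "crossvol"))
  est <- csm_estimate(csv, "csm", density = crossvol:::config_density(cfg$density),
                      boundary_stations = cfg$slab_bounds)
  expect_equal(length(cfg$slab_bounds), 13)   # 12 unequal slabs
  expect_gt(min(diff(cfg$slab_bounds)), 0)
  expect_gt(length(unique(round(diff(cfg$slab_bounds), 6))), 1)  # unequal
  expect_equal(est$mass, est$volume * 1027, tolerance = 1e-12)
  expect_gt(est$mass, 250); expect_lt(est$mass, 400)
  cm_frac <- est$cm_station / max(cfg$slab_bounds)
  expect_gt(cm_frac, 0.35); expect_lt(cm_frac, 0.55)
})

test_that("csm_measure writes a CSV matching analytic values within 1%", {
  sol <- make_solid("frustum", r0 = 0.3, r1 = 0.12, L = 1)
  bounds <- seq(0, 1, length.out = 5)
  masks <- render_masks(sol, stations = bounds, width = 1200, height = 900,
                        section_px = 900)
  td <- withr::local_tempdir()
  sil_png <- file.path(td, "sil.png")
  png::writePNG(masks$silhouette$pixels * 1.0, sil_png)
  sec_pngs <- vapply(seq_along(masks$sections), function(i) {
    p <- file.path(td, sprintf("sec%d.png", i))
    png::writePNG(masks$sections[[i]]$pixels * 1.0, p)
    p
  }, character(1))
  out <- file.path(td, "meas.csv")
  tab <- csm_measure(sil_png, sec_pngs, scale = masks$scale,
                     slab_bounds = bounds, n_subslabs = 5, out = out)
  expect_true(file.exists(out))
  bidx <- which(tab$label == "boundary")
  sec <- sol$section(tab$station[bidx])
  expect_lt(max(abs(tab$d[bidx] / sec$d - 1)), 0.01)
  expect_lt(max(abs(tab$S[bidx] / sec$S - 1)), 0.01)
  expect_lt(max(abs(tab$C[bidx] / sec$C - 1)), 0.01)
  # rerun is byte-identical
  out2 <- file.path(td, "meas2.csv")
  csm_measure(sil_png, sec_pngs, scale = masks$scale,
              slab_bounds = bounds, n_subslabs = 5, out = out2)
  expect_identical(readLines(out), readLines(out2))
  expect_error(csm_measure(sil_png, sec_pngs, scale = NULL,
                           slab_bounds = bounds, n_subslabs = 5), "scale")
})

test_that("csm_validate tabulates signed errors with a consistent Mean row", {
  suite <- standard_fixture_suite()[c("cylinder", "cone", "loft_k16")]
  tab <- csm_validate(suite, digits = 4)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$model[4], "Mean")
  # Mean row equals mean_error of each column (computed before rounding,
  # so compare at the table's own precision)
  for (col in c("volume_csm", "volume_gdi", "area_csm")) {
    expect_equal(tab[[col]][4], round(mean_error(tab[[col]][1:3]), 4),
                 tolerance = 2e-4)
  }
  # sign convention: GDI overestimates the k = 1.6 loft volume
  expect_gt(tab$volume_gdi[3], 9)
  expect_lt(abs(tab$volume_csm[3]), 0.01)
  # reruns are identical (no hidden randomness)
  expect_identical(tab, csm_validate(suite, digits = 4))
})

test_that("run configs parse and validate", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("slab_bounds: [0, 0.5, 1]", "n_subslabs: 10",
               "k_range: [1.6, 2.4]", "density:", "  default: 1000"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$slab_bounds, c(0, 0.5, 1))
  expect_s3_class(crossvol:::config_density(cfg$density), "density_model")
  writeLines("k_range: [2.4, 1.6]", path)
  expect_error(read_run_config(path))
})

test_that("reports serialise to JSON and CSV", {
  body <- sample_measurements(make_solid("cylinder", r = 0.3, L = 1),
                              seq(0, 1, 0.5), 5)
  rep <- csm_estimate(body, "csm", density = density_model(1000))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report(rep, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(back$mass, rep$mass)
  expect_equal(nrow(back$slab_table), 2)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, cpath, format = "csv")
  expect_equal(nrow(utils::read.csv(cpath)), 2)
})
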