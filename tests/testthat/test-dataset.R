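test_that("a small records/patches fixture parses into a validated dataset", {
  td <- withr::local_tempdir()
  patches <- two_patch_network()
  pat_path <- file.path(td, "patches.geojson")
  write_patches(patches, pat_path)
  rec_path <- file.path(td, "records.csv")
  writeLines(c("individual_id,date,sex,patch_id,lon,lat",
               "i1,2014-07-19,F,P1,19.8005,46.1004",
               "i2,2014-07-19,M,P1,19.8006,46.1005",
               "i1,2014-07-21,F,P1,19.8004,46.1003"), rec_path)
  ds <- read_dataset(rec_path, pat_path)
  expect_s3_class(ds, "mrr_dataset")
  expect_equal(nrow(ds$records), 3L)
  expect_equal(length(ds$calendar$dates), 2L)
  expect_equal(ds$calendar$intervals, 2L)
  expect_equal(sort(unique(ds$records$occasion)), c(0L, 1L))
  expect_equal(ds$patches$area_m2, rep(1e4, 2), tolerance = 0.005)
})

test_that("schema and referential errors are caught by name", {
  td <- withr::local_tempdir()
  pat_path <- file.path(td, "patches.geojson")
  write_patches(two_patch_network(), pat_path)
  rec_path <- file.path(td, "bad.csv")
  writeLines(c("individual_id,date,sex,lon,lat",
               "i1,2014-07-19,F,19.8,46.1"), rec_path)
  expect_error(read_dataset(rec_path, pat_path), "patch_id")
  writeLines(c("individual_id,date,sex,patch_id,lon,lat",
               "i1,2014-07-19,F,NOPE,19.8,46.1"), rec_path)
  expect_error(read_dataset(rec_path, pat_path), "NOPE")
})

test_that("duplicate individual-by-occasion captures are rejected", {
  caps <- data.frame(id = c("i1", "i1"), day = c(1, 1), sex = "F",
                     patch = "P1", stringsAsFactors = FALSE)
  expect_error(toy_dataset(caps), "duplicate")
})

test_that("self-intersecting polygons are rejected", {
  td <- withr::local_tempdir()
  bow <- two_patch_network()
  bow$ring[[1]] <- bow$ring[[1]][c(1, 3, 2, 4, 1), ]  # bow-tie
  path <- file.path(td, "bad.geojson")
  write_patches(bow, path)
  expect_error(read_patches(path), "invalid polygon")
})

test_that("computed area of a 100 m square is 10,000 m2 within 0.5%", {
  ring <- square_ring(19.713, 46.169, 100)
  expect_equal(polygon_area_m2(ring), 1e4, tolerance = 0.005)
})

test_that("regime assignment follows the 15-day reflowering rule", {
  fs <- as.Date("2014-07-19")
  expect_identical(assign_regime(fs - 20, fs), "recovered")
  expect_identical(assign_regime(fs - 15, fs), "recovered")
  expect_identical(assign_regime(fs - 5, fs), "mown")
  expect_identical(assign_regime(NA, fs), "unmown")
  expect_identical(assign_regime(NULL, fs), "unmown")
  expect_error(assign_regime(fs + 60, fs, flight_end = fs + 40), "after")
  # total over a sweep of dates
  for (off in -40:0)
    expect_true(assign_regime(fs + off, fs) %in% c("recovered", "mown"))
})

test_that("validation flags GPS drift, calendar gaps and sex conflicts", {
  patches <- two_patch_network()
  caps <- data.frame(id = c("i1", "i1", "i2", "i2"), day = c(1, 3, 1, 3),
                     sex = c("F", "F", "M", "M"),
                     patch = c("P1", "P1", "P1", "P1"),
                     stringsAsFactors = FALSE)
  ds <- toy_dataset(caps, patches)
  expect_true(validate_dataset(ds)$clean)

  # displace one point ~50 m south of P1's SW corner
  drift <- caps
  ds2 <- toy_dataset(drift, patches)
  ds2$records$lat[1] <- 46.10 - 50 / M_PER_DEG_LAT
  ds2$records$lon[1] <- 19.80
  rep10 <- validate_dataset(ds2, tolerance_m = 10)
  expect_equal(nrow(rep10$outside_patch), 1L)
  expect_gt(rep10$outside_patch$distance_m, 40)
  expect_true(validate_dataset(ds2, tolerance_m = 60)$clean)

  # sex inconsistency
  ds3 <- toy_dataset(caps, patches)
  ds3$records$sex[2] <- "M"
  expect_equal(unique(validate_dataset(ds3)$sex_conflicts$individual_id), "i1")

  # oversized calendar gap
  gap <- data.frame(id = c("i1", "i1"), day = c(1, 9), sex = "F",
                    patch = "P1", stringsAsFactors = FALSE)
  ds4 <- toy_dataset(gap, patches)
  expect_equal(nrow(validate_dataset(ds4)$calendar_gaps), 1L)
})

test_that("read-write round trip is byte-identical for canonical files", {
  td <- withr::local_tempdir()
  sim <- simulate_mrr(small_sim_config(), seed = 17)
  p1 <- file.path(td, "r1.csv"); g1 <- file.path(td, "p1.geojson")
  write_dataset(sim$dataset, p1, g1)
  ds <- read_dataset(p1, g1)
  p2 <- file.path(td, "r2.csv"); g2 <- file.path(td, "p2.geojson")
  write_dataset(ds, p2, g2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(g1), readLines(g2))
})
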