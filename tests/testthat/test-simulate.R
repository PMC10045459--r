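test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_sim_config()
  s1 <- simulate_mrr(cfg, seed = 10)
  s2 <- simulate_mrr(cfg, seed = 10)
  expect_identical(s1$dataset$records, s2$dataset$records)
  expect_identical(s1$truth$ever_alive_by_patch, s2$truth$ever_alive_by_patch)
  td <- withr::local_tempdir()
  write_patches(generate_patches(cfg, seed = 10), file.path(td, "a.geojson"))
  write_patches(generate_patches(cfg, seed = 10), file.path(td, "b.geojson"))
  expect_identical(readLines(file.path(td, "a.geojson")),
                   readLines(file.path(td, "b.geojson")))
  expect_false(identical(
    simulate_mrr(cfg, seed = 11)$dataset$records, s1$dataset$records))
})

test_that("patch networks match the configured geometry", {
  cfg <- sim_config()
  meds <- sapply(1:20, function(s) median(generate_patches(cfg, s)$area_m2))
  expect_lt(abs(median(meds) - 9000) / 9000, 0.2)

  p <- generate_patches(cfg, seed = 2)
  expect_equal(nrow(p), cfg$n_patches)
  expect_equal(length(unique(p$locality)), cfg$n_localities)
  # regime proportions within multinomial error of the configuration
  obs <- table(factor(p$regime, levels = names(cfg$regime_probs)))
  expected <- cfg$regime_probs * cfg$n_patches
  se <- sqrt(cfg$n_patches * cfg$regime_probs * (1 - cfg$regime_probs))
  expect_true(all(abs(obs - expected) <= 3 * se + 3))
  # patches do not overlap (bounding boxes separated)
  for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
    sep <- p$xmin[i] >= p$xmax[j] || p$xmax[i] <= p$xmin[j] ||
      p$ymin[i] >= p$ymax[j] || p$ymax[i] <= p$ymin[j]
    expect_true(sep)
  }
})

test_that("perfect detection captures every alive individual every session", {
  cfg <- small_sim_config(p = 1, gap_prob = 0, n_emerge = 150L,
                          season_days = 12L)
  sim <- simulate_mrr(cfg, seed = 6)
  rec <- sim$dataset$records
  expect_equal(length(unique(rec$individual_id)), sim$truth$n_emerged)
  # with p = 1 each individual is seen on every day from emergence to death:
  # capture dates are consecutive calendar days
  spans <- tapply(as.integer(rec$date), rec$individual_id,
                  function(d) all(diff(sort(d)) == 1))
  expect_true(all(spans))

  # day-to-day persistence equals daily survival within Monte-Carlo error
  caps <- table(factor(rec$individual_id), factor(as.integer(rec$date)))
  present <- caps[, -ncol(caps), drop = FALSE] > 0
  nxt <- caps[, -1, drop = FALSE] > 0
  n_atrisk <- sum(present)
  phi_hat <- sum(present & nxt) / n_atrisk
  se <- sqrt(cfg$phi * (1 - cfg$phi) / n_atrisk)
  expect_lt(abs(phi_hat - cfg$phi), 3 * se)
})

test_that("the emigration-hazard calibration inverts the observation model", {
  occ <- rep(TRUE, 41)
  w <- rep(1, 41)
  f <- function(h) expected_emigrant_fraction(h, 0.79, 0.32, occ, w)
  # monotone increasing in the hazard
  hs <- seq(0.01, 0.3, length.out = 10)
  expect_true(all(diff(sapply(hs, f)) > 0))
  for (target in c(0.09, 0.16, 0.22)) {
    h <- calibrate_emigration_hazard(target, 0.79, 0.32, occ, w)
    expect_equal(f(h), target, tolerance = 1e-8)
  }
  # naive lifetime conversion would understate the observed fraction
  h_naive <- 1 - (1 - 0.22)^(1 - 0.79)
  expect_lt(f(h_naive), 0.19)
})

test_that("event-level simulators hit their kernel means and are reproducible", {
  cfg <- sim_config()
  ev <- simulate_dispersal_events(2000, cfg, seed = 3)
  expect_identical(ev, simulate_dispersal_events(2000, cfg, seed = 3))
  m <- tapply(ev$distance_m, ev$regime, mean)
  for (r in names(cfg$dispersal_mean_m))
    expect_lt(abs(m[[r]] - cfg$dispersal_mean_m[[r]]) /
                cfg$dispersal_mean_m[[r]], 0.12)
  ev2 <- simulate_displacement_events(3000, cfg, seed = 4)
  m2 <- tapply(ev2$distance_m, ev2$sex, mean)
  for (s in c("F", "M"))
    expect_lt(abs(m2[[s]] - cfg$displacement_mean_m[[s]]) /
                cfg$displacement_mean_m[[s]], 0.12)
})

test_that("records always lie inside their declared patches", {
  sim <- simulate_mrr(small_sim_config(), seed = 13)
  v <- validate_dataset(sim$dataset, tolerance_m = 1)
  expect_equal(nrow(v$outside_patch), 0L)
})
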