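test_that("geodesic distance matches an independent spherical oracle", {
  expect_identical(geodesic_distance_m(c(19.8, 46.1), c(19.8, 46.1)), 0)
  # 0.001 degrees of latitude at 46.1 N is ~111.1 m of meridian arc
  expect_equal(geodesic_distance_m(c(19.8, 46.1), c(19.8, 46.101)),
               111.1, tolerance = 0.001)
  set.seed(5)
  for (k in 1:100) {
    a <- c(stats::runif(1, 19, 21), stats::runif(1, 45, 47))
    b <- a + stats::rnorm(2, 0, 0.01)
    d_ab <- geodesic_distance_m(a, b)
    expect_identical(d_ab, geodesic_distance_m(b, a))
    expect_equal(d_ab, haversine_m(a, b), tolerance = 0.006)
  }
  expect_error(geodesic_distance_m(c(NaN, 46), c(19.8, 46.1)), "NaN")
})

test_that("consecutive capture pairs classify into displacement and dispersal", {
  patches <- two_patch_network()
  pt_in <- function(pid, dx_m, dy_m) {
    sw <- patches$ring[[match(pid, patches$patch_id)]][1, ]
    c(sw[1] + dx_m / (M_PER_DEG_LAT * cos(sw[2] * pi / 180)),
      sw[2] + dy_m / M_PER_DEG_LAT)
  }
  a <- pt_in("P1", 10, 10); b <- pt_in("P1", 60, 10); c2 <- pt_in("P2", 20, 50)
  caps <- data.frame(id = "i1", day = c(1, 2, 4), sex = "F",
                     patch = c("P1", "P1", "P2"),
                     lon = c(a[1], b[1], c2[1]), lat = c(a[2], b[2], c2[2]),
                     stringsAsFactors = FALSE)
  mv <- classify_movements(toy_dataset(caps, patches))
  expect_equal(mv$kind, c("displacement", "dispersal"))
  expect_equal(mv$origin_regime, c("unmown", "unmown"))
  expect_equal(mv$distance_m[1], haversine_m(a, b), tolerance = 0.006)
  expect_equal(mv$distance_m[2], haversine_m(b, c2), tolerance = 0.006)
  expect_equal(mv$from_occasion, c(0L, 1L))
})

test_that("movement events conserve capture-pair counts on simulated data", {
  sim <- simulate_mrr(small_sim_config(), seed = 4)
  mv <- classify_movements(sim$dataset)
  caps_per_ind <- table(sim$dataset$records$individual_id)
  expect_equal(nrow(mv), sum(pmax(caps_per_ind - 1L, 0L)))
  expect_true(all(mv$distance_m >= 0))
  expect_true(all(mv$origin_patch[mv$kind == "displacement"] ==
                    mv$dest_patch[mv$kind == "displacement"]))
  expect_true(all(mv$origin_patch[mv$kind == "dispersal"] !=
                    mv$dest_patch[mv$kind == "dispersal"]))
})

test_that("emigration table counts individuals, not events", {
  patches <- two_patch_network()
  # 10 recaptured individuals originating in P1, 3 of them ever seen in P2;
  # one emigrant bounces P1 -> P2 -> P1 -> P2 and must count once
  caps <- do.call(rbind, c(
    lapply(1:7, function(i) data.frame(id = sprintf("s%02d", i), day = c(1, 2),
                                       sex = "F", patch = "P1")),
    lapply(8:9, function(i) data.frame(id = sprintf("s%02d", i), day = c(1, 3),
                                       sex = "M", patch = c("P1", "P2"))),
    list(data.frame(id = "s10", day = 1:4, sex = "F",
                    patch = c("P1", "P2", "P1", "P2"))),
    list(data.frame(id = "never", day = 1, sex = "F", patch = "P1"))))
  emi <- emigration_table(toy_dataset(caps, patches))
  p1 <- emi[emi$patch_id == "P1", ]
  expect_equal(p1$n_recaptured, 10L)
  expect_equal(p1$n_emigrants, 3L)
  expect_equal(p1$emigration_probability, 0.3)
  # P2 originates nobody that was recaptured -> undefined, not zero
  expect_true(is.na(emi$emigration_probability[emi$patch_id == "P2"]))

  # all recaptures within natal patches -> probability 0
  caps0 <- data.frame(id = rep(c("a", "b"), each = 2), day = c(1, 2, 1, 2),
                      sex = "M", patch = "P1", stringsAsFactors = FALSE)
  emi0 <- emigration_table(toy_dataset(caps0, patches))
  expect_equal(emi0$emigration_probability[emi0$patch_id == "P1"], 0)
})

test_that("pooled per-regime emigration estimates recover the generating rates", {
  cfg <- sim_config(n_emerge = 3000L)
  sim <- simulate_mrr(cfg, seed = 8)
  pooled <- pool_emigration_by_regime(emigration_table(sim$dataset))
  for (r in pooled$regime) {
    row <- pooled[pooled$regime == r, ]
    target <- cfg$emigration_lifetime[[r]]
    expect_lt(abs(row$emigration_probability - target), 3 * row$se + 1e-9)
  }
})
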