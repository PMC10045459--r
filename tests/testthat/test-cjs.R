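test_that("m-array tabulates hand-checked histories", {
  ch <- rbind(c(1, 0, 1), c(1, 1, 0), c(1, 0, 0))
  marr <- build_m_array(ch)
  expect_equal(marr$R, c(3L, 1L))
  expect_equal(marr$m[1, ], c(0L, 1L, 1L))
  expect_equal(marr$m[2, ], c(0L, 0L, 0L))
  expect_equal(marr$never, c(1L, 1L))

  singletons <- diag(1L, 4)
  expect_true(all(build_m_array(singletons)$m == 0L))

  set.seed(11)
  for (k in 1:20) {
    chr <- matrix(rbinom(60, 1, 0.4), 10, 6)
    chr[rowSums(chr) == 0, 1] <- 1L
    mr <- build_m_array(chr)
    expect_true(all(rowSums(mr$m) <= mr$R))
    expect_equal(sum(mr$m), sum(pmax(rowSums(chr) - 1L, 0L)))
  }
})

test_that("likelihood closed forms for single histories hold", {
  phi <- 0.7; p <- 0.4
  par <- qlogis(c(phi, p))
  # history 11 over a 1-day interval: log(phi * p)
  expect_equal(cjs_loglik_individual(par, rbind(c(1, 1)), intervals = 1L),
               log(phi * p))
  # history 10: log(1 - phi * p)
  expect_equal(cjs_loglik_individual(par, rbind(c(1, 0)), intervals = 1L),
               log(1 - phi * p))
  # 2-day interval: survival phi^2
  expect_equal(cjs_loglik_individual(par, rbind(c(1, 1)), intervals = 2L),
               log(phi^2 * p))
  # probability-1 data: phi = p = 1 and everyone caught always -> loglik 0
  full <- matrix(1L, 5, 4)
  expect_equal(cjs_loglik_individual(qlogis(c(1 - 1e-12, 1 - 1e-12)), full,
                                     intervals = rep(1L, 3)), 0,
               tolerance = 1e-6)
})

test_that("m-array and individual-history likelihoods agree everywhere", {
  set.seed(23)
  for (k in 1:10) {
    intervals <- sample(1:3, 5, replace = TRUE)
    ch <- sim_histories(20, 6, phi = runif(1, 0.6, 0.9),
                        p = runif(1, 0.2, 0.6), intervals = intervals)
    marr <- build_m_array(ch)
    for (par in list(c(0, 0), rnorm(2), rnorm(2, 0, 2))) {
      expect_lt(abs(cjs_loglik(par, marr, intervals) -
                      cjs_loglik_individual(par, ch, intervals)), 1e-8)
    }
  }
})

test_that("doubling intervals with phi -> sqrt(phi) leaves the likelihood unchanged", {
  ch <- sim_histories(40, 5, 0.8, 0.4, seed = 3)
  marr <- build_m_array(ch)
  l1 <- cjs_loglik(qlogis(c(0.8, 0.4)), marr, rep(1L, 4))
  l2 <- cjs_loglik(qlogis(c(sqrt(0.8), 0.4)), marr, rep(2L, 4))
  expect_equal(l1, l2, tolerance = 1e-10)
})

# tiny local wrapper: free 2-parameter optimisation on one m-array
fit_cjs_grid_free <- function(marr, intervals) {
  opt <- optim(c(0, 0), function(par) -cjs_loglik(par, marr, intervals),
               method = "BFGS")
  list(phi = plogis(opt$par[1]), p = plogis(opt$par[2]), loglik = -opt$value)
}

test_that("2-occasion MLE matches a dense grid-search oracle", {
  ch <- rbind(matrix(rep(c(1, 1), 30), ncol = 2, byrow = TRUE),
              matrix(rep(c(1, 0), 70), ncol = 2, byrow = TRUE))
  marr <- build_m_array(ch)
  grid <- expand.grid(phi = seq(0.01, 0.99, 5e-4), p = seq(0.01, 0.99, 5e-4))
  # only the product phi*p is identifiable with two occasions; compare the
  # maximised likelihood and the fitted product
  ll <- marr$m[1, 2] * log(grid$phi * grid$p) +
    marr$never[1] * log(1 - grid$phi * grid$p)
  best <- grid[which.max(ll), ]
  fit <- fit_cjs_grid_free(marr, intervals = 1L)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-3)
  expect_equal(fit$phi * fit$p, best$phi * best$p, tolerance = 1e-3)
})

test_that("CJS estimates recover simulated survival and capture probability", {
  cfg <- sim_config(n_patches = 10L, n_localities = 2L, n_emerge = 500L,
                    season_days = 30L, gap_prob = 0)
  sim <- simulate_mrr(cfg, seed = 31)
  chm <- capture_history(sim$dataset)
  fits <- fit_cjs(chm, seed = 31)
  pooled <- fits$fits[["phi(.)p(.)"]]
  expect_true(pooled$convergence)
  expect_lt(abs(pooled$phi[["all"]] - cfg$phi), 3 * pooled$phi_se[["all"]])
  expect_lt(abs(pooled$p[["all"]] - cfg$p), 3 * pooled$p_se[["all"]])

  # adding a sex term can never lower the maximised log-likelihood
  ll <- sapply(fits$fits, `[[`, "loglik")
  expect_gte(ll[["phi(sex)p(.)"]], ll[["phi(.)p(.)"]] - 1e-6)
  expect_gte(ll[["phi(sex)p(sex)"]], ll[["phi(sex)p(.)"]] - 1e-6)
  expect_gte(ll[["phi(sex)p(sex)"]], ll[["phi(.)p(sex)"]] - 1e-6)
})

test_that("saturated detection drives p to the boundary with a flag", {
  ch <- matrix(1L, 30, 5)
  chm <- structure(list(ch = ch, sex = rep(c("F", "M"), 15),
                        intervals = rep(1L, 4)), class = "capture_history")
  fit <- fit_cjs(chm, models = "phi(.)p(.)")$fits[[1]]
  expect_gt(fit$p[["all"]], 0.999)
  expect_true(fit$boundary)
})

test_that("estimator is unbiased with nominal CI coverage over replicates", {
  phi <- 0.79; p <- 0.32
  n_rep <- 200L
  est <- matrix(NA_real_, n_rep, 4)
  set.seed(77)
  for (r in seq_len(n_rep)) {
    ch <- sim_histories(200, 15, phi, p)
    chm <- structure(list(ch = ch, sex = rep("F", nrow(ch)),
                          intervals = rep(1L, 14)), class = "capture_history")
    f <- fit_cjs(chm, models = "phi(.)p(.)", n_starts = 2L, seed = r)$fits[[1]]
    est[r, ] <- c(f$phi[["all"]], f$phi_se[["all"]], f$p[["all"]], f$p_se[["all"]])
  }
  expect_lt(abs(mean(est[, 1]) - phi), 0.01)
  expect_lt(abs(mean(est[, 3]) - p), 0.01)
  cover_phi <- mean(abs(est[, 1] - phi) <= 1.96 * est[, 2])
  cover_p <- mean(abs(est[, 3] - p) <= 1.96 * est[, 4])
  expect_gte(cover_phi, 0.90); expect_lte(cover_phi, 0.98)
  expect_gte(cover_p, 0.90); expect_lte(cover_p, 0.98)
})
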