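sim_glmm_binomial <- function(n = 1200, n_loc = 5, sd_loc = 0.4,
                              beta = c(-1.9, -0.694), seed = 1) {
  set.seed(seed)
  g <- sample(LETTERS[1:n_loc], n, TRUE)
  b <- stats::setNames(rnorm(n_loc, 0, sd_loc), LETTERS[1:n_loc])
  sex <- factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M"))
  eta <- beta[1] + beta[2] * (sex == "M") + b[g]
  data.frame(y = rbinom(n, 1, plogis(eta)), sex = sex, g = g)
}

test_that("zero group variance reduces the GLMM to the GLM", {
  set.seed(3)
  d <- data.frame(x = rnorm(400), g = sample(LETTERS[1:5], 400, TRUE))
  d$y <- rbinom(400, 1, plogis(-0.5 + 0.8 * d$x))  # no group effect
  fm <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  fg <- fit_glm(y ~ x, d, "binomial")
  expect_lt(fm$random_sd, 0.15)
  expect_equal(fm$coefficients, fg$coefficients, tolerance = 0.02)
  # and with the variance pinned at the boundary the match is numerical
  ll_at_zero <- -meadowmrr:::glmm_marginal_loglik(
    fg$coefficients, log(1e-6), 1, d$y,
    model.matrix(~x, d), split(seq_len(400), factor(d$g)),
    meadowmrr:::mrr_family("binomial"))$loglik
  expect_equal(-ll_at_zero, fg$loglik, tolerance = 1e-4)
})

test_that("binomial GLMM recovers a sex effect of the fitted-model magnitude", {
  d <- sim_glmm_binomial(seed = 1)
  fit <- fit_glmm(y ~ sex + (1 | g), d, "binomial")
  i <- match("sexM", fit$table$term)
  expect_lt(abs(fit$table$estimate[i] - (-0.694)), 3 * fit$table$se[i])
  expect_gt(fit$random_sd, 0.05)
})

test_that("our Laplace fit matches lme4 on shared test problems", {
  library(lme4)
  d <- sim_glmm_binomial(seed = 1)
  ours <- fit_glmm(y ~ sex + (1 | g), d, "binomial")
  ref <- glmer(y ~ sex + (1 | g), d, binomial)
  expect_equal(ours$coefficients, fixef(ref), tolerance = 1e-3)
  expect_equal(ours$random_sd, sqrt(unlist(VarCorr(ref))[[1]]), tolerance = 1e-2)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-3)

  # Gaussian: against lmer ML
  set.seed(8)
  dg <- data.frame(g = rep(LETTERS[1:6], each = 30), x = rnorm(180))
  dg$y <- 1 + 0.5 * dg$x + rep(rnorm(6, 0, 0.7), each = 30) + rnorm(180, 0, 0.9)
  og <- fit_glmm(y ~ x + (1 | g), dg, "gaussian")
  rg <- lmer(y ~ x + (1 | g), dg, REML = FALSE)
  expect_equal(og$coefficients, fixef(rg), tolerance = 1e-3)
  expect_equal(og$loglik, as.numeric(logLik(rg)), tolerance = 1e-3)
})

test_that("Laplace log-likelihood agrees with 25-node adaptive quadrature", {
  set.seed(4)
  n <- 250; g <- sample(LETTERS[1:5], n, TRUE)
  b <- stats::setNames(rnorm(5, 0, 0.5), LETTERS[1:5])
  x <- rnorm(n)
  for (fam in c("binomial", "poisson", "gamma")) {
    y <- switch(fam,
      binomial = rbinom(n, 1, plogis(-0.5 + 0.6 * x + b[g])),
      poisson = rpois(n, exp(0.8 + 0.3 * x + b[g])),
      gamma = rgamma(n, 2, rate = 2 / exp(3 + 0.4 * x + b[g])))
    d <- data.frame(y = y, x = x, g = g)
    fit <- fit_glmm(y ~ x + (1 | g), d, fam)
    ll_agq <- glmm_loglik_agq(fit, d, nAGQ = 25L)
    expect_lt(abs(fit$loglik - ll_agq), 0.05)
  }
})

test_that("response predictions match sample summaries and bootstrap SEs", {
  set.seed(12)
  d <- data.frame(y = rbinom(150, 1, 0.3))
  fit <- fit_glm(y ~ 1, d, "binomial")
  pr <- predict_response(fit, data.frame(.dummy = 1))
  expect_equal(pr$fit, mean(d$y), tolerance = 1e-8)

  # parametric bootstrap oracle for the delta-method SE
  d2 <- data.frame(x = rnorm(150))
  d2$y <- rbinom(150, 1, plogis(-0.3 + 0.7 * d2$x))
  f2 <- fit_glm(y ~ x, d2, "binomial")
  nd <- data.frame(x = c(-1, 0, 1))
  pr2 <- predict_response(f2, nd)
  mu_hat <- plogis(f2$coefficients[1] + f2$coefficients[2] * nd$x)
  boot <- replicate(1000, {
    yb <- rbinom(150, 1, plogis(f2$coefficients[1] + f2$coefficients[2] * d2$x))
    fb <- fit_glm(y ~ x, data.frame(y = yb, x = d2$x), "binomial")
    plogis(fb$coefficients[1] + fb$coefficients[2] * nd$x)
  })
  boot_se <- apply(boot, 1, sd)
  expect_true(all(abs(pr2$se - boot_se) / boot_se < 0.15))
})

test_that("prediction honours the stored covariate scaling", {
  set.seed(9)
  d <- data.frame(area = runif(200, 1e3, 9e4))
  d$y <- rgamma(200, 2, rate = 2 / exp(4 + 0.5 * scale(d$area)[, 1]))
  sc <- scale_covariates(d, "area")
  fit <- fit_glm(y ~ area, sc$data, "gamma", scaling = sc$scaling)
  pr <- predict_response(fit, data.frame(area = mean(d$area)))
  expect_equal(log(pr$fit), fit$coefficients[[1]], tolerance = 1e-6)
  expect_error(predict_response(fit, data.frame(wrong = 1)), "area")
})

test_that("unseen factor levels in prediction are an error", {
  d <- sim_glmm_binomial(n = 300, seed = 5)
  fit <- fit_glm(y ~ sex, d, "binomial")
  expect_error(predict_response(fit, data.frame(sex = "X")), "level|factor")
})

test_that("AIC selection prefers simpler models within two units", {
  mk <- function(aic, k) list(AIC = aic, npar = k)
  f1 <- list(a = mk(100, 4), b = mk(105, 4))
  expect_equal(attr(aic_select(f1), "selection")$selected, c(TRUE, FALSE))
  f2 <- list(complex = mk(100, 5), simple = mk(101.5, 3))
  expect_equal(aic_select(f2)$npar, 3)
  f3 <- list(zeta = mk(100, 3), alpha = mk(100, 3))
  sel3 <- attr(aic_select(f3), "selection")
  expect_equal(sel3$model[sel3$selected], "alpha")
  expect_error(aic_select(list()), "no fits")
})

test_that("Wald CIs from the GLMM attain near-nominal coverage", {
  n_rep <- 200L
  beta_true <- -0.694
  hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- sim_glmm_binomial(n = 300, seed = 1000 + r)
    fit <- fit_glmm(y ~ sex + (1 | g), d, "binomial")
    i <- match("sexM", fit$table$term)
    hit[r] <- abs(fit$table$estimate[i] - beta_true) <= 1.96 * fit$table$se[i]
  }
  expect_gte(mean(hit), 0.90)
  expect_lte(mean(hit), 0.98)
})
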