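# Family toolkit for the IRLS / Laplace machinery.  Canonical links
# throughout except gamma, which uses the log link (the standard choice for
# strictly positive movement distances).
mrr_family <- function(name) {
  switch(name,
    binomial = list(
      name = "binomial", link = "logit",
      linkfun = stats::qlogis, linkinv = stats::plogis,
      mu_eta = function(eta) { m <- stats::plogis(eta); m * (1 - m) },
      variance = function(mu) mu * (1 - mu),
      dll = function(y, eta, disp) y - stats::plogis(eta),
      d2ll = function(y, eta, disp) { m <- stats::plogis(eta); -m * (1 - m) },
      loglik = function(y, mu, disp) sum(stats::dbinom(y, 1, mu, log = TRUE)),
      mustart = function(y) (y + 0.5) / 2,
      n_disp = 0L, stat = "z"),
    poisson = list(
      name = "poisson", link = "log",
      linkfun = log, linkinv = exp,
      mu_eta = exp,
      variance = function(mu) mu,
      dll = function(y, eta, disp) y - exp(eta),
      d2ll = function(y, eta, disp) -exp(eta),
      loglik = function(y, mu, disp) sum(stats::dpois(y, mu, log = TRUE)),
      mustart = function(y) y + 0.1,
      n_disp = 0L, stat = "z"),
    gamma = list(
      name = "gamma", link = "log",
      linkfun = log, linkinv = exp,
      mu_eta = exp,
      variance = function(mu) mu^2,
      # disp = shape alpha; ll_i = alpha(log alpha - eta) + (alpha-1)log y
      #        - alpha y e^{-eta} - lgamma(alpha)
      dll = function(y, eta, disp) disp * (y * exp(-eta) - 1),
      d2ll = function(y, eta, disp) -disp * y * exp(-eta),
      loglik = function(y, mu, disp)
        sum(stats::dgamma(y, shape = disp, rate = disp / mu, log = TRUE)),
      mustart = function(y) y,
      n_disp = 1L, stat = "t"),
    gaussian = list(
      name = "gaussian", link = "identity",
      linkfun = identity, linkinv = identity,
      mu_eta = function(eta) rep(1, length(eta)),
      variance = function(mu) rep(1, length(mu)),
      # disp = residual variance sigma^2
      dll = function(y, eta, disp) (y - eta) / disp,
      d2ll = function(y, eta, disp) rep(-1 / disp, length(eta)),
      loglik = function(y, mu, disp)
        sum(stats::dnorm(y, mu, sqrt(disp), log = TRUE)),
      mustart = function(y) y,
      n_disp = 1L, stat = "t"),
    stop("unknown family: ", name)
  )
}

#' Normalise covariates by mean and standard deviation
#'
#' Continuous predictors are centred and scaled to unit SD before modelling;
#' the scaling record is kept so that prediction grids can be expressed in
#' the original units.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric columns to scale.
#' @return List with `data` (scaled copy) and `scaling` (data frame
#'   `column`, `center`, `scale`).
#' @export
scale_covariates <- function(data, columns) {
  scaling <- data.frame(column = columns, center = NA_real_, scale = NA_real_,
                        stringsAsFactors = FALSE)
  for (k in seq_along(columns)) {
    col <- columns[k]
    x <- data[[col]]
    if (!is.numeric(x)) stop("column ", col, " is not numeric")
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("column ", col, " has zero SD; cannot scale")
    scaling$center[k] <- mean(x); scaling$scale[k] <- s
    data[[col]] <- (x - mean(x)) / s
  }
  list(data = data, scaling = scaling)
}

#' Apply (or invert) a covariate scaling record
#'
#' @param data Data frame with columns in original units.
#' @param scaling Scaling record from [scale_covariates()].
#' @param invert If `TRUE`, map scaled values back to original units.
#' @return Transformed data frame.
#' @export
apply_scaling <- function(data, scaling, invert = FALSE) {
  for (k in seq_len(nrow(scaling))) {
    col <- scaling$column[k]
    if (!col %in% names(data)) next
    data[[col]] <- if (invert)
      data[[col]] * scaling$scale[k] + scaling$center[k]
    else (data[[col]] - scaling$center[k]) / scaling$scale[k]
  }
  data
}

# Split y ~ fixed + (1 | g) into the fixed-effects formula and group variable.
split_formula <- function(formula) {
  txt <- paste(deparse(formula), collapse = " ")
  m <- regmatches(txt, regexpr("\\(\\s*1\\s*\\|\\s*[^)]+\\)", txt))
  if (!length(m)) return(list(fixed = formula, group = NULL))
  group <- trimws(sub(".*\\|", "", sub("\\)$", "", m)))
  fixed_txt <- gsub("\\s*\\+?\\s*\\(\\s*1\\s*\\|\\s*[^)]+\\)", "", txt)
  fixed_txt <- sub("~\\s*\\+", "~", fixed_txt)
  if (grepl("~\\s*$", fixed_txt)) fixed_txt <- paste(fixed_txt, "1")
  list(fixed = stats::as.formula(fixed_txt, env = environment(formula)),
       group = group)
}

#' Fit a generalised linear model by IRLS
#'
#' Iteratively reweighted least squares with the family's canonical link
#' (log link for gamma); the gamma shape is estimated by maximum likelihood
#' from the deviance after convergence. Wald statistics are z for
#' binomial/Poisson and t (residual df) for gamma/Gaussian.
#'
#' @param formula Fixed-effects formula (no random term).
#' @param data Data frame.
#' @param family One of `"binomial"`, `"gamma"`, `"poisson"`, `"gaussian"`.
#'   Binomial responses may be logical, 0/1 numeric, or a factor whose
#'   second level is the event.
#' @param scaling Optional scaling record from [scale_covariates()] already
#'   applied to `data` (stored for prediction).
#' @return Object of class `mrr_glm`: coefficient table, `vcov`, `loglik`,
#'   `AIC`, `dispersion` (gamma shape or Gaussian residual variance),
#'   `deviance_path`, and the model frame metadata needed by
#'   [predict_response()].
#' @export
fit_glm <- function(formula, data, family, scaling = NULL) {
  fam <- mrr_family(match.arg(family, c("binomial", "gamma", "poisson", "gaussian")))
  parts <- split_formula(formula)
  if (!is.null(parts$group))
    stop("fit_glm takes no random term; use fit_glmm")
  mf <- stats::model.frame(parts$fixed, data)
  y <- prep_response(stats::model.response(mf), fam)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix rank-deficient; aliased column(s): ",
         paste(dropped, collapse = ", "))
  }
  n <- length(y); p <- ncol(X)

  mu <- fam$mustart(y)
  eta <- fam$linkfun(pmax(pmin(mu, 1 - 1e-6), 1e-6) * (fam$name == "binomial") +
                       mu * (fam$name != "binomial"))
  if (fam$name == "binomial") eta <- fam$linkfun(fam$mustart(y))
  dev_path <- numeric(0)
  beta <- rep(0, p)
  for (iter in seq_len(200L)) {
    mu_eta <- fam$mu_eta(eta)
    W <- mu_eta^2 / fam$variance(mu)
    z <- eta + (y - mu) / mu_eta
    fit <- stats::lm.wfit(X, z, W)
    beta_new <- fit$coefficients
    eta <- drop(X %*% beta_new)
    mu <- fam$linkinv(eta)
    dev <- glm_deviance(y, mu, fam)
    dev_path <- c(dev_path, dev)
    if (iter > 1L &&
        abs(dev_path[iter - 1L] - dev) < 1e-10 * (abs(dev) + 1e-10)) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }

  disp <- switch(fam$name,
    binomial = , poisson = 1,
    gaussian = sum((y - mu)^2) / n,           # ML estimate
    gamma = gamma_shape_ml(y, mu))
  ll <- fam$loglik(y, mu, disp)
  mu_eta <- fam$mu_eta(eta)
  W <- mu_eta^2 / fam$variance(mu)
  XtWX <- crossprod(X * sqrt(W))
  a_phi <- switch(fam$name, binomial = 1, poisson = 1,
                  gaussian = disp, gamma = 1 / disp)
  vcov <- a_phi * solve(XtWX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  k <- p + fam$n_disp
  res <- list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vcov, family = fam$name, formula = parts$fixed,
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    scaling = scaling, loglik = ll, npar = k, AIC = 2 * k - 2 * ll,
    dispersion = disp, df_residual = n - p, n = n,
    deviance_path = dev_path, fitted = mu, group = NULL,
    random_sd = 0, boundary = FALSE)
  res$table <- coef_table(res, fam$stat)
  class(res) <- c("mrr_glm", "mrr_fit")
  res
}

prep_response <- function(y, fam) {
  if (fam$name == "binomial") {
    if (is.logical(y)) y <- as.numeric(y)
    if (is.factor(y)) y <- as.numeric(y) - 1
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
  }
  if (fam$name == "gamma" && any(y <= 0)) stop("gamma response must be positive")
  if (fam$name == "poisson" && any(y < 0 | y != round(y)))
    stop("poisson response must be non-negative integer")
  as.numeric(y)
}

glm_deviance <- function(y, mu, fam) {
  switch(fam$name,
    binomial = -2 * sum(y * log(pmax(mu, 1e-300)) +
                          (1 - y) * log(pmax(1 - mu, 1e-300))),
    poisson = 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)),
    gamma = 2 * sum(-log(y / mu) + (y - mu) / mu),
    gaussian = sum((y - mu)^2))
}

# ML estimate of the gamma shape given fitted means: solve
# log(a) - digamma(a) = mean deviance / 2.
gamma_shape_ml <- function(y, mu) {
  Dbar <- mean(-log(y / mu) + (y - mu) / mu)
  if (Dbar <= 0) return(1e8)
  f <- function(la) { a <- exp(la); log(a) - digamma(a) - Dbar }
  la <- stats::uniroot(f, c(-10, 20), tol = 1e-12)$root
  exp(la)
}

coef_table <- function(fit, stat) {
  est <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  z <- est / se
  pval <- if (stat == "z") 2 * stats::pnorm(-abs(z))
          else 2 * stats::pt(-abs(z), df = fit$df_residual)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             stat = unname(z), p_value = unname(pval),
             stringsAsFactors = FALSE)
}

#' @export
print.mrr_fit <- function(x, ...) {
  cat(sprintf("%s %s model: loglik = %.3f, AIC = %.2f\n",
              if (is.null(x$group)) "GLM" else
                sprintf("GLMM (random intercept: %s, sd = %.3f%s)", x$group,
                        x$random_sd, if (x$boundary) ", boundary" else ""),
              x$family, x$loglik, x$AIC))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
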