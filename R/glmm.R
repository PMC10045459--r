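# Gauss-Hermite nodes/weights by Golub-Welsch (eigen-decomposition of the
# Jacobi matrix for the Hermite weight exp(-x^2)).
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

# Mode and curvature of the per-group joint log-density
#   h(b) = sum_i loglik_i(eta_i + b) + dnorm(b, 0, sigma_b, log = TRUE)
# by damped Newton.  Returns b_hat, h(b_hat) and h''(b_hat).
group_mode <- function(y, eta0, fam, disp, sigma_b, b_start = 0) {
  h <- function(b) fam$loglik(y, fam$linkinv(eta0 + b), disp) +
    stats::dnorm(b, 0, sigma_b, log = TRUE)
  b <- b_start
  hb <- h(b)
  for (it in seq_len(100L)) {
    g1 <- sum(fam$dll(y, eta0 + b, disp)) - b / sigma_b^2
    g2 <- sum(fam$d2ll(y, eta0 + b, disp)) - 1 / sigma_b^2
    step <- -g1 / g2
    if (!is.finite(step)) break
    b_new <- b + step
    h_new <- h(b_new)
    halvings <- 0L
    while ((!is.finite(h_new) || h_new < hb - 1e-12) && halvings < 30L) {
      step <- step / 2; b_new <- b + step; h_new <- h(b_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(h_new)) break
    conv <- abs(b_new - b) < 1e-10 * (abs(b) + 1e-8)
    b <- b_new; hb <- h_new
    if (conv) break
  }
  g2 <- sum(fam$d2ll(y, eta0 + b, disp)) - 1 / sigma_b^2
  list(b = b, h = hb, curv = g2)
}

# Marginal log-likelihood of a single-random-intercept GLMM.  nAGQ = 1 is
# the Laplace approximation; larger odd values use adaptive Gauss-Hermite
# quadrature centred at the group modes.
glmm_marginal_loglik <- function(beta, log_sigma, disp, y, X, group_idx, fam,
                                 nAGQ = 1L, b_start = NULL) {
  sigma_b <- exp(log_sigma)
  eta_fixed <- drop(X %*% beta)
  gh <- if (nAGQ > 1L) gauss_hermite(nAGQ) else NULL
  ll <- 0
  b_hat <- numeric(length(group_idx))
  for (g in seq_along(group_idx)) {
    idx <- group_idx[[g]]
    md <- group_mode(y[idx], eta_fixed[idx], fam, disp, sigma_b,
                     if (is.null(b_start)) 0 else b_start[g])
    b_hat[g] <- md$b
    if (md$curv >= 0) return(list(loglik = -Inf, b_hat = b_hat))
    s <- 1 / sqrt(-md$curv)
    if (is.null(gh)) {
      ll <- ll + md$h + 0.5 * log(2 * pi) + log(s)
    } else {
      bs <- md$b + sqrt(2) * s * gh$nodes
      hvals <- vapply(bs, function(b)
        fam$loglik(y[idx], fam$linkinv(eta_fixed[idx] + b), disp) +
          stats::dnorm(b, 0, sigma_b, log = TRUE), 0)
      terms <- log(gh$weights) + gh$nodes^2 + hvals
      M <- max(terms)
      ll <- ll + M + log(sum(exp(terms - M))) + log(sqrt(2) * s)
    }
  }
  list(loglik = ll, b_hat = b_hat)
}

#' Fit a random-intercept GLMM by Laplace-approximated maximum likelihood
#'
#' Single scalar random intercept per group (the study locality), integrated
#' out of the likelihood with a Laplace approximation (optionally adaptive
#' Gauss-Hermite quadrature for validation). Fixed effects, the random-
#' intercept SD and the family dispersion are estimated jointly by
#' quasi-Newton optimisation.
#'
#' @param formula Model formula with a `(1 | group)` term, e.g.
#'   `emigrated ~ regime + sex + (1 | locality)`.
#' @param data Data frame.
#' @param family `"binomial"`, `"gamma"`, `"poisson"` or `"gaussian"`.
#' @param nAGQ Number of quadrature nodes; 1 = Laplace (default).
#' @param scaling Optional scaling record from [scale_covariates()] already
#'   applied to `data`.
#' @return Object of class `mrr_glmm`/`mrr_fit` with the same surface as
#'   [fit_glm()] plus `random_sd`, `ranef` (group modes) and `boundary`
#'   (`TRUE` when the variance estimate hit the zero boundary).
#' @export
fit_glmm <- function(formula, data, family, nAGQ = 1L, scaling = NULL) {
  fam <- mrr_family(match.arg(family, c("binomial", "gamma", "poisson", "gaussian")))
  parts <- split_formula(formula)
  if (is.null(parts$group)) {
    warning("no random term in formula; falling back to fit_glm")
    return(fit_glm(formula, data, family, scaling = scaling))
  }
  gvar <- data[[parts$group]]
  if (is.null(gvar)) stop("grouping variable not found: ", parts$group)
  gfac <- factor(gvar)
  if (nlevels(gfac) < 2L)
    stop("grouping factor needs >= 2 levels; got ", nlevels(gfac))
  mf <- stats::model.frame(parts$fixed, data)
  y <- prep_response(stats::model.response(mf), fam)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X); n <- length(y)
  group_idx <- split(seq_len(n), gfac)

  init <- fit_glm(parts$fixed, data, fam$name)
  th0 <- c(init$coefficients, log_sigma = log(0.3))
  disp_idx <- NULL
  if (fam$n_disp == 1L) {
    d0 <- if (fam$name == "gaussian") log(max(init$dispersion, 1e-6))
          else log(init$dispersion)
    th0 <- c(th0, log_disp = d0)
    disp_idx <- p + 2L
  }
  unpack <- function(th) {
    th <- unname(th)
    disp <- if (is.null(disp_idx)) 1 else exp(th[disp_idx])
    list(beta = th[seq_len(p)], log_sigma = th[p + 1L], disp = disp)
  }
  nll <- function(th) {
    u <- unpack(th)
    -glmm_marginal_loglik(u$beta, u$log_sigma, u$disp, y, X, group_idx, fam,
                          nAGQ = nAGQ)$loglik
  }
  lower <- rep(-Inf, length(th0)); lower[p + 1L] <- log(1e-6)
  upper <- rep(Inf, length(th0)); upper[p + 1L] <- log(50)
  opt <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  u <- unpack(opt$par)
  boundary <- opt$par[p + 1L] <= log(1e-6) + 1e-6
  final <- glmm_marginal_loglik(u$beta, u$log_sigma, u$disp, y, X, group_idx,
                                fam, nAGQ = nAGQ)

  H <- try(stats::optimHess(opt$par, nll), silent = TRUE)
  vcov_beta <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  if (!inherits(H, "try-error")) {
    beta_block <- function(V) {
      Vb <- V[seq_len(p), seq_len(p), drop = FALSE]
      if (all(is.finite(diag(Vb))) && all(diag(Vb) >= 0)) Vb else NULL
    }
    V <- try(solve(H), silent = TRUE)
    Vb <- if (!inherits(V, "try-error")) beta_block(V) else NULL
    if (is.null(Vb)) {
      # curvature wrt log sigma is degenerate at (or near) the zero-variance
      # boundary: condition on sigma_b and invert the remaining block
      free <- setdiff(seq_along(opt$par), p + 1L)
      Vf <- try(solve(H[free, free, drop = FALSE]), silent = TRUE)
      if (!inherits(Vf, "try-error"))
        Vb <- beta_block(Vf)
    }
    if (!is.null(Vb)) vcov_beta <- Vb
  }
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  k <- p + 1L + fam$n_disp
  res <- list(
    coefficients = stats::setNames(u$beta, colnames(X)),
    vcov = vcov_beta, family = fam$name, formula = formula,
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    scaling = scaling, loglik = final$loglik, npar = k,
    AIC = 2 * k - 2 * final$loglik,
    dispersion = u$disp, df_residual = n - p, n = n,
    group = parts$group, random_sd = exp(u$log_sigma),
    ranef = stats::setNames(final$b_hat, names(group_idx)),
    boundary = boundary, nAGQ = nAGQ,
    convergence = opt$convergence == 0)
  res$table <- coef_table(res, fam$stat)
  class(res) <- c("mrr_glmm", "mrr_fit")
  res
}

#' GLMM marginal log-likelihood at the fitted parameters
#'
#' Re-evaluates the integrated likelihood of a fitted model with a given
#' number of adaptive Gauss-Hermite nodes; used to validate the Laplace
#' approximation (`nAGQ = 1`) against high-order quadrature.
#'
#' @param fit An `mrr_glmm`.
#' @param data The data the model was fitted to.
#' @param nAGQ Number of quadrature nodes.
#' @return Log-likelihood.
#' @export
glmm_loglik_agq <- function(fit, data, nAGQ = 25L) {
  fam <- mrr_family(fit$family)
  parts <- split_formula(fit$formula)
  mf <- stats::model.frame(parts$fixed, data)
  y <- prep_response(stats::model.response(mf), fam)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  group_idx <- split(seq_along(y), factor(data[[fit$group]]))
  glmm_marginal_loglik(fit$coefficients, log(fit$random_sd), fit$dispersion,
                       y, X, group_idx, fam, nAGQ = nAGQ)$loglik
}

#' Predicted response with delta-method standard errors
#'
#' Population-level prediction (random effect at zero): inverse link of the
#' linear predictor at `newdata`, with SE propagated from the fixed-effect
#' covariance by the delta method. Covariates named in the fit's scaling
#' record may be given in original units; they are scaled automatically.
#'
#' @param fit An `mrr_glm` or `mrr_glmm`.
#' @param newdata Data frame of predictor values.
#' @return Data frame `fit` (response scale), `se`, plus `newdata` columns.
#' @export
predict_response <- function(fit, newdata) {
  fam <- mrr_family(fit$family)
  if (!is.null(fit$scaling)) newdata <- apply_scaling(newdata, fit$scaling)
  tt <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% fit$coefficients)
  se_eta <- sqrt(rowSums((X %*% fit$vcov) * X))
  mu <- fam$linkinv(eta)
  se_mu <- se_eta * abs(fam$mu_eta(eta))
  cbind(newdata, data.frame(fit = mu, se = se_mu))
}

#' AIC-based model selection with a simplicity rule
#'
#' The lowest-AIC model wins unless a simpler model (fewer parameters) lies
#' within 2 AIC units of it, in which case the simplest such model is
#' chosen. Ties break deterministically by parameter count, then AIC, then
#' name.
#'
#' @param fits Named list of fitted models (each with `AIC` and `npar`).
#' @return The selected element of `fits`, with attribute `"selection"`
#'   holding the comparison table.
#' @export
aic_select <- function(fits) {
  if (!length(fits)) stop("no fits to select among")
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  aics <- vapply(fits, `[[`, 0, "AIC")
  npars <- vapply(fits, function(f) as.numeric(f$npar), 0)
  sel <- aic_select_rule(aics, npars, names(fits))
  out <- fits[[sel]]
  attr(out, "selection") <- data.frame(
    model = names(fits), npar = npars, AIC = aics,
    delta_AIC = aics - min(aics), selected = names(fits) == sel,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Export a fitted model's coefficient table as CSV
#'
#' @param fit An `mrr_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path) {
  utils::write.csv(fit$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
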