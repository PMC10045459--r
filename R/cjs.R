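#' Capture-history matrix
#'
#' Binary individuals-by-occasions matrix over the full occasion calendar,
#' with the sex recorded at first capture. When `patch_id` is given, only
#' captures made in that patch are used (the per-patch analysis unit).
#'
#' @param dataset An `mrr_dataset`.
#' @param patch_id Optional patch to restrict to.
#' @return List of class `capture_history` with elements `ch` (0/1 matrix,
#'   rownames = individual ids), `sex`, `intervals` (days between
#'   occasions) and `occasions`.
#' @export
capture_history <- function(dataset, patch_id = NULL) {
  rec <- dataset$records
  if (!is.null(patch_id)) rec <- rec[rec$patch_id %in% patch_id, , drop = FALSE]
  if (!nrow(rec)) stop("no captures for the requested patch")
  ids <- unique(rec$individual_id)
  K <- length(dataset$calendar$dates)
  ch <- matrix(0L, length(ids), K, dimnames = list(ids, NULL))
  ch[cbind(match(rec$individual_id, ids), rec$occasion + 1L)] <- 1L
  first <- !duplicated(rec$individual_id)
  sex <- rec$sex[first][match(ids, rec$individual_id[first])]
  structure(list(ch = ch, sex = sex, intervals = dataset$calendar$intervals,
                 occasions = seq_len(K) - 1L),
            class = "capture_history")
}

#' Reduced m-array of a capture-history matrix
#'
#' Sufficient statistic for the CJS likelihood: for each release occasion i,
#' the number released `R_i` (captures at i, all re-released) and `m[i, j]`,
#' the number of those first recaptured at occasion j > i.
#'
#' @param chm A `capture_history` (or plain 0/1 matrix).
#' @return List of class `m_array` with `R` (length K-1), `m`
#'   ((K-1) x K matrix, column j = first recapture at occasion j) and
#'   `never` (R_i minus row sums of m).
#' @export
build_m_array <- function(chm) {
  ch <- if (is.list(chm)) chm$ch else chm
  if (is.null(dim(ch)) || nrow(ch) == 0L || ncol(ch) < 2L)
    stop("capture-history matrix must have >= 1 individual and >= 2 occasions")
  K <- ncol(ch)
  R <- colSums(ch[, -K, drop = FALSE])
  m <- matrix(0L, K - 1L, K)
  for (ind in seq_len(nrow(ch))) {
    occ <- which(ch[ind, ] == 1L)
    if (length(occ) < 2L) next
    for (t in seq_len(length(occ) - 1L))
      m[occ[t], occ[t + 1L]] <- m[occ[t], occ[t + 1L]] + 1L
  }
  structure(list(R = as.integer(R), m = m,
                 never = as.integer(R - rowSums(m))),
            class = "m_array")
}

# Cell probabilities of the m-array multinomial: pi[i, j] is the probability
# that an animal released at i is next caught at j, with daily survival phi
# raised to the interval lengths, and (1 - p) for each occasion skipped.
cjs_cell_probs <- function(phi, p, intervals) {
  K <- length(intervals) + 1L
  cumdays <- c(0, cumsum(intervals))
  pi <- matrix(0, K - 1L, K)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      surv <- phi^(cumdays[j] - cumdays[i])
      pi[i, j] <- surv * (1 - p)^(j - i - 1L) * p
    }
  }
  pi
}

#' CJS log-likelihood from an m-array
#'
#' Multinomial log-likelihood of the reduced m-array under time-constant
#' daily survival `phi` and capture probability `p`; survival over an
#' interval of `l` days is `phi^l`.
#'
#' @param params Numeric `c(logit_phi, logit_p)` on the unconstrained scale.
#' @param marr An `m_array`.
#' @param intervals Integer vector of interval lengths in days.
#' @return Log-likelihood (finite for interior parameters).
#' @export
cjs_loglik <- function(params, marr, intervals) {
  phi <- stats::plogis(params[1]); p <- stats::plogis(params[2])
  if (phi <= 0 || phi >= 1 || p <= 0 || p >= 1) return(-Inf)
  pi <- cjs_cell_probs(phi, p, intervals)
  chi <- pmax(1 - rowSums(pi), 1e-300)
  ll <- sum(marr$m * log(pmax(pi, 1e-300))) + sum(marr$never * log(chi))
  ll
}

#' CJS log-likelihood from individual histories
#'
#' Brute-force evaluation of the same likelihood as [cjs_loglik()] directly
#' from each capture history, using the chi recursion for the probability of
#' never being seen after the last capture. Used as an independent oracle
#' for the m-array implementation.
#'
#' @param params `c(logit_phi, logit_p)`.
#' @param chm A `capture_history` or plain 0/1 matrix.
#' @param intervals Interval lengths in days (taken from `chm` if absent).
#' @return Log-likelihood.
#' @export
cjs_loglik_individual <- function(params, chm, intervals = NULL) {
  ch <- if (is.list(chm)) chm$ch else chm
  if (is.null(intervals)) intervals <- chm$intervals
  phi <- stats::plogis(params[1]); p <- stats::plogis(params[2])
  K <- ncol(ch)
  # chi[i]: P(never seen after occasion i | alive at i)
  chi <- numeric(K); chi[K] <- 1
  if (K > 1L) for (i in (K - 1L):1L) {
    s <- phi^intervals[i]
    chi[i] <- (1 - s) + s * (1 - p) * chi[i + 1L]
  }
  ll <- 0
  for (ind in seq_len(nrow(ch))) {
    occ <- which(ch[ind, ] == 1L)
    f <- occ[1]; l <- occ[length(occ)]
    if (l > f) for (k in f:(l - 1L)) {
      ll <- ll + intervals[k] * log(phi) +
        log(if ((k + 1L) %in% occ) p else 1 - p)
    }
    ll <- ll + log(chi[l])
  }
  ll
}

cjs_model_set <- c("phi(.)p(.)", "phi(sex)p(.)", "phi(.)p(sex)", "phi(sex)p(sex)")

#' Fit Cormack-Jolly-Seber models with optional sex structure
#'
#' Fits time-constant CJS models by maximum likelihood on the m-array, with
#' survival and/or capture probability allowed to differ between the sexes,
#' and selects among them by AIC (a simpler model within two AIC units of
#' the best is preferred). Daily survival is estimated; interval survival is
#' `phi^l_i`. Optimisation is quasi-Newton on the logit scale from several
#' starts; standard errors come from the inverse observed information via
#' the delta method.
#'
#' @param chm A `capture_history`.
#' @param models Subset of `c("phi(.)p(.)", "phi(sex)p(.)", "phi(.)p(sex)",
#'   "phi(sex)p(sex)")`.
#' @param n_starts Number of optimiser starts (default 5).
#' @param seed Seed for the start jitter.
#' @return List of class `cjs_fit_set`: `fits` (per-model lists with `phi`,
#'   `phi_se`, `p`, `p_se`, `loglik`, `npar`, `AIC`, `convergence`,
#'   `boundary`), `selected` (model name) and `table` (summary data frame).
#' @export
fit_cjs <- function(chm, models = cjs_model_set, n_starts = 5L, seed = 1L) {
  models <- match.arg(models, cjs_model_set, several.ok = TRUE)
  if (sum(pmax(rowSums(chm$ch) - 1L, 0L)) < 1L)
    stop("no recapture transitions; CJS model is not estimable")
  sexes <- sort(unique(chm$sex))
  marrs <- lapply(sexes, function(s)
    build_m_array(chm$ch[chm$sex == s, , drop = FALSE]))
  names(marrs) <- sexes
  pooled <- build_m_array(chm$ch)

  fits <- lapply(models, function(mod)
    fit_cjs_one(mod, marrs, pooled, chm$intervals, sexes, n_starts, seed))
  names(fits) <- models
  ok <- vapply(fits, function(f) isTRUE(f$convergence), TRUE)
  if (!any(ok)) stop("no CJS model converged")
  if (any(!ok)) warning("dropping non-converged CJS model(s): ",
                        paste(models[!ok], collapse = ", "))
  keep <- fits[ok]
  aics <- vapply(keep, `[[`, 0, "AIC")
  npars <- vapply(keep, `[[`, 0L, "npar")
  sel <- aic_select_rule(aics, npars, names(keep))
  tab <- data.frame(model = names(keep),
                    npar = npars, loglik = vapply(keep, `[[`, 0, "loglik"),
                    AIC = aics, selected = names(keep) == sel,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(fits = fits, selected = sel, table = tab),
            class = "cjs_fit_set")
}

fit_cjs_one <- function(model, marrs, pooled, intervals, sexes, n_starts, seed) {
  phi_by_sex <- grepl("phi\\(sex\\)", model)
  p_by_sex <- grepl("p\\(sex\\)", model)
  if ((phi_by_sex || p_by_sex) && length(sexes) < 2L)
    phi_by_sex <- p_by_sex <- FALSE
  n_phi <- if (phi_by_sex) length(sexes) else 1L
  n_p <- if (p_by_sex) length(sexes) else 1L
  npar <- n_phi + n_p
  nll <- function(par) {
    ll <- 0
    for (g in seq_along(sexes)) {
      pf <- par[if (phi_by_sex) g else 1L]
      pp <- par[n_phi + if (p_by_sex) g else 1L]
      ll <- ll + cjs_loglik(c(pf, pp), marrs[[g]], intervals)
    }
    -ll
  }
  if (n_phi == 1L && n_p == 1L)
    nll <- function(par) -cjs_loglik(par, pooled, intervals)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  starts <- rbind(rep(0, npar),
                  matrix(stats::rnorm((n_starts - 1L) * npar, 0, 1.5),
                         n_starts - 1L, npar))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- try(stats::optim(starts[s, ], nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    return(list(model = model, convergence = FALSE))
  H <- try(stats::optimHess(best$par, nll), silent = TRUE)
  se_logit <- rep(NA_real_, npar)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) >= 0))
      se_logit <- sqrt(diag(V))
  }
  est <- stats::plogis(best$par)
  se <- se_logit * est * (1 - est)  # delta method to probability scale
  phi <- est[seq_len(n_phi)]; p <- est[n_phi + seq_len(n_p)]
  names(phi) <- if (phi_by_sex) sexes else "all"
  names(p) <- if (p_by_sex) sexes else "all"
  boundary <- any(est > 0.999) || any(est < 0.001)
  list(model = model, phi = phi,
       phi_se = stats::setNames(se[seq_len(n_phi)], names(phi)),
       p = p, p_se = stats::setNames(se[n_phi + seq_len(n_p)], names(p)),
       loglik = -best$value, npar = npar, AIC = 2 * npar + 2 * best$value,
       convergence = best$convergence == 0, boundary = boundary)
}

# Lowest AIC wins unless a simpler model lies within 2 AIC units; ties break
# by parameter count, then by name order.
aic_select_rule <- function(aics, npars, names) {
  best <- min(aics)
  cand <- which(aics < best + 2)
  cand <- cand[order(npars[cand], aics[cand], names[cand])]
  names[cand[1]]
}

#' Per-patch CJS eligibility
#'
#' A patch enters the per-patch CJS analysis only with a large enough
#' sample: at least `min_marked` individuals and `min_transitions` recapture
#' transitions.
#'
#' @param chm A `capture_history`.
#' @param min_marked,min_transitions Eligibility thresholds (defaults 20
#'   and 5).
#' @return Logical.
#' @export
cjs_eligible <- function(chm, min_marked = 20L, min_transitions = 5L) {
  nrow(chm$ch) >= min_marked &&
    sum(pmax(rowSums(chm$ch) - 1L, 0L)) >= min_transitions
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
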