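#' Run the complete MRR analysis
#'
#' End-to-end orchestration: load or simulate a dataset, validate it,
#' classify movements, build the per-patch emigration table, compute
#' connectivity (alpha defaulting to 1/mean observed dispersal distance),
#' fit per-patch CJS models and recruitment-based seasonal population
#' sizes, and fit the regime-comparison mixed models: a binomial GLMM for
#' individual emigration, gamma GLMMs for dispersal and displacement
#' distances, a Poisson GLMM for patch population size, and Gaussian mixed
#' models for per-patch survival and capture probability. Continuous
#' covariates are normalised by mean and SD before fitting.
#'
#' @param config List with either `records_path` + `patches_path` (read a
#'   dataset) or `sim` (a [sim_config()]; simulate one). Optional entries:
#'   `tolerance_m` (validation, default 25), `min_marked`,
#'   `min_transitions` (CJS eligibility), `alpha`, `xi`, `buffer_km`,
#'   `distance_mode` (connectivity overrides).
#' @param seed Seed for simulation and model fitting.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV.
#' @return List of class `mrr_report`: `dataset`, `validation`,
#'   `movements`, `emigration`, `emigration_by_regime`, `connectivity`,
#'   `cjs_table`, `patch_table`, `models` (fitted model objects),
#'   `model_tables` and `meta`.
#' @export
run_all <- function(config = list(sim = sim_config()), seed = 1L,
                    out_dir = NULL) {
  t0 <- Sys.time()
  truth <- NULL
  if (!is.null(config$records_path)) {
    dataset <- read_dataset(config$records_path, config$patches_path)
  } else {
    sim <- simulate_mrr(config$sim %||% sim_config(), seed = seed)
    dataset <- sim$dataset
    truth <- sim$truth
  }
  validation <- validate_dataset(dataset, config$tolerance_m %||% 25)
  movements <- classify_movements(dataset)
  emigration <- emigration_table(dataset)
  emi_regime <- pool_emigration_by_regime(emigration)

  alpha <- config$alpha %||% alpha_from_movements(movements)
  cpar <- connectivity_params(alpha, xi = config$xi %||% 0.5,
                              buffer_km = config$buffer_km %||% 3,
                              distance_mode = config$distance_mode %||% "centroid")
  conn <- connectivity(dataset$patches, cpar)

  cjs <- per_patch_cjs(dataset, min_marked = config$min_marked %||% 20L,
                       min_transitions = config$min_transitions %||% 5L,
                       seed = seed)
  patch_table <- merge(
    dataset$patches[, c("patch_id", "locality", "regime", "area_m2")],
    conn, by = "patch_id")
  patch_table <- merge(patch_table,
                       cjs$table[, c("patch_id", "phi", "p", "N_total")],
                       by = "patch_id", all.x = TRUE)
  patch_table <- patch_table[order(patch_table$patch_id), ]
  rownames(patch_table) <- NULL

  models <- fit_regime_models(dataset, movements, patch_table)

  meta <- list(seed = seed, n_individuals = length(unique(dataset$records$individual_id)),
               n_captures = nrow(dataset$records),
               n_recaptured = sum(individual_summary(dataset)$recaptured),
               alpha = alpha, elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
  report <- structure(
    list(dataset = dataset, truth = truth, validation = validation,
         movements = movements, emigration = emigration,
         emigration_by_regime = emi_regime, connectivity = conn,
         cjs_table = cjs$table, cjs_fits = cjs$fits,
         patch_table = patch_table, models = models$fits,
         model_tables = models$tables, meta = meta),
    class = "mrr_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Per-patch CJS fits and seasonal population sizes
#'
#' Fits the sex-structured CJS model set to every patch with a large enough
#' sample and derives each patch's recruitment-based seasonal total.
#' Sex-structured models compete by AIC; abundance uses the pooled
#' phi(.)p(.) estimates, since N_i = n_i / p needs a single capture
#' probability. Patches whose pooled fit fails, sits on a boundary or is
#' ineligible are skipped.
#'
#' @param dataset An `mrr_dataset`.
#' @param min_marked,min_transitions Eligibility thresholds (see
#'   [cjs_eligible()]).
#' @param seed Seed for the optimiser starts.
#' @return List with `table` (one row per fitted patch: estimates, AIC,
#'   selected model, `N_total`) and `fits` (the `cjs_fit_set` objects).
#' @export
per_patch_cjs <- function(dataset, min_marked = 20L, min_transitions = 5L,
                          seed = 1L) {
  rows <- list(); fits <- list()
  for (pid in dataset$patches$patch_id) {
    chm <- try(capture_history(dataset, pid), silent = TRUE)
    if (inherits(chm, "try-error")) next
    if (!cjs_eligible(chm, min_marked, min_transitions)) next
    fit <- try(fit_cjs(chm, seed = seed), silent = TRUE)
    if (inherits(fit, "try-error")) next
    pooled <- fit$fits[["phi(.)p(.)"]]
    if (!isTRUE(pooled$convergence) || pooled$boundary) next
    ab <- abundance_estimate(chm, pooled$phi[["all"]], pooled$p[["all"]],
                             pooled$p_se[["all"]])
    fits[[pid]] <- fit
    rows[[pid]] <- data.frame(
      patch_id = pid, n_marked = nrow(chm$ch),
      model = fit$selected,
      phi = pooled$phi[["all"]], phi_se = pooled$phi_se[["all"]],
      p = pooled$p[["all"]], p_se = pooled$p_se[["all"]],
      loglik = pooled$loglik, AIC = pooled$AIC,
      N_total = ab$N_total, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patch_id = character(), n_marked = integer(), model = character(),
               phi = numeric(), phi_se = numeric(), p = numeric(),
               p_se = numeric(), loglik = numeric(), AIC = numeric(),
               N_total = numeric(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

# The four regime-comparison model families, mirroring the field analysis:
# binomial emigration, gamma dispersal and displacement distances, Poisson
# population size, Gaussian survival/capture comparisons.
fit_regime_models <- function(dataset, movements, patch_table) {
  fits <- list(); tables <- list()
  covars <- c("pop_size", "connectivity", "area")
  ptab <- data.frame(patch_id = patch_table$patch_id,
                     locality = patch_table$locality,
                     regime = factor(patch_table$regime, levels = REGIME_LEVELS),
                     area = patch_table$area_m2,
                     connectivity = patch_table$S_j,
                     pop_size = patch_table$N_total,
                     stringsAsFactors = FALSE)

  # individual-level emigration (recaptured individuals only)
  ind <- individual_summary(dataset)
  ind <- ind[ind$recaptured, ]
  emi_dat <- merge(ind, ptab, by.x = "origin_patch", by.y = "patch_id")
  emi_dat <- emi_dat[stats::complete.cases(emi_dat[, covars]), ]
  emi_dat$emigrated <- as.numeric(emi_dat$emigrant)
  emi_dat$sex <- factor(emi_dat$sex, levels = c("F", "M"))
  emi_dat$regime <- factor(emi_dat$regime, levels = REGIME_LEVELS)
  if (nrow(emi_dat) > 50 && length(unique(emi_dat$locality.y)) >= 2) {
    emi_dat$locality <- emi_dat$locality.y
    sc <- scale_covariates(emi_dat, covars)
    f <- emigrated ~ regime + sex + pop_size + connectivity +
      pop_size:connectivity + pop_size:connectivity:area + (1 | locality)
    fits$emigration <- try(fit_glmm(f, sc$data, "binomial", scaling = sc$scaling),
                           silent = TRUE)
  }

  # movement distances with origin-patch covariates
  mv <- merge(movements, ptab, by.x = "origin_patch", by.y = "patch_id")
  mv$regime <- factor(mv$origin_regime, levels = REGIME_LEVELS)
  mv$sex <- factor(mv$sex, levels = c("F", "M"))
  mv <- mv[mv$distance_m > 0, ]
  disp <- mv[mv$kind == "dispersal" & stats::complete.cases(mv[, covars]), ]
  if (nrow(disp) > 30 && length(unique(disp$locality)) >= 2) {
    sc <- scale_covariates(disp, covars)
    fits$dispersal_distance <- try(
      fit_glmm(distance_m ~ regime + sex + area + (1 | locality),
               sc$data, "gamma", scaling = sc$scaling), silent = TRUE)
  }
  displ <- mv[mv$kind == "displacement" & stats::complete.cases(mv[, covars]), ]
  if (nrow(displ) > 30 && length(unique(displ$locality)) >= 2) {
    sc <- scale_covariates(displ, covars)
    fits$displacement_distance <- try(
      fit_glmm(distance_m ~ sex + pop_size + pop_size:area + (1 | locality),
               sc$data, "gamma", scaling = sc$scaling), silent = TRUE)
  }

  # patch-level population size, survival, capture probability
  pt <- ptab[stats::complete.cases(ptab[, c("connectivity", "area", "pop_size")]), ]
  pt <- merge(pt, patch_table[, c("patch_id", "phi", "p")], by = "patch_id")
  if (nrow(pt) >= 10 && length(unique(pt$locality)) >= 2) {
    sc <- scale_covariates(pt, c("connectivity", "area"))
    pt_sc <- sc$data
    pt_sc$N_round <- round(pt_sc$pop_size)
    fits$population_size <- try(
      fit_glmm(N_round ~ regime + connectivity + area + connectivity:area +
                 (1 | locality), pt_sc, "poisson", scaling = sc$scaling),
      silent = TRUE)
    for (resp in c("phi", "p")) {
      f_full <- stats::as.formula(paste(resp, "~ regime + (1 | locality)"))
      f_null <- stats::as.formula(paste(resp, "~ 1 + (1 | locality)"))
      cand <- list(regime = try(fit_glmm(f_full, pt_sc, "gaussian"), silent = TRUE),
                   intercept_only = try(fit_glmm(f_null, pt_sc, "gaussian"),
                                        silent = TRUE))
      cand <- cand[!vapply(cand, inherits, TRUE, "try-error")]
      if (length(cand))
        fits[[paste0(resp, "_comparison")]] <- aic_select(cand)
    }
  }

  fits <- fits[!vapply(fits, inherits, TRUE, "try-error")]
  tables <- lapply(fits, `[[`, "table")
  list(fits = fits, tables = tables)
}

#' @export
print.mrr_report <- function(x, ...) {
  cat("MRR analysis report\n")
  cat("  individuals:", x$meta$n_individuals,
      " captures:", x$meta$n_captures,
      " recaptured:", x$meta$n_recaptured, "\n")
  cat("  alpha (1/km):", round(x$meta$alpha, 3),
      " CJS-eligible patches:", nrow(x$cjs_table), "\n")
  cat("  emigration by regime:\n")
  print(x$emigration_by_regime, digits = 3, row.names = FALSE)
  cat("  fitted models:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' Write all report tables to a directory
#'
#' @param report An `mrr_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  write_movements(report$movements, file.path(out_dir, "movements.csv"))
  w(report$emigration[, setdiff(names(report$emigration), "ring")],
    "emigration.csv")
  w(report$emigration_by_regime, "emigration_by_regime.csv")
  w(report$connectivity, "connectivity.csv")
  w(report$cjs_table, "cjs_per_patch.csv")
  w(report$patch_table, "patch_table.csv")
  for (nm in names(report$model_tables))
    w(report$model_tables[[nm]], paste0("model_", nm, ".csv"))
  invisible(out_dir)
}
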