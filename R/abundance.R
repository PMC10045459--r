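#' Occasion abundance from capture counts and capture probability
#'
#' Jolly-Seber-style estimate: the number alive at occasion i is the number
#' caught divided by the estimated capture probability, N_i = n_i / p-hat,
#' with a delta-method standard error propagating the uncertainty in p-hat.
#'
#' @param chm A `capture_history` (counts n_i are its column sums), or a
#'   numeric vector of per-occasion capture counts.
#' @param p_hat Estimated capture probability (scalar, pooled sexes).
#' @param p_se Standard error of `p_hat` (0 if omitted).
#' @return Data frame `occasion`, `n_i`, `N_i`, `N_se`.
#' @export
occasion_abundance <- function(chm, p_hat, p_se = 0) {
  n_i <- if (is.list(chm)) colSums(chm$ch) else as.numeric(chm)
  if (p_hat <= 0 || p_hat >= 1 + 1e-12) stop("p_hat must lie in (0, 1]")
  N <- n_i / p_hat
  # var(N) = var(n)/p^2 + n^2 var(p)/p^4; binomial var(n) = N p (1-p)
  N_se <- sqrt(N * (1 - p_hat) / p_hat + (n_i^2 * p_se^2) / p_hat^4)
  data.frame(occasion = seq_along(n_i) - 1L, n_i = n_i, N_i = N, N_se = N_se)
}

#' Raw recruitment between occasions
#'
#' B_i = N_{i+1} - phi^{l_i} * N_i: the number of individuals present at
#' occasion i+1 that were not survivors from occasion i. Negative values
#' (sampling noise) are truncated to zero with a warning.
#'
#' @param N Numeric vector of occasion abundances.
#' @param phi Daily survival probability.
#' @param intervals Interval lengths l_i in days (length `length(N) - 1`).
#' @return Numeric vector B of length `length(N) - 1`.
#' @export
recruitment <- function(N, phi, intervals) {
  if (length(intervals) != length(N) - 1L)
    stop("intervals must have length(N) - 1 entries")
  B <- N[-1L] - phi^intervals * N[-length(N)]
  if (any(B < 0)) {
    warning(sum(B < 0), " negative raw recruitment value(s) truncated to 0")
    B <- pmax(B, 0)
  }
  B
}

#' Correction factor for within-interval mortality of recruits
#'
#' Individuals that emerge between two capture days and die before the next
#' one are invisible to the raw recruitment B_i. Under uniform daily
#' emergence within the interval and daily survival phi, the expected
#' fraction of an interval's recruits still alive at its end is
#' (1 - phi^l) / (l * (1 - phi)), so the corrected recruitment is
#' B*_i = B_i * l_i * (1 - phi) / (1 - phi^l_i). The factor is 1 at l = 1
#' and in the limit phi -> 1, and grows with the interval length.
#'
#' @param B Raw recruitment values.
#' @param phi Daily survival in (0, 1].
#' @param intervals Interval lengths in days (recycled against B).
#' @return Corrected recruitment B*.
#' @export
corrected_recruitment <- function(B, phi, intervals) {
  factor <- recruitment_correction_factor(phi, intervals)
  B * factor
}

#' @rdname corrected_recruitment
#' @export
recruitment_correction_factor <- function(phi, intervals) {
  if (any(intervals < 1)) stop("intervals must be >= 1 day")
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]")
  if (phi == 1) return(rep(1, length(intervals)))
  ifelse(intervals == 1, 1, intervals * (1 - phi) / (1 - phi^intervals))
}

#' Seasonal total population size
#'
#' N_total = N_1 + sum of corrected recruitments: every individual alive
#' during the season was either already present at the first occasion or
#' recruited later.
#'
#' @param N Occasion abundance vector.
#' @param B_star Corrected recruitment vector (length `length(N) - 1`).
#' @return N_total.
#' @export
total_population <- function(N, B_star) {
  N[1L] + sum(B_star)
}

#' Full abundance estimate for one capture-history matrix
#'
#' Chains [occasion_abundance()], [recruitment()], [corrected_recruitment()]
#' and [total_population()] for the pooled-sex CJS estimates of one patch.
#'
#' @param chm A `capture_history`.
#' @param phi,p Daily survival and capture probability estimates.
#' @param p_se SE of p (for the N_i standard errors).
#' @return List of class `abundance_estimate` with the per-occasion `table`
#'   (`occasion`, `n_i`, `N_i`, `N_se`, `B_i`, `B_star_i`) and `N_total`.
#' @export
abundance_estimate <- function(chm, phi, p, p_se = 0) {
  ab <- occasion_abundance(chm, p, p_se)
  B <- suppressWarnings(recruitment(ab$N_i, phi, chm$intervals))
  B_star <- corrected_recruitment(B, phi, chm$intervals)
  ab$B_i <- c(NA, B)
  ab$B_star_i <- c(NA, B_star)
  structure(list(table = ab, N_total = total_population(ab$N_i, B_star),
                 phi = phi, p = p),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat("Abundance estimate: N_total =", round(x$N_total, 1),
      "over", nrow(x$table), "occasions (phi =", round(x$phi, 3),
      ", p =", round(x$p, 3), ")\n")
  invisible(x)
}
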