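#' Configuration of the synthetic MRR study
#'
#' Defaults describe a metapopulation MRR season of a short-lived meadow
#' butterfly: 46 rectangular habitat patches in 5 localities, a 41-day
#' season sampled daily with weather gaps of at most 3 days, daily survival
#' 0.79, per-occasion capture probability 0.32, per-lifetime emigration
#' probabilities of 0.22 / 0.16 / 0.09 for mown / recovered / unmown
#' patches, dispersal-distance kernel means of 102 / 198 / 246 m for the
#' same regimes, and within-patch daily displacement step means of 57 m
#' (females) and 43 m (males).
#'
#' @param n_patches,n_localities Patch network size.
#' @param area_range_m2 Log-uniform patch-area bounds (median 0.9 ha).
#' @param regime_probs Named proportions of the three mowing regimes.
#' @param flight_start First day of the season (ISO date).
#' @param season_days Season length in days.
#' @param gap_prob Daily probability that a session is lost to weather.
#' @param max_interval Largest allowed gap between sessions (days).
#' @param phi Daily survival probability.
#' @param p Per-occasion capture probability.
#' @param emigration_lifetime Named per-regime probabilities that a
#'   recaptured individual is ever recaptured outside its patch of first
#'   capture; converted internally to daily emigration hazards through the
#'   observation model (see [calibrate_emigration_hazard()]).
#' @param dispersal_mean_m Named per-regime means of the dispersal step
#'   kernel (m).
#' @param displacement_mean_m Named per-sex means of the daily within-patch
#'   step (m).
#' @param step_shape Gamma shape of all step kernels.
#' @param sex_ratio Proportion of females.
#' @param n_emerge Expected number of individuals emerging over the season.
#' @param unmown_abundance_mult Relative per-area emergence density of
#'   unmown patches (unmown meadows host roughly twice as many adults).
#' @param alpha,xi,buffer_km Connectivity kernel used for destination
#'   choice (alpha in 1/km).
#' @param locality_log_sd SD of the log-scale locality random effect used by
#'   the event-level simulators.
#' @param origin_lon,origin_lat Anchor of the local metric frame.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patches = 46L, n_localities = 5L,
                       area_range_m2 = c(900, 90000),
                       regime_probs = c(unmown = 0.4, recovered = 0.3, mown = 0.3),
                       flight_start = "2014-07-19", season_days = 41L,
                       gap_prob = 0.15, max_interval = 3L,
                       phi = 0.79, p = 0.32,
                       emigration_lifetime = c(unmown = 0.09, recovered = 0.16,
                                               mown = 0.22),
                       dispersal_mean_m = c(unmown = 246, recovered = 198,
                                            mown = 102),
                       displacement_mean_m = c(F = 57, M = 43),
                       step_shape = 2, sex_ratio = 0.5,
                       n_emerge = 5800L, unmown_abundance_mult = 2,
                       alpha = 1 / 0.18, xi = 0.5, buffer_km = 3,
                       locality_log_sd = 0.04,
                       origin_lon = 19.80, origin_lat = 46.10) {
  stopifnot(phi > 0, phi < 1, p > 0, p <= 1,
            all(emigration_lifetime > 0), all(emigration_lifetime < 1),
            all(dispersal_mean_m > 0), all(displacement_mean_m > 0),
            season_days >= 2L, n_localities >= 1L,
            n_patches >= n_localities)
  structure(as.list(environment()), class = "sim_config")
}

# Locality centres in the metric frame (m): an irregular spread with
# within-locality scales of a few hundred metres and between-locality
# separations of 2.5 km and more, as in a fragmented meadow landscape.
locality_centres <- function(n) {
  base <- cbind(x = c(0, 2600, 5200, 1300, 3900, 6500, 0, 2600),
                y = c(0, 900, 0, 3000, 2800, 2900, 5600, 5800))
  base[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic patch network
#'
#' Non-overlapping rectangular patches are packed around locality centres;
#' areas are drawn log-uniformly (median 0.9 ha by default) and regimes are
#' assigned to the configured proportions, with every locality containing
#' each regime at least once when it holds three or more patches.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return An `mrr_patches` data frame with additional metric-frame columns
#'   (`xmin`, `xmax`, `ymin`, `ymax`) and the frame anchor in
#'   `attr(, "frame_origin")`.
#' @export
generate_patches <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frame <- local_frame(config$origin_lon, config$origin_lat)
  n <- config$n_patches
  nl <- config$n_localities
  per_loc <- diff(round(seq(0, n, length.out = nl + 1L)))
  centres <- locality_centres(nl)
  loc_names <- LETTERS[seq_len(nl)]

  rows <- list(); k <- 0L
  for (li in seq_len(nl)) {
    placed <- matrix(numeric(0), 0, 4)  # xmin xmax ymin ymax
    # stratified regime assignment: one of each first, then multinomial
    m <- per_loc[li]
    regs <- character(m)
    base <- rep(names(config$regime_probs), length.out = min(3L, m))
    regs[seq_along(base)] <- base
    if (m > 3L)
      regs[4:m] <- sample(names(config$regime_probs), m - 3L, replace = TRUE,
                          prob = config$regime_probs)
    regs <- sample(regs)
    for (pi in seq_len(m)) {
      area <- exp(stats::runif(1, log(config$area_range_m2[1]),
                               log(config$area_range_m2[2])))
      aspect <- exp(stats::runif(1, log(0.5), log(2)))
      w <- sqrt(area * aspect); h <- area / w
      ok <- FALSE
      for (try in seq_len(400L)) {
        cx <- centres[li, 1] + stats::runif(1, -700, 700)
        cy <- centres[li, 2] + stats::runif(1, -700, 700)
        rect <- c(cx - w / 2, cx + w / 2, cy - h / 2, cy + h / 2)
        if (nrow(placed) == 0L ||
            !any(rect[1] < placed[, 2] + 20 & rect[2] > placed[, 1] - 20 &
                   rect[3] < placed[, 4] + 20 & rect[4] > placed[, 3] - 20)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place patch ", k + 1L,
                    " without overlap; reduce n_patches or areas")
      placed <- rbind(placed, rect)
      k <- k + 1L
      ring_xy <- rbind(c(rect[1], rect[3]), c(rect[2], rect[3]),
                       c(rect[2], rect[4]), c(rect[1], rect[4]),
                       c(rect[1], rect[3]))
      ring <- frame$to_lonlat(ring_xy[, 1], ring_xy[, 2])
      colnames(ring) <- NULL
      cen <- polygon_centroid(ring)
      rows[[k]] <- list(patch_id = sprintf("P%02d", k),
                        locality = loc_names[li], regime = regs[pi],
                        area_m2 = polygon_area_m2(ring),
                        centroid_lon = cen[1], centroid_lat = cen[2],
                        ring = ring, rect = rect)
    }
  }
  patches <- data.frame(
    patch_id = vapply(rows, `[[`, "", "patch_id"),
    locality = vapply(rows, `[[`, "", "locality"),
    regime = vapply(rows, `[[`, "", "regime"),
    mowing_date = as.Date(NA),
    area_m2 = vapply(rows, `[[`, 0, "area_m2"),
    centroid_lon = vapply(rows, `[[`, 0, "centroid_lon"),
    centroid_lat = vapply(rows, `[[`, 0, "centroid_lat"),
    xmin = vapply(rows, function(r) r$rect[1], 0),
    xmax = vapply(rows, function(r) r$rect[2], 0),
    ymin = vapply(rows, function(r) r$rect[3], 0),
    ymax = vapply(rows, function(r) r$rect[4], 0),
    stringsAsFactors = FALSE)
  patches$ring <- lapply(rows, `[[`, "ring")
  attr(patches, "frame_origin") <- c(lon = config$origin_lon,
                                     lat = config$origin_lat)
  class(patches) <- c("mrr_patches", class(patches))
  patches
}

#' Daily emigration hazard matching a target observed emigration fraction
#'
#' The emigration probability reported by [emigration_table()] is an
#' observed quantity: the fraction of recaptured individuals ever recaptured
#' outside their patch of first capture. Because individuals are watched
#' only between their first and last captures, a naive lifetime-to-daily
#' hazard conversion understates the observed fraction's complement of
#' detection. This routine inverts the full observation model instead: a
#' day-by-day absorbing-state recursion over the occasion calendar computes,
#' for a given daily hazard `h`, the expected fraction of recaptured
#' individuals with at least one post-move capture, and the hazard is solved
#' so that this fraction equals `target`.
#'
#' @param target Observed emigration fraction to realise.
#' @param phi Daily survival.
#' @param p Per-occasion capture probability.
#' @param occ Logical vector over season days: capture session held that day.
#' @param emergence_w Non-negative emergence weights over season days.
#' @return Daily emigration hazard in (0, 1).
#' @export
calibrate_emigration_hazard <- function(target, phi, p, occ, emergence_w) {
  f <- function(h) expected_emigrant_fraction(h, phi, p, occ, emergence_w)
  if (f(0.9) < target)
    stop("target emigration fraction ", target, " not reachable")
  stats::uniroot(function(h) f(h) - target, c(1e-8, 0.9), tol = 1e-10)$root
}

#' @rdname calibrate_emigration_hazard
#' @param h Daily emigration hazard.
#' @export
expected_emigrant_fraction <- function(h, phi, p, occ, emergence_w) {
  T <- length(occ)
  emergence_w <- emergence_w / sum(emergence_w)
  # backward recursions from the season end; states: away (A), home and
  # counting away-captures only (He), home and counting any capture (Hr)
  PA <- PHe <- PHr <- numeric(T + 1L)
  for (d in T:1L) {
    contA <- phi * PA[d + 1L]
    PA[d] <- if (occ[d]) p + (1 - p) * contA else contA
    PHe[d] <- phi * (h * PA[d + 1L] + (1 - h) * PHe[d + 1L])
    contH <- phi * (h * PA[d + 1L] + (1 - h) * PHr[d + 1L])
    PHr[d] <- if (occ[d]) p + (1 - p) * contH else contH
  }
  # weight by the distribution of the first-capture day
  num <- den <- 0
  occ_days <- which(occ)
  for (e in seq_len(T)) {
    if (emergence_w[e] == 0) next
    prior_missed <- 1
    for (t in occ_days[occ_days >= e]) {
      w_first <- emergence_w[e] * phi^(t - e) * prior_missed * p
      em_t <- phi * (h * PA[t + 1L] + (1 - h) * PHe[t + 1L])
      rec_t <- phi * (h * PA[t + 1L] + (1 - h) * PHr[t + 1L])
      num <- num + w_first * em_t
      den <- den + w_first * rec_t
      prior_missed <- prior_missed * (1 - p)
    }
  }
  if (den == 0) return(0)
  num / den
}

# Occasion-day pattern for a season: first and last day always sampled,
# interior days dropped with prob gap_prob subject to the max-gap bound.
draw_occasion_days <- function(T, gap_prob, max_interval) {
  occ <- rep(TRUE, T)
  last_kept <- 1L
  if (T > 2L) for (d in 2L:(T - 1L)) {
    if (d - last_kept < max_interval && stats::runif(1) < gap_prob)
      occ[d] <- FALSE
    else last_kept <- d
  }
  occ
}

#' Simulate a full mark-release-recapture season
#'
#' Individual-based daily simulation over a patch network: individuals
#' emerge on a peaked seasonal curve at rates proportional to patch area
#' (unmown patches at twice the density), survive each night with
#' probability `phi`, emigrate with a regime-specific daily hazard to a
#' neighbouring patch chosen with weight `exp(-alpha d) * A^xi`, move by
#' gamma-distributed steps (regime-mean steps between patches, sex-mean
#' steps within), and on session days every individual alive is captured
#' with probability `p` at its current coordinates.
#'
#' @param config A [sim_config()].
#' @param patches Optional pre-generated patch network; generated from
#'   `config` when omitted.
#' @param seed Integer seed driving the whole simulation.
#' @return List with `dataset` (an `mrr_dataset`) and `truth` (generating
#'   parameters, daily hazards used, per-patch ever-alive counts and totals).
#' @export
simulate_mrr <- function(config, patches = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(patches)) patches <- generate_patches(config, seed = NULL)
  frame <- local_frame(config$origin_lon, config$origin_lat)
  T <- config$season_days
  occ <- draw_occasion_days(T, config$gap_prob, config$max_interval)
  dates <- as.Date(config$flight_start) + seq_len(T) - 1L
  emergence_w <- stats::dbeta((seq_len(T) - 0.5) / T, 2, 2)

  hazards <- vapply(REGIME_LEVELS, function(r)
    calibrate_emigration_hazard(config$emigration_lifetime[[r]], config$phi,
                                config$p, occ, emergence_w), 0)

  # expected emergences per patch: proportional to area, unmown patches
  # at unmown_abundance_mult times the density
  dens <- ifelse(patches$regime == "unmown", config$unmown_abundance_mult, 1)
  lam <- patches$area_m2 * dens
  lam <- lam / sum(lam) * config$n_emerge
  n_k <- stats::rpois(nrow(patches), lam)
  n_ind <- sum(n_k)
  natal <- rep(seq_len(nrow(patches)), n_k)
  sex <- sample(c("F", "M"), n_ind, replace = TRUE,
                prob = c(config$sex_ratio, 1 - config$sex_ratio))
  e_day <- sample(seq_len(T), n_ind, replace = TRUE, prob = emergence_w)

  # destination weights for emigration: exp(-alpha d) * A^xi within buffer
  cen <- cbind((patches$xmin + patches$xmax) / 2,
               (patches$ymin + patches$ymax) / 2)
  D_km <- as.matrix(stats::dist(cen)) / 1000
  Wdest <- exp(-config$alpha * D_km) *
    matrix(patches$area_m2^config$xi, nrow(cen), nrow(cen), byrow = TRUE)
  Wdest[D_km > config$buffer_km] <- 0
  diag(Wdest) <- 0

  px <- stats::runif(n_ind, patches$xmin[natal] + 0.5, patches$xmax[natal] - 0.5)
  py <- stats::runif(n_ind, patches$ymin[natal] + 0.5, patches$ymax[natal] - 0.5)
  patch_of <- natal
  alive <- rep(TRUE, n_ind)
  shape <- config$step_shape
  disp_mean <- config$dispersal_mean_m[patches$regime]
  sex_mean <- config$displacement_mean_m[sex]

  cap_ind <- integer(0); cap_day <- integer(0)
  cap_x <- numeric(0); cap_y <- numeric(0); cap_patch <- integer(0)

  for (d in seq_len(T)) {
    act <- which(alive & e_day <= d)
    if (!length(act)) next
    if (occ[d]) {
      caught <- act[stats::runif(length(act)) < config$p]
      if (length(caught)) {
        cap_ind <- c(cap_ind, caught)
        cap_day <- c(cap_day, rep(d, length(caught)))
        cap_x <- c(cap_x, px[caught]); cap_y <- c(cap_y, py[caught])
        cap_patch <- c(cap_patch, patch_of[caught])
      }
    }
    # overnight: survival, then movement
    die <- act[stats::runif(length(act)) >= config$phi]
    alive[die] <- FALSE
    act <- setdiff(act, die)
    if (!length(act)) next
    hz <- hazards[patches$regime[patch_of[act]]]
    mig <- act[stats::runif(length(act)) < hz]
    stay <- setdiff(act, mig)
    for (i in mig) {
      w <- Wdest[patch_of[i], ]
      if (sum(w) == 0) { stay <- c(stay, i); next }
      dest <- sample.int(length(w), 1L, prob = w)
      dx <- cen[dest, 1] - px[i]; dy <- cen[dest, 2] - py[i]
      nrm <- sqrt(dx^2 + dy^2)
      step <- stats::rgamma(1, shape, rate = shape / disp_mean[patch_of[i]])
      nx <- px[i] + step * dx / nrm; ny <- py[i] + step * dy / nrm
      px[i] <- min(max(nx, patches$xmin[dest] + 0.5), patches$xmax[dest] - 0.5)
      py[i] <- min(max(ny, patches$ymin[dest] + 0.5), patches$ymax[dest] - 0.5)
      patch_of[i] <- dest
    }
    if (length(stay)) {
      step <- stats::rgamma(length(stay), shape, rate = shape / sex_mean[stay])
      ang <- stats::runif(length(stay), 0, 2 * pi)
      nx <- px[stay] + step * cos(ang); ny <- py[stay] + step * sin(ang)
      pp <- patch_of[stay]
      px[stay] <- pmin(pmax(nx, patches$xmin[pp] + 0.5), patches$xmax[pp] - 0.5)
      py[stay] <- pmin(pmax(ny, patches$ymin[pp] + 0.5), patches$ymax[pp] - 0.5)
    }
  }

  if (!length(cap_ind)) stop("simulation produced no captures")
  lonlat <- frame$to_lonlat(cap_x, cap_y)
  records <- data.frame(
    individual_id = sprintf("ind%05d", cap_ind),
    date = dates[cap_day],
    sex = sex[cap_ind],
    patch_id = patches$patch_id[cap_patch],
    lon = lonlat[, 1], lat = lonlat[, 2],
    stringsAsFactors = FALSE)
  calendar <- occasion_calendar(dates[occ], config$max_interval)
  dataset <- mrr_dataset(records, patches, calendar = calendar)
  truth <- list(
    seed = seed, phi = config$phi, p = config$p,
    daily_emigration_hazard = hazards,
    emigration_lifetime = config$emigration_lifetime,
    dispersal_mean_m = config$dispersal_mean_m,
    displacement_mean_m = config$displacement_mean_m,
    n_emerged = n_ind,
    ever_alive_by_patch = stats::setNames(n_k, patches$patch_id),
    n_marked = length(unique(cap_ind)),
    occasion_days = which(occ))
  list(dataset = dataset, truth = truth)
}

#' Simulate dispersal events with regime-specific distance kernels
#'
#' Event-level generator for distance-model recovery: `n_per_regime`
#' between-patch movements per mowing regime, distances gamma-distributed
#' around the regime kernel mean with a log-normal locality random effect,
#' sexes balanced (the kernels are sex-neutral so that the regime means are
#' the marginal generating means).
#'
#' @param n_per_regime Events per regime.
#' @param config A [sim_config()] supplying kernel means, gamma shape,
#'   locality count and locality effect SD.
#' @param seed Integer seed.
#' @return Data frame `distance_m`, `regime`, `sex`, `locality`.
#' @export
simulate_dispersal_events <- function(n_per_regime = 500L,
                                      config = sim_config(), seed = 1L) {
  simulate_events(config$dispersal_mean_m[REGIME_LEVELS], "regime",
                  n_per_regime, config, seed)
}

#' Simulate within-patch displacement events with sex-specific step kernels
#'
#' @param n_per_sex Events per sex.
#' @inheritParams simulate_dispersal_events
#' @return Data frame `distance_m`, `regime` (balanced labels), `sex`,
#'   `locality`.
#' @export
simulate_displacement_events <- function(n_per_sex = 1000L,
                                         config = sim_config(), seed = 1L) {
  simulate_events(config$displacement_mean_m[c("F", "M")], "sex",
                  n_per_sex, config, seed)
}

simulate_events <- function(means, by, n_each, config, seed) {
  set.seed(seed)
  lev <- names(means)
  n <- n_each * length(lev)
  loc <- sample(LETTERS[seq_len(config$n_localities)], n, replace = TRUE)
  b_loc <- stats::setNames(
    stats::rnorm(config$n_localities, 0, config$locality_log_sd),
    LETTERS[seq_len(config$n_localities)])
  grp <- rep(lev, each = n_each)
  mu <- means[grp] * exp(b_loc[loc])
  d <- stats::rgamma(n, config$step_shape, rate = config$step_shape / mu)
  out <- data.frame(
    distance_m = d,
    regime = if (by == "regime") factor(grp, levels = REGIME_LEVELS)
             else factor(sample(REGIME_LEVELS, n, replace = TRUE),
                         levels = REGIME_LEVELS),
    sex = if (by == "sex") factor(grp, levels = c("F", "M"))
          else factor(sample(c("F", "M"), n, replace = TRUE),
                      levels = c("F", "M")),
    locality = loc, stringsAsFactors = FALSE)
  out
}
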