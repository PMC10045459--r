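#' Classify movements into displacement and dispersal
#'
#' For every individual with two or more captures, each consecutive capture
#' pair yields one movement event. A movement that stays within one habitat
#' patch is a displacement; a movement during which the individual changes
#' patch is a dispersal. Distances are geodesic distances between the two
#' capture coordinates.
#'
#' @param dataset An `mrr_dataset`.
#' @return Data frame with one row per movement event: `individual_id`,
#'   `kind` (`"displacement"`/`"dispersal"`), `origin_patch`, `dest_patch`,
#'   `origin_regime`, `sex` (sex at first capture), `from_occasion`,
#'   `to_occasion`, `distance_m`.
#' @export
classify_movements <- function(dataset) {
  rec <- dataset$records  # already ordered by individual, occasion
  n <- nrow(rec)
  if (n < 2L) return(empty_movements())
  same_ind <- rec$individual_id[-n] == rec$individual_id[-1L]
  i <- which(same_ind)            # row index of the 'from' capture
  if (!length(i)) return(empty_movements())
  j <- i + 1L
  d <- geodesic_distance_m(cbind(rec$lon[i], rec$lat[i]),
                           cbind(rec$lon[j], rec$lat[j]))
  first_sex <- rec$sex[!duplicated(rec$individual_id)]
  names(first_sex) <- rec$individual_id[!duplicated(rec$individual_id)]
  regime <- dataset$patches$regime[match(rec$patch_id[i], dataset$patches$patch_id)]
  out <- data.frame(
    individual_id = rec$individual_id[i],
    kind = ifelse(rec$patch_id[i] == rec$patch_id[j], "displacement", "dispersal"),
    origin_patch = rec$patch_id[i],
    dest_patch = rec$patch_id[j],
    origin_regime = regime,
    sex = unname(first_sex[rec$individual_id[i]]),
    from_occasion = rec$occasion[i],
    to_occasion = rec$occasion[j],
    distance_m = d,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_movements <- function() {
  data.frame(individual_id = character(), kind = character(),
             origin_patch = character(), dest_patch = character(),
             origin_regime = character(), sex = character(),
             from_occasion = integer(), to_occasion = integer(),
             distance_m = numeric(), stringsAsFactors = FALSE)
}

#' Per-patch emigration table
#'
#' Emigration (dispersal) probability of a patch is the proportion of
#' individuals first captured there and later recaptured in a different
#' patch, among all recaptured individuals originating from the patch
#' (including those only ever recaptured in the natal patch). Individuals
#' never recaptured do not enter the denominator; a patch with no recaptured
#' individuals gets `NA` (undefined), not 0.
#'
#' @param dataset An `mrr_dataset`.
#' @param by_sex If `TRUE`, add per-sex rows (sex at first capture).
#' @return Data frame with `patch_id`, `regime`, `locality`, optionally
#'   `sex`, `n_recaptured`, `n_emigrants`, `emigration_probability`.
#' @export
emigration_table <- function(dataset, by_sex = FALSE) {
  ind <- individual_summary(dataset)
  tab_for <- function(dat) {
    agg <- lapply(split(dat, dat$origin_patch), function(d) {
      data.frame(patch_id = d$origin_patch[1],
                 n_recaptured = sum(d$recaptured),
                 n_emigrants = sum(d$emigrant), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  }
  base <- dataset$patches[, c("patch_id", "regime", "locality")]
  if (!by_sex) {
    tab <- tab_for(ind)
    out <- merge(base, tab, by = "patch_id", all.x = TRUE, sort = TRUE)
  } else {
    tabs <- lapply(split(ind, ind$sex), tab_for)
    out <- do.call(rbind, lapply(names(tabs), function(s) {
      m <- merge(base, tabs[[s]], by = "patch_id", all.x = TRUE, sort = TRUE)
      m$sex <- s
      m
    }))
  }
  out$n_recaptured[is.na(out$n_recaptured)] <- 0L
  out$n_emigrants[is.na(out$n_emigrants)] <- 0L
  out$emigration_probability <-
    ifelse(out$n_recaptured > 0, out$n_emigrants / out$n_recaptured, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("mrr_emigration", class(out))
  out
}

#' Per-individual capture summary
#'
#' One row per individual: natal (first-capture) patch and its regime, sex at
#' first capture, number of captures, whether the individual was ever
#' recaptured, and whether any recapture happened outside the natal patch.
#'
#' @param dataset An `mrr_dataset`.
#' @return Data frame keyed by `individual_id`.
#' @export
individual_summary <- function(dataset) {
  rec <- dataset$records
  first <- !duplicated(rec$individual_id)
  n_caps <- as.integer(table(rec$individual_id)[rec$individual_id[first]])
  origin <- rec$patch_id[first]
  ids <- rec$individual_id[first]
  moved <- tapply(rec$patch_id, rec$individual_id,
                  function(p) any(p != p[1]))[ids]
  out <- data.frame(
    individual_id = ids,
    origin_patch = origin,
    origin_regime = dataset$patches$regime[match(origin, dataset$patches$patch_id)],
    locality = dataset$patches$locality[match(origin, dataset$patches$patch_id)],
    sex = rec$sex[first],
    first_occasion = rec$occasion[first],
    n_captures = n_caps,
    recaptured = n_caps > 1L,
    emigrant = unname(moved),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pool emigration counts by mowing regime
#'
#' @param emi An emigration table from [emigration_table()].
#' @return Data frame with one row per regime: pooled `n_recaptured`,
#'   `n_emigrants`, `emigration_probability` and its binomial SE.
#' @export
pool_emigration_by_regime <- function(emi) {
  out <- do.call(rbind, lapply(split(emi, emi$regime), function(d) {
    n <- sum(d$n_recaptured); k <- sum(d$n_emigrants)
    p <- if (n > 0) k / n else NA_real_
    data.frame(regime = d$regime[1], n_recaptured = n, n_emigrants = k,
               emigration_probability = p,
               se = if (n > 0) sqrt(p * (1 - p) / n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[match(intersect(REGIME_LEVELS, out$regime), out$regime), ]
  rownames(out) <- NULL
  out
}

#' Export movement events as CSV
#'
#' @param movements Data frame from [classify_movements()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_movements <- function(movements, path) {
  utils::write.csv(
    movements[, c("individual_id", "kind", "origin_patch", "dest_patch",
                  "origin_regime", "sex", "distance_m")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
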