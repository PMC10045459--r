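#' Occasion calendar for a capture-session series
#'
#' Builds the occasion calendar from the distinct session dates: occasions are
#' indexed from 0 in date order and `intervals` holds the gap in days between
#' consecutive occasions (the `l_i` used for interval survival `phi^l_i`).
#'
#' @param dates Vector of `Date`s (or ISO-8601 strings), one per session;
#'   duplicates are collapsed.
#' @param max_interval Largest permissible gap in days between sessions;
#'   larger gaps are flagged by [validate_dataset()].
#' @return An object of class `mrr_calendar` with elements `dates`,
#'   `occasions` (0-based integer indices) and `intervals`.
#' @export
occasion_calendar <- function(dates, max_interval = 3L) {
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) < 1L) stop("calendar needs at least one date")
  l <- as.integer(diff(dates))
  if (any(l < 1L)) stop("calendar dates must be strictly increasing")
  structure(
    list(dates = dates, occasions = seq_along(dates) - 1L, intervals = l,
         max_interval = as.integer(max_interval)),
    class = "mrr_calendar")
}

#' @export
print.mrr_calendar <- function(x, ...) {
  cat("Occasion calendar:", length(x$dates), "occasions,",
      format(x$dates[1]), "to", format(x$dates[length(x$dates)]), "\n")
  if (length(x$intervals))
    cat("Intervals (days): ", paste(x$intervals, collapse = " "), "\n")
  invisible(x)
}

#' Assign a mowing regime from the mowing date
#'
#' Patches never mown in the season are `unmown`; patches mown at least
#' `threshold_days` before the start of the flight period have had time for
#' the host plants to reflower and are `recovered`; patches mown later than
#' that are `mown`.
#'
#' @param mowing_date `Date` (or string) of the mowing event, or `NA`/`NULL`
#'   for patches that were not mown.
#' @param flight_start `Date` on which the investigated flight period starts.
#' @param flight_end Optional last date of the flight period; a mowing date
#'   after it is rejected.
#' @param threshold_days Days of regrowth required to count as recovered
#'   (default 15).
#' @return One of `"unmown"`, `"recovered"`, `"mown"`.
#' @export
assign_regime <- function(mowing_date, flight_start, flight_end = NULL,
                          threshold_days = 15L) {
  if (threshold_days < 0) stop("threshold_days must be >= 0")
  if (is.null(mowing_date) || length(mowing_date) == 0L || is.na(mowing_date))
    return("unmown")
  mowing_date <- as.Date(mowing_date)
  flight_start <- as.Date(flight_start)
  if (!is.null(flight_end) && mowing_date > as.Date(flight_end))
    stop("mowing_date falls after the end of the flight season")
  if (as.integer(flight_start - mowing_date) >= threshold_days) "recovered" else "mown"
}

REGIME_LEVELS <- c("unmown", "recovered", "mown")

#' Read habitat patches from GeoJSON
#'
#' Expects a FeatureCollection of polygons with properties `patch_id`,
#' `locality` and either `regime` or `mowing_date`. When both are present the
#' explicit `regime` wins (with a warning on conflict with the derived one).
#' Areas are computed from the polygon rings on the WGS84 ellipsoid.
#'
#' @param path Path to a GeoJSON file.
#' @param flight_start Flight-period start used when regimes must be derived
#'   from `mowing_date`; defaults to `NULL`, in which case a missing `regime`
#'   property is an error.
#' @param threshold_days Passed to [assign_regime()].
#' @return A data frame of class `mrr_patches` with columns `patch_id`,
#'   `locality`, `regime`, `mowing_date`, `area_m2`, `centroid_lon`,
#'   `centroid_lat` and a list column `ring` of lon/lat vertex matrices.
#' @export
read_patches <- function(path, flight_start = NULL, threshold_days = 15L) {
  if (!file.exists(path)) stop("patches file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("patches GeoJSON must be a FeatureCollection")
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    pr <- f$properties
    if (is.null(pr$patch_id)) stop("patch feature missing patch_id property")
    geom <- f$geometry
    if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon"))
      stop("patch ", pr$patch_id, ": geometry must be Polygon")
    ring <- geom$coordinates[[1]]
    if (geom$type == "MultiPolygon") ring <- ring[[1]]
    ring <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (!ring_is_valid(ring))
      stop("patch ", pr$patch_id, ": invalid polygon (self-intersecting or degenerate)")
    mow <- if (!is.null(pr$mowing_date)) as.Date(pr$mowing_date) else as.Date(NA)
    regime <- pr$regime
    if (is.null(regime)) {
      if (is.null(flight_start))
        stop("patch ", pr$patch_id, ": no regime property and no flight_start to derive it")
      regime <- assign_regime(mow, flight_start, threshold_days = threshold_days)
    } else if (!is.na(mow) && !is.null(flight_start)) {
      derived <- assign_regime(mow, flight_start, threshold_days = threshold_days)
      if (derived != regime)
        warning("patch ", pr$patch_id, ": explicit regime '", regime,
                "' overrides regime derived from mowing_date ('", derived, "')")
    }
    if (!regime %in% REGIME_LEVELS)
      stop("patch ", pr$patch_id, ": unknown regime '", regime, "'")
    cen <- polygon_centroid(ring)
    list(patch_id = as.character(pr$patch_id),
         locality = as.character(pr$locality %||% ""),
         regime = regime, mowing_date = mow,
         area_m2 = polygon_area_m2(ring),
         centroid_lon = cen[1], centroid_lat = cen[2], ring = ring)
  })
  patches <- data.frame(
    patch_id = vapply(rows, `[[`, "", "patch_id"),
    locality = vapply(rows, `[[`, "", "locality"),
    regime = vapply(rows, `[[`, "", "regime"),
    mowing_date = as.Date(vapply(rows, function(r) as.character(r$mowing_date),
                                 NA_character_)),
    area_m2 = vapply(rows, `[[`, 0, "area_m2"),
    centroid_lon = vapply(rows, `[[`, 0, "centroid_lon"),
    centroid_lat = vapply(rows, `[[`, 0, "centroid_lat"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(patches$patch_id))
    stop("duplicate patch_id in patches file")
  if (any(patches$locality == ""))
    stop("patch with empty locality")
  patches$ring <- lapply(rows, `[[`, "ring")
  class(patches) <- c("mrr_patches", class(patches))
  patches
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal representation that parses back to the same double,
# so written files round-trip bit-identically
format_shortest <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write habitat patches to GeoJSON
#'
#' Inverse of [read_patches()]; vertex coordinates are written with enough
#' digits for a bit-stable round trip.
#'
#' @param patches An `mrr_patches` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patches <- function(patches, path) {
  feats <- lapply(seq_len(nrow(patches)), function(i) {
    ring <- close_ring(patches$ring[[i]])
    props <- list(patch_id = patches$patch_id[i],
                  locality = patches$locality[i],
                  regime = patches$regime[i])
    if (!is.na(patches$mowing_date[i]))
      props$mowing_date <- format(patches$mowing_date[i])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  txt <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                          auto_unbox = TRUE, digits = NA)
  writeLines(txt, path)
  invisible(path)
}

RECORD_COLS <- c("individual_id", "date", "sex", "patch_id", "lon", "lat")

#' Read capture records from delimited text
#'
#' @param path CSV/TSV with header
#'   `individual_id,date,sex,patch_id,lon,lat` (an `occasion` column, if
#'   present, is ignored and re-derived from the dates).
#' @param sep Field separator; inferred from the extension by default.
#' @return Data frame of capture records (no occasion index yet).
#' @export
read_records <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("records file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character")
  missing <- setdiff(RECORD_COLS, names(rec))
  if (length(missing))
    stop("records file missing required column(s): ",
         paste(missing, collapse = ", "))
  rec$lon <- as.numeric(rec$lon)
  rec$lat <- as.numeric(rec$lat)
  if (anyNA(rec$lon) || anyNA(rec$lat)) stop("unparseable coordinate in records file")
  if ("occasion" %in% names(rec)) rec$occasion <- as.integer(rec$occasion)
  rec$date <- as.Date(rec$date)
  if (anyNA(rec$date)) stop("unparseable date in records file")
  if (!all(rec$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  rec
}

#' Assemble and validate an MRR dataset
#'
#' Reads capture records and patch polygons, infers the occasion calendar
#' from the distinct record dates, attaches 0-based occasion indices, and
#' enforces the structural invariants (known patch ids, unique
#' individual-by-occasion captures).
#'
#' @param records_path Delimited-text capture records (see [read_records()]).
#' @param patches_path GeoJSON patches file (see [read_patches()]).
#' @param flight_start,threshold_days Passed to [read_patches()] for regime
#'   derivation; `flight_start` defaults to the first record date.
#' @param max_interval Calendar gap bound in days (default 3).
#' @return An object of class `mrr_dataset`: a list with elements `records`
#'   (with `occasion` column), `patches` and `calendar`.
#' @export
read_dataset <- function(records_path, patches_path, flight_start = NULL,
                         threshold_days = 15L, max_interval = 3L) {
  rec <- read_records(records_path)
  if (is.null(flight_start)) flight_start <- min(rec$date)
  patches <- read_patches(patches_path, flight_start = flight_start,
                          threshold_days = threshold_days)
  mrr_dataset(rec, patches, max_interval = max_interval)
}

#' Construct an `mrr_dataset` from in-memory pieces
#'
#' @param records Capture-record data frame with the columns of
#'   [read_records()].
#' @param patches An `mrr_patches` data frame.
#' @param calendar Optional `mrr_calendar`; inferred from record dates when
#'   omitted.
#' @param max_interval Calendar gap bound when the calendar is inferred.
#' @return An `mrr_dataset`.
#' @export
mrr_dataset <- function(records, patches, calendar = NULL, max_interval = 3L) {
  unknown <- setdiff(unique(records$patch_id), patches$patch_id)
  if (length(unknown))
    stop("records refer to unknown patch_id(s): ", paste(unknown, collapse = ", "))
  if (is.null(calendar)) calendar <- occasion_calendar(records$date, max_interval)
  records$occasion <- match(as.Date(records$date), calendar$dates) - 1L
  if (anyNA(records$occasion))
    stop("record date not present in the occasion calendar")
  key <- paste(records$individual_id, records$occasion)
  if (anyDuplicated(key))
    stop("duplicate (individual_id, occasion) capture: ",
         key[anyDuplicated(key)])
  records <- records[order(records$individual_id, records$occasion), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, patches = patches, calendar = calendar),
            class = "mrr_dataset")
}

#' @export
print.mrr_dataset <- function(x, ...) {
  cat("MRR dataset:", length(unique(x$records$individual_id)), "individuals,",
      nrow(x$records), "captures,", nrow(x$patches), "patches,",
      length(x$calendar$dates), "occasions\n")
  cat("Regimes:", paste(names(table(x$patches$regime)),
                        table(x$patches$regime), collapse = ", "), "\n")
  invisible(x)
}

#' Write an MRR dataset back to its text formats
#'
#' @param dataset An `mrr_dataset`.
#' @param records_path,patches_path Output paths (CSV and GeoJSON).
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, records_path, patches_path) {
  rec <- dataset$records[, RECORD_COLS]
  rec$date <- format(rec$date)
  rec$lon <- format_shortest(rec$lon)
  rec$lat <- format_shortest(rec$lat)
  utils::write.csv(rec, records_path, row.names = FALSE, quote = FALSE)
  write_patches(dataset$patches, patches_path)
  invisible(c(records_path, patches_path))
}

#' Validate an MRR dataset
#'
#' Report-only checks beyond the structural invariants: capture coordinates
#' farther than `tolerance_m` outside their declared patch polygon (GPS
#' drift), calendar gaps exceeding the configured maximum, and individuals
#' whose recorded sex changes between captures.
#'
#' @param dataset An `mrr_dataset`.
#' @param tolerance_m Permitted distance (m) outside the declared polygon
#'   before a record is flagged (default 25, on the order of GPS error).
#' @return A list of class `mrr_validation` with data frames
#'   `outside_patch`, `calendar_gaps`, `sex_conflicts` and the logical
#'   `clean`.
#' @export
validate_dataset <- function(dataset, tolerance_m = 25) {
  rec <- dataset$records
  patches <- dataset$patches
  dist_out <- numeric(nrow(rec))
  for (pid in unique(rec$patch_id)) {
    idx <- which(rec$patch_id == pid)
    ring <- patches$ring[[match(pid, patches$patch_id)]]
    dist_out[idx] <- distance_to_patch_m(cbind(rec$lon[idx], rec$lat[idx]), ring)
  }
  outside <- rec[dist_out > tolerance_m, , drop = FALSE]
  outside$distance_m <- dist_out[dist_out > tolerance_m]

  l <- dataset$calendar$intervals
  bad <- which(l > dataset$calendar$max_interval)
  gaps <- data.frame(after_occasion = bad - 1L, interval_days = l[bad])

  sex_tab <- tapply(rec$sex, rec$individual_id, function(s) length(unique(s)))
  conflicted <- names(sex_tab)[sex_tab > 1L]
  sex_conflicts <- rec[rec$individual_id %in% conflicted, , drop = FALSE]

  structure(list(outside_patch = outside, calendar_gaps = gaps,
                 sex_conflicts = sex_conflicts,
                 clean = nrow(outside) == 0L && nrow(gaps) == 0L &&
                   nrow(sex_conflicts) == 0L),
            class = "mrr_validation")
}

#' @export
print.mrr_validation <- function(x, ...) {
  if (x$clean) cat("Dataset validation: clean\n")
  else cat("Dataset validation:", nrow(x$outside_patch), "record(s) outside patch,",
           nrow(x$calendar_gaps), "oversized calendar gap(s),",
           length(unique(x$sex_conflicts$individual_id)), "sex conflict(s)\n")
  invisible(x)
}
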