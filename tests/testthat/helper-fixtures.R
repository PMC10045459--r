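# Fixture builders shared across the suite.  Everything is generated in code;
# no data files.

M_PER_DEG_LAT <- 111194.93

# metres per degree of longitude at a latitude, measured on the ellipsoid
m_per_deg_lon <- function(lat, lon = 19.8) {
  geodesic_distance_m(c(lon - 0.05, lat), c(lon + 0.05, lat)) / 0.1
}

# Square patch ring with south-west corner at (lon, lat) and side side_m.
square_ring <- function(lon, lat, side_m) {
  dlat <- side_m / M_PER_DEG_LAT
  dlon <- side_m / m_per_deg_lon(lat, lon)
  cbind(c(lon, lon + dlon, lon + dlon, lon, lon),
        c(lat, lat, lat + dlat, lat + dlat, lat))
}

# Minimal mrr_patches data frame from a list of
# list(patch_id, locality, regime, ring).
toy_patches <- function(specs) {
  p <- data.frame(
    patch_id = vapply(specs, `[[`, "", "patch_id"),
    locality = vapply(specs, function(s) s$locality %||% "A", ""),
    regime = vapply(specs, function(s) s$regime %||% "unmown", ""),
    mowing_date = as.Date(NA),
    area_m2 = vapply(specs, function(s) polygon_area_m2(s$ring), 0),
    centroid_lon = vapply(specs, function(s) polygon_centroid(s$ring)[1], 0),
    centroid_lat = vapply(specs, function(s) polygon_centroid(s$ring)[2], 0),
    stringsAsFactors = FALSE)
  p$ring <- lapply(specs, `[[`, "ring")
  class(p) <- c("mrr_patches", class(p))
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two 100 m squares, centroids almost exactly 1 km apart (east-west).
two_patch_network <- function() {
  lat <- 46.10
  dlon_1km <- 1000 / m_per_deg_lon(lat)
  toy_patches(list(
    list(patch_id = "P1", locality = "A", regime = "unmown",
         ring = square_ring(19.80, lat, 100)),
    list(patch_id = "P2", locality = "A", regime = "mown",
         ring = square_ring(19.80 + dlon_1km, lat, 100))))
}

# Capture records for a toy dataset; caps is a data frame with columns
# id, day (1-based), sex, patch, and optionally lon/lat.
toy_records <- function(caps, patches, start = as.Date("2014-07-19")) {
  lon <- caps$lon; lat <- caps$lat
  if (is.null(lon)) {
    cen <- patches[match(caps$patch, patches$patch_id), ]
    lon <- cen$centroid_lon; lat <- cen$centroid_lat
  }
  data.frame(individual_id = caps$id, date = start + caps$day - 1L,
             sex = caps$sex, patch_id = caps$patch, lon = lon, lat = lat,
             stringsAsFactors = FALSE)
}

toy_dataset <- function(caps, patches = two_patch_network(), ...) {
  mrr_dataset(toy_records(caps, patches), patches, ...)
}

# Direct CJS history simulator: n individuals all released at occasion 1,
# daily survival phi, capture probability p at each occasion; `intervals`
# gives the day gaps between the K occasions.
sim_histories <- function(n, K, phi, p, intervals = rep(1L, K - 1L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- matrix(0L, n, K)
  ch[, 1L] <- 1L
  alive <- rep(TRUE, n)
  for (j in 2L:K) {
    alive <- alive & (stats::runif(n) < phi^intervals[j - 1L])
    ch[alive & stats::runif(n) < p, j] <- 1L
  }
  ch
}

# Haversine great-circle distance (spherical oracle, independent of the
# package's ellipsoidal implementation); accurate to ~0.5%.
haversine_m <- function(a, b) {
  r <- 6371008.8
  to_rad <- pi / 180
  dlat <- (b[2] - a[2]) * to_rad; dlon <- (b[1] - a[1]) * to_rad
  h <- sin(dlat / 2)^2 + cos(a[2] * to_rad) * cos(b[2] * to_rad) * sin(dlon / 2)^2
  2 * r * asin(sqrt(h))
}

# Small simulation config used across tests (fast: ~1 s per simulate_mrr).
small_sim_config <- function(...) {
  args <- utils::modifyList(list(n_patches = 10L, n_localities = 2L,
                                 n_emerge = 800L, season_days = 25L),
                            list(...))
  do.call(sim_config, args)
}
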